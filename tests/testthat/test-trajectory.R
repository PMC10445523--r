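# Trajectory analysis: centres, radial profiles, core radii, fusion.

test_that("component centres unwrap periodic images", {
  sys <- bead_system(rbind(c(0, 0, 0), c(2, 0, 0)), 1:2, c("A", "A"),
                     c("c", "c"), c("X", "X"), box = c(100, 100, 100))
  expect_equal(component_center(sys, "c"), c(1, 0, 0))

  wrapped <- bead_system(rbind(c(0.5, 1, 1), c(9.5, 1, 1)), 1:2, c("A", "A"),
                         c("c", "c"), c("X", "X"), box = c(10, 10, 10))
  expect_equal(component_center(wrapped, "c"), c(0, 1, 1))

  ball <- uniform_ball_system(4000, 3, center = c(10, 10, 10), seed = 8)
  expect_lt(max(abs(component_center(ball, "core") - c(10, 10, 10))),
            3 * 3 / sqrt(4000) * 2)
  expect_error(component_center(ball, "nope"), "empty component")
})

test_that("radial profiles recover uniform and step densities and conserve", {
  n <- 20000; R <- 5
  ball <- uniform_ball_system(n, R, seed = 3)
  prof <- radial_component_density(ball, "core", n_bins = 200)
  rho <- n / (4 / 3 * pi * R^3)

  # interior bins sit at the true density (counting noise only)
  mid <- prof$mids > 1 & prof$mids < 4
  expect_lt(rel_err(mean(prof$density[mid, "core"]), rho), 0.05)

  # conservation: sum(density x shell volume) = bead count, single frame
  vol <- 4 / 3 * pi * diff(prof$edges^3)
  expect_equal(sum(prof$density[, "core"] * vol), n, tolerance = 1e-6)
  expect_equal(unname(prof$overflow["core"]), 0)

  # step edge localised within one bin width
  bw <- diff(prof$edges[1:2])
  expect_lt(abs(estimate_core_radius(prof, "core") - R), bw)

  expect_error(radial_component_density(ball, "core", r_max = -1), "positive")
})

test_that("core radius estimation needs a plateau and interpolates", {
  ball <- uniform_ball_system(20000, 5, seed = 4)
  prof <- radial_component_density(ball, "core", n_bins = 100)
  expect_lt(abs(estimate_core_radius(prof, "core") - 5), 0.1)

  # all-zero (hollow centre) profiles are rejected
  shell_only <- uniform_ball_system(500, 1, center = c(20, 20, 20),
                                    box = c(40, 40, 40), seed = 5)
  shell_only$pos <- shell_only$pos +
    7 * (shell_only$pos - 20) /
      sqrt(rowSums((shell_only$pos - 20)^2))
  prof2 <- radial_component_density(shell_only, "core", n_bins = 50)
  expect_error(estimate_core_radius(prof2, "core"), "plateau")
})

test_that("profiles are invariant to translation and periodic wrapping", {
  ball <- uniform_ball_system(5000, 3, center = c(2, 10, 10), seed = 6)
  prof <- radial_component_density(ball, "core", n_bins = 50)
  shifted <- wrap_system(translate_system(ball, c(-4.7, 3.3, 8.9)))
  prof2 <- radial_component_density(shifted, "core", n_bins = 50)
  expect_equal(prof2$density, prof$density, tolerance = 1e-9)
})

test_that("built droplets show the head-over-tail radial ordering", {
  d <- mini_droplet(seed = 31)
  g <- chemistry_groups(d)
  prof <- radial_component_density(frame_set(list(d)), "oleosome_core",
                                   groups = g, n_bins = 60, r_max = 5)
  peak <- function(col) prof$mids[which.max(prof$density[, col])]
  # heads peak outside tails, which peak outside the mid-core plateau
  expect_gt(peak("pl_head"), peak("pl_tail"))
  r_core <- estimate_core_radius(prof, "tag_tail")
  expect_gt(peak("pl_tail"), r_core / 2)
  expect_gt(peak("pl_head"), r_core)
})

test_that("fusion detection matches scripted ground truth", {
  sa <- droplet_spec(40, core_radius = 2.2, n_shell = 30,
                     shell_density = 0.7)
  sb <- droplet_spec(40, core_radius = 2.2)
  tr <- gen_two_droplet_trajectory(sa, sb, n_frames = 45, jitter_sd = 0.01,
                                   fuse_at = 30, gap = 2,
                                   core_template = mini_core_template(),
                                   shell_template = mini_shell_template(),
                                   seed = 5)
  rec <- detect_fusion(tr, cutoff = 0.6, persistence = 3)
  expect_true(rec$fused)
  expect_gte(rec$first_contact, 30)
  expect_lte(rec$first_contact, 33)

  # monotone in the cutoff
  for (cutoff in c(0.8, 1.2)) {
    expect_true(detect_fusion(tr, cutoff = cutoff, persistence = 3)$fused)
  }

  # a never-fusing run stays unfused at a cutoff below the gap
  tr0 <- gen_two_droplet_trajectory(sa, sb, n_frames = 20, jitter_sd = 0.01,
                                    gap = 2,
                                    core_template = mini_core_template(),
                                    shell_template = mini_shell_template(),
                                    seed = 5)
  expect_false(detect_fusion(tr0, cutoff = 0.6, persistence = 3)$fused)
})

test_that("persistence filters single-frame grazing contacts", {
  # two single-bead molecules: in contact only at frame 2
  mk <- function(x) bead_system(rbind(c(1, 1, 1), c(x, 1, 1)), 1:2,
                                c("A", "A"), c("a", "b"), c("X", "Y"),
                                box = c(10, 10, 10))
  frames <- frame_set(list(mk(3), mk(1.3), mk(3), mk(3)))
  r1 <- detect_fusion(frames, "a", "b", cutoff = 0.5, persistence = 1)
  expect_true(r1$fused)
  expect_equal(r1$first_contact, 2L)
  r3 <- detect_fusion(frames, "a", "b", cutoff = 0.5, persistence = 3)
  expect_false(r3$fused)
})

test_that("shell density time series tracks the scripted fusion", {
  sa <- droplet_spec(40, core_radius = 2.2, n_shell = 30,
                     shell_density = 0.7)
  sb <- droplet_spec(40, core_radius = 2.2)

  # static droplet: constant series at the built density
  tr0 <- gen_two_droplet_trajectory(sa, sb, n_frames = 5, jitter_sd = 0,
                                    gap = 2,
                                    core_template = mini_core_template(),
                                    shell_template = mini_shell_template(),
                                    seed = 9)
  s0 <- shell_density_timeseries(tr0, n_bins = 40)
  expect_lt(diff(range(s0)), 1e-9)
  expect_lt(rel_err(s0[1], 0.7), 0.05)

  # scripted fusion doubling the core volume: density drops by ~2^(2/3)
  tr <- gen_two_droplet_trajectory(sa, sb, n_frames = 45, jitter_sd = 0.01,
                                   fuse_at = 25, gap = 2,
                                   core_template = mini_core_template(),
                                   shell_template = mini_shell_template(),
                                   seed = 9)
  s <- shell_density_timeseries(tr, n_bins = 40)
  expect_lt(rel_err(s[1] / s[45], 2^(2 / 3)), 0.05)
})

test_that("jitter-free generated frames are identical to frame 0", {
  sa <- droplet_spec(20, core_radius = 1.8, n_shell = 16,
                     shell_density = 0.6)
  sb <- droplet_spec(20, core_radius = 1.8)
  tr <- gen_two_droplet_trajectory(sa, sb, n_frames = 5, jitter_sd = 0,
                                   gap = 1.5,
                                   core_template = mini_core_template(),
                                   shell_template = mini_shell_template(),
                                   seed = 2)
  for (f in 2:5) {
    expect_identical(tr$frames[[f]]$pos, tr$frames[[1]]$pos)
  }
})
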