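# Coarse-grained droplet construction: packing, shells, boxes, hydration.

test_that("core packing is deterministic, in-sphere and contact-safe", {
  tpl <- mini_core_template()
  a <- build_core(tpl, 30, radius = 2.0, seed = 3)
  b <- build_core(tpl, 30, radius = 2.0, seed = 3)
  expect_identical(a$pos, b$pos)              # bitwise determinism
  c2 <- build_core(tpl, 30, radius = 2.0, seed = 4)
  expect_false(identical(a$pos, c2$pos))

  # single molecule stays within radius + one bond of the centre
  one <- build_core(tpl, 1, radius = 1.0, seed = 1)
  expect_true(all(sqrt(rowSums(one$pos^2)) <= 1.0 + tpl$bond_length + 1e-9))

  # all beads inside the sphere allowance; inter-molecular contacts respected
  r <- sqrt(rowSums(a$pos^2))
  expect_true(all(r <= 2.0 + tpl$bond_length + 1e-9))
  expect_gte(min_intermolecular_distance(a, 1.0, method = "brute"),
             tpl$contact_distance)

  # hopeless packing is rejected up front with a diagnostic
  expect_error(build_core(tpl, 5000, radius = 1.0, seed = 1), "packing")
})

test_that("cell-list and brute-force contact checkers agree", {
  for (seed in c(2, 9)) {
    sys <- mini_droplet(seed)
    cell <- min_intermolecular_distance(sys, 1.0, method = "cell")
    brute <- min_intermolecular_distance(sys, 1.0, method = "brute")
    expect_equal(cell, brute, tolerance = 1e-12)
  }
})

test_that("shells are quasi-uniform, oriented and at the declared density", {
  tpl <- template_dppc()
  # the three study shell loadings at their density-implied radii
  cases <- list(c(1200, 0.7), c(1600, 0.9), c(2000, 1.1))
  caps <- numeric(length(cases))
  for (i in seq_along(cases)) {
    n <- cases[[i]][1]; rho <- cases[[i]][2]
    R <- sqrt(n / (4 * pi * rho))
    sh <- build_shell(NULL, tpl, n, radius = R, seed = 5,
                      center = c(0, 0, 0))
    dens <- measure_shell_density(sh, "oleosome_shell")
    expect_lt(rel_err(dens, rho), 0.02)

    # orientation: every molecule's head lies outside all its tails
    rad <- sqrt(rowSums(sh$pos^2))
    by_mol <- split(seq_len(n_beads(sh)), sh$molid)
    head_r <- vapply(by_mol, function(ix) min(rad[ix[1:2]]), 0)
    tail_r <- vapply(by_mol, function(ix) max(rad[ix[-(1:2)]]), 0)
    expect_true(all(head_r > tail_r))

    # largest empty angular cap via fixed probe directions
    heads <- sh$pos[sh$atom == "NC3", ] / rad[sh$atom == "NC3"]
    k <- seq_len(500) - 0.5
    pz <- 1 - 2 * k / 500
    pr <- sqrt(pmax(0, 1 - pz^2))
    golden <- pi * (3 - sqrt(5))
    probes <- cbind(pr * cos(golden * k), pr * sin(golden * k), pz)
    cosang <- probes %*% t(heads)
    caps[i] <- max(acos(pmin(1, apply(cosang, 1, max))))
  }
  # coverage tightens monotonically over the 1200/1600/2000 series
  expect_true(all(diff(caps) < 0))

  # no-shell and over-dense requests
  expect_null(build_shell(NULL, tpl, 0, radius = 10, seed = 1))
  expect_error(build_shell(NULL, tpl, 40000, radius = 5, seed = 1,
                           center = c(0, 0, 0)),
               "contact")
})

test_that("declared and measured densities agree on full droplets", {
  d <- mini_droplet(seed = 21, n_shell = 60, density = 0.9)
  expect_lt(rel_err(measure_shell_density(d), attr(d, "declared_density")),
            0.02)
  # doubling the shell count at the same radius doubles the density
  r <- attr(d, "shell_radius")
  d2 <- build_droplet(mini_core_template(), 40, radius = 2.2,
                      shell_template = mini_shell_template(), n_shell = 120,
                      shell_radius = r, seed = 21)
  expect_lt(rel_err(measure_shell_density(d2),
                    2 * measure_shell_density(d)), 0.03)
})

test_that("two-droplet composition honours gap, box and component tags", {
  a <- mini_droplet(7)
  b <- build_droplet(mini_core_template(), 40, radius = 2.2, seed = 8,
                     core_component = "free_tag")
  sys <- compose_two_droplet_box(a, b, gap = 0.47, box = c(16, 11, 11))

  # surface-to-surface distance along x equals the gap within 0.01 nm
  xa <- max(sys$pos[sys$component != "free_tag", 1])
  xb <- min(sys$pos[sys$component == "free_tag", 1])
  expect_equal(xb - xa, 0.47, tolerance = 0.01)

  # pair centred in the box, tags preserved, positions inside the box
  expect_setequal(unique(sys$component),
                  c("oleosome_core", "oleosome_shell", "free_tag"))
  expect_true(all(sys$pos >= 0 & sys$pos <= rep(c(16, 11, 11),
                                                each = n_beads(sys))))
  ctr <- attr(sys, "centers")
  expect_equal(mean(range(sys$pos[, 1])), 8, tolerance = 0.5)
  expect_equal(ctr[, 2], c(5.5, 5.5), ignore_attr = TRUE)

  # gap 0: surfaces touch
  sys0 <- compose_two_droplet_box(a, b, gap = 0, box = c(16, 11, 11))
  xa0 <- max(sys0$pos[sys0$component != "free_tag", 1])
  xb0 <- min(sys0$pos[sys0$component == "free_tag", 1])
  expect_equal(xb0 - xa0, 0, tolerance = 1e-9)

  # droplets that cannot fit are rejected
  expect_error(compose_two_droplet_box(a, b, gap = 0.47, box = c(9, 11, 11)),
               "boundary")
})

test_that("hydration fills the accessible volume at the target density", {
  # empty box: count equals the lattice rounding of density x volume
  empty <- bead_system(matrix(numeric(), 0, 3), integer(), character(),
                       character(), character(), box = c(10, 10, 10))
  h <- hydrate(empty, density = 8.3, seed = 2)
  nvec <- pmax(1, round(10 * 8.3^(1 / 3)))
  expect_equal(attr(h, "water_count"), prod(rep(nvec, 3)))
  expect_lt(rel_err(attr(h, "water_count"), 8.3 * 1000), 0.05)

  # density 0 adds nothing
  h0 <- hydrate(mini_pair(), density = 0)
  expect_equal(attr(h0, "water_count"), 0L)

  # solvated bare-droplet pair: water respects the exclusion distance and
  # the box, and every remaining inter-molecular contact is safe
  sys <- hydrate(mini_bare_pair(), density = 8.3, exclusion = 0.4, seed = 3)
  expect_gt(attr(sys, "water_count"), 0)
  rep <- contact_report(sys, 0.40)
  expect_equal(rep$n_violations, 0)
})

test_that("build_droplet output is reproducible end to end", {
  expect_identical(mini_droplet(5)$pos, mini_droplet(5)$pos)
  d <- mini_droplet(5)
  expect_equal(sort(unique(d$component)),
               c("oleosome_core", "oleosome_shell"))
  expect_equal(length(unique(d$molid)), 40 + 63)
})
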