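# Miniature molecule templates and droplet fixtures: full-size triolein/DPPC
# droplets are exercised in the acceptance tests; everything else runs on
# 4-bead species so fixtures build in milliseconds.

mini_core_template <- function() {
  molecule_template("MTAG", "core", c("GL1", "C1A", "C2A", "C3A"),
                    molecule_volume = 0.6)
}

mini_shell_template <- function() {
  molecule_template("MPL", "shell", c("NC3", "PO4", "C1A", "C2A"),
                    head_beads = c(1L, 2L))
}

mini_component_map <- function() {
  c(oleosome_core = "MTAG", oleosome_shell = "MPL", free_tag = "TRIF",
    water = "W")
}

# 63 shell molecules at 0.7 nm-2 put the head sphere (R = 2.68) just outside
# the 2.2 nm core, mirroring the full-size droplet geometry
mini_droplet <- function(seed = 7, n_core = 40, n_shell = 63,
                         density = 0.7) {
  build_droplet(mini_core_template(), n_core, radius = 2.2,
                shell_template = mini_shell_template(), n_shell = n_shell,
                shell_density = density, seed = seed)
}

mini_bare_pair <- function(seed = 7, gap = 2, box = c(16, 11, 11)) {
  a <- build_droplet(mini_core_template(), 40, radius = 2.2, seed = seed)
  b <- build_droplet(mini_core_template(), 40, radius = 2.2,
                     seed = seed + 1, core_component = "free_tag")
  compose_two_droplet_box(a, b, gap = gap, box = box)
}

mini_pair <- function(seed = 7, gap = 2, box = c(16, 11, 11)) {
  a <- mini_droplet(seed)
  b <- build_droplet(mini_core_template(), 40, radius = 2.2,
                     seed = seed + 1, core_component = "free_tag")
  compose_two_droplet_box(a, b, gap = gap, box = box)
}

# uniform-density ball of single-bead molecules: an ideal step profile
uniform_ball_system <- function(n, radius, center = c(10, 10, 10),
                                box = c(20, 20, 20), seed = 1,
                                component = "core") {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u * u))
  p <- sweep(u * radius * runif(n)^(1 / 3), 2, center, "+")
  bead_system(p, molid = seq_len(n), atom = rep("C1A", n),
              component = rep(component, n), template = rep("X", n),
              box = box)
}

rel_err <- function(x, y) abs(x - y) / abs(y)
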