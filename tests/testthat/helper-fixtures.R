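# Shared fixture builders (all generated in code; nothing on disk).

# noiseless arctangent edge on a fine grid, Ca K-edge geometry
ca_edge_fixture <- function(step = 1, slope = 0.002, offset = 0.1,
                            gamma = 0.5, de = 0.5) {
  grid <- seq(4000, 4250, by = de)
  make_endmember_spectrum(
    edge_model(e0 = 4043.39, step_height = step, pre_slope = slope,
               pre_offset = offset, gamma = gamma),
    peaks = list(peak_model(4049, 1.2, 0.8)),
    grid = grid, edge_label = "Ca K")
}

# small common grid + two distinct normalized-looking standards for LCF
lcf_pair_fixture <- function(n = 60) {
  grid <- seq(283, 295, length.out = n)
  A <- spectrum(grid, 0.5 + 0.5 * tanh((grid - 286) / 0.8) +
                  0.6 * exp(-(grid - 285)^2 / 0.3), "C K")
  B <- spectrum(grid, 0.5 + 0.5 * tanh((grid - 289) / 1.2) +
                  0.7 * exp(-(grid - 289.5)^2 / 0.5), "C K")
  list(grid = grid, A = A, B = B)
}

# random multi-standard pool on a common grid (smooth, independent shapes)
random_pool_fixture <- function(k, n = 80, seed = 1) {
  set.seed(seed)
  grid <- seq(280, 300, length.out = n)
  pool <- lapply(seq_len(k), function(i) {
    centers <- runif(3, 283, 297)
    amps <- runif(3, 0.3, 1)
    y <- 0.5 + 0.5 * tanh((grid - runif(1, 284, 292)) / runif(1, 0.5, 2))
    for (j in 1:3) y <- y + amps[j] * exp(-(grid - centers[j])^2 / 0.4)
    spectrum(grid, y, "C K")
  })
  names(pool) <- paste0("std", seq_len(k))
  pool
}

# two-class scene + noiseless stack for round-trip style tests
small_stack_fixture <- function(seed = 1, noise = "none", shape = c(48, 48),
                                n_particles = 25,
                                mix = c(CaC = 0.5, FeC = 0.5)) {
  scene <- make_scene(shape, n_particles, mix, seed = seed)
  list(scene = scene,
       stack = render_stack(scene, noise = noise, seed = seed + 100))
}
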