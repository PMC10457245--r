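test_that("endmember forward model obeys the arctangent-limit and peak placement", {
  grid <- seq(280, 300, 0.1)
  edge_only <- make_endmember_spectrum(
    edge_model(285, step_height = 1, pre_offset = 0.2, gamma = 0.5),
    grid = grid)
  # far above the edge the intensity approaches baseline + step
  expect_equal(tail(edge_only$intensities, 1), 1.2, tolerance = 0.02)
  # Ca L endmember shows four local maxima at the assigned peak energies
  lib <- endmember_library()
  ca <- lib$Ca
  y <- ca$intensities; e <- ca$energies
  loc_max <- e[which(diff(sign(diff(y))) == -2) + 1]
  for (pk in c(348.1, 349.2, 351.5, 352.2)) {
    expect_true(min(abs(loc_max - pk)) < 0.25)
  }
  # plant-like vs microbial-like C signatures differ where expected
  at <- function(s, e0) spectrum_at(s, e0)
  expect_gt(at(lib$C_plant, 285.0), at(lib$C_microbial, 285.0))
  expect_gt(at(lib$C_microbial, 289.5), at(lib$C_plant, 289.5))
  expect_error(make_endmember_spectrum(edge_model(285), grid = c(1, 1, 2)),
               "invalid-grid")
})

test_that("scene generation is deterministic and mass-balanced", {
  mix <- c(CaC = 0.4, FeC = 0.4, background = 0.2)
  s1 <- make_scene(c(40, 40), 30, mix, seed = 11)
  s2 <- make_scene(c(40, 40), 30, mix, seed = 11)
  expect_identical(s1$label_map, s2$label_map)
  expect_identical(s1$thickness_map, s2$thickness_map)
  # mass fractions sum to 1 on particles, 0 on background
  W <- camap:::scene_weights(s1)
  on <- as.vector(s1$label_map > 0)
  expect_true(all(abs(rowSums(W[on, , drop = FALSE]) - 1) < 1e-12))
  expect_true(all(rowSums(W[!on, , drop = FALSE]) == 0))
  expect_true(all(s1$thickness_map >= 0))
  expect_error(make_scene(c(20, 20), 5, c(CaC = 0.6, FeC = 0.3)),
               "invalid-spec")
})

test_that("degenerate C-only mix gives no Ca or Fe mass anywhere", {
  s <- make_scene(c(30, 30), 3, c(Conly = 1.0), seed = 2)
  W <- camap:::scene_weights(s)
  expect_true(all(W[, c("Ca", "Fe")] == 0))
  expect_gt(sum(s$label_map > 0), 0)
})

test_that("realized class counts respect binomial sampling of the mix", {
  s <- make_scene(c(200, 200), 200, c(CaC = 0.5, FeC = 0.5), seed = 1,
                  axis_range = c(2, 4))
  n_cac <- sum(s$particle_classes == "CaC")
  lim <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(n_cac, lim[1]); expect_lte(n_cac, lim[2])
})

test_that("rendered stacks satisfy Beer-Lambert exactly without noise", {
  fx <- small_stack_fixture(seed = 4)
  od <- to_optical_density(fx$stack)
  # background pixels transmit I0 at every energy
  bg <- which(fx$scene$label_map == 0)[1]
  rc <- arrayInd(bg, dim(fx$scene$label_map))
  expect_equal(fx$stack$counts[, rc[1], rc[2]],
               rep(2000, length(fx$stack$energies)))
  # round trip: OD equals the forward absorbance field everywhere
  W <- camap:::scene_weights(fx$scene)
  mu <- vapply(endmember_library()[colnames(W)], spectrum_at,
               numeric(length(fx$stack$energies)),
               energies = fx$stack$energies)
  A <- as.vector(fx$scene$thickness_map) * (W %*% t(mu))
  for (j in seq_along(fx$stack$energies)) {
    expect_lt(max(abs(od$od[j, , ] -
                        matrix(A[, j], nrow(fx$scene$label_map)))), 1e-10)
  }
})

test_that("a unit-thickness pixel with mu = 0.7 yields OD 0.7", {
  grid <- seq(280, 300, 1)
  em <- list(X = spectrum(grid, rep(0.7, length(grid))))
  scene <- make_scene(c(5, 5), 0, c(Conly = 1), seed = 1)
  scene$label_map[3, 3] <- 1L
  scene$thickness_map[3, 3] <- 1
  scene$class_table <- matrix(1, 1, 1, dimnames = list("CaC", "X"))
  scene$classes <- "CaC"
  st <- render_stack(scene, em, energies = grid, noise = "none")
  od <- to_optical_density(st)
  expect_equal(od$od[5, 3, 3], 0.7, tolerance = 1e-12)
})

test_that("Poisson noise on background pixels has the counting variance", {
  scene <- make_scene(c(40, 40), 0, c(background = 1), seed = 1)
  i0 <- 1e4
  st <- render_stack(scene, energies = c(280, 290), i0_level = i0,
                     noise = "poisson", seed = 42)
  x <- as.vector(st$counts[1, , ]) / i0       # 1600 background pixels
  v <- var(x)
  # var(I/i0) = 1/i0 for Poisson(i0); 3-sigma band of the sample variance
  se <- sqrt(2 / (length(x) - 1)) / i0
  expect_lt(abs(v - 1 / i0), 3 * se)
})

test_that("bulk tables hit their target SOC-Ca correlation", {
  # noiseless line: R2 = 1 exactly
  t1 <- make_bulk_table(bulk_table_spec(n_samples = 50, target_r2 = 1))
  expect_equal(attr(t1, "realized_r2"), 1.0, tolerance = 1e-12)
  # independence target: slope inside the null 95% interval
  t0 <- make_bulk_table(bulk_table_spec(n_samples = 150, target_r2 = 0,
                                        seed = 5))
  fit <- summary(lm(Ca_exch ~ SOC_pct, data = t0))
  expect_gt(fit$coefficients[2, 4], 0.05)
  # the study regime: target 0.69, n = 200, realized within +/- 0.10
  t69 <- make_bulk_table(bulk_table_spec(n_samples = 200, target_r2 = 0.69,
                                         seed = 7))
  expect_gt(attr(t69, "realized_r2"), 0.59)
  expect_lt(attr(t69, "realized_r2"), 0.79)
  expect_true(all(t69$Ca_exch >= 0))
  expect_true(all(c("sample_id", "depth_cm", "pH", "SOC_pct", "Ca_exch",
                    "Mg_exch", "K_exch", "Na_exch", "Al_exch") %in%
                    names(t69)))
  # unreachable target warns and falls back to the stated noise floor
  expect_warning(
    make_bulk_table(bulk_table_spec(n_samples = 100, target_r2 = 0.95,
                                    noise_sd = 10)),
    "unreachable")
})

test_that("thickness exceedance probability matches simulation", {
  dist <- thickness_dist(meanlog = log(0.8), sdlog = 0.5, max = Inf)
  p <- thickness_exceedance_prob(dist, od_per_unit = 1.1, cutoff = 1)
  set.seed(9)
  t_dr <- rlnorm(2e5, dist$meanlog, dist$sdlog)
  expect_equal(mean(t_dr * 1.1 > 1), p, tolerance = 0.01)
  # clipping below the threshold forces exceedance to zero
  d2 <- thickness_dist(meanlog = log(0.8), sdlog = 0.5, max = 0.5)
  expect_equal(thickness_exceedance_prob(d2, 1.1), 0)
})
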