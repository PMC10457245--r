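test_that("first_derivative reproduces closed forms", {
  e <- seq(0, 10, 0.5)
  expect_equal(first_derivative(spectrum(e, 2 * e + 1))$intensities,
               rep(2, length(e)))
  # symmetric Gaussian: derivative vanishes at the centre point
  e <- seq(-5, 5, 0.25)
  d <- first_derivative(spectrum(e + 290, exp(-e^2 / 2)))
  expect_equal(d$intensities[e == 0], 0)
  expect_error(first_derivative(spectrum(1:2, 1:2)), "size error")
})

test_that("arctangent edge derivative height matches the analytic value", {
  gamma <- 0.5; step <- 1
  s <- make_endmember_spectrum(
    edge_model(4043.39, step_height = step, gamma = gamma),
    grid = seq(4030, 4060, 0.05))
  d <- first_derivative(s)
  analytic <- step / (pi * gamma)
  expect_lt(abs(max(d$intensities) - analytic) / analytic, 0.02)
  expect_equal(d$energies[which.max(d$intensities)], 4043.39,
               tolerance = 0.05)
})

test_that("energy calibration is a rigid translation to the reference", {
  s <- ca_edge_fixture()
  cal <- calibrate_energy(s, 4043.89)
  # intensities untouched; spacing preserved
  expect_identical(cal$intensities, s$intensities)
  expect_equal(diff(cal$energies), diff(s$energies))
  # derivative max of a noiseless arctangent sits at e0: shift = 4043.89 - 4043.39
  expect_equal(cal$provenance$calibration_shift_eV, 0.5, tolerance = 0.05)
  # already-calibrated spectrum: shift ~ 0
  cal2 <- calibrate_energy(cal, 4043.89)
  expect_equal(cal2$provenance$calibration_shift_eV, 0, tolerance = 1e-6)
  expect_equal(cal2$energies, cal$energies, tolerance = 1e-6)
})

test_that("tied derivative maxima raise an ambiguity error naming the energies", {
  # two separated rises of equal steepness -> tied derivative maxima
  y <- c(0, 1, 2, 2, 3, 4, 4)
  s <- spectrum(1:7, y)
  expect_error(calibrate_energy(s, 10), "ambiguity.*2.*5")
})

test_that("merge_replicates averages after interpolation onto a common grid", {
  s <- ca_edge_fixture()
  expect_equal(merge_replicates(list(s, s, s))$intensities, s$intensities)
  s3 <- spectrum(s$energies, 3 * s$intensities)
  expect_equal(merge_replicates(list(s, s3))$intensities, 2 * s$intensities)
  # shifted grids: values match an independent interpolation oracle
  sh <- spectrum(s$energies + 0.2, s$intensities)
  m <- merge_replicates(list(s, sh), grid = "first")
  oracle <- (spectrum_at(s, m$energies) + spectrum_at(sh, m$energies)) / 2
  expect_equal(m$intensities, oracle, tolerance = 1e-12)
  # permutation invariance
  m2 <- merge_replicates(list(sh, s), grid = m$energies)
  expect_equal(m2$intensities, m$intensities, tolerance = 1e-12)
  expect_identical(m$provenance$n_replicates, 2L)
  # disjoint ranges are a coverage error
  far <- spectrum(seq(5000, 5010), rep(1, 11))
  expect_error(merge_replicates(list(s, far)), "coverage")
})

test_that("normalization matches an independently coded least-squares oracle", {
  p <- norm_preset("Ca-K-PtReyes")
  s <- ca_edge_fixture(step = 2.3, slope = 0.004, offset = 0.7)
  out <- normalize_xanes(s, p)
  # oracle: explicit normal-equations solve, coded independently
  e <- s$energies; y <- s$intensities
  ipre <- e >= p$pre_lo & e <= p$pre_hi
  X <- cbind(1, e[ipre] - p$e0)
  beta <- solve(t(X) %*% X, t(X) %*% y[ipre])
  y1 <- y - (beta[1] + beta[2] * (e - p$e0))
  ipost <- e >= p$post_lo & e <= p$post_hi
  Xp <- cbind(1, e[ipost] - p$e0, (e[ipost] - p$e0)^2)
  bp <- solve(t(Xp) %*% Xp, t(Xp) %*% y1[ipost])
  expect_equal(out$intensities, y1 / bp[1], tolerance = 1e-9)
  expect_equal(out$provenance$pre_edge_slope, beta[2], tolerance = 1e-9)
  expect_equal(out$provenance$edge_step, bp[1], tolerance = 1e-9)
})

test_that("normalization is scale invariant and idempotent on normalized input", {
  p <- norm_preset("Ca-K-PtReyes")
  s <- ca_edge_fixture()
  ref <- normalize_xanes(s, p)
  for (c_ in c(0.1, 5, 10)) {
    sc <- spectrum(s$energies, c_ * s$intensities, s$edge_label)
    expect_lt(max(abs(normalize_xanes(sc, p)$intensities - ref$intensities)),
              1e-10)
  }
  again <- normalize_xanes(ref, p)
  expect_lt(max(abs(again$intensities - ref$intensities)), 1e-10)
})

test_that("normalized edge step at E0 is exactly the target by construction", {
  p <- norm_preset("Ca-K-PtReyes")
  out <- normalize_xanes(ca_edge_fixture(step = 1.7), p)
  e <- out$energies; y <- out$intensities
  ipost <- e >= p$post_lo & e <= p$post_hi
  Xp <- cbind(1, e[ipost] - p$e0, (e[ipost] - p$e0)^2)
  bp <- solve(t(Xp) %*% Xp, t(Xp) %*% y[ipost])
  expect_equal(unname(bp[1]), 1.0, tolerance = 1e-12)
})

test_that("normalization error contracts: windows and degenerate edges", {
  p <- norm_preset("Ca-K-PtReyes")
  short <- spectrum(seq(4040, 4050, 0.5), rnorm(21))
  expect_error(normalize_xanes(short, p), "window error")
  # negative step -> non-positive post-edge polynomial at E0
  neg <- ca_edge_fixture(step = -0, offset = 0)
  neg$intensities <- -ca_edge_fixture(step = 1, offset = 0,
                                      slope = 0)$intensities
  expect_error(normalize_xanes(neg, p), "degenerate-edge")
  # >= 10% truncation of a window warns
  cut <- ca_edge_fixture()
  cut_s <- spectrum(cut$energies[cut$energies <= 4200],
                    cut$intensities[cut$energies <= 4200])
  expect_warning(normalize_xanes(cut_s, p), "truncated")
})
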