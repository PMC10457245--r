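test_that("active-set NNLS agrees with pracma::lsqnonneg on random problems", {
  skip_if_not_installed("pracma")
  set.seed(17)
  for (i in 1:20) {
    A <- matrix(runif(40 * 4), 40)
    b <- runif(40)
    ours <- nnls_solve(A, b)
    ref <- pracma::lsqnonneg(A, b)
    expect_equal(ours$x, ref$x, tolerance = 1e-8)
    expect_equal(ours$rss, ref$resid.norm, tolerance = 1e-8)
  }
})

test_that("fit statistics implement the R-factor and reduced chi-squared", {
  s <- fit_statistics(c(1, 2, 3), c(1, 2, 2), p = 1)
  expect_equal(s$r_factor, 1 / 14)
  expect_equal(s$reduced_chi2, 1 / 2)
  expect_equal(fit_statistics(1:5, 1:5, 2), list(r_factor = 0,
                                                 reduced_chi2 = 0))
  set.seed(2)
  for (i in 1:10) {
    y <- rnorm(30); yh <- rnorm(30); p <- sample(1:5, 1)
    expect_equal(fit_statistics(y, yh, p)$r_factor,
                 sum((y - yh)^2) / sum(y^2), tolerance = 1e-14)
    expect_equal(fit_statistics(y, yh, p)$reduced_chi2,
                 sum((y - yh)^2) / (30 - p), tolerance = 1e-14)
  }
  expect_error(fit_statistics(1:3, 1:3, 3), "degrees-of-freedom")
})

test_that("LCF recovers pure and mixed targets exactly when noiseless", {
  fx <- lcf_pair_fixture()
  # target equals standard A: weights 100/0, zero misfit
  f <- lcf_fit(fx$A, list(A = fx$A, B = fx$B))
  expect_equal(unname(f$weights), c(100, 0), tolerance = 1e-8)
  expect_lt(f$r_factor, 1e-20)
  # 30/70 mixture
  mix <- spectrum(fx$grid, 0.3 * fx$A$intensities + 0.7 * fx$B$intensities)
  f2 <- lcf_fit(mix, list(A = fx$A, B = fx$B))
  expect_equal(unname(f2$weights), c(30, 70), tolerance = 1e-6)
  expect_equal(f2$raw_sum, 100, tolerance = 1e-6)
  expect_false(f2$out_of_range)
})

test_that("raw sums below 100% are rescaled to 100% on reporting", {
  fx <- lcf_pair_fixture()
  # raw coefficients 0.297 + 0.693 sum to 0.99: raw_sum 99%
  mix <- spectrum(fx$grid, 0.297 * fx$A$intensities +
                    0.693 * fx$B$intensities)
  f <- lcf_fit(mix, list(A = fx$A, B = fx$B))
  expect_equal(f$raw_sum, 99, tolerance = 1e-6)
  expect_equal(unname(f$weights), c(29.7, 69.3) * (100 / 99),
               tolerance = 1e-6)
  expect_equal(sum(f$weights), 100, tolerance = 1e-9)
})

test_that("LCF invariances: rescaling, zero-weight removal, non-negativity", {
  set.seed(33)
  pool <- random_pool_fixture(4)
  w_true <- c(0.2, 0.5, 0.3, 0)
  grid <- pool[[1]]$energies
  y <- Reduce(`+`, Map(function(s, w) w * s$intensities, pool, w_true))
  target <- spectrum(grid, y)
  f <- lcf_fit(target, pool)
  expect_true(all(f$coefficients >= 0))
  expect_equal(unname(f$weights), 100 * w_true, tolerance = 1e-6)
  # r-factor invariant under common positive rescaling
  f_scaled <- lcf_fit(spectrum(grid, 5 * y),
                      lapply(pool, function(s) spectrum(grid,
                                                        5 * s$intensities)))
  expect_equal(f_scaled$r_factor, f$r_factor, tolerance = 1e-12)
  # removing the zero-weight standard leaves the others unchanged
  f3 <- lcf_fit(target, pool[1:3])
  expect_equal(unname(f3$weights), unname(f$weights[1:3]), tolerance = 1e-9)
})

test_that("exact recovery holds over random noiseless simplex mixtures", {
  set.seed(91)
  pool <- random_pool_fixture(4, seed = 91)
  grid <- pool[[1]]$energies
  for (i in 1:20) {
    w <- rexp(4); w <- w / sum(w)
    y <- Reduce(`+`, Map(function(s, wk) wk * s$intensities, pool, w))
    f <- lcf_fit(spectrum(grid, y), pool)
    expect_equal(unname(f$weights), 100 * w, tolerance = 1e-6)
  }
})

test_that("collinear standards trigger a warning naming the pair", {
  fx <- lcf_pair_fixture()
  twin <- spectrum(fx$A$energies, fx$A$intensities * 2)
  expect_warning(lcf_fit(fx$B, list(A = fx$A, Acopy = twin)),
                 "collinearity.*Acopy")
})

test_that("standard-set search enumerates, ranks and reproduces the winner", {
  set.seed(12)
  pool <- random_pool_fixture(6, seed = 12)
  grid <- pool[[1]]$energies
  target <- spectrum(grid, 0.4 * pool$std2$intensities +
                       0.6 * pool$std5$intensities)
  fits <- search_standard_sets(target, pool, max_components = 3)
  rk <- attr(fits, "ranking")
  expect_equal(nrow(rk), choose(6, 1) + choose(6, 2) + choose(6, 3))
  # top-ranked subset is exactly the generating pair
  expect_identical(rk$subset[1], "std2+std5")
  expect_lt(rk$r_factor[1], 1e-12)
  # winner reproduces a direct lcf_fit bit for bit
  direct <- lcf_fit(target, pool[c("std2", "std5")])
  expect_identical(fits[[1]]$weights, direct$weights)
  expect_identical(fits[[1]]$r_factor, direct$r_factor)
  # single-standard pool returns a single fit
  expect_length(search_standard_sets(target, pool[1], 1), 1)
  expect_error(search_standard_sets(target, list(), 1), "empty-pool")
})

test_that("total-C partition exposes the Ca-C share and flags misfits", {
  fx <- lcf_pair_fixture()
  f <- total_c_partition(fx$B, fe_c = fx$A, ca_c = fx$B)
  expect_equal(f$ca_c_share, 100, tolerance = 1e-6)
  # target orthogonal to both standards: nothing fits, raw sum out of range
  orth <- spectrum(fx$grid, sin(200 * fx$grid))
  f2 <- suppressWarnings(total_c_partition(orth, fx$A, fx$B))
  expect_true(f2$out_of_range)
})

test_that("LCF CSV export writes weights in reporting order", {
  fx <- lcf_pair_fixture()
  f <- lcf_fit(fx$A, list(A = fx$A, B = fx$B))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_lcf_csv(f, path)
  got <- read.csv(path)
  expect_equal(got$A, 100, tolerance = 1e-6)
  expect_true(all(c("raw_sum", "r_factor", "reduced_chi2") %in% names(got)))
})
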