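test_that("optical density matches the per-pixel log-ratio formula", {
  set.seed(8)
  counts <- array(runif(3 * 6 * 5, 100, 2000), dim = c(3, 6, 5))
  st <- image_stack(c(280, 290, 300), counts, i0 = 2000)
  od <- to_optical_density(st)
  for (j in 1:3) for (r in 1:6) for (cc in 1:5) {
    expect_equal(od$od[j, r, cc], -log(counts[j, r, cc] / 2000),
                 tolerance = 1e-12)
  }
  # counts = I0 -> OD 0; counts = I0/e -> OD 1
  c2 <- array(0, dim = c(2, 2, 2))
  c2[1, , ] <- 100
  c2[2, , ] <- 100 * exp(-1)
  st2 <- image_stack(c(280, 290), c2, i0 = 100)
  od2 <- to_optical_density(st2)
  expect_equal(as.vector(od2$od[1, , ]), rep(0, 4), tolerance = 1e-12)
  expect_equal(as.vector(od2$od[2, , ]), rep(1, 4), tolerance = 1e-12)
  expect_error(to_optical_density(image_stack(c(1, 2), counts[1:2, , ],
                                              i0 = -5)), "invalid-I0")
})

test_that("zero-count pixels are flagged invalid, never clamped", {
  counts <- array(100, dim = c(2, 3, 3))
  counts[1, 2, 2] <- 0
  st <- image_stack(c(280, 290), counts, i0 = 100)
  od <- to_optical_density(st)
  expect_true(is.na(od$od[1, 2, 2]))
  expect_true(od$invalid[2, 2])
  expect_false(saturation_mask(od)[2, 2])
})

test_that("I0 can be resolved from a pixel region", {
  counts <- array(500, dim = c(2, 4, 4))
  counts[, 3:4, 3:4] <- 100      # sample region darker than the I0 region
  st <- image_stack(c(280, 290), counts, i0 = list(rows = 1:2, cols = 1:2))
  od <- to_optical_density(st)
  expect_equal(od$od[1, 1, 1], 0, tolerance = 1e-12)
  expect_equal(od$od[1, 3, 3], -log(100 / 500), tolerance = 1e-12)
})

test_that("element maps subtract below-edge from above-edge frames", {
  e <- c(280, 295)
  od_arr <- array(0, dim = c(2, 2, 2))
  od_arr[1, , ] <- 0.3; od_arr[2, , ] <- 0.8
  od <- structure(list(energies = e, od = od_arr,
                       invalid = matrix(FALSE, 2, 2)),
                  class = "camap_od_stack")
  m <- element_map(od, "C", above_e = 295, below_e = 280)
  expect_equal(as.vector(m$values), rep(0.5, 4))
  m0 <- element_map(od, "C", above_e = 295, below_e = 294.9)
  expect_equal(as.vector(m0$values), rep(0, 4))
  expect_error(element_map(od, "C", above_e = 290, below_e = 280),
               "frame-lookup")
})

test_that("saturation mask is strict: OD 1.0 retained, 1.01 removed", {
  od_arr <- array(0.2, dim = c(2, 1, 3))
  od_arr[2, 1, 1] <- 1.0
  od_arr[2, 1, 2] <- 1.01
  od <- structure(list(energies = c(280, 290), od = od_arr,
                       invalid = matrix(FALSE, 1, 3)),
                  class = "camap_od_stack")
  keep <- saturation_mask(od, cutoff = 1.0)
  expect_true(keep[1, 1])
  expect_false(keep[1, 2])
  expect_true(keep[1, 3])
})

test_that("Boolean classes match a brute-force truth table on random maps", {
  set.seed(21)
  for (rep_i in 1:5) {
    d <- c(32, 32)
    cm <- matrix(runif(prod(d), -0.2, 1), d[1])
    cam <- matrix(runif(prod(d), -0.2, 1), d[1])
    fm <- matrix(runif(prod(d), -0.2, 1), d[1])
    sat <- matrix(runif(prod(d)) > 0.1, d[1])
    th <- c(C = 0.3, Ca = 0.5, Fe = 0.4)
    ck <- classify_pixels(cm, cam, fm, thresholds = th, sat = sat)
    bf <- list(C_total = matrix(FALSE, d[1], d[2]),
               CaC_noFe = matrix(FALSE, d[1], d[2]),
               FeC_noCa = matrix(FALSE, d[1], d[2]),
               FeCaC = matrix(FALSE, d[1], d[2]))
    for (px in seq_len(prod(d))) {
      C <- cm[px] > th[["C"]] && sat[px]
      Ca <- cam[px] > th[["Ca"]]; Fe <- fm[px] > th[["Fe"]]
      bf$C_total[px] <- C
      bf$CaC_noFe[px] <- C && Ca && !Fe
      bf$FeC_noCa[px] <- C && Fe && !Ca
      bf$FeCaC[px] <- C && Ca && Fe
    }
    expect_identical(ck$masks, bf)
    # structural invariants
    expect_false(any(ck$masks$CaC_noFe & ck$masks$FeC_noCa))
    for (cl in c("CaC_noFe", "FeC_noCa", "FeCaC")) {
      expect_true(all(!ck$masks[[cl]] | ck$masks$C_total))
    }
  }
})

test_that("single-pixel truth-table cases land in the right class", {
  z <- matrix(0, 1, 1)
  one <- matrix(1, 1, 1)
  th <- c(C = 0.5, Ca = 0.5, Fe = 0.5)
  ck <- classify_pixels(one, one, z, thresholds = th)
  expect_true(ck$masks$CaC_noFe[1, 1])
  expect_false(ck$masks$FeC_noCa[1, 1] || ck$masks$FeCaC[1, 1])
  # everything below threshold -> all masks empty
  ck0 <- classify_pixels(z, z, z, thresholds = th)
  expect_equal(sum(unlist(ck0$pixel_counts)), 0)
  expect_error(classify_pixels(one, matrix(0, 2, 2), z, thresholds = th),
               "shape error")
})

test_that("subset spectra are masked means and recombine by pixel counts", {
  e <- c(280, 290, 300)
  od_arr <- array(rnorm(3 * 4 * 4, 0.5, 0.1), dim = c(3, 4, 4))
  od <- structure(list(energies = e, od = od_arr,
                       invalid = matrix(FALSE, 4, 4)),
                  class = "camap_od_stack")
  # two-pixel mask: intensity is the average of the two pixels
  m2 <- matrix(FALSE, 4, 4); m2[1, 1] <- TRUE; m2[2, 3] <- TRUE
  sp <- subset_spectrum(od, m2)
  expect_equal(sp$intensities,
               (od_arr[, 1, 1] + od_arr[, 2, 3]) / 2, tolerance = 1e-12)
  expect_identical(sp$provenance$n_pixels, 2L)
  # weighted recombination: union mean equals count-weighted subclass means
  ma <- matrix(FALSE, 4, 4); ma[1, ] <- TRUE
  mb <- matrix(FALSE, 4, 4); mb[2:3, 2] <- TRUE
  u <- subset_spectrum(od, ma | mb)
  wa <- sum(ma); wb <- sum(mb)
  rec <- (wa * subset_spectrum(od, ma)$intensities +
            wb * subset_spectrum(od, mb)$intensities) / (wa + wb)
  expect_equal(u$intensities, rec, tolerance = 1e-12)
  expect_error(subset_spectrum(od, matrix(FALSE, 4, 4)), "empty-class")
})

test_that("pixel correlation recovers exact linear relations and nulls", {
  set.seed(5)
  a <- matrix(runif(10000), 100)
  b <- 2 * a + 1
  pc <- pixel_correlation(a, b)
  expect_equal(pc$slope, 2, tolerance = 1e-12)
  expect_equal(pc$intercept, 1, tolerance = 1e-12)
  expect_equal(pc$r2, 1, tolerance = 1e-12)
  # agreement with lm() as an independent oracle on noisy maps
  bn <- b + matrix(rnorm(10000, 0, 0.5), 100)
  pc2 <- pixel_correlation(a, bn)
  fit <- summary(lm(as.vector(bn) ~ as.vector(a)))
  expect_equal(pc2$r2, fit$r.squared, tolerance = 1e-10)
  expect_equal(pc2$adjusted_r2, fit$adj.r.squared, tolerance = 1e-10)
  # independent maps: R2 below 0.01 at n = 1e4
  ind <- matrix(rnorm(10000), 100)
  expect_lt(pixel_correlation(a, ind)$r2, 0.01)
  expect_error(pixel_correlation(matrix(1, 3, 3), matrix(rnorm(9), 3)),
               "undefined-slope")
  expect_warning(pixel_correlation(matrix(rnorm(9), 3), matrix(1, 3, 3)),
                 "zero variance")
})

test_that("tricolour export scales channels to 0-255 on masked pixels", {
  cmap <- matrix(c(0, 1, 2, 3), 2)
  zero <- matrix(0, 2, 2)
  rgb <- tricolour_export(cmap, zero, zero)
  expect_equal(max(rgb[, , 1]), 255L)
  expect_true(all(rgb[, , 2] == 0) && all(rgb[, , 3] == 0))
  # all-equal maps -> grey particles
  g <- tricolour_export(cmap, cmap, cmap)
  expect_identical(g[, , 1], g[, , 2])
  expect_identical(g[, , 2], g[, , 3])
  # masked-out pixels are black
  msk <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2)
  rgbm <- tricolour_export(cmap, cmap, cmap, mask = msk)
  expect_equal(rgbm[2, 1, ], c(0L, 0L, 0L))
})

test_that("stack TIFF-directory round trip preserves counts and energies", {
  fx <- small_stack_fixture(seed = 3, shape = c(16, 16), n_particles = 6)
  dir <- withr::local_tempdir()
  write_stack(fx$stack, dir)
  back <- read_stack(dir)
  expect_equal(back$energies, fx$stack$energies)
  # 16-bit quantization: relative error bounded by scale/2^16
  expect_lt(max(abs(back$counts - fx$stack$counts)),
            max(fx$stack$counts) / 65535 + 1e-9)
  expect_true(file.exists(file.path(dir, "truth_labels.csv")))
})

test_that("integer-pixel alignment recovers a known shift", {
  base <- matrix(0, 20, 20); base[8:12, 8:12] <- 5
  shifted <- matrix(0, 20, 20); shifted[10:14, 6:10] <- 5
  counts <- array(0, dim = c(2, 20, 20))
  counts[1, , ] <- base + 1; counts[2, , ] <- shifted + 1
  st <- image_stack(c(280, 290), counts, i0 = 10)
  al <- align_stack(st, reference = 1, max_shift = 4)
  expect_equal(al$meta$alignment_shifts[2, ], c(-2, 2))
  expect_equal(al$counts[2, 8:12, 8:12], base[8:12, 8:12] + 1)
})
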