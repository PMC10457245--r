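#' Active-set non-negative least squares
#'
#' Deterministic Lawson-Hanson active-set solver for
#' `min ||A x - b||^2  subject to  x >= 0`. Used by all LCF and species-map
#' fitting in camap; small systems (a handful of standards) solve exactly
#' in a few active-set iterations.
#'
#' @param A Numeric matrix (m x n), m >= 1.
#' @param b Numeric vector of length m.
#' @param tol Dual-feasibility tolerance; default scales with the problem.
#' @return List with `x` (solution, length n), `active` (logical, positive
#'   set), `residual` vector, and `rss`.
#' @export
nnls_solve <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m)
  if (is.null(tol)) {
    tol <- 10 * .Machine$double.eps * max(m, n) * max(abs(A)) * max(max(abs(b)), 1)
  }
  x <- numeric(n)
  P <- logical(n)
  w <- drop(crossprod(A, b))
  iter <- 0L; max_iter <- 30L * n
  while (any(!P) && max(w[!P]) > tol && iter < max_iter) {
    iter <- iter + 1L
    cand <- which(!P)
    j <- cand[which.max(w[cand])]
    P[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, P, drop = FALSE]
      s[P] <- drop(qr.coef(qr(Ap), b))
      s[P][is.na(s[P])] <- 0
      if (all(s[P] > 0)) { x <- s; break }
      neg <- P & (s <= 0)
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      P[P & (x <= tol / max(abs(A)))] <- FALSE
      x[!P] <- 0
      if (!any(P)) { x <- numeric(n); break }
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  r <- drop(b - A %*% x)
  list(x = x, active = P, residual = r, rss = sum(r^2))
}

#' R-factor and reduced chi-squared of a fit
#'
#' `r_factor = sum((y - yhat)^2) / sum(y^2)` (the XAS misfit convention;
#' invariant to common positive rescaling of data and fit) and
#' `reduced_chi2 = sum((y - yhat)^2) / (n - p)`.
#'
#' @param y Observed values.
#' @param yhat Fitted values, same length.
#' @param p Number of fitted parameters (standards); requires `n >= p + 1`.
#' @return List `r_factor`, `reduced_chi2`.
#' @export
fit_statistics <- function(y, yhat, p) {
  stopifnot(length(y) == length(yhat))
  n <- length(y)
  if (n <= p) stop("degrees-of-freedom error: need n > p", call. = FALSE)
  rss <- sum((y - yhat)^2)
  list(r_factor = rss / sum(y^2), reduced_chi2 = rss / (n - p))
}

# resample standards onto the target grid over fit_range; returns the
# design matrix and the grid actually used
lcf_design <- function(target, standards, fit_range) {
  stopifnot(is_spectrum(target), length(standards) >= 1)
  lo <- max(c(target$energies[1],
              vapply(standards, function(s) s$energies[1], 0)))
  hi <- min(c(max(target$energies),
              vapply(standards, function(s) max(s$energies), 0)))
  if (!is.null(fit_range)) {
    lo <- max(lo, fit_range[1]); hi <- min(hi, fit_range[2])
  }
  grid <- target$energies[target$energies >= lo & target$energies <= hi]
  if (length(grid) < length(standards) + 1) {
    stop("coverage error: fit range leaves too few common grid points",
         call. = FALSE)
  }
  A <- vapply(standards, spectrum_at, numeric(length(grid)), energies = grid)
  list(A = as.matrix(A), b = spectrum_at(target, grid), grid = grid)
}

standard_names <- function(standards) {
  nm <- names(standards)
  if (is.null(nm)) nm <- rep("", length(standards))
  fill <- !nzchar(nm)
  nm[fill] <- paste0("standard_", which(fill))
  nm
}

#' Linear combination fit of a spectrum against a standard set
#'
#' Solves for non-negative weights minimizing the squared misfit between
#' the target and a weighted sum of standards over the fit range, with the
#' weight sum left unconstrained. The raw weight sum (in %) is recorded
#' and flagged when outside `sum_range`; the weights are then normalized
#' to sum to 100%, the reporting convention for XANES LCF tables.
#' 1-sigma weight uncertainties come from the linearized covariance of the
#' active (positive) set scaled by the residual variance.
#'
#' @param target A normalized [spectrum()].
#' @param standards Named list of normalized [spectrum()] objects.
#' @param fit_range `c(lo, hi)` in eV, or `NULL` for the full common grid.
#'   Typical choices: Ca K 4030-4100 eV, C K 283-295 eV.
#' @param sum_range Raw-sum window (%) outside which the result is
#'   flagged out-of-range. The quality convention is that raw sums between
#'   99 and 101% indicate a trustworthy fit.
#' @return A `camap_lcf` object: `weights` (%, sum 100), `raw_sum` (%),
#'   `weight_uncertainties` (%), `r_factor`, `reduced_chi2`, `fit_range`,
#'   `standards` (names), `out_of_range` flag, raw `coefficients`, and the
#'   fitted curve.
#' @export
lcf_fit <- function(target, standards, fit_range = NULL,
                    sum_range = c(95, 105)) {
  if (is_spectrum(standards)) standards <- list(standards)
  nm <- standard_names(standards)
  des <- lcf_design(target, standards, fit_range)
  A <- des$A; b <- des$b
  if (ncol(A) > 1) {
    sv <- svd(A, nu = 0, nv = 0)$d
    if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > 1e10) {
      cm <- abs(stats::cor(A)); diag(cm) <- 0
      worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      warning(sprintf(
        "collinearity: standards '%s' and '%s' are nearly dependent (condition number > 1e10)",
        nm[worst[1]], nm[worst[2]]), call. = FALSE)
    }
  }
  sol <- nnls_solve(A, b)
  w <- sol$x
  raw_sum <- 100 * sum(w)
  n <- length(b); p <- length(w)
  stats_ <- fit_statistics(b, drop(A %*% w), p)
  # covariance of the unconstrained solve restricted to the active set
  unc <- rep(0, p)
  n_act <- sum(sol$active)
  if (n_act > 0 && n > n_act) {
    sigma2 <- sol$rss / (n - n_act)
    Ap <- A[, sol$active, drop = FALSE]
    cv <- tryCatch(sigma2 * chol2inv(chol(crossprod(Ap))),
                   error = function(e) NULL)
    if (!is.null(cv)) unc[sol$active] <- sqrt(pmax(diag(cv), 0))
  }
  out_of_range <- raw_sum < sum_range[1] || raw_sum > sum_range[2]
  if (sum(w) > 0) {
    weights <- 100 * w / sum(w)
    unc_pct <- 100 * unc * (100 / raw_sum)
  } else {
    weights <- rep(NA_real_, p)
    unc_pct <- rep(NA_real_, p)
  }
  names(weights) <- names(unc_pct) <- nm
  structure(list(weights = weights, raw_sum = raw_sum,
                 weight_uncertainties = unc_pct,
                 r_factor = stats_$r_factor,
                 reduced_chi2 = stats_$reduced_chi2,
                 fit_range = range(des$grid), standards = nm,
                 out_of_range = out_of_range,
                 coefficients = stats::setNames(w, nm),
                 grid = des$grid, fitted = drop(A %*% w), data = b),
            class = "camap_lcf")
}

#' @export
print.camap_lcf <- function(x, ...) {
  cat(sprintf("<camap_lcf> %d standards, R-factor %.3g, reduced chi^2 %.3g\n",
              length(x$standards), x$r_factor, x$reduced_chi2))
  cat(sprintf("  raw weight sum %.2f%%%s\n", x$raw_sum,
              if (x$out_of_range) "  [out of range]" else ""))
  for (i in seq_along(x$weights)) {
    cat(sprintf("  %-20s %6.1f +/- %.1f %%\n", x$standards[i],
                x$weights[i], x$weight_uncertainties[i]))
  }
  invisible(x)
}

#' Exhaustive combinatorial search over standard subsets
#'
#' Fits every subset of the pool up to `max_components` standards and
#' ranks the fits by R-factor (ascending), breaking ties by fewer
#' components and then lexicographically by standard names.
#'
#' @param target A normalized [spectrum()].
#' @param pool Named list of candidate standards.
#' @param max_components Largest subset size tried.
#' @param fit_range Passed to [lcf_fit()].
#' @return List of `camap_lcf` fits in rank order; a summary table is
#'   attached as attribute `"ranking"`.
#' @export
search_standard_sets <- function(target, pool, max_components = 3,
                                 fit_range = NULL) {
  if (length(pool) == 0) stop("empty-pool: no standards supplied", call. = FALSE)
  stopifnot(max_components <= length(pool), max_components >= 1)
  nm <- standard_names(pool)
  names(pool) <- nm
  fits <- list(); keys <- character(); sizes <- integer()
  for (k in seq_len(max_components)) {
    for (idx in utils::combn(length(pool), k, simplify = FALSE)) {
      fits[[length(fits) + 1L]] <- lcf_fit(target, pool[idx], fit_range)
      keys <- c(keys, paste(sort(nm[idx]), collapse = "+"))
      sizes <- c(sizes, k)
    }
  }
  rf <- vapply(fits, `[[`, 0, "r_factor")
  ord <- order(rf, sizes, keys)
  ranking <- data.frame(subset = keys[ord], n_components = sizes[ord],
                        r_factor = rf[ord],
                        raw_sum = vapply(fits, `[[`, 0, "raw_sum")[ord])
  fits <- fits[ord]
  attr(fits, "ranking") <- ranking
  fits
}

#' Partition the total C signal between Fe-associated and Ca-associated C
#'
#' Two-component LCF of the total-C subset spectrum using only the Fe-C
#' and Ca-C subset spectra as standards — the approximation of how much of
#' the organic carbon is associated with each metal. The headline scalar
#' is the Ca-C percentage.
#'
#' @param total_c,fe_c,ca_c Normalized C K-edge [spectrum()] objects on a
#'   common grid.
#' @param fit_range LCF energy window, default `c(283, 295)` eV.
#' @return A `camap_lcf` with an extra `ca_c_share` field (%).
#' @export
total_c_partition <- function(total_c, fe_c, ca_c, fit_range = c(283, 295)) {
  fit <- lcf_fit(total_c, list(FeC = fe_c, CaC = ca_c), fit_range)
  fit$ca_c_share <- unname(fit$weights["CaC"])
  fit
}

#' Write LCF results as a CSV table
#'
#' One row per fit, columns in the reporting order: standard weights with
#' uncertainties, raw sum, R-factor, reduced chi-squared.
#'
#' @param fits A `camap_lcf` or list of them.
#' @param path Output CSV path.
#' @param labels Optional row labels.
#' @return The data frame written, invisibly.
#' @export
write_lcf_csv <- function(fits, path, labels = NULL) {
  if (inherits(fits, "camap_lcf")) fits <- list(fits)
  all_std <- unique(unlist(lapply(fits, `[[`, "standards")))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    row <- stats::setNames(as.list(rep(NA_real_, 2 * length(all_std))),
                           c(all_std, paste0(all_std, "_sd")))
    for (s in f$standards) {
      row[[s]] <- unname(f$weights[s])
      row[[paste0(s, "_sd")]] <- unname(f$weight_uncertainties[s])
    }
    c(list(fit = if (is.null(labels)) paste0("fit_", i) else labels[i]),
      row,
      list(raw_sum = f$raw_sum, r_factor = f$r_factor,
           reduced_chi2 = f$reduced_chi2))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
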