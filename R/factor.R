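#' Principal-component factor model of a sample-spectrum set
#'
#' Eigen-analysis of the sample cross-product matrix in the Malinowski
#' factor-analysis convention: the data matrix D has one column per sample
#' spectrum (r energy channels x c samples) and is by default NOT
#' mean-centred, because absorption spectra share a common edge that is
#' itself a meaningful factor. The abstract components are the left
#' singular vectors of D; the eigenvalues are those of t(D) D.
#'
#' The number of retained components can be chosen automatically by the
#' minimum of Malinowski's embedded error
#' `IE(n) = sqrt(n * sum_(j>n) lambda_j / (r c (c - n)))`.
#'
#' @param samples List of [spectrum()] objects on a common grid (>= 2).
#' @param n_retained Number of components to keep, or `"auto"`.
#' @param centered Mean-centre the channels first (default `FALSE`).
#' @return A `camap_factor_model`: `components` (r x n orthonormal),
#'   `eigenvalues` (all c, descending), `n_retained`, `re` (real error of
#'   the retained model), `grid`, `sample_count`, `channel_count`,
#'   `centered`, `mean_spectrum`.
#' @export
fit_factor_model <- function(samples, n_retained = "auto", centered = FALSE) {
  stopifnot(length(samples) >= 2, all(vapply(samples, is_spectrum, TRUE)))
  if (!assert_common_grid(samples)) {
    stop("samples must share a common energy grid", call. = FALSE)
  }
  grid <- samples[[1]]$energies
  D <- vapply(samples, `[[`, numeric(length(grid)), "intensities")
  r <- nrow(D); cc <- ncol(D)
  mu <- rowMeans(D)
  if (centered) D <- D - mu
  sv <- svd(D)
  # t(D) D is c x c with rank <= min(r, c): pad the spectrum with zeros
  lambda <- c(sv$d^2, rep(0, max(0, cc - length(sv$d))))
  if (identical(n_retained, "auto")) {
    ns <- seq_len(cc - 1)
    ie <- vapply(ns, function(n) {
      sqrt(n * sum(lambda[(n + 1):cc]) / (r * cc * (cc - n)))
    }, 0)
    n_retained <- ns[which.min(ie)]
  }
  n_retained <- as.integer(n_retained)
  if (n_retained < 1 || n_retained > min(cc, r)) {
    stop("rank error: n_retained must be between 1 and min(sample count, channels)",
         call. = FALSE)
  }
  re <- if (n_retained < cc) {
    sqrt(sum(lambda[(n_retained + 1):cc]) / (r * (cc - n_retained)))
  } else {
    0
  }
  # a numerically exact low-rank set has no real error: snap RE to zero when
  # the discarded eigenvalues are pure floating-point residue
  if (re < 1e-10 * sqrt(lambda[1] / r)) re <- 0
  structure(list(components = sv$u[, seq_len(n_retained), drop = FALSE],
                 eigenvalues = lambda, n_retained = n_retained, re = re,
                 grid = grid, sample_count = cc, channel_count = r,
                 centered = centered, mean_spectrum = mu),
            class = "camap_factor_model")
}

#' @export
print.camap_factor_model <- function(x, ...) {
  ev <- x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf(
    "<camap_factor_model> %d samples x %d channels, %d retained (RE %.3g)\n",
    x$sample_count, x$channel_count, x$n_retained, x$re))
  cat("  eigenvalue fractions:",
      paste(sprintf("%.3g", utils::head(ev, 6)), collapse = " "), "\n")
  invisible(x)
}

#' SPOIL classification bands
#'
#' Malinowski's published scale for target-transform SPOIL values.
#'
#' @param spoil Numeric SPOIL value (>= 0, may be `Inf`).
#' @return One of `"excellent"`, `"good"`, `"fair"`, `"acceptable"`,
#'   `"unacceptable"`.
#' @export
spoil_category <- function(spoil) {
  if (is.na(spoil)) return(NA_character_)
  if (spoil < 1.5) "excellent"
  else if (spoil < 3) "good"
  else if (spoil < 4.5) "fair"
  else if (spoil < 6) "acceptable"
  else "unacceptable"
}

#' Target-transform test of a candidate standard
#'
#' Projects the candidate onto the retained principal components and
#' partitions the misfit following Malinowski's error theory for target
#' factor analysis:
#' * AET (apparent error in target) = RMS of `x - xhat`, where
#'   `xhat = U (U' x)` is the projection onto the retained components;
#' * REP (real error in predicted vector) = `RE * ||t|| / sqrt(r)`, the
#'   per-channel error expected in `xhat` from the model's own noise
#'   level, with `RE` computed from the discarded eigenvalues and
#'   `t = U' x` the target loadings;
#' * RET (real error in target) = `sqrt(max(AET^2 - REP^2, 0))`;
#' * SPOIL = RET / REP.
#'
#' A SPOIL near 0 means the candidate is explained by the sample space to
#' within the data's noise; large SPOIL means the candidate imports
#' structure the samples do not contain. For a noiseless model
#' (`REP = 0`) an out-of-space target yields SPOIL = `Inf`
#' ("unacceptable"); an in-space target yields SPOIL = 0.
#'
#' @param model A [fit_factor_model()].
#' @param standard A [spectrum()] on the model's grid.
#' @return A `camap_spoil` list: `name`, `aet`, `rep`, `ret`, `spoil`,
#'   `category`, `loadings`.
#' @export
target_transform <- function(model, standard) {
  stopifnot(inherits(model, "camap_factor_model"), is_spectrum(standard))
  if (length(standard$energies) != model$channel_count ||
      max(abs(standard$energies - model$grid)) > 1e-9) {
    stop("standard must be on the model's energy grid", call. = FALSE)
  }
  x <- standard$intensities
  if (model$centered) x <- x - model$mean_spectrum
  U <- model$components
  t_load <- drop(crossprod(U, x))
  xhat <- drop(U %*% t_load)
  r <- model$channel_count
  aet <- sqrt(mean((x - xhat)^2))
  rep_ <- model$re * sqrt(sum(t_load^2)) / sqrt(r)
  ret <- sqrt(max(aet^2 - rep_^2, 0))
  spoil <- if (rep_ > 0) {
    ret / rep_
  } else if (aet > 1e-10) {
    Inf
  } else {
    0
  }
  nm <- standard$provenance$name
  if (is.null(nm)) nm <- standard$provenance$column
  if (is.null(nm)) nm <- "target"
  structure(list(name = nm, aet = aet, rep = rep_, ret = ret,
                 spoil = spoil, category = spoil_category(spoil),
                 loadings = t_load),
            class = "camap_spoil")
}

#' @export
print.camap_spoil <- function(x, ...) {
  cat(sprintf("<camap_spoil> %s: SPOIL %.3g (%s); AET %.3g REP %.3g RET %.3g\n",
              x$name, x$spoil, x$category, x$aet, x$rep, x$ret))
  invisible(x)
}

#' Screen a pool of candidate standards by SPOIL
#'
#' Runs [target_transform()] on every pool member and returns the reports
#' sorted by SPOIL ascending (ties broken by name) — the screening step
#' that selects the standard set offered to LCF.
#'
#' @param model A [fit_factor_model()].
#' @param pool Named list of candidate [spectrum()] objects.
#' @return A `data.frame` with columns `name`, `aet`, `rep`, `ret`,
#'   `spoil`, `category`, sorted ascending by SPOIL; the full reports are
#'   attached as attribute `"reports"`.
#' @export
screen_pool <- function(model, pool) {
  if (length(pool) == 0) stop("empty pool", call. = FALSE)
  nm <- standard_names(pool)
  reports <- lapply(seq_along(pool), function(i) {
    rp <- target_transform(model, pool[[i]])
    rp$name <- nm[i]
    rp
  })
  df <- data.frame(
    name = nm,
    aet = vapply(reports, `[[`, 0, "aet"),
    rep = vapply(reports, `[[`, 0, "rep"),
    ret = vapply(reports, `[[`, 0, "ret"),
    spoil = vapply(reports, `[[`, 0, "spoil"),
    category = vapply(reports, `[[`, "", "category"),
    stringsAsFactors = FALSE
  )
  ord <- order(df$spoil, df$name)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "reports") <- reports[ord]
  df
}
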