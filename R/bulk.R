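#' Exchangeable-cation profile
#'
#' Amounts (mol per kg) of the exchangeable cations Al3+, Ca2+, Mg2+,
#' Na+ and K+ with their valences; H+ is deliberately excluded from all
#' charge sums.
#'
#' @param Al,Ca,Mg,Na,K Amounts in mol per kg, all >= 0.
#' @return A `camap_exch_profile` object.
#' @export
exchangeable_profile <- function(Al = 0, Ca = 0, Mg = 0, Na = 0, K = 0) {
  amounts <- c(Al = Al, Ca = Ca, Mg = Mg, Na = Na, K = K)
  if (any(amounts < 0)) {
    stop("validation error: cation amounts must be >= 0", call. = FALSE)
  }
  structure(list(amounts = amounts,
                 charges = c(Al = 3, Ca = 2, Mg = 2, Na = 1, K = 1)),
            class = "camap_exch_profile")
}

#' Cation exchange capacity as a charge sum
#'
#' CEC (cmol_c per kg) = sum over cations of valence x amount (mol/kg)
#' x 100, over Al3+, Ca2+, Mg2+, Na+ and K+, excluding H+.
#'
#' @param p An [exchangeable_profile()].
#' @param cations Subset of cation names to sum (default all five).
#' @return CEC in cmol_c per kg.
#' @export
cec_sum <- function(p, cations = names(p$amounts)) {
  stopifnot(inherits(p, "camap_exch_profile"))
  sum(p$charges[cations] * p$amounts[cations]) * 100
}

#' Base saturation of the exchange complex
#'
#' Percentage of the CEC charge held by the base cations Ca2+, Mg2+, Na+
#' and K+ (H+ not included anywhere; Al3+ is the only acid cation in the
#' sum).
#'
#' @param p An [exchangeable_profile()].
#' @return Base saturation in percent, in \[0, 100\].
#' @export
base_saturation <- function(p) {
  total <- cec_sum(p)
  if (total <= 0) {
    stop("undefined: base saturation requires CEC > 0", call. = FALSE)
  }
  100 * cec_sum(p, c("Ca", "Mg", "Na", "K")) / total
}

#' Simple linear association between two table columns
#'
#' Ordinary least squares of `response` on `predictor` over complete
#' rows; incomplete rows are dropped and counted.
#'
#' @param table A data frame.
#' @param response,predictor Column names.
#' @return List `r2`, `slope`, `intercept`, `n`, `n_dropped`.
#' @export
table_associations <- function(table, response, predictor) {
  stopifnot(all(c(response, predictor) %in% names(table)))
  x <- table[[predictor]]; y <- table[[response]]
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) stop("need >= 3 complete rows", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  vx <- stats::var(x)
  if (vx == 0) {
    stop("undefined-slope: predictor is constant", call. = FALSE)
  }
  slope <- stats::cov(x, y) / vx
  r2 <- if (stats::var(y) > 0) stats::cor(x, y)^2 else 0
  list(r2 = r2, slope = slope, intercept = mean(y) - slope * mean(x),
       n = n, n_dropped = length(ok) - n)
}

#' PCA of a bulk characterization table on the correlation matrix
#'
#' Standardizes the chosen columns (equivalent to PCA of the correlation
#' matrix) before eigen-decomposition; zero-variance columns are dropped
#' with a warning. Explained-variance fractions sum to 1.
#'
#' @param table A data frame.
#' @param columns Names of the numeric columns to include (>= 2).
#' @return List `loadings` (variables x PCs, orthonormal), `scores`,
#'   `explained` (variance fractions), `sdev`, `columns_used`.
#' @export
table_pca <- function(table, columns) {
  stopifnot(length(columns) >= 2, all(columns %in% names(table)))
  X <- as.matrix(table[, columns, drop = FALSE])
  if (nrow(X) < 3) stop("need >= 3 rows", call. = FALSE)
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance columns: ",
            paste(columns[v == 0], collapse = ", "), call. = FALSE)
    X <- X[, v > 0, drop = FALSE]
    columns <- columns[v > 0]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(loadings = pc$rotation, scores = pc$x, explained = expl,
       sdev = pc$sdev, columns_used = columns)
}

#' Row-wise CEC and base saturation for a bulk table
#'
#' Convenience wrapper applying [cec_sum()] and [base_saturation()] to
#' the exchangeable-cation columns of a bulk table whose amounts are in
#' cmol_c per kg already (the generator's convention): the charge
#' weighting is then already folded in, so CEC is the plain column sum.
#' For mol-per-kg inputs build [exchangeable_profile()]s instead.
#'
#' @param table Data frame with columns `Ca_exch`, `Mg_exch`, `K_exch`,
#'   `Na_exch`, `Al_exch` in cmol_c per kg.
#' @return The table with extra columns `CEC` and `base_sat_pct`.
#' @export
bulk_cec_table <- function(table) {
  need <- c("Ca_exch", "Mg_exch", "K_exch", "Na_exch", "Al_exch")
  stopifnot(all(need %in% names(table)))
  bases <- table$Ca_exch + table$Mg_exch + table$K_exch + table$Na_exch
  cec <- bases + table$Al_exch
  table$CEC <- cec
  table$base_sat_pct <- ifelse(cec > 0, 100 * bases / cec, NA_real_)
  table
}
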