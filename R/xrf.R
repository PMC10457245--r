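#' Multi-energy micro-XRF map set
#'
#' Fluorescence count maps of one element collected at several incident
#' energies chosen to contrast chemical species (pre-edge, white line,
#' shoulder, post-edge), plus optional auxiliary single-energy element
#' channels (Al, Mg, P, S, Si, ...).
#'
#' @param energies Incident energies (eV), length m >= 2.
#' @param maps Numeric array m x rows x cols of counts, >= 0.
#' @param channels Optional named list of rows x cols matrices for
#'   auxiliary element channels.
#' @return A `camap_mem` object.
#' @export
multi_energy_map <- function(energies, maps, channels = list()) {
  energies <- as.numeric(energies)
  stopifnot(length(energies) >= 2)
  if (length(dim(maps)) != 3 || dim(maps)[1] != length(energies)) {
    stop("maps must be an m x rows x cols array matching energies",
         call. = FALSE)
  }
  if (any(maps < 0, na.rm = TRUE)) stop("counts must be >= 0", call. = FALSE)
  structure(list(energies = energies, maps = maps, channels = channels),
            class = "camap_mem")
}

#' Default multi-energy acquisition energies for Ca K-edge species mapping
#'
#' Four energies spanning the features that distinguish Ca species:
#' pre-edge (4040 eV), white line (4049 eV), the shoulder feature
#' (4055 eV) and post-edge (4080 eV).
#'
#' @return Numeric vector of energies (eV).
#' @export
default_xrf_energies <- function() c(4040, 4049, 4055, 4080)

#' Sample reference spectra at the map energies
#'
#' Linear interpolation of each normalized standard at the incident
#' energies of a multi-energy map, producing the m x k design matrix for
#' per-pixel species fitting.
#'
#' @param standards Named list of normalized [spectrum()] objects.
#' @param energies Map energies (eV); each must lie inside every
#'   standard's grid.
#' @return Numeric matrix m x k with standards as named columns.
#' @export
sample_standards_at <- function(standards, energies) {
  nm <- standard_names(standards)
  cols <- lapply(seq_along(standards), function(i) {
    s <- standards[[i]]
    tryCatch(spectrum_at(s, energies), error = function(e) {
      stop(sprintf("coverage error for standard '%s': %s", nm[i],
                   conditionMessage(e)), call. = FALSE)
    })
  })
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

#' Per-pixel species maps from a multi-energy XRF map
#'
#' At each pixel, the m-vector of counts across incident energies is fit
#' by non-negative least squares on the standards matrix, giving one
#' weight map per species. Pixels whose total counts fall below
#' `min_signal` are left unfit (NA weights) and flagged — masking is
#' always explicit. The dominant species is the argmax weight; exact ties
#' go to the first standard in column order and are flagged.
#'
#' @param mem A [multi_energy_map()].
#' @param standards_matrix m x k matrix from [sample_standards_at()];
#'   must have full column rank.
#' @param min_signal Total-count threshold below which a pixel is unfit.
#' @return A `camap_species_maps`: `weights` (named list of rows x cols
#'   matrices), `residual` (RMS per pixel), `dominant` (integer matrix,
#'   NA where unfit), `tie` (logical matrix), `unfit` (logical matrix),
#'   `standards` (names), `area_fractions` (share of fit pixels whose
#'   dominant species is each standard).
#' @export
fit_species_maps <- function(mem, standards_matrix, min_signal = 0) {
  stopifnot(inherits(mem, "camap_mem"))
  S <- as.matrix(standards_matrix)
  m <- nrow(S); k <- ncol(S)
  if (m != length(mem$energies)) {
    stop("standards matrix rows must match map energies", call. = FALSE)
  }
  if (k > m) stop("need at least as many energies as standards", call. = FALSE)
  if (qr(S)$rank < k) {
    stop("collinearity: standards matrix is rank deficient", call. = FALSE)
  }
  d <- dim(mem$maps)[2:3]
  n_px <- prod(d)
  Y <- matrix(mem$maps, nrow = m)        # m x pixels
  tot <- colSums(Y)
  unfit <- tot < min_signal
  W <- matrix(NA_real_, k, n_px)
  res <- rep(NA_real_, n_px)
  for (p in which(!unfit)) {
    sol <- nnls_solve(S, Y[, p])
    W[, p] <- sol$x
    res[p] <- sqrt(sol$rss / m)
  }
  dominant <- rep(NA_integer_, n_px)
  tie <- rep(FALSE, n_px)
  fitted_px <- which(!unfit)
  if (length(fitted_px)) {
    dominant[fitted_px] <- apply(W[, fitted_px, drop = FALSE], 2, which.max)
    tie[fitted_px] <- apply(W[, fitted_px, drop = FALSE], 2, function(w) {
      sum(w == max(w)) > 1
    })
  }
  nm <- colnames(S)
  if (is.null(nm)) nm <- paste0("species_", seq_len(k))
  weights <- stats::setNames(
    lapply(seq_len(k), function(j) matrix(W[j, ], d[1], d[2])), nm)
  af <- if (length(fitted_px)) {
    tabulate(dominant[fitted_px], nbins = k) / length(fitted_px)
  } else {
    rep(NA_real_, k)
  }
  structure(list(weights = weights,
                 residual = matrix(res, d[1], d[2]),
                 dominant = matrix(dominant, d[1], d[2]),
                 tie = matrix(tie, d[1], d[2]),
                 unfit = matrix(unfit, d[1], d[2]),
                 standards = nm,
                 area_fractions = stats::setNames(af, nm)),
            class = "camap_species_maps")
}

#' @export
print.camap_species_maps <- function(x, ...) {
  cat("<camap_species_maps> dominant-species area fractions:\n")
  print(round(x$area_fractions, 4))
  cat(sprintf("  unfit pixels: %d\n", sum(x$unfit)))
  invisible(x)
}

#' Inter-element correlation against a reference channel
#'
#' Ordinary least squares of each auxiliary channel against the reference
#' channel over valid pixels, reporting the adjusted R^2 — the statistic
#' used to ask whether the reference element's distribution tracks any
#' other measured element.
#'
#' @param channels Named list of rows x cols matrices (including the
#'   reference).
#' @param reference Name of the reference channel.
#' @param mask Optional logical matrix of pixels to include.
#' @return `data.frame` with columns `channel`, `adjusted_r2`, `r2`,
#'   `slope`, `n`; constant channels get `NA` with a warning.
#' @export
interelement_correlation <- function(channels, reference, mask = NULL) {
  stopifnot(reference %in% names(channels))
  ref <- channels[[reference]]
  others <- setdiff(names(channels), reference)
  rows <- lapply(others, function(ch) {
    v <- channels[[ch]]
    if (!identical(dim(v), dim(ref))) {
      stop("shape error: channel '", ch, "' does not match reference",
           call. = FALSE)
    }
    if (stats::sd(as.vector(v), na.rm = TRUE) == 0) {
      warning(sprintf("channel '%s' is constant; correlation undefined", ch),
              call. = FALSE)
      return(data.frame(channel = ch, adjusted_r2 = NA_real_, r2 = NA_real_,
                        slope = NA_real_, n = sum(is.finite(v))))
    }
    pc <- pixel_correlation(ref, v, mask)
    data.frame(channel = ch, adjusted_r2 = pc$adjusted_r2, r2 = pc$r2,
               slope = pc$slope, n = pc$n)
  })
  do.call(rbind, rows)
}

#' Render a synthetic multi-energy XRF map set from ground-truth weights
#'
#' Forward model for species-map benchmarking: per pixel, counts at each
#' incident energy are the weighted sum of the standard spectra sampled at
#' that energy, with optional Poisson noise.
#'
#' @param weight_maps Named list of rows x cols ground-truth weight
#'   matrices (>= 0), one per standard.
#' @param standards_matrix m x k matrix from [sample_standards_at()], with
#'   columns matching `weight_maps` names.
#' @param energies The m incident energies (eV).
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed for the noise draw.
#' @return A [multi_energy_map()].
#' @export
render_xrf_maps <- function(weight_maps, standards_matrix, energies,
                            noise = c("none", "poisson"), seed = 1L) {
  noise <- match.arg(noise)
  S <- as.matrix(standards_matrix)
  k <- ncol(S)
  stopifnot(length(weight_maps) == k, nrow(S) == length(energies))
  d <- dim(weight_maps[[1]])
  W <- vapply(weight_maps, as.vector, numeric(prod(d)))   # pixels x k
  Y <- S %*% t(W)                                         # m x pixels
  if (noise == "poisson") {
    set.seed(seed)
    Y[] <- stats::rpois(length(Y), Y)
  }
  multi_energy_map(energies, array(Y, dim = c(nrow(S), d[1], d[2])))
}
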