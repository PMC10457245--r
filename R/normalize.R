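#' Edge-step normalization parameters
#'
#' Pre-edge and post-edge fit windows, the reference energy E0, the
#' post-edge polynomial order and the target edge step. E0 is always an
#' explicit parameter: it is never inferred from the data, because the
#' normalization E0 and the energy-calibration reference are distinct
#' conventions at the Ca K-edge (named presets ship both).
#'
#' @param pre_lo,pre_hi Pre-edge linear fit window (eV), `pre_lo < pre_hi`.
#' @param post_lo,post_hi Post-edge polynomial fit window (eV).
#' @param e0 Reference energy (eV) at which the post-edge polynomial is
#'   evaluated to define the edge step; `pre_hi <= e0 <= post_lo`.
#' @param post_order Post-edge polynomial order: 0, 1 or 2.
#' @param edge_step_target Edge step the output is scaled to (default 1.0).
#' @return A `camap_norm_params` object.
#' @seealso [norm_preset()] for the shipped parameter sets.
#' @export
norm_params <- function(pre_lo, pre_hi, post_lo, post_hi, e0,
                        post_order = 2, edge_step_target = 1.0) {
  stopifnot(post_order %in% 0:2, edge_step_target > 0)
  if (!(pre_lo < pre_hi && pre_hi <= e0 && e0 <= post_lo && post_lo < post_hi)) {
    stop("invalid windows: need pre_lo < pre_hi <= e0 <= post_lo < post_hi",
         call. = FALSE)
  }
  structure(list(pre_lo = pre_lo, pre_hi = pre_hi, post_lo = post_lo,
                 post_hi = post_hi, e0 = e0, post_order = post_order,
                 edge_step_target = edge_step_target),
            class = "camap_norm_params")
}

#' Named normalization presets
#'
#' `"Ca-K-PtReyes"`: linear pre-edge 4013.39-4033.39 eV, second-order
#' post-edge 4063.39-4243.39 eV, E0 = 4043.39 eV. `"C-K-PtReyes"`: linear
#' pre-edge 279.8-283.3 eV, second-order post-edge 291.8-302.0 eV, edge
#' jump fixed to 1.0 at 284.8 eV.
#'
#' @param name Preset name.
#' @return A [norm_params()] object.
#' @export
norm_preset <- function(name = c("Ca-K-PtReyes", "C-K-PtReyes")) {
  name <- match.arg(name)
  switch(name,
    "Ca-K-PtReyes" = norm_params(4013.39, 4033.39, 4063.39, 4243.39,
                                 e0 = 4043.39, post_order = 2),
    "C-K-PtReyes"  = norm_params(279.8, 283.3, 291.8, 302.0,
                                 e0 = 284.8, post_order = 2)
  )
}

# clip a window to the grid; warn when >= 10% of its width is lost
clip_window <- function(lo, hi, energies, what) {
  glo <- energies[1]; ghi <- energies[length(energies)]
  nlo <- max(lo, glo); nhi <- min(hi, ghi)
  if (nlo >= nhi) {
    stop(sprintf("window error: %s window [%g, %g] outside grid [%g, %g]",
                 what, lo, hi, glo, ghi), call. = FALSE)
  }
  if ((hi - lo) - (nhi - nlo) >= 0.10 * (hi - lo)) {
    warning(sprintf("%s window [%g, %g] truncated to [%g, %g] by grid limits",
                    what, lo, hi, nlo, nhi), call. = FALSE)
  }
  c(nlo, nhi)
}

#' First derivative of a spectrum
#'
#' Central differences on the interior, one-sided differences at the two
#' ends; the returned spectrum keeps the input grid.
#'
#' @param s A [spectrum()] with at least 3 points.
#' @return A [spectrum()] of d(intensity)/dE.
#' @export
first_derivative <- function(s) {
  stopifnot(is_spectrum(s))
  n <- length(s$energies)
  if (n < 3) stop("size error: first_derivative needs >= 3 points", call. = FALSE)
  e <- s$energies; y <- s$intensities
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (e[2] - e[1])
  d[n] <- (y[n] - y[n - 1]) / (e[n] - e[n - 1])
  i <- 2:(n - 1)
  d[i] <- (y[i + 1] - y[i - 1]) / (e[i + 1] - e[i - 1])
  spectrum(e, d, edge_label = s$edge_label,
           provenance = c(s$provenance, list(derivative = 1L)))
}

# locate the derivative maximum with parabolic refinement through the three
# points around the discrete maximum (sub-grid accuracy, no line-shape model)
derivative_max_energy <- function(s, tol = 1e-12) {
  d <- first_derivative(s)
  y <- d$intensities; e <- d$energies
  imax <- which(y >= max(y) - tol)
  if (length(imax) > 1 && any(diff(imax) > 1)) {
    stop(sprintf("ambiguity: tied derivative maxima at energies %s eV",
                 paste(format(e[imax]), collapse = ", ")), call. = FALSE)
  }
  i <- imax[1]
  if (i == 1 || i == length(y)) return(e[i])
  # vertex of the parabola through (e[i-1..i+1], y[i-1..i+1])
  x1 <- e[i - 1]; x2 <- e[i]; x3 <- e[i + 1]
  y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
  denom <- (x1 - x2) * (x1 - x3) * (x2 - x3)
  a <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / denom
  b <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / denom
  if (a >= 0) return(x2)   # degenerate (not concave): keep the grid point
  -b / (2 * a)
}

#' Calibrate the energy axis against a reference edge position
#'
#' Rigidly translates the energy axis so that the maximum of the spectrum's
#' first derivative falls at `reference_e` — the standard monochromator
#' calibration against a reference compound (e.g. setting the gypsum Ca
#' K-edge derivative maximum to 4043.89 eV). Intensities are untouched.
#'
#' @param s A [spectrum()].
#' @param reference_e Reference energy (eV) for the derivative maximum.
#' @return The shifted [spectrum()]; the applied shift (eV) is recorded in
#'   `provenance$calibration_shift_eV`.
#' @export
calibrate_energy <- function(s, reference_e) {
  stopifnot(is_spectrum(s))
  if (length(s$energies) < 5) {
    stop("calibrate_energy needs >= 5 points around the rising edge",
         call. = FALSE)
  }
  observed <- derivative_max_energy(s)
  shift <- reference_e - observed
  prov <- utils::modifyList(s$provenance,
                            list(calibration_shift_eV = shift,
                                 calibration_reference_eV = reference_e))
  spectrum(s$energies + shift, s$intensities, edge_label = s$edge_label,
           provenance = prov)
}

#' Average replicate scans onto a common grid
#'
#' Replicates are linearly interpolated onto the chosen grid and averaged
#' pointwise; the replicate count is recorded in the provenance. The grid
#' is restricted to the energy range covered by every replicate.
#'
#' @param replicates List of [spectrum()] objects with overlapping coverage.
#' @param grid `"first"` (grid of the first replicate), `"union"` (sorted
#'   union of all grids), or an explicit numeric vector of energies.
#' @return The merged [spectrum()].
#' @export
merge_replicates <- function(replicates, grid = "first") {
  stopifnot(length(replicates) >= 1, all(vapply(replicates, is_spectrum, TRUE)))
  lo <- max(vapply(replicates, function(s) s$energies[1], 0))
  hi <- min(vapply(replicates, function(s) s$energies[length(s$energies)], 0))
  if (lo >= hi) {
    stop("coverage error: replicate energy ranges do not overlap", call. = FALSE)
  }
  g <- if (is.numeric(grid)) {
    grid
  } else if (identical(grid, "union")) {
    sort(unique(unlist(lapply(replicates, `[[`, "energies"))))
  } else {
    replicates[[1]]$energies
  }
  g <- g[g >= lo & g <= hi]
  if (length(g) < 2) stop("coverage error: common grid has < 2 points", call. = FALSE)
  ys <- vapply(replicates, spectrum_at, numeric(length(g)), energies = g)
  spectrum(g, rowMeans(ys), edge_label = replicates[[1]]$edge_label,
           provenance = list(n_replicates = length(replicates)))
}

#' Edge-step normalization of a XANES spectrum
#'
#' Fits a straight line to the pre-edge window and subtracts it everywhere,
#' fits a polynomial of order `p$post_order` to the pre-edge-subtracted
#' post-edge window, and divides by that polynomial evaluated at E0, so the
#' fitted edge step at E0 equals `edge_step_target` (1.0 by default)
#' exactly by construction. The result is invariant to any positive
#' rescaling of the input.
#'
#' @param s A [spectrum()].
#' @param p A [norm_params()] object (see [norm_preset()]).
#' @return The normalized [spectrum()]; fitted pre-edge coefficients and
#'   the edge step are stored in the provenance.
#' @export
normalize_xanes <- function(s, p) {
  stopifnot(is_spectrum(s), inherits(p, "camap_norm_params"))
  e <- s$energies; y <- s$intensities
  pre <- clip_window(p$pre_lo, p$pre_hi, e, "pre-edge")
  post <- clip_window(p$post_lo, p$post_hi, e, "post-edge")
  ipre <- which(e >= pre[1] & e <= pre[2])
  ipost <- which(e >= post[1] & e <= post[2])
  if (length(ipre) < 3) stop("window error: < 3 points in pre-edge window",
                             call. = FALSE)
  if (length(ipost) < max(3, p$post_order + 1)) {
    stop("window error: too few points in post-edge window", call. = FALSE)
  }
  # pre-edge line, least squares about e0 for conditioning
  X <- cbind(1, e[ipre] - p$e0)
  cf <- stats::lm.fit(X, y[ipre])$coefficients
  y1 <- y - (cf[1] + cf[2] * (e - p$e0))
  # post-edge polynomial on the pre-edge-subtracted data
  Xp <- stats::poly(e[ipost] - p$e0, degree = max(p$post_order, 1),
                    raw = TRUE, simple = TRUE)
  if (p$post_order == 0) Xp <- Xp[, 0, drop = FALSE]
  Xp <- cbind(1, Xp)
  cp <- stats::lm.fit(Xp, y1[ipost])$coefficients
  edge_step <- cp[1]   # polynomial in (E - e0) evaluated at e0
  if (!is.finite(edge_step) || edge_step <= 0) {
    stop("degenerate-edge: post-edge polynomial non-positive at E0",
         call. = FALSE)
  }
  spectrum(e, y1 / edge_step * p$edge_step_target,
           edge_label = s$edge_label,
           provenance = c(s$provenance, list(
             pre_edge_offset = unname(cf[1]), pre_edge_slope = unname(cf[2]),
             edge_step = unname(edge_step),
             norm_e0_eV = p$e0,
             norm_pre_window_eV = pre, norm_post_window_eV = post)))
}
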