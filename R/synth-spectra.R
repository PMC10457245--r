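#' Gaussian peak model for a synthetic endmember spectrum
#'
#' @param center Peak center (eV).
#' @param width Gaussian sigma (eV), > 0.
#' @param amplitude Dimensionless peak amplitude, >= 0.
#' @return A `camap_peak` object.
#' @export
peak_model <- function(center, width, amplitude) {
  if (!(width > 0)) stop("peak width must be > 0", call. = FALSE)
  if (amplitude < 0) stop("peak amplitude must be >= 0", call. = FALSE)
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "camap_peak")
}

#' Arctangent absorption-edge model
#'
#' Phenomenological edge shape used by the synthetic generator: a linear
#' pre-edge baseline plus an arctangent step of width `gamma` centred on
#' the inflection energy `e0`.
#'
#' @param e0 Inflection energy of the step (eV).
#' @param step_height Edge step height, >= 0.
#' @param pre_slope Baseline slope (per eV).
#' @param pre_offset Baseline offset.
#' @param gamma Arctangent half-width (eV), default 0.5.
#' @return A `camap_edge` object.
#' @export
edge_model <- function(e0, step_height = 1, pre_slope = 0, pre_offset = 0,
                       gamma = 0.5) {
  if (step_height < 0) stop("step_height must be >= 0", call. = FALSE)
  if (!(gamma > 0)) stop("gamma must be > 0", call. = FALSE)
  structure(list(e0 = e0, step_height = step_height, pre_slope = pre_slope,
                 pre_offset = pre_offset, gamma = gamma),
            class = "camap_edge")
}

#' Synthesize an endmember XANES spectrum
#'
#' Deterministic forward model: baseline + arctangent step + a sum of
#' Gaussian peaks,
#' \deqn{\mu(E) = b_0 + b_1 (E - E_0) + h\,[1/2 + \arctan((E-E_0)/\gamma)/\pi]
#'   + \sum_k a_k e^{-(E-c_k)^2 / (2\sigma_k^2)}.}
#'
#' @param edge An [edge_model()].
#' @param peaks List of [peak_model()] objects (possibly empty).
#' @param grid Strictly increasing energy grid (eV) spanning `edge$e0`.
#' @param edge_label Edge label for the resulting [spectrum()].
#' @return A [spectrum()].
#' @export
make_endmember_spectrum <- function(edge, peaks = list(), grid,
                                    edge_label = "other") {
  stopifnot(inherits(edge, "camap_edge"))
  if (any(diff(grid) <= 0)) {
    stop("invalid-grid: grid must be strictly increasing", call. = FALSE)
  }
  y <- edge$pre_offset + edge$pre_slope * (grid - edge$e0) +
    edge$step_height * (0.5 + atan((grid - edge$e0) / edge$gamma) / pi)
  for (pk in peaks) {
    stopifnot(inherits(pk, "camap_peak"))
    y <- y + pk$amplitude * exp(-(grid - pk$center)^2 / (2 * pk$width^2))
  }
  spectrum(grid, y, edge_label = edge_label,
           provenance = list(synthetic = TRUE, e0 = edge$e0))
}

#' High-frequency decoy spectrum for out-of-space screening tests
#'
#' A rapidly oscillating waveform that no smooth absorption spectrum set
#' can reproduce — used as a negative control in SPOIL screens: a factor
#' model of real (smooth) sample spectra must classify it unacceptable.
#'
#' @param grid Energy grid (eV).
#' @param period Oscillation period in grid steps (default: alternates
#'   every other point).
#' @return A [spectrum()].
#' @export
decoy_spectrum <- function(grid, period = 2) {
  y <- sin(pi * seq_along(grid) * 2 / period + 0.3)
  spectrum(grid, y, edge_label = "other",
           provenance = list(name = "decoy", synthetic = TRUE))
}

#' Default multi-edge energy grid for synthetic stacks
#'
#' Thirty energies: 1-eV sampling over the C K-edge (278-302 eV, for
#' subset spectra and edge-step normalization) plus the edge-jump energy
#' 284.8 eV, and the below/above frame pairs used for the Ca
#' (342/349.4 eV) and Fe (698/710 eV) element-contrast maps.
#'
#' @return Sorted numeric vector of 30 energies (eV).
#' @export
default_stack_energies <- function() {
  sort(c(seq(278, 302, by = 1), 284.8, 342, 349.4, 698, 710))
}

#' Synthetic endmember spectral library
#'
#' Four endmembers on a shared multi-edge grid, used as the generator's
#' ground-truth absorption cross-sections:
#' * `C_plant` — C K-edge with aromatic (285.0 eV), phenolic (286.4 eV) and
#'   carboxylic (288.0 eV) peaks, a plant-litter-like signature;
#' * `C_microbial` — C K-edge with carboxylic (288.0 eV) and O-alkyl
#'   (289.5 eV) peaks, a microbially processed signature;
#' * `Ca` — Ca L-edge with the L3 (348.1, 349.2 eV) and L2 (351.5,
#'   352.2 eV) crystal-field/spin-orbit peak quartet;
#' * `Fe` — Fe L3-edge step near 708 eV, used as a presence channel only.
#'
#' @param grid Energy grid (eV); must span all four edges. Defaults to a
#'   dense composite grid over 270-730 eV.
#' @return Named list of [spectrum()] objects.
#' @export
endmember_library <- function(grid = NULL) {
  if (is.null(grid)) {
    grid <- sort(unique(c(seq(270, 320, 0.2), seq(330, 370, 0.2),
                          seq(380, 420, 1), seq(660, 730, 0.5))))
  }
  c_edge <- function() edge_model(e0 = 290.0, step_height = 1, gamma = 1.0)
  list(
    C_plant = make_endmember_spectrum(
      c_edge(),
      list(peak_model(285.0, 0.45, 1.0),
           peak_model(286.4, 0.55, 0.8),
           peak_model(288.0, 0.50, 0.6)),
      grid, edge_label = "C K"),
    C_microbial = make_endmember_spectrum(
      c_edge(),
      list(peak_model(288.0, 0.50, 0.9),
           peak_model(289.5, 0.60, 0.8)),
      grid, edge_label = "C K"),
    Ca = make_endmember_spectrum(
      edge_model(e0 = 350.0, step_height = 0.35, gamma = 0.6),
      list(peak_model(348.1, 0.25, 1.0),
           peak_model(349.2, 0.25, 0.85),
           peak_model(351.5, 0.25, 0.55),
           peak_model(352.2, 0.25, 0.45)),
      grid, edge_label = "Ca L"),
    Fe = make_endmember_spectrum(
      edge_model(e0 = 707.8, step_height = 1, gamma = 0.8),
      list(peak_model(708.3, 0.7, 0.9)),
      grid, edge_label = "Fe L")
  )
}
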