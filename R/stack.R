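#' STXM transmission image stack
#'
#' A series of transmission images over increasing photon energy, with an
#' incident-intensity (I0) specification: a scalar, a per-energy vector,
#' or a pixel region (`list(rows =, cols =)`) whose mean counts per energy
#' frame define I0.
#'
#' @param energies Strictly increasing energy list (eV).
#' @param counts Numeric array `energy x rows x cols` of transmitted
#'   counts, all non-negative.
#' @param i0 Scalar, vector of `length(energies)`, or
#'   `list(rows =, cols =)` region specification.
#' @param meta Free-form metadata list (seed, scene truth, ...).
#' @return A `camap_stack` object.
#' @export
image_stack <- function(energies, counts, i0, meta = list()) {
  energies <- as.numeric(energies)
  if (any(diff(energies) <= 0)) {
    stop("invalid-grid: energies must be strictly increasing", call. = FALSE)
  }
  if (length(dim(counts)) != 3 || dim(counts)[1] != length(energies)) {
    stop("counts must be an energy x rows x cols array matching energies",
         call. = FALSE)
  }
  if (any(counts < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(list(energies = energies, counts = counts, i0 = i0, meta = meta),
            class = "camap_stack")
}

#' @export
print.camap_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<camap_stack> %d energies (%.1f-%.1f eV), %d x %d pixels\n",
              d[1], min(x$energies), max(x$energies), d[2], d[3]))
  invisible(x)
}

# resolve I0 to a per-energy numeric vector
resolve_i0 <- function(stack) {
  i0 <- stack$i0
  n_e <- length(stack$energies)
  v <- if (is.list(i0)) {
    vapply(seq_len(n_e), function(j) {
      mean(stack$counts[j, i0$rows, i0$cols])
    }, 0)
  } else if (length(i0) == 1) {
    rep(as.numeric(i0), n_e)
  } else if (length(i0) == n_e) {
    as.numeric(i0)
  } else {
    stop("invalid-I0: i0 must be scalar, per-energy, or a region spec",
         call. = FALSE)
  }
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("invalid-I0: I0 must be positive at every energy", call. = FALSE)
  }
  v
}

#' Convert a transmission stack to optical density
#'
#' `OD = -ln(counts / I0(E))` per pixel and energy (Beer-Lambert).
#' Zero-count pixels have no finite OD; they are set to `NA` and flagged
#' in the returned `invalid` mask rather than clamped, so downstream masks
#' can exclude them explicitly.
#'
#' @param stack An [image_stack()].
#' @return A `camap_od_stack` with fields `energies`, `od`
#'   (energy x rows x cols), `invalid` (rows x cols logical: any
#'   zero-count frame at that pixel), and the resolved per-energy `i0`.
#' @export
to_optical_density <- function(stack) {
  stopifnot(inherits(stack, "camap_stack"))
  i0 <- resolve_i0(stack)
  od <- stack$counts
  for (j in seq_along(i0)) od[j, , ] <- -log(stack$counts[j, , ] / i0[j])
  invalid <- apply(stack$counts == 0, c(2, 3), any)
  od[!is.finite(od)] <- NA_real_
  structure(list(energies = stack$energies, od = od, invalid = invalid,
                 i0 = i0, meta = stack$meta),
            class = "camap_od_stack")
}

# index of the stack frame nearest to `e`, required within `tol` eV
frame_index <- function(energies, e, tol = 0.2) {
  i <- which.min(abs(energies - e))
  if (abs(energies[i] - e) > tol) {
    stop(sprintf(
      "frame-lookup: no stack frame within %.2f eV of %.2f eV (nearest %.2f)",
      tol, e, energies[i]), call. = FALSE)
  }
  i
}

#' Elemental contrast map from an OD stack
#'
#' Difference of the optical-density frames just above and just below an
#' element's absorption edge, `OD(above) - OD(below)` per pixel — the
#' standard STXM element map (C: 295/280 eV, Ca L: 349.4/342 eV,
#' Fe L: 710/698 eV).
#'
#' @param od A [to_optical_density()] result.
#' @param element `"C"`, `"Ca"`, or `"Fe"` (label only).
#' @param above_e,below_e Frame energies (eV), `above_e > below_e`; the
#'   nearest stack frame within 0.2 eV is used.
#' @return A `camap_element_map` with the `values` matrix and the energies
#'   used.
#' @export
element_map <- function(od, element, above_e, below_e) {
  stopifnot(inherits(od, "camap_od_stack"), above_e > below_e)
  ia <- frame_index(od$energies, above_e)
  ib <- frame_index(od$energies, below_e)
  structure(list(element = element,
                 above_e = od$energies[ia], below_e = od$energies[ib],
                 values = od$od[ia, , ] - od$od[ib, , ]),
            class = "camap_element_map")
}

#' Saturation mask from per-pixel optical density
#'
#' Excludes pixels whose optical density exceeds the cutoff (strictly
#' greater), the standard guard against thickness/saturation artifacts in
#' soft X-ray stacks. The test value per pixel is by default the maximum
#' OD over all energy frames — the most conservative basis — or a single
#' frame chosen by `at_energy`.
#'
#' @param od A [to_optical_density()] result.
#' @param cutoff OD cutoff, default 1.0.
#' @param at_energy Optional single frame energy (eV) to test instead of
#'   the per-pixel maximum.
#' @return Logical rows x cols matrix: `TRUE` = retained. Pixels with
#'   invalid (zero-count) frames are excluded.
#' @export
saturation_mask <- function(od, cutoff = 1.0, at_energy = NULL) {
  stopifnot(inherits(od, "camap_od_stack"), cutoff > 0)
  test <- if (is.null(at_energy)) {
    apply(od$od, c(2, 3), max)
  } else {
    od$od[frame_index(od$energies, at_energy), , ]
  }
  keep <- !is.na(test) & test <= cutoff & !od$invalid
  keep
}

#' Automatic element-presence threshold
#'
#' The paper-style Boolean classification needs a presence threshold per
#' element map; the default rule is mean + 2 SD of the map over a
#' background region. If no region is given, background is auto-detected
#' as the pixels at or below the map's median value (valid when particles
#' cover less than half the field).
#'
#' @param map A `camap_element_map` or numeric matrix.
#' @param background Optional logical matrix marking background pixels.
#' @return Scalar threshold.
#' @export
threshold_auto <- function(map, background = NULL) {
  v <- if (inherits(map, "camap_element_map")) map$values else map
  if (is.null(background)) background <- v <= stats::median(v, na.rm = TRUE)
  bg <- v[background & !is.na(v)]
  mean(bg) + 2 * stats::sd(bg)
}

#' Boolean pixel co-localization classes
#'
#' Classifies pixels into the four co-localization classes used to subset
#' stack spectra: total C, Ca-C (no Fe), Fe-C (no Ca), and Fe-Ca-C. All
#' classes are restricted to pixels passing the saturation mask:
#' `C_total = (C > t_C) & sat`; the three subclasses further require
#' Ca and/or Fe presence as named. By construction `CaC_noFe` and
#' `FeC_noCa` are disjoint and all subclasses are nested in `C_total`.
#'
#' @param c_map,ca_map,fe_map Element maps ([element_map()]) or numeric
#'   matrices of identical shape.
#' @param thresholds Named numeric vector `c(C =, Ca =, Fe =)` of presence
#'   thresholds (all >= 0), or `"auto"` for [threshold_auto()] per map.
#' @param sat Logical saturation mask ([saturation_mask()]); `NULL` keeps
#'   every pixel.
#' @return A `camap_class_masks` with logical masks `C_total`,
#'   `CaC_noFe`, `FeC_noCa`, `FeCaC`, the thresholds used, and per-class
#'   pixel counts.
#' @export
classify_pixels <- function(c_map, ca_map, fe_map, thresholds = "auto",
                            sat = NULL) {
  vals <- lapply(list(C = c_map, Ca = ca_map, Fe = fe_map), function(m) {
    if (inherits(m, "camap_element_map")) m$values else m
  })
  dims <- lapply(vals, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("shape error: element maps must share dimensions", call. = FALSE)
  }
  if (identical(thresholds, "auto")) {
    thresholds <- vapply(vals, threshold_auto, 0)
  }
  thresholds <- thresholds[c("C", "Ca", "Fe")]
  if (any(is.na(thresholds)) || any(thresholds < 0)) {
    stop("thresholds must be named (C, Ca, Fe) and >= 0", call. = FALSE)
  }
  if (is.null(sat)) sat <- matrix(TRUE, dims[[1]][1], dims[[1]][2])
  if (!identical(dim(sat), dims[[1]])) {
    stop("shape error: saturation mask must match map shape", call. = FALSE)
  }
  has <- function(m, t) !is.na(m) & m > t
  C <- has(vals$C, thresholds["C"])
  Ca <- has(vals$Ca, thresholds["Ca"])
  Fe <- has(vals$Fe, thresholds["Fe"])
  masks <- list(
    C_total  = C & sat,
    CaC_noFe = C & sat & Ca & !Fe,
    FeC_noCa = C & sat & Fe & !Ca,
    FeCaC    = C & sat & Ca & Fe
  )
  structure(list(masks = masks, thresholds = thresholds,
                 saturation = sat,
                 pixel_counts = vapply(masks, sum, 0L)),
            class = "camap_class_masks")
}

#' @export
print.camap_class_masks <- function(x, ...) {
  cat("<camap_class_masks> pixel counts:\n")
  print(x$pixel_counts)
  invisible(x)
}

#' Mean stack spectrum over a pixel mask
#'
#' The subset spectrum of a co-localization class: at each energy, the
#' mean optical density over the masked-in pixels. An empty mask is an
#' error (an empty class is reported, never fabricated).
#'
#' @param od A [to_optical_density()] result.
#' @param mask Logical rows x cols matrix.
#' @param energy_range Optional `c(lo, hi)` (eV) restricting the output to
#'   one edge region of a multi-edge stack.
#' @param edge_label Edge label for the returned [spectrum()].
#' @return A [spectrum()]; the pixel count is in
#'   `provenance$n_pixels`.
#' @export
subset_spectrum <- function(od, mask, energy_range = NULL,
                            edge_label = "other") {
  stopifnot(inherits(od, "camap_od_stack"), is.logical(mask))
  if (!any(mask)) stop("empty-class: mask selects no pixels", call. = FALSE)
  keep_e <- if (is.null(energy_range)) {
    rep(TRUE, length(od$energies))
  } else {
    od$energies >= energy_range[1] & od$energies <= energy_range[2]
  }
  idx <- which(mask)
  n_e <- sum(keep_e)
  flat <- matrix(od$od[keep_e, , ], nrow = n_e)
  y <- rowMeans(flat[, idx, drop = FALSE])
  spectrum(od$energies[keep_e], y, edge_label = edge_label,
           provenance = list(n_pixels = length(idx)))
}

#' Pixel-wise linear correlation between two element maps
#'
#' Ordinary least squares of map `b` on map `a` over the masked pixels —
#' the micro-scale spatial-association statistic. Adjusted R^2 uses
#' `1 - (1 - R^2)(n - 1)/(n - 2)`.
#'
#' @param map_a,map_b Element maps or numeric matrices of equal shape.
#' @param mask Logical matrix of pixels to include; `NULL` = all finite.
#' @return List `slope`, `intercept`, `r2`, `adjusted_r2`, `n`.
#' @export
pixel_correlation <- function(map_a, map_b, mask = NULL) {
  a <- if (inherits(map_a, "camap_element_map")) map_a$values else map_a
  b <- if (inherits(map_b, "camap_element_map")) map_b$values else map_b
  stopifnot(identical(dim(a), dim(b)))
  ok <- is.finite(a) & is.finite(b)
  if (!is.null(mask)) ok <- ok & mask
  x <- a[ok]; y <- b[ok]
  n <- length(x)
  if (n < 3) stop("pixel_correlation needs >= 3 masked pixels", call. = FALSE)
  vx <- stats::var(x)
  if (vx == 0) stop("undefined-slope: zero variance in map_a", call. = FALSE)
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  vy <- stats::var(y)
  if (vy == 0) {
    warning("zero variance in map_b; R^2 reported as 0", call. = FALSE)
    r2 <- 0
  } else {
    r2 <- stats::cor(x, y)^2
  }
  list(slope = slope, intercept = intercept, r2 = r2,
       adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - 2), n = n)
}

#' Tricolour RGB composite of three element maps
#'
#' C in red, Ca in green, Fe in blue: each channel is min-max scaled to
#' 0-255 over the masked-in pixels (channel maxima map to 255 exactly);
#' masked-out pixels are black.
#'
#' @param c_map,ca_map,fe_map Element maps or numeric matrices.
#' @param mask Logical matrix of pixels to display; `NULL` = all.
#' @return Integer array rows x cols x 3 in 0-255.
#' @export
tricolour_export <- function(c_map, ca_map, fe_map, mask = NULL) {
  vals <- lapply(list(c_map, ca_map, fe_map), function(m) {
    if (inherits(m, "camap_element_map")) m$values else m
  })
  d <- dim(vals[[1]])
  stopifnot(all(vapply(vals, function(v) identical(dim(v), d), TRUE)))
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  out <- array(0L, dim = c(d, 3))
  for (ch in 1:3) {
    v <- vals[[ch]]
    sel <- mask & is.finite(v)
    if (any(sel)) {
      rng <- range(v[sel])
      scaled <- if (rng[2] > rng[1]) {
        (v - rng[1]) / (rng[2] - rng[1])
      } else if (rng[2] > 0) {
        v * 0 + 1            # constant positive channel: full intensity
      } else {
        v * 0                # all-zero channel stays dark
      }
      plane <- matrix(0L, d[1], d[2])
      plane[sel] <- as.integer(round(255 * scaled[sel]))
      out[, , ch] <- plane
    }
  }
  out
}

#' Integer-pixel stack alignment by cross-correlation
#'
#' Convenience aligner for stacks with frame-to-frame drift: each frame is
#' shifted by the integer offset maximizing its cross-correlation with the
#' reference frame. Stacks from the synthetic generator are already
#' aligned; real stacks are normally aligned upstream and this helper is
#' not part of the analysis contract.
#'
#' @param stack An [image_stack()].
#' @param reference Index of the reference frame (default 1).
#' @param max_shift Maximum |shift| searched per axis, pixels.
#' @return An [image_stack()] with shifted frames (edges zero-filled) and
#'   the applied shifts in `meta$alignment_shifts`.
#' @export
align_stack <- function(stack, reference = 1L, max_shift = 5L) {
  stopifnot(inherits(stack, "camap_stack"))
  ref <- stack$counts[reference, , ]
  ref0 <- ref - mean(ref)
  d <- dim(ref)
  shifts <- matrix(0L, dim(stack$counts)[1], 2)
  out <- stack$counts
  shift_mat <- function(m, dr, dc) {
    res <- matrix(0, d[1], d[2])
    r_src <- seq_len(d[1]) - dr; c_src <- seq_len(d[2]) - dc
    ok_r <- r_src >= 1 & r_src <= d[1]; ok_c <- c_src >= 1 & c_src <= d[2]
    res[which(ok_r), which(ok_c)] <- m[r_src[ok_r], c_src[ok_c]]
    res
  }
  for (j in seq_len(dim(stack$counts)[1])) {
    if (j == reference) next
    fr <- stack$counts[j, , ]
    fr0 <- fr - mean(fr)
    best <- c(0L, 0L); best_cc <- -Inf
    for (dr in -max_shift:max_shift) {
      for (dc in -max_shift:max_shift) {
        cc <- sum(shift_mat(fr0, dr, dc) * ref0)
        if (cc > best_cc) { best_cc <- cc; best <- c(dr, dc) }
      }
    }
    shifts[j, ] <- best
    out[j, , ] <- shift_mat(fr, best[1], best[2])
  }
  image_stack(stack$energies, out, stack$i0,
              meta = c(stack$meta, list(alignment_shifts = shifts)))
}
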