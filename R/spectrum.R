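#' X-ray absorption spectrum
#'
#' The basic unit of all XANES arithmetic in camap: a strictly increasing
#' energy grid (eV) with one intensity value per grid point, an edge label,
#' and free-form provenance metadata that downstream operations append to
#' (calibration shifts, normalization parameters, pixel counts).
#'
#' @param energies Numeric vector of photon energies in eV, strictly
#'   increasing.
#' @param intensities Numeric vector of the same length; all values finite.
#' @param edge_label One of `"C K"`, `"Ca K"`, `"Ca L"`, `"Fe L"`, `"other"`.
#' @param provenance Named list of metadata carried along with the spectrum.
#' @return An object of class `camap_spectrum`.
#' @examples
#' s <- spectrum(seq(280, 300, 0.5), exp(-((seq(280, 300, 0.5) - 285)^2)))
#' print(s)
#' @export
spectrum <- function(energies, intensities, edge_label = "other",
                     provenance = list()) {
  energies <- as.numeric(energies)
  intensities <- as.numeric(intensities)
  if (length(energies) != length(intensities)) {
    stop("`energies` and `intensities` must have equal length", call. = FALSE)
  }
  if (length(energies) == 0) stop("empty spectrum", call. = FALSE)
  if (any(!is.finite(energies)) || any(diff(energies) <= 0)) {
    stop("invalid-grid: `energies` must be finite and strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("`intensities` must be finite", call. = FALSE)
  }
  edge_label <- match.arg(edge_label,
                          c("other", "C K", "Ca K", "Ca L", "Fe L"))
  structure(
    list(energies = energies, intensities = intensities,
         edge_label = edge_label, provenance = provenance),
    class = "camap_spectrum"
  )
}

#' @export
print.camap_spectrum <- function(x, ...) {
  cat(sprintf("<camap_spectrum> %s edge, %d points, %.2f-%.2f eV\n",
              x$edge_label, length(x$energies),
              min(x$energies), max(x$energies)))
  if (length(x$provenance)) {
    keys <- names(x$provenance)
    cat("  provenance:", paste(keys, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.camap_spectrum <- function(x) length(x$energies)

is_spectrum <- function(x) inherits(x, "camap_spectrum")

#' Evaluate a spectrum at arbitrary energies by linear interpolation
#'
#' Piecewise-linear interpolation is used throughout camap (replicate
#' merging, grid alignment, standard resampling): it preserves two-column
#' data fidelity and cannot ring.
#'
#' @param s A [spectrum()].
#' @param energies Energies (eV) at which to evaluate; each must lie inside
#'   the spectrum's grid.
#' @return Numeric vector of interpolated intensities.
#' @export
spectrum_at <- function(s, energies) {
  stopifnot(is_spectrum(s))
  lo <- s$energies[1]; hi <- s$energies[length(s$energies)]
  if (any(energies < lo - 1e-9) || any(energies > hi + 1e-9)) {
    stop(sprintf(
      "coverage: requested energies [%g, %g] outside spectrum grid [%g, %g]",
      min(energies), max(energies), lo, hi), call. = FALSE)
  }
  stats::approx(s$energies, s$intensities, xout = energies, rule = 2)$y
}

#' Write a spectrum as two-column text
#'
#' Plain text with `#`-prefixed header lines recording the edge label and
#' any scalar provenance entries (e.g. calibration shift, normalization
#' window), followed by `energy intensity` pairs.
#'
#' @param s A [spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(is_spectrum(s))
  hdr <- c(sprintf("# edge_label: %s", s$edge_label))
  for (k in names(s$provenance)) {
    v <- s$provenance[[k]]
    if (is.atomic(v) && length(v) <= 8) {
      hdr <- c(hdr, sprintf("# %s: %s", k, paste(format(v, digits = 12),
                                                 collapse = " ")))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("# energy_eV intensity", con)
  utils::write.table(
    data.frame(e = format(s$energies, digits = 12),
               y = format(s$intensities, digits = 12)),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column text spectrum
#'
#' @param path File with optional `#` header lines and two numeric columns
#'   (energy eV, intensity).
#' @param edge_label Edge label to attach; if `NULL`, taken from an
#'   `# edge_label:` header line when present.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, edge_label = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(edge_label)) {
    m <- grep("^# edge_label:", hdr, value = TRUE)
    edge_label <- if (length(m)) trimws(sub("^# edge_label:", "", m[1])) else "other"
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  mat <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:],]+"),
                               function(x) as.numeric(x[1:2])))
  spectrum(mat[, 1], mat[, 2], edge_label = edge_label,
           provenance = list(source = path))
}

#' Read a multi-column normalized spectrum export
#'
#' Supports standard-library ingestion: a text file whose first column is
#' energy (eV) and whose remaining columns are one sample/standard each,
#' with a `#`-prefixed (or plain) header row naming the columns.
#'
#' @param path File path.
#' @param edge_label Edge label attached to every returned spectrum.
#' @return Named list of [spectrum()] objects, one per non-energy column.
#' @export
read_spectrum_table <- function(path, edge_label = "other") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  first_data <- which(!grepl("^#", lines))[1]
  header <- NULL
  if (first_data > 1) {
    header <- strsplit(trimws(sub("^#+\\s*", "", lines[first_data - 1])),
                       "[[:space:],]+")[[1]]
  }
  fields <- strsplit(trimws(lines[first_data:length(lines)]), "[[:space:],]+")
  # a non-numeric first data row is a plain column-name header
  if (any(is.na(suppressWarnings(as.numeric(fields[[1]]))))) {
    header <- fields[[1]]
    fields <- fields[-1]
  }
  mat <- do.call(rbind, lapply(fields, as.numeric))
  ncols <- ncol(mat)
  nm <- if (!is.null(header) && length(header) == ncols) {
    header[-1]
  } else {
    paste0("sample_", seq_len(ncols - 1))
  }
  out <- lapply(seq_len(ncols - 1), function(j) {
    spectrum(mat[, 1], mat[, j + 1], edge_label = edge_label,
             provenance = list(source = path, column = nm[j]))
  })
  names(out) <- nm
  out
}

# common-grid check used by LCF and factor analysis
assert_common_grid <- function(spectra, tol = 1e-9) {
  e0 <- spectra[[1]]$energies
  for (s in spectra[-1]) {
    if (length(s$energies) != length(e0) ||
        max(abs(s$energies - e0)) > tol) {
      return(FALSE)
    }
  }
  TRUE
}
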