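#' Write an image stack as a directory of per-energy TIFF images
#'
#' The on-disk stack dialect: one 16-bit greyscale TIFF per energy frame
#' (`frame_000.tif`, ...), an `energies.txt` table (frame file, energy eV),
#' an `i0.txt` with the per-energy incident intensity, and a `meta.txt`
#' with the count scale factor and any scalar metadata (seed, noise
#' model). When the stack carries generator ground truth, the label and
#' thickness maps are written as `truth_labels.csv` / `truth_thickness.csv`.
#'
#' @param stack An [image_stack()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "camap_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_e <- length(stack$energies)
  scale <- max(stack$counts) * 1.0001
  files <- sprintf("frame_%03d.tif", seq_len(n_e) - 1)
  for (j in seq_len(n_e)) {
    tiff::writeTIFF(stack$counts[j, , ] / scale, file.path(dir, files[j]),
                    bits.per.sample = 16L)
  }
  utils::write.table(data.frame(file = files, energy_eV = stack$energies),
                     file.path(dir, "energies.txt"),
                     row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(energy_eV = stack$energies, i0 = resolve_i0(stack)),
    file.path(dir, "i0.txt"), row.names = FALSE, quote = FALSE)
  meta_lines <- c(sprintf("count_scale: %.10g", scale))
  for (k in names(stack$meta)) {
    v <- stack$meta[[k]]
    if (is.atomic(v) && length(v) == 1) {
      meta_lines <- c(meta_lines, sprintf("%s: %s", k, format(v)))
    }
  }
  writeLines(meta_lines, file.path(dir, "meta.txt"))
  truth <- stack$meta$truth
  if (inherits(truth, "camap_scene")) {
    utils::write.table(truth$label_map, file.path(dir, "truth_labels.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(truth$thickness_map,
                       file.path(dir, "truth_thickness.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read an image stack from a per-energy TIFF directory
#'
#' Counterpart of [write_stack()]; also accepts externally produced
#' directories that follow the same layout (`energies.txt` naming one TIFF
#' per energy, optional `i0.txt`, optional `count_scale` in `meta.txt`).
#'
#' @param dir Stack directory.
#' @param i0 Overrides the stored I0 (scalar, vector, or region spec).
#' @return An [image_stack()].
#' @export
read_stack <- function(dir, i0 = NULL) {
  etab <- utils::read.table(file.path(dir, "energies.txt"), header = TRUE,
                            stringsAsFactors = FALSE)
  scale <- 1
  meta <- list()
  meta_path <- file.path(dir, "meta.txt")
  if (file.exists(meta_path)) {
    for (ln in readLines(meta_path)) {
      kv <- strsplit(ln, ":\\s*")[[1]]
      if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
    }
    if (!is.null(meta$count_scale)) scale <- as.numeric(meta$count_scale)
  }
  frames <- lapply(etab$file, function(f) {
    tiff::readTIFF(file.path(dir, f)) * scale
  })
  d <- dim(frames[[1]])
  counts <- array(0, dim = c(length(frames), d[1], d[2]))
  for (j in seq_along(frames)) counts[j, , ] <- frames[[j]]
  if (is.null(i0)) {
    i0_path <- file.path(dir, "i0.txt")
    i0 <- if (file.exists(i0_path)) {
      utils::read.table(i0_path, header = TRUE)$i0
    } else {
      stop("invalid-I0: no i0.txt in stack directory and no i0 given",
           call. = FALSE)
    }
  }
  image_stack(etab$energy_eV, counts, i0, meta = meta)
}

#' Write a 2-D map (element map, weight map, mask) as a 16-bit TIFF
#'
#' Values are scaled into \[0, 1\] by `scale` (default: the map maximum);
#' the scale is returned so a sidecar can record it.
#'
#' @param map Numeric or logical matrix, or a `camap_element_map`.
#' @param path Output TIFF path.
#' @param scale Value mapped to full intensity; `NULL` = map maximum.
#' @return The scale used, invisibly.
#' @export
write_map_tiff <- function(map, path, scale = NULL) {
  v <- if (inherits(map, "camap_element_map")) map$values else map
  v <- apply(v, 2, as.numeric)
  v[!is.finite(v)] <- 0
  v <- pmax(v, 0)
  if (is.null(scale)) scale <- max(v, 1e-12)
  tiff::writeTIFF(pmin(v / scale, 1), path, bits.per.sample = 16L)
  invisible(scale)
}
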