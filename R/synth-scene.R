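#' Default composition-class table for synthetic scenes
#'
#' Mass fractions of the four endmember cross-sections
#' (`C_plant`, `C_microbial`, `Ca`, `Fe`) for each particle class. Each row
#' sums to 1. Ca-bearing organic particles carry the plant-like C
#' signature and Fe-bearing ones the microbial signature, so that the two
#' co-localization classes are spectrally distinguishable — the contrast
#' the pipeline is designed to quantify.
#'
#' @return Numeric matrix, rows `CaC`, `FeC`, `FeCaC`, `Conly`.
#' @export
default_class_table <- function() {
  m <- rbind(
    CaC    = c(C_plant = 0.70, C_microbial = 0.00, Ca = 0.30, Fe = 0.00),
    FeC    = c(C_plant = 0.00, C_microbial = 0.70, Ca = 0.00, Fe = 0.30),
    FeCaC  = c(C_plant = 0.25, C_microbial = 0.25, Ca = 0.20, Fe = 0.30),
    Conly  = c(C_plant = 0.50, C_microbial = 0.50, Ca = 0.00, Fe = 0.00)
  )
  m
}

#' Log-normal pixel-thickness distribution
#'
#' Optical path factors are drawn i.i.d. per particle pixel from a
#' log-normal distribution, optionally clipped at `max`. The clip keeps a
#' controllable fraction of pixels above the optical-density saturation
#' cutoff so the saturation mask is exercised.
#'
#' @param meanlog,sdlog Log-normal parameters.
#' @param max Upper clip (same units as thickness); `Inf` disables.
#' @return A `camap_thickness_dist` object.
#' @export
thickness_dist <- function(meanlog = log(0.6), sdlog = 0.45, max = Inf) {
  stopifnot(sdlog > 0, max > 0)
  structure(list(type = "lognormal", meanlog = meanlog, sdlog = sdlog,
                 max = max), class = "camap_thickness_dist")
}

#' Analytic probability that a pixel's optical density exceeds a cutoff
#'
#' For thickness T ~ clipped log-normal and per-unit-thickness optical
#' density `od_per_unit`, returns P(T * od_per_unit > cutoff) in closed
#' form — the oracle for the saturation-mask exceedance tests.
#'
#' @param dist A [thickness_dist()].
#' @param od_per_unit Optical density per unit thickness at the test
#'   energy (e.g. the maximum of the class absorption over the stack
#'   energies).
#' @param cutoff OD cutoff (default 1.0).
#' @return Exceedance probability in \[0, 1\].
#' @export
thickness_exceedance_prob <- function(dist, od_per_unit, cutoff = 1.0) {
  stopifnot(inherits(dist, "camap_thickness_dist"), od_per_unit > 0)
  thr <- cutoff / od_per_unit
  if (dist$max <= thr) return(0)
  stats::plnorm(thr, dist$meanlog, dist$sdlog, lower.tail = FALSE)
}

#' Generate a synthetic particle scene
#'
#' Particles are axis-aligned ellipses with uniformly random centres and
#' semi-axes; overlaps are resolved by draw order (later particles
#' overwrite earlier ones). Each particle is assigned a composition class
#' by sampling `class_mix`; a `background` entry in the mix makes that
#' fraction of draws leave no particle. Thickness is drawn i.i.d. per
#' particle pixel from `thickness`.
#'
#' @param shape `c(rows, cols)` of the scene.
#' @param n_particles Number of particle draws.
#' @param class_mix Named proportions over a subset of
#'   `c("CaC", "FeC", "FeCaC", "Conly", "background")`; must sum to 1
#'   (tolerance 1e-9).
#' @param thickness A [thickness_dist()].
#' @param axis_range Ellipse semi-axis range in pixels.
#' @param class_table Class composition matrix (see
#'   [default_class_table()]); rows must sum to 1.
#' @param seed Integer seed; the scene is reproducible bit for bit.
#' @return A `camap_scene` with `label_map` (integer matrix, 0 =
#'   background), `thickness_map`, `class_table`, `classes` (level names),
#'   and the realized per-class pixel counts.
#' @export
make_scene <- function(shape, n_particles, class_mix,
                       thickness = thickness_dist(),
                       axis_range = NULL,
                       class_table = default_class_table(),
                       seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 4), n_particles >= 0)
  known <- c(rownames(class_table), "background")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% known)) {
    stop("invalid-spec: class_mix names must be in ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(class_mix) - 1) > 1e-9) {
    stop("invalid-spec: class_mix proportions must sum to 1", call. = FALSE)
  }
  if (max(abs(rowSums(class_table) - 1)) > 1e-9) {
    stop("invalid-spec: class_table rows must sum to 1", call. = FALSE)
  }
  if (is.null(axis_range)) {
    axis_range <- c(2, max(3, round(min(shape) / 10)))
  }
  set.seed(seed)
  rows <- shape[1]; cols <- shape[2]
  label <- matrix(0L, rows, cols)
  thick <- matrix(0, rows, cols)
  classes <- rownames(class_table)
  draws <- sample(names(class_mix), n_particles, replace = TRUE,
                  prob = class_mix)
  rc <- row(label); cc <- col(label)
  for (i in seq_len(n_particles)) {
    if (draws[i] == "background") next
    r0 <- stats::runif(1, 1, rows); c0 <- stats::runif(1, 1, cols)
    a <- stats::runif(1, axis_range[1], axis_range[2])
    b <- stats::runif(1, axis_range[1], axis_range[2])
    inside <- ((rc - r0) / a)^2 + ((cc - c0) / b)^2 <= 1
    if (!any(inside)) next
    label[inside] <- match(draws[i], classes)
    t_dr <- stats::rlnorm(sum(inside), thickness$meanlog, thickness$sdlog)
    thick[inside] <- pmin(t_dr, thickness$max)
  }
  thick[label == 0L] <- 0
  counts <- table(factor(label, levels = 0:length(classes),
                         labels = c("background", classes)))
  structure(list(label_map = label, thickness_map = thick,
                 class_table = class_table, classes = classes,
                 class_mix = class_mix, thickness = thickness,
                 pixel_counts = counts, particle_classes = draws,
                 seed = seed, shape = shape),
            class = "camap_scene")
}

#' @export
print.camap_scene <- function(x, ...) {
  cat(sprintf("<camap_scene> %d x %d, seed %d\n", x$shape[1], x$shape[2],
              x$seed))
  print(x$pixel_counts)
  invisible(x)
}

# per-pixel endmember mass-fraction matrix (pixels x endmembers)
scene_weights <- function(scene) {
  k <- ncol(scene$class_table)
  W <- matrix(0, length(scene$label_map), k,
              dimnames = list(NULL, colnames(scene$class_table)))
  on_part <- scene$label_map > 0L
  W[on_part, ] <- scene$class_table[scene$label_map[on_part], , drop = FALSE]
  W
}

#' Ground-truth carbon partition of a scene
#'
#' The realized fraction of total C mass (thickness times class C mass
#' fraction, summed over pixels) held by the Ca-C versus the Fe-C particle
#' class — the generator-side truth that the total-C LCF partition is
#' benchmarked against.
#'
#' @param scene A [make_scene()] result.
#' @param mask Optional logical matrix restricting the accounting to the
#'   pixels actually measured (e.g. those passing the saturation mask).
#' @return Named vector `c(FeC = , CaC = )` of percentages summing to 100.
#' @export
scene_c_partition <- function(scene, mask = NULL) {
  c_cols <- intersect(c("C_plant", "C_microbial"), colnames(scene$class_table))
  c_frac <- rowSums(scene$class_table[, c_cols, drop = FALSE])
  lab <- scene$label_map
  if (is.null(mask)) mask <- matrix(TRUE, nrow(lab), ncol(lab))
  mass <- vapply(c("FeC", "CaC"), function(cl) {
    i <- which(lab == match(cl, scene$classes) & mask)
    sum(scene$thickness_map[i]) * c_frac[cl]
  }, 0)
  100 * mass / sum(mass)
}

#' Render a transmission image stack from a scene
#'
#' Beer-Lambert forward model: at energy E and pixel p the transmitted
#' intensity is `i0_level * exp(-thickness(p) * sum_k w_k(p) mu_k(E))`,
#' with optional Poisson counting noise (default for realism) or additive
#' Gaussian noise. With `noise = "none"`, [to_optical_density()] recovers
#' the absorbance field exactly.
#'
#' @param scene A [make_scene()] result.
#' @param endmembers Named list of [spectrum()] cross-sections covering all
#'   stack energies; names must match the scene's class-table columns.
#' @param energies Stack energy list (eV); default
#'   [default_stack_energies()].
#' @param i0_level Incident intensity in counts.
#' @param noise `"none"`, `"poisson"`, or `"gaussian"`.
#' @param noise_sd Gaussian noise standard deviation (counts), used only
#'   for `noise = "gaussian"`.
#' @param seed Integer seed for the noise draw.
#' @return An [image_stack()]; the scene travels along as
#'   `meta$truth` and the noiseless absorbance as `meta` when requested.
#' @export
render_stack <- function(scene, endmembers = endmember_library(),
                         energies = default_stack_energies(),
                         i0_level = 2000, noise = c("poisson", "none", "gaussian"),
                         noise_sd = 0, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(inherits(scene, "camap_scene"))
  need <- colnames(scene$class_table)
  if (!all(need %in% names(endmembers))) {
    stop("endmembers must be named for every class-table column", call. = FALSE)
  }
  mu <- vapply(endmembers[need], spectrum_at, numeric(length(energies)),
               energies = energies)          # E x k (coverage error inside)
  W <- scene_weights(scene)                  # pixels x k
  A_px <- as.vector(scene$thickness_map) * (W %*% t(mu))  # pixels x E
  n_e <- length(energies)
  rows <- scene$shape[1]; cols <- scene$shape[2]
  counts <- array(0, dim = c(n_e, rows, cols))
  ideal <- i0_level * exp(-A_px)
  if (noise != "none") set.seed(seed)
  for (j in seq_len(n_e)) {
    frame <- ideal[, j]
    if (noise == "poisson") {
      frame <- stats::rpois(length(frame), frame)
    } else if (noise == "gaussian") {
      frame <- frame + stats::rnorm(length(frame), 0, noise_sd)
    }
    counts[j, , ] <- matrix(frame, rows, cols)
  }
  image_stack(energies, counts, i0 = i0_level,
              meta = list(truth = scene, seed = seed, noise = noise,
                          i0_level = i0_level))
}

#' Specification for a synthetic bulk soil-characterization table
#'
#' @param n_samples Number of rows (>= 3).
#' @param soc_range Soil organic carbon range, % w/w.
#' @param ca_exch_range Exchangeable-Ca range, cmol_c per kg.
#' @param target_r2 Squared SOC-Ca_exch correlation aimed for, in \[0, 1\].
#' @param noise_sd Measurement noise floor on Ca_exch (cmol_c per kg).
#' @param seed Integer seed.
#' @return A `camap_bulk_spec` object.
#' @export
bulk_table_spec <- function(n_samples = 200, soc_range = c(0.6, 4.0),
                            ca_exch_range = c(2, 10), target_r2 = 0.69,
                            noise_sd = 0, seed = 1L) {
  if (!(target_r2 >= 0 && target_r2 <= 1)) {
    stop("target_r2 must be in [0, 1]", call. = FALSE)
  }
  if (n_samples < 3) stop("n_samples must be >= 3", call. = FALSE)
  structure(list(n_samples = n_samples, soc_range = soc_range,
                 ca_exch_range = ca_exch_range, target_r2 = target_r2,
                 noise_sd = noise_sd, seed = seed),
            class = "camap_bulk_spec")
}

#' Generate a synthetic bulk soil table
#'
#' Emulates an acidic-grassland characterization table: SOC uniform over
#' its range, exchangeable Ca linearly coupled to SOC with noise scaled so
#' the expected squared correlation equals `target_r2`, pH and the other
#' exchangeable cations drawn independently in field-plausible ranges.
#' Exchangeable amounts are in cmol_c per kg. If `noise_sd` alone already
#' exceeds the noise budget implied by `target_r2`, the target is
#' unreachable: a warning is raised and the realized R^2 is reported in
#' the attribute `realized_r2` (also set on normal runs).
#'
#' @param spec A [bulk_table_spec()].
#' @return A `data.frame` with columns `sample_id`, `depth_cm`, `pH`,
#'   `SOC_pct`, `Ca_exch`, `Mg_exch`, `K_exch`, `Na_exch`, `Al_exch`.
#' @export
make_bulk_table <- function(spec = bulk_table_spec()) {
  stopifnot(inherits(spec, "camap_bulk_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  soc <- stats::runif(n, spec$soc_range[1], spec$soc_range[2])
  slope <- diff(spec$ca_exch_range) / diff(spec$soc_range)
  ca_line <- spec$ca_exch_range[1] + slope * (soc - spec$soc_range[1])
  v_sig <- slope^2 * stats::var(soc)
  if (spec$target_r2 == 0) {
    ca <- mean(spec$ca_exch_range) +
      stats::rnorm(n, 0, max(spec$noise_sd, sqrt(v_sig)))
  } else {
    v_noise <- v_sig * (1 - spec$target_r2) / spec$target_r2
    if (spec$target_r2 < 1 && spec$noise_sd^2 > v_noise) {
      warning(sprintf(
        "target_r2 %.2f unreachable with noise_sd %.3g; using noise_sd",
        spec$target_r2, spec$noise_sd), call. = FALSE)
      v_noise <- spec$noise_sd^2
    }
    ca <- ca_line + stats::rnorm(n, 0, sqrt(v_noise))
  }
  ca <- pmax(ca, 0)
  depth <- rep(c(5, 35, 65), length.out = n)
  ph <- stats::runif(n, 3.8, 5.3)
  tab <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    depth_cm = depth,
    pH = ph,
    SOC_pct = soc,
    Ca_exch = ca,
    Mg_exch = pmax(stats::rnorm(n, 1.5, 0.4), 0),
    K_exch = pmax(stats::rnorm(n, 0.5, 0.15), 0),
    Na_exch = pmax(stats::rnorm(n, 0.3, 0.1), 0),
    Al_exch = pmax(stats::rnorm(n, 0.8 - 0.3 * (ph - 4.5), 0.25), 0)
  )
  attr(tab, "realized_r2") <- stats::cor(tab$SOC_pct, tab$Ca_exch)^2
  attr(tab, "spec") <- spec
  tab
}

#' Generate a channel map coupled to a reference map at a target R-squared
#'
#' Linear response plus Gaussian noise scaled so the expected squared
#' correlation with `reference` equals `target_r2` — used to emulate
#' inter-element coupling (e.g. Mg co-deposited with Ca) in synthetic
#' micro-XRF channel sets.
#'
#' @param reference Numeric matrix (the reference element map).
#' @param target_r2 Target squared correlation in \[0, 1\].
#' @param gain Linear gain applied to the reference.
#' @param seed Integer seed.
#' @return Numeric matrix of the same shape, non-negative.
#' @export
make_coupled_channel <- function(reference, target_r2, gain = 1, seed = 1L) {
  stopifnot(is.matrix(reference), target_r2 >= 0, target_r2 <= 1)
  set.seed(seed)
  v_sig <- gain^2 * stats::var(as.vector(reference))
  y <- if (target_r2 == 0) {
    matrix(stats::rnorm(length(reference), mean(reference), sqrt(v_sig)),
           nrow(reference))
  } else {
    v_noise <- v_sig * (1 - target_r2) / target_r2
    gain * reference +
      matrix(stats::rnorm(length(reference), 0, sqrt(v_noise)),
             nrow(reference))
  }
  pmax(y, 0)
}
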