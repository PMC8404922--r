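# Physics-based phantom generator: 2D knee-like slices whose tissue
# intensities follow the classical spin-echo signal equation
# S = PD * (1 - exp(-TR/T1)) * exp(-TE/T2), so that the acquisition
# parameters (TR, TE) leave a recoverable, physically meaningful contrast
# signature in every image. Serves as the labeled stand-in for a clinical
# DICOM knee dataset and writes DICOM fixtures for the curation pipeline.

#' Acquisition condition
#'
#' The conditioning triple: repetition time (TR, ms), echo time (TE, ms) and
#' imaging orientation. Vectorized: all fields may have length > 1.
#'
#' @param tr Repetition time(s) in ms.
#' @param te Echo time(s) in ms.
#' @param orientation Orientation class(es), by default one of `"sagittal"`,
#'   `"coronal"`.
#' @param tr_bounds,te_bounds Admissible ranges (ms); defaults are the ranges
#'   the conditioning is restricted to (TR 1800-5000, TE 12-50).
#' @param classes Allowed orientation classes.
#' @return An object of class `acquisition_condition`.
#' @export
acquisition_condition <- function(tr, te, orientation,
                                  tr_bounds = c(1800, 5000),
                                  te_bounds = c(12, 50),
                                  classes = c("sagittal", "coronal")) {
  stopifnot(length(tr) == length(te), length(te) == length(orientation))
  if (any(!is.finite(tr)) || any(tr < tr_bounds[1] | tr > tr_bounds[2]))
    stop("TR must be within [", tr_bounds[1], ", ", tr_bounds[2], "] ms")
  if (any(!is.finite(te)) || any(te < te_bounds[1] | te > te_bounds[2]))
    stop("TE must be within [", te_bounds[1], ", ", te_bounds[2], "] ms")
  if (!all(orientation %in% classes))
    stop("orientation must be one of: ", paste(classes, collapse = ", "))
  structure(list(tr = as.numeric(tr), te = as.numeric(te),
                 orientation = as.character(orientation),
                 tr_bounds = tr_bounds, te_bounds = te_bounds,
                 classes = classes),
            class = "acquisition_condition")
}

#' @export
print.acquisition_condition <- function(x, ...) {
  n <- length(x$tr)
  cat("<acquisition_condition>", n, if (n == 1) "condition:" else
    "conditions; first:", sprintf("TR=%.0f ms, TE=%.0f ms, %s", x$tr[1],
                                  x$te[1], x$orientation[1]), "\n")
  invisible(x)
}

#' Spin-echo signal equation
#'
#' `S = PD * (1 - exp(-TR/T1)) * exp(-TE/T2)`: the classical intensity law of
#' a spin-echo sequence. Long TR removes T1 saturation, long TE adds T2
#' decay. Vectorized over all arguments.
#'
#' @param pd Relative proton density (>= 0).
#' @param t1,t2 Longitudinal/transverse relaxation times in ms (> 0).
#' @param tr,te Repetition/echo time in ms (`tr > 0`, `te >= 0`).
#' @return Nonnegative signal values.
#' @export
spin_echo_signal <- function(pd, t1, t2, tr, te) {
  if (any(!is.finite(pd)) || any(!is.finite(t1)) || any(!is.finite(t2)) ||
      any(pd < 0) || any(t1 <= 0) || any(t2 <= 0))
    stop("invalid tissue parameters: PD must be >= 0 and T1, T2 > 0, finite")
  if (any(!is.finite(tr)) || any(!is.finite(te)) || any(tr <= 0) ||
      any(te < 0))
    stop("invalid sequence parameters: TR > 0 and TE >= 0 required")
  pd * (1 - exp(-tr / t1)) * exp(-te / t2)
}

# Literature-plausible relaxation parameters at 1.5 T; free parameters of the
# phantom, recorded here as the configuration defaults.
default_tissues <- function() {
  data.frame(
    label = c("fat", "muscle", "bone", "cartilage", "fluid"),
    pd = c(1.00, 0.70, 0.20, 0.80, 1.00),
    t1 = c(260, 870, 250, 1060, 2850),
    t2 = c(85, 45, 10, 40, 300),
    stringsAsFactors = FALSE
  )
}

#' Tissue phantom specification
#'
#' Per-tissue proton density and relaxation times plus a jitter seed that
#' deforms the geometric layout, so distinct specs stand for distinct
#' anatomies.
#'
#' @param tissues data.frame with columns `label`, `pd`, `t1` (ms), `t2`
#'   (ms). Default: five knee tissues (fat, muscle, bone, cartilage, fluid)
#'   with literature-plausible values at 1.5 T.
#' @param jitter_seed Integer controlling the anatomical shape jitter.
#' @return An object of class `tissue_phantom_spec`.
#' @export
tissue_phantom_spec <- function(tissues = default_tissues(),
                                jitter_seed = 1L) {
  stopifnot(all(c("label", "pd", "t1", "t2") %in% names(tissues)))
  if (any(tissues$pd < 0) || any(tissues$t1 <= 0) || any(tissues$t2 <= 0))
    stop("PD must be >= 0 and T1, T2 > 0 for every tissue")
  if (any(tissues$t2 > tissues$t1))
    stop("T2 must not exceed T1 for any tissue")
  structure(list(tissues = tissues, jitter_seed = as.integer(jitter_seed)),
            class = "tissue_phantom_spec")
}

#' @export
print.tissue_phantom_spec <- function(x, ...) {
  cat("<tissue_phantom_spec>", nrow(x$tissues), "tissues (",
      paste(x$tissues$label, collapse = ", "), "), jitter seed",
      x$jitter_seed, "\n")
  invisible(x)
}

# Orientation-specific layered-ellipse templates in unit coordinates.
# Shapes are painted in order (later shapes overwrite earlier ones).
# Each row: tissue label, center (cx, cy), radii (rx, ry), rotation (rad).
phantom_template <- function(orientation) {
  if (orientation == "sagittal") {
    list(
      list("fat",       0.50, 0.50, 0.46, 0.48, 0.0),
      list("muscle",    0.52, 0.52, 0.38, 0.42, 0.1),
      list("bone",      0.42, 0.30, 0.14, 0.19, 0.3),   # femur
      list("bone",      0.56, 0.72, 0.13, 0.17, -0.2),  # tibia
      list("cartilage", 0.49, 0.50, 0.17, 0.055, 0.15),
      list("fluid",     0.66, 0.45, 0.055, 0.09, 0.0)
    )
  } else if (orientation == "coronal") {
    list(
      list("fat",       0.50, 0.50, 0.48, 0.44, 0.0),
      list("muscle",    0.50, 0.50, 0.42, 0.36, 0.0),
      list("bone",      0.50, 0.27, 0.17, 0.15, 0.0),   # distal femur
      list("bone",      0.50, 0.75, 0.16, 0.14, 0.0),   # proximal tibia
      list("cartilage", 0.50, 0.50, 0.27, 0.045, 0.0),
      list("fluid",     0.24, 0.50, 0.05, 0.10, 0.0),
      list("fluid",     0.76, 0.50, 0.05, 0.10, 0.0)
    )
  } else stop("no layout template for orientation: ", orientation)
}

# Jittered, slice-dependent geometry for one anatomy. slice_frac in [-0.5,
# 0.5] shrinks structures away from the central slice, emulating adjacent
# slices of one volume.
phantom_geometry <- function(spec, orientation, slice_frac = 0) {
  template <- phantom_template(orientation)
  set.seed(substream_seed(spec$jitter_seed, paste0("geom_", orientation)))
  scale <- 1 - 0.25 * abs(slice_frac)
  lapply(template, function(sh) {
    list(label = sh[[1]],
         cx = sh[[2]] + stats::rnorm(1, 0, 0.02),
         cy = sh[[3]] + stats::rnorm(1, 0, 0.02),
         rx = sh[[4]] * scale * stats::rnorm(1, 1, 0.06),
         ry = sh[[5]] * scale * stats::rnorm(1, 1, 0.06),
         theta = sh[[6]] + stats::rnorm(1, 0, 0.05))
  })
}

#' Tissue label map of a phantom slice
#'
#' @param spec A [tissue_phantom_spec()].
#' @param orientation Orientation class selecting the layout template.
#' @param size Image side length in pixels.
#' @param slice_frac Relative slice offset in \[-0.5, 0.5\] (0 = central).
#' @return Integer matrix (`size` x `size`): 0 = background, otherwise the
#'   row index into `spec$tissues`.
#' @export
phantom_tissue_map <- function(spec, orientation, size = 32L,
                               slice_frac = 0) {
  geom <- phantom_geometry(spec, orientation, slice_frac)
  u <- (seq_len(size) - 0.5) / size
  xg <- matrix(u, size, size)        # x varies along rows
  yg <- matrix(u, size, size, byrow = TRUE)
  lab <- matrix(0L, size, size)
  for (sh in geom) {
    dx <- xg - sh$cx
    dy <- yg - sh$cy
    xr <- dx * cos(sh$theta) + dy * sin(sh$theta)
    yr <- -dx * sin(sh$theta) + dy * cos(sh$theta)
    inside <- (xr / sh$rx)^2 + (yr / sh$ry)^2 <= 1
    lab[inside] <- match(sh$label, spec$tissues$label)
  }
  lab
}

#' Render a phantom slice
#'
#' Paints each tissue region at its spin-echo signal for the requested
#' (TR, TE), adds Rician noise (magnitude of a complex Gaussian), and
#' min-max normalizes to \[-1, 1\]. Deterministic for fixed
#' `(spec, cond, seed)`.
#'
#' @param spec A [tissue_phantom_spec()].
#' @param cond A length-1 [acquisition_condition()].
#' @param size Image side length in pixels (>= 8).
#' @param seed Integer seed for the noise draws.
#' @param noise_sd Rician noise level as a fraction of the maximal tissue
#'   signal (default 0.02; 0 disables noise).
#' @param normalize Min-max map to \[-1, 1\] (default). With
#'   `normalize = FALSE` raw signal units are returned.
#' @param slice_frac Relative slice offset, see [phantom_tissue_map()].
#' @return `size` x `size` numeric matrix with attribute `"tissue_map"`.
#' @export
render_phantom <- function(spec, cond, size = 32L, seed = 1L,
                           noise_sd = 0.02, normalize = TRUE,
                           slice_frac = 0) {
  if (size < 8) stop("invalid size: must be >= 8 pixels")
  stopifnot(inherits(spec, "tissue_phantom_spec"),
            inherits(cond, "acquisition_condition"), length(cond$tr) == 1)
  lab <- phantom_tissue_map(spec, cond$orientation, size, slice_frac)
  sig <- spin_echo_signal(spec$tissues$pd, spec$tissues$t1, spec$tissues$t2,
                          cond$tr, cond$te)
  img <- matrix(0, size, size)
  nz <- lab > 0
  img[nz] <- sig[lab[nz]]
  if (noise_sd > 0) {
    set.seed(substream_seed(seed, "rician"))
    s <- noise_sd * max(sig)
    img <- sqrt((img + stats::rnorm(size^2, 0, s))^2 +
                  stats::rnorm(size^2, 0, s)^2)
  }
  if (normalize) img <- normalize_minmax(img)
  attr(img, "tissue_map") <- lab
  img
}

normalize_minmax <- function(img) {
  rng <- range(img)
  if (rng[2] - rng[1] < .Machine$double.eps) return(img * 0)
  (img - rng[1]) / (rng[2] - rng[1]) * 2 - 1
}

#' Condition mixture
#'
#' A multimodal joint distribution over (TR, TE): a weighted mixture of
#' bivariate (independent) truncated normals, emulating the several modes
#' that distinct clinical sequence parameterizations produce.
#'
#' @param components data.frame with columns `weight`, `mean_tr`, `mean_te`,
#'   `sd_tr`, `sd_te`. Default: three modes at (2750, 28), (3800, 33) and
#'   (2200, 20) ms with weights 0.45/0.35/0.20.
#' @param tr_bounds,te_bounds Truncation bounds in ms.
#' @param orientation_prior Named probabilities of the orientation classes
#'   (default uniform over sagittal/coronal).
#' @return An object of class `condition_mixture`.
#' @export
condition_mixture <- function(components = NULL,
                              tr_bounds = c(1800, 5000),
                              te_bounds = c(12, 50),
                              orientation_prior = c(sagittal = 0.5,
                                                    coronal = 0.5)) {
  if (is.null(components))
    components <- data.frame(weight = c(0.45, 0.35, 0.20),
                             mean_tr = c(2750, 3800, 2200),
                             mean_te = c(28, 33, 20),
                             sd_tr = c(250, 300, 150),
                             sd_te = c(4, 5, 3))
  if (!nrow(components)) stop("empty mixture")
  stopifnot(all(components$weight >= 0), sum(components$weight) > 0,
            all(components$mean_tr >= tr_bounds[1] &
                  components$mean_tr <= tr_bounds[2]),
            all(components$mean_te >= te_bounds[1] &
                  components$mean_te <= te_bounds[2]),
            abs(sum(orientation_prior) - 1) < 1e-9)
  components$weight <- components$weight / sum(components$weight)
  structure(list(components = components, tr_bounds = tr_bounds,
                 te_bounds = te_bounds,
                 orientation_prior = orientation_prior),
            class = "condition_mixture")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Sample acquisition conditions from a mixture
#'
#' Draws a mixture component by weight, then TR and TE from truncated
#' normals within the bounds; the orientation is drawn from the mixture's
#' class prior.
#'
#' @param mixture A [condition_mixture()].
#' @param n Number of conditions.
#' @param seed Integer seed (same seed, same conditions).
#' @return An [acquisition_condition()] of length `n`.
#' @export
sample_condition <- function(mixture, n = 1L, seed = 1L) {
  stopifnot(inherits(mixture, "condition_mixture"), n >= 1)
  set.seed(substream_seed(seed, "cond"))
  comp <- sample.int(nrow(mixture$components), n, replace = TRUE,
                     prob = mixture$components$weight)
  cm <- mixture$components[comp, ]
  tr <- rtruncnorm1(n, cm$mean_tr, cm$sd_tr, mixture$tr_bounds[1],
                    mixture$tr_bounds[2])
  te <- rtruncnorm1(n, cm$mean_te, cm$sd_te, mixture$te_bounds[1],
                    mixture$te_bounds[2])
  ori <- sample(names(mixture$orientation_prior), n, replace = TRUE,
                prob = mixture$orientation_prior)
  acquisition_condition(tr, te, ori, tr_bounds = mixture$tr_bounds,
                        te_bounds = mixture$te_bounds,
                        classes = names(mixture$orientation_prior))
}

#' Generate a labeled phantom dataset
#'
#' Images are grouped into synthetic "studies" of `slices_per_study` slices
#' that share one anatomy (jitter seed) and one acquisition condition,
#' mirroring the central-slice structure of clinical volumes; slices within
#' a study differ by their through-plane position and noise.
#'
#' @param n Number of images (>= 1).
#' @param mixture A [condition_mixture()] to draw per-study conditions from.
#' @param seed Master seed; disjoint seeds give disjoint study IDs.
#' @param size Image side length in pixels.
#' @param slices_per_study Slices per synthetic study (default 6).
#' @param noise_sd Rician noise level, see [render_phantom()].
#' @return An object of class `phantom_dataset`: list with `images`
#'   (`size^2` x n matrix, one column per image, values in \[-1, 1\]),
#'   `meta` (data.frame: `study_id`, `series_id`, `slice_index`, `tr`, `te`,
#'   `orientation`), `size`, and `specs` (per-study phantom specs).
#' @export
make_phantom_dataset <- function(n, mixture = condition_mixture(),
                                 seed = 1L, size = 32L,
                                 slices_per_study = 6L, noise_sd = 0.02) {
  stopifnot(n >= 1)
  n_studies <- ceiling(n / slices_per_study)
  conds <- sample_condition(mixture, n_studies, seed = seed)
  set.seed(substream_seed(seed, "anatomy"))
  jitter_seeds <- sample.int(2^30, n_studies)
  images <- matrix(0, size^2, n)
  meta <- data.frame(study_id = character(n), series_id = character(n),
                     slice_index = integer(n), tr = numeric(n),
                     te = numeric(n), orientation = character(n),
                     stringsAsFactors = FALSE)
  specs <- vector("list", n_studies)
  sf <- if (slices_per_study == 1) 0 else
    seq(-0.4, 0.4, length.out = slices_per_study)
  i <- 0L
  for (st in seq_len(n_studies)) {
    spec <- tissue_phantom_spec(jitter_seed = jitter_seeds[st])
    specs[[st]] <- spec
    cond <- acquisition_condition(conds$tr[st], conds$te[st],
                                  conds$orientation[st],
                                  tr_bounds = mixture$tr_bounds,
                                  te_bounds = mixture$te_bounds,
                                  classes = names(mixture$orientation_prior))
    study_id <- sprintf("1.2.826.0.1.3680043.9999.%d.%d", seed, st)
    for (sl in seq_len(slices_per_study)) {
      i <- i + 1L
      if (i > n) break
      img <- render_phantom(spec, cond, size = size,
                            seed = substream_seed(seed, sprintf("n%d", i)),
                            noise_sd = noise_sd, slice_frac = sf[sl])
      images[, i] <- as.vector(img)
      meta$study_id[i] <- study_id
      meta$series_id[i] <- paste0(study_id, ".1")
      meta$slice_index[i] <- sl - 1L
      meta$tr[i] <- cond$tr
      meta$te[i] <- cond$te
      meta$orientation[i] <- cond$orientation
    }
  }
  structure(list(images = images, meta = meta, size = size, specs = specs,
                 mixture = mixture),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat("<phantom_dataset>", ncol(x$images), "images (", x$size, "x", x$size,
      "px ) in", length(unique(x$meta$study_id)), "studies\n")
  invisible(x)
}

#' Write a phantom dataset as DICOM fixtures
#'
#' One DICOM file per slice, with TR, TE, orientation, field strength,
#' manufacturer, receive-coil name, fat-saturation flag and study/series
#' identifiers populated. A configurable fraction of files omits the
#' manufacturer attribute (so curation must fall back to coil-based vendor
#' inference).
#'
#' @param dataset A [make_phantom_dataset()] result.
#' @param dir Output directory (created if needed).
#' @param manufacturer Manufacturer string.
#' @param coil_name Receive-coil name (the default carries the vendor name,
#'   supporting coil-based inference).
#' @param field_strength Field strength in tesla.
#' @param missing_manufacturer_fraction Fraction of files written without
#'   the manufacturer attribute.
#' @param fat_sat Logical vector (recycled) marking fat-saturated slices.
#' @param seed Seed for choosing which files omit the manufacturer.
#' @return Character vector of file paths (one per slice), invisibly; a
#'   `manifest.csv` (path, study, series, slice, TR, TE, orientation) is
#'   written alongside.
#' @export
write_dicom_fixtures <- function(dataset, dir, manufacturer = "SIEMENS",
                                 coil_name = "Tx_Rx_Knee_Siemens",
                                 field_strength = 1.5,
                                 missing_manufacturer_fraction = 0,
                                 fat_sat = FALSE, seed = 1L) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  n <- ncol(dataset$images)
  fat_sat <- rep_len(fat_sat, n)
  set.seed(substream_seed(seed, "missing_mfr"))
  n_missing <- round(missing_manufacturer_fraction * n)
  missing <- rep(FALSE, n)
  if (n_missing > 0) missing[sample.int(n, n_missing)] <- TRUE
  paths <- character(n)
  size <- dataset$size
  for (i in seq_len(n)) {
    m <- dataset$meta[i, ]
    paths[i] <- file.path(dir, sprintf("img%05d.dcm", i))
    dcm_write(paths[i],
              pixels = matrix(dataset$images[, i], size, size),
              tr = m$tr, te = m$te, orientation = m$orientation,
              field_strength = field_strength,
              manufacturer = if (missing[i]) NA_character_ else manufacturer,
              coil_name = coil_name, fat_sat = fat_sat[i],
              study_uid = m$study_id, series_uid = m$series_id,
              instance = m$slice_index + 1L)
  }
  manifest <- cbind(data.frame(path = paths, stringsAsFactors = FALSE),
                    dataset$meta)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(paths)
}

#' Write a DICOM fixture with planted curation violations
#'
#' Builds `n_series` single-condition series and plants four disjoint groups
#' of violations: TR below the admissible range, TE above the cap,
#' fat-saturated series, and series whose manufacturer is missing and whose
#' coil name maps to no vendor. All remaining series pass the default
#' filters.
#'
#' @param dir Output directory.
#' @param n_series Total series count.
#' @param n_tr_low,n_te_high,n_fat_sat,n_bad_vendor Sizes of the violation
#'   groups (assigned to distinct series, in this order).
#' @param slices_per_series Slices per series.
#' @param size Image side length in pixels.
#' @param seed Master seed.
#' @return data.frame describing each series (`series_uid`, `study_uid`,
#'   `violation` in `none/tr_range/te_max/fat_sat/manufacturer`), invisibly;
#'   files are written under `dir`.
#' @export
make_curation_fixture <- function(dir, n_series = 120L, n_tr_low = 10L,
                                  n_te_high = 10L, n_fat_sat = 10L,
                                  n_bad_vendor = 10L,
                                  slices_per_series = 3L, size = 16L,
                                  seed = 1L) {
  stopifnot(n_tr_low + n_te_high + n_fat_sat + n_bad_vendor <= n_series)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  violation <- rep("none", n_series)
  violation[seq_len(n_tr_low)] <- "tr_range"
  violation[n_tr_low + seq_len(n_te_high)] <- "te_max"
  violation[n_tr_low + n_te_high + seq_len(n_fat_sat)] <- "fat_sat"
  violation[n_tr_low + n_te_high + n_fat_sat + seq_len(n_bad_vendor)] <-
    "manufacturer"
  mixture <- condition_mixture()
  conds <- sample_condition(mixture, n_series, seed = seed)
  set.seed(substream_seed(seed, "fixture"))
  img <- matrix(stats::runif(size^2, -1, 1), size, size)
  rows <- vector("list", n_series)
  for (i in seq_len(n_series)) {
    study_uid <- sprintf("1.2.826.0.1.3680043.9998.%d.%d", seed, i)
    series_uid <- paste0(study_uid, ".1")
    tr <- conds$tr[i]; te <- conds$te[i]
    fat <- FALSE
    mfr <- "SIEMENS"
    coil <- "Tx_Rx_Knee_Siemens"
    switch(violation[i],
           tr_range = { tr <- 1500 },
           te_high = ,
           te_max = { te <- 60 },
           fat_sat = { fat <- TRUE },
           manufacturer = { mfr <- NA_character_; coil <- "GENERIC_COIL_X" },
           NULL)
    for (sl in seq_len(slices_per_series)) {
      dcm_write(file.path(dir, sprintf("s%04d_i%02d.dcm", i, sl)),
                pixels = img, tr = tr, te = te,
                orientation = conds$orientation[i], field_strength = 1.5,
                manufacturer = mfr, coil_name = coil, fat_sat = fat,
                study_uid = study_uid, series_uid = series_uid,
                instance = sl)
    }
    rows[[i]] <- data.frame(series_uid = series_uid, study_uid = study_uid,
                            violation = violation[i],
                            stringsAsFactors = FALSE)
  }
  invisible(do.call(rbind, rows))
}

#' Export phantom images as PNG
#'
#' @param images Matrix (pixels x n) or a single image matrix.
#' @param size Image side length (needed for the matrix form).
#' @param path Output PNG path (a montage with up to 8 columns).
#' @return `path`, invisibly.
#' @export
write_phantom_png <- function(images, size, path) {
  if (is.matrix(images) && nrow(images) != size^2 && ncol(images) == nrow(images))
    images <- matrix(as.vector(images), ncol = 1)
  n <- ncol(images)
  ncols <- min(8L, n)
  nrows <- ceiling(n / ncols)
  canvas <- matrix(0, nrows * size, ncols * size)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% ncols
    cc <- (i - 1) %% ncols
    canvas[r * size + seq_len(size), cc * size + seq_len(size)] <-
      matrix(images[, i], size, size)
  }
  canvas <- (canvas + 1) / 2
  grDevices::png(path, width = ncol(canvas), height = nrow(canvas))
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(t(canvas[nrow(canvas):1, ]), col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, useRaster = TRUE)
  grDevices::dev.off()
  invisible(path)
}
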