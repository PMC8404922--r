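# DICOM-header dataset curation: vendor resolution (with coil-based
# inference), header filtering with reason codes, central-slice selection,
# bilinear resizing with [-1, 1] intensity normalization, and a
# study-level train/validation/test split.

#' Curation configuration
#'
#' @param tr_range Admissible TR range in ms, inclusive (default
#'   `c(1800, 5000)`).
#' @param te_max Upper TE limit in ms, inclusive (default 50).
#' @param required_field_strength Field strength in tesla (default 1.5).
#' @param allowed_manufacturers Vendor strings that pass the filter
#'   (matched case-insensitively as substrings, so "Siemens Healthineers"
#'   passes for "SIEMENS").
#' @param coil_map Named character vector mapping lowercase coil-name
#'   substrings to vendors, used when the manufacturer attribute is missing.
#' @param fat_sat_keywords Scan-option tokens marking fat saturation.
#' @param central_k Number of central slices retained per series (default 6).
#' @param target_size Output resolution in pixels (default 256).
#' @param val_images,test_images Image budgets of the validation and test
#'   splits.
#' @param split_seed Seed of the study-level shuffle.
#' @return An object of class `curation_config`.
#' @export
curation_config <- function(tr_range = c(1800, 5000), te_max = 50,
                            required_field_strength = 1.5,
                            allowed_manufacturers = "SIEMENS",
                            coil_map = c(siemens = "SIEMENS", ge = "GE",
                                         philips = "PHILIPS"),
                            fat_sat_keywords = c("FS", "FATSAT", "SPIR",
                                                 "SPAIR"),
                            central_k = 6L, target_size = 256L,
                            val_images = 2000L, test_images = 2000L,
                            split_seed = 1L) {
  stopifnot(tr_range[1] < tr_range[2], central_k >= 1, target_size >= 8)
  structure(list(tr_range = tr_range, te_max = te_max,
                 required_field_strength = required_field_strength,
                 allowed_manufacturers = allowed_manufacturers,
                 coil_map = coil_map, fat_sat_keywords = fat_sat_keywords,
                 central_k = as.integer(central_k),
                 target_size = as.integer(target_size),
                 val_images = as.integer(val_images),
                 test_images = as.integer(test_images),
                 split_seed = as.integer(split_seed)),
            class = "curation_config")
}

#' Series header
#'
#' A light container for the per-series DICOM header fields the filters act
#' on.
#'
#' @param tr,te TR/TE in ms (`NA` for malformed values).
#' @param field_strength Field strength in tesla.
#' @param manufacturer,coil_name Optional strings (`NA` when absent).
#' @param fat_saturated Logical flag.
#' @param orientation Orientation class.
#' @param study_id,series_id Identifiers (`study_id` must be nonempty).
#' @param n_slices Slice count of the series.
#' @return An object of class `series_header`.
#' @export
series_header <- function(tr, te, field_strength = 1.5,
                          manufacturer = NA_character_,
                          coil_name = NA_character_, fat_saturated = FALSE,
                          orientation = "sagittal", study_id = "S1",
                          series_id = "S1.1", n_slices = 1L) {
  if (!nzchar(study_id)) stop("study_id must be nonempty")
  structure(list(tr = tr, te = te, field_strength = field_strength,
                 manufacturer = manufacturer, coil_name = coil_name,
                 fat_saturated = fat_saturated, orientation = orientation,
                 study_id = study_id, series_id = series_id,
                 n_slices = as.integer(n_slices)),
            class = "series_header")
}

#' Resolve the manufacturer of a series
#'
#' Returns the explicit manufacturer when present; otherwise infers the
#' vendor from the receive-coil name via the configured substring map;
#' otherwise `NA` (and the series will fail the manufacturer filter).
#'
#' @param header A [series_header()].
#' @param cfg A [curation_config()].
#' @return Vendor string or `NA_character_`.
#' @export
resolve_manufacturer <- function(header, cfg = curation_config()) {
  if (!is.na(header$manufacturer) && nzchar(header$manufacturer))
    return(header$manufacturer)
  if (!is.na(header$coil_name)) {
    tokens <- strsplit(tolower(header$coil_name), "[^a-z0-9]+")[[1]]
    for (pat in names(cfg$coil_map)) {
      if (tolower(pat) %in% tokens) return(unname(cfg$coil_map[[pat]]))
    }
  }
  NA_character_
}

# Fat-saturation detection from scan-option tokens (DICOM dialects vary; the
# keyword list is configurable).
detect_fat_sat <- function(scan_options, cfg) {
  if (is.na(scan_options) || !nzchar(scan_options)) return(FALSE)
  tokens <- toupper(strsplit(scan_options, "[\\\\ ,;]+")[[1]])
  any(tokens %in% toupper(cfg$fat_sat_keywords))
}

#' Header filter
#'
#' A series passes iff TR lies within the admissible range (inclusive), TE
#' does not exceed the cap (inclusive), it is not fat-saturated, the field
#' strength matches, and the resolved manufacturer is allowed. The reason
#' code names the first failing rule; malformed numeric headers are excluded
#' (reason `"malformed"`), never an error.
#'
#' @param header A [series_header()].
#' @param cfg A [curation_config()].
#' @return List with `pass` (logical) and `reason` (`NA` when passing, else
#'   one of `malformed`, `tr_range`, `te_max`, `fat_sat`, `field_strength`,
#'   `manufacturer`).
#' @export
passes_filters <- function(header, cfg = curation_config()) {
  fail <- function(reason) list(pass = FALSE, reason = reason)
  if (is.na(header$tr) || is.na(header$te) || is.na(header$field_strength))
    return(fail("malformed"))
  if (header$tr < cfg$tr_range[1] || header$tr > cfg$tr_range[2])
    return(fail("tr_range"))
  if (header$te > cfg$te_max) return(fail("te_max"))
  if (isTRUE(header$fat_saturated)) return(fail("fat_sat"))
  if (abs(header$field_strength - cfg$required_field_strength) > 1e-6)
    return(fail("field_strength"))
  mfr <- resolve_manufacturer(header, cfg)
  ok <- !is.na(mfr) && any(vapply(cfg$allowed_manufacturers, function(a)
    grepl(tolower(a), tolower(mfr), fixed = TRUE), logical(1)))
  if (!ok) return(fail("manufacturer"))
  list(pass = TRUE, reason = NA_character_)
}

#' Central slice indices
#'
#' The `k` contiguous zero-based slice positions centered in
#' `0 .. n_slices - 1`; all positions when `n_slices <= k`. For an odd
#' remainder the extra slice is dropped from the end of the stack.
#'
#' @param n_slices Slice count (>= 1).
#' @param k Number of central slices to keep (>= 1).
#' @return Integer vector of zero-based slice indices.
#' @export
central_slice_indices <- function(n_slices, k) {
  stopifnot(n_slices >= 1, k >= 1)
  if (n_slices <= k) return(seq_len(n_slices) - 1L)
  start <- (n_slices - k) %/% 2L
  seq.int(start, start + k - 1L)
}

#' Preprocess one image
#'
#' Bilinear resize to `target_size` x `target_size` followed by per-image
#' min-max normalization to \[-1, 1\]; constant images map to all zeros.
#'
#' @param img Nonempty numeric matrix with finite entries.
#' @param target_size Output side length in pixels.
#' @return `target_size` x `target_size` matrix in \[-1, 1\].
#' @export
preprocess_image <- function(img, target_size) {
  stopifnot(is.matrix(img), length(img) > 0, target_size >= 8)
  if (any(!is.finite(img))) stop("non-finite pixel values")
  res <- EBImage::resize(EBImage::Image(img), w = target_size,
                         h = target_size, filter = "bilinear")
  normalize_minmax(EBImage::imageData(res))
}

#' Study-level split
#'
#' Shuffles the study IDs with the configured seed, then fills the
#' validation and test splits greedily with whole studies until each reaches
#' its image budget (the first study crossing a budget completes that
#' split); all remaining studies form the training split. No study appears
#' in two splits.
#'
#' @param manifest data.frame with one row per image and a `study_id`
#'   column.
#' @param cfg A [curation_config()] supplying `val_images`, `test_images`
#'   and `split_seed`.
#' @return Named list of manifests: `train`, `validation`, `test`.
#' @export
split_by_study <- function(manifest, cfg = curation_config()) {
  stopifnot("study_id" %in% names(manifest))
  if (nrow(manifest) < cfg$val_images + cfg$test_images)
    stop("dataset smaller than the validation+test budgets")
  set.seed(cfg$split_seed)
  studies <- sample(unique(manifest$study_id))
  counts <- table(manifest$study_id)[studies]
  assign_split <- rep("train", length(studies))
  cum <- 0L
  i <- 1L
  for (budget_name in c("validation", "test")) {
    budget <- if (budget_name == "validation") cfg$val_images else
      cfg$test_images
    got <- 0L
    while (got < budget && i <= length(studies)) {
      assign_split[i] <- budget_name
      got <- got + counts[[i]]
      i <- i + 1L
    }
    if (got < budget) stop("not enough studies to fill the ", budget_name,
                           " split")
  }
  split_of <- stats::setNames(assign_split, studies)
  out <- split(manifest, split_of[manifest$study_id])
  list(train = out[["train"]], validation = out[["validation"]],
       test = out[["test"]])
}

#' Curate a directory of DICOM files
#'
#' Implements the full dataset construction: reads every `.dcm` file, groups
#' slices into series, applies the header filters (with coil-based vendor
#' inference), keeps the `central_k` central slices per surviving series,
#' and splits the result by study. Writes per-split CSV manifests and a JSON
#' curation report when `out_dir` is given.
#'
#' @param input_dir Directory tree containing DICOM files.
#' @param cfg A [curation_config()].
#' @param out_dir Optional output directory for `train.csv`,
#'   `validation.csv`, `test.csv` and `curation_report.json`.
#' @param split Perform the study-level split (disable for fixtures smaller
#'   than the split budgets).
#' @return List with `manifest` (surviving images: path, study, series,
#'   slice index, TR, TE, orientation), `splits` (when `split = TRUE`), and
#'   `report` (counts per exclusion reason and totals).
#' @export
curate_directory <- function(input_dir, cfg = curation_config(),
                             out_dir = NULL, split = TRUE) {
  files <- list.files(input_dir, pattern = "\\.dcm$", recursive = TRUE,
                      full.names = TRUE)
  files <- setdiff(files, files[basename(files) == "manifest.csv"])
  if (!length(files)) stop("no DICOM files under ", input_dir)
  hdr <- lapply(files, dcm_read, pixels = FALSE)
  slices <- data.frame(
    path = files,
    study_id = vapply(hdr, `[[`, "", "study_uid"),
    series_id = vapply(hdr, `[[`, "", "series_uid"),
    instance = vapply(hdr, function(h) h$instance %||% NA_integer_,
                      integer(1)),
    tr = vapply(hdr, `[[`, 0, "tr"),
    te = vapply(hdr, `[[`, 0, "te"),
    orientation = vapply(hdr, `[[`, "", "orientation"),
    stringsAsFactors = FALSE)
  series_ids <- unique(slices$series_id)
  reasons <- character(0)
  keep_rows <- list()
  for (sid in series_ids) {
    rows <- which(slices$series_id == sid)
    first <- hdr[[rows[1]]]
    h <- series_header(tr = first$tr, te = first$te,
                       field_strength = first$field_strength,
                       manufacturer = first$manufacturer,
                       coil_name = first$coil_name,
                       fat_saturated = detect_fat_sat(first$scan_options,
                                                      cfg),
                       orientation = first$orientation,
                       study_id = first$study_uid, series_id = sid,
                       n_slices = length(rows))
    verdict <- passes_filters(h, cfg)
    if (!verdict$pass) {
      reasons <- c(reasons, verdict$reason)
      next
    }
    ord <- rows[order(slices$instance[rows])]
    central <- central_slice_indices(length(ord), cfg$central_k) + 1L
    sel <- ord[central]
    keep_rows[[sid]] <- data.frame(
      path = slices$path[sel], study_id = slices$study_id[sel],
      series_id = sid,
      slice_index = central_slice_indices(length(ord), cfg$central_k),
      tr = slices$tr[sel], te = slices$te[sel],
      orientation = slices$orientation[sel], stringsAsFactors = FALSE)
  }
  manifest <- if (length(keep_rows)) do.call(rbind, keep_rows) else
    data.frame()
  rownames(manifest) <- NULL
  report <- list(
    n_files = length(files),
    n_series = length(series_ids),
    n_series_kept = length(keep_rows),
    n_images_kept = nrow(manifest),
    exclusions = as.list(table(factor(reasons, levels = c(
      "malformed", "tr_range", "te_max", "fat_sat", "field_strength",
      "manufacturer")))))
  splits <- NULL
  if (split && nrow(manifest)) splits <- split_by_study(manifest, cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(splits)) {
      for (nm in names(splits)) {
        if (!is.null(splits[[nm]]))
          utils::write.csv(splits[[nm]],
                           file.path(out_dir, paste0(nm, ".csv")),
                           row.names = FALSE)
      }
    } else if (nrow(manifest)) {
      utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "curation_report.json"),
                         auto_unbox = TRUE)
  }
  list(manifest = manifest, splits = splits, report = report)
}

#' Load and preprocess curated images
#'
#' Reads the pixel data of every manifest row and applies
#' [preprocess_image()].
#'
#' @param manifest A manifest data.frame with a `path` column.
#' @param target_size Output resolution in pixels.
#' @return Matrix (`target_size^2` x n), one column per image.
#' @export
load_curated_images <- function(manifest, target_size) {
  out <- matrix(0, target_size^2, nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    d <- dcm_read(manifest$path[i], pixels = TRUE)
    out[, i] <- as.vector(preprocess_image(d$pixels, target_size))
  }
  out
}
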