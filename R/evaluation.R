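# Evaluation: conditioning-fidelity metrics (AC-recovered TR/TE/orientation
# against the intended values), acquisition-parameter interpolation grids for
# a single latent vector, and the bias-corrected visual Turing test harness
# (balanced 3x2 grids, forced-balance answers, confusion/accuracy/
# inter-reader-agreement scoring).

#' Conditioning-fidelity metrics
#'
#' Runs the auxiliary classifier over labeled images (real, or generated at
#' requested conditions), decodes its outputs to physical units and reports
#' the mean absolute error of TR and TE in ms and the orientation accuracy
#' in percent.
#'
#' @param images Image batch matrix (pixels x n), or a generator function
#'   `function(conds) -> image batch` (e.g. a closure around
#'   [generate_images()] or an oracle renderer).
#' @param conds The intended conditions (`acquisition_condition` or
#'   data.frame with `tr`, `te`, `orientation`).
#' @param ac A trained AC.
#' @param codec A [condition_codec()].
#' @param source Label recorded in the report (`"real_test"` or
#'   `"synthetic"`).
#' @param batch_size Evaluation minibatch size.
#' @return An object of class `conditioning_report`: `mae_tr` (ms), `mae_te`
#'   (ms), `orientation_accuracy` (percent), `n`, `source`, plus the
#'   per-image predictions in `$predictions`.
#' @export
conditioning_metrics <- function(images, conds, ac, codec,
                                 source = c("real_test", "synthetic"),
                                 batch_size = 256L) {
  source <- match.arg(source)
  df <- as_condition_df(conds)
  if (is.function(images)) images <- images(conds)
  n <- ncol(images)
  if (!n || n != nrow(df)) stop("need n >= 1 images matching the conditions")
  vm <- ac_validation_metrics(ac, images, df, codec, batch_size)
  pred <- local({
    out <- ac_forward(ac, images)
    decode_condition(rbind(out$tr, out$te, out$orient), codec)
  })
  structure(list(mae_tr = vm$mae_tr, mae_te = vm$mae_te,
                 orientation_accuracy = vm$orientation_accuracy, n = n,
                 source = source, predictions = pred),
            class = "conditioning_report")
}

#' @export
print.conditioning_report <- function(x, ...) {
  cat(sprintf(
    "<conditioning_report> %s (n = %d): MAE(TR) %.1f ms, MAE(TE) %.2f ms, orientation %.1f%%\n",
    x$source, x$n, x$mae_tr, x$mae_te, x$orientation_accuracy))
  invisible(x)
}

#' Acquisition-parameter interpolation grid
#'
#' Reconstructs a single latent vector at every combination of the requested
#' TR and TE values, annotating each panel with the acquisition parameters
#' the AC reads back from the generated image.
#'
#' @param gen A trained generator.
#' @param z Latent vector (length `latent_dim`); the same `z` is used for
#'   every panel.
#' @param tr_values,te_values Nonempty vectors of requested values (ms),
#'   within the codec ranges.
#' @param orientation Orientation class of all panels.
#' @param ac A trained AC.
#' @param codec A [condition_codec()].
#' @param png_path,csv_path Optional export paths (PNG montage; CSV of
#'   intended vs AC-read values).
#' @return List with `images` (pixels x panels, TE varying fastest) and
#'   `table` (data.frame: panel, intended and AC-read TR/TE).
#' @export
interpolation_grid <- function(gen, z, tr_values, te_values,
                               orientation = "sagittal", ac, codec,
                               png_path = NULL, csv_path = NULL) {
  if (!length(tr_values) || !length(te_values))
    stop("tr_values and te_values must be nonempty")
  grid <- expand.grid(te = te_values, tr = tr_values)
  conds <- data.frame(tr = grid$tr, te = grid$te, orientation = orientation)
  target <- encode_condition(conds, codec)  # errors on out-of-range values
  n <- nrow(grid)
  zmat <- matrix(rep(z, n), length(z), n)
  images <- generator_forward(gen, zmat, target)$y
  out <- ac_forward(ac, images)
  read <- decode_condition(rbind(out$tr, out$te, out$orient), codec)
  tab <- data.frame(panel = seq_len(n), tr_intended = grid$tr,
                    te_intended = grid$te, tr_read = read$tr,
                    te_read = read$te, orientation_read = read$orientation)
  if (!is.null(png_path))
    write_phantom_png(images, sqrt(nrow(images)), png_path)
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  list(images = images, table = tab)
}

#' Build a visual Turing test session
#'
#' Arranges real and synthetic images into 3 x 2 grids, each holding exactly
#' three real and three synthetic images in seeded random cell order. The
#' order is fixed once, so every rater sees the same session. Only TR/TE
#' metadata is attached for display.
#'
#' @param real_images,synthetic_images Image batch matrices (at least
#'   `3 * n_grids` columns each).
#' @param n_grids Number of grids.
#' @param metadata Optional data.frame with `tr`, `te` per image
#'   (real first, then synthetic) to display alongside the cells.
#' @param seed Session seed.
#' @return An object of class `turing_session`: `cells` data.frame with
#'   `grid`, `cell` (1..6), `truth` (`real`/`synthetic`), `image_index`
#'   (column in the respective source matrix), display `tr`/`te`; plus the
#'   images.
#' @export
build_turing_session <- function(real_images, synthetic_images, n_grids,
                                 metadata = NULL, seed = 1L) {
  need <- 3L * n_grids
  if (ncol(real_images) < need || ncol(synthetic_images) < need)
    stop("insufficient images: need at least ", need, " per class")
  set.seed(substream_seed(seed, "turing"))
  real_pick <- sample.int(ncol(real_images), need)
  syn_pick <- sample.int(ncol(synthetic_images), need)
  rows <- vector("list", n_grids)
  for (g in seq_len(n_grids)) {
    truth <- sample(rep(c("real", "synthetic"), each = 3L))
    idx_r <- real_pick[(g - 1L) * 3L + 1:3]
    idx_s <- syn_pick[(g - 1L) * 3L + 1:3]
    image_index <- integer(6)
    image_index[truth == "real"] <- idx_r
    image_index[truth == "synthetic"] <- idx_s
    rows[[g]] <- data.frame(grid = g, cell = 1:6, truth = truth,
                            image_index = image_index,
                            stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, rows)
  if (!is.null(metadata)) {
    n_real <- ncol(real_images)
    midx <- ifelse(cells$truth == "real", cells$image_index,
                   n_real + cells$image_index)
    cells$tr <- metadata$tr[midx]
    cells$te <- metadata$te[midx]
  }
  structure(list(cells = cells, n_grids = n_grids,
                 real_images = real_images,
                 synthetic_images = synthetic_images),
            class = "turing_session")
}

#' @export
print.turing_session <- function(x, ...) {
  cat("<turing_session>", x$n_grids, "grids of 3x2 cells (3 real + 3",
      "synthetic each),", nrow(x$cells), "cells total\n")
  invisible(x)
}

validate_turing_answers <- function(session, answers) {
  stopifnot(all(c("rater", "grid", "cell", "label") %in% names(answers)))
  if (!all(answers$label %in% c("real", "synthetic")))
    stop("labels must be 'real' or 'synthetic'")
  for (r in unique(answers$rater)) {
    a <- answers[answers$rater == r, ]
    if (nrow(a) != nrow(session$cells) ||
        anyDuplicated(a[, c("grid", "cell")]))
      stop("rater ", r, " must answer every cell exactly once")
    per_grid <- tapply(a$label == "real", a$grid, sum)
    bad <- names(per_grid)[per_grid != 3L]
    if (length(bad))
      stop("unbalanced answer in grid ", bad[1], " (rater ", r,
           "): must mark the same number of images as real and synthetic ",
           "within each grid")
  }
  invisible(TRUE)
}

#' Score a visual Turing test session
#'
#' Checks the balance constraint (each answered grid must mark exactly three
#' cells real and three synthetic), then reports per-rater confusion
#' matrices, accuracies and the inter-reader agreement: the number of images
#' all raters labeled correctly, split by true class.
#'
#' @param session A [build_turing_session()].
#' @param answers data.frame with columns `rater`, `grid`, `cell`, `label`
#'   (`"real"`/`"synthetic"`), e.g. read from a CSV answer sheet.
#' @return An object of class `turing_scores`: per-rater list with
#'   `confusion` (2 x 2 matrix, predicted x true), `accuracy_pct` (rounded
#'   to nearest integer), `accuracy_raw` (fraction); plus `ira`, the
#'   per-true-class counts of images every rater got right.
#' @export
score_turing_session <- function(session, answers) {
  validate_turing_answers(session, answers)
  truth <- session$cells
  raters <- unique(answers$rater)
  per_rater <- list()
  correct_mat <- NULL
  for (r in raters) {
    a <- merge(answers[answers$rater == r, ], truth,
               by = c("grid", "cell"), sort = TRUE)
    cm <- table(predicted = factor(a$label, c("real", "synthetic")),
                true = factor(a$truth, c("real", "synthetic")))
    acc <- sum(diag(cm)) / sum(cm)
    per_rater[[as.character(r)]] <- list(
      confusion = unclass(cm), accuracy_raw = acc,
      accuracy_pct = round(100 * acc))
    ord <- order(a$grid, a$cell)
    correct <- (a$label == a$truth)[ord]
    correct_mat <- cbind(correct_mat, correct)
  }
  ord_truth <- truth$truth[order(truth$grid, truth$cell)]
  all_correct <- rowSums(correct_mat) == ncol(correct_mat)
  ira <- c(real = sum(all_correct & ord_truth == "real"),
           synthetic = sum(all_correct & ord_truth == "synthetic"))
  structure(list(raters = per_rater, ira = ira,
                 n_cells = nrow(truth)), class = "turing_scores")
}

#' @export
print.turing_scores <- function(x, ...) {
  for (r in names(x$raters)) {
    cat("Rater", r, ": accuracy", x$raters[[r]]$accuracy_pct, "% (",
        sprintf("%.2f%%", 100 * x$raters[[r]]$accuracy_raw), "raw )\n")
    print(x$raters[[r]]$confusion)
  }
  cat("Inter-reader agreement (all raters correct): real =", x$ira["real"],
      ", synthetic =", x$ira["synthetic"], "\n")
  invisible(x)
}

#' Scripted rater with prescribed per-class correctness
#'
#' Produces a balanced answer sheet in which the rater labels exactly
#' `n_correct_real` of the true-real cells and `n_correct_syn` of the
#' true-synthetic cells correctly — the per-grid balance constraint is kept
#' by mislabeling real and synthetic cells in pairs within a grid. Used to
#' replay published confusion counts through the scorer and to test it
#' without human raters.
#'
#' @param session A [build_turing_session()].
#' @param rater Rater identifier.
#' @param n_correct_real,n_correct_syn Number of correctly labeled cells per
#'   true class; their difference must be attainable under the balance
#'   constraint (equal per-class totals imply
#'   `n_correct_real - n_correct_syn` is realized grid by grid, so equal
#'   values are always attainable).
#' @param seed Seed choosing which cells are mislabeled.
#' @return data.frame answer sheet (`rater`, `grid`, `cell`, `label`).
#' @export
simulate_turing_answers <- function(session, rater, n_correct_real,
                                    n_correct_syn, seed = 1L) {
  cells <- session$cells
  n_per_class <- sum(cells$truth == "real")
  stopifnot(n_correct_real <= n_per_class, n_correct_syn <= n_per_class)
  n_err_real <- n_per_class - n_correct_real   # real cells marked synthetic
  n_err_syn <- n_per_class - n_correct_syn     # synthetic cells marked real
  if (n_err_real != n_err_syn)
    stop("the balance constraint forces equally many errors per class")
  # errors come in within-grid pairs: swap one real and one synthetic cell
  set.seed(substream_seed(seed, paste0("rater", rater)))
  n_swaps <- n_err_real
  max_swaps_per_grid <- 3L
  grid_swaps <- integer(session$n_grids)
  remaining <- n_swaps
  while (remaining > 0) {
    g <- sample.int(session$n_grids, 1L)
    if (grid_swaps[g] < max_swaps_per_grid) {
      grid_swaps[g] <- grid_swaps[g] + 1L
      remaining <- remaining - 1L
    }
  }
  label <- cells$truth
  for (g in seq_len(session$n_grids)) {
    if (!grid_swaps[g]) next
    in_grid <- which(cells$grid == g)
    reals <- sample(in_grid[cells$truth[in_grid] == "real"], grid_swaps[g])
    syns <- sample(in_grid[cells$truth[in_grid] == "synthetic"],
                   grid_swaps[g])
    label[reals] <- "synthetic"
    label[syns] <- "real"
  }
  data.frame(rater = rater, grid = cells$grid, cell = cells$cell,
             label = label, stringsAsFactors = FALSE)
}

#' Degraded copies of images
#'
#' Gaussian blur plus noise; a stand-in for "synthetic" images when testing
#' the Turing harness without a trained generator.
#'
#' @param images Image batch matrix (pixels x n).
#' @param size Image side length.
#' @param sigma Blur standard deviation (pixels).
#' @param noise_sd Added Gaussian noise level.
#' @param seed Seed.
#' @return Degraded image batch, same shape, renormalized to \[-1, 1\].
#' @export
degrade_images <- function(images, size, sigma = 1, noise_sd = 0.05,
                           seed = 1L) {
  set.seed(substream_seed(seed, "degrade"))
  arr <- array(images, c(size, size, ncol(images)))
  blurred <- EBImage::gblur(EBImage::Image(arr), sigma = sigma)
  out <- matrix(EBImage::imageData(blurred), size^2, ncol(images))
  out <- out + stats::rnorm(length(out), 0, noise_sd)
  apply(out, 2, normalize_minmax)
}
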