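cfg0 <- curation_config(val_images = 12, test_images = 12)

test_that("manufacturer resolution prefers the header, then the coil map", {
  h <- series_header(3000, 30, manufacturer = "Siemens Healthineers")
  expect_identical(resolve_manufacturer(h, cfg0), "Siemens Healthineers")
  h <- series_header(3000, 30, coil_name = "Tx_Rx_Knee_Siemens")
  expect_identical(resolve_manufacturer(h, cfg0), "SIEMENS")
  h <- series_header(3000, 30, coil_name = "GENERIC_COIL_X")
  expect_true(is.na(resolve_manufacturer(h, cfg0)))
  h <- series_header(3000, 30)
  expect_true(is.na(resolve_manufacturer(h, cfg0)))
})

test_that("header filter applies every rule with inclusive boundaries", {
  mk <- function(tr, te, ...) series_header(tr, te, manufacturer = "SIEMENS",
                                            ...)
  ok <- mk(3000, 30)
  expect_true(passes_filters(ok, cfg0)$pass)

  low <- mk(1700, 30)
  v <- passes_filters(low, cfg0)
  expect_false(v$pass)
  expect_identical(v$reason, "tr_range")

  # boundary values are included
  expect_true(passes_filters(mk(1800, 50), cfg0)$pass)
  expect_true(passes_filters(mk(5000, 12), cfg0)$pass)
  expect_false(passes_filters(mk(5000.1, 12), cfg0)$pass)
  expect_identical(passes_filters(mk(3000, 50.5), cfg0)$reason, "te_max")

  fs <- mk(3000, 30, fat_saturated = TRUE)
  expect_identical(passes_filters(fs, cfg0)$reason, "fat_sat")

  wrong_b0 <- mk(3000, 30, field_strength = 3)
  expect_identical(passes_filters(wrong_b0, cfg0)$reason, "field_strength")

  noven <- series_header(3000, 30, coil_name = "GENERIC_COIL_X")
  expect_identical(passes_filters(noven, cfg0)$reason, "manufacturer")

  bad <- series_header(NA_real_, 30)
  expect_identical(passes_filters(bad, cfg0)$reason, "malformed")
})

test_that("central slice selection is centered, contiguous and capped", {
  expect_identical(central_slice_indices(12, 6), 3:8)
  expect_identical(central_slice_indices(6, 6), 0:5)
  expect_identical(central_slice_indices(13, 6), 3:8)
  expect_identical(central_slice_indices(3, 6), 0:2)
  for (n in 1:20) for (k in c(1, 4, 6)) {
    idx <- central_slice_indices(n, k)
    expect_length(idx, min(k, n))
    expect_true(all(diff(idx) == 1) || length(idx) == 1)
    expect_true(all(idx >= 0 & idx < n))
  }
})

test_that("preprocessing resizes bilinearly and normalizes to [-1, 1]", {
  set.seed(1)
  img <- matrix(runif(40 * 40), 40, 40)
  out <- preprocess_image(img, 32)
  expect_equal(dim(out), c(32, 32))
  expect_equal(min(out), -1)
  expect_equal(max(out), 1)

  expect_equal(preprocess_image(matrix(5, 20, 20), 16), matrix(0, 16, 16))

  ramp <- matrix(rep(seq_len(40), each = 40), 40, 40)
  r <- preprocess_image(ramp, 32)
  expect_true(all(diff(r[16, ]) >= 0))  # monotone along the ramp axis
  expect_true(all(r >= -1 & r <= 1))

  img[3, 3] <- NA
  expect_error(preprocess_image(img, 32), "non-finite")
})

test_that("study-level split is disjoint, budget-greedy and seeded", {
  manifest <- data.frame(study_id = rep(sprintf("S%03d", 1:100), each = 6))
  sp <- split_by_study(manifest, cfg0)
  expect_equal(length(unique(sp$validation$study_id)), 2)  # 2 x 6 = 12
  expect_equal(length(unique(sp$test$study_id)), 2)
  ids <- lapply(sp, function(m) unique(m$study_id))
  expect_length(intersect(ids$train, ids$validation), 0)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$validation, ids$test), 0)
  expect_equal(nrow(sp$train) + nrow(sp$validation) + nrow(sp$test), 600)

  sp2 <- split_by_study(manifest, cfg0)
  expect_identical(sp, sp2)

  expect_error(split_by_study(manifest[1:20, , drop = FALSE], cfg0),
               "smaller than")
})

test_that("filtering is order-invariant and exact on a planted fixture", {
  dir <- withr::local_tempdir()
  truth <- make_curation_fixture(dir, n_series = 24, n_tr_low = 3,
                                 n_te_high = 3, n_fat_sat = 3,
                                 n_bad_vendor = 3, slices_per_series = 2,
                                 seed = 4)
  cfg <- curation_config(central_k = 6, val_images = 2, test_images = 2)
  res <- curate_directory(dir, cfg, split = FALSE)
  expect_equal(res$report$n_series, 24)
  expect_equal(res$report$n_series_kept, 12)
  expect_equal(res$report$exclusions$tr_range, 3)
  expect_equal(res$report$exclusions$te_max, 3)
  expect_equal(res$report$exclusions$fat_sat, 3)
  expect_equal(res$report$exclusions$manufacturer, 3)
  # surviving series are exactly those without a planted violation
  expect_setequal(unique(res$manifest$series_id),
                  truth$series_uid[truth$violation == "none"])
  # 2 slices per series, k = 6 -> all slices kept
  expect_equal(nrow(res$manifest), 24)

  # order invariance: filtering headers in any order keeps the same set
  headers <- lapply(seq_len(24), function(i)
    series_header(3000 + i, 30, manufacturer = "SIEMENS",
                  fat_saturated = i %% 7 == 0))
  keep1 <- vapply(headers, function(h) passes_filters(h, cfg)$pass,
                  logical(1))
  perm <- sample(24)
  keep2 <- vapply(headers[perm], function(h) passes_filters(h, cfg)$pass,
                  logical(1))
  expect_identical(keep1[perm], keep2)
})
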