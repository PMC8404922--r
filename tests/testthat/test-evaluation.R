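make_session <- function(n_grids = 25, size = 8, seed = 1) {
  set.seed(seed)
  n <- 3 * n_grids
  real <- matrix(runif(size^2 * n, -1, 1), size^2, n)
  syn <- matrix(runif(size^2 * n, -1, 1), size^2, n)
  build_turing_session(real, syn, n_grids, seed = seed)
}

test_that("turing sessions are balanced, sized and reproducible", {
  s <- make_session(25)
  expect_equal(s$n_grids, 25)          # 150 images / 6 per grid
  expect_equal(nrow(s$cells), 150)
  per_grid <- tapply(s$cells$truth == "real", s$cells$grid, sum)
  expect_true(all(per_grid == 3))
  s2 <- make_session(25)
  expect_identical(s$cells, s2$cells)
  expect_error(build_turing_session(matrix(0, 64, 5), matrix(0, 64, 75),
                                    25), "insufficient")
})

test_that("scorer reproduces published-style confusion counts", {
  s <- make_session(25)
  a1 <- simulate_turing_answers(s, "expert1", 53, 53, seed = 2)
  a2 <- simulate_turing_answers(s, "expert2", 36, 36, seed = 3)
  sc <- score_turing_session(s, rbind(a1, a2))
  cm1 <- sc$raters$expert1$confusion
  expect_equal(unname(cm1), matrix(c(53, 22, 22, 53), 2))
  expect_equal(sc$raters$expert1$accuracy_pct, 71)
  expect_equal(sc$raters$expert1$accuracy_raw, 106 / 150, tolerance = 1e-12)
  cm2 <- sc$raters$expert2$confusion
  expect_equal(unname(cm2), matrix(c(36, 39, 39, 36), 2))
  expect_equal(sc$raters$expert2$accuracy_pct, 48)
  # true-class column sums are total/2 by construction
  expect_equal(unname(colSums(cm1)), c(75, 75))
  # IRA cannot exceed either rater's per-class correct count
  expect_lte(sc$ira[["real"]], min(cm1[1, 1], cm2[1, 1]))
  expect_lte(sc$ira[["synthetic"]], min(cm1[2, 2], cm2[2, 2]))
})

test_that("scorer enforces the per-grid balance constraint", {
  s <- make_session(4)
  perfect <- data.frame(rater = "r", grid = s$cells$grid,
                        cell = s$cells$cell, label = s$cells$truth)
  sc <- score_turing_session(s, perfect)
  expect_equal(sc$raters$r$accuracy_pct, 100)
  expect_equal(unname(sc$raters$r$confusion[1, 2]), 0)
  expect_equal(unname(sc$raters$r$confusion[2, 1]), 0)
  expect_equal(unname(sc$ira), c(12, 12))

  bad <- perfect
  bad$label[bad$grid == 2] <- "real"   # 6 reals in grid 2
  expect_error(score_turing_session(s, bad), "grid 2")
  # per rater, predicted-real equals predicted-synthetic overall
  a <- simulate_turing_answers(s, "r2", 9, 9, seed = 5)
  expect_equal(sum(a$label == "real"), sum(a$label == "synthetic"))
})

test_that("conditioning metrics decode AC outputs into physical units", {
  ds <- tiny_phantom_dataset(n = 120, seed = 61, size = 16)
  cfg <- net_config(final_resolution = 16)
  acr <- pretrain_ac(ds, cfg = cfg, epochs = 4,
                     optim = optim_config(32, 1e-3, 0, 0.99), seed = 2)
  codec <- condition_codec()
  test_ds <- tiny_phantom_dataset(n = 36, seed = 62, size = 16)
  rep1 <- conditioning_metrics(test_ds$images, test_ds$meta, acr$ac, codec,
                               source = "real_test")
  expect_s3_class(rep1, "conditioning_report")
  expect_gte(rep1$mae_tr, 0)
  expect_gte(rep1$mae_te, 0)
  expect_true(rep1$orientation_accuracy >= 0 &&
                rep1$orientation_accuracy <= 100)
  expect_equal(rep1$n, 36)
  # invariant to sample order
  perm <- sample(36)
  rep2 <- conditioning_metrics(test_ds$images[, perm],
                               test_ds$meta[perm, ], acr$ac, codec)
  expect_equal(rep2$mae_tr, rep1$mae_tr, tolerance = 1e-12)
  expect_equal(rep2$orientation_accuracy, rep1$orientation_accuracy)
  expect_error(conditioning_metrics(test_ds$images[, 0, drop = FALSE],
                                    test_ds$meta[0, ], acr$ac, codec),
               "n >= 1")
})

test_that("interpolation grids reuse one latent vector across panels", {
  cfg <- tiny_net_config()
  gen <- build_generator(cfg, seed = 4)
  accfg <- net_config(final_resolution = 16)
  ac <- build_ac(accfg, seed = 4)
  codec <- condition_codec()
  z <- rnorm(cfg$latent_dim)
  csv <- tempfile(fileext = ".csv")
  g <- interpolation_grid(gen, z, tr_values = c(2000, 3000, 4500),
                          te_values = c(15, 30, 45), ac = ac, codec = codec,
                          csv_path = csv)
  expect_equal(ncol(g$images), 9)
  expect_equal(nrow(g$table), 9)
  expect_true(all(c("tr_intended", "te_intended", "tr_read", "te_read") %in%
                    names(g$table)))
  expect_true(file.exists(csv))
  # regenerating the first panel reproduces it (same z; tolerance covers
  # BLAS blocking differences between batch sizes)
  again <- interpolation_grid(gen, z, tr_values = 2000, te_values = 15,
                              ac = ac, codec = codec)
  expect_equal(again$images[, 1], g$images[, 1], tolerance = 1e-10)
  expect_error(interpolation_grid(gen, z, tr_values = 100, te_values = 15,
                                  ac = ac, codec = codec), "TR outside")
})

test_that("degraded copies keep shape and range", {
  ds <- tiny_phantom_dataset(n = 12, seed = 71, size = 16)
  d <- degrade_images(ds$images, 16, seed = 1)
  expect_equal(dim(d), dim(ds$images))
  expect_true(all(d >= -1 & d <= 1))
  expect_gt(mean(abs(d - ds$images)), 0.01)
})
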