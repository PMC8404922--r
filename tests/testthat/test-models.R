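cfg <- tiny_net_config()

test_that("generator outputs bounded images at every stage resolution", {
  gen <- build_generator(cfg, seed = 3)
  set.seed(1)
  z <- matrix(rnorm(6 * 5), 6, 5)
  cond <- matrix(runif(4 * 5), 4, 5)
  for (s in 1:3) {
    y <- generator_forward(gen, z, cond, stage = s)$y
    expect_equal(nrow(y), (4 * 2^(s - 1))^2)
    expect_equal(ncol(y), 5)
    expect_true(all(y >= -1 & y <= 1))
  }
  # deterministic in inference
  expect_identical(generator_forward(gen, z, cond)$y,
                   generator_forward(gen, z, cond)$y)
  expect_error(generator_forward(gen, z[1:3, ], cond), "dimension mismatch")
})

test_that("fade-in blend is exact at the endpoints and linear between", {
  set.seed(4)
  a <- matrix(rnorm(64), 8, 8)
  b <- matrix(rnorm(64), 8, 8)
  expect_identical(fade_in_blend(a, b, 0), a)
  expect_identical(fade_in_blend(a, b, 1), b)
  expect_equal(fade_in_blend(a, b, 0.5), (a + b) / 2, tolerance = 1e-15)
  expect_error(fade_in_blend(a, b[1:4, ], 0.5), "shape mismatch")
  expect_error(fade_in_blend(a, b, 1.2), "alpha")
})

test_that("growing preserves the computed function at alpha = 0", {
  gen <- build_generator(cfg, seed = 9)
  set.seed(2)
  z <- matrix(rnorm(6 * 3), 6, 3)
  cond <- matrix(0, 4, 3)
  for (s in 2:3) {
    y_prev <- generator_forward(gen, z, cond, stage = s - 1)$y
    y_fade0 <- generator_forward(gen, z, cond, stage = s, alpha = 0)$y
    lin_prev <- atanh(pmin(pmax(y_prev, -1 + 1e-12), 1 - 1e-12))
    res_prev <- 4 * 2^(s - 2)
    up <- contrastgan:::layer_forward(
      contrastgan:::layer_upsample2(res_prev, res_prev, 1L), lin_prev)$y
    expect_equal(y_fade0, tanh(up), tolerance = 1e-9)
  }
})

test_that("critic scores are finite scalars with usable input gradients", {
  disc <- build_discriminator(cfg, seed = 5)
  set.seed(3)
  for (s in 1:3) {
    res <- 4 * 2^(s - 1)
    x <- matrix(runif(res^2 * 6, -1, 1), res^2, 6)
    fw <- discriminator_forward(disc, x, stage = s, alpha = 0.7)
    expect_equal(dim(fw$y), c(1L, 6L))
    expect_true(all(is.finite(fw$y)))
  }
  # finite-difference check of the input gradient on a tiny critic
  x <- matrix(runif(16 * 3, -1, 1), 16, 3)
  fw <- discriminator_forward(disc, x, stage = 1)
  g <- discriminator_backward(disc, fw, matrix(1, 1, 3))$dx
  expect_true(all(is.finite(g)))
  f <- function(xv) sum(discriminator_forward(disc, matrix(xv, 16, 3),
                                              stage = 1)$y)
  idx <- c(1, 7, 30)
  for (i in idx) {
    e <- numeric(48); e[i] <- 1e-5
    num <- (f(as.vector(x) + e) - f(as.vector(x) - e)) / 2e-5
    expect_equal(num, g[i], tolerance = 1e-6)
  }
  expect_error(discriminator_forward(disc, x, stage = 2), "resolution")
})

test_that("generator and critic resolutions agree at every stage", {
  gen <- build_generator(cfg, seed = 1)
  disc <- build_discriminator(cfg, seed = 1)
  set.seed(5)
  z <- matrix(rnorm(6 * 2), 6, 2)
  cond <- matrix(0, 4, 2)
  for (s in 1:3) for (a in c(0.3, 1)) {
    y <- generator_forward(gen, z, cond, s, a)$y
    sc <- discriminator_forward(disc, y, s, a)$y
    expect_equal(dim(sc), c(1L, 2L))
  }
})

test_that("AC heads are normalized, bounded and desk-scale small", {
  accfg <- net_config(final_resolution = 32, ac_backbone = "demo_cnn")
  ac <- build_ac(accfg, seed = 2)
  expect_lt(contrastgan:::count_parameters(ac$modules), 1e6)
  set.seed(6)
  x <- matrix(runif(1024 * 7, -1, 1), 1024, 7)
  out <- ac_forward(ac, x)
  expect_equal(colSums(out$orient), rep(1, 7), tolerance = 1e-12)
  expect_true(all(out$tr >= 0 & out$tr <= 1))
  expect_true(all(out$te >= 0 & out$te <= 1))
  expect_error(net_config(ac_backbone = "resnet"))
  expect_error(net_config(base_resolution = 4, final_resolution = 24),
               "2\\^s")
})

test_that("densenet backbone builds the 121 layout and runs end to end", {
  accfg <- net_config(final_resolution = 32, ac_backbone = "densenet121")
  ac <- build_ac(accfg, seed = 1)
  # 6 + 12 + 24 + 16 composite layers plus stem, transitions, final, heads
  expect_equal(sum(grepl("^b\\d+_l\\d+$", names(ac$modules))), 58)
  expect_gt(contrastgan:::count_parameters(ac$modules), 5e6)
  x <- matrix(runif(1024 * 2, -1, 1), 1024, 2)
  out <- ac_forward(ac, x, training = TRUE)
  expect_equal(colSums(out$orient), rep(1, 2), tolerance = 1e-12)
  expect_true(all(out$te >= 0 & out$te <= 1))
})
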