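codec <- condition_codec()

test_that("condition codec is an exact bijection on the condition box", {
  v <- encode_condition(data.frame(tr = c(1800, 5000, 3100),
                                   te = c(12, 50, 31),
                                   orientation = c("sagittal", "coronal",
                                                   "sagittal")), codec)
  expect_equal(v["tr", ], c(0, 1, (3100 - 1800) / 3200), tolerance = 1e-15)
  expect_equal(v["te", ], c(0, 1, (31 - 12) / 38), tolerance = 1e-15)
  expect_equal(colSums(v[3:4, ]), c(1, 1, 1))

  set.seed(8)
  cond <- data.frame(tr = runif(50, 1800, 5000), te = runif(50, 12, 50),
                     orientation = sample(c("sagittal", "coronal"), 50,
                                          TRUE))
  back <- decode_condition(encode_condition(cond, codec), codec)
  expect_equal(back$tr, cond$tr, tolerance = 1e-12)
  expect_equal(back$te, cond$te, tolerance = 1e-12)
  expect_identical(back$orientation, cond$orientation)

  expect_error(encode_condition(data.frame(tr = 1000, te = 30,
                                           orientation = "sagittal"), codec),
               "TR outside")
  expect_error(decode_condition(c(0.5, 0.5, 1), codec), "length mismatch")
})

test_that("critic and generator losses follow the Wasserstein form", {
  expect_equal(critic_loss(c(1, 3), c(0, 0), gp = 0.5), -1.5)
  expect_equal(critic_loss(c(2, 2), c(2, 2), gp = 0), 0)
  # invariance to additive constants on all scores
  set.seed(1)
  dr <- rnorm(10); df <- rnorm(10)
  expect_equal(critic_loss(dr + 13.7, df + 13.7, 1), critic_loss(dr, df, 1),
               tolerance = 1e-12)
  expect_error(critic_loss(numeric(0), df), "empty")

  expect_equal(generator_adversarial_loss(c(2, 4)), -3)
  expect_equal(generator_adversarial_loss(c(0, 0, 0)), 0)
  expect_lt(generator_adversarial_loss(df + 1),
            generator_adversarial_loss(df))
  expect_error(generator_adversarial_loss(numeric(0)), "empty")
})

test_that("gradient penalty matches analytic values for linear critics", {
  linear_critic <- function(w) {
    function(x) list(scores = drop(crossprod(w, x)),
                     input_grad_fn = function(dy)
                       w %*% matrix(dy, 1, ncol(x)))
  }
  set.seed(2)
  d <- 16
  x_real <- matrix(runif(d * 8, -1, 1), d, 8)
  x_fake <- matrix(runif(d * 8, -1, 1), d, 8)

  # unit-norm gradient everywhere -> zero penalty
  w <- rep(1 / sqrt(d), d)
  expect_lt(abs(gradient_penalty(linear_critic(matrix(w)), x_real, x_fake,
                                 lambda_gp = 10, seed = 1)), 1e-12)

  # D(x) = 2 * sum(x) on 4-pixel images: |grad| = 4, penalty = 9 * lambda
  x4r <- x_real[1:4, ]; x4f <- x_fake[1:4, ]
  gp <- gradient_penalty(linear_critic(matrix(2, 4, 1)), x4r, x4f,
                         lambda_gp = 10, seed = 1)
  expect_equal(as.numeric(gp), 10 * (4 - 1)^2, tolerance = 1e-12)
  expect_equal(as.numeric(gradient_penalty(linear_critic(matrix(2, 4, 1)),
                                           x4r, x4f, lambda_gp = 0,
                                           seed = 1)), 0)
  expect_error(gradient_penalty(linear_critic(matrix(2, 4, 1)), x4r,
                                x_fake, 10), "shape mismatch")
})

test_that("AC training loss is the weighted sum of its three terms", {
  # one sample engineered to exact components: CCE 0.2, MSE_TE 0.01,
  # MSE_TR 0.04
  p_true <- exp(-0.2)
  pred <- list(orient = matrix(c(p_true, 1 - p_true), 2, 1),
               tr = 0.5 + 0.2, te = 0.5 + 0.1)
  target <- encode_condition(data.frame(tr = 1800 + 0.5 * 3200,
                                        te = 12 + 0.5 * 38,
                                        orientation = "sagittal"), codec)
  total <- ac_training_loss(pred, target, loss_weights())
  expect_equal(as.numeric(total), 0.2 + 10 * 0.01 + 10 * 0.04,
               tolerance = 1e-12)
  comp <- attr(total, "components")
  expect_equal(unname(comp), c(0.2, 0.01, 0.04), tolerance = 1e-12)

  # doubling lambda_te doubles only the TE contribution
  t2 <- ac_training_loss(pred, target, loss_weights(lambda_te = 20))
  expect_equal(as.numeric(t2 - total), 0.1, tolerance = 1e-12)

  # perfect prediction -> 0
  perfect <- list(orient = matrix(c(1, 0), 2, 1), tr = 0.5, te = 0.5)
  expect_equal(as.numeric(ac_training_loss(perfect, target)), 0,
               tolerance = 1e-12)

  bad <- list(orient = matrix(c(0.5, 0.5), 2, 1), tr = 0.5, te = 0.5)
  expect_error(ac_training_loss(bad, rbind(target[1:2, , drop = FALSE],
                                           matrix(c(0.4, 0.4), 2, 1))),
               "invalid target")
})

test_that("adaptive weight updates follow the clamped recurrence", {
  st <- adaptive_weight_state()
  expect_equal(unname(st$gamma), c(0, 0, 0))

  # zero increment stays clamped at zero
  st1 <- update_adaptive_weight(st, "te", 1, 1)
  expect_equal(st1$gamma[["te"]], 0)

  # plain increment: 0.5 + 0.01 * (2 - 1) = 0.51
  st$gamma[["tr"]] <- 0.5
  st2 <- update_adaptive_weight(st, "tr", 2, 1)
  expect_equal(st2$gamma[["tr"]], 0.51, tolerance = 1e-15)

  # cap at tau = 100
  st$gamma[["iop"]] <- 99.9995
  st3 <- update_adaptive_weight(st, "iop", 1e6, 0)
  expect_equal(st3$gamma[["iop"]], 100)

  expect_error(update_adaptive_weight(st, "te", NaN, 1), "non-finite")
  expect_error(update_adaptive_weight(st, "flip", 1, 1), "unknown")
})

test_that("adaptive weights match a brute-force recurrence and stay in
          [0, tau]", {
  brute <- function(lf, lr, r, tau, e_hat) {
    g <- 0
    out <- numeric(length(lf))
    for (i in seq_along(lf)) {
      g <- min(tau, max(0, g + r * (lf[i] - e_hat * lr[i])))
      out[i] <- g
    }
    out
  }
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(20:60, 1)
    lf <- rexp(n, rate = 0.5)
    lr <- rexp(n, rate = 0.5)
    st <- adaptive_weight_state(tau = 100, r = 0.01, e_hat = 1)
    got <- numeric(n)
    for (i in seq_len(n)) {
      st <- update_adaptive_weight(st, "te", lf[i], lr[i])
      got[i] <- st$gamma[["te"]]
    }
    want <- brute(lf, lr, 0.01, 100, 1)
    expect_lt(max(abs(got - want)) / max(1, max(abs(want))), 1e-14)
    expect_true(all(got >= 0 & got <= 100))
  }
})

test_that("conditioning loss is the gamma-weighted sum", {
  st <- adaptive_weight_state()
  target <- encode_condition(data.frame(tr = 3400, te = 31,
                                        orientation = "coronal"), codec)
  pred <- list(orient = matrix(c(exp(-0.1), 1 - exp(-0.1))[2:1], 2, 1),
               tr = target["tr", ] + sqrt(0.02),
               te = target["te", ] + 0.1)
  # gamma all zero -> 0 regardless of the AC output
  expect_equal(as.numeric(conditioning_loss(st, pred, target)), 0)

  st$gamma <- c(iop = 1, te = 2, tr = 3)
  got <- conditioning_loss(st, pred, target)
  expect_equal(as.numeric(got), 1 * 0.1 + 2 * 0.01 + 3 * 0.02,
               tolerance = 1e-12)

  # equals the AC training loss when gamma matches the lambdas
  st$gamma <- c(iop = 1, te = 10, tr = 10)
  expect_equal(as.numeric(conditioning_loss(st, pred, target)),
               as.numeric(ac_training_loss(pred, target, loss_weights())),
               tolerance = 1e-12)
})
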