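# Analytic backward passes checked against central differences. These are
# the load-bearing correctness tests for everything the training loop does.

check_layer_grads <- function(make_layer, in_dim, n = 3, tol = 1e-6) {
  set.seed(42)
  l <- make_layer()
  x <- matrix(rnorm(in_dim * n), in_dim, n)
  fw <- contrastgan:::layer_forward(l, x, TRUE)
  dy <- matrix(rnorm(length(fw$y)), nrow(fw$y), ncol(fw$y))
  bk <- contrastgan:::layer_backward(l, fw$cache, dy)
  gx <- num_grad(function(xv)
    sum(contrastgan:::layer_forward(l, matrix(xv, in_dim, n), TRUE)$y * dy),
    as.vector(x))
  expect_rel_equal(as.vector(bk$dx), gx, tol)
  for (f in names(bk$grads)) {
    gw <- num_grad(function(wv) {
      l2 <- l
      l2[[f]] <- if (is.null(dim(l[[f]]))) wv else
        array(wv, dim = dim(l[[f]]))
      sum(contrastgan:::layer_forward(l2, x, TRUE)$y * dy)
    }, as.vector(l[[f]]))
    expect_rel_equal(as.vector(bk$grads[[f]]), gw, tol)
  }
}

test_that("layer backward passes match central differences", {
  ns <- asNamespace("contrastgan")
  check_layer_grads(function() ns$layer_dense(10, 4), 10)
  check_layer_grads(function() ns$layer_conv2d(6, 6, 2, 3), 72)
  check_layer_grads(function() ns$layer_conv2d(6, 6, 2, 3, kernel = 1), 72)
  check_layer_grads(function() ns$layer_conv2d(8, 8, 1, 2, kernel = 7,
                                               stride = 2, pad = 3), 64)
  check_layer_grads(function() ns$layer_act("lrelu"), 20)
  check_layer_grads(function() ns$layer_act("tanh"), 20)
  check_layer_grads(function() ns$layer_avgpool2(6, 6, 2), 72)
  check_layer_grads(function() ns$layer_upsample2(4, 4, 2), 32)
  check_layer_grads(function() ns$layer_pixelnorm(16, 3), 48)
  check_layer_grads(function() ns$layer_mbstd(9, 2), 18, n = 4)
  check_layer_grads(function() ns$layer_batchnorm(3, 16), 48, n = 4)
  check_layer_grads(function() ns$layer_global_avgpool(16, 3), 48)
})

test_that("generator backward matches central differences through the fade
          path", {
  cfg <- tiny_net_config()
  gen <- build_generator(cfg, seed = 7)
  set.seed(1)
  n <- 3
  z <- matrix(rnorm(6 * n), 6, n)
  cond <- matrix(runif(4 * n), 4, n)
  dy <- matrix(rnorm(256 * n), 256, n)
  fw <- generator_forward(gen, z, cond, 3, 0.6, keep_cache = TRUE)
  bk <- contrastgan:::generator_backward(gen, fw, dy)
  gloss <- function(g) sum(generator_forward(g, z, cond, 3, 0.6)$y * dy)
  set.seed(2)
  for (m in names(bk$grads)) for (i in seq_along(bk$grads[[m]])) {
    gr <- bk$grads[[m]][[i]]
    if (is.null(gr)) next
    for (f in names(gr)) {
      for (j in sample(seq_along(gr[[f]]), min(2, length(gr[[f]])))) {
        g2 <- gen
        g2$modules[[m]]$layers[[i]][[f]][j] <-
          g2$modules[[m]]$layers[[i]][[f]][j] + 1e-5
        g3 <- gen
        g3$modules[[m]]$layers[[i]][[f]][j] <-
          g3$modules[[m]]$layers[[i]][[f]][j] - 1e-5
        num <- (gloss(g2) - gloss(g3)) / 2e-5
        expect_equal(unname(gr[[f]][j]), num, tolerance = 1e-4)
      }
    }
  }
})

test_that("gradient-penalty parameter gradient matches central differences", {
  cfg <- tiny_net_config()
  disc <- build_discriminator(cfg, seed = 7)
  set.seed(3)
  n <- 3
  x <- matrix(runif(256 * n, -1, 1), 256, n)
  gp_of <- function(d) {
    fw <- discriminator_forward(d, x, 3, 0.6, freeze_mbstd = TRUE)
    bk <- discriminator_backward(d, fw, matrix(1, 1, n))
    10 * mean((sqrt(colSums(bk$dx^2)) - 1)^2)
  }
  gpg <- contrastgan:::discriminator_gp_grads(disc, x, 3, 0.6, 10)
  expect_equal(gpg$penalty, gp_of(disc), tolerance = 1e-12)
  set.seed(4)
  for (m in names(gpg$grads)) for (i in seq_along(gpg$grads[[m]])) {
    gr <- gpg$grads[[m]][[i]]
    if (is.null(gr)) next
    for (f in setdiff(names(gr), "b")) {
      for (j in sample(seq_along(gr[[f]]), min(2, length(gr[[f]])))) {
        d2 <- disc
        d2$modules[[m]]$layers[[i]][[f]][j] <-
          d2$modules[[m]]$layers[[i]][[f]][j] + 1e-5
        d3 <- disc
        d3$modules[[m]]$layers[[i]][[f]][j] <-
          d3$modules[[m]]$layers[[i]][[f]][j] - 1e-5
        num <- (gp_of(d2) - gp_of(d3)) / 2e-5
        expect_equal(unname(gr[[f]][j]), num, tolerance = 1e-4)
      }
    }
  }
})

test_that("AC backward matches central differences", {
  accfg <- net_config(final_resolution = 16, ac_backbone = "demo_cnn")
  ac <- build_ac(accfg, seed = 3)
  set.seed(5)
  n <- 4
  x <- matrix(runif(256 * n, -1, 1), 256, n)
  target <- encode_condition(
    data.frame(tr = c(2000, 3000, 4000, 2500), te = c(15, 25, 35, 45),
               orientation = c("sagittal", "coronal", "sagittal",
                               "coronal")), condition_codec())
  fwa <- ac_forward(ac, x, keep_cache = TRUE)
  bka <- contrastgan:::ac_backward(ac, fwa, target, c(1, 10, 10))
  acl <- function(a) as.numeric(ac_training_loss(ac_forward(a, x), target))
  set.seed(6)
  for (m in names(bka$grads)) for (i in seq_along(bka$grads[[m]])) {
    gr <- bka$grads[[m]][[i]]
    if (is.null(gr)) next
    for (f in names(gr)) {
      for (j in sample(seq_along(gr[[f]]), min(2, length(gr[[f]])))) {
        a2 <- ac
        a2$modules[[m]]$layers[[i]][[f]][j] <-
          a2$modules[[m]]$layers[[i]][[f]][j] + 1e-5
        a3 <- ac
        a3$modules[[m]]$layers[[i]][[f]][j] <-
          a3$modules[[m]]$layers[[i]][[f]][j] - 1e-5
        num <- (acl(a2) - acl(a3)) / 2e-5
        expect_equal(unname(gr[[f]][j]), num, tolerance = 1e-4)
      }
    }
  }
  # gradient w.r.t. the input image (used to guide the generator)
  e <- matrix(0, 256, n); e[100, 3] <- 1e-5
  aclx <- function(xx) as.numeric(ac_training_loss(ac_forward(ac, xx),
                                                   target))
  num <- (aclx(x + e) - aclx(x - e)) / 2e-5
  expect_equal(bka$dx[100, 3], num, tolerance = 1e-6)
})
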