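# Network builders: the progressive-growing generator and Wasserstein critic,
# and the multi-head auxiliary classifier (AC). All three are built from the
# layer engine in nn_engine.R; each network object carries a flat named list
# of sequential modules so one Adam implementation serves them all.

#' Network configuration
#'
#' @param latent_dim Length of the latent vector `z`.
#' @param base_resolution Resolution of the first progressive stage (pixels).
#' @param final_resolution Final output resolution; must equal
#'   `base_resolution * 2^s` for an integer `s >= 0`.
#' @param channel_schedule Integer vector of feature widths, one per stage
#'   (resolution doubling). Default halves from 64 down to a floor of 8.
#' @param n_orientation_classes Number of imaging-orientation classes.
#' @param ac_backbone `"demo_cnn"` (small CNN for desk-scale runs) or
#'   `"densenet121"` (DenseNet-style backbone in the 121 layout).
#' @param use_pixelnorm Pixelwise feature normalization in the generator.
#' @param use_mbstd Minibatch standard-deviation feature in the critic.
#' @param equalized_lr Runtime weight scaling by `gain/sqrt(fan_in)`.
#' @return An object of class `cg_net_config`.
#' @export
net_config <- function(latent_dim = 32, base_resolution = 4,
                       final_resolution = 32, channel_schedule = NULL,
                       n_orientation_classes = 2,
                       ac_backbone = c("demo_cnn", "densenet121"),
                       use_pixelnorm = TRUE, use_mbstd = TRUE,
                       equalized_lr = TRUE) {
  ac_backbone <- match.arg(ac_backbone)
  s <- log2(final_resolution / base_resolution)
  if (s < 0 || abs(s - round(s)) > 1e-9)
    stop("final_resolution must be base_resolution * 2^s for integer s >= 0")
  n_stages <- as.integer(round(s)) + 1L
  if (is.null(channel_schedule))
    channel_schedule <- pmax(8L, 64L %/% 2L^(seq_len(n_stages) - 1L))
  if (length(channel_schedule) != n_stages)
    stop("channel_schedule must have one entry per stage (", n_stages, ")")
  if (any(channel_schedule <= 0)) stop("channel widths must be positive")
  structure(list(latent_dim = latent_dim,
                 base_resolution = as.integer(base_resolution),
                 final_resolution = as.integer(final_resolution),
                 n_stages = n_stages,
                 channel_schedule = as.integer(channel_schedule),
                 n_orientation_classes = as.integer(n_orientation_classes),
                 cond_dim = 2L + as.integer(n_orientation_classes),
                 ac_backbone = ac_backbone,
                 use_pixelnorm = use_pixelnorm, use_mbstd = use_mbstd,
                 equalized_lr = equalized_lr),
            class = "cg_net_config")
}

#' @export
print.cg_net_config <- function(x, ...) {
  cat("<cg_net_config>", x$base_resolution, "->", x$final_resolution, "px,",
      x$n_stages, "stages, channels", paste(x$channel_schedule,
                                            collapse = "/"),
      "| z dim", x$latent_dim, "| cond dim", x$cond_dim,
      "| AC backbone", x$ac_backbone, "\n")
  invisible(x)
}

stage_resolution <- function(cfg, stage) cfg$base_resolution * 2L^(stage - 1L)

# ---- generator --------------------------------------------------------------

#' Build the progressive-growing generator
#'
#' The generator maps `(z, c_normalized)` — concatenated at the input — to a
#' square image in \[-1, 1\]. At progressive stage `s` it outputs
#' `base_resolution * 2^(s-1)` pixels; new stages are blended in with a fade
#' weight alpha. The condition sub-vector may be all zeros, which is how
#' conditioning is disabled during progressive growing.
#'
#' @param cfg A [net_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `pg_generator`.
#' @export
build_generator <- function(cfg, seed = 1L) {
  set.seed(substream_seed(seed, "generator"))
  ch <- cfg$channel_schedule
  base <- cfg$base_resolution
  eq <- cfg$equalized_lr
  modules <- list()
  lay <- list(layer_dense(cfg$latent_dim + cfg$cond_dim, base^2 * ch[1],
                          equalized = eq),
              layer_act("lrelu"))
  if (cfg$use_pixelnorm) lay <- c(lay, list(layer_pixelnorm(base^2, ch[1])))
  lay <- c(lay, list(layer_conv2d(base, base, ch[1], ch[1], equalized = eq),
                     layer_act("lrelu")))
  if (cfg$use_pixelnorm) lay <- c(lay, list(layer_pixelnorm(base^2, ch[1])))
  modules$block1 <- structure(list(layers = lay), class = "cg_seq")
  rgb_up <- list(NULL)
  for (s in seq_len(cfg$n_stages)[-1]) {
    res_prev <- stage_resolution(cfg, s - 1L)
    res <- stage_resolution(cfg, s)
    lay <- list(layer_upsample2(res_prev, res_prev, ch[s - 1]),
                layer_conv2d(res, res, ch[s - 1], ch[s], equalized = eq),
                layer_act("lrelu"))
    if (cfg$use_pixelnorm) lay <- c(lay, list(layer_pixelnorm(res^2, ch[s])))
    modules[[paste0("block", s)]] <- structure(list(layers = lay),
                                               class = "cg_seq")
    rgb_up[[s]] <- layer_upsample2(res_prev, res_prev, 1L)
  }
  for (s in seq_len(cfg$n_stages)) {
    res <- stage_resolution(cfg, s)
    modules[[paste0("torgb", s)]] <- seq_net(
      layer_conv2d(res, res, ch[s], 1L, kernel = 1L, gain = 1,
                   equalized = eq))
  }
  structure(list(cfg = cfg, modules = modules, rgb_up = rgb_up),
            class = "pg_generator")
}

#' @export
print.pg_generator <- function(x, ...) {
  cat("<pg_generator>", x$cfg$base_resolution, "->", x$cfg$final_resolution,
      "px,", format(count_parameters(x$modules), big.mark = ","),
      "parameters\n")
  invisible(x)
}

#' Run the generator
#'
#' @param gen A [build_generator()] network.
#' @param z Latent matrix (`latent_dim` x n).
#' @param cond Normalized condition matrix (`cond_dim` x n), e.g. from
#'   [encode_condition()]; pass zeros to generate unconditionally.
#' @param stage Progressive stage (1 = base resolution).
#' @param alpha Fade-in weight in \[0, 1\] blending the upsampled previous
#'   stage with the new one; 1 = fully grown.
#' @param keep_cache Keep layer caches for a subsequent backward pass.
#' @return List with `y` (pixels x n image batch in \[-1, 1\]) and, when
#'   `keep_cache`, the forward caches.
#' @export
generator_forward <- function(gen, z, cond, stage = gen$cfg$n_stages,
                              alpha = 1, keep_cache = FALSE) {
  cfg <- gen$cfg
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  if (is.null(dim(cond))) cond <- matrix(cond, ncol = 1)
  if (nrow(z) != cfg$latent_dim || nrow(cond) != cfg$cond_dim ||
      ncol(z) != ncol(cond))
    stop("latent/condition dimension mismatch: expected ", cfg$latent_dim,
         " x n and ", cfg$cond_dim, " x n")
  if (stage < 1 || stage > cfg$n_stages) stop("invalid stage")
  x <- rbind(z, cond)
  block_caches <- vector("list", stage)
  h_prev <- NULL
  for (s in seq_len(stage)) {
    if (s == stage && s > 1) h_prev <- x
    fw <- seq_forward(gen$modules[[paste0("block", s)]], x)
    x <- fw$y
    block_caches[[s]] <- fw$caches
  }
  faded <- stage > 1 && alpha < 1
  fine <- seq_forward(gen$modules[[paste0("torgb", stage)]], x)
  if (faded) {
    coarse <- seq_forward(gen$modules[[paste0("torgb", stage - 1)]], h_prev)
    up <- layer_forward(gen$rgb_up[[stage]], coarse$y)
    lin <- fade_in_blend(up$y, fine$y, alpha)
  } else {
    coarse <- NULL
    lin <- fine$y
  }
  y <- tanh(lin)
  out <- list(y = y, stage = stage, alpha = alpha, faded = faded)
  if (keep_cache) {
    out$cache <- list(blocks = block_caches, fine = fine$caches,
                      coarse = if (faded) coarse$caches, y = y)
  }
  out
}

#' Fade-in blend of two resolution branches
#'
#' `(1 - alpha) * coarse_upsampled + alpha * fine`, elementwise.
#'
#' @param coarse_upsampled,fine Equal-shaped numeric arrays.
#' @param alpha Blend weight in \[0, 1\].
#' @return The blended array.
#' @export
fade_in_blend <- function(coarse_upsampled, fine, alpha) {
  if (!identical(dim(coarse_upsampled), dim(fine)) ||
      length(coarse_upsampled) != length(fine))
    stop("shape mismatch between coarse and fine branches")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (alpha == 0) return(coarse_upsampled)
  if (alpha == 1) return(fine)
  (1 - alpha) * coarse_upsampled + alpha * fine
}

# Backward through the generator. `dy` is the gradient w.r.t. the output
# image batch. Returns parameter grads (named by module) and the gradient
# w.r.t. the concatenated (z, cond) input.
generator_backward <- function(gen, fw, dy) {
  stopifnot(!is.null(fw$cache))
  stage <- fw$stage
  dlin <- dy * (1 - fw$cache$y^2)  # through tanh
  grads <- list()
  if (fw$faded) {
    a <- fw$alpha
    fine_bk <- seq_backward(gen$modules[[paste0("torgb", stage)]],
                            fw$cache$fine, a * dlin)
    grads[[paste0("torgb", stage)]] <- fine_bk$grads
    dup <- layer_backward(gen$rgb_up[[stage]], list(), (1 - a) * dlin)$dx
    coarse_bk <- seq_backward(gen$modules[[paste0("torgb", stage - 1)]],
                              fw$cache$coarse, dup)
    grads[[paste0("torgb", stage - 1)]] <- coarse_bk$grads
    dh <- fine_bk$dx
    dh_prev_extra <- coarse_bk$dx
  } else {
    fine_bk <- seq_backward(gen$modules[[paste0("torgb", stage)]],
                            fw$cache$fine, dlin)
    grads[[paste0("torgb", stage)]] <- fine_bk$grads
    dh <- fine_bk$dx
    dh_prev_extra <- NULL
  }
  for (s in rev(seq_len(stage))) {
    bk <- seq_backward(gen$modules[[paste0("block", s)]],
                       fw$cache$blocks[[s]], dh)
    grads[[paste0("block", s)]] <- bk$grads
    dh <- bk$dx
    if (!is.null(dh_prev_extra) && s == stage) dh <- dh + dh_prev_extra
  }
  list(grads = grads, dinput = dh)
}

# ---- discriminator (critic) -------------------------------------------------

#' Build the progressive-growing Wasserstein critic
#'
#' Mirrors the generator's stages; outputs one unbounded scalar score per
#' image (no final squashing). A minibatch standard-deviation feature is
#' appended before the final block when `cfg$use_mbstd` is set.
#'
#' @param cfg A [net_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `pg_discriminator`.
#' @export
build_discriminator <- function(cfg, seed = 1L) {
  set.seed(substream_seed(seed, "discriminator"))
  ch <- cfg$channel_schedule
  base <- cfg$base_resolution
  eq <- cfg$equalized_lr
  modules <- list()
  in_pool <- list(NULL)
  for (s in seq_len(cfg$n_stages)) {
    res <- stage_resolution(cfg, s)
    modules[[paste0("fromrgb", s)]] <- structure(
      list(layers = list(layer_conv2d(res, res, 1L, ch[s], kernel = 1L,
                                      equalized = eq),
                         layer_act("lrelu"))), class = "cg_seq")
    if (s > 1) {
      modules[[paste0("block", s)]] <- structure(
        list(layers = list(layer_conv2d(res, res, ch[s], ch[s - 1],
                                        equalized = eq),
                           layer_act("lrelu"),
                           layer_avgpool2(res, res, ch[s - 1]))),
        class = "cg_seq")
      in_pool[[s]] <- layer_avgpool2(res, res, 1L)
    }
  }
  c_head <- ch[1] + as.integer(cfg$use_mbstd)
  lay <- list()
  if (cfg$use_mbstd) lay <- c(lay, list(layer_mbstd(base^2, ch[1])))
  lay <- c(lay, list(layer_conv2d(base, base, c_head, ch[1], equalized = eq),
                     layer_act("lrelu"),
                     layer_dense(base^2 * ch[1], ch[1], equalized = eq),
                     layer_act("lrelu"),
                     layer_dense(ch[1], 1L, gain = 1, equalized = eq)))
  modules$head <- structure(list(layers = lay), class = "cg_seq")
  structure(list(cfg = cfg, modules = modules, in_pool = in_pool),
            class = "pg_discriminator")
}

#' @export
print.pg_discriminator <- function(x, ...) {
  cat("<pg_discriminator>", x$cfg$final_resolution, "->",
      x$cfg$base_resolution, "px,",
      format(count_parameters(x$modules), big.mark = ","), "parameters\n")
  invisible(x)
}

#' Run the critic
#'
#' @param disc A [build_discriminator()] network.
#' @param x Image batch matrix (`res^2` x n) at the stage's resolution.
#' @param stage Progressive stage.
#' @param alpha Fade-in weight of the newest stage.
#' @param freeze_mbstd Treat the minibatch-stddev statistic as a constant
#'   (used on the gradient-penalty path so the critic is piecewise linear in
#'   its input).
#' @return List with `y` (1 x n score matrix) plus forward caches for
#'   [discriminator_backward()].
#' @export
discriminator_forward <- function(disc, x, stage = disc$cfg$n_stages,
                                  alpha = 1, freeze_mbstd = FALSE) {
  cfg <- disc$cfg
  res <- stage_resolution(cfg, stage)
  if (nrow(x) != res^2)
    stop("input resolution does not match stage ", stage, ": expected ",
         res, "x", res)
  caches <- list()
  fr <- seq_forward(disc$modules[[paste0("fromrgb", stage)]], x)
  caches$fromrgb <- fr$caches
  h <- fr$y
  faded <- stage > 1 && alpha < 1
  if (stage > 1) {
    bk <- seq_forward(disc$modules[[paste0("block", stage)]], h)
    caches$top_block <- bk$caches
    h <- bk$y
    if (faded) {
      pool <- layer_forward(disc$in_pool[[stage]], x)
      frc <- seq_forward(disc$modules[[paste0("fromrgb", stage - 1)]],
                         pool$y)
      caches$fromrgb_coarse <- frc$caches
      h <- fade_in_blend(frc$y, h, alpha)
    }
  }
  caches$blocks <- list()
  s <- stage - 1L
  while (s >= 2L) {
    bk <- seq_forward(disc$modules[[paste0("block", s)]], h)
    caches$blocks[[paste0("block", s)]] <- bk$caches
    h <- bk$y
    s <- s - 1L
  }
  hd <- seq_forward(disc$modules$head, h)
  caches$head <- hd$caches
  if (freeze_mbstd && cfg$use_mbstd) caches$head[[1]]$frozen <- TRUE
  list(y = hd$y, caches = caches, stage = stage, alpha = alpha,
       faded = faded, freeze_mbstd = freeze_mbstd)
}

#' Backward pass of the critic
#'
#' @param disc A [build_discriminator()] network.
#' @param fw Output of [discriminator_forward()].
#' @param dy Gradient w.r.t. the scores (1 x n).
#' @return List with `dx` (gradient w.r.t. the input images) and `grads`
#'   (parameter gradients, named by module).
#' @export
discriminator_backward <- function(disc, fw, dy) {
  cfg <- disc$cfg
  stage <- fw$stage
  grads <- list()
  hd <- seq_backward(disc$modules$head, fw$caches$head, dy)
  grads$head <- hd$grads
  dh <- hd$dx
  for (s in seq.int(2L, length.out = max(0L, stage - 2L))) {
    bk <- seq_backward(disc$modules[[paste0("block", s)]],
                       fw$caches$blocks[[paste0("block", s)]], dh)
    grads[[paste0("block", s)]] <- bk$grads
    dh <- bk$dx
  }
  dx <- NULL
  if (stage > 1) {
    if (fw$faded) {
      a <- fw$alpha
      frc <- seq_backward(disc$modules[[paste0("fromrgb", stage - 1)]],
                          fw$caches$fromrgb_coarse, (1 - a) * dh)
      grads[[paste0("fromrgb", stage - 1)]] <- frc$grads
      dx <- layer_backward(disc$in_pool[[stage]],
                           list(n = ncol(frc$dx)), frc$dx)$dx
      dh <- a * dh
    }
    bk <- seq_backward(disc$modules[[paste0("block", stage)]],
                       fw$caches$top_block, dh)
    grads[[paste0("block", stage)]] <- bk$grads
    dh <- bk$dx
  }
  fr <- seq_backward(disc$modules[[paste0("fromrgb", stage)]],
                     fw$caches$fromrgb, dh)
  grads[[paste0("fromrgb", stage)]] <- fr$grads
  dx <- if (is.null(dx)) fr$dx else fr$dx + dx
  list(dx = dx, grads = grads)
}

# Forward-mode tangent pass through the critic, reusing the primal caches of
# `fw` (activation masks, frozen batch statistic). Returns the tangent score
# and tangent caches shaped like the primal ones, so that seq_backward over
# the tangent caches yields the parameter gradient of a scalar function of
# the tangent output. Used by the gradient-penalty parameter gradient.
discriminator_forward_dual <- function(disc, fw, xdot) {
  stage <- fw$stage
  tc <- list()
  dual_seq <- function(net, caches, xd) {
    tcaches <- vector("list", length(net$layers))
    for (i in seq_along(net$layers)) {
      l <- net$layers[[i]]
      yd <- layer_forward_tangent(l, caches[[i]], xd)
      tcaches[[i]] <- switch(l$type,
        dense = list(x = xd),
        conv2d = {
          n <- ncol(xd)
          xc <- gather_rows(xd, l$idx)
          dim(xc) <- c(l$k, l$p * n)
          list(xc = xc, n = n)
        },
        caches[[i]])
      xd <- yd
    }
    list(y = xd, caches = tcaches)
  }
  fr <- dual_seq(disc$modules[[paste0("fromrgb", stage)]],
                 fw$caches$fromrgb, xdot)
  tc$fromrgb <- fr$caches
  hd_t <- fr$y
  if (stage > 1) {
    bk <- dual_seq(disc$modules[[paste0("block", stage)]],
                   fw$caches$top_block, hd_t)
    tc$top_block <- bk$caches
    hd_t <- bk$y
    if (fw$faded) {
      pool_t <- layer_forward_tangent(disc$in_pool[[stage]], list(), xdot)
      frc <- dual_seq(disc$modules[[paste0("fromrgb", stage - 1)]],
                      fw$caches$fromrgb_coarse, pool_t)
      tc$fromrgb_coarse <- frc$caches
      hd_t <- (1 - fw$alpha) * frc$y + fw$alpha * hd_t
    }
  }
  tc$blocks <- list()
  s <- stage - 1L
  while (s >= 2L) {
    bk <- dual_seq(disc$modules[[paste0("block", s)]],
                   fw$caches$blocks[[paste0("block", s)]], hd_t)
    tc$blocks[[paste0("block", s)]] <- bk$caches
    hd_t <- bk$y
    s <- s - 1L
  }
  hd <- dual_seq(disc$modules$head, fw$caches$head, hd_t)
  tc$head <- hd$caches
  if (fw$freeze_mbstd && disc$cfg$use_mbstd)
    tc$head[[1]]$frozen <- TRUE
  list(y = hd$y, caches = tc, stage = stage, alpha = fw$alpha,
       faded = fw$faded, freeze_mbstd = fw$freeze_mbstd)
}

# Parameter gradient of the gradient-penalty term
# lambda * mean((||grad_x D(x_hat)|| - 1)^2) w.r.t. the critic weights.
# Reverse-over-forward: per-sample input gradients g_n come from a standard
# backward pass; the directional derivative <grad_x D, v_n> is then formed in
# forward (tangent) mode and differentiated in reverse. Bias parameters do
# not enter the tangent stream, so their penalty gradient is zero.
discriminator_gp_grads <- function(disc, x_hat, stage, alpha, lambda_gp) {
  n <- ncol(x_hat)
  fw <- discriminator_forward(disc, x_hat, stage, alpha, freeze_mbstd = TRUE)
  bk <- discriminator_backward(disc, fw, matrix(1, 1, n))
  g <- bk$dx
  norms <- sqrt(colSums(g^2))
  coef <- 2 * lambda_gp / n * (norms - 1) / pmax(norms, 1e-12)
  v <- g * rep(coef, each = nrow(g))
  dual <- discriminator_forward_dual(disc, fw, v)
  gp_bk <- discriminator_backward(disc, dual, matrix(1, 1, n))
  grads <- gp_bk$grads
  for (m in names(grads)) for (i in seq_along(grads[[m]])) {
    if (!is.null(grads[[m]][[i]]$b)) grads[[m]][[i]]$b <- 0 * grads[[m]][[i]]$b
  }
  list(grads = grads, penalty = lambda_gp * mean((norms - 1)^2),
       grad_norms = norms)
}

# ---- auxiliary classifier ---------------------------------------------------

#' Build the auxiliary classifier
#'
#' A shared convolutional backbone with three heads: orientation class
#' probabilities (softmax), and two scalar regressions for the normalized TR
#' and TE, each bounded to \[0, 1\] by a sigmoid. The `demo_cnn` backbone is
#' a small three-block CNN (< 1e6 parameters) for desk-scale work; the
#' `densenet121` backbone follows the DenseNet-121 layout (dense blocks of
#' 6/12/24/16 composite layers, growth 32, 1x1 bottlenecks, 0.5-compression
#' transitions).
#'
#' @param cfg A [net_config()]; `cfg$ac_backbone` selects the backbone and
#'   `cfg$final_resolution` the input size.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cg_ac`.
#' @export
build_ac <- function(cfg, seed = 1L) {
  set.seed(substream_seed(seed, "ac"))
  res <- cfg$final_resolution
  k <- cfg$n_orientation_classes
  eq <- cfg$equalized_lr
  if (cfg$ac_backbone == "demo_cnn") {
    widths <- c(8L, 16L, 32L)
    lay <- list()
    r <- res; cin <- 1L
    for (wd in widths) {
      lay <- c(lay, list(layer_conv2d(r, r, cin, wd, equalized = eq),
                         layer_act("lrelu"),
                         layer_avgpool2(r, r, wd)))
      r <- r %/% 2L; cin <- wd
    }
    n_feat <- 64L
    lay <- c(lay, list(layer_dense(r^2 * cin, n_feat, equalized = eq),
                       layer_act("lrelu")))
    modules <- list(trunk = structure(list(layers = lay), class = "cg_seq"))
    blocks <- NULL
  } else if (cfg$ac_backbone == "densenet121") {
    built <- build_densenet(res, eq)
    modules <- built$modules
    blocks <- built$blocks
    n_feat <- built$n_feat
  } else stop("unknown AC backbone: ", cfg$ac_backbone)
  modules$head_orient <- seq_net(layer_dense(n_feat, k, gain = 1,
                                             equalized = eq))
  modules$head_tr <- seq_net(layer_dense(n_feat, 1L, gain = 1,
                                         equalized = eq))
  modules$head_te <- seq_net(layer_dense(n_feat, 1L, gain = 1,
                                         equalized = eq))
  structure(list(cfg = cfg, modules = modules, blocks = blocks,
                 backbone = cfg$ac_backbone),
            class = "cg_ac")
}

#' @export
print.cg_ac <- function(x, ...) {
  cat("<cg_ac>", x$backbone, "backbone,",
      format(count_parameters(x$modules), big.mark = ","),
      "parameters, input", x$cfg$final_resolution, "px\n")
  invisible(x)
}

# DenseNet-121-layout backbone: stem (7x7/2 conv, BN, ReLU, 2x2 avg pool),
# four dense blocks with growth rate 32 and 4*growth bottlenecks, 0.5
# compression transitions, final BN-ReLU-global average pool.
build_densenet <- function(res, eq, block_config = c(6L, 12L, 24L, 16L),
                           growth = 32L) {
  modules <- list()
  r <- res %/% 2L
  stem_conv <- layer_conv2d(res, res, 1L, 64L, kernel = 7L, stride = 2L,
                            pad = 3L, equalized = eq)
  modules$stem <- structure(list(layers = list(
    stem_conv, layer_batchnorm(64L, r^2), layer_act("relu"),
    layer_avgpool2(r, r, 64L))), class = "cg_seq")
  r <- r %/% 2L
  c_now <- 64L
  blocks <- list()
  for (b in seq_along(block_config)) {
    lids <- character(0)
    for (l in seq_len(block_config[b])) {
      id <- sprintf("b%d_l%d", b, l)
      bott <- 4L * growth
      modules[[id]] <- structure(list(layers = list(
        layer_batchnorm(c_now, r^2), layer_act("relu"),
        layer_conv2d(r, r, c_now, bott, kernel = 1L, equalized = eq),
        layer_batchnorm(bott, r^2), layer_act("relu"),
        layer_conv2d(r, r, bott, growth, equalized = eq))),
        class = "cg_seq")
      lids <- c(lids, id)
      c_now <- c_now + growth
    }
    blocks[[b]] <- list(layers = lids, hw = r^2)
    if (b < length(block_config)) {
      c_out <- c_now %/% 2L
      modules[[sprintf("t%d", b)]] <- structure(list(layers = list(
        layer_batchnorm(c_now, r^2), layer_act("relu"),
        layer_conv2d(r, r, c_now, c_out, kernel = 1L, equalized = eq),
        layer_avgpool2(r, r, c_out))), class = "cg_seq")
      blocks[[b]]$transition <- sprintf("t%d", b)
      c_now <- c_out
      r <- r %/% 2L
    }
  }
  modules$final <- structure(list(layers = list(
    layer_batchnorm(c_now, r^2), layer_act("relu"),
    layer_global_avgpool(r^2, c_now))), class = "cg_seq")
  list(modules = modules, blocks = blocks, n_feat = c_now)
}

ac_trunk_forward <- function(ac, x, training = TRUE) {
  if (ac$backbone == "demo_cnn") {
    fw <- seq_forward(ac$modules$trunk, x, training)
    return(list(feat = fw$y, caches = list(trunk = fw$caches)))
  }
  caches <- list()
  fw <- seq_forward(ac$modules$stem, x, training)
  caches$stem <- fw$caches
  h <- fw$y
  for (b in seq_along(ac$blocks)) {
    hw <- ac$blocks[[b]]$hw
    for (id in ac$blocks[[b]]$layers) {
      lf <- seq_forward(ac$modules[[id]], h, training)
      caches[[id]] <- lf$caches
      h <- rbind(h, lf$y)  # channel concat (rows are channel-major)
    }
    tid <- ac$blocks[[b]]$transition
    if (!is.null(tid)) {
      tf <- seq_forward(ac$modules[[tid]], h, training)
      caches[[tid]] <- tf$caches
      h <- tf$y
    }
  }
  fin <- seq_forward(ac$modules$final, h, training)
  caches$final <- fin$caches
  list(feat = fin$y, caches = caches)
}

ac_trunk_backward <- function(ac, tr_fw, dfeat) {
  if (ac$backbone == "demo_cnn") {
    bk <- seq_backward(ac$modules$trunk, tr_fw$caches$trunk, dfeat)
    return(list(dx = bk$dx, grads = list(trunk = bk$grads)))
  }
  grads <- list()
  fin <- seq_backward(ac$modules$final, tr_fw$caches$final, dfeat)
  grads$final <- fin$grads
  dh <- fin$dx
  for (b in rev(seq_along(ac$blocks))) {
    tid <- ac$blocks[[b]]$transition
    if (!is.null(tid)) {
      tb <- seq_backward(ac$modules[[tid]], tr_fw$caches[[tid]], dh)
      grads[[tid]] <- tb$grads
      dh <- tb$dx
    }
    hw <- ac$blocks[[b]]$hw
    growth_rows <- hw * 32L
    for (id in rev(ac$blocks[[b]]$layers)) {
      n_rows <- nrow(dh)
      d_new <- dh[(n_rows - growth_rows + 1L):n_rows, , drop = FALSE]
      dh <- dh[seq_len(n_rows - growth_rows), , drop = FALSE]
      lb <- seq_backward(ac$modules[[id]], tr_fw$caches[[id]], d_new)
      grads[[id]] <- lb$grads
      dh <- dh + lb$dx
    }
  }
  st <- seq_backward(ac$modules$stem, tr_fw$caches$stem, dh)
  grads$stem <- st$grads
  list(dx = st$dx, grads = grads)
}

softmax_cols <- function(l) {
  l <- l - rep(apply(l, 2, max), each = nrow(l))
  e <- exp(l)
  e / rep(colSums(e), each = nrow(l))
}

#' Run the auxiliary classifier
#'
#' @param ac A [build_ac()] network.
#' @param x Image batch matrix (`res^2` x n).
#' @param training Use batch statistics in normalization layers.
#' @param keep_cache Keep caches for [ac_backward()].
#' @return List with `orient` (class-probability matrix, classes x n, columns
#'   summing to 1), `tr` and `te` (numeric vectors in \[0, 1\]).
#' @export
ac_forward <- function(ac, x, training = FALSE, keep_cache = FALSE) {
  res <- ac$cfg$final_resolution
  if (nrow(x) != res^2)
    stop("AC input must be ", res, "x", res, " images")
  tr_fw <- ac_trunk_forward(ac, x, training)
  lo <- seq_forward(ac$modules$head_orient, tr_fw$feat)
  ltr <- seq_forward(ac$modules$head_tr, tr_fw$feat)
  lte <- seq_forward(ac$modules$head_te, tr_fw$feat)
  p <- softmax_cols(lo$y)
  tr_hat <- 1 / (1 + exp(-drop(ltr$y)))
  te_hat <- 1 / (1 + exp(-drop(lte$y)))
  out <- list(orient = p, tr = tr_hat, te = te_hat)
  if (keep_cache)
    out$cache <- list(trunk = tr_fw, orient = lo$caches, tr = ltr$caches,
                      te = lte$caches, p = p, tr_hat = tr_hat,
                      te_hat = te_hat)
  out
}

# Gradient of w_iop*CCE + w_te*MSE(te) + w_tr*MSE(tr) (batch means) w.r.t.
# the AC parameters and input. `weights` is c(iop, te, tr). Softmax+CCE and
# sigmoid+MSE head gradients are closed-form.
ac_backward <- function(ac, fw, target, weights) {
  stopifnot(!is.null(fw$cache))
  n <- ncol(fw$orient)
  k <- nrow(fw$orient)
  onehot <- target[3:(2 + k), , drop = FALSE]
  dlo <- weights[1] * (fw$cache$p - onehot) / n
  dtr <- weights[3] * 2 * (fw$cache$tr_hat - target["tr", ]) *
    fw$cache$tr_hat * (1 - fw$cache$tr_hat) / n
  dte <- weights[2] * 2 * (fw$cache$te_hat - target["te", ]) *
    fw$cache$te_hat * (1 - fw$cache$te_hat) / n
  grads <- list()
  bo <- seq_backward(ac$modules$head_orient, fw$cache$orient, dlo)
  btr <- seq_backward(ac$modules$head_tr, fw$cache$tr, matrix(dtr, 1, n))
  bte <- seq_backward(ac$modules$head_te, fw$cache$te, matrix(dte, 1, n))
  grads$head_orient <- bo$grads
  grads$head_tr <- btr$grads
  grads$head_te <- bte$grads
  dfeat <- bo$dx + btr$dx + bte$dx
  tb <- ac_trunk_backward(ac, fw$cache$trunk, dfeat)
  grads <- c(grads, tb$grads)
  list(grads = grads, dx = tb$dx)
}
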