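# Training orchestration: auxiliary-classifier pretraining (with image-only
# augmentation) and the progressive conditional WGAN-GP loop with balanced
# critic/generator updates, fade-in blending, and adaptive conditioning
# weights that become active once the final resolution is reached.

#' Optimizer configuration
#'
#' @param batch_size Minibatch size (>= 1).
#' @param lr Adam learning rate (> 0).
#' @param beta1,beta2 Adam moment decays in \[0, 1).
#' @return An object of class `cg_optim_config`.
#' @export
optim_config <- function(batch_size, lr, beta1, beta2) {
  stopifnot(batch_size >= 1, lr > 0, beta1 >= 0, beta1 < 1, beta2 >= 0,
            beta2 < 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2), class = "cg_optim_config")
}

#' Default optimizer for the auxiliary classifier
#' (batch 64, Adam, lr 0.001, beta1 = 0, beta2 = 0.99).
#' @return A [optim_config()].
#' @export
ac_optim_config <- function() optim_config(64L, 0.001, 0, 0.99)

#' Default optimizer for generator and critic
#' (batch 16, Adam, lr 0.001, beta1 = 0.9, beta2 = 0.99).
#' @return A [optim_config()].
#' @export
gan_optim_config <- function() optim_config(16L, 0.001, 0.9, 0.99)

#' Progressive training schedule
#'
#' @param stages data.frame with columns `resolution`, `fade_images`,
#'   `stabilize_images`. Resolutions must strictly double. The first stage
#'   has nothing to fade in; its fade budget is spent as additional
#'   stabilization.
#' @param total_images_cap Hard cap on total images seen.
#' @return An object of class `progressive_schedule`.
#' @export
progressive_schedule <- function(stages, total_images_cap = Inf) {
  stopifnot(all(c("resolution", "fade_images", "stabilize_images") %in%
                  names(stages)))
  if (nrow(stages) > 1 &&
      any(stages$resolution[-1] != 2 * stages$resolution[-nrow(stages)]))
    stop("stage resolutions must strictly double")
  if (any(stages$fade_images <= 0) || any(stages$stabilize_images <= 0))
    stop("image budgets must be positive")
  structure(list(stages = stages, total_images_cap = total_images_cap),
            class = "progressive_schedule")
}

#' @export
print.progressive_schedule <- function(x, ...) {
  cat("<progressive_schedule>", nrow(x$stages), "stages:",
      paste(sprintf("%dpx(%g/%g)", x$stages$resolution, x$stages$fade_images,
                    x$stages$stabilize_images), collapse = " "),
      "| cap", x$total_images_cap, "\n")
  invisible(x)
}

#' Default progressive schedules
#'
#' The `reference` profile (the full-scale configuration) doubles from the
#' base resolution with 800,000
#' stabilization images plus 800,000 fade-in images per stage, capped at ten
#' million images in total. The `demo` profile keeps the same shape at desk
#' scale: final resolution 32, per-stage budgets of a few thousand images
#' (at most 20,000 per stage) with the largest budget at the final stage,
#' where conditioning is learned.
#'
#' @param final_resolution Final stage resolution (power-of-two multiple of
#'   `base_resolution`).
#' @param profile `"reference"` (full scale) or `"demo"`.
#' @param base_resolution Base stage resolution (default 4).
#' @return A [progressive_schedule()].
#' @export
default_schedule <- function(final_resolution = NULL,
                             profile = c("reference", "demo"),
                             base_resolution = 4L) {
  profile <- match.arg(profile)
  if (is.null(final_resolution))
    final_resolution <- if (profile == "reference") 256L else 32L
  s <- log2(final_resolution / base_resolution)
  if (s < 0 || abs(s - round(s)) > 1e-9) stop("invalid final resolution")
  n_stages <- as.integer(round(s)) + 1L
  res <- base_resolution * 2L^(seq_len(n_stages) - 1L)
  if (profile == "reference") {
    stages <- data.frame(resolution = res, fade_images = 8e5,
                         stabilize_images = 8e5)
    progressive_schedule(stages, total_images_cap = 1e7)
  } else {
    fade <- rep(2000, n_stages)
    stab <- rep(2000, n_stages)
    fade[n_stages] <- 3000
    stab[n_stages] <- 7000
    stages <- data.frame(resolution = res, fade_images = fade,
                         stabilize_images = stab)
    progressive_schedule(stages, total_images_cap = 3e5)
  }
}

#' Augmentation policy for AC pretraining
#'
#' Random horizontal flips (per image), rotations up to `max_rotate` degrees
#' and translations up to `max_translate` of the image side (shared within a
#' minibatch). Applied to images only; labels are never transformed. The
#' critic sees no augmentation.
#'
#' @param enabled Master switch.
#' @param hflip Allow horizontal flips.
#' @param max_rotate Maximal absolute rotation (degrees).
#' @param max_translate Maximal absolute translation (fraction of side).
#' @return An object of class `cg_augment_policy`.
#' @export
augment_policy <- function(enabled = TRUE, hflip = TRUE, max_rotate = 10,
                           max_translate = 0.05) {
  structure(list(enabled = enabled, hflip = hflip, max_rotate = max_rotate,
                 max_translate = max_translate),
            class = "cg_augment_policy")
}

# Augment a batch (pixels x n). Flips are drawn per image; the rotation
# angle and translation vector are drawn per batch.
augment_batch <- function(x, size, policy) {
  if (!policy$enabled) return(x)
  n <- ncol(x)
  if (policy$hflip) {
    flip <- stats::runif(n) < 0.5
    if (any(flip)) {
      a <- array(x[, flip, drop = FALSE], c(size, size, sum(flip)))
      x[, flip] <- a[, size:1, , drop = FALSE]
    }
  }
  arr <- array(x, c(size, size, n))
  img <- EBImage::Image(arr)
  if (policy$max_rotate > 0) {
    ang <- stats::runif(1, -policy$max_rotate, policy$max_rotate)
    img <- EBImage::rotate(img, ang, output.dim = c(size, size),
                           bg.col = -1)
  }
  if (policy$max_translate > 0) {
    v <- round(stats::runif(2, -1, 1) * policy$max_translate * size)
    img <- EBImage::translate(img, v, bg.col = -1)
  }
  matrix(EBImage::imageData(img), size^2, n)
}

# Validation metrics of an AC on a labeled image batch, in physical units.
ac_validation_metrics <- function(ac, images, meta, codec,
                                  batch_size = 256L) {
  n <- ncol(images)
  tr_hat <- te_hat <- numeric(n)
  ori_hat <- character(n)
  for (b in seq(1L, n, by = batch_size)) {
    cols <- b:min(n, b + batch_size - 1L)
    out <- ac_forward(ac, images[, cols, drop = FALSE])
    dec <- decode_condition(rbind(out$tr, out$te, out$orient), codec)
    tr_hat[cols] <- dec$tr
    te_hat[cols] <- dec$te
    ori_hat[cols] <- dec$orientation
  }
  list(mae_tr = mean(abs(tr_hat - meta$tr)),
       mae_te = mean(abs(te_hat - meta$te)),
       orientation_accuracy = 100 * mean(ori_hat == meta$orientation))
}

#' Pretrain the auxiliary classifier
#'
#' Minimizes the weighted AC loss (cross-entropy on orientation, MSE on the
#' normalized TR and TE) with Adam on a labeled dataset at the final
#' resolution. Augmentation is applied to the AC's training images only.
#'
#' @param dataset A [make_phantom_dataset()]-style dataset: list with
#'   `images` (pixels x n), `meta` (`tr`, `te`, `orientation`, `study_id`),
#'   `size`.
#' @param ac An AC from [build_ac()] (built fresh from `cfg` when `NULL`).
#' @param codec A [condition_codec()].
#' @param cfg A [net_config()] (used when `ac` is `NULL`).
#' @param optim An [optim_config()]; default batch 64, Adam lr 0.001,
#'   beta1 0, beta2 0.99.
#' @param epochs Training epochs.
#' @param augment An [augment_policy()].
#' @param weights A [loss_weights()] (lambda_iop 1, lambda_te/tr 10).
#' @param val_fraction Fraction of studies held out for the per-epoch
#'   validation metrics.
#' @param lr_schedule Optional numeric vector of per-epoch learning rates
#'   (recycled to `epochs`), overriding `optim$lr`; e.g. a step decay for
#'   stable late epochs. Default: constant `optim$lr`.
#' @param seed Master seed (data order, augmentation, initialization).
#' @return List with `ac` (trained), `log` (per-epoch data.frame: training
#'   loss, validation MAE for TR and TE in ms, orientation accuracy in
#'   percent) and `val_index` (columns used for validation).
#' @export
pretrain_ac <- function(dataset, ac = NULL, codec = condition_codec(),
                        cfg = NULL, optim = ac_optim_config(), epochs = 20L,
                        augment = augment_policy(),
                        weights = loss_weights(), val_fraction = 0.15,
                        lr_schedule = NULL, seed = 1L) {
  n <- ncol(dataset$images)
  if (!n) stop("empty dataset")
  if (is.null(ac)) {
    if (is.null(cfg)) cfg <- net_config(final_resolution = dataset$size)
    ac <- build_ac(cfg, seed = seed)
  }
  set.seed(substream_seed(seed, "ac_split"))
  studies <- unique(dataset$meta$study_id)
  val_studies <- sample(studies, max(1, round(val_fraction *
                                                length(studies))))
  val_idx <- which(dataset$meta$study_id %in% val_studies)
  train_idx <- setdiff(seq_len(n), val_idx)
  target_all <- encode_condition(dataset$meta, codec)
  w3 <- c(weights$lambda_iop, weights$lambda_te, weights$lambda_tr)
  st <- adam_init(ac$modules)
  t_adam <- 0L
  log_rows <- vector("list", epochs)
  lr_by_epoch <- if (is.null(lr_schedule)) rep(optim$lr, epochs) else
    rep_len(lr_schedule, epochs)
  set.seed(substream_seed(seed, "ac_train"))
  for (ep in seq_len(epochs)) {
    lr_ep <- lr_by_epoch[ep]
    ord <- sample(train_idx)
    losses <- c()
    for (b in seq(1L, length(ord), by = optim$batch_size)) {
      cols <- ord[b:min(length(ord), b + optim$batch_size - 1L)]
      if (length(cols) < 2) next
      x <- augment_batch(dataset$images[, cols, drop = FALSE], dataset$size,
                         augment)
      target <- target_all[, cols, drop = FALSE]
      fw <- ac_forward(ac, x, training = TRUE, keep_cache = TRUE)
      losses <- c(losses, as.numeric(ac_training_loss(fw, target, weights)))
      bk <- ac_backward(ac, fw, target, w3)
      t_adam <- t_adam + 1L
      upd <- adam_step(ac$modules, bk$grads, st, lr_ep, optim$beta1,
                       optim$beta2, t_adam)
      ac$modules <- upd$modules
      st <- upd$state
    }
    vm <- ac_validation_metrics(ac, dataset$images[, val_idx, drop = FALSE],
                                dataset$meta[val_idx, ], codec)
    log_rows[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                                 val_mae_tr = vm$mae_tr,
                                 val_mae_te = vm$mae_te,
                                 val_orientation_accuracy =
                                   vm$orientation_accuracy)
  }
  list(ac = ac, log = do.call(rbind, log_rows), val_index = val_idx)
}

# Downsample an image batch by repeated 2x2 average pooling.
downsample_batch <- function(x, from_res, to_res) {
  r <- from_res
  while (r > to_res) {
    pool <- layer_avgpool2(r, r, 1L)
    x <- layer_forward(pool, x)$y
    r <- r %/% 2L
  }
  x
}

#' Train the progressive conditional GAN
#'
#' Alternates one critic update and one generator update (balanced counts).
#' The critic minimizes the Wasserstein loss with gradient penalty; the
#' generator minimizes its adversarial loss plus the gamma-weighted
#' conditioning loss. Conditioning is inactive (condition sub-vector zeroed,
#' gamma frozen at 0) until the final resolution is reached; at the final
#' stage the adaptive weights are updated once per generator step from the
#' step's batch losses.
#'
#' @param dataset Labeled dataset (images at the final resolution + `meta`).
#' @param ac A pretrained AC ([pretrain_ac()]).
#' @param gen,disc Networks from [build_generator()] /
#'   [build_discriminator()].
#' @param codec A [condition_codec()].
#' @param schedule A [progressive_schedule()].
#' @param optim An [optim_config()]; default batch 16, Adam lr 0.001,
#'   beta1 0.9, beta2 0.99.
#' @param weights A [loss_weights()] (supplies `lambda_gp`).
#' @param adaptive An [adaptive_weight_state()].
#' @param continue_ac Also update the AC on real images during GAN training
#'   (default `FALSE`: the AC stays frozen).
#' @param checkpoint_every Interval (in images seen) between conditioning
#'   checkpoints during the final stage.
#' @param eval_batch Size of the fixed evaluation batch used at checkpoints.
#' @param seed Master seed.
#' @param verbose Print per-phase progress.
#' @return List with `gen`, `disc`, `ac`, `adaptive` (final state),
#'   `history` (one row per iteration), `checkpoints` (conditioning loss on
#'   the fixed evaluation batch across the final stage) and counters
#'   `n_d_updates`, `n_g_updates`, `images_seen`.
#' @export
train_gan <- function(dataset, ac, gen, disc, codec = condition_codec(),
                      schedule = default_schedule(profile = "demo"),
                      optim = gan_optim_config(), weights = loss_weights(),
                      adaptive = adaptive_weight_state(),
                      continue_ac = FALSE, checkpoint_every = 2000L,
                      eval_batch = 64L, seed = 1L, verbose = FALSE) {
  cfg <- gen$cfg
  n_stages <- nrow(schedule$stages)
  if (schedule$stages$resolution[1] != cfg$base_resolution ||
      n_stages > cfg$n_stages)
    stop("schedule does not match the network configuration")
  n_data <- ncol(dataset$images)
  bs <- optim$batch_size
  target_all <- encode_condition(dataset$meta, codec)

  # image pyramid: dataset images at every stage resolution
  pyramid <- vector("list", n_stages)
  pyramid[[n_stages]] <- dataset$images
  for (s in rev(seq_len(n_stages - 1L)))
    pyramid[[s]] <- downsample_batch(pyramid[[s + 1L]],
                                     schedule$stages$resolution[s + 1L],
                                     schedule$stages$resolution[s])

  g_state <- adam_init(gen$modules)
  d_state <- adam_init(disc$modules)
  ac_state <- if (continue_ac) adam_init(ac$modules) else NULL
  g_t <- d_t <- ac_t <- 0L
  n_d_updates <- n_g_updates <- 0L
  images_seen <- 0
  history <- list()
  checkpoints <- list()

  # fixed evaluation batch for the conditioning checkpoints
  set.seed(substream_seed(seed, "eval"))
  eval_rows <- sample.int(n_data, eval_batch, replace = eval_batch > n_data)
  eval_target <- target_all[, eval_rows, drop = FALSE]
  eval_z <- matrix(stats::rnorm(cfg$latent_dim * eval_batch),
                   cfg$latent_dim, eval_batch)
  checkpoint_cond <- function(stage, alpha) {
    gfw <- generator_forward(gen, eval_z, eval_target, stage, alpha)
    out <- ac_forward(ac, gfw$y)
    tot <- ac_training_loss(out, eval_target, weights)
    comp <- attr(tot, "components")
    data.frame(images_seen = images_seen, cond_loss = as.numeric(tot),
               cce = comp["cce"], mse_te = comp["mse_te"],
               mse_tr = comp["mse_tr"], row.names = NULL)
  }

  set.seed(substream_seed(seed, "gan"))
  done <- FALSE
  for (s in seq_len(n_stages)) {
    res <- schedule$stages$resolution[s]
    final_stage <- s == n_stages
    conditioning <- final_stage
    next_ckpt <- images_seen + checkpoint_every
    if (conditioning)
      checkpoints[[length(checkpoints) + 1L]] <- checkpoint_cond(s, 0)
    for (phase in c("fade", "stabilize")) {
      budget <- if (phase == "fade") schedule$stages$fade_images[s] else
        schedule$stages$stabilize_images[s]
      n_iter <- ceiling(budget / bs)
      for (it in seq_len(n_iter)) {
        if (images_seen >= schedule$total_images_cap) { done <- TRUE; break }
        alpha <- if (phase == "fade" && s > 1) min(1, (it * bs) / budget)
          else 1
        rows <- sample.int(n_data, bs)
        x_real <- pyramid[[s]][, rows, drop = FALSE]
        target_real <- target_all[, rows, drop = FALSE]
        cond_rows <- sample.int(n_data, bs)
        cond <- if (conditioning) target_all[, cond_rows, drop = FALSE] else
          matrix(0, cfg$cond_dim, bs)

        # ---- critic update ----
        z <- matrix(stats::rnorm(cfg$latent_dim * bs), cfg$latent_dim, bs)
        x_fake <- generator_forward(gen, z, cond, s, alpha)$y
        fw_real <- discriminator_forward(disc, x_real, s, alpha)
        fw_fake <- discriminator_forward(disc, x_fake, s, alpha)
        bk_real <- discriminator_backward(disc, fw_real,
                                          matrix(-1 / bs, 1, bs))
        bk_fake <- discriminator_backward(disc, fw_fake,
                                          matrix(1 / bs, 1, bs))
        u <- stats::runif(bs)
        x_hat <- x_real * rep(u, each = res^2) +
          x_fake * rep(1 - u, each = res^2)
        gpg <- discriminator_gp_grads(disc, x_hat, s, alpha,
                                      weights$lambda_gp)
        d_grads <- grads_add(grads_add(bk_real$grads, bk_fake$grads),
                             gpg$grads)
        d_t <- d_t + 1L
        upd <- adam_step(disc$modules, d_grads, d_state, optim$lr,
                         optim$beta1, optim$beta2, d_t)
        disc$modules <- upd$modules
        d_state <- upd$state
        n_d_updates <- n_d_updates + 1L
        d_loss <- critic_loss(drop(fw_real$y), drop(fw_fake$y),
                              gpg$penalty)

        # ---- generator update ----
        z <- matrix(stats::rnorm(cfg$latent_dim * bs), cfg$latent_dim, bs)
        gfw <- generator_forward(gen, z, cond, s, alpha, keep_cache = TRUE)
        dfw <- discriminator_forward(disc, gfw$y, s, alpha)
        g_adv <- generator_adversarial_loss(drop(dfw$y))
        dbk <- discriminator_backward(disc, dfw, matrix(-1 / bs, 1, bs))
        dimg <- dbk$dx
        cond_contrib <- 0
        comp_fake <- NULL
        if (conditioning) {
          acfw <- ac_forward(ac, gfw$y, keep_cache = TRUE)
          cl <- conditioning_loss(adaptive, acfw, cond)
          cond_contrib <- as.numeric(cl)
          comp_fake <- attr(cl, "components")
          if (any(adaptive$gamma > 0)) {
            acbk <- ac_backward(ac, acfw, cond, weights = unname(
              adaptive$gamma[c("iop", "te", "tr")]))
            dimg <- dimg + acbk$dx
          }
        }
        gbk <- generator_backward(gen, gfw, dimg)
        g_t <- g_t + 1L
        upd <- adam_step(gen$modules, gbk$grads, g_state, optim$lr,
                         optim$beta1, optim$beta2, g_t)
        gen$modules <- upd$modules
        g_state <- upd$state
        n_g_updates <- n_g_updates + 1L

        # ---- adaptive weights (final stage, once per generator step) ----
        if (conditioning) {
          ac_real <- ac_forward(ac, x_real)
          comp_real <- condition_loss_components(ac_real, target_real)
          adaptive <- update_adaptive_weight(adaptive, "iop",
                                             comp_fake[["cce"]],
                                             comp_real[["cce"]])
          adaptive <- update_adaptive_weight(adaptive, "te",
                                             comp_fake[["mse_te"]],
                                             comp_real[["mse_te"]])
          adaptive <- update_adaptive_weight(adaptive, "tr",
                                             comp_fake[["mse_tr"]],
                                             comp_real[["mse_tr"]])
          if (continue_ac) {
            acfw_r <- ac_forward(ac, x_real, training = TRUE,
                                 keep_cache = TRUE)
            acbk_r <- ac_backward(ac, acfw_r, target_real,
                                  weights = c(1, 10, 10))
            ac_t <- ac_t + 1L
            upd <- adam_step(ac$modules, acbk_r$grads, ac_state, 0.001, 0,
                             0.99, ac_t)
            ac$modules <- upd$modules
            ac_state <- upd$state
          }
        }

        images_seen <- images_seen + bs
        history[[length(history) + 1L]] <- data.frame(
          stage = s, resolution = res, phase = phase, alpha = alpha,
          images = bs, images_seen = images_seen, d_loss = d_loss,
          g_adv = g_adv, cond_loss = cond_contrib,
          gamma_iop = adaptive$gamma[["iop"]],
          gamma_te = adaptive$gamma[["te"]],
          gamma_tr = adaptive$gamma[["tr"]])
        if (conditioning && images_seen >= next_ckpt) {
          checkpoints[[length(checkpoints) + 1L]] <- checkpoint_cond(s,
                                                                     alpha)
          next_ckpt <- next_ckpt + checkpoint_every
        }
      }
      if (verbose)
        message(sprintf("stage %d (%dpx) %s done; %d images seen", s, res,
                        phase, images_seen))
      if (done) break
    }
    if (done) break
  }
  if (n_stages == cfg$n_stages)
    checkpoints[[length(checkpoints) + 1L]] <- checkpoint_cond(n_stages, 1)
  list(gen = gen, disc = disc, ac = ac, adaptive = adaptive,
       history = do.call(rbind, history),
       checkpoints = do.call(rbind, checkpoints),
       n_d_updates = n_d_updates, n_g_updates = n_g_updates,
       images_seen = images_seen)
}

#' Generate images for given conditions
#'
#' @param gen A trained generator.
#' @param conds Conditions (`acquisition_condition` or data.frame).
#' @param codec A [condition_codec()].
#' @param stage,alpha Progressive stage and fade weight (default: fully
#'   grown final stage).
#' @param seed Seed for the latent draws (`z ~ N(0, 1)`).
#' @param z Optional fixed latent matrix overriding the draws.
#' @return Image batch matrix (pixels x n).
#' @export
generate_images <- function(gen, conds, codec, stage = gen$cfg$n_stages,
                            alpha = 1, seed = 1L, z = NULL) {
  target <- encode_condition(conds, codec)
  n <- ncol(target)
  if (is.null(z)) {
    set.seed(substream_seed(seed, "z"))
    z <- matrix(stats::rnorm(gen$cfg$latent_dim * n), gen$cfg$latent_dim, n)
  }
  generator_forward(gen, z, target, stage, alpha)$y
}
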