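# Loss functions and the adaptive conditioning-weight mechanism: the
# Wasserstein critic loss with gradient penalty, the auxiliary-classifier
# loss (weighted categorical cross-entropy on orientation plus mean-squared
# errors on the normalized repetition and echo times), the adaptively
# gamma-weighted conditioning loss applied to the generator, and the codec
# that maps acquisition conditions onto the normalized vectors the networks
# consume.

#' Condition codec
#'
#' Maps an acquisition condition (TR in ms, TE in ms, orientation class) to
#' the normalized representation fed to the networks: TR and TE are min-max
#' scaled onto \[0, 1\] by the codec ranges and the orientation is one-hot
#' encoded.
#'
#' @param tr_range Numeric length-2, TR range in ms. Default `c(1800, 5000)`,
#'   the range the conditioning is restricted to.
#' @param te_range Numeric length-2, TE range in ms. Default `c(12, 50)`.
#' @param orientation_classes Ordered character vector of orientation class
#'   names.
#' @return An object of class `cg_codec`.
#' @export
condition_codec <- function(tr_range = c(1800, 5000), te_range = c(12, 50),
                            orientation_classes = c("sagittal", "coronal")) {
  stopifnot(length(tr_range) == 2, diff(tr_range) > 0,
            length(te_range) == 2, diff(te_range) > 0,
            length(orientation_classes) >= 2)
  structure(list(tr_range = as.numeric(tr_range),
                 te_range = as.numeric(te_range),
                 orientation_classes = orientation_classes),
            class = "cg_codec")
}

#' @export
print.cg_codec <- function(x, ...) {
  cat("<cg_codec> TR", x$tr_range[1], "-", x$tr_range[2], "ms | TE",
      x$te_range[1], "-", x$te_range[2], "ms | orientations:",
      paste(x$orientation_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Encode acquisition conditions
#'
#' @param cond An `acquisition_condition` or a data.frame with columns
#'   `tr`, `te`, `orientation`.
#' @param codec A [condition_codec()].
#' @return A matrix with one column per condition and rows
#'   `(tr, te, <one-hot orientation>)`, all entries in \[0, 1\].
#' @export
encode_condition <- function(cond, codec) {
  df <- as_condition_df(cond)
  if (any(df$tr < codec$tr_range[1] - 1e-9 | df$tr > codec$tr_range[2] + 1e-9))
    stop("TR outside codec range [", codec$tr_range[1], ", ",
         codec$tr_range[2], "] ms")
  if (any(df$te < codec$te_range[1] - 1e-9 | df$te > codec$te_range[2] + 1e-9))
    stop("TE outside codec range [", codec$te_range[1], ", ",
         codec$te_range[2], "] ms")
  ocls <- match(as.character(df$orientation), codec$orientation_classes)
  if (anyNA(ocls)) stop("unknown orientation class")
  k <- length(codec$orientation_classes)
  onehot <- matrix(0, k, nrow(df))
  onehot[cbind(ocls, seq_len(nrow(df)))] <- 1
  rbind(tr = (df$tr - codec$tr_range[1]) / diff(codec$tr_range),
        te = (df$te - codec$te_range[1]) / diff(codec$te_range),
        onehot)
}

#' Decode normalized condition vectors
#'
#' Inverts [encode_condition()]: maps normalized TR/TE back to ms and the
#' orientation one-hot (or probability vector) to the arg-max class.
#'
#' @param v A vector or matrix as produced by [encode_condition()] (columns
#'   are conditions).
#' @param codec A [condition_codec()].
#' @return A data.frame with columns `tr`, `te`, `orientation`.
#' @export
decode_condition <- function(v, codec) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 1)
  k <- length(codec$orientation_classes)
  if (nrow(v) != 2 + k) stop("condition vector length mismatch: expected ",
                             2 + k, " rows, got ", nrow(v))
  ori <- codec$orientation_classes[
    apply(v[3:(2 + k), , drop = FALSE], 2, which.max)]
  data.frame(tr = v[1, ] * diff(codec$tr_range) + codec$tr_range[1],
             te = v[2, ] * diff(codec$te_range) + codec$te_range[1],
             orientation = ori, stringsAsFactors = FALSE)
}

as_condition_df <- function(cond) {
  if (inherits(cond, "acquisition_condition"))
    return(data.frame(tr = cond$tr, te = cond$te,
                      orientation = cond$orientation,
                      stringsAsFactors = FALSE))
  if (is.data.frame(cond)) {
    stopifnot(all(c("tr", "te", "orientation") %in% names(cond)))
    return(cond)
  }
  stop("cond must be an acquisition_condition or a data.frame")
}

# ---- WGAN-GP ----------------------------------------------------------------

#' Critic (discriminator) loss of the Wasserstein GAN with gradient penalty
#'
#' `mean(d_fake) - mean(d_real) + gp`: the critic is trained to score real
#' images higher than generated ones; the penalty term keeps it approximately
#' 1-Lipschitz.
#'
#' @param d_real_scores,d_fake_scores Numeric vectors of critic scores.
#' @param gp Scalar gradient-penalty term (already weighted), default 0.
#' @return Scalar loss.
#' @export
critic_loss <- function(d_real_scores, d_fake_scores, gp = 0) {
  if (!length(d_real_scores) || !length(d_fake_scores))
    stop("empty score batch")
  mean(d_fake_scores) - mean(d_real_scores) + gp
}

#' Generator adversarial loss
#'
#' The generator side of the Wasserstein objective: `-mean(d_fake)`.
#'
#' @param d_fake_scores Numeric vector of critic scores on generated images.
#' @return Scalar loss.
#' @export
generator_adversarial_loss <- function(d_fake_scores) {
  if (!length(d_fake_scores)) stop("empty score batch")
  -mean(d_fake_scores)
}

#' Gradient penalty
#'
#' Samples points uniformly along straight lines between paired real and
#' generated images, `x_hat = u * x_real + (1 - u) * x_fake` with one uniform
#' `u` per sample, and returns
#' `lambda_gp * mean((||grad_x D(x_hat)||_2 - 1)^2)`.
#'
#' @param critic A critic built by [build_discriminator()], or any function
#'   taking an image batch matrix and returning `list(scores, input_grad_fn)`
#'   where `input_grad_fn(dy)` backpropagates per-sample seeds to the input.
#' @param x_real,x_fake Image batch matrices (pixels x n), equal shapes.
#' @param lambda_gp Penalty weight; the training default is 10.
#' @param seed Integer seed for the interpolation draws.
#' @param stage,alpha Progressive stage and fade weight when `critic` is a
#'   progressive discriminator.
#' @return Scalar penalty (already multiplied by `lambda_gp`), with the
#'   per-sample gradient norms in attribute `"grad_norms"` and the
#'   interpolates in attribute `"x_hat"`.
#' @export
gradient_penalty <- function(critic, x_real, x_fake, lambda_gp = 10,
                             seed = NULL, stage = NULL, alpha = 1) {
  if (!identical(dim(x_real), dim(x_fake))) stop("batch shape mismatch")
  n <- ncol(x_real)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  x_hat <- x_real * rep(u, each = nrow(x_real)) +
    x_fake * rep(1 - u, each = nrow(x_real))
  g <- critic_input_grad(critic, x_hat, stage = stage, alpha = alpha)
  norms <- sqrt(colSums(g$grad^2))
  structure(lambda_gp * mean((norms - 1)^2),
            grad_norms = norms, x_hat = x_hat)
}

# Per-sample input gradients of a critic. Works for progressive
# discriminators and for plain functions exposing a backward closure.
critic_input_grad <- function(critic, x, stage = NULL, alpha = 1) {
  if (inherits(critic, "pg_discriminator")) {
    if (is.null(stage)) stage <- critic$cfg$n_stages
    fw <- discriminator_forward(critic, x, stage, alpha,
                                freeze_mbstd = TRUE)
    bk <- discriminator_backward(critic, fw, matrix(1, 1, ncol(x)))
    list(scores = drop(fw$y), grad = bk$dx)
  } else if (is.function(critic)) {
    out <- critic(x)
    list(scores = out$scores, grad = out$input_grad_fn(rep(1, ncol(x))))
  } else {
    stop("critic must support input gradients")
  }
}

# ---- auxiliary-classifier losses -------------------------------------------

#' Loss weights
#'
#' Fixed weights of the auxiliary-classifier training loss and the
#' gradient-penalty weight. Defaults are the values used for training:
#' `lambda_gp = 10`, `lambda_iop = 1`, `lambda_te = lambda_tr = 10`.
#'
#' @param lambda_gp,lambda_iop,lambda_te,lambda_tr Nonnegative scalars.
#' @return An object of class `cg_loss_weights`.
#' @export
loss_weights <- function(lambda_gp = 10, lambda_iop = 1, lambda_te = 10,
                         lambda_tr = 10) {
  stopifnot(lambda_gp >= 0, lambda_iop >= 0, lambda_te >= 0, lambda_tr >= 0)
  structure(list(lambda_gp = lambda_gp, lambda_iop = lambda_iop,
                 lambda_te = lambda_te, lambda_tr = lambda_tr),
            class = "cg_loss_weights")
}

# Unweighted per-condition losses: categorical cross-entropy on orientation
# and mean-squared errors on the normalized TE/TR. `pred` is an AC output
# (list with orient (k x n), tr (n), te (n)); `target` an encoded condition
# matrix from encode_condition().
condition_loss_components <- function(pred, target) {
  k <- nrow(pred$orient)
  if (nrow(target) != 2 + k) stop("prediction/target arity mismatch")
  onehot <- target[3:(2 + k), , drop = FALSE]
  if (any(onehot < 0) || any(abs(colSums(onehot) - 1) > 1e-6))
    stop("invalid target orientation probabilities")
  p <- pmax(pred$orient, 1e-12)
  c(cce = -mean(colSums(onehot * log(p))),
    mse_te = mean((pred$te - target["te", ])^2),
    mse_tr = mean((pred$tr - target["tr", ])^2))
}

#' Auxiliary-classifier training loss
#'
#' The weighted sum `lambda_iop * CCE(orientation) + lambda_te * MSE(TE) +
#' lambda_tr * MSE(TR)` on normalized targets.
#'
#' @param pred AC output: list with `orient` (class-probability matrix,
#'   classes x n), `tr`, `te` (numeric vectors in \[0, 1\]).
#' @param target Encoded condition matrix from [encode_condition()].
#' @param w A [loss_weights()] object.
#' @return Scalar total loss with attribute `"components"` holding the three
#'   unweighted terms (`cce`, `mse_te`, `mse_tr`).
#' @export
ac_training_loss <- function(pred, target, w = loss_weights()) {
  if (any(target[c("tr", "te"), ] < -1e-9 | target[c("tr", "te"), ] > 1 + 1e-9))
    stop("TR/TE targets must be normalized to [0, 1]")
  comp <- condition_loss_components(pred, target)
  structure(w$lambda_iop * comp["cce"] + w$lambda_te * comp["mse_te"] +
              w$lambda_tr * comp["mse_tr"],
            names = NULL, components = comp)
}

# ---- adaptive conditioning weights ------------------------------------------

#' Adaptive conditioning-weight state
#'
#' Holds the per-condition adaptive weights `gamma` (orientation, TE, TR)
#' together with their hyperparameters: the cap `tau`, the gamma learning
#' rate `r`, and the real/fake balance `e_hat`. Each update moves gamma by
#' `r * (L_c(fake) - e_hat * L_c(real))`, clamped to `[0, tau]`, so a
#' condition the auxiliary classifier reads worse on generated images than on
#' real ones gets more weight, and a condition already matched gets less.
#' `gamma` starts at zero.
#'
#' @param tau Upper bound for each gamma (default 100).
#' @param r Learning rate of the gamma recurrence (default 0.01).
#' @param e_hat Balance factor applied to the real-data loss (default 1).
#' @param conditions Character vector of condition names.
#' @return An object of class `cg_adaptive_weights`.
#' @export
adaptive_weight_state <- function(tau = 100, r = 0.01, e_hat = 1,
                                  conditions = c("iop", "te", "tr")) {
  stopifnot(tau > 0, r > 0, e_hat >= 0)
  tau <- rep_len(tau, length(conditions))
  names(tau) <- conditions
  gamma <- stats::setNames(numeric(length(conditions)), conditions)
  structure(list(gamma = gamma, tau = tau, r = r, e_hat = e_hat, t = 0L,
                 history = list()),
            class = "cg_adaptive_weights")
}

#' @export
print.cg_adaptive_weights <- function(x, ...) {
  cat("<cg_adaptive_weights> t =", x$t, "| gamma:",
      paste(sprintf("%s=%.4g", names(x$gamma), x$gamma), collapse = ", "),
      "| tau =", x$tau[1], ", r =", x$r, ", e_hat =", x$e_hat, "\n")
  invisible(x)
}

#' Update one adaptive conditioning weight
#'
#' Applies the recurrence
#' `gamma_t = min(tau, max(0, gamma_{t-1} + r * (L_fake - e_hat * L_real)))`
#' for a single condition; other conditions are untouched. The step counter
#' is incremented and the update appended to the state's history.
#'
#' @param state A [adaptive_weight_state()].
#' @param cond_name One of the state's condition names.
#' @param loss_on_fake Condition loss of the AC on generated images.
#' @param loss_on_real Condition loss of the AC on real images.
#' @return The updated state.
#' @export
update_adaptive_weight <- function(state, cond_name, loss_on_fake,
                                   loss_on_real) {
  if (!cond_name %in% names(state$gamma)) stop("unknown condition: ",
                                               cond_name)
  if (!is.finite(loss_on_fake) || !is.finite(loss_on_real))
    stop("non-finite condition loss")
  g <- state$gamma[[cond_name]] +
    state$r * (loss_on_fake - state$e_hat * loss_on_real)
  g <- min(state$tau[[cond_name]], max(0, g))
  state$gamma[[cond_name]] <- g
  state$t <- state$t + 1L
  state$history[[length(state$history) + 1L]] <-
    data.frame(t = state$t, condition = cond_name, gamma = g,
               loss_fake = loss_on_fake, loss_real = loss_on_real)
  state
}

#' Adaptive-weight history as a data.frame
#' @param state A [adaptive_weight_state()].
#' @return data.frame with one row per update.
#' @export
adaptive_weight_history <- function(state) {
  if (!length(state$history))
    return(data.frame(t = integer(), condition = character(),
                      gamma = numeric(), loss_fake = numeric(),
                      loss_real = numeric()))
  do.call(rbind, state$history)
}

#' Conditioning loss applied to the generator
#'
#' The gamma-weighted sum of the three condition losses evaluated on
#' generated samples:
#' `gamma_iop * CCE + gamma_te * MSE(TE) + gamma_tr * MSE(TR)`.
#'
#' @param state A [adaptive_weight_state()].
#' @param ac_out_on_fake AC output on generated images (as in
#'   [ac_training_loss()]).
#' @param target Encoded condition matrix the images were generated for.
#' @return Scalar loss with attribute `"components"`.
#' @export
conditioning_loss <- function(state, ac_out_on_fake, target) {
  comp <- condition_loss_components(ac_out_on_fake, target)
  structure(state$gamma[["iop"]] * comp["cce"] +
              state$gamma[["te"]] * comp["mse_te"] +
              state$gamma[["tr"]] * comp["mse_tr"],
            names = NULL, components = comp)
}
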