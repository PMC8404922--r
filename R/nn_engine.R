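# Minimal batched neural-network layer engine.
#
# A batch of images is a numeric matrix of shape (H*W*C, N): one column per
# sample, rows flattened column-major with the row index h fastest, then the
# column index w, then the channel c. Convolutions run as im2col gathers
# (C++ kernel) followed by BLAS matrix products; every layer provides an
# explicit backward pass so gradients can be propagated to the parameters and
# to the input (the latter is required by the Wasserstein gradient penalty and
# by the auxiliary-classifier guidance of the generator).

PARAM_FIELDS <- c("W", "b", "gamma", "beta")

#' @useDynLib contrastgan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- index builders ---------------------------------------------------------

# 1-based linear index into an (h, w, c) volume; 0 encodes an implicit zero
# (padding) entry understood by the C++ gather/scatter kernels.
vol_index <- function(hi, wi, ci, h, w) hi + h * (wi - 1L) + h * w * (ci - 1L)

build_im2col_idx <- function(h, w, c_in, kernel, stride = 1L, pad = 0L) {
  h_out <- (h + 2L * pad - kernel) %/% stride + 1L
  w_out <- (w + 2L * pad - kernel) %/% stride + 1L
  ho <- rep(seq_len(h_out), times = w_out)
  wo <- rep(seq_len(w_out), each = h_out)
  ki <- rep(seq_len(kernel), times = kernel * c_in)
  kj <- rep(rep(seq_len(kernel), each = kernel), times = c_in)
  ci <- rep(seq_len(c_in), each = kernel * kernel)
  # rows: (ki, kj, ci) fastest; columns: output positions (ho fastest)
  hi <- outer((ki - pad - 1L), (ho - 1L) * stride, `+`) + 1L  # (K, P)
  wi <- outer((kj - pad - 1L), (wo - 1L) * stride, `+`) + 1L
  cc <- matrix(ci, nrow = length(ci), ncol = length(ho))
  idx <- vol_index(hi, wi, cc, h, w)
  idx[hi < 1L | hi > h | wi < 1L | wi > w] <- 0L
  list(idx = as.integer(idx), k = length(ki), p = h_out * w_out,
       h_out = h_out, w_out = w_out)
}

build_pool_idx <- function(h, w, c) {
  stopifnot(h %% 2L == 0L, w %% 2L == 0L)
  ho <- rep(seq_len(h %/% 2L), times = (w %/% 2L) * c)
  wo <- rep(rep(seq_len(w %/% 2L), each = h %/% 2L), times = c)
  cc <- rep(seq_len(c), each = (h %/% 2L) * (w %/% 2L))
  base_h <- 2L * (ho - 1L)
  base_w <- 2L * (wo - 1L)
  idx <- rbind(vol_index(base_h + 1L, base_w + 1L, cc, h, w),
               vol_index(base_h + 2L, base_w + 1L, cc, h, w),
               vol_index(base_h + 1L, base_w + 2L, cc, h, w),
               vol_index(base_h + 2L, base_w + 2L, cc, h, w))
  as.integer(idx)  # 4 fastest, then output position
}

build_upsample_idx <- function(h, w, c) {
  ho <- rep(seq_len(2L * h), times = 2L * w * c)
  wo <- rep(rep(seq_len(2L * w), each = 2L * h), times = c)
  cc <- rep(seq_len(c), each = 4L * h * w)
  as.integer(vol_index((ho + 1L) %/% 2L, (wo + 1L) %/% 2L, cc, h, w))
}

# ---- layer constructors -----------------------------------------------------

new_layer <- function(type, ...) structure(list(type = type, ...),
                                           class = "cg_layer")

layer_dense <- function(n_in, n_out, gain = sqrt(2), equalized = TRUE) {
  W <- matrix(stats::rnorm(n_in * n_out), n_in, n_out)
  scale <- gain / sqrt(n_in)
  if (!equalized) { W <- W * scale; scale <- 1 }
  new_layer("dense", W = W, b = numeric(n_out), scale = scale,
            n_in = n_in, n_out = n_out)
}

layer_conv2d <- function(h, w, c_in, c_out, kernel = 3L, stride = 1L,
                         pad = (kernel - 1L) %/% 2L, gain = sqrt(2),
                         equalized = TRUE) {
  im <- build_im2col_idx(h, w, c_in, kernel, stride, pad)
  W <- matrix(stats::rnorm(im$k * c_out), im$k, c_out)
  scale <- gain / sqrt(im$k)
  if (!equalized) { W <- W * scale; scale <- 1 }
  new_layer("conv2d", W = W, b = numeric(c_out), scale = scale,
            idx = im$idx, k = im$k, p = im$p, c_in = c_in, c_out = c_out,
            h = h, w = w, h_out = im$h_out, w_out = im$w_out)
}

layer_act <- function(kind = c("lrelu", "relu", "tanh", "sigmoid", "linear"),
                      slope = 0.2) {
  new_layer("act", kind = match.arg(kind), slope = slope)
}

layer_avgpool2 <- function(h, w, c) {
  new_layer("avgpool2", idx = build_pool_idx(h, w, c),
            m = (h %/% 2L) * (w %/% 2L) * c, n_in = h * w * c)
}

layer_upsample2 <- function(h, w, c) {
  new_layer("upsample2", idx = build_upsample_idx(h, w, c), n_in = h * w * c)
}

layer_pixelnorm <- function(hw, c) new_layer("pixelnorm", hw = hw, c = c)

layer_mbstd <- function(hw, c) new_layer("mbstd", hw = hw, c = c)

layer_global_avgpool <- function(hw, c) new_layer("gap", hw = hw, c = c)

layer_batchnorm <- function(c, hw, momentum = 0.9) {
  new_layer("batchnorm", gamma = rep(1, c), beta = numeric(c), c = c, hw = hw,
            momentum = momentum, run_mean = numeric(c), run_var = rep(1, c))
}

# ---- forward ----------------------------------------------------------------

channel_view <- function(x, hw, c, n) { dim(x) <- c(hw, c * n); x }

layer_forward <- function(layer, x, training = TRUE) {
  switch(layer$type,
    dense = {
      y <- crossprod(layer$W, x) * layer$scale + layer$b
      list(y = y, cache = list(x = x))
    },
    conv2d = {
      n <- ncol(x)
      xc <- gather_rows(x, layer$idx)
      dim(xc) <- c(layer$k, layer$p * n)
      y <- crossprod(xc, layer$W) * layer$scale
      y <- y + rep(layer$b, each = layer$p * n)
      dim(y) <- c(layer$p, n, layer$c_out)
      y <- aperm(y, c(1L, 3L, 2L))
      dim(y) <- c(layer$p * layer$c_out, n)
      list(y = y, cache = list(xc = xc, n = n))
    },
    act = switch(layer$kind,
      lrelu = {
        mask <- x > 0
        list(y = x * (layer$slope + (1 - layer$slope) * mask),
             cache = list(mask = mask))
      },
      relu = {
        mask <- x > 0
        list(y = x * mask, cache = list(mask = mask))
      },
      tanh = { y <- tanh(x); list(y = y, cache = list(y = y)) },
      sigmoid = { y <- 1 / (1 + exp(-x)); list(y = y, cache = list(y = y)) },
      linear = list(y = x, cache = list())
    ),
    avgpool2 = {
      n <- ncol(x)
      xc <- gather_rows(x, layer$idx)
      dim(xc) <- c(4L, layer$m * n)
      y <- .colMeans(xc, 4L, layer$m * n)
      dim(y) <- c(layer$m, n)
      list(y = y, cache = list(n = n))
    },
    upsample2 = list(y = gather_rows(x, layer$idx), cache = list()),
    pixelnorm = {
      n <- ncol(x); hw <- layer$hw; cc <- layer$c
      ms <- matrix(0, hw, n)
      for (ci in seq_len(cc)) {
        rows <- (ci - 1L) * hw + seq_len(hw)
        ms <- ms + x[rows, , drop = FALSE]^2
      }
      r <- 1 / sqrt(ms / cc + 1e-8)
      y <- x  # broadcast r (hw, n) over channels
      for (ci in seq_len(cc)) {
        rows <- (ci - 1L) * hw + seq_len(hw)
        y[rows, ] <- x[rows, , drop = FALSE] * r
      }
      list(y = y, cache = list(x = x, r = r))
    },
    mbstd = {
      n <- ncol(x)
      mu <- rowMeans(x)
      vr <- rowMeans((x - mu)^2)
      sdf <- sqrt(vr + 1e-8)
      v <- mean(sdf)
      list(y = rbind(x, matrix(v, layer$hw, n)),
           cache = list(x = x, mu = mu, sdf = sdf, n = n))
    },
    gap = {
      n <- ncol(x)
      y <- .colMeans(channel_view(x, layer$hw, layer$c, n), layer$hw,
                     layer$c * n)
      dim(y) <- c(layer$c, n)
      list(y = y, cache = list(n = n))
    },
    batchnorm = {
      n <- ncol(x); hw <- layer$hw; cc <- layer$c
      xa <- x; dim(xa) <- c(hw, cc, n)
      xa <- aperm(xa, c(1L, 3L, 2L)); dim(xa) <- c(hw * n, cc)
      if (training) {
        mu <- .colMeans(xa, hw * n, cc)
        vr <- .colMeans(xa^2, hw * n, cc) - mu^2
      } else {
        mu <- layer$run_mean; vr <- layer$run_var
      }
      inv <- 1 / sqrt(vr + 1e-5)
      xhat <- (xa - rep(mu, each = hw * n)) * rep(inv, each = hw * n)
      ya <- xhat * rep(layer$gamma, each = hw * n) +
        rep(layer$beta, each = hw * n)
      dim(ya) <- c(hw, n, cc)
      ya <- aperm(ya, c(1L, 3L, 2L)); dim(ya) <- c(hw * cc, n)
      list(y = ya, cache = list(xhat = xhat, inv = inv, n = n,
                                training = training))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# ---- backward ---------------------------------------------------------------

# Returns list(dx, grads) where grads holds derivatives for the layer's
# parameter fields (NULL when the layer has none).
layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    dense = {
      list(dx = (layer$W %*% dy) * layer$scale,
           grads = list(W = (cache$x %*% t(dy)) * layer$scale,
                        b = rowSums(dy)))
    },
    conv2d = {
      n <- cache$n
      dim(dy) <- c(layer$p, layer$c_out, n)
      dy <- aperm(dy, c(1L, 3L, 2L))
      dim(dy) <- c(layer$p * n, layer$c_out)
      dW <- (cache$xc %*% dy) * layer$scale
      db <- colSums(dy)
      dxc <- (layer$W %*% t(dy)) * layer$scale
      dim(dxc) <- c(layer$k * layer$p, n)
      dx <- scatter_rows(dxc, layer$idx, layer$h * layer$w * layer$c_in)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    act = switch(layer$kind,
      lrelu = list(dx = dy * (layer$slope + (1 - layer$slope) * cache$mask),
                   grads = NULL),
      relu = list(dx = dy * cache$mask, grads = NULL),
      tanh = list(dx = dy * (1 - cache$y^2), grads = NULL),
      sigmoid = list(dx = dy * cache$y * (1 - cache$y), grads = NULL),
      linear = list(dx = dy, grads = NULL)
    ),
    avgpool2 = {
      n <- cache$n
      d4 <- 0.25 * dy[rep(seq_len(layer$m), each = 4L), , drop = FALSE]
      list(dx = scatter_rows(d4, layer$idx, layer$n_in), grads = NULL)
    },
    upsample2 = list(dx = scatter_rows(dy, layer$idx, layer$n_in),
                     grads = NULL),
    pixelnorm = {
      hw <- layer$hw; cc <- layer$c; x <- cache$x; r <- cache$r
      n <- ncol(x)
      s <- matrix(0, hw, n)
      for (ci in seq_len(cc)) {
        rows <- (ci - 1L) * hw + seq_len(hw)
        s <- s + x[rows, , drop = FALSE] * dy[rows, , drop = FALSE]
      }
      coef <- r^3 * s / cc
      dx <- dy
      for (ci in seq_len(cc)) {
        rows <- (ci - 1L) * hw + seq_len(hw)
        dx[rows, ] <- dy[rows, , drop = FALSE] * r -
          x[rows, , drop = FALSE] * coef
      }
      list(dx = dx, grads = NULL)
    },
    mbstd = {
      f <- length(cache$mu); n <- cache$n
      top <- seq_len(f)
      dx <- dy[top, , drop = FALSE]
      if (!isTRUE(cache$frozen)) {
        dv <- sum(dy[-top, , drop = FALSE])
        dvar <- dv * 0.5 / (f * cache$sdf)
        dx <- dx + (cache$x - cache$mu) * (dvar * 2 / n)
      }
      list(dx = dx, grads = NULL)
    },
    gap = {
      dx <- dy[rep(seq_len(layer$c), each = layer$hw), , drop = FALSE] /
        layer$hw
      list(dx = dx, grads = NULL)
    },
    batchnorm = {
      hw <- layer$hw; cc <- layer$c; n <- cache$n; m <- hw * n
      dya <- dy; dim(dya) <- c(hw, cc, n)
      dya <- aperm(dya, c(1L, 3L, 2L)); dim(dya) <- c(m, cc)
      dgamma <- .colSums(dya * cache$xhat, m, cc)
      dbeta <- .colSums(dya, m, cc)
      g <- rep(layer$gamma, each = m)
      if (cache$training) {
        dxhat <- dya * g
        mean_d <- rep(.colMeans(dxhat, m, cc), each = m)
        mean_dx <- rep(.colMeans(dxhat * cache$xhat, m, cc), each = m)
        dxa <- (dxhat - mean_d - cache$xhat * mean_dx) *
          rep(cache$inv, each = m)
      } else {
        dxa <- dya * g * rep(cache$inv, each = m)
      }
      dim(dxa) <- c(hw, n, cc)
      dxa <- aperm(dxa, c(1L, 3L, 2L)); dim(dxa) <- c(hw * cc, n)
      list(dx = dxa, grads = list(gamma = dgamma, beta = dbeta))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# Forward-mode tangent propagation through a layer whose primal cache is
# given. For the piecewise-linear layers used by the critic the tangent map
# is the layer itself with activation masks frozen; the minibatch-stddev
# statistic is treated as a constant in this mode (its appended channel gets
# a zero tangent), which keeps the gradient-penalty path piecewise linear.
layer_forward_tangent <- function(layer, cache, xdot) {
  switch(layer$type,
    dense = crossprod(layer$W, xdot) * layer$scale,
    conv2d = {
      n <- ncol(xdot)
      xc <- gather_rows(xdot, layer$idx)
      dim(xc) <- c(layer$k, layer$p * n)
      y <- crossprod(xc, layer$W) * layer$scale
      dim(y) <- c(layer$p, n, layer$c_out)
      y <- aperm(y, c(1L, 3L, 2L))
      dim(y) <- c(layer$p * layer$c_out, n)
      y
    },
    act = switch(layer$kind,
      lrelu = xdot * (layer$slope + (1 - layer$slope) * cache$mask),
      relu = xdot * cache$mask,
      linear = xdot,
      stop("tangent mode supports piecewise-linear activations only")
    ),
    avgpool2 = {
      n <- ncol(xdot)
      xc <- gather_rows(xdot, layer$idx)
      dim(xc) <- c(4L, layer$m * n)
      y <- .colMeans(xc, 4L, layer$m * n)
      dim(y) <- c(layer$m, n)
      y
    },
    upsample2 = gather_rows(xdot, layer$idx),
    mbstd = rbind(xdot, matrix(0, layer$hw, ncol(xdot))),
    stop("tangent mode not supported for layer type: ", layer$type)
  )
}

# ---- sequential helper ------------------------------------------------------

seq_net <- function(...) structure(list(layers = list(...)), class = "cg_seq")

seq_forward <- function(net, x, training = TRUE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    out <- layer_forward(net$layers[[i]], x, training)
    x <- out$y
    caches[[i]] <- out$cache
  }
  list(y = x, caches = caches)
}

seq_backward <- function(net, caches, dy) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    out <- layer_backward(net$layers[[i]], caches[[i]], dy)
    dy <- out$dx
    grads[i] <- list(out$grads)  # keep NULLs (parameter-free layers)
  }
  list(dx = dy, grads = grads)
}

seq_forward_tangent <- function(net, caches, xdot) {
  for (i in seq_along(net$layers)) {
    xdot <- layer_forward_tangent(net$layers[[i]], caches[[i]], xdot)
  }
  xdot
}

# Count trainable parameters of a module list (list of seq_nets).
count_parameters <- function(modules) {
  total <- 0
  for (m in modules) for (l in m$layers) for (f in PARAM_FIELDS) {
    if (!is.null(l[[f]])) total <- total + length(l[[f]])
  }
  total
}

# ---- Adam over module lists -------------------------------------------------

adam_init <- function(modules) {
  lapply(modules, function(m) lapply(m$layers, function(l) {
    st <- list()
    for (f in PARAM_FIELDS) if (!is.null(l[[f]])) {
      st[[f]] <- list(m = l[[f]] * 0, v = l[[f]] * 0)
    }
    st
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam update. `modules` and `grads` are parallel structures:
# modules[[m]]$layers[[i]]$W etc., grads[[m]][[i]]$W etc.
adam_step <- function(modules, grads, state, lr, beta1, beta2, t,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (mn in names(modules)) {
    g_mod <- grads[[mn]]
    if (is.null(g_mod)) next
    for (i in seq_along(modules[[mn]]$layers)) {
      g <- g_mod[[i]]
      if (is.null(g)) next
      for (f in names(g)) {
        if (is.null(g[[f]])) next
        st <- state[[mn]][[i]][[f]]
        st$m <- beta1 * st$m + (1 - beta1) * g[[f]]
        st$v <- beta2 * st$v + (1 - beta2) * g[[f]]^2
        state[[mn]][[i]][[f]] <- st
        upd <- lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
        modules[[mn]]$layers[[i]][[f]] <-
          modules[[mn]]$layers[[i]][[f]] - upd
      }
    }
  }
  list(modules = modules, state = state)
}

# Accumulate two grad structures (a + b), tolerating NULLs.
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (mn in union(names(a), names(b))) {
    if (is.null(a[[mn]])) { a[[mn]] <- b[[mn]]; next }
    if (is.null(b[[mn]])) next
    for (i in seq_along(b[[mn]])) {
      bi <- b[[mn]][[i]]
      if (is.null(bi)) next  # parameter-free layer
      ai <- if (i <= length(a[[mn]])) a[[mn]][[i]] else NULL
      if (is.null(ai)) { a[[mn]][i] <- list(bi); next }
      for (f in names(bi)) {
        ai[[f]] <- if (is.null(ai[[f]])) bi[[f]] else ai[[f]] + bi[[f]]
      }
      a[[mn]][[i]] <- ai
    }
  }
  a
}

# Deterministic substream seed derived from a master seed and a tag.
substream_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 10007L
  as.integer((as.numeric(master) * 1009L + h * 7919L) %% 2147483629)
}
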