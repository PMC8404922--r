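# Shared tiny fixtures, built once per test run.

tiny_net_config <- function() {
  net_config(latent_dim = 6, base_resolution = 4, final_resolution = 16,
             channel_schedule = c(8, 6, 4))
}

# A small labeled phantom set reused across tests (cached).
local({
  env <- new.env(parent = emptyenv())
  tiny_phantom_dataset <<- function(n = 120, seed = 11, size = 16) {
    key <- paste(n, seed, size, sep = "_")
    if (is.null(env[[key]]))
      env[[key]] <- make_phantom_dataset(n, seed = seed, size = size)
    env[[key]]
  }
})

# central-difference gradient of a scalar function
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

expect_rel_equal <- function(actual, expected, tol = 1e-8) {
  expect_lt(max(abs(actual - expected)) / max(1, max(abs(expected))), tol)
}
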