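# Shared fixtures. All synthetic data is generated in code at test time.

ns <- asNamespace("apunet")

# Reduced-width model used by training-based tests; the architecture is the
# full parallel network, only the channel budget is scaled down so the suite
# runs on one CPU.
scaled_spec <- function(variant = "apu_net") {
  model_spec(variant, base_channels_a = 4, base_channels_b = 8,
             mfa_per_scale_ch = 4)
}

default_phantoms <- function(n, seed = 11, config = phantom_config(seed = seed)) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    generate_phantom(config, sample_id = sprintf("s%03d", i)))
}

# A noiseless bright disk on a dark background.
disk_image <- function(H, W, cr, cc, r, fg = 0.9, bg = 0.1) {
  g <- expand.grid(row = seq_len(H), col = seq_len(W))
  m <- matrix(bg, H, W)
  inside <- (g$row - cr)^2 + (g$col - cc)^2 <= r^2
  m[cbind(g$row[inside], g$col[inside])] <- fg
  m
}

random_mask <- function(H, W, p = 0.3) {
  matrix(as.integer(stats::runif(H * W) < p), H, W)
}

# Finite-difference gradient of a scalar-valued function of an array.
numeric_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(as.array(x)))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
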