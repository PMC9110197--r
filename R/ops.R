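# Differentiable operations. All activation tensors are 4-d arrays with
# dim (H, W, C, N); pooled/MLP tensors are (N, C) matrices. Each op returns
# a new tensor whose backfn maps the output gradient to per-parent
# gradients in the same order as `parents`.

dims_hwcn <- function(x) {
  d <- dim(x)
  list(H = d[1], W = d[2], C = d[3], N = d[4])
}

# ---- convolution ----------------------------------------------------------

op_conv2d <- function(x, w, b) {
  y <- cpp_conv2d_forward(x$value, w$value, b$value)
  new_tensor(y, list(x, w, b), function(g) {
    r <- cpp_conv2d_backward(x$value, w$value, g)
    list(r$dx, r$dw, r$db)
  })
}

op_convt2x2 <- function(x, w, b, oh, ow) {
  y <- cpp_convt2x2_forward(x$value, w$value, b$value, oh, ow)
  new_tensor(y, list(x, w, b), function(g) {
    r <- cpp_convt2x2_backward(x$value, w$value, g, oh, ow)
    list(r$dx, r$dw, r$db)
  })
}

op_maxpool2 <- function(x) {
  r <- cpp_maxpool2_forward(x$value)
  xd <- dim(x$value)
  new_tensor(r$y, list(x), function(g) {
    list(cpp_maxpool2_backward(g, r$idx, xd))
  })
}

# ---- pointwise ------------------------------------------------------------

op_relu <- function(x) {
  m <- x$value > 0
  y <- x$value * m
  new_tensor(y, list(x), function(g) list(g * m))
}

op_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$value))
  new_tensor(y, list(x), function(g) list(g * y * (1 - y)))
}

op_add <- function(x, y) {
  stopifnot(identical(dim(x$value), dim(y$value)))
  new_tensor(x$value + y$value, list(x, y), function(g) list(g, g))
}

op_mul <- function(x, y) {
  stopifnot(identical(dim(x$value), dim(y$value)))
  new_tensor(x$value * y$value, list(x, y),
             function(g) list(g * y$value, g * x$value))
}

op_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  keep <- (stats::runif(length(x$value)) >= p) / (1 - p)
  new_tensor(x$value * keep, list(x), function(g) list(g * keep))
}

# ---- broadcast multiplies -------------------------------------------------

# alpha: (N, C) matrix, one weight per channel per sample.
op_scale_channel <- function(x, alpha) {
  d <- dims_hwcn(x$value)
  HW <- d$H * d$W
  a_full <- rep(as.vector(t(alpha$value)), each = HW)
  y <- x$value * a_full
  dim(y) <- dim(x$value)
  new_tensor(y, list(x, alpha), function(g) {
    gx <- g * a_full
    dim(gx) <- dim(x$value)
    s <- colSums(matrix(g * x$value, nrow = HW))      # (C*N)
    da <- t(matrix(s, d$C, d$N))
    list(gx, da)
  })
}

# s: (H, W, 1, N) spatial gate broadcast over channels.
op_scale_spatial <- function(x, s) {
  d <- dims_hwcn(x$value)
  HW <- d$H * d$W
  sm <- matrix(s$value, HW, d$N)
  s_full <- as.vector(sm[, rep(seq_len(d$N), each = d$C), drop = FALSE])
  y <- x$value * s_full
  dim(y) <- dim(x$value)
  new_tensor(y, list(x, s), function(g) {
    gx <- g * s_full
    dim(gx) <- dim(x$value)
    gp <- aperm(array(g * x$value, c(HW, d$C, d$N)), c(1, 3, 2))
    ds <- array(rowSums(matrix(gp, HW * d$N, d$C)), c(d$H, d$W, 1, d$N))
    list(gx, ds)
  })
}

# ---- channel concatenation / split ---------------------------------------

op_concat <- function(xs) {
  ds <- lapply(xs, function(x) dims_hwcn(x$value))
  cc <- vapply(ds, function(d) d$C, numeric(1))
  d1 <- ds[[1]]
  y <- array(0, c(d1$H, d1$W, sum(cc), d1$N))
  off <- 0L
  for (i in seq_along(xs)) {
    y[, , off + seq_len(cc[i]), ] <- xs[[i]]$value
    off <- off + cc[i]
  }
  new_tensor(y, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, , off + seq_len(cc[i]), , drop = FALSE]
      off <- off + cc[i]
    }
    out
  })
}

# ---- batch normalization --------------------------------------------------

# Per-channel normalization over (H, W, N). `layer` holds running stats and
# is mutated in training mode.
op_batchnorm <- function(x, gamma, beta, layer, training, eps = 1e-5,
                         momentum = 0.1) {
  # Recalibration mode: replace the exponential running average by a true
  # cumulative mean over the recalibration batches (precise-BN refresh).
  if (training && isTRUE(layer$recal_mode)) {
    layer$recal_count <- layer$recal_count + 1L
    momentum <- 1 / layer$recal_count
  }
  d <- dims_hwcn(x$value)
  HW <- d$H * d$W
  m <- HW * d$N
  x3 <- x$value
  dim(x3) <- c(HW, d$C, d$N)
  if (training) {
    cs <- colSums(x3)                      # (C, N)
    mu <- rowSums(matrix(cs, d$C, d$N)) / m
    ex2 <- rowSums(matrix(colSums(x3 * x3), d$C, d$N)) / m
    v <- pmax(ex2 - mu^2, 0)
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    ub <- if (m > 1) m / (m - 1) else 1
    layer$running_var <- (1 - momentum) * layer$running_var + momentum * v * ub
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  inv <- 1 / sqrt(v + eps)
  mu_f <- rep(mu, each = HW)
  inv_f <- rep(inv, each = HW)
  xhat <- (x$value - mu_f) * inv_f
  gam_f <- rep(gamma$value, each = HW)
  y <- gam_f * xhat + rep(beta$value, each = HW)
  dim(y) <- dim(x$value)
  new_tensor(y, list(x, gamma, beta), function(g) {
    sg <- rowSums(matrix(colSums(array(g, c(HW, d$C, d$N))), d$C, d$N))
    sgx <- rowSums(matrix(colSums(array(g * xhat, c(HW, d$C, d$N))), d$C, d$N))
    if (training) {
      gx <- (gam_f * inv_f) *
        (g - rep(sg / m, each = HW) - xhat * rep(sgx / m, each = HW))
    } else {
      gx <- gam_f * inv_f * g
    }
    dim(gx) <- dim(x$value)
    list(gx, sgx, sg)
  })
}

# ---- pooling to (N, C) ----------------------------------------------------

op_global_avgpool <- function(x) {
  d <- dims_hwcn(x$value)
  HW <- d$H * d$W
  x3 <- x$value
  dim(x3) <- c(HW, d$C, d$N)
  y <- t(matrix(colSums(x3), d$C, d$N)) / HW       # (N, C)
  new_tensor(y, list(x), function(g) {
    gv <- rep(as.vector(t(g)) / HW, each = HW)
    dim(gv) <- dim(x$value)
    list(gv)
  })
}

op_global_maxpool <- function(x) {
  d <- dims_hwcn(x$value)
  HW <- d$H * d$W
  m <- matrix(x$value, HW, d$C * d$N)
  idx <- max.col(t(m), ties.method = "first")      # per (c, n) column
  v <- m[cbind(idx, seq_len(d$C * d$N))]
  y <- t(matrix(v, d$C, d$N))
  new_tensor(y, list(x), function(g) {
    gm <- matrix(0, HW, d$C * d$N)
    gm[cbind(idx, seq_len(d$C * d$N))] <- as.vector(t(g))
    dim(gm) <- dim(x$value)
    list(gm)
  })
}

# Channel-wise mean and max maps, stacked as a (H, W, 2, N) tensor
# (the pooling pair feeding the spatial-attention convolution).
op_channel_meanmax <- function(x) {
  d <- dims_hwcn(x$value)
  HW <- d$H * d$W
  xp <- aperm(x$value, c(1, 2, 4, 3))
  m <- matrix(xp, HW * d$N, d$C)                   # rows ordered (h, w, n)
  idx <- max.col(m, ties.method = "first")
  mx <- m[cbind(seq_len(nrow(m)), idx)]
  mn <- rowMeans(m)
  y <- array(0, c(d$H, d$W, 2, d$N))
  y[, , 1, ] <- array(mn, c(d$H, d$W, d$N))
  y[, , 2, ] <- array(mx, c(d$H, d$W, d$N))
  new_tensor(y, list(x), function(g) {
    g1 <- as.vector(g[, , 1, ])
    g2 <- as.vector(g[, , 2, ])
    dm <- matrix(g1 / d$C, HW * d$N, d$C)
    dm[cbind(seq_len(nrow(dm)), idx)] <-
      dm[cbind(seq_len(nrow(dm)), idx)] + g2
    dx <- aperm(array(dm, c(d$H, d$W, d$N, d$C)), c(1, 2, 4, 3))
    list(dx)
  })
}

# ---- dense ----------------------------------------------------------------

# x: (N, C_in); w: (C_in, C_out); optional bias (C_out).
op_linear <- function(x, w, b = NULL) {
  y <- x$value %*% w$value
  if (!is.null(b)) y <- y + matrix(b$value, nrow(y), ncol(y), byrow = TRUE)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_tensor(y, parents, function(g) {
    out <- list(g %*% t(w$value), crossprod(x$value, g))
    if (!is.null(b)) out <- c(out, list(colSums(g)))
    out
  })
}

# ---- bilinear resampling --------------------------------------------------

# Interpolation matrix mapping `n_in` samples to `n_out` (half-pixel-center
# convention, clamped at the borders).
bilinear_matrix <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5
    i0 <- floor(src)
    t <- src - i0
    i0 <- min(max(i0, 0), n_in - 1)
    i1 <- min(i0 + 1, n_in - 1)
    if (src < 0) t <- 0
    if (src > n_in - 1) t <- 1
    M[i, i0 + 1] <- M[i, i0 + 1] + (1 - t)
    M[i, i1 + 1] <- M[i, i1 + 1] + t
  }
  M
}

op_bilinear <- function(x, oh, ow) {
  d <- dims_hwcn(x$value)
  if (oh == d$H && ow == d$W) return(x)
  Mr <- bilinear_matrix(oh, d$H)
  Mc <- bilinear_matrix(ow, d$W)
  K <- d$C * d$N
  x3 <- array(x$value, c(d$H, d$W, K))
  y <- array(0, c(oh, ow, K))
  for (k in seq_len(K)) y[, , k] <- Mr %*% x3[, , k] %*% t(Mc)
  dim(y) <- c(oh, ow, d$C, d$N)
  new_tensor(y, list(x), function(g) {
    g3 <- array(g, c(oh, ow, K))
    dx <- array(0, c(d$H, d$W, K))
    for (k in seq_len(K)) dx[, , k] <- t(Mr) %*% g3[, , k] %*% Mc
    dim(dx) <- dim(x$value)
    list(dx)
  })
}

# ---- losses ---------------------------------------------------------------

# Mean softmax cross-entropy over pixels. logits: (H, W, K, N); target:
# (H, W, N) integer array with classes in 0..K-1.
op_softmax_ce <- function(logits, target) {
  d <- dims_hwcn(logits$value)
  HW <- d$H * d$W
  K <- d$C
  lp <- aperm(logits$value, c(1, 2, 4, 3))
  m <- matrix(lp, HW * d$N, K)                     # rows (h, w, n)
  mx <- do.call(pmax, lapply(seq_len(K), function(k) m[, k]))
  es <- exp(m - mx)
  Z <- rowSums(es)
  p <- es / Z
  ti <- as.integer(as.vector(target)) + 1L
  npx <- HW * d$N
  loss <- -mean(log(pmax(p[cbind(seq_len(npx), ti)], 1e-300)))
  new_tensor(loss, list(logits), function(g) {
    dm <- p
    dm[cbind(seq_len(npx), ti)] <- dm[cbind(seq_len(npx), ti)] - 1
    dm <- dm * (as.numeric(g) / npx)
    dx <- aperm(array(dm, c(d$H, d$W, d$N, K)), c(1, 2, 4, 3))
    list(dx)
  })
}

# Weighted sum of scalar tensors.
op_wsum <- function(xs, w) {
  v <- sum(vapply(seq_along(xs), function(i) w[i] * xs[[i]]$value, numeric(1)))
  new_tensor(v, xs, function(g) {
    lapply(seq_along(xs), function(i) g * w[i])
  })
}
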