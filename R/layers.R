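# Layer containers. A layer is an environment holding parameter tensors
# (in `$params`) plus any buffers (batch-norm running statistics). Layers
# draw their initial weights from R's RNG, so a set.seed() before model
# construction makes the whole network reproducible.

new_layer <- function(.kind, ...) {
  l <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = l)
  l$kind <- .kind
  class(l) <- c(paste0("apu_", .kind), "apu_layer")
  l
}

# He/Kaiming normal initialization for ReLU networks.
kaiming <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))

nn_conv2d <- function(in_ch, out_ch, k = 3) {
  w <- array(kaiming(k * k * in_ch, k * k * in_ch * out_ch),
             c(k, k, in_ch, out_ch))
  l <- new_layer("conv2d", w = ag_param(w), b = ag_param(numeric(out_ch)),
                 in_ch = in_ch, out_ch = out_ch, k = k)
  l$params <- list(l$w, l$b)
  l
}

nn_convt2x2 <- function(in_ch, out_ch) {
  w <- array(kaiming(4 * in_ch, 4 * in_ch * out_ch), c(2, 2, in_ch, out_ch))
  l <- new_layer("convt2x2", w = ag_param(w), b = ag_param(numeric(out_ch)),
                 in_ch = in_ch, out_ch = out_ch)
  l$params <- list(l$w, l$b)
  l
}

nn_batchnorm <- function(ch) {
  l <- new_layer("batchnorm",
                 gamma = ag_param(rep(1, ch)), beta = ag_param(numeric(ch)),
                 running_mean = numeric(ch), running_var = rep(1, ch),
                 ch = ch)
  l$params <- list(l$gamma, l$beta)
  l
}

nn_linear <- function(in_f, out_f, bias = FALSE) {
  l <- new_layer("linear",
                 w = ag_param(matrix(kaiming(in_f, in_f * out_f), in_f, out_f)),
                 b = if (bias) ag_param(numeric(out_f)) else NULL)
  l$params <- if (bias) list(l$w, l$b) else list(l$w)
  l
}

layer_forward <- function(l, x, training = FALSE) {
  switch(l$kind,
    conv2d = op_conv2d(x, l$w, l$b),
    batchnorm = op_batchnorm(x, l$gamma, l$beta, l, training),
    linear = op_linear(x, l$w, l$b),
    stop("layer_forward: unhandled layer kind ", l$kind)
  )
}

# Collect every parameter tensor below an arbitrarily nested structure of
# layers and lists (deduplicated so shared MLPs are stepped once).
nn_parameters <- function(x) {
  acc <- new.env(parent = emptyenv())
  walk <- function(o) {
    if (inherits(o, "apu_layer")) {
      for (p in o$params) assign(as.character(p$id), p, envir = acc)
    } else if (inherits(o, "apu_block")) {
      walk(o$layers)
    } else if (is.list(o)) {
      for (el in o) if (!is.null(el)) walk(el)
    }
  }
  walk(x)
  out <- as.list(acc)
  out[order(as.integer(names(out)))]
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params, lr = 0.005, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 1e-7) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- lapply(params, function(p) p$value * 0)
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2
  st$eps <- eps; st$weight_decay <- weight_decay
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad + st$weight_decay * p$value
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g * g
    p$value <- p$value -
      st$lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + st$eps)
  }
  invisible(st)
}
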