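# Building blocks: shape arithmetic, gate ranges, residual limits.

test_that("double convolution block preserves space, maps channels, clips at zero", {
  set.seed(1)
  b <- new_conv_block(16, 32)
  x <- array(rnorm(16 * 50 * 50), c(50, 50, 16, 1))
  y <- block_forward(b, x)
  expect_identical(dim(y$value), c(50L, 50L, 32L, 1L))
  expect_gte(min(y$value), 0)
  # zero input, eval-mode normalization with fresh running stats -> zero out
  z <- block_forward(b, array(0, c(50, 50, 16, 1)))
  expect_equal(max(abs(z$value)), 0)
})

test_that("two-modal gate doubles channels and multiplies the concatenation", {
  set.seed(2)
  b <- new_two_modal_block(16)
  x1 <- array(rnorm(16 * 50 * 50), c(50, 50, 16, 1))
  x2 <- array(rnorm(16 * 50 * 50), c(50, 50, 16, 1))
  y <- block_forward(b, x1, x2)
  expect_identical(dim(y$value), c(50L, 50L, 32L, 1L))
  expect_true(all(b$last_gate >= 0 & b$last_gate <= 1))

  # brute-force product check on a small input, via the recorded gate
  bs <- new_two_modal_block(2)
  a1 <- array(rnorm(2 * 4 * 4), c(4, 4, 2, 1))
  a2 <- array(rnorm(2 * 4 * 4), c(4, 4, 2, 1))
  ys <- block_forward(bs, a1, a2)
  cc <- array(c(a1, a2), c(4, 4, 4, 1))
  manual <- array(0, c(4, 4, 4, 1))
  for (h in 1:4) for (w in 1:4) for (ch in 1:4)
    manual[h, w, ch, 1] <- cc[h, w, ch, 1] * bs$last_gate[h, w, ch, 1]
  expect_equal(ys$value, manual, tolerance = 1e-12)

  # zero pre-activations -> sigmoid(0) = 0.5 -> half the concatenation
  for (l in list(bs$g1, bs$g2)) {
    l$w$value[] <- 0
    l$b$value[] <- 0
  }
  y0 <- block_forward(bs, a1, a2)
  expect_equal(y0$value, 0.5 * cc, tolerance = 1e-12)

  expect_error(block_forward(bs, a1, array(0, c(4, 4, 3, 1))))
})

test_that("the all-1x1 gate variant of the two-modal block also works", {
  set.seed(3)
  b <- new_two_modal_block(4, text_variant = TRUE)
  x <- array(rnorm(4 * 8 * 8), c(8, 8, 4, 1))
  y <- block_forward(b, x, x)
  expect_identical(dim(y$value), c(8L, 8L, 8L, 1L))
  expect_identical(dim(b$g2$w$value)[1:2], c(1L, 1L))
})

test_that("spatial attention: residual limits and channel-max localization", {
  set.seed(4)
  b <- new_spatial_attention()
  x <- array(rnorm(3 * 6 * 6), c(6, 6, 3, 1))
  b$force_gate <- 0
  expect_identical(block_forward(b, x)$value, x)
  b$force_gate <- 1
  expect_equal(block_forward(b, x)$value, 2 * x, tolerance = 1e-15)
  b$force_gate <- NULL
  y <- block_forward(b, x)
  expect_true(all(b$last_gate >= 0 & b$last_gate <= 1))
  expect_identical(dim(y$value), dim(x))

  # one hot pixel dominates the channel-max map
  hot <- array(0, c(4, 4, 3, 1))
  hot[2, 3, 1, 1] <- 10
  mm <- ns$op_channel_meanmax(ns$as_feature_map(hot))
  mx <- mm$value[, , 2, 1]
  expect_identical(which.max(mx), 2L + 4L * (3L - 1L))
})

test_that("channel attention: hidden width, residual limits, C < 3 error", {
  set.seed(5)
  b <- new_channel_attention(96)
  expect_identical(b$hidden, 32)
  expect_identical(dim(b$fc1$w$value), c(96L, 32L))
  x <- array(rnorm(96 * 5 * 5), c(5, 5, 96, 1))
  b$force_gate <- 0
  expect_identical(block_forward(b, x)$value, x)
  b$force_gate <- 1
  expect_equal(block_forward(b, x)$value, 2 * x, tolerance = 1e-15)
  b$force_gate <- NULL
  block_forward(b, x)
  expect_true(all(b$last_gate >= 0 & b$last_gate <= 1))
  expect_error(new_channel_attention(2), "at least 3 channels")
})

test_that("hybrid attention concatenates then gates, staying finite and doubled-residual", {
  set.seed(6)
  b <- new_hybrid_attention(32, 64)
  x1 <- array(runif(32 * 25 * 25, -10, 10), c(25, 25, 32, 1))
  x2 <- array(runif(64 * 25 * 25, -10, 10), c(25, 25, 64, 1))
  y <- block_forward(b, x1, x2)
  expect_identical(dim(y$value), c(25L, 25L, 96L, 1L))
  expect_true(all(is.finite(y$value)))
  b$ca$force_gate <- 0
  b$sa$force_gate <- 0
  y0 <- block_forward(b, x1, x2)
  expect_identical(y0$value, array(c(x1, x2), c(25, 25, 96, 1)))
})

test_that("aggregation head: channel arithmetic and the residual algebra limits", {
  set.seed(7)
  mk_pairs <- function(chs_a, chs_b, szs)
    lapply(1:4, function(i) list(
      array(rnorm(chs_a[i] * szs[i]^2), c(szs[i], szs[i], chs_a[i], 1)),
      array(rnorm(chs_b[i] * szs[i]^2), c(szs[i], szs[i], chs_b[i], 1))))
  pairs <- mk_pairs(c(128, 64, 32, 16), c(256, 128, 64, 32), c(6, 12, 25, 50))
  b <- new_mfa_block(c(384, 192, 96, 48), out_size = 50)
  y <- block_forward(b, pairs)
  expect_identical(dim(y$value), c(50L, 50L, 64L, 1L))

  # small block for the algebra checks
  bs <- new_mfa_block(c(4, 4, 4, 4), out_size = 4, per_scale_ch = 2)
  ps <- mk_pairs(c(2, 2, 2, 2), c(2, 2, 2, 2), c(1, 2, 3, 4))
  bs$force_alpha <- 1; bs$force_beta <- 0
  y10 <- block_forward(bs, ps)
  bs$force_alpha <- 0; bs$force_beta <- NULL
  y0 <- block_forward(bs, ps)
  # recover F from the alpha = 0 limit: F_MFA = F
  f <- y0$value
  expect_equal(y10$value, 2 * f, tolerance = 1e-12)

  # full elementwise recomputation from the recorded gates
  bs$force_alpha <- NULL; bs$force_beta <- NULL
  y <- block_forward(bs, ps)
  al <- bs$last_gate$alpha
  be <- bs$last_gate$beta
  manual <- array(0, dim(f))
  for (h in 1:4) for (w in 1:4) for (ch in 1:8) {
    fa <- f[h, w, ch, 1] * al[1, ch]
    manual[h, w, ch, 1] <- fa * be[h, w, ch, 1] + fa + f[h, w, ch, 1]
  }
  expect_equal(y$value, manual, tolerance = 1e-12)
  expect_error(block_forward(bs, ps[1:3]), "4 decoder scales")
})
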