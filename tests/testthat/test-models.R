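# Model assembly: shape schedules against the reference tables, variant
# lattice, prediction contract, parameter counting.

test_that("encoder/decoder schedules follow the reference tables at defaults", {
  tri <- default_phantoms(1, seed = 3)[[1]]
  set.seed(1)
  m <- build_model(model_spec("apu_net"))
  tr <- forward_trace(m, tri)
  g <- function(nm) tr[tr$name == nm, ]
  for (l in 1:5) {
    sz <- c(50, 25, 12, 6, 3)[l]
    expect_equal(g(sprintf("encoder1_A/block%d", l))$height, sz)
    expect_identical(g(sprintf("encoder1_A/block%d", l))$channels,
                     c(16L, 32L, 64L, 128L, 256L)[l])
    expect_identical(g(sprintf("encoder_B/block%d", l))$channels,
                     c(32L, 64L, 128L, 256L, 512L)[l])
  }
  for (l in 1:4) {
    sz <- c(50, 25, 12, 6)[l]
    expect_equal(g(sprintf("decoder_A/U%d", l))$height, sz)
    expect_identical(g(sprintf("decoder_A/U%d", l))$channels,
                     c(16L, 32L, 64L, 128L)[l])
    expect_identical(g(sprintf("decoder_B/U%d", l))$channels,
                     c(32L, 64L, 128L, 256L)[l])
  }
  expect_identical(g("bottleneck_A")$channels, 256L)
  expect_identical(g("bottleneck_B")$channels, 512L)
  expect_identical(g("mfa")$channels, 64L)
  expect_identical(g("mfa")$height, 50L)
  expect_identical(g("head_mfa")$channels, 2L)
})

test_that("plain U-Net and the three-encoder variant use the 64..1024 schedule", {
  tri <- default_phantoms(1, seed = 3)[[1]]
  set.seed(1)
  tr <- forward_trace(build_model(model_spec("unet")), tri)
  expect_identical(tr[tr$name == "encoder1/block5", ]$channels, 1024L)
  expect_identical(tr[grepl("^encoder1/", tr$name), ]$channels,
                   c(64L, 128L, 256L, 512L, 1024L))
  expect_identical(tr[grepl("^decoder/", tr$name), ]$channels,
                   c(512L, 256L, 128L, 64L))
  set.seed(1)
  trm <- forward_trace(build_model(model_spec("meu_net")), tri)
  expect_equal(sum(grepl("^encoder[123]/block1$", trm$name)), 3)
})

test_that("the parallel baseline sums the two subnetwork outputs", {
  tri <- default_phantoms(1, seed = 3)[[1]]
  set.seed(2)
  m <- build_model(scaled_spec("pu_net"))
  b <- ns$triplet_batch(list(tri))
  out <- ns$model_forward(m, b$ct, b$pet, b$fused)
  expect_length(out$heads, 2)
  expect_equal(out$final$value,
               out$heads[[1]]$value + out$heads[[2]]$value,
               tolerance = 1e-15)
})

test_that("all seven variants emit identically shaped logits", {
  tri <- default_phantoms(1, seed = 3)[[1]]
  b <- ns$triplet_batch(list(tri))
  for (v in c("unet", "meu_net", "pu_net", "sapu_net", "capu_net",
              "mfpu_net", "apu_net")) {
    set.seed(3)
    spec <- if (v %in% c("unet", "meu_net"))
      model_spec(v, base_channels_u = 4) else scaled_spec(v)
    out <- ns$model_forward(build_model(spec), b$ct, b$pet, b$fused)
    expect_identical(dim(out$final$value), c(50L, 50L, 2L, 1L))
  }
})

test_that("mask prediction is binary, input-sized and eval-deterministic", {
  tri <- default_phantoms(1, seed = 6)[[1]]
  set.seed(4)
  m <- build_model(scaled_spec("apu_net"))
  p1 <- predict_mask(m, tri)
  p2 <- predict_mask(m, tri)
  expect_identical(dim(p1), c(50L, 50L))
  expect_true(all(p1 %in% c(0L, 1L)))
  expect_identical(p1, p2)
  small <- lapply(tri, function(x) if (is.matrix(x)) x[1:40, 1:40] else x)
  expect_error(predict_mask(m, small), "does not match")
})

test_that("parameter counts scale and match a hand-computed toy total", {
  set.seed(5)
  pu <- build_model(scaled_spec("pu_net"))
  apu <- build_model(scaled_spec("apu_net"))
  expect_lt(count_parameters(pu), count_parameters(apu))

  n1 <- count_parameters(build_model(
    model_spec("pu_net", base_channels_a = 4, base_channels_b = 8)))
  n2 <- count_parameters(build_model(
    model_spec("pu_net", base_channels_a = 8, base_channels_b = 16)))
  expect_gt(n2 / n1, 3); expect_lt(n2 / n1, 4.5)

  # depth-2 toy, base 4/8: every 3x3 conv contributes 9*Cin*Cout + Cout,
  # batch norms 2*C, 1x1 reductions Cin*Cout + Cout, transpose convs
  # 4*Cin*Cout + Cout. Summed by hand:
  enc_a <- (9 * 1 * 4 + 4 + 2 * 4 + 9 * 4 * 4 + 4 + 2 * 4) +
           (9 * 4 * 8 + 8 + 2 * 8 + 9 * 8 * 8 + 8 + 2 * 8)
  enc_b <- (9 * 1 * 8 + 8 + 2 * 8 + 9 * 8 * 8 + 8 + 2 * 8) +
           (9 * 8 * 16 + 16 + 2 * 16 + 9 * 16 * 16 + 16 + 2 * 16)
  red <- (12 * 4 + 4) + (12 * 8 + 8)
  ups <- (4 * 8 * 4 + 4) + (4 * 16 * 8 + 8)
  dec_a <- 9 * 8 * 4 + 4 + 2 * 4 + 9 * 4 * 4 + 4 + 2 * 4
  dec_b <- 9 * 16 * 8 + 8 + 2 * 8 + 9 * 8 * 8 + 8 + 2 * 8
  heads <- (4 * 2 + 2) + (8 * 2 + 2)
  expected <- 2 * enc_a + enc_b + red + ups + dec_a + dec_b + heads
  toy <- build_model(model_spec("pu_net", base_channels_a = 4,
                                base_channels_b = 8, depth = 2,
                                input_size = 8))
  expect_identical(count_parameters(toy), expected)
})
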