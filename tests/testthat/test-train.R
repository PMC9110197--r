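# Loss closed forms, optimizer descent, reproducibility.

test_that("cross-entropy loss matches its closed forms", {
  mask <- matrix(c(1, 0, 0, 1), 2, 2)
  # near-certain correct logits -> loss ~ 0
  logits <- array(0, c(2, 2, 2, 1))
  logits[, , 1, 1] <- 50 * (1 - mask)
  logits[, , 2, 1] <- 50 * mask
  expect_lt(apu_loss(list(logits), mask)$value, 1e-12)
  # uniform logits -> ln 2 per pixel
  expect_equal(apu_loss(list(array(0, c(2, 2, 2, 1))), mask)$value, log(2),
               tolerance = 1e-12)
  # hand-enumerated 2x2 example
  l2 <- array(0, c(2, 2, 2, 1))
  l2[, , 2, 1] <- matrix(c(1, -1, 0.5, 2), 2, 2)
  p1 <- 1 / (1 + exp(-l2[, , 2, 1]))      # softmax of (0, z) = sigmoid(z)
  hand <- -mean(ifelse(mask == 1, log(p1), log(1 - p1)))
  expect_equal(apu_loss(list(l2), mask)$value, hand, tolerance = 1e-12)
})

test_that("head weighting behaves as a weighted sum and validates lengths", {
  mask <- matrix(c(1, 0, 0, 1), 2, 2)
  h1 <- array(rnorm(8), c(2, 2, 2, 1))
  h2 <- array(rnorm(8), c(2, 2, 2, 1))
  h3 <- array(rnorm(8), c(2, 2, 2, 1))
  single <- apu_loss(list(h1), mask)$value
  expect_equal(apu_loss(list(h1, h2, h3), mask, c(1, 0, 0))$value, single,
               tolerance = 1e-12)
  full <- apu_loss(list(h1, h2, h3), mask, c(1, 2, 0.5))$value
  expect_equal(full,
               apu_loss(list(h1), mask)$value +
                 2 * apu_loss(list(h2), mask)$value +
                 0.5 * apu_loss(list(h3), mask)$value,
               tolerance = 1e-12)
  expect_error(apu_loss(list(h1, h2), mask, c(1, 1, 1)), "heads")
})

test_that("one small-step update decreases the single-sample loss", {
  tri <- default_phantoms(1, seed = 21)[[1]]
  set.seed(21)
  spec <- scaled_spec("pu_net")
  spec$dropout_p <- 0
  model <- build_model(spec)
  b <- ns$triplet_batch(list(tri))
  loss_now <- function() {
    out <- ns$model_forward(model, b$ct, b$pet, b$fused, training = TRUE)
    apu_loss(out$heads, b$mask)
  }
  l0 <- loss_now()
  ns$ag_zero_grad(model$params)
  ns$ag_backward(l0)
  opt <- ns$adam_init(model$params, lr = 1e-4, weight_decay = 0)
  ns$adam_step(opt)
  l1 <- loss_now()
  expect_lt(l1$value, l0$value)
})

test_that("training is reproducible and logs every epoch", {
  train <- default_phantoms(8, seed = 31)
  run <- function() {
    set.seed(33)
    model <- build_model(scaled_spec("pu_net"))
    train_model(model, train,
                train_config(epochs = 2, batch_size = 4, seed = 33))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(nrow(f1$log), 2L)
  expect_true(all(is.finite(f1$log$loss)))
  expect_s3_class(tidy(f1), "tbl_df")
  expect_identical(nrow(glance(f1)), 1L)
})

test_that("evaluation is self-consistent and sized to the test set", {
  train <- default_phantoms(4, seed = 41)
  set.seed(41)
  model <- build_model(scaled_spec("pu_net"))
  fit <- train_model(model, train,
                     train_config(epochs = 2, batch_size = 4, seed = 41))
  rep <- evaluate_model(fit$model, train)
  expect_identical(nrow(rep$per_sample), 4L)
  # a model scored against its own predictions is perfect by definition
  preds <- lapply(train, function(tr) predict_mask(fit$model, tr))
  self <- metric_report(preds, preds)
  expect_equal(self$aggregate[["dsc"]], 1)
  expect_equal(self$aggregate[["voe"]], 0)
})

test_that("model checkpoints round-trip through disk", {
  tri <- default_phantoms(1, seed = 51)[[1]]
  set.seed(51)
  model <- build_model(scaled_spec("apu_net"))
  p0 <- predict_mask(model, tri)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, f, seed = 51)
  m2 <- load_model(f)
  expect_identical(predict_mask(m2, tri), p0)
  expect_identical(m2$spec$variant, "apu_net")
})
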