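# Training and evaluation: pixelwise cross-entropy on every supervised
# head, mini-batch Adam, per-epoch logging, and test-set metric reports.

#' Training hyperparameters
#'
#' Defaults follow the reference training schedule: Adam with initial learning rate
#' 0.005, batch size 8, 150 epochs, weight decay 1e-7.
#'
#' @param learning_rate positive Adam step size.
#' @param batch_size mini-batch size (>= 1).
#' @param epochs training epochs.
#' @param weight_decay L2 penalty added to gradients.
#' @param seed integer seed for shuffling, dropout and (by convention)
#'   weight initialization.
#' @param loss_weights per-head loss weights, or NULL for equal weights
#'   over all heads the variant exposes.
#' @param device `"cpu"` (the only supported device).
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.005, batch_size = 8, epochs = 150,
                         weight_decay = 1e-7, seed = 1, loss_weights = NULL,
                         device = "cpu") {
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop("invalid value for field 'learning_rate': must be > 0")
  if (!is.numeric(batch_size) || batch_size < 1)
    stop("invalid value for field 'batch_size': must be >= 1")
  if (!is.numeric(epochs) || epochs < 1)
    stop("invalid value for field 'epochs': must be >= 1")
  if (!is.numeric(weight_decay) || weight_decay < 0)
    stop("invalid value for field 'weight_decay': must be >= 0")
  device <- match.arg(device, c("cpu", "accelerator"))
  if (device == "accelerator")
    stop("invalid value for field 'device': only 'cpu' is supported")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weight_decay = weight_decay,
                 seed = as.integer(seed), loss_weights = loss_weights,
                 device = device),
            class = "train_config")
}

#' Multi-head pixelwise cross-entropy loss
#'
#' @param outputs list of per-head logit tensors/arrays, each
#'   (H, W, classes, N).
#' @param mask integer array (H, W, N) or matrix of class labels in
#'   0..classes-1.
#' @param weights numeric head weights; length must equal the number of
#'   heads.
#' @return a scalar loss tensor (use `$value` for the number).
#' @export
apu_loss <- function(outputs, mask, weights = NULL) {
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  if (is.null(weights)) weights <- rep(1, length(outputs))
  if (length(weights) != length(outputs))
    stop("loss_weights has length ", length(weights), " but the model has ",
         length(outputs), " heads")
  terms <- lapply(outputs, function(o)
    op_softmax_ce(if (is_tensor(o)) o else ag_const(o), mask))
  op_wsum(terms, weights)
}

batch_dsc <- function(logits, mask) {
  # argmax over classes, Dice per sample, mean
  d <- dim(logits)
  n <- d[4]
  vals <- vapply(seq_len(n), function(i) {
    pred <- (logits[, , 2, i] > logits[, , 1, i]) * 1
    P <- sum(pred); G <- sum(mask[, , i])
    if (P + G == 0) 1 else 2 * sum(pred * mask[, , i]) / (P + G)
  }, numeric(1))
  mean(vals)
}

#' Train a model
#'
#' Mini-batch Adam with cross-entropy supervision on every head the
#' variant exposes (aggregation head plus both subnetwork heads when
#' present). Deterministic given `config$seed` on CPU. The state with the
#' best training DSC is kept and restored at the end.
#'
#' @param model an `apu_model` from [build_model()].
#' @param dataset a list of training triplets, or a list with `$train`
#'   (and optionally `$test`) triplet lists.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return an `apu_fit`: list with the trained `model`, the per-epoch
#'   `log` tibble, and `config`.
#' @export
train_model <- function(model, dataset, config = train_config(),
                        verbose = FALSE) {
  train_set <- if (!is.null(dataset$train)) dataset$train else dataset
  stopifnot(length(train_set) > 0)
  set.seed(config$seed)
  opt <- adam_init(model$params, lr = config$learning_rate,
                   weight_decay = config$weight_decay)
  n <- length(train_set)
  n_heads <- n_model_heads(model)
  weights <- config$loss_weights
  if (is.null(weights)) weights <- rep(1, n_heads)
  if (length(weights) != n_heads)
    stop("loss_weights has length ", length(weights), " but the model has ",
         n_heads, " heads")
  log_rows <- vector("list", config$epochs)
  best <- list(dsc = -Inf, state = NULL)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_dsc <- 0; nb <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      b <- triplet_batch(train_set[idx])
      ag_zero_grad(model$params)
      out <- model_forward(model, b$ct, b$pet, b$fused, training = TRUE)
      loss <- apu_loss(out$heads, b$mask, weights)
      if (!is.finite(loss$value))
        stop("training diverged: non-finite loss at epoch ", epoch)
      ag_backward(loss)
      adam_step(opt)
      ep_loss <- ep_loss + loss$value
      ep_dsc <- ep_dsc + batch_dsc(out$final$value, b$mask)
      nb <- nb + 1
    }
    ep_loss <- ep_loss / nb; ep_dsc <- ep_dsc / nb
    log_rows[[epoch]] <- tibble::tibble(epoch = epoch, loss = ep_loss,
                                        train_dsc = ep_dsc)
    if (ep_dsc > best$dsc) best <- list(dsc = ep_dsc,
                                        state = model_state(model))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  train DSC %.4f",
                      epoch, ep_loss, ep_dsc))
  }
  if (!is.null(best$state)) set_model_state(model, best$state)
  recalibrate_bn(model, train_set, config$batch_size)
  structure(list(model = model, log = do.call(rbind, log_rows),
                 config = config),
            class = "apu_fit")
}

# Batch-norm statistics are averaged over dropout-perturbed activations
# during training; with bottleneck dropout this biases evaluation-mode
# normalization. Refresh the running statistics with dropout-free forward
# passes (cumulative mean over the batches), the precise-BN recipe.
recalibrate_bn <- function(model, train_set, batch_size, passes = 2L) {
  bns <- collect_bn_layers(model$modules)
  for (l in bns) { l$recal_mode <- TRUE; l$recal_count <- 0L }
  p0 <- model$spec$dropout_p
  model$spec$dropout_p <- 0
  on.exit({
    model$spec$dropout_p <- p0
    for (l in bns) l$recal_mode <- FALSE
  })
  n <- length(train_set)
  for (pass in seq_len(passes))
    for (start in seq(1, n, by = batch_size)) {
      b <- triplet_batch(train_set[start:min(start + batch_size - 1, n)])
      model_forward(model, b$ct, b$pet, b$fused, training = TRUE)
    }
  invisible(model)
}

n_model_heads <- function(model) {
  fl <- model$flags
  if (!fl$dual) 1L else if (fl$mfa) 3L else 2L
}

#' @export
print.apu_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat("<apu_fit ", x$model$spec$variant, ": ", nrow(x$log),
      " epochs, final loss ", signif(last$loss, 4),
      ", best train DSC ", signif(max(x$log$train_dsc), 4), ">\n", sep = "")
  invisible(x)
}

#' Per-epoch training log
#'
#' @param x an `apu_fit`.
#' @param ... unused.
#' @return tibble with `epoch`, `loss`, `train_dsc`.
#' @export
tidy.apu_fit <- function(x, ...) x$log

#' One-row training summary
#'
#' @inheritParams tidy.apu_fit
#' @return one-row tibble: variant, epochs, final loss, best train DSC.
#' @export
glance.apu_fit <- function(x, ...) {
  tibble::tibble(variant = x$model$spec$variant, epochs = nrow(x$log),
                 final_loss = x$log$loss[nrow(x$log)],
                 best_train_dsc = max(x$log$train_dsc))
}

#' Training-loss curve
#'
#' @param object an `apu_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.apu_fit <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loss, colour = "loss")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$train_dsc,
                                    colour = "train DSC")) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Evaluate a model on a set of triplets
#'
#' Predicts every triplet, scores it against its ground-truth mask and
#' optionally writes the per-sample CSV report (footer row of means).
#'
#' @param model an `apu_model` (trained).
#' @param triplets list of image triplets with ground-truth masks.
#' @param out_csv optional CSV path.
#' @return an `apu_metric_report`.
#' @export
evaluate_model <- function(model, triplets, out_csv = NULL) {
  preds <- lapply(triplets, function(tr) predict_mask(model, tr))
  gts <- lapply(triplets, function(tr) tr$mask)
  ids <- vapply(triplets, function(tr) tr$sample_id, character(1))
  rep <- metric_report(preds, gts, ids)
  if (!is.null(out_csv)) write_metric_report(rep, out_csv)
  rep
}
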