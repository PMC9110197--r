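# Segmentation overlap metrics: Dice similarity coefficient (DSC), recall,
# volumetric overlap error (VOE) and relative volume difference (RVD),
# defined from pixelwise confusion counts between a predicted mask P and a
# ground-truth mask G:
#
#   DSC    = 2|P n G| / (|P| + |G|)
#   Recall = TP / (TP + FN)
#   VOE    = |1 - |P n G| / |P u G||
#   RVD    = ||P| / |G| - 1|
#
# Empty-mask conventions (documented, warned): both masks empty gives
# DSC = 1 and VOE = 0; an empty ground truth leaves recall and RVD
# undefined (NA).

check_masks <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("mask shapes differ: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(gt), collapse = "x"))
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop("masks must be strictly binary (values 0/1)")
}

#' Pixelwise confusion counts
#'
#' @param pred,gt binary matrices of identical shape.
#' @return list with `tp`, `fp`, `tn`, `fn`; the four sum to the pixel
#'   count.
#' @export
confusion <- function(pred, gt) {
  check_masks(pred, gt)
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  tn <- sum(pred == 0 & gt == 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "apu_confusion")
}

#' Dice similarity coefficient
#'
#' @inheritParams confusion
#' @return value in \[0,1\]; 1 (with a warning) when both masks are empty.
#' @export
dsc <- function(pred, gt) {
  check_masks(pred, gt)
  P <- sum(pred); G <- sum(gt)
  if (P + G == 0) {
    warning("both masks empty; DSC defined as 1")
    return(1)
  }
  2 * sum(pred == 1 & gt == 1) / (P + G)
}

#' Pixel recall (sensitivity)
#'
#' @inheritParams confusion
#' @return TP / (TP + FN); NA (with a warning) when the ground truth is
#'   empty.
#' @export
recall <- function(pred, gt) {
  check_masks(pred, gt)
  G <- sum(gt)
  if (G == 0) {
    warning("empty ground truth; recall undefined")
    return(NA_real_)
  }
  sum(pred == 1 & gt == 1) / G
}

#' Volumetric overlap error
#'
#' @inheritParams confusion
#' @return `|1 - |P n G| / |P u G||`; 0 (with a warning) when both masks
#'   are empty.
#' @export
voe <- function(pred, gt) {
  check_masks(pred, gt)
  i <- sum(pred == 1 & gt == 1)
  u <- sum(pred == 1 | gt == 1)
  if (u == 0) {
    warning("both masks empty; VOE defined as 0")
    return(0)
  }
  abs(1 - i / u)
}

#' Relative volume difference
#'
#' @inheritParams confusion
#' @return `||P|/|G| - 1|`; NA (with a warning) when the ground truth is
#'   empty.
#' @export
rvd <- function(pred, gt) {
  check_masks(pred, gt)
  G <- sum(gt)
  if (G == 0) {
    warning("empty ground truth; RVD undefined")
    return(NA_real_)
  }
  abs(sum(pred) / G - 1)
}

#' Per-sample and aggregate metric report
#'
#' @param preds,gts lists of binary masks (same length).
#' @param sample_ids optional character ids.
#' @return an `apu_metric_report`: list with `per_sample` (tibble) and
#'   `aggregate` (named means over samples, NA-removed).
#' @export
metric_report <- function(preds, gts, sample_ids = NULL) {
  stopifnot(length(preds) == length(gts))
  n <- length(preds)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(n))
  per <- tibble::tibble(
    sample_id = sample_ids,
    dsc = vapply(seq_len(n), function(i) dsc(preds[[i]], gts[[i]]),
                 numeric(1)),
    recall = vapply(seq_len(n), function(i) recall(preds[[i]], gts[[i]]),
                    numeric(1)),
    voe = vapply(seq_len(n), function(i) voe(preds[[i]], gts[[i]]),
                 numeric(1)),
    rvd = vapply(seq_len(n), function(i) rvd(preds[[i]], gts[[i]]),
                 numeric(1)))
  agg <- vapply(per[c("dsc", "recall", "voe", "rvd")],
                function(v) mean(v, na.rm = TRUE), numeric(1))
  structure(list(per_sample = per, aggregate = agg),
            class = "apu_metric_report")
}

#' @export
print.apu_metric_report <- function(x, ...) {
  cat("Segmentation metrics over", nrow(x$per_sample), "samples\n")
  cat(sprintf("  mean DSC %.4f | recall %.4f | VOE %.4f | RVD %.4f\n",
              x$aggregate["dsc"], x$aggregate["recall"],
              x$aggregate["voe"], x$aggregate["rvd"]))
  invisible(x)
}

#' Tidy a metric report (per-sample rows)
#'
#' @param x an `apu_metric_report`.
#' @param ... unused.
#' @return the per-sample tibble.
#' @export
tidy.apu_metric_report <- function(x, ...) x$per_sample

#' One-row metric summary
#'
#' @inheritParams tidy.apu_metric_report
#' @return a one-row tibble of aggregate means.
#' @export
glance.apu_metric_report <- function(x, ...) {
  tibble::as_tibble(as.list(x$aggregate))
}

#' Write a metric report as CSV with a footer row of means
#'
#' @param report an `apu_metric_report`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  df <- as.data.frame(report$per_sample)
  df <- rbind(df, data.frame(sample_id = "mean",
                             as.list(report$aggregate)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Bar chart of aggregate segmentation metrics
#'
#' @param object an `apu_metric_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.apu_metric_report <- function(object, ...) {
  df <- data.frame(metric = factor(names(object$aggregate),
                                   levels = names(object$aggregate)),
                   value = as.numeric(object$aggregate))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "mean over samples",
                  title = "Segmentation overlap metrics") +
    ggplot2::theme_minimal()
}
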