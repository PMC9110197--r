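# Plot helpers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Display an image triplet
#'
#' Four base-graphics panels: CT, PET, fused and the lesion mask (with an
#' optional predicted mask outline value overlaid as a fifth panel when
#' supplied).
#'
#' @param triplet an image triplet.
#' @param pred optional predicted binary mask.
#' @return invisibly, the triplet.
#' @export
plot_triplet <- function(triplet, pred = NULL) {
  show <- function(m, title) {
    graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(256,
                    start = 0, end = 1), axes = FALSE, main = title,
                    useRaster = TRUE)
  }
  panels <- if (is.null(pred)) c(2, 2) else c(2, 3)
  old <- graphics::par(mfrow = panels, mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(old))
  show(triplet$ct, "CT")
  show(triplet$pet, "PET")
  show(triplet$fused, "fused")
  show(triplet$mask, "mask")
  if (!is.null(pred)) show(pred, "prediction")
  invisible(triplet)
}
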