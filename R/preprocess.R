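# Preprocessing: circular-Hough ROI extraction, contrast enhancement, and
# lossless rotation/mirror augmentation.

conv3 <- function(img, k) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- img
  pad[1, ] <- pad[2, ]; pad[H + 2, ] <- pad[H + 1, ]
  pad[, 1] <- pad[, 2]; pad[, W + 2] <- pad[, W + 1]
  for (i in 1:3) for (j in 1:3)
    if (k[i, j] != 0)
      out <- out + k[i, j] * pad[i:(i + H - 1), j:(j + W - 1)]
  out
}

sobel_magnitude <- function(img) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gy <- conv3(img, kx)
  gx <- conv3(img, t(kx))
  sqrt(gx^2 + gy^2)
}

ring_offsets <- function(r) {
  np <- max(8L, ceiling(2 * pi * r))
  th <- seq(0, 2 * pi, length.out = np + 1)[-(np + 1)]
  unique(cbind(round(r * cos(th)), round(r * sin(th))))
}

#' Locate a region of interest with a circular Hough transform
#'
#' Edge pixels (Sobel magnitude above `edge_frac` of its maximum) vote for
#' circle centers at every integer radius in `radius_range`; votes are
#' normalized by ring circumference so radii compete fairly. The strongest
#' peak (ties break toward the smaller radius, then row-major order) becomes
#' the ROI center.
#'
#' @param image grayscale matrix, larger than `out_size` in both dimensions.
#' @param radius_range integer radius bounds in pixels, `c(min, max)`.
#' @param out_size side of the square ROI box.
#' @param threshold minimum normalized accumulator peak (fraction of the
#'   ring supported by edges) below which no ROI is reported.
#' @param edge_frac edge binarization level relative to the maximum
#'   gradient magnitude.
#' @return an `roi_box`: list with `center_row`, `center_col`, `size`
#'   (1-based pixel indices) plus the peak `score` and `radius`.
#' @export
hough_roi <- function(image, radius_range = c(3, 20), out_size = 50,
                      threshold = 0.3, edge_frac = 0.5) {
  H <- nrow(image); W <- ncol(image)
  if (H <= out_size || W <= out_size)
    stop("image (", H, "x", W, ") must exceed out_size ", out_size)
  radii <- seq.int(ceiling(radius_range[1]), floor(radius_range[2]))
  if (length(radii) == 0) stop("empty radius range")
  g <- sobel_magnitude(image)
  gmax <- max(g)
  best <- list(score = -Inf)
  if (gmax > 0) {
    E <- (g >= edge_frac * gmax) * 1
    for (r in radii) {
      off <- ring_offsets(r)
      A <- matrix(0, H, W)
      for (k in seq_len(nrow(off))) {
        dr <- off[k, 1]; dc <- off[k, 2]
        rs <- max(1, 1 - dr):min(H, H - dr)
        cs <- max(1, 1 - dc):min(W, W - dc)
        A[rs, cs] <- A[rs, cs] + E[rs + dr, cs + dc]
      }
      A <- A / nrow(off)
      pk <- max(A)
      if (pk > best$score + 1e-12) {
        # row-major tie-break within this radius plane
        hits <- which(A >= pk - 1e-12, arr.ind = TRUE)
        hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
        best <- list(score = pk, radius = r,
                     row = hits[1, 1], col = hits[1, 2])
      }
    }
  }
  if (!is.finite(best$score) || best$score < threshold)
    stop("no circular Hough peak above threshold ", threshold,
         " (best ", signif(max(0, best$score), 3),
         "); supply a manual ROI instead")
  structure(list(center_row = best$row, center_col = best$col,
                 size = out_size, score = best$score, radius = best$radius),
            class = "roi_box")
}

#' Crop a square ROI with edge replication
#'
#' The window of side `box$size` is centered on the box center; rows and
#' columns beyond the image border are replicated from the nearest edge, so
#' the crop is always exactly `size x size`.
#'
#' @param image grayscale matrix.
#' @param box an `roi_box` from [hough_roi()].
#' @return a `size x size` matrix.
#' @export
crop_roi <- function(image, box) {
  half <- box$size %/% 2
  rows <- pmin(pmax(box$center_row - half + seq_len(box$size) - 1, 1),
               nrow(image))
  cols <- pmin(pmax(box$center_col - half + seq_len(box$size) - 1, 1),
               ncol(image))
  image[rows, cols]
}

#' Enhance image contrast
#'
#' `"none"` is the identity; `"gamma"` applies `x^gamma` (the default
#' `gamma = 2` emphasizes bright hot spots); `"clahe_like"` is a
#' contrast-limited percentile stretch: intensities are clipped at the
#' `clip_quantiles` and rescaled to \[0,1\], which cannot decrease the
#' lesion-to-background mean ratio of a bright-lesion phantom.
#'
#' @param image grayscale matrix with intensities in \[0,1\].
#' @param method `"clahe_like"`, `"gamma"` or `"none"`.
#' @param gamma exponent for `method = "gamma"`.
#' @param clip_quantiles lower/upper clipping quantiles for
#'   `method = "clahe_like"`.
#' @return matrix with intensities in \[0,1\].
#' @export
enhance_contrast <- function(image, method = c("clahe_like", "gamma", "none"),
                             gamma = 2, clip_quantiles = c(0.01, 0.99)) {
  if (min(image) < 0 || max(image) > 1)
    stop("intensities must lie in [0,1]")
  method <- match.arg(method)
  switch(method,
    none = image,
    gamma = image^gamma,
    clahe_like = {
      q <- stats::quantile(image, clip_quantiles, names = FALSE)
      if (q[2] - q[1] <= .Machine$double.eps) return(image)
      pmin(pmax((image - q[1]) / (q[2] - q[1]), 0), 1)
    })
}

#' Describe an augmentation set
#'
#' @param rotations subset of `c(90, 180, 270)` degrees (lossless on a
#'   square grid).
#' @param mirror_horizontal,mirror_vertical logical flip flags.
#' @return an `augment_spec` list.
#' @export
augment_spec <- function(rotations = c(90, 180, 270),
                         mirror_horizontal = TRUE, mirror_vertical = TRUE) {
  if (!all(rotations %in% c(90, 180, 270)))
    stop("rotations must be multiples of 90 in {90, 180, 270}")
  structure(list(rotations = rotations,
                 mirror_horizontal = isTRUE(mirror_horizontal),
                 mirror_vertical = isTRUE(mirror_vertical)),
            class = "augment_spec")
}

rot90_once <- function(m) t(m[nrow(m):1, , drop = FALSE])

rot90_k <- function(m, k) {
  for (i in seq_len(k %% 4)) m <- rot90_once(m)
  m
}

apply_rigid <- function(triplet, fn, suffix) {
  out <- triplet
  for (ch in c("ct", "pet", "fused", "mask")) out[[ch]] <- fn(triplet[[ch]])
  out$sample_id <- paste0(triplet$sample_id, suffix)
  out
}

#' Augment a triplet by rotations and mirrors
#'
#' Every transform is a pixel permutation applied identically to all four
#' grids; the original triplet is included first. When both mirror flags are
#' set, the combined (horizontal + vertical) flip is emitted as well, so the
#' default spec yields 6 transforms plus the original.
#'
#' @param triplet an image triplet.
#' @param spec an [augment_spec()].
#' @return list of triplets (original + one per transform).
#' @export
augment <- function(triplet, spec = augment_spec()) {
  stopifnot(inherits(spec, "augment_spec"))
  out <- list(triplet)
  for (ang in spec$rotations)
    out[[length(out) + 1L]] <-
      apply_rigid(triplet, function(m) rot90_k(m, ang / 90),
                  paste0("_rot", ang))
  if (spec$mirror_horizontal)
    out[[length(out) + 1L]] <-
      apply_rigid(triplet, function(m) m[, ncol(m):1, drop = FALSE], "_mirh")
  if (spec$mirror_vertical)
    out[[length(out) + 1L]] <-
      apply_rigid(triplet, function(m) m[nrow(m):1, , drop = FALSE], "_mirv")
  if (spec$mirror_horizontal && spec$mirror_vertical)
    out[[length(out) + 1L]] <-
      apply_rigid(triplet, function(m) m[nrow(m):1, ncol(m):1, drop = FALSE],
                  "_mirhv")
  out
}
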