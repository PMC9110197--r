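# Synthetic tri-modal phantom generator.
#
# Emulates the structure of 50x50 lung-lesion ROI crops: a compact bright
# lesion; a PET channel with high lesion contrast, blur and noise; a CT
# channel with smooth anatomical background, texture and weak lesion
# contrast; and a fused channel that is a convex blend of the two. Every
# pixel is a deterministic function of (seed, config).

#' Phantom generation settings
#'
#' @param image_size square image side in pixels.
#' @param lesion_area_range lesion area as a fraction of the image area,
#'   `c(min, max)`, inside (0, 1).
#' @param lesion_shape `"ellipse"`, `"blob"`, `"lobulated"`, or `"mixed"`
#'   (one of the three drawn per sample).
#' @param pet_contrast lesion-to-background mean-intensity ratio of the PET
#'   channel before blur and noise.
#' @param ct_contrast same for the CT channel; anatomically realistic values
#'   are close to 1 (low lesion conspicuity on CT).
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units on the \[0,1\] scale).
#' @param pet_blur_sigma Gaussian blur sigma of the PET channel, pixels.
#' @param fusion_alpha PET weight of the fused channel, in \[0,1\].
#' @param seed integer seed used by [generate_dataset()].
#' @param max_attempts rejection-sampling bound for mask generation.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(image_size = 50, lesion_area_range = c(0.02, 0.15),
                           lesion_shape = "blob", pet_contrast = 2.5,
                           ct_contrast = 1.3, noise_sd = 0.03,
                           pet_blur_sigma = 1, fusion_alpha = 0.5, seed = 0,
                           max_attempts = 100) {
  stopifnot(image_size >= 8,
            length(lesion_area_range) == 2,
            lesion_area_range[1] > 0, lesion_area_range[2] < 1,
            lesion_area_range[1] <= lesion_area_range[2],
            pet_contrast > 1, ct_contrast >= 1, noise_sd >= 0,
            pet_blur_sigma >= 0,
            fusion_alpha >= 0, fusion_alpha <= 1)
  lesion_shape <- match.arg(lesion_shape,
                            c("ellipse", "blob", "lobulated", "mixed"))
  cfg <- list(image_size = image_size, lesion_area_range = lesion_area_range,
              lesion_shape = lesion_shape, pet_contrast = pet_contrast,
              ct_contrast = ct_contrast, noise_sd = noise_sd,
              pet_blur_sigma = pet_blur_sigma, fusion_alpha = fusion_alpha,
              seed = seed, max_attempts = max_attempts)
  class(cfg) <- "phantom_config"
  cfg
}

# 8-neighbour binary dilation.
dilate8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-H, ]
  out[-H, ] <- out[-H, ] | m[-1, ]
  rowdil <- out
  out[, -1] <- out[, -1] | rowdil[, -W]
  out[, -W] <- out[, -W] | rowdil[, -1]
  out
}

#' Count 8-connected components of a binary mask
#'
#' @param mask binary matrix.
#' @return integer label matrix (attribute-free); `max()` of it is the
#'   component count.
#' @export
label_components <- function(mask) {
  mask <- mask > 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  repeat {
    left <- which(mask & lab == 0L)
    if (length(left) == 0) break
    comp <- comp + 1L
    region <- matrix(FALSE, nrow(mask), ncol(mask))
    region[left[1]] <- TRUE
    repeat {
      grown <- dilate8(region) & mask
      if (sum(grown) == sum(region)) break
      region <- grown
    }
    lab[region] <- comp
  }
  lab
}

# Rasterization helpers -----------------------------------------------------

pixel_grid <- function(S) {
  list(r = matrix(rep(seq_len(S), S), S, S),
       c = matrix(rep(seq_len(S), each = S), S, S))
}

mask_ellipse <- function(S, area_px) {
  g <- pixel_grid(S)
  q <- stats::runif(1, 0.5, 1)
  th <- stats::runif(1, 0, pi)
  r1 <- sqrt(area_px / (pi * q))
  r2 <- q * r1
  cr <- stats::runif(1, 0.32 * S, 0.68 * S)
  cc <- stats::runif(1, 0.32 * S, 0.68 * S)
  dr <- g$r - cr; dc <- g$c - cc
  u <- cos(th) * dr + sin(th) * dc
  v <- -sin(th) * dr + cos(th) * dc
  (u / r1)^2 + (v / r2)^2 <= 1
}

mask_blob <- function(S, area_px) {
  g <- pixel_grid(S)
  k <- sample(3:5, 1)
  cr0 <- stats::runif(1, 0.38 * S, 0.62 * S)
  cc0 <- stats::runif(1, 0.38 * S, 0.62 * S)
  field <- matrix(0, S, S)
  for (i in seq_len(k)) {
    cr <- cr0 + stats::rnorm(1, 0, 0.10 * S)
    cc <- cc0 + stats::rnorm(1, 0, 0.10 * S)
    sg <- stats::runif(1, 0.07 * S, 0.14 * S)
    field <- field + exp(-((g$r - cr)^2 + (g$c - cc)^2) / (2 * sg^2))
  }
  thr <- sort(field, decreasing = TRUE)[area_px]
  field >= thr
}

mask_lobulated <- function(S, area_px) {
  g <- pixel_grid(S)
  k <- sample(3:6, 1)
  r0 <- sqrt(area_px / (1.8 * pi))
  cr <- stats::runif(1, 0.35 * S, 0.65 * S)
  cc <- stats::runif(1, 0.35 * S, 0.65 * S)
  mask <- matrix(FALSE, S, S)
  pr <- r0
  for (i in seq_len(k)) {
    ri <- if (i == 1) r0 else stats::runif(1, 0.55, 0.95) * r0
    mask <- mask | (((g$r - cr)^2 + (g$c - cc)^2) <= ri^2)
    ang <- stats::runif(1, 0, 2 * pi)
    step <- stats::runif(1, 0.7, 1.1) * pr
    cr <- min(max(cr + step * cos(ang), 0.2 * S), 0.8 * S)
    cc <- min(max(cc + step * sin(ang), 0.2 * S), 0.8 * S)
    pr <- ri
  }
  mask
}

#' Generate a binary lesion mask
#'
#' Rejection-samples until the rasterized lesion is a single 8-connected
#' region whose area fraction falls inside `lesion_area_range`.
#'
#' @param config a [phantom_config()].
#' @param seed optional integer; when given, the local RNG state is seeded
#'   so the same (seed, config) pair always yields the same mask.
#' @return integer matrix with values 0/1.
#' @export
generate_mask <- function(config, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(seed)) set.seed(seed)
  S <- config$image_size
  lo <- config$lesion_area_range[1] * S^2
  hi <- config$lesion_area_range[2] * S^2
  for (attempt in seq_len(config$max_attempts)) {
    shape <- config$lesion_shape
    if (shape == "mixed")
      shape <- sample(c("ellipse", "blob", "lobulated"), 1)
    area_target <- round(stats::runif(1, lo, hi))
    m <- switch(shape,
                ellipse = mask_ellipse(S, area_target),
                blob = mask_blob(S, area_target),
                lobulated = mask_lobulated(S, area_target))
    lab <- label_components(m)
    ncomp <- max(lab)
    if (ncomp == 0) next
    if (ncomp > 1) {
      sizes <- tabulate(lab[lab > 0], nbins = ncomp)
      m <- lab == which.max(sizes)
    }
    a <- sum(m)
    if (a >= lo && a <= hi) return(matrix(as.integer(m), S, S))
  }
  stop("generate_mask: could not draw a single-component lesion with area ",
       "fraction in [", config$lesion_area_range[1], ", ",
       config$lesion_area_range[2], "] (shape '", config$lesion_shape,
       "', size ", S, ") after ", config$max_attempts, " attempts")
}

# Separable Gaussian blur via banded row/column operators (truncated kernel
# renormalized at the borders; sigma = 0 is the identity).
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  blur_mat <- function(n) {
    rad <- ceiling(3 * sigma)
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - rad):min(n, i + rad)
      w <- exp(-(j - i)^2 / (2 * sigma^2))
      B[i, j] <- w / sum(w)
    }
    B
  }
  Br <- blur_mat(nrow(img))
  Bc <- blur_mat(ncol(img))
  Br %*% img %*% t(Bc)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Render a tri-modal image triplet from a lesion mask
#'
#' PET: flat background (0.3) with the lesion at `pet_contrast` times the
#' background, then Gaussian blur and additive noise. CT: smooth random
#' anatomical background plus texture, with a weak `ct_contrast` lesion.
#' Fused: `fusion_alpha * pet + (1 - fusion_alpha) * ct` (exact convex
#' blend).
#'
#' @param mask binary matrix matching `config$image_size`.
#' @param config a [phantom_config()].
#' @param sample_id character id stored in the triplet.
#' @return an image triplet: list with `ct`, `pet`, `fused`, `mask`,
#'   `sample_id`.
#' @export
render_triplet <- function(mask, config, sample_id = "sample") {
  stopifnot(inherits(config, "phantom_config"),
            all(mask %in% c(0, 1)),
            nrow(mask) == config$image_size,
            ncol(mask) == config$image_size)
  S <- config$image_size
  bg <- 0.3
  pet <- bg * (1 + (config$pet_contrast - 1) * mask)
  pet <- gauss_blur(pet, config$pet_blur_sigma)
  if (config$noise_sd > 0)
    pet <- clip01(pet + matrix(stats::rnorm(S^2, 0, config$noise_sd), S, S))

  field <- gauss_blur(matrix(stats::runif(S^2), S, S), S / 6)
  rng <- range(field)
  span <- if (diff(rng) > 0) diff(rng) else 1
  field <- 0.25 + 0.30 * (field - rng[1]) / span
  ct <- field + (config$ct_contrast - 1) * mean(field) * mask
  if (config$noise_sd > 0)
    ct <- ct + matrix(stats::rnorm(S^2, 0, config$noise_sd), S, S)
  ct <- clip01(ct)

  fused <- config$fusion_alpha * pet + (1 - config$fusion_alpha) * ct
  structure(list(ct = ct, pet = pet, fused = fused,
                 mask = matrix(as.integer(mask), S, S),
                 sample_id = sample_id),
            class = "apu_triplet")
}

#' Generate one phantom triplet (mask + rendering)
#'
#' @inheritParams generate_mask
#' @param sample_id character id.
#' @return an image triplet.
#' @export
generate_phantom <- function(config, seed = NULL, sample_id = "sample") {
  if (!is.null(seed)) set.seed(seed)
  render_triplet(generate_mask(config), config, sample_id)
}

#' Generate a phantom dataset on disk
#'
#' Writes one 8-bit grayscale PNG per modality plus a `{0, 255}` mask PNG
#' per sample and a CSV manifest, split into train and test. Fully
#' reproducible from `config$seed`.
#'
#' @param n_train,n_test positive sample counts.
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if missing).
#' @return a dataset split: list with `train` and `test` id vectors, the
#'   manifest tibble, and `dir`.
#' @export
generate_dataset <- function(n_train, n_test, config, out_dir) {
  stopifnot(n_train > 0, n_test > 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  set.seed(config$seed)
  n <- n_train + n_test
  ids <- sprintf("s%04d", seq_len(n))
  split <- rep(c("train", "test"), c(n_train, n_test))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tri <- generate_phantom(config, sample_id = ids[i])
    paths <- sprintf("%s_%s.png", ids[i], c("ct", "pet", "fused", "mask"))
    write_gray_png(tri$ct, file.path(out_dir, paths[1]))
    write_gray_png(tri$pet, file.path(out_dir, paths[2]))
    write_gray_png(tri$fused, file.path(out_dir, paths[3]))
    write_gray_png(tri$mask, file.path(out_dir, paths[4]))
    rows[[i]] <- tibble::tibble(sample_id = ids[i], split = split[i],
                                ct = paths[1], pet = paths[2],
                                fused = paths[3], mask = paths[4])
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  structure(list(train = ids[split == "train"], test = ids[split == "test"],
                 manifest = manifest, dir = out_dir),
            class = "apu_dataset_split")
}
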