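# On-disk formats: 8-bit grayscale PNG per modality, {0,255} mask PNG, CSV
# manifests, YAML run configuration.

#' Write a grayscale image as 8-bit PNG
#'
#' Intensities are clipped to \[0,1\] and quantized to 8 bits before
#' writing, so write -> read round-trips within 1/255.
#'
#' @param img numeric matrix in \[0,1\] (masks: 0/1).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' Read a grayscale PNG
#'
#' @param path PNG file; color images are reduced to their first channel.
#' @return numeric matrix with intensities in \[0,1\].
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) stop("missing image file: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Read one image triplet from a manifest row
#'
#' All four PNGs must exist and share the same size; the mask is binarized
#' at 128/255.
#'
#' @param row one manifest row (list or one-row data frame with columns
#'   `sample_id`, `ct`, `pet`, `fused`, `mask`).
#' @param dir directory the manifest paths are relative to.
#' @return an image triplet.
#' @export
read_triplet <- function(row, dir = ".") {
  imgs <- lapply(c("ct", "pet", "fused", "mask"), function(ch)
    read_gray_png(file.path(dir, row[[ch]])))
  dims <- vapply(imgs, function(i) paste(dim(i), collapse = "x"), character(1))
  if (length(unique(dims)) != 1)
    stop("size mismatch across modalities for sample ", row$sample_id,
         ": ", paste(dims, collapse = ", "))
  structure(list(ct = imgs[[1]], pet = imgs[[2]], fused = imgs[[3]],
                 mask = matrix(as.integer(imgs[[4]] >= 128 / 255),
                               nrow(imgs[[4]]), ncol(imgs[[4]])),
                 sample_id = as.character(row$sample_id)),
            class = "apu_triplet")
}

#' Load a phantom dataset from its manifest
#'
#' @param dir dataset directory containing `manifest.csv`.
#' @return list with `train` and `test` lists of triplets and the manifest
#'   tibble.
#' @export
load_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- tibble::as_tibble(utils::read.csv(mpath,
                                                stringsAsFactors = FALSE))
  tris <- lapply(seq_len(nrow(manifest)), function(i)
    read_triplet(manifest[i, ], dir))
  list(train = tris[manifest$split == "train"],
       test = tris[manifest$split == "test"],
       manifest = manifest)
}

# ---- run configuration ----------------------------------------------------

check_known_keys <- function(given, allowed, where) {
  bad <- setdiff(names(given), allowed)
  if (length(bad) > 0)
    stop("unknown ", where, " configuration key(s): ",
         paste(bad, collapse = ", "))
}

#' Load a run configuration from YAML
#'
#' Missing sections and fields fall back to the documented defaults of
#' [phantom_config()], [train_config()] and [model_spec()]; unknown keys are
#' rejected; invalid values raise an error naming the field.
#'
#' @param path YAML file; an empty file yields the full default config.
#' @return a `run_config` list with elements `phantom`, `train`, `model`,
#'   `paths`.
#' @export
load_config <- function(path) {
  raw <- if (is.null(path)) NULL else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  check_known_keys(raw, c("phantom", "train", "model", "paths"), "top-level")
  section <- function(name, ctor) {
    args <- raw[[name]]
    if (is.null(args)) args <- list()
    check_known_keys(args, names(formals(ctor)), name)
    do.call(ctor, args)
  }
  cfg <- list(phantom = section("phantom", phantom_config),
              train = section("train", train_config),
              model = section("model", model_spec),
              paths = if (is.null(raw$paths)) list() else raw$paths)
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration to YAML
#'
#' `load_config(dump_config(cfg, path))` reproduces `cfg` (round-trip
#' idempotence).
#'
#' @param cfg a `run_config`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  plain <- lapply(cfg, function(s) { s <- unclass(s); s })
  yaml::write_yaml(plain, path)
  invisible(path)
}
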