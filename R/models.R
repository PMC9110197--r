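# Model assembly: the parallel U-Net family.
#
# Variants:
#   unet      single-encoder U-Net on CT (channel schedule 64..1024)
#   meu_net   three encoders (CT, PET, fused), skips and bottleneck summed
#   pu_net    parallel U-Nets; skip = concat of branch features, reduced 1x1
#   sapu_net  pu_net + spatial attention on the skips
#   capu_net  pu_net + channel attention on the skips
#   mfpu_net  pu_net + multiscale feature-aggregation head
#   apu_net   two-modal gate + hybrid attention + aggregation head
#
# UNet_A (dual encoder, fused + PET) uses base 16 channels; UNet_B (CT)
# base 32; encoder spatial sizes follow repeated floor-halving
# (50 -> 25 -> 12 -> 6 -> 3) and the decoders mirror them back with 2x2
# transpose convolutions.

APU_VARIANTS <- c("unet", "meu_net", "pu_net", "sapu_net", "capu_net",
                  "mfpu_net", "apu_net")

#' Describe a model architecture
#'
#' @param variant one of `"unet"`, `"meu_net"`, `"pu_net"`, `"sapu_net"`,
#'   `"capu_net"`, `"mfpu_net"`, `"apu_net"`.
#' @param base_channels_a first-level channels of the dual-encoder
#'   subnetwork (doubles per level).
#' @param base_channels_b first-level channels of the CT subnetwork.
#' @param base_channels_u first-level channels of the plain/multi-encoder
#'   U-Net variants.
#' @param depth number of encoder levels.
#' @param input_size square input side in pixels.
#' @param num_classes output classes (background/lesion).
#' @param two_modal_text_variant use the all-1x1 gate path of the two-modal
#'   block instead of the 1x1 + 3x3 path.
#' @param attention_order order of the hybrid attention stages.
#' @param dropout_p dropout probability applied at the bottlenecks during
#'   training.
#' @param mfa_per_scale_ch channels kept per scale by the aggregation head
#'   (16 at the reference scale).
#' @return a `model_spec` list.
#' @export
model_spec <- function(variant = "apu_net", base_channels_a = 16,
                       base_channels_b = 32, base_channels_u = 64,
                       depth = 5, input_size = 50, num_classes = 2,
                       two_modal_text_variant = FALSE,
                       attention_order = c("channel", "spatial"),
                       dropout_p = 0.5, mfa_per_scale_ch = 16) {
  variant <- match.arg(variant, APU_VARIANTS)
  stopifnot(depth >= 2, input_size >= 2^(depth - 1), num_classes >= 2,
            base_channels_a >= 1, base_channels_b >= 1)
  spec <- list(variant = variant, base_channels_a = base_channels_a,
               base_channels_b = base_channels_b,
               base_channels_u = base_channels_u, depth = depth,
               input_size = input_size, num_classes = num_classes,
               two_modal_text_variant = two_modal_text_variant,
               attention_order = attention_order, dropout_p = dropout_p,
               mfa_per_scale_ch = mfa_per_scale_ch)
  class(spec) <- "apu_model_spec"
  spec
}

spec_flags <- function(spec) {
  v <- spec$variant
  list(dual = !v %in% c("unet", "meu_net"),
       two_modal = v == "apu_net",
       ca = v %in% c("capu_net", "apu_net"),
       sa = v %in% c("sapu_net", "apu_net"),
       mfa = v %in% c("mfpu_net", "apu_net"))
}

spec_sizes <- function(spec) {
  s <- integer(spec$depth)
  s[1] <- spec$input_size
  for (l in seq_len(spec$depth - 1)) s[l + 1] <- s[l] %/% 2
  s
}

#' Build a network from a model spec
#'
#' Weight initialization draws from R's RNG: call `set.seed()` first for a
#' reproducible model.
#'
#' @param spec a [model_spec()].
#' @return an `apu_model` object.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "apu_model_spec"))
  fl <- spec_flags(spec)
  m <- new.env(parent = emptyenv())
  m$spec <- spec
  m$flags <- fl
  d <- spec$depth
  if (fl$dual) {
    chA <- spec$base_channels_a * 2^(seq_len(d) - 1)
    chB <- spec$base_channels_b * 2^(seq_len(d) - 1)
    m$chA <- chA; m$chB <- chB
    m$encA1 <- lapply(seq_len(d), function(l)
      new_conv_block(if (l == 1) 1 else chA[l - 1], chA[l]))
    m$encA2 <- lapply(seq_len(d), function(l)
      new_conv_block(if (l == 1) 1 else chA[l - 1], chA[l]))
    m$encB <- lapply(seq_len(d), function(l)
      new_conv_block(if (l == 1) 1 else chB[l - 1], chB[l]))
    hybC <- if (fl$two_modal) 2 * chA else chA
    if (fl$two_modal)
      m$tm <- lapply(seq_len(d - 1), function(l)
        new_two_modal_block(chA[l], spec$two_modal_text_variant))
    catC <- hybC[seq_len(d - 1)] + chB[seq_len(d - 1)]
    if (fl$ca) m$ca <- lapply(catC, new_channel_attention)
    if (fl$sa) m$sa <- lapply(catC, function(...) new_spatial_attention())
    m$redA <- lapply(seq_len(d - 1), function(l) nn_conv2d(catC[l], chA[l], 1))
    m$redB <- lapply(seq_len(d - 1), function(l) nn_conv2d(catC[l], chB[l], 1))
    m$upA <- lapply(seq_len(d - 1), function(l) nn_convt2x2(chA[l + 1], chA[l]))
    m$upB <- lapply(seq_len(d - 1), function(l) nn_convt2x2(chB[l + 1], chB[l]))
    m$decA <- lapply(seq_len(d - 1), function(l)
      new_conv_block(2 * chA[l], chA[l]))
    m$decB <- lapply(seq_len(d - 1), function(l)
      new_conv_block(2 * chB[l], chB[l]))
    m$headA <- nn_conv2d(chA[1], spec$num_classes, 1)
    m$headB <- nn_conv2d(chB[1], spec$num_classes, 1)
    if (fl$mfa) {
      if (d != 5) stop("the aggregation head expects 4 decoder scales ",
                       "(depth 5)")
      scales <- rev(seq_len(d - 1))              # coarsest first
      m$mfa <- new_mfa_block(chA[scales] + chB[scales],
                             out_size = spec$input_size,
                             per_scale_ch = spec$mfa_per_scale_ch)
      m$headM <- nn_conv2d(m$mfa$ftot, spec$num_classes, 1)
    }
    m$modules <- list(m$encA1, m$encA2, m$encB, m$tm, m$ca, m$sa, m$redA,
                      m$redB, m$upA, m$upB, m$decA, m$decB, m$headA,
                      m$headB, m$mfa, m$headM)
  } else {
    chU <- spec$base_channels_u * 2^(seq_len(d) - 1)
    m$chU <- chU
    n_enc <- if (spec$variant == "meu_net") 3L else 1L
    m$enc <- lapply(seq_len(n_enc), function(e)
      lapply(seq_len(d), function(l)
        new_conv_block(if (l == 1) 1 else chU[l - 1], chU[l])))
    m$up <- lapply(seq_len(d - 1), function(l) nn_convt2x2(chU[l + 1], chU[l]))
    m$dec <- lapply(seq_len(d - 1), function(l)
      new_conv_block(2 * chU[l], chU[l]))
    m$head <- nn_conv2d(chU[1], spec$num_classes, 1)
    m$modules <- list(m$enc, m$up, m$dec, m$head)
  }
  m$params <- nn_parameters(m$modules)
  class(m) <- "apu_model"
  m
}

#' @export
print.apu_model <- function(x, ...) {
  cat("<apu_model ", x$spec$variant, ": depth ", x$spec$depth,
      ", input ", x$spec$input_size, "x", x$spec$input_size,
      ", ", format(count_parameters(x), big.mark = ","),
      " trainable parameters>\n", sep = "")
  invisible(x)
}

# Forward pass over a batch. ct/pet/fused: arrays (H, W, 1, N).
# Returns list(final, heads, trace) of tensors / trace rows.
model_forward <- function(m, ct, pet, fused, training = FALSE,
                          with_trace = FALSE) {
  tr <- if (with_trace) new.env(parent = emptyenv()) else NULL
  if (with_trace) tr$rows <- list()
  note <- function(name, t) {
    if (!is.null(tr)) {
      d <- dim(t$value)
      tr$rows[[length(tr$rows) + 1L]] <-
        list(name = name, channels = d[3], height = d[1], width = d[2])
    }
    t
  }
  spec <- m$spec
  fl <- m$flags
  d <- spec$depth
  sizes <- spec_sizes(spec)
  drop_p <- spec$dropout_p

  if (fl$dual) {
    xa1 <- as_feature_map(fused)
    xa2 <- as_feature_map(pet)
    xb <- as_feature_map(ct)
    skipsA <- skipsB <- vector("list", d - 1)
    decA_outs <- decB_outs <- vector("list", d - 1)
    for (l in seq_len(d)) {
      xa1 <- note(sprintf("encoder1_A/block%d", l),
                  fwd_conv_block(m$encA1[[l]], xa1, training))
      xa2 <- note(sprintf("encoder2_A/block%d", l),
                  fwd_conv_block(m$encA2[[l]], xa2, training))
      xb <- note(sprintf("encoder_B/block%d", l),
                 fwd_conv_block(m$encB[[l]], xb, training))
      if (l < d) {
        fhyb <- if (fl$two_modal)
          note(sprintf("two_modal/level%d", l),
               fwd_two_modal(m$tm[[l]], xa1, xa2, training))
        else op_add(xa1, xa2)
        sk <- op_concat(list(fhyb, xb))
        for (step in spec$attention_order) {
          if (step == "channel" && fl$ca)
            sk <- fwd_channel_attention(m$ca[[l]], sk, training)
          if (step == "spatial" && fl$sa)
            sk <- fwd_spatial_attention(m$sa[[l]], sk, training)
        }
        note(sprintf("skip/level%d", l), sk)
        skipsA[[l]] <- op_conv2d(sk, m$redA[[l]]$w, m$redA[[l]]$b)
        skipsB[[l]] <- op_conv2d(sk, m$redB[[l]]$w, m$redB[[l]]$b)
        xa1 <- op_maxpool2(xa1)
        xa2 <- op_maxpool2(xa2)
        xb <- op_maxpool2(xb)
      }
    }
    xa <- note("bottleneck_A", op_add(xa1, xa2))
    xa <- op_dropout(xa, drop_p, training)
    xb <- note("bottleneck_B", op_dropout(xb, drop_p, training))
    da <- xa; db <- xb
    for (l in rev(seq_len(d - 1))) {
      da <- op_convt2x2(da, m$upA[[l]]$w, m$upA[[l]]$b, sizes[l], sizes[l])
      da <- fwd_conv_block(m$decA[[l]], op_concat(list(da, skipsA[[l]])),
                           training)
      note(sprintf("decoder_A/U%d", l), da)
      db <- op_convt2x2(db, m$upB[[l]]$w, m$upB[[l]]$b, sizes[l], sizes[l])
      db <- fwd_conv_block(m$decB[[l]], op_concat(list(db, skipsB[[l]])),
                           training)
      note(sprintf("decoder_B/U%d", l), db)
      i <- d - l                                  # 1 = coarsest
      decA_outs[[i]] <- da
      decB_outs[[i]] <- db
    }
    la <- note("head_A", op_conv2d(da, m$headA$w, m$headA$b))
    lb <- note("head_B", op_conv2d(db, m$headB$w, m$headB$b))
    if (fl$mfa) {
      pairs <- lapply(seq_len(d - 1), function(i)
        list(decA_outs[[i]], decB_outs[[i]]))
      fm <- note("mfa", fwd_mfa(m$mfa, pairs, training))
      lf <- note("head_mfa", op_conv2d(fm, m$headM$w, m$headM$b))
      list(final = lf, heads = list(lf, la, lb), trace = tr)
    } else {
      list(final = note("head_sum", op_add(la, lb)),
           heads = list(la, lb), trace = tr)
    }
  } else {
    ins <- if (spec$variant == "meu_net")
      list(as_feature_map(ct), as_feature_map(pet), as_feature_map(fused))
    else list(as_feature_map(ct))
    skips <- vector("list", d - 1)
    for (l in seq_len(d)) {
      for (e in seq_along(ins))
        ins[[e]] <- note(sprintf("encoder%d/block%d", e, l),
                         fwd_conv_block(m$enc[[e]][[l]], ins[[e]], training))
      if (l < d) {
        sk <- ins[[1]]
        if (length(ins) > 1)
          for (e in 2:length(ins)) sk <- op_add(sk, ins[[e]])
        skips[[l]] <- sk
        ins <- lapply(ins, op_maxpool2)
      }
    }
    x <- ins[[1]]
    if (length(ins) > 1) for (e in 2:length(ins)) x <- op_add(x, ins[[e]])
    x <- note("bottleneck", op_dropout(x, drop_p, training))
    for (l in rev(seq_len(d - 1))) {
      x <- op_convt2x2(x, m$up[[l]]$w, m$up[[l]]$b, sizes[l], sizes[l])
      x <- note(sprintf("decoder/U%d", l),
                fwd_conv_block(m$dec[[l]], op_concat(list(x, skips[[l]])),
                               training))
    }
    lf <- note("head", op_conv2d(x, m$head$w, m$head$b))
    list(final = lf, heads = list(lf), trace = tr)
  }
}

triplet_batch <- function(triplets) {
  H <- nrow(triplets[[1]]$ct)
  W <- ncol(triplets[[1]]$ct)
  N <- length(triplets)
  pack <- function(field) {
    a <- array(0, c(H, W, 1, N))
    for (i in seq_len(N)) a[, , 1, i] <- triplets[[i]][[field]]
    a
  }
  list(ct = pack("ct"), pet = pack("pet"), fused = pack("fused"),
       mask = {
         msk <- array(0L, c(H, W, N))
         for (i in seq_len(N)) msk[, , i] <- triplets[[i]]$mask
         msk
       })
}

#' Record per-block output shapes for one triplet
#'
#' Runs the network in evaluation mode on a single image triplet and
#' returns a tibble with one row per recorded block output.
#'
#' @param model an [build_model()] result.
#' @param triplet an image triplet (list with `ct`, `pet`, `fused`, `mask`).
#' @return a tibble with columns `name`, `channels`, `height`, `width`.
#' @export
forward_trace <- function(model, triplet) {
  b <- triplet_batch(list(triplet))
  out <- model_forward(model, b$ct, b$pet, b$fused, training = FALSE,
                       with_trace = TRUE)
  rows <- out$trace$rows
  tibble::tibble(
    name = vapply(rows, `[[`, character(1), "name"),
    channels = vapply(rows, function(r) as.integer(r$channels), integer(1)),
    height = vapply(rows, function(r) as.integer(r$height), integer(1)),
    width = vapply(rows, function(r) as.integer(r$width), integer(1)))
}

#' Predict a binary lesion mask for one triplet
#'
#' Evaluation-mode forward pass followed by an argmax over classes.
#'
#' @inheritParams forward_trace
#' @return integer matrix (H x W) with values 0/1.
#' @export
predict_mask <- function(model, triplet) {
  if (nrow(triplet$ct) != model$spec$input_size)
    stop("triplet size ", nrow(triplet$ct), " does not match model input ",
         model$spec$input_size)
  b <- triplet_batch(list(triplet))
  out <- model_forward(model, b$ct, b$pet, b$fused, training = FALSE)
  logits <- out$final$value
  cls <- apply(logits[, , , 1], c(1, 2), which.max) - 1L
  matrix(as.integer(cls > 0), nrow(cls), ncol(cls))
}

#' Count trainable parameters
#'
#' @param model an `apu_model`.
#' @return integer scalar: total number of trainable weights.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

# ---- weights snapshot / persistence --------------------------------------

collect_bn_layers <- function(x) {
  out <- list()
  walk <- function(o) {
    if (inherits(o, "apu_batchnorm")) out[[length(out) + 1L]] <<- o
    else if (inherits(o, "apu_layer")) NULL
    else if (inherits(o, "apu_block")) walk(o$layers)
    else if (is.list(o)) for (el in o) if (!is.null(el)) walk(el)
  }
  walk(x)
  out
}

model_state <- function(model) {
  bns <- collect_bn_layers(model$modules)
  list(params = lapply(model$params, function(p) p$value),
       bn = lapply(bns, function(b)
         list(mean = b$running_mean, var = b$running_var)))
}

set_model_state <- function(model, state) {
  stopifnot(length(state$params) == length(model$params))
  for (i in seq_along(model$params))
    model$params[[i]]$value <- state$params[[i]]
  bns <- collect_bn_layers(model$modules)
  stopifnot(length(bns) == length(state$bn))
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- state$bn[[i]]$mean
    bns[[i]]$running_var <- state$bn[[i]]$var
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' Weights go to `<path>` (RDS) and the architecture spec plus the training
#' seed to a YAML sidecar `<path>.yaml`.
#'
#' @param model an `apu_model`.
#' @param path checkpoint file path.
#' @param seed optional integer recorded in the sidecar.
#' @return `path`, invisibly (`load_model` returns the rebuilt model).
#' @export
save_model <- function(model, path, seed = NULL) {
  saveRDS(model_state(model), path)
  side <- model$spec
  class(side) <- NULL
  side$seed <- seed
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  seed <- side$seed
  side$seed <- NULL
  spec <- do.call(model_spec, side)
  model <- build_model(spec)
  set_model_state(model, readRDS(path))
  model$seed <- seed
  model
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row model summary
#'
#' @param x an `apu_model`.
#' @param ... unused.
#' @return a one-row tibble: variant, depth, input size, parameter count.
#' @export
glance.apu_model <- function(x, ...) {
  tibble::tibble(variant = x$spec$variant, depth = x$spec$depth,
                 input_size = x$spec$input_size,
                 n_parameters = count_parameters(x))
}
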