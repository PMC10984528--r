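# Full-network assembly: per-scale MFB modules on the backbone pyramid, the
# progressive-upsampling decoder with skip concatenation, and the prediction
# head producing one logit channel at input resolution.

#' Model configuration
#'
#' Stage widths, depths and heads of the backbone, the attention window, the
#' FFN expansion, the MFB/decoder width and the VSA toggle. The default
#' configuration totals about 23 million trainable parameters.
#'
#' @param widths 4 embedding widths, one per stage.
#' @param depths 4 normal-cell depths.
#' @param heads 4 attention head counts (each must divide its width).
#' @param window default attention window side.
#' @param ffn_ratio feed-forward expansion ratio of the normal cells.
#' @param mfb_width channel width of the MFB branches, the decoder and the
#'   head.
#' @param vsa use varied-size window attention (FALSE gives fixed windows).
#' @param in_channels image channels.
#' @return Object of class `pmffnet_config`.
#' @export
pmffnet_config <- function(widths = c(64L, 64L, 192L, 448L),
                           depths = c(2L, 2L, 8L, 2L),
                           heads = c(1L, 2L, 4L, 8L),
                           window = 7L,
                           ffn_ratio = 4L,
                           mfb_width = 64L,
                           vsa = TRUE,
                           in_channels = 3L) {
  stopifnot(length(widths) == 4, length(depths) == 4, length(heads) == 4,
            all(widths %% heads == 0), window >= 1, mfb_width >= 8)
  structure(list(widths = as.integer(widths), depths = as.integer(depths),
                 heads = as.integer(heads), window = as.integer(window),
                 ffn_ratio = ffn_ratio, mfb_width = as.integer(mfb_width),
                 vsa = isTRUE(vsa), in_channels = as.integer(in_channels)),
            class = "pmffnet_config")
}

#' A small configuration for desk-scale experiments
#'
#' Same architecture, reduced widths and depths; used for quick CPU training
#' runs and tests.
#' @export
pmffnet_config_small <- function() {
  pmffnet_config(widths = c(16L, 16L, 32L, 64L), depths = c(1L, 1L, 2L, 1L),
                 heads = c(1L, 1L, 2L, 2L), window = 7L, ffn_ratio = 2L,
                 mfb_width = 16L)
}

#' Progressive-upsampling decoder
#'
#' Starting from the deepest MFB output, each fusion step upsamples by
#' exactly 2x (bilinear), concatenates with the next-shallower MFB output to
#' 2 x width channels, and applies RB(2w -> w) then RB(w -> w). After the
#' 1/4-scale step the map is upsampled to full input resolution. The output
#' channel count stays at `width` throughout.
#'
#' @param width decoder channel width (matches the MFB output width).
#' @return A module whose forward takes the list of four MFB maps
#'   (shallowest first) and returns a full-resolution feature map.
#' @export
decoder_block <- function(width = 64L) {
  steps <- lapply(1:3, function(i) {
    list(rb1 = rb_block(2L * width, width), rb2 = rb_block(width, width))
  })
  params <- list()
  for (i in 1:3) {
    params <- c(params,
                prefixed(sprintf("step%d.rb1", i), steps[[i]]$rb1),
                prefixed(sprintf("step%d.rb2", i), steps[[i]]$rb2))
  }
  fwd <- function(mfbs, out_side = NULL) {
    x <- mfbs[[4]]
    for (i in 1:3) {
      skip <- mfbs[[4 - i]]
      ds <- dim(ad_value(skip))
      x <- ad_upsample_bilinear(x, ds[1], ds[2])
      x <- ad_concat_channels(list(x, skip))
      x <- steps[[i]]$rb2$fwd(steps[[i]]$rb1$fwd(x))
    }
    if (!is.null(out_side)) {
      x <- ad_upsample_bilinear(x, out_side[1], out_side[2])
    }
    x
  }
  new_module(params, fwd, meta = list(width = width))
}

#' Apply the decoder to a feature pyramid
#'
#' @param decoder a [decoder_block()] module (or full model).
#' @param pyramid_mfb list of four MFB output arrays (strides 4/8/16/32,
#'   shallowest first), each with the decoder width's channel count.
#' @param out_side optional (H, W) of the network input for the final
#'   upsample; defaults to 4x the shallowest map.
#' @return Full-resolution feature array.
#' @export
decoder_forward <- function(decoder, pyramid_mfb, out_side = NULL) {
  if (inherits(decoder, "pmffnet_model")) decoder <- decoder$decoder
  if (is.null(out_side)) {
    d1 <- dim(ad_value(pyramid_mfb[[1]]))
    out_side <- c(4L * d1[1], 4L * d1[2])
  }
  if (is_ad(pyramid_mfb[[1]])) return(decoder$fwd(pyramid_mfb, out_side))
  ad_value(ad_no_grad(
    decoder$fwd(lapply(pyramid_mfb, function(m) ad_const(as_feature_map(m))),
                out_side)))
}

#' Prediction head: two RBs and a 1x1 convolution to one logit channel
#'
#' @param width input channel width.
#' @return A module; apply with [prediction_head_forward()].
#' @export
prediction_head_block <- function(width = 64L) {
  rb1 <- rb_block(width, width)
  rb2 <- rb_block(width, width)
  params <- c(prefixed("rb1", rb1), prefixed("rb2", rb2),
              list(Wout = ad_param(conv_weight(1, width, 1L)),
                   bout = ad_param(numeric(1))))
  fwd <- function(x) {
    ad_conv2d(rb2$fwd(rb1$fwd(x)), params$Wout, params$bout, pad = 0L)
  }
  new_module(params, fwd, meta = list(width = width))
}

#' @rdname cb_forward
#' @export
prediction_head_forward <- function(block, x) run_module(block, x)

#' Assemble the full segmentation network
#'
#' Backbone pyramid -> one MFB per scale -> progressive decoder -> prediction
#' head. Construction is seeded, so the same seed and configuration give
#' bit-identical initial weights.
#'
#' @param config a [pmffnet_config()].
#' @param seed integer seed for weight initialization.
#' @return Object of class `pmffnet_model` with fields `config`, `backbone`,
#'   `mfbs`, `decoder`, `head` and the flat named parameter list `params`.
#' @export
pmffnet_model <- function(config = pmffnet_config(), seed = 42L) {
  stopifnot(inherits(config, "pmffnet_config"))
  set.seed(seed)
  backbone <- v2s_backbone(config)
  mfbs <- lapply(1:4, function(st) {
    mfb_block(config$widths[st], config$mfb_width)
  })
  decoder <- decoder_block(config$mfb_width)
  head <- prediction_head_block(config$mfb_width)
  params <- c(prefixed("backbone", backbone),
              prefixed("mfb1", mfbs[[1]]), prefixed("mfb2", mfbs[[2]]),
              prefixed("mfb3", mfbs[[3]]), prefixed("mfb4", mfbs[[4]]),
              prefixed("decoder", decoder), prefixed("head", head))
  structure(list(config = config, backbone = backbone, mfbs = mfbs,
                 decoder = decoder, head = head, params = params,
                 seed = seed),
            class = "pmffnet_model")
}

#' @export
print.pmffnet_model <- function(x, ...) {
  cat(sprintf(paste0("<pmffnet model: widths %s, depths %s, %s windows, ",
                     "%.2f M parameters>\n"),
              paste(x$config$widths, collapse = "/"),
              paste(x$config$depths, collapse = "/"),
              if (x$config$vsa) "varied-size" else "fixed",
              count_parameters(x) / 1e6))
  invisible(x)
}

# graph-building forward used by both inference and training
pmffnet_graph <- function(model, x, taps = FALSE) {
  d <- dim(ad_value(x))
  pyr <- model$backbone$fwd(x)
  mfb_out <- lapply(1:4, function(st) model$mfbs[[st]]$fwd(pyr[[st]]))
  dec <- model$decoder$fwd(mfb_out, c(d[1], d[2]))
  logits <- model$head$fwd(dec)
  if (!taps) return(logits)
  list(logits = logits, pyramid = pyr, mfb = mfb_out, decoder = dec)
}

#' Forward pass of the full network
#'
#' @param model a [pmffnet_model()].
#' @param image (H, W, 3) or (H, W, 3, N) array, sides divisible by 32.
#' @param taps also return the backbone/MFB/decoder intermediate maps.
#' @return Logit array (H, W, 1, N), or a list when `taps = TRUE`. Apply
#'   `1 / (1 + exp(-logits))` and threshold at 0.5 for a binary mask.
#' @export
pmffnet_forward <- function(model, image, taps = FALSE) {
  stopifnot(inherits(model, "pmffnet_model"))
  if (is_ad(image)) return(pmffnet_graph(model, image, taps))
  out <- ad_no_grad(pmffnet_graph(model, ad_const(as_feature_map(image)), taps))
  if (!taps) return(ad_value(out))
  list(logits = ad_value(out$logits),
       pyramid = lapply(out$pyramid, ad_value),
       mfb = lapply(out$mfb, ad_value),
       decoder = ad_value(out$decoder))
}
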