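# Four-stage hybrid pyramid encoder: reduction cells (RC) downsample and
# embed with a parallel multi-dilation convolution path, normal cells (NC)
# mix tokens with varied-size window attention (VSA) plus a parallel
# convolution, and the pyramid is tapped after the last NC of each stage.

#' Varied-size window attention block
#'
#' Multi-head attention inside `w0 x w0` windows. Queries always come from
#' the default window grid; with VSA enabled a small regression head (window
#' average pool, two-layer perceptron) predicts a per-head, per-window scale
#' and offset, and keys/values are bilinearly resampled from the transformed
#' windows. The scale goes through an exponential map and the final
#' regression layer is zero-initialized, so at initialization the block is
#' exactly fixed-window attention. Relative position bias is stored on the
#' integer offset grid and interpolated at the (possibly fractional) sampled
#' offsets; feature maps whose sides are not multiples of `w0` are zero-padded
#' on the bottom/right and cropped after attention.
#'
#' @param channels token embedding width (must be divisible by `heads`).
#' @param heads number of attention heads.
#' @param w0 default window side length.
#' @param vsa logical: varied-size windows (TRUE) or fixed windows (FALSE).
#' @return A module; apply with [vsa_forward()].
#' @export
vsa_block <- function(channels, heads, w0 = 7L, vsa = TRUE) {
  stopifnot(channels %% heads == 0)
  dh <- channels %/% heads
  l <- 2L * w0 - 1L
  hidden <- max(8L, channels %/% 4L)
  params <- list(
    Wqkv = ad_param(matrix(trunc_normal(channels * 3 * channels), channels)),
    bqkv = ad_param(numeric(3 * channels)),
    Wproj = ad_param(matrix(trunc_normal(channels * channels), channels)),
    bproj = ad_param(numeric(channels))
  )
  if (vsa) {
    params$Wr1 <- ad_param(matrix(trunc_normal(channels * hidden), channels))
    params$br1 <- ad_param(numeric(hidden))
    # zero-initialized: identity windows at the start of training
    params$Wr2 <- ad_param(matrix(0, hidden, 4L * heads))
    params$br2 <- ad_param(numeric(4L * heads))
  }
  for (h in seq_len(heads)) {
    params[[paste0("bias", h)]] <- ad_param(matrix(trunc_normal(l * l), l, l))
  }

  tok_r <- (seq_len(w0 * w0) - 1L) %% w0        # 0-based row within window
  tok_c <- (seq_len(w0 * w0) - 1L) %/% w0       # 0-based col within window
  rel_y <- tok_r - (w0 - 1) / 2
  rel_x <- tok_c - (w0 - 1) / 2
  tt <- w0 * w0
  # fixed-window relative offsets (key minus query), shared by all windows
  # [i, j] = rel[j] - rel[i]: offset of key j relative to query i
  dy_fix <- outer(rel_y, rel_y, function(qi, kj) kj - qi)
  dx_fix <- outer(rel_x, rel_x, function(qi, kj) kj - qi)

  fwd <- function(x) {
    d <- dim(ad_value(x))
    h_in <- d[1]; w_in <- d[2]; n <- d[4]
    hp <- as.integer(ceiling(h_in / w0) * w0)
    wp <- as.integer(ceiling(w_in / w0) * w0)
    nwy <- hp %/% w0; nwx <- wp %/% w0
    nw <- nwy * nwx
    s <- hp * wp
    # window top-left corners, ordered wy fastest (partition order)
    win_y0 <- rep(seq_len(nwy) - 1L, times = nwx) * w0
    win_x0 <- rep(seq_len(nwx) - 1L, each = nwy) * w0
    cy <- win_y0 + (w0 - 1) / 2
    cx <- win_x0 + (w0 - 1) / 2
    qy <- outer(win_y0, tok_r, "+")  # (nw, tt) integer query rows
    qx <- outer(win_x0, tok_c, "+")
    rel_y_row <- matrix(rel_y, 1)
    rel_x_row <- matrix(rel_x, 1)
    ones_row <- matrix(1, 1, tt)
    cy_mat <- matrix(cy, nw, tt)
    cx_mat <- matrix(cx, nw, tt)

    partition <- function(t_node, width) {
      # (S, width) tokens -> (tt, width, nw) windows
      z <- ad_reshape(t_node, c(w0, nwy, w0, nwx, width))
      z <- ad_aperm(z, c(1, 3, 2, 4, 5))
      z <- ad_reshape(z, c(tt, nw, width))
      ad_aperm(z, c(1, 3, 2))
    }
    unpartition <- function(z_node, width) {
      z <- ad_aperm(z_node, c(1, 3, 2))            # (tt, nw, width)
      z <- ad_reshape(z, c(w0, w0, nwy, nwx, width))
      z <- ad_aperm(z, c(1, 3, 2, 4, 5))
      ad_reshape(z, c(s, width))
    }

    outs <- vector("list", n)
    for (si in seq_len(n)) {
      sample <- if (n == 1L) x else ad_slice_sample(x, si)
      sample <- ad_pad_hw(sample, hp, wp)
      tokens <- ad_reshape(sample, c(s, d[3]))
      qkv <- ad_linear(tokens, params$Wqkv, params$bqkv)

      reg <- NULL
      if (vsa) {
        pooled <- ad_tokmean(ad_aperm(partition(tokens, d[3]), c(3, 1, 2)))
        reg <- ad_linear(ad_gelu(ad_linear(pooled, params$Wr1, params$br1)),
                         params$Wr2, params$br2)   # (nw, 4 * heads)
      }

      head_outs <- vector("list", heads)
      for (h in seq_len(heads)) {
        cols <- (h - 1L) * dh + seq_len(dh)
        q <- ad_cols(qkv, cols)
        k <- ad_cols(qkv, d[3] + cols)
        v <- ad_cols(qkv, 2L * d[3] + cols)
        qw <- partition(q, dh)

        if (vsa) {
          base <- (h - 1L) * 4L
          sx <- ad_exp(ad_cols(reg, base + 1L))
          sy <- ad_exp(ad_cols(reg, base + 2L))
          ox <- ad_cols(reg, base + 3L)
          oy <- ad_cols(reg, base + 4L)
          py <- ad_add(ad_add(ad_matmul(sy, rel_y_row),
                              ad_matmul(oy, ones_row)), cy_mat)
          px <- ad_add(ad_add(ad_matmul(sx, rel_x_row),
                              ad_matmul(ox, ones_row)), cx_mat)
          py <- ad_clamp(py, 0, hp - 1)
          px <- ad_clamp(px, 0, wp - 1)
          pyv <- ad_reshape(py, nw * tt)
          pxv <- ad_reshape(px, nw * tt)
          kw <- ad_aperm(ad_reshape(ad_bilin_sample(k, pyv, pxv, hp, wp),
                                    c(nw, tt, dh)), c(2, 3, 1))
          vw <- ad_aperm(ad_reshape(ad_bilin_sample(v, pyv, pxv, hp, wp),
                                    c(nw, tt, dh)), c(2, 3, 1))
          # offsets for the interpolated position bias (treated as constants)
          pyn <- ad_value(py); pxn <- ad_value(px)
          key_y <- aperm(array(pyn, c(nw, tt, tt)), c(3, 2, 1))
          key_x <- aperm(array(pxn, c(nw, tt, tt)), c(3, 2, 1))
          qry_y <- aperm(array(qy, c(nw, tt, tt)), c(2, 3, 1))
          qry_x <- aperm(array(qx, c(nw, tt, tt)), c(2, 3, 1))
          dya <- key_y - qry_y
          dxa <- key_x - qry_x
        } else {
          kw <- partition(k, dh)
          vw <- partition(v, dh)
          dya <- array(dy_fix, c(tt, tt, nw))
          dxa <- array(dx_fix, c(tt, tt, nw))
        }

        logits <- ad_mul(ad_bmm(qw, kw, FALSE, TRUE), 1 / sqrt(dh))
        logits <- ad_add(logits,
                         ad_bias_interp(params[[paste0("bias", h)]],
                                        dya, dxa, w0))
        sm <- ad_reshape(ad_aperm(logits, c(1, 3, 2)), c(tt * nw, tt))
        sm <- ad_softmax_rows(sm)
        attn <- ad_aperm(ad_reshape(sm, c(tt, nw, tt)), c(1, 3, 2))
        head_outs[[h]] <- unpartition(ad_bmm(attn, vw), dh)
      }
      merged <- if (heads == 1L) head_outs[[1L]] else ad_cbind(head_outs)
      proj <- ad_linear(merged, params$Wproj, params$bproj)
      out <- ad_reshape(proj, c(hp, wp, d[3], 1L))
      outs[[si]] <- ad_crop_hw(out, h_in, w_in)
    }
    if (n == 1L) outs[[1L]] else ad_stack_samples(outs)
  }
  new_module(params, fwd,
             meta = list(channels = channels, heads = heads, w0 = w0, vsa = vsa))
}

#' @rdname cb_forward
#' @export
vsa_forward <- function(block, x) run_module(block, x)

# layer normalization applied channel-wise to an (H, W, C, N) map
map_layernorm <- function(x, gamma, beta) {
  d <- dim(ad_value(x))
  t <- ad_reshape(ad_aperm(x, c(1, 2, 4, 3)), c(d[1] * d[2] * d[4], d[3]))
  t <- ad_layernorm(t, gamma, beta)
  ad_aperm(ad_reshape(t, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

#' Normal cell: attention + parallel convolution + feed-forward
#'
#' Pre-norm transformer cell with a parallel convolutional path:
#' `x <- x + Attn(LN(x)) + PCM(x)` followed by `x <- x + FFN(LN(x))`, where
#' PCM is a 3x3 convolution with group normalization and SiLU, and the FFN is
#' a two-layer GELU perceptron of the given expansion ratio. Spatial
#' dimensions are preserved.
#'
#' @inheritParams vsa_block
#' @param ffn_ratio FFN expansion ratio.
#' @return A module; apply with [nc_forward()].
#' @export
nc_block <- function(channels, heads, w0 = 7L, ffn_ratio = 4L, vsa = TRUE) {
  attn <- vsa_block(channels, heads, w0, vsa)
  hidden <- as.integer(ffn_ratio * channels)
  g <- gn_groups(channels)
  params <- c(
    list(
      ln1_g = ad_param(rep(1, channels)), ln1_b = ad_param(numeric(channels)),
      ln2_g = ad_param(rep(1, channels)), ln2_b = ad_param(numeric(channels)),
      Wpcm = ad_param(conv_weight(3, channels, channels)),
      bpcm = ad_param(numeric(channels)),
      gpcm = ad_param(rep(1, channels)), bpcm2 = ad_param(numeric(channels)),
      Wf1 = ad_param(matrix(trunc_normal(channels * hidden), channels)),
      bf1 = ad_param(numeric(hidden)),
      Wf2 = ad_param(matrix(trunc_normal(hidden * channels), hidden)),
      bf2 = ad_param(numeric(channels))
    ),
    prefixed("attn", attn)
  )
  fwd <- function(x) {
    a <- attn$fwd(map_layernorm(x, params$ln1_g, params$ln1_b))
    p <- ad_silu(ad_groupnorm(ad_conv2d(x, params$Wpcm, params$bpcm),
                              params$gpcm, params$bpcm2, g))
    x1 <- ad_add(ad_add(x, a), p)
    d <- dim(ad_value(x1))
    t <- ad_reshape(ad_aperm(map_layernorm(x1, params$ln2_g, params$ln2_b),
                             c(1, 2, 4, 3)), c(d[1] * d[2] * d[4], d[3]))
    f <- ad_linear(ad_gelu(ad_linear(t, params$Wf1, params$bf1)),
                   params$Wf2, params$bf2)
    f <- ad_aperm(ad_reshape(f, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    ad_add(x1, f)
  }
  new_module(params, fwd, meta = list(channels = channels, heads = heads))
}

#' @rdname cb_forward
#' @export
nc_forward <- function(block, x) run_module(block, x)

#' Reduction cell: strided multi-dilation embedding
#'
#' Downsamples by the stage factor with three parallel strided 3x3
#' convolutions at dilations 1, 2 and 3 (a pyramid-reduction locality bias),
#' concatenates them, projects 1x1 to the stage width with group
#' normalization and SiLU, then applies a residual token-mixing perceptron.
#'
#' @param cin,cout input/output channels.
#' @param factor integer downsampling factor (input side must be divisible
#'   by it).
#' @return A module; apply with [rc_forward()].
#' @export
rc_block <- function(cin, cout, factor) {
  params <- list(
    W1 = ad_param(conv_weight(3, cin, cout)), b1 = ad_param(numeric(cout)),
    W2 = ad_param(conv_weight(3, cin, cout)), b2 = ad_param(numeric(cout)),
    W3 = ad_param(conv_weight(3, cin, cout)), b3 = ad_param(numeric(cout)),
    Wp = ad_param(conv_weight(1, 3L * cout, cout)),
    bp = ad_param(numeric(cout)),
    gamma = ad_param(rep(1, cout)), beta = ad_param(numeric(cout)),
    lng = ad_param(rep(1, cout)), lnb = ad_param(numeric(cout)),
    Wm1 = ad_param(matrix(trunc_normal(cout * cout), cout)),
    bm1 = ad_param(numeric(cout)),
    Wm2 = ad_param(matrix(trunc_normal(cout * cout), cout)),
    bm2 = ad_param(numeric(cout))
  )
  g <- gn_groups(cout)
  fwd <- function(x) {
    d <- dim(ad_value(x))
    if (d[1] %% factor != 0 || d[2] %% factor != 0) {
      stop(sprintf("input side (%d x %d) not divisible by the stage factor %d",
                   d[1], d[2], factor), call. = FALSE)
    }
    ys <- list(
      ad_conv2d(x, params$W1, params$b1, dilation = 1L, stride = factor, pad = 1L),
      ad_conv2d(x, params$W2, params$b2, dilation = 2L, stride = factor, pad = 2L),
      ad_conv2d(x, params$W3, params$b3, dilation = 3L, stride = factor, pad = 3L)
    )
    y <- ad_conv2d(ad_concat_channels(ys), params$Wp, params$bp, pad = 0L)
    y <- ad_silu(ad_groupnorm(y, params$gamma, params$beta, g))
    dd <- dim(ad_value(y))
    t <- ad_reshape(ad_aperm(map_layernorm(y, params$lng, params$lnb),
                             c(1, 2, 4, 3)), c(dd[1] * dd[2] * dd[4], dd[3]))
    m <- ad_linear(ad_gelu(ad_linear(t, params$Wm1, params$bm1)),
                   params$Wm2, params$bm2)
    m <- ad_aperm(ad_reshape(m, c(dd[1], dd[2], dd[4], dd[3])), c(1, 2, 4, 3))
    ad_add(y, m)
  }
  new_module(params, fwd, meta = list(cin = cin, cout = cout, factor = factor))
}

#' @rdname cb_forward
#' @export
rc_forward <- function(block, x) run_module(block, x)

#' Four-stage pyramid backbone (V2S)
#'
#' Builds the reduction/normal-cell stages from a model configuration and
#' returns the module whose forward pass yields the four pyramid taps at
#' strides 4, 8, 16 and 32 of the input (the tap is the output of each
#' stage's last normal cell).
#'
#' @param config a [pmffnet_config()].
#' @return A module; apply with [v2s_forward()].
#' @export
v2s_backbone <- function(config) {
  factors <- c(4L, 2L, 2L, 2L)
  params <- list()
  stages <- vector("list", 4L)
  cin <- config$in_channels
  for (st in 1:4) {
    rc <- rc_block(cin, config$widths[st], factors[st])
    ncs <- lapply(seq_len(config$depths[st]), function(i) {
      nc_block(config$widths[st], config$heads[st], config$window,
               config$ffn_ratio, config$vsa)
    })
    params <- c(params, prefixed(sprintf("stage%d.rc", st), rc))
    for (i in seq_along(ncs)) {
      params <- c(params, prefixed(sprintf("stage%d.nc%d", st, i), ncs[[i]]))
    }
    stages[[st]] <- list(rc = rc, ncs = ncs)
    cin <- config$widths[st]
  }
  fwd <- function(x) {
    d <- dim(ad_value(x))
    if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
      stop(sprintf(paste0("input side (%d x %d) must be divisible by 32; ",
                          "resize the image first"), d[1], d[2]), call. = FALSE)
    }
    taps <- vector("list", 4L)
    for (st in 1:4) {
      x <- stages[[st]]$rc$fwd(x)
      for (nc in stages[[st]]$ncs) x <- nc$fwd(x)
      taps[[st]] <- x
    }
    taps
  }
  new_module(params, fwd, meta = list(config = config))
}

#' Run the backbone and return the feature pyramid
#'
#' @param backbone a [v2s_backbone()] module (or a full model, whose backbone
#'   is used).
#' @param image (H, W, 3, N) array with H, W divisible by 32.
#' @return List of four feature arrays at strides 4/8/16/32.
#' @export
v2s_forward <- function(backbone, image) {
  if (inherits(backbone, "pmffnet_model")) backbone <- backbone$backbone
  if (is_ad(image)) return(backbone$fwd(image))
  out <- ad_no_grad(backbone$fwd(ad_const(as_feature_map(image))))
  lapply(out, ad_value)
}
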