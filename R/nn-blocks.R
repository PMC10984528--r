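# Convolutional building blocks. All 3x3 convolutions run at stride 1 with
# padding equal to their dilation, so spatial dimensions are preserved
# throughout; group normalization uses 8 groups wherever 8 divides the
# channel count.

gn_groups <- function(channels, preferred = 8L) {
  if (channels %% preferred == 0L) preferred else 1L
}

trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

conv_weight <- function(k, cin, cout) {
  # fan-in scaled (He) normal: keeps activation variance bounded through the
  # residual stacks and the narrow prediction head alike
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

new_module <- function(params, fwd, meta = list()) {
  structure(list(params = params, fwd = fwd, meta = meta),
            class = "pmff_module")
}

prefixed <- function(prefix, module) {
  stats::setNames(module$params, paste0(prefix, ".", names(module$params)))
}

#' Convolution block (CB): 3x3 conv, group norm, SiLU, residual
#'
#' The elementary unit of the MFB branches and the decoder. A 3x3 convolution
#' with the given dilation (padding preserves the spatial dims), group
#' normalization, SiLU activation, then addition of the block input; when
#' input and output channel counts differ the residual path goes through a
#' learned 1x1 projection.
#'
#' @param cin,cout input/output channel counts.
#' @param dilation dilation factor of the 3x3 convolution.
#' @param groups preferred group count for group normalization.
#' @return A module; apply it with [cb_forward()].
#' @export
cb_block <- function(cin, cout, dilation = 1L, groups = 8L) {
  g <- gn_groups(cout, groups)
  params <- list(
    W = ad_param(conv_weight(3, cin, cout)),
    b = ad_param(numeric(cout)),
    gamma = ad_param(rep(1, cout)),
    beta = ad_param(numeric(cout))
  )
  if (cin != cout) {
    params$Wp <- ad_param(conv_weight(1, cin, cout))
    params$bp <- ad_param(numeric(cout))
  }
  fwd <- function(x) {
    y <- ad_conv2d(x, params$W, params$b, dilation = dilation)
    y <- ad_groupnorm(y, params$gamma, params$beta, g)
    y <- ad_silu(y)
    res <- if (cin == cout) x else ad_conv2d(x, params$Wp, params$bp, pad = 0L)
    ad_add(y, res)
  }
  new_module(params, fwd, meta = list(cin = cin, cout = cout, dilation = dilation))
}

#' Residual block (RB): two cascaded CB blocks at dilation 1
#'
#' @inheritParams cb_block
#' @return A module; apply it with [rb_forward()].
#' @export
rb_block <- function(cin, cout, groups = 8L) {
  cb1 <- cb_block(cin, cout, 1L, groups)
  cb2 <- cb_block(cout, cout, 1L, groups)
  fwd <- function(x) cb2$fwd(cb1$fwd(x))
  new_module(c(prefixed("cb1", cb1), prefixed("cb2", cb2)), fwd,
             meta = list(cin = cin, cout = cout))
}

#' Dilated block (DB): three cascaded CB blocks with a hybrid schedule
#'
#' The dilation schedule (default 1, 2, 5) is validated against the HDC
#' design rules before construction: hard violations are an error, a
#' monotone-ramp zigzag advisory only warns.
#'
#' @inheritParams cb_block
#' @param dilations length-3 dilation schedule for the three CBs.
#' @return A module; apply it with [db_forward()].
#' @export
db_block <- function(cin, cout, dilations = c(1L, 2L, 5L), groups = 8L) {
  stopifnot(length(dilations) == 3)
  report <- hdc_rule_check(dilation_schedule(dilations))
  if (!report$passed) {
    stop("dilation schedule violates the HDC design rules: ",
         paste(report$violations, collapse = ", "), call. = FALSE)
  }
  if (report$zigzag) {
    warning("monotone dilation ramp; a zigzag pattern is recommended",
            call. = FALSE)
  }
  cbs <- list(cb_block(cin, cout, dilations[1], groups),
              cb_block(cout, cout, dilations[2], groups),
              cb_block(cout, cout, dilations[3], groups))
  fwd <- function(x) cbs[[3]]$fwd(cbs[[2]]$fwd(cbs[[1]]$fwd(x)))
  params <- c(prefixed("cb1", cbs[[1]]), prefixed("cb2", cbs[[2]]),
              prefixed("cb3", cbs[[3]]))
  new_module(params, fwd, meta = list(cin = cin, cout = cout,
                                      dilations = dilations))
}

#' Expanded-receptive-field branch (ERF): two cascaded DB blocks
#'
#' Stacks the hybrid dilation schedule twice, giving a 33-pixel receptive
#' field with no sampling holes — the global-context branch of the MFB.
#'
#' @param cin backbone channel count at this pyramid scale.
#' @param width branch width (default 64).
#' @return A module; apply it with [erf_forward()].
#' @export
erf_branch <- function(cin, width = 64L) {
  db1 <- db_block(cin, width)
  db2 <- db_block(width, width)
  fwd <- function(x) db2$fwd(db1$fwd(x))
  new_module(c(prefixed("db1", db1), prefixed("db2", db2)), fwd,
             meta = list(cin = cin, width = width))
}

#' Local-emphasis branch (LE): two cascaded RB blocks
#'
#' Four plain 3x3 convolutions (receptive field 9) that re-emphasize local
#' detail against the attention dispersion of deep transformer features.
#'
#' @inheritParams erf_branch
#' @return A module; apply it with [le_forward()].
#' @export
le_branch <- function(cin, width = 64L) {
  rb1 <- rb_block(cin, width)
  rb2 <- rb_block(width, width)
  fwd <- function(x) rb2$fwd(rb1$fwd(x))
  new_module(c(prefixed("rb1", rb1), prefixed("rb2", rb2)), fwd,
             meta = list(cin = cin, width = width))
}

#' Multi-scale feature fusion block (MFB)
#'
#' Runs the ERF and LE branches in parallel on one pyramid level,
#' concatenates their outputs channel-wise (2 x width) and fuses them with
#' two RB blocks back down to `width` channels, which the decoder's
#' concatenation arithmetic requires at every scale.
#'
#' @inheritParams erf_branch
#' @return A module; apply it with [mfb_forward()].
#' @export
mfb_block <- function(cin, width = 64L) {
  erf <- erf_branch(cin, width)
  le <- le_branch(cin, width)
  fuse1 <- rb_block(2L * width, width)
  fuse2 <- rb_block(width, width)
  fwd <- function(x) {
    both <- ad_concat_channels(list(erf$fwd(x), le$fwd(x)))
    fuse2$fwd(fuse1$fwd(both))
  }
  new_module(c(prefixed("erf", erf), prefixed("le", le),
               prefixed("fuse1", fuse1), prefixed("fuse2", fuse2)),
             fwd, meta = list(cin = cin, width = width))
}

# shared functional wrapper: plain arrays in, plain arrays out; ad nodes pass
# through untouched so the blocks compose inside the training graph
run_module <- function(module, x) {
  if (is_ad(x)) return(module$fwd(x))
  ad_value(ad_no_grad(module$fwd(ad_const(as_feature_map(x)))))
}

as_feature_map <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  x
}

#' Apply a convolutional block to a feature map
#'
#' Functional wrappers around the block modules: arrays of shape
#' (H, W, C, N) (or (H, W, C), treated as batch 1) go in and come out;
#' autodiff nodes pass through so the same blocks compose inside the
#' training graph.
#'
#' @param block a module built by [cb_block()], [rb_block()], [db_block()],
#'   [erf_branch()], [le_branch()] or [mfb_block()].
#' @param x feature array (H, W, C, N).
#' @return Output feature array of identical spatial dims.
#' @export
cb_forward <- function(block, x) run_module(block, x)

#' @rdname cb_forward
#' @export
rb_forward <- function(block, x) run_module(block, x)

#' @rdname cb_forward
#' @export
db_forward <- function(block, x) run_module(block, x)

#' @rdname cb_forward
#' @export
erf_forward <- function(block, x) run_module(block, x)

#' @rdname cb_forward
#' @export
le_forward <- function(block, x) run_module(block, x)

#' @rdname cb_forward
#' @export
mfb_forward <- function(block, x) run_module(block, x)

#' Number of trainable scalar parameters of a module or model
#'
#' @param x a block module or a full model.
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(x) {
  sum(vapply(x$params, function(p) length(p$v), numeric(1)))
}
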