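#' @title Separable image resizing
#' @description Bilinear resizing is expressed as two interpolation matrices
#'   (`out = A_h X t(A_w)`), the half-pixel-center convention (no corner
#'   alignment). The same matrices back the network's decoder upsampling, so
#'   their transposes give the exact adjoint for gradients.
#' @name resize
NULL

interp_matrix_cache <- new.env(parent = emptyenv())

#' Bilinear interpolation matrix
#'
#' Maps a length-`n_in` signal to length `n_out` using half-pixel centers:
#' output index i samples input coordinate `(i + 0.5) * n_in / n_out - 0.5`,
#' clamped to the valid range. Cached per (n_in, n_out) pair.
#'
#' @param n_in,n_out input/output lengths.
#' @return `n_out` x `n_in` dense matrix with rows summing to 1.
#' @keywords internal
bilinear_matrix <- function(n_in, n_out) {
  key <- paste0(n_in, "x", n_out)
  hit <- interp_matrix_cache[[key]]
  if (!is.null(hit)) return(hit)
  pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
  pos <- pmin(pmax(pos, 0), n_in - 1)
  lo <- floor(pos)
  frac <- pos - lo
  hi <- pmin(lo + 1, n_in - 1)
  m <- matrix(0, n_out, n_in)
  idx <- seq_len(n_out)
  m[cbind(idx, lo + 1)] <- m[cbind(idx, lo + 1)] + (1 - frac)
  m[cbind(idx, hi + 1)] <- m[cbind(idx, hi + 1)] + frac
  interp_matrix_cache[[key]] <- m
  m
}

nearest_index <- function(n_in, n_out) {
  pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
  pmin(pmax(round(pos), 0), n_in - 1) + 1
}

#' Resize a 2-D plane or H x W x C image bilinearly
#'
#' @param x matrix or 3-axis array (height, width, channels).
#' @param h,w target height and width.
#' @return Resized array of the same rank.
#' @export
resize_bilinear <- function(x, h, w) {
  if (is.matrix(x)) {
    ah <- bilinear_matrix(nrow(x), h)
    aw <- bilinear_matrix(ncol(x), w)
    return(ah %*% x %*% t(aw))
  }
  stopifnot(length(dim(x)) == 3)
  ah <- bilinear_matrix(dim(x)[1], h)
  aw <- bilinear_matrix(dim(x)[2], w)
  out <- array(0, c(h, w, dim(x)[3]))
  for (ch in seq_len(dim(x)[3])) out[, , ch] <- ah %*% x[, , ch] %*% t(aw)
  out
}

#' Resize with nearest-neighbour sampling (mask-safe)
#'
#' Keeps binary masks binary: every output value is an input value.
#'
#' @inheritParams resize_bilinear
#' @export
resize_nearest <- function(x, h, w) {
  ri <- nearest_index(if (is.matrix(x)) nrow(x) else dim(x)[1], h)
  ci <- nearest_index(if (is.matrix(x)) ncol(x) else dim(x)[2], w)
  if (is.matrix(x)) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}
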