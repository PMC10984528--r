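# Differentiable operations for the autodiff engine. Each op computes its
# forward value eagerly and registers a backward closure that maps the output
# gradient to the parents' gradients via accum_grad().

# ---- elementwise arithmetic -------------------------------------------------

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  new_ad(a$v + b$v, list(a, b), function(g) {
    accum_grad(a, if (length(a$v) == 1) sum(g) else g)
    accum_grad(b, if (length(b$v) == 1) sum(g) else g)
  })
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  new_ad(a$v - b$v, list(a, b), function(g) {
    accum_grad(a, if (length(a$v) == 1) sum(g) else g)
    accum_grad(b, if (length(b$v) == 1) -sum(g) else -g)
  })
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$v; bv <- b$v
  new_ad(av * bv, list(a, b), function(g) {
    accum_grad(a, if (length(av) == 1) sum(g * bv) else g * bv)
    accum_grad(b, if (length(bv) == 1) sum(g * av) else g * av)
  })
}

ad_div <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$v; bv <- b$v
  new_ad(av / bv, list(a, b), function(g) {
    accum_grad(a, if (length(av) == 1) sum(g / bv) else g / bv)
    gb <- -g * av / bv^2
    accum_grad(b, if (length(bv) == 1) sum(gb) else gb)
  })
}

ad_sum <- function(x) {
  x <- as_ad(x)
  shape <- dim(x$v) %||% length(x$v)
  new_ad(sum(x$v), list(x), function(g) {
    accum_grad(x, array(g, shape))
  })
}

ad_mean <- function(x) {
  x <- as_ad(x)
  n <- length(x$v)
  shape <- dim(x$v) %||% n
  new_ad(mean(x$v), list(x), function(g) {
    accum_grad(x, array(g / n, shape))
  })
}

# ---- activations ------------------------------------------------------------

ad_sigmoid <- function(x) {
  x <- as_ad(x)
  s <- 1 / (1 + exp(-x$v))
  new_ad(s, list(x), function(g) accum_grad(x, g * s * (1 - s)))
}

ad_silu <- function(x) {
  x <- as_ad(x)
  s <- 1 / (1 + exp(-x$v))
  new_ad(x$v * s, list(x), function(g) {
    accum_grad(x, g * (s + x$v * s * (1 - s)))
  })
}

ad_gelu <- function(x) {
  x <- as_ad(x)
  ph <- stats::pnorm(x$v)
  new_ad(x$v * ph, list(x), function(g) {
    accum_grad(x, g * (ph + x$v * stats::dnorm(x$v)))
  })
}

ad_exp <- function(x) {
  x <- as_ad(x)
  e <- exp(x$v)
  new_ad(e, list(x), function(g) accum_grad(x, g * e))
}

ad_clamp <- function(x, lo, hi) {
  x <- as_ad(x)
  inside <- x$v >= lo & x$v <= hi
  new_ad(pmin(pmax(x$v, lo), hi), list(x), function(g) {
    accum_grad(x, g * inside)
  })
}

# ---- linear algebra ---------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$v; bv <- b$v
  new_ad(av %*% bv, list(a, b), function(g) {
    accum_grad(a, g %*% t(bv))
    accum_grad(b, t(av) %*% g)
  })
}

# x: (n, din); W: (din, dout); b: length dout or NULL
ad_linear <- function(x, w, b = NULL) {
  x <- as_ad(x); w <- as_ad(w)
  xv <- x$v; wv <- w$v
  y <- xv %*% wv
  if (!is.null(b)) {
    b <- as_ad(b)
    y <- y + rep(b$v, each = nrow(y))
    new_ad(y, list(x, w, b), function(g) {
      accum_grad(x, g %*% t(wv))
      accum_grad(w, crossprod(xv, g))
      accum_grad(b, colSums(g))
    })
  } else {
    new_ad(y, list(x, w), function(g) {
      accum_grad(x, g %*% t(wv))
      accum_grad(w, crossprod(xv, g))
    })
  }
}

# batched matmul on (m, k, B) arrays with optional transposes
ad_bmm <- function(a, b, ta = FALSE, tb = FALSE) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$v; bv <- b$v
  y <- cpp_bmm(av, dim(av), bv, dim(bv), ta, tb)
  new_ad(y, list(a, b), function(g) {
    # d(A op B): piecewise by transpose flags
    if (!ta && !tb) {
      accum_grad(a, cpp_bmm(g, dim(g), bv, dim(bv), FALSE, TRUE))
      accum_grad(b, cpp_bmm(av, dim(av), g, dim(g), TRUE, FALSE))
    } else if (!ta && tb) {
      accum_grad(a, cpp_bmm(g, dim(g), bv, dim(bv), FALSE, FALSE))
      accum_grad(b, cpp_bmm(g, dim(g), av, dim(av), TRUE, FALSE))
    } else if (ta && !tb) {
      accum_grad(a, cpp_bmm(bv, dim(bv), g, dim(g), FALSE, TRUE))
      accum_grad(b, cpp_bmm(av, dim(av), g, dim(g), FALSE, FALSE))
    } else {
      # y = A^T B^T: dA = B^T g^T, dB = g^T A^T
      accum_grad(a, cpp_bmm(bv, dim(bv), g, dim(g), TRUE, TRUE))
      accum_grad(b, cpp_bmm(g, dim(g), av, dim(av), TRUE, TRUE))
    }
  })
}

# ---- convolution ------------------------------------------------------------

# x: (H, W, C, N); w: (K, K, Cin, Cout); 3x3 convs use pad = dilation so the
# spatial dims are preserved at stride 1.
ad_conv2d <- function(x, w, b = NULL, dilation = 1L, stride = 1L, pad = NULL) {
  x <- as_ad(x); w <- as_ad(w)
  if (!is.null(b)) b <- as_ad(b)
  xv <- x$v; wv <- w$v
  k <- dim(wv)[1]
  if (is.null(pad)) pad <- as.integer(dilation * (k - 1) / 2)
  if (dim(xv)[3] != dim(wv)[3]) {
    stop(sprintf("conv2d: input has %d channels, weights expect %d",
                 dim(xv)[3], dim(wv)[3]), call. = FALSE)
  }
  y <- cpp_conv2d_forward(xv, dim(xv), wv, dim(wv),
                          if (is.null(b)) numeric(0) else b$v,
                          as.integer(dilation), as.integer(stride),
                          as.integer(pad))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_ad(y, parents, function(g) {
    gr <- cpp_conv2d_backward(xv, dim(xv), wv, dim(wv), g,
                              as.integer(dilation), as.integer(stride),
                              as.integer(pad), !is.null(b))
    accum_grad(x, gr$dx)
    accum_grad(w, gr$dw)
    if (!is.null(b)) accum_grad(b, gr$db)
  })
}

# ---- shape ops --------------------------------------------------------------

ad_reshape <- function(x, dims) {
  x <- as_ad(x)
  old <- dim(x$v) %||% length(x$v)
  v <- x$v
  dim(v) <- dims
  new_ad(v, list(x), function(g) {
    dim(g) <- old
    accum_grad(x, g)
  })
}

ad_aperm <- function(x, perm) {
  x <- as_ad(x)
  inv <- order(perm)
  new_ad(aperm(x$v, perm), list(x), function(g) {
    accum_grad(x, aperm(g, inv))
  })
}

# concatenate (H, W, C_i, N) arrays along the channel axis
ad_concat_channels <- function(xs) {
  xs <- lapply(xs, as_ad)
  vals <- lapply(xs, `[[`, "v")
  d1 <- dim(vals[[1]])
  chans <- vapply(vals, function(v) dim(v)[3], integer(1))
  out <- array(0, c(d1[1], d1[2], sum(chans), d1[4]))
  at <- 0L
  for (v in vals) {
    out[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  new_ad(out, xs, function(g) {
    at <- 0L
    for (xi in xs) {
      ci <- dim(xi$v)[3]
      accum_grad(xi, g[, , at + seq_len(ci), , drop = FALSE])
      at <- at + ci
    }
  })
}

ad_slice_channels <- function(x, from, to) {
  x <- as_ad(x)
  d <- dim(x$v)
  new_ad(x$v[, , from:to, , drop = FALSE], list(x), function(g) {
    full <- array(0, d)
    full[, , from:to, ] <- g
    accum_grad(x, full)
  })
}

# zero-pad the bottom/right of the spatial dims to (ph, pw)
ad_pad_hw <- function(x, ph, pw) {
  x <- as_ad(x)
  d <- dim(x$v)
  if (ph == d[1] && pw == d[2]) return(x)
  out <- array(0, c(ph, pw, d[3], d[4]))
  out[seq_len(d[1]), seq_len(d[2]), , ] <- x$v
  new_ad(out, list(x), function(g) {
    accum_grad(x, g[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE])
  })
}

ad_crop_hw <- function(x, h, w) {
  x <- as_ad(x)
  d <- dim(x$v)
  if (h == d[1] && w == d[2]) return(x)
  new_ad(x$v[seq_len(h), seq_len(w), , , drop = FALSE], list(x), function(g) {
    full <- array(0, d)
    full[seq_len(h), seq_len(w), , ] <- g
    accum_grad(x, full)
  })
}

ad_cols <- function(x, idx) {
  x <- as_ad(x)
  d <- dim(x$v)
  new_ad(x$v[, idx, drop = FALSE], list(x), function(g) {
    full <- matrix(0, d[1], d[2])
    full[, idx] <- g
    accum_grad(x, full)
  })
}

ad_cbind <- function(xs) {
  xs <- lapply(xs, as_ad)
  widths <- vapply(xs, function(x) ncol(x$v), integer(1))
  out <- do.call(cbind, lapply(xs, `[[`, "v"))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  new_ad(out, xs, function(g) {
    for (i in seq_along(xs)) {
      accum_grad(xs[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

# one sample of an (H, W, C, N) batch, keeping the batch axis
ad_slice_sample <- function(x, n) {
  x <- as_ad(x)
  d <- dim(x$v)
  new_ad(x$v[, , , n, drop = FALSE], list(x), function(g) {
    full <- array(0, d)
    full[, , , n] <- g
    accum_grad(x, full)
  })
}

# stack single-sample (H, W, C, 1) arrays back into a batch
ad_stack_samples <- function(xs) {
  xs <- lapply(xs, as_ad)
  d1 <- dim(xs[[1]]$v)
  out <- array(0, c(d1[1], d1[2], d1[3], length(xs)))
  for (i in seq_along(xs)) out[, , , i] <- xs[[i]]$v
  new_ad(out, xs, function(g) {
    for (i in seq_along(xs)) {
      accum_grad(xs[[i]], g[, , , i, drop = FALSE])
    }
  })
}

# ---- resampling -------------------------------------------------------------

# bilinear resize of (H, W, C, N) to (oh, ow); the adjoint is the transposed
# interpolation, applied through two GEMMs
ad_upsample_bilinear <- function(x, oh, ow) {
  x <- as_ad(x)
  d <- dim(x$v)
  if (oh == d[1] && ow == d[2]) return(x)
  ah <- bilinear_matrix(d[1], oh)
  aw <- bilinear_matrix(d[2], ow)
  fwd <- function(v, m1, m2) {
    dd <- dim(v)
    y1 <- m1 %*% matrix(v, dd[1], prod(dd[-1]))         # (oh, W*C*N)
    dim(y1) <- c(nrow(m1), dd[2], dd[3], dd[4])
    y1 <- aperm(y1, c(2, 1, 3, 4))                       # (W, oh, C, N)
    y2 <- m2 %*% matrix(y1, dd[2], prod(dim(y1)[-1]))    # (ow, oh*C*N)
    dim(y2) <- c(nrow(m2), nrow(m1), dd[3], dd[4])
    aperm(y2, c(2, 1, 3, 4))
  }
  y <- fwd(x$v, ah, aw)
  new_ad(y, list(x), function(g) {
    accum_grad(x, fwd(g, t(ah), t(aw)))
  })
}

# ---- normalization ----------------------------------------------------------

# group normalization over (H, W, C, N); channels are grouped contiguously
ad_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  d <- dim(x$v)
  h <- d[1]; w <- d[2]; cc <- d[3]; n <- d[4]
  if (cc %% groups != 0) stop("groups must divide channels", call. = FALSE)
  m <- h * w * (cc / groups)
  xm <- matrix(x$v, m, groups * n)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = m)
  va <- colMeans(xc^2)
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(inv_sd, each = m)
  garr <- rep(rep(gamma$v, each = h * w), times = n)
  barr <- rep(rep(beta$v, each = h * w), times = n)
  y <- xhat
  dim(y) <- NULL
  y <- y * garr + barr
  dim(y) <- d
  new_ad(y, list(x, gamma, beta), function(g) {
    gv <- as.numeric(g)
    dxhat <- matrix(gv * garr, m, groups * n)
    t1 <- colMeans(dxhat)
    t2 <- colMeans(dxhat * xhat)
    dx <- (dxhat - xhat * rep(t2, each = m) - rep(t1, each = m)) *
      rep(inv_sd, each = m)
    dim(dx) <- d
    accum_grad(x, dx)
    # channel reductions for the affine parameters
    xh <- xhat; dim(xh) <- NULL
    prod_g <- matrix(gv * xh, h * w, cc * n)
    dgamma <- rowSums(matrix(colSums(prod_g), cc, n))
    dbeta <- rowSums(matrix(colSums(matrix(gv, h * w, cc * n)), cc, n))
    accum_grad(gamma, dgamma)
    accum_grad(beta, dbeta)
  })
}

# layer normalization over the last axis of a (tokens, C) matrix
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  xv <- x$v
  cc <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- xc * inv_sd
  nr <- nrow(xv)
  y <- xhat * rep(gamma$v, each = nr) + rep(beta$v, each = nr)
  new_ad(y, list(x, gamma, beta), function(g) {
    dxhat <- g * rep(gamma$v, each = nr)
    t1 <- rowMeans(dxhat)
    t2 <- rowMeans(dxhat * xhat)
    dx <- (dxhat - t1 - xhat * t2) * inv_sd
    accum_grad(x, dx)
    accum_grad(gamma, colSums(g * xhat))
    accum_grad(beta, colSums(g))
  })
}

# row-wise softmax of a matrix (any stack of rows)
ad_softmax_rows <- function(x) {
  x <- as_ad(x)
  v <- x$v
  v <- v - apply(v, 1, max)
  e <- exp(v)
  y <- e / rowSums(e)
  new_ad(y, list(x), function(g) {
    accum_grad(x, y * (g - rowSums(g * y)))
  })
}

# mean over the middle axis of an (A, T, C) array -> (A, C)
ad_tokmean <- function(x) {
  x <- as_ad(x)
  d <- dim(x$v)
  t1 <- aperm(x$v, c(2, 1, 3))
  y <- matrix(colMeans(matrix(t1, d[2], d[1] * d[3])), d[1], d[3])
  new_ad(y, list(x), function(g) {
    spread <- array(rep(g / d[2], each = d[2]), c(d[2], d[1], d[3]))
    accum_grad(x, aperm(spread, c(2, 1, 3)))
  })
}

# per-sample spatial sums of an (H, W, C, N) array -> length-N vector (1 x N)
ad_sum_per_sample <- function(x) {
  x <- as_ad(x)
  d <- dim(x$v)
  y <- matrix(colSums(matrix(x$v, prod(d[1:3]), d[4])), 1, d[4])
  new_ad(y, list(x), function(g) {
    accum_grad(x, array(rep(as.numeric(g), each = prod(d[1:3])), d))
  })
}

# ---- losses -----------------------------------------------------------------

# numerically stable binary cross-entropy on logits; target is a plain array
ad_bce_logits <- function(logits, target) {
  logits <- as_ad(logits)
  z <- logits$v
  t <- as.numeric(target)
  val <- mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
  n <- length(z)
  shape <- dim(z)
  new_ad(val, list(logits), function(g) {
    s <- 1 / (1 + exp(-z))
    dz <- g * (s - t) / n
    dim(dz) <- shape
    accum_grad(logits, dz)
  })
}

# soft Dice loss, computed per sample then averaged over the batch
ad_dice_loss <- function(probs, target, smooth = 1) {
  probs <- as_ad(probs)
  inter <- ad_sum_per_sample(ad_mul(probs, target))
  psum <- ad_sum_per_sample(probs)
  tsum <- matrix(colSums(matrix(as.numeric(target), ncol = dim(probs$v)[4])), 1)
  num <- ad_add(ad_mul(inter, 2), smooth)
  den <- ad_add(ad_add(psum, tsum), smooth)
  ad_sub(1, ad_mean(ad_div(num, den)))
}

# compound training loss on logits: BCE + Dice
ad_total_loss <- function(logits, target, smooth = 1) {
  ad_add(ad_bce_logits(logits, target),
         ad_dice_loss(ad_sigmoid(logits), target, smooth))
}

# ---- sampling ---------------------------------------------------------------

# bilinear gather from a token plane. plane: (Hp*Wp, C) with rows ordered
# h-fastest (token (h, w) at row h + Hp * w + 1); py/px: 0-based fractional
# row/col coordinates (ad nodes or plain vectors), already clamped to the
# plane extent. Returns (P, C).
ad_bilin_sample <- function(plane, py, px, hp, wp) {
  plane <- as_ad(plane); py <- as_ad(py); px <- as_ad(px)
  pv <- plane$v
  yv <- as.numeric(py$v); xv <- as.numeric(px$v)
  y0 <- floor(yv); x0 <- floor(xv)
  fy <- yv - y0; fx <- xv - x0
  y1 <- pmin(y0 + 1, hp - 1); x1 <- pmin(x0 + 1, wp - 1)
  i00 <- y0 + hp * x0 + 1; i01 <- y0 + hp * x1 + 1
  i10 <- y1 + hp * x0 + 1; i11 <- y1 + hp * x1 + 1
  w00 <- (1 - fy) * (1 - fx); w01 <- (1 - fy) * fx
  w10 <- fy * (1 - fx); w11 <- fy * fx
  val <- pv[i00, , drop = FALSE] * w00 + pv[i01, , drop = FALSE] * w01 +
    pv[i10, , drop = FALSE] * w10 + pv[i11, , drop = FALSE] * w11
  new_ad(val, list(plane, py, px), function(g) {
    if (plane$rg) {
      stacked <- rbind(g * w00, g * w01, g * w10, g * w11)
      rs <- rowsum(stacked, c(i00, i01, i10, i11))
      dp <- matrix(0, nrow(pv), ncol(pv))
      dp[as.integer(rownames(rs)), ] <- rs
      accum_grad(plane, dp)
    }
    if (py$rg || px$rg) {
      dgy <- rowSums(g * ((1 - fx) * (pv[i10, , drop = FALSE] - pv[i00, , drop = FALSE]) +
                            fx * (pv[i11, , drop = FALSE] - pv[i01, , drop = FALSE])))
      dgx <- rowSums(g * ((1 - fy) * (pv[i01, , drop = FALSE] - pv[i00, , drop = FALSE]) +
                            fy * (pv[i11, , drop = FALSE] - pv[i10, , drop = FALSE])))
      accum_grad(py, dgy)
      accum_grad(px, dgx)
    }
  })
}

# relative-position bias looked up by (possibly fractional) offsets.
# tab: (L, L) parameter with L = 2 * w0 - 1; dy/dx: plain numeric matrices of
# row/col offsets in [-(w0 - 1), w0 - 1]. Offsets are treated as constants
# (no gradient flows into the window-regression head through the bias).
ad_bias_interp <- function(tab, dy, dx, w0) {
  tab <- as_ad(tab)
  l <- 2 * w0 - 1
  r <- pmin(pmax(as.numeric(dy) + w0 - 1, 0), l - 1)
  c <- pmin(pmax(as.numeric(dx) + w0 - 1, 0), l - 1)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, l - 1); c1 <- pmin(c0 + 1, l - 1)
  i00 <- r0 + l * c0 + 1; i01 <- r0 + l * c1 + 1
  i10 <- r1 + l * c0 + 1; i11 <- r1 + l * c1 + 1
  tv <- as.numeric(tab$v)
  w00 <- (1 - fr) * (1 - fc); w01 <- (1 - fr) * fc
  w10 <- fr * (1 - fc); w11 <- fr * fc
  val <- tv[i00] * w00 + tv[i01] * w01 + tv[i10] * w10 + tv[i11] * w11
  dim(val) <- dim(dy)
  new_ad(val, list(tab), function(g) {
    gv <- as.numeric(g)
    contrib <- c(gv * w00, gv * w01, gv * w10, gv * w11)
    rs <- rowsum(contrib, c(i00, i01, i10, i11))
    dt <- numeric(l * l)
    dt[as.integer(rownames(rs))] <- rs
    dim(dt) <- c(l, l)
    accum_grad(tab, dt)
  })
}
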