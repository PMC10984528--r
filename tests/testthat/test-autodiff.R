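# Correctness of the reverse-mode engine: forward values against independent
# oracles and gradients against central differences.

test_that("convolution forward matches a direct-loop oracle", {
  ad_conv2d <- adx("ad_conv2d")
  ad_const <- adx("ad_const")
  ad_value <- adx("ad_value")
  # naive dilated convolution, looped over every tap
  conv_oracle <- function(x, w, b, dilation, stride, pad) {
    k <- dim(w)[1]; H <- dim(x)[1]; W <- dim(x)[2]
    cin <- dim(x)[3]; cout <- dim(w)[4]; n <- dim(x)[4]
    ho <- (H + 2 * pad - dilation * (k - 1) - 1) %/% stride + 1
    wo <- (W + 2 * pad - dilation * (k - 1) - 1) %/% stride + 1
    y <- array(0, c(ho, wo, cout, n))
    for (ni in 1:n) for (o in 1:cout) for (i in 1:ho) for (j in 1:wo) {
      acc <- b[o]
      for (c in 1:cin) for (k1 in 1:k) for (k2 in 1:k) {
        hi <- (i - 1) * stride - pad + (k1 - 1) * dilation + 1
        wi <- (j - 1) * stride - pad + (k2 - 1) * dilation + 1
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
          acc <- acc + x[hi, wi, c, ni] * w[k1, k2, c, o]
        }
      }
      y[i, j, o, ni] <- acc
    }
    y
  }
  set.seed(1)
  cases <- list(list(d = 1L, s = 1L, p = 1L), list(d = 2L, s = 1L, p = 2L),
                list(d = 5L, s = 1L, p = 5L), list(d = 1L, s = 2L, p = 1L),
                list(d = 3L, s = 4L, p = 3L))
  for (cs in cases) {
    x <- rarr(12, 12, 3, 2)
    w <- rarr(3, 3, 3, 4)
    b <- rnorm(4)
    got <- ad_value(ad_conv2d(ad_const(x), ad_const(w), ad_const(b),
                              dilation = cs$d, stride = cs$s, pad = cs$p))
    expect_equal(got, conv_oracle(x, w, b, cs$d, cs$s, cs$p), tolerance = 1e-12)
  }
})

test_that("convolution gradients match central differences", {
  ad_conv2d <- adx("ad_conv2d")
  ad_sum <- adx("ad_sum")
  ad_mul <- adx("ad_mul")
  probe <- rarr(8, 8, 2, 1, seed = 3)   # fixed weighting of the output
  for (cfg in list(list(d = 1L, s = 1L), list(d = 2L, s = 1L),
                   list(d = 1L, s = 2L))) {
    set.seed(cfg$d + 10 * cfg$s)
    inputs <- list(x = rarr(8, 8, 2, 1) * 0.5,
                   w = rarr(3, 3, 2, 2) * 0.3,
                   b = rnorm(2) * 0.1)
    pr <- if (cfg$s == 1L) probe else probe[1:4, 1:4, , , drop = FALSE]
    check_grads(function(p) {
      y <- ad_conv2d(p$x, p$w, p$b, dilation = cfg$d, stride = cfg$s,
                     pad = cfg$d)
      ad_sum(ad_mul(y, pr))
    }, inputs, tol = 1e-6)
  }
})

test_that("normalization, activation and softmax gradients are exact", {
  ad_groupnorm <- adx("ad_groupnorm")
  ad_layernorm <- adx("ad_layernorm")
  ad_softmax_rows <- adx("ad_softmax_rows")
  ad_silu <- adx("ad_silu"); ad_gelu <- adx("ad_gelu")
  ad_sigmoid <- adx("ad_sigmoid")
  ad_sum <- adx("ad_sum"); ad_mul <- adx("ad_mul")

  pr4 <- rarr(5, 4, 4, 2, seed = 5)
  check_grads(function(p) {
    ad_sum(ad_mul(ad_groupnorm(p$x, p$gamma, p$beta, groups = 2L), pr4))
  }, list(x = rarr(5, 4, 4, 2, seed = 6), gamma = rnorm(4), beta = rnorm(4)),
  tol = 1e-5)

  pr2 <- rarr(6, 5, seed = 7)
  check_grads(function(p) {
    ad_sum(ad_mul(ad_layernorm(p$x, p$gamma, p$beta), pr2))
  }, list(x = rarr(6, 5, seed = 8), gamma = rnorm(5), beta = rnorm(5)),
  tol = 1e-5)

  pr3 <- rarr(4, 6, seed = 9)
  check_grads(function(p) {
    ad_sum(ad_mul(ad_softmax_rows(p$x), pr3))
  }, list(x = rarr(4, 6, seed = 10)), tol = 1e-6)

  for (act in list(ad_silu, ad_gelu, ad_sigmoid)) {
    check_grads(function(p) ad_sum(ad_mul(act(p$x), pr3)),
                list(x = rarr(4, 6, seed = 11)), tol = 1e-6)
  }
})

test_that("batched matmul values and gradients match per-slice products", {
  ad_bmm <- adx("ad_bmm")
  ad_const <- adx("ad_const")
  ad_value <- adx("ad_value")
  ad_sum <- adx("ad_sum"); ad_mul <- adx("ad_mul")
  set.seed(12)
  a <- rarr(3, 4, 5); b <- rarr(4, 2, 5)
  got <- ad_value(ad_bmm(ad_const(a), ad_const(b)))
  for (i in 1:5) expect_equal(got[, , i], a[, , i] %*% b[, , i])
  # transposed variants agree with explicit transposition
  gt <- ad_value(ad_bmm(ad_const(aperm(a, c(2, 1, 3))), ad_const(b), ta = TRUE))
  expect_equal(gt, got)
  pr <- rarr(3, 2, 5, seed = 13)
  check_grads(function(p) ad_sum(ad_mul(ad_bmm(p$a, p$b), pr)),
              list(a = a, b = b), tol = 1e-6)
  check_grads(function(p) ad_sum(ad_mul(ad_bmm(p$a, p$b, ta = TRUE, tb = TRUE),
                                        rarr(4, 4, 5, seed = 14))),
              list(a = rarr(3, 4, 5), b = rarr(4, 3, 5)), tol = 1e-6)
})

test_that("bilinear upsampling is the adjoint-consistent linear map", {
  ad_upsample_bilinear <- adx("ad_upsample_bilinear")
  ad_const <- adx("ad_const"); ad_value <- adx("ad_value")
  ad_sum <- adx("ad_sum"); ad_mul <- adx("ad_mul")
  x <- rarr(4, 6, 3, 2, seed = 15)
  up <- ad_value(ad_upsample_bilinear(ad_const(x), 8L, 12L))
  expect_identical(dim(up), c(8L, 12L, 3L, 2L))
  # against the separable reference used for image preprocessing
  expect_equal(up[, , 2, 1], resize_bilinear(x[, , 2, 1], 8, 12))
  check_grads(function(p) {
    ad_sum(ad_mul(ad_upsample_bilinear(p$x, 8L, 12L), rarr(8, 12, 3, 2, seed = 16)))
  }, list(x = x), tol = 1e-6)
})

test_that("bilinear token sampling matches direct evaluation and differentiates", {
  ad_bilin_sample <- adx("ad_bilin_sample")
  ad_const <- adx("ad_const"); ad_value <- adx("ad_value")
  ad_sum <- adx("ad_sum"); ad_mul <- adx("ad_mul")
  hp <- 5L; wp <- 4L
  set.seed(17)
  plane <- matrix(rnorm(hp * wp * 3), hp * wp, 3)
  # integer coordinates reproduce exact rows
  py <- c(0, 2, 4); px <- c(0, 1, 3)
  got <- ad_value(ad_bilin_sample(ad_const(plane), ad_const(py), ad_const(px),
                                  hp, wp))
  expect_equal(got, plane[py + hp * px + 1, ])
  # fractional coordinates: hand-computed bilinear blend
  gf <- ad_value(ad_bilin_sample(ad_const(plane), ad_const(1.5), ad_const(0.25),
                                 hp, wp))
  hand <- 0.75 * (0.5 * plane[2, ] + 0.5 * plane[3, ]) +
    0.25 * (0.5 * plane[2 + hp, ] + 0.5 * plane[3 + hp, ])
  expect_equal(as.numeric(gf), hand)
  # gradients flow to the plane and to the coordinates
  pr <- matrix(rnorm(12), 4, 3)
  check_grads(function(p) {
    ad_sum(ad_mul(ad_bilin_sample(p$plane, p$py, p$px, hp, wp), pr))
  }, list(plane = plane, py = c(0.7, 1.3, 2.6, 3.1), px = c(0.2, 1.9, 0.4, 2.2)),
  tol = 1e-5)
})

test_that("relative-bias interpolation reduces to lookup on integer offsets", {
  ad_bias_interp <- adx("ad_bias_interp")
  ad_const <- adx("ad_const"); ad_value <- adx("ad_value")
  ad_sum <- adx("ad_sum"); ad_mul <- adx("ad_mul")
  w0 <- 3L; l <- 2L * w0 - 1L
  set.seed(18)
  tab <- matrix(rnorm(l * l), l, l)
  dy <- matrix(c(-2, 0, 1, 2), 2, 2)
  dx <- matrix(c(1, -1, 0, 2), 2, 2)
  got <- ad_value(ad_bias_interp(ad_const(tab), dy, dx, w0))
  expect_equal(got, matrix(tab[cbind(as.numeric(dy) + w0, as.numeric(dx) + w0)], 2, 2))
  pr <- matrix(rnorm(4), 2, 2)
  check_grads(function(p) {
    ad_sum(ad_mul(ad_bias_interp(p$tab, dy + 0.3, dx + 0.1, w0), pr))
  }, list(tab = tab), tol = 1e-6)
})

test_that("loss ops agree with the plain-array implementations", {
  ad_bce_logits <- adx("ad_bce_logits")
  ad_dice_loss <- adx("ad_dice_loss")
  ad_total_loss <- adx("ad_total_loss")
  ad_sigmoid <- adx("ad_sigmoid")
  ad_const <- adx("ad_const"); ad_value <- adx("ad_value")
  set.seed(19)
  z <- rarr(6, 6, 1, 2)
  t <- array(rbinom(72, 1, 0.4), c(6, 6, 1, 2))
  p <- 1 / (1 + exp(-z))
  expect_equal(ad_value(ad_bce_logits(ad_const(z), t)), bce_loss(t, p),
               tolerance = 1e-10)
  # per-sample dice then batch mean
  d1 <- dice_loss(t[, , , 1], p[, , , 1])
  d2 <- dice_loss(t[, , , 2], p[, , , 2])
  expect_equal(ad_value(ad_dice_loss(ad_sigmoid(ad_const(z)), t)),
               (d1 + d2) / 2, tolerance = 1e-10)
  expect_equal(ad_value(ad_total_loss(ad_const(z), t)),
               bce_loss(t, p) + (d1 + d2) / 2, tolerance = 1e-10)
  check_grads(function(pp) ad_total_loss(pp$z, t), list(z = z), tol = 1e-5)
})

test_that("composite blocks differentiate end to end", {
  ad_sum <- adx("ad_sum"); ad_mul <- adx("ad_mul")
  set.seed(20)
  blk <- cb_block(3L, 8L, dilation = 2L)
  pr <- rarr(6, 6, 8, 1, seed = 21)
  # check input gradient and two representative parameters
  x0 <- rarr(6, 6, 3, 1, seed = 22) * 0.5
  inputs <- list(x = x0, W = blk$params$W$v, gamma = blk$params$gamma$v)
  check_grads(function(p) {
    blk$params$W <- p$W
    blk$params$gamma <- p$gamma
    ad_sum(ad_mul(blk$fwd(p$x), pr))
  }, inputs, tol = 1e-5)
})
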