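# Central-difference gradient checking against the autodiff engine.
# Internal engine functions are accessed via ::: on purpose: the ops are not
# user-facing API but their correctness underpins every trained model.

adx <- function(name) get(name, envir = asNamespace("pmffnet"))

# numeric gradient of scalar-valued f at x (plain array)
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Compare autodiff gradients of `build` (function of a named list of ad
# params returning a scalar ad node) with central differences, for every
# input in `inputs`.
check_grads <- function(build, inputs, tol = 1e-6) {
  ad_param <- adx("ad_param")
  ad_backward <- adx("ad_backward")
  ad_value <- adx("ad_value")
  nodes <- lapply(inputs, ad_param)
  loss <- build(nodes)
  ad_backward(loss)
  for (nm in names(inputs)) {
    fn <- function(xv) {
      probe <- lapply(inputs, ad_param)
      probe[[nm]] <- ad_param(xv)
      ad_value(build(probe))
    }
    ng <- num_grad(fn, inputs[[nm]])
    ag <- nodes[[nm]]$grad
    if (is.null(ag)) ag <- ng * 0
    scale <- max(1, max(abs(ng)))
    expect_lt(max(abs(ag - ng)) / scale, tol,
              label = sprintf("gradient mismatch for '%s'", nm))
  }
  invisible(ad_value(loss))
}

# deterministic random arrays
rarr <- function(..., seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- c(...)
  array(stats::rnorm(prod(d)), d)
}
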