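# Reverse-mode automatic differentiation over dense arrays.
#
# Every tensor in the network is an `ad` node: an environment holding the
# forward value, an accumulated gradient, the parent nodes and a backward
# closure mapping the node's output gradient to parent gradients. Nodes are
# numbered at creation; backpropagation visits reachable nodes in reverse
# creation order, which is a valid topological order because an op's inputs
# always exist before its output. Gradient recording can be switched off for
# inference, in which case ops compute values only and retain no graph.

.ad_state <- new.env(parent = emptyenv())
.ad_state$next_id <- 1L
.ad_state$recording <- TRUE

ad_recording <- function() .ad_state$recording

#' Evaluate an expression without building an autodiff graph
#' @param expr expression to evaluate.
#' @return The expression's value.
#' @keywords internal
ad_no_grad <- function(expr) {
  old <- .ad_state$recording
  .ad_state$recording <- FALSE
  on.exit(.ad_state$recording <- old)
  force(expr)
}

new_ad <- function(value, parents = list(), backward = NULL, param = FALSE) {
  node <- new.env(parent = emptyenv())
  node$v <- value
  node$grad <- NULL
  node$param <- param
  rg <- param || any(vapply(parents, function(p) p$rg, logical(1)))
  if (!ad_recording() && !param) rg <- FALSE
  node$rg <- rg
  if (rg && !param) {
    node$parents <- parents
    node$bw <- backward
  } else {
    node$parents <- list()
    node$bw <- NULL
  }
  node$nid <- .ad_state$next_id
  .ad_state$next_id <- .ad_state$next_id + 1L
  class(node) <- "ad"
  node
}

#' Create a trainable parameter node
#' @param value numeric array of initial values.
#' @keywords internal
ad_param <- function(value) new_ad(value, param = TRUE)

ad_const <- function(value) new_ad(value)

is_ad <- function(x) inherits(x, "ad")

#' Forward value of an autodiff node (or pass a plain array through)
#' @param x node or array.
#' @keywords internal
ad_value <- function(x) if (is_ad(x)) x$v else x

as_ad <- function(x) if (is_ad(x)) x else ad_const(x)

#' @export
print.ad <- function(x, ...) {
  d <- dim(x$v) %||% length(x$v)
  cat(sprintf("<ad tensor [%s]%s%s>\n", paste(d, collapse = "x"),
              if (x$param) " param" else "",
              if (x$rg) " grad" else ""))
  invisible(x)
}

# Accumulate `g` into a parent's gradient slot.
accum_grad <- function(node, g) {
  if (!node$rg) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node
#'
#' Seeds the loss gradient with 1, walks the reachable graph in reverse
#' creation order and leaves accumulated gradients on every parameter node's
#' `$grad`.
#'
#' @param loss an `ad` node holding a scalar.
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(is_ad(loss), length(loss$v) == 1)
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- list()
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$nid)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) if (p$rg) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$nid, integer(1)), decreasing = TRUE)
  loss$grad <- 1
  for (nd in nodes[ord]) {
    if (is.null(nd$grad) || is.null(nd$bw)) next
    nd$bw(nd$grad)
    if (!nd$param) nd$grad <- NULL  # free intermediate gradients eagerly
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
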