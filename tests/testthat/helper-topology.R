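# 4-connected component count by stack-based flood fill; independent oracle
# for lesion-topology checks on binary masks.
n_components <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  comps <- 0L
  for (start in which(mask == 1L & !seen)) {
    if (seen[start]) next
    comps <- comps + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[p] || mask[p] != 1L) next
      seen[p] <- TRUE
      r <- (p - 1L) %% nrow(mask) + 1L
      c <- (p - 1L) %/% nrow(mask) + 1L
      if (r > 1L) stack <- c(stack, p - 1L)
      if (r < nrow(mask)) stack <- c(stack, p + 1L)
      if (c > 1L) stack <- c(stack, p - nrow(mask))
      if (c < ncol(mask)) stack <- c(stack, p + nrow(mask))
    }
  }
  comps
}
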