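#' Dilation schedules for stacked dilated convolutions
#'
#' A dilation schedule describes a cascade of stride-1 dilated convolutions,
#' ordered from the layer closest to the input (bottom, layer 1) to the layer
#' producing the final output (top, layer Z). It is the object the hybrid
#' dilated convolution (HDC) design calculus operates on: the maximum-distance
#' recursion, the design-rule checker, the receptive-field accumulator and the
#' brute-force usage-count oracle all take a schedule.
#'
#' @param dilations integer vector of per-layer dilation factors, bottom to
#'   top; every entry must be >= 1.
#' @param kernel odd kernel side length(s) >= 1; either a scalar recycled to
#'   all layers or one value per layer.
#' @return An object of class `dilation_schedule`: a list with integer vectors
#'   `kernel` and `dilation` of equal length.
#' @examples
#' sched <- dilation_schedule(c(1, 2, 5))
#' hdc_max_distances(sched)
#' receptive_field(sched)
#' @export
dilation_schedule <- function(dilations, kernel = 3L) {
  if (length(dilations) == 0) {
    stop("a dilation schedule needs at least one layer", call. = FALSE)
  }
  dilations <- as.integer(dilations)
  kernel <- as.integer(kernel)
  if (length(kernel) == 1L) kernel <- rep(kernel, length(dilations))
  if (length(kernel) != length(dilations)) {
    stop("`kernel` must be a scalar or one value per layer", call. = FALSE)
  }
  if (anyNA(dilations) || any(dilations < 1L)) {
    stop("all dilation factors must be integers >= 1", call. = FALSE)
  }
  if (anyNA(kernel) || any(kernel < 1L) || any(kernel %% 2L == 0L)) {
    stop("kernel side lengths must be odd integers >= 1", call. = FALSE)
  }
  structure(list(kernel = kernel, dilation = dilations),
            class = "dilation_schedule")
}

#' @export
print.dilation_schedule <- function(x, ...) {
  cat(sprintf("<dilation schedule: %d layer%s>\n", length(x$dilation),
              if (length(x$dilation) == 1L) "" else "s"))
  cat(sprintf("  kernel:   %s\n", paste(x$kernel, collapse = ", ")))
  cat(sprintf("  dilation: %s\n", paste(x$dilation, collapse = ", ")))
  invisible(x)
}

as_schedule <- function(x) {
  if (inherits(x, "dilation_schedule")) return(x)
  dilation_schedule(x)
}

#' Maximum distance between adjacent nonzero taps, per layer
#'
#' Computes, for each layer of a cascade of dilated convolutions, the maximum
#' distance between two adjacent nonzero kernel taps as seen from the input of
#' that layer. The top layer is seeded with its own dilation,
#' `M[Z] = d[Z]`, and lower layers follow the recursion
#' `M[i] = max(M[i+1] - 2 d[i], 2 d[i] - M[i+1], d[i])`.
#' A cascade covers its receptive field without holes exactly when the
#' bottom-layer value is 1 (nonzero taps are adjacent).
#'
#' @param schedule a [dilation_schedule()] (or a bare dilation vector,
#'   coerced with kernel 3).
#' @return Integer vector `M`, one value per layer, bottom to top.
#' @examples
#' hdc_max_distances(dilation_schedule(c(1, 2, 5)))  # 1 2 5
#' hdc_max_distances(dilation_schedule(c(2, 2, 2)))  # 2 2 2
#' @export
hdc_max_distances <- function(schedule) {
  schedule <- as_schedule(schedule)
  d <- schedule$dilation
  z <- length(d)
  m <- integer(z)
  m[z] <- d[z]
  if (z > 1L) {
    for (i in seq(z - 1L, 1L)) {
      m[i] <- max(m[i + 1L] - 2L * d[i], 2L * d[i] - m[i + 1L], d[i])
    }
  }
  m
}

#' Check a dilation schedule against the HDC design rules
#'
#' Applies the hybrid-dilated-convolution design guidelines to a cascade of
#' dilated convolutions:
#' \itemize{
#'   \item the second-layer maximum tap distance must not exceed the kernel
#'     size (`max_distance_exceeds_kernel` otherwise);
#'   \item the dilation factors must not share a common divisor greater than 1
#'     (`common_divisor_gt_one`);
#'   \item a cascade that repeats one dilation factor greater than 1 suffers
#'     the gridding effect (`constant_dilation_gridding`);
#'   \item the bottom-layer maximum distance should equal 1 so that every
#'     input pixel in the receptive field is used (`m1_not_one`).
#' }
#' A long monotone non-decreasing ramp of dilations additionally raises a
#' zigzag advisory (`zigzag = TRUE`), not a failure: the canonical accepted
#' cascade 1, 2, 5 is itself monotone, so a strict zigzag requirement would
#' reject it.
#'
#' Single-layer schedules pass vacuously: the guidelines constrain cascades.
#'
#' @inheritParams hdc_max_distances
#' @return An object of class `hdc_rule_report`: list with `passed` (logical),
#'   `violations` (character vector of tags), `zigzag` advisory flag, and the
#'   computed `max_distances`.
#' @examples
#' hdc_rule_check(dilation_schedule(c(1, 2, 5)))$passed   # TRUE
#' hdc_rule_check(dilation_schedule(c(2, 2, 2)))$violations
#' @export
hdc_rule_check <- function(schedule) {
  schedule <- as_schedule(schedule)
  d <- schedule$dilation
  k <- schedule$kernel
  m <- hdc_max_distances(schedule)
  z <- length(d)
  violations <- character(0)
  zigzag <- FALSE
  if (z >= 2L) {
    if (m[2L] > k[2L]) violations <- c(violations, "max_distance_exceeds_kernel")
    if (gcd_all(d) > 1L) violations <- c(violations, "common_divisor_gt_one")
    if (length(unique(d)) == 1L && d[1L] > 1L) {
      violations <- c(violations, "constant_dilation_gridding")
    }
    if (m[1L] != 1L) violations <- c(violations, "m1_not_one")
    zigzag <- z >= 4L && !is.unsorted(d)
  }
  structure(list(passed = length(violations) == 0L,
                 violations = violations,
                 zigzag = zigzag,
                 max_distances = m),
            class = "hdc_rule_report")
}

#' @export
print.hdc_rule_report <- function(x, ...) {
  cat(sprintf("<HDC rule report: %s>\n", if (x$passed) "PASSED" else "FAILED"))
  cat(sprintf("  max distances (bottom..top): %s\n",
              paste(x$max_distances, collapse = ", ")))
  if (length(x$violations)) {
    cat("  violations:", paste(x$violations, collapse = ", "), "\n")
  }
  if (x$zigzag) {
    cat("  advisory: monotone dilation ramp; consider a zigzag pattern\n")
  }
  invisible(x)
}

gcd2 <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

gcd_all <- function(x) Reduce(gcd2, as.integer(x))

#' Receptive field of a cascade of stride-1 dilated convolutions
#'
#' Closed-form accumulator: starting from a single pixel (side 1), each layer
#' with kernel K and dilation d adds `(K - 1) * d` to the side of the input
#' region influencing one output pixel.
#'
#' @inheritParams hdc_max_distances
#' @return Side length (pixels) of the square input footprint.
#' @examples
#' receptive_field(dilation_schedule(c(1, 2)))     # 7
#' receptive_field(dilation_schedule(c(1, 2, 5)))  # 17
#' @export
receptive_field <- function(schedule) {
  schedule <- as_schedule(schedule)
  1L + sum((schedule$kernel - 1L) * schedule$dilation)
}

#' Brute-force pixel usage-count oracle
#'
#' Back-propagates kernel-tap counts from a single output pixel through every
#' layer of the cascade, on an unbounded canvas (the output pixel is taken in
#' the interior of the image, so no boundary clipping applies). The resulting
#' grid records how many times each input pixel is used to compute that one
#' output pixel; zeros strictly inside the footprint are the holes of the
#' gridding effect.
#'
#' @inheritParams hdc_max_distances
#' @param output_pixel integer length-2 coordinate (row, col) of the output
#'   pixel on the input grid; only shifts the reported origin.
#' @return An object of class `usage_count_map`: list with `counts` (an
#'   RF x RF integer matrix), `origin` (input coordinate of the top-left
#'   cell) and the `schedule`.
#' @examples
#' m <- usage_count_map(dilation_schedule(c(1, 1)))
#' m$counts[3, 3]  # 9: center of the 5x5 triangular profile
#' @export
usage_count_map <- function(schedule, output_pixel = c(0L, 0L)) {
  schedule <- as_schedule(schedule)
  output_pixel <- as.integer(output_pixel)
  stopifnot(length(output_pixel) == 2L)
  counts <- matrix(1L, 1L, 1L)
  z <- length(schedule$dilation)
  # walk top layer -> bottom layer, spreading each count over the kernel taps
  for (i in seq(z, 1L)) {
    k <- schedule$kernel[i]
    d <- schedule$dilation[i]
    half <- (k - 1L) %/% 2L
    grow <- (k - 1L) * d
    side <- nrow(counts) + grow
    nxt <- matrix(0L, side, side)
    for (a in seq(-half, half)) {
      for (b in seq(-half, half)) {
        r0 <- (a + half) * d
        c0 <- (b + half) * d
        idx_r <- seq_len(nrow(counts)) + r0
        idx_c <- seq_len(ncol(counts)) + c0
        nxt[idx_r, idx_c] <- nxt[idx_r, idx_c] + counts
      }
    }
    counts <- nxt
  }
  rf <- receptive_field(schedule)
  stopifnot(nrow(counts) == rf)
  structure(list(counts = counts,
                 origin = output_pixel - (rf - 1L) %/% 2L,
                 schedule = schedule),
            class = "usage_count_map")
}

#' @export
print.usage_count_map <- function(x, ...) {
  cat(sprintf("<usage-count map: %dx%d, origin (%d, %d), %d hole%s>\n",
              nrow(x$counts), ncol(x$counts), x$origin[1], x$origin[2],
              count_holes(x), if (count_holes(x) == 1L) "" else "s"))
  print(x$counts)
  invisible(x)
}

#' Number of holes in a usage-count map
#'
#' A hole is a zero-count cell inside the square footprint of the cascade:
#' an input pixel that never contributes to the output pixel even though it
#' lies within the receptive field.
#'
#' @param map a [usage_count_map()].
#' @return Non-negative integer count of zero cells.
#' @export
count_holes <- function(map) {
  stopifnot(inherits(map, "usage_count_map"))
  sum(map$counts == 0L)
}
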