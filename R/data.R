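#' Configuration of the synthetic speckle-phantom generator
#'
#' The generator emulates the salient structure of 2-D ovarian ultrasound
#' imagery at desk scale: a smooth low-frequency echogenic background
#' multiplied by gamma-distributed speckle (unit mean), with exactly one
#' hypoechoic lesion per image — an ellipse with a sinusoidally perturbed,
#' softly blurred boundary — and a pixel-exact binary mask of the lesion
#' interior. Image sizes vary from phantom to phantom, as they do in the real
#' archive, so the resize step of preprocessing is always exercised.
#'
#' @param image_size base image side in pixels; each phantom draws its height
#'   and width independently from `[image_size, 1.25 * image_size]`.
#' @param area_fraction length-2 range `[f_min, f_max]` of the lesion area as
#'   a fraction of the image; must satisfy `0 < f_min < f_max < 0.6`.
#' @param contrast fractional intensity drop inside the lesion (0.55 means
#'   the lesion interior is 45% as bright as the surrounding tissue).
#' @param speckle_shape shape of the unit-mean gamma speckle; variance is
#'   `1 / speckle_shape`, so smaller values mean grainier images.
#' @param boundary_amp relative amplitude of the sinusoidal boundary
#'   perturbation (0 gives exact ellipses).
#' @param seed integer seed; together with the config it fully determines the
#'   phantom.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128L,
                           area_fraction = c(0.05, 0.25),
                           contrast = 0.55,
                           speckle_shape = 4,
                           boundary_amp = 0.08,
                           seed = 1L) {
  stopifnot(image_size >= 32,
            length(area_fraction) == 2,
            area_fraction[1] > 0,
            area_fraction[1] < area_fraction[2],
            area_fraction[2] < 0.6,
            contrast > 0, contrast < 1,
            speckle_shape > 0,
            boundary_amp >= 0, boundary_amp < 0.3)
  structure(list(image_size = as.integer(image_size),
                 area_fraction = as.numeric(area_fraction),
                 contrast = contrast,
                 speckle_shape = speckle_shape,
                 boundary_amp = boundary_amp,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate one synthetic ultrasound phantom
#'
#' @param cfg a [phantom_config()].
#' @return A sample record: list with `id`, `image` (H x W x 3 integer array,
#'   0-255), `mask` (H x W 0/1 integer matrix) and `subset` (initially
#'   `"train"`), class `sample_record`.
#' @examples
#' rec <- generate_phantom(phantom_config(image_size = 64, seed = 7))
#' mean(rec$mask)  # lesion area fraction
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  h <- sample(seq(cfg$image_size, as.integer(1.25 * cfg$image_size)), 1)
  w <- sample(seq(cfg$image_size, as.integer(1.25 * cfg$image_size)), 1)

  # smooth low-frequency background: base level plus a few random plane waves
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  bg <- runif(1, 0.45, 0.6)
  for (k in 1:3) {
    freq <- runif(1, 0.5, 2) / cfg$image_size
    ang <- runif(1, 0, pi)
    phase <- runif(1, 0, 2 * pi)
    bg <- bg + runif(1, 0.02, 0.06) *
      cos(2 * pi * freq * (cos(ang) * xx + sin(ang) * yy) + phase)
  }
  bg <- pmin(pmax(bg, 0.15), 0.9)

  # one perturbed-ellipse lesion, placed so the footprint fits in the image
  f_lo <- cfg$area_fraction[1]
  f_hi <- cfg$area_fraction[2]
  f <- runif(1, f_lo + 0.1 * (f_hi - f_lo), f_hi - 0.1 * (f_hi - f_lo))
  area <- f * h * w
  aspect <- runif(1, 0.7, 1.4)
  r0 <- sqrt(area / pi)
  a <- r0 * sqrt(aspect)
  b <- r0 / sqrt(aspect)
  margin <- max(a, b) * (1 + cfg$boundary_amp) + 2
  if (2 * margin >= min(h, w)) {
    stop("lesion area fraction infeasible for this image size", call. = FALSE)
  }
  cy <- runif(1, margin, h - margin)
  cx <- runif(1, margin, w - margin)
  theta <- runif(1, 0, pi)

  u <- cos(theta) * (xx - cx) + sin(theta) * (yy - cy)
  v <- -sin(theta) * (xx - cx) + cos(theta) * (yy - cy)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  phi <- atan2(v / b, u / a)
  wobble <- 0
  if (cfg$boundary_amp > 0) {
    amps <- runif(3)
    amps <- amps / sum(amps)
    phases <- runif(3, 0, 2 * pi)
    for (j in 1:3) {
      wobble <- wobble + amps[j] * sin((j + 1) * phi + phases[j])
    }
  }
  boundary <- 1 + cfg$boundary_amp * wobble
  mask <- (rho <= boundary) * 1L

  # soft lesion border: linear ramp over ~6% of the lesion radius
  edge <- 0.06
  inside <- pmin(pmax((boundary + edge - rho) / (2 * edge), 0), 1)
  tissue <- bg * (1 - cfg$contrast * inside)

  speckle <- matrix(stats::rgamma(h * w, shape = cfg$speckle_shape,
                                  rate = cfg$speckle_shape), h, w)
  img <- pmin(pmax(tissue * speckle, 0), 1)
  img8 <- array(as.integer(round(img * 255)), c(h, w, 1))[, , c(1, 1, 1), drop = FALSE]

  structure(list(id = sprintf("phantom_%08d", cfg$seed),
                 image = img8,
                 mask = matrix(as.integer(mask), h, w),
                 subset = "train"),
            class = "sample_record")
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("<sample %s: %dx%d, lesion fraction %.3f, subset %s>\n",
              x$id, nrow(x$mask), ncol(x$mask), mean(x$mask), x$subset))
  invisible(x)
}

#' Write a corpus of phantoms in the on-disk dataset layout
#'
#' Creates `<out_root>/<subset>/images/*.png` and matching
#' `<out_root>/<subset>/masks/*.png` so that [load_dataset()] round-trips
#' them. The `shifted` flag produces a distribution-shifted variant (stronger
#' speckle, weaker lesion contrast) emulating a generalization set acquired
#' with a different protocol.
#'
#' @param n number of phantoms (>= 1).
#' @param cfg base [phantom_config()]; per-phantom seeds are derived as
#'   `cfg$seed + 1000 * i`.
#' @param out_root dataset root directory.
#' @param subset subdirectory name (`train`, `val`, `test`, `generalization`).
#' @param shifted apply the distribution shift.
#' @param force overwrite a non-empty subset directory.
#' @return Invisibly, the vector of written sample ids.
#' @export
generate_corpus <- function(n, cfg, out_root, subset = "train",
                            shifted = FALSE, force = FALSE) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (n < 1) stop("a corpus needs at least one phantom", call. = FALSE)
  img_dir <- file.path(out_root, subset, "images")
  msk_dir <- file.path(out_root, subset, "masks")
  if (dir.exists(img_dir) && length(dir(img_dir)) > 0 && !force) {
    stop("output directory is not empty; use force = TRUE to overwrite",
         call. = FALSE)
  }
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  if (shifted) {
    cfg$contrast <- cfg$contrast * 0.7
    cfg$speckle_shape <- cfg$speckle_shape / 2
  }
  ids <- character(n)
  for (i in seq_len(n)) {
    ci <- cfg
    ci$seed <- cfg$seed + 1000L * i
    rec <- generate_phantom(ci)
    ids[i] <- rec$id
    png::writePNG(rec$image / 255, file.path(img_dir, paste0(rec$id, ".png")))
    png::writePNG(rec$mask + 0, file.path(msk_dir, paste0(rec$id, ".png")))
  }
  invisible(ids)
}

#' Load an image/mask dataset from the on-disk layout
#'
#' Pairs `<root>/<subset>/images/*.png` with masks of the same filename stem.
#' Images lacking a mask (or vice versa) are skipped with a warning. Masks are
#' binarized by thresholding 8-bit values at 127, which tolerates interpolated
#' grey pixels in stored masks. An optional `classes.csv` manifest
#' (columns `id`, `category`) at the dataset root enables exclusion of normal
#' ovary samples, which carry no lesion to segment.
#'
#' @param root dataset root directory.
#' @param subset subdirectory to read.
#' @param exclude_normal drop samples whose manifest category contains
#'   "normal" (case-insensitive); only applies when a manifest is present.
#' @return List of `sample_record`s.
#' @export
load_dataset <- function(root, subset = "train", exclude_normal = TRUE) {
  img_dir <- file.path(root, subset, "images")
  msk_dir <- file.path(root, subset, "masks")
  if (!dir.exists(img_dir)) stop("no images directory under ", img_dir, call. = FALSE)
  stems <- sub("\\.png$", "", dir(img_dir, pattern = "\\.png$"))
  mask_stems <- sub("\\.png$", "", dir(msk_dir, pattern = "\\.png$"))
  for (s in setdiff(stems, mask_stems)) {
    warning("image without mask skipped: ", s, call. = FALSE)
  }
  for (s in setdiff(mask_stems, stems)) {
    warning("mask without image skipped: ", s, call. = FALSE)
  }
  stems <- intersect(stems, mask_stems)

  manifest <- file.path(root, "classes.csv")
  if (exclude_normal && file.exists(manifest)) {
    cls <- utils::read.csv(manifest, colClasses = "character")
    normal <- cls$id[grepl("normal", cls$category, ignore.case = TRUE)]
    stems <- setdiff(stems, normal)
  }
  if (length(stems) == 0) stop("no paired image/mask samples found", call. = FALSE)

  lapply(stems, function(s) {
    img <- png::readPNG(file.path(img_dir, paste0(s, ".png")))
    if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1))
    if (dim(img)[3] == 1) img <- img[, , c(1, 1, 1), drop = FALSE]
    if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
    msk <- png::readPNG(file.path(msk_dir, paste0(s, ".png")))
    if (length(dim(msk)) == 3) msk <- msk[, , 1]
    structure(list(id = s,
                   image = array(as.integer(round(img * 255)), dim(img)),
                   mask = matrix(as.integer(msk * 255 > 127),
                                 nrow(msk), ncol(msk)),
                   subset = subset),
              class = "sample_record")
  })
}

#' Default per-channel normalization statistics
#'
#' Mean/sd of the pixel intensities of a list of records, computed once per
#' corpus and reused for every split; [preprocess()] falls back to a neutral
#' (0.5, 0.25) pair when no corpus statistics are supplied.
#'
#' @param records list of `sample_record`s.
#' @return List with numeric length-3 `mean` and `sd`.
#' @export
corpus_stats <- function(records) {
  stopifnot(length(records) > 0)
  sums <- numeric(3); sqs <- numeric(3); n <- 0
  for (r in records) {
    x <- r$image / 255
    for (ch in 1:3) {
      sums[ch] <- sums[ch] + sum(x[, , ch])
      sqs[ch] <- sqs[ch] + sum(x[, , ch]^2)
    }
    n <- n + length(x[, , 1])
  }
  m <- sums / n
  list(mean = m, sd = sqrt(pmax(sqs / n - m^2, 1e-12)))
}

#' Preprocess one record into network tensors
#'
#' Resizes the image bilinearly to `side x side`, scales it to [0, 1] and
#' standardizes per channel; the mask is resized with nearest-neighbour
#' sampling so it stays strictly binary.
#'
#' @param rec a `sample_record`.
#' @param side target side length (the network requires a multiple of 32).
#' @param stats optional list(mean, sd) from [corpus_stats()]; defaults to
#'   mean 0.5, sd 0.25 per channel.
#' @return List with `image` (side x side x 3 numeric array) and `mask`
#'   (side x side 0/1 matrix).
#' @export
preprocess <- function(rec, side = 384L, stats = NULL) {
  stopifnot(inherits(rec, "sample_record"))
  if (is.null(stats)) stats <- list(mean = rep(0.5, 3), sd = rep(0.25, 3))
  img <- resize_bilinear(rec$image / 255, side, side)
  for (ch in 1:3) img[, , ch] <- (img[, , ch] - stats$mean[ch]) / stats$sd[ch]
  msk <- resize_nearest(rec$mask, side, side)
  if (!all(msk %in% c(0L, 1L))) {
    stop("mask lost binarity during resize", call. = FALSE)
  }
  list(image = img, mask = msk)
}

#' Paired flip augmentation
#'
#' Applies an independent 50% horizontal and 50% vertical flip, identically
#' to image and mask. Randomness comes from the session RNG, so seeding the
#' session makes augmentation reproducible.
#'
#' @param image H x W x C array.
#' @param mask H x W matrix.
#' @return List with flipped `image`, `mask` and the logical `flips` applied.
#' @export
augment <- function(image, mask) {
  do_h <- stats::runif(1) < 0.5
  do_v <- stats::runif(1) < 0.5
  if (do_h) {
    image <- image[, rev(seq_len(ncol(mask))), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (do_v) {
    image <- image[rev(seq_len(nrow(mask))), , , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  }
  list(image = image, mask = mask, flips = c(horizontal = do_h, vertical = do_v))
}

#' Seeded train/validation split
#'
#' Shuffles the records with the given seed, then assigns the first
#' `round(fraction * n)` to training and the remainder to validation; the two
#' parts are disjoint and exhaustive.
#'
#' @param records list of records.
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed for the shuffle.
#' @return List with `train` and `val` record lists.
#' @export
split_train_val <- function(records, fraction = 0.8, seed = 1L) {
  n <- length(records)
  if (n < 2) stop("need at least two records to split", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- round(fraction * n)
  train <- records[perm[seq_len(n_train)]]
  val <- records[perm[seq(n_train + 1L, n)]]
  train <- lapply(train, function(r) { r$subset <- "train"; r })
  val <- lapply(val, function(r) { r$subset <- "val"; r })
  list(train = train, val = val)
}
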