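cfg64 <- phantom_config(image_size = 64, seed = 123)

test_that("phantom generation is deterministic and respects its envelope", {
  a <- generate_phantom(cfg64)
  b <- generate_phantom(cfg64)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(dim(a$image)[1:2], dim(a$mask))
  expect_true(all(a$mask %in% c(0L, 1L)))
  expect_true(all(a$image >= 0L & a$image <= 255L))
  # side lengths vary within [base, 1.25 base]
  expect_true(all(dim(a$mask) >= 64 & dim(a$mask) <= 80))
})

test_that("lesion area and hypoechoic contrast hold across 100 seeded draws", {
  darker <- 0L
  for (s in 1:100) {
    rec <- generate_phantom(phantom_config(image_size = 64, seed = s))
    f <- mean(rec$mask)
    expect_gte(f, 0.05)
    expect_lte(f, 0.25)
    # one lesion: a single connected component (4-connectivity flood fill)
    expect_identical(n_components(rec$mask), 1L)
    gray <- rec$image[, , 1]
    if (mean(gray[rec$mask == 1]) < mean(gray[rec$mask == 0])) darker <- darker + 1L
  }
  expect_identical(darker, 100L)
})

test_that("corpus writing round-trips through load_dataset", {
  root <- withr::local_tempdir()
  ids <- generate_corpus(20, cfg64, root, subset = "train")
  recs <- load_dataset(root, "train")
  expect_length(recs, 20)
  expect_setequal(vapply(recs, `[[`, "", "id"), ids)
  # masks are bit-identical after the PNG round trip
  ref <- generate_phantom(phantom_config(image_size = 64, seed = 123 + 1000))
  got <- recs[[which(vapply(recs, `[[`, "", "id") == ref$id)]]
  expect_identical(got$mask, ref$mask)
  expect_identical(got$image, ref$image)
  # refusal to clobber, unless forced
  expect_error(generate_corpus(2, cfg64, root, subset = "train"), "not empty")
  expect_silent(generate_corpus(2, cfg64, root, subset = "train", force = TRUE))
  expect_error(generate_corpus(0, cfg64, root), "at least one")
})

test_that("distribution-shifted corpus is darker-lesioned and noisier", {
  root <- withr::local_tempdir()
  generate_corpus(40, cfg64, root, subset = "test")
  generate_corpus(40, cfg64, root, subset = "generalization", shifted = TRUE)
  plain <- load_dataset(root, "test")
  shift <- load_dataset(root, "generalization")
  contrast_of <- function(recs) {
    vapply(recs, function(r) {
      g <- r$image[, , 1]
      mean(g[r$mask == 0]) - mean(g[r$mask == 1])
    }, numeric(1))
  }
  # weaker lesion contrast in the shifted variant
  expect_lt(mean(contrast_of(shift)), mean(contrast_of(plain)))
})

test_that("unpaired files are skipped with a warning and manifests exclude normals", {
  root <- withr::local_tempdir()
  generate_corpus(3, cfg64, root, subset = "train")
  # orphan an image by removing its mask
  recs <- load_dataset(root, "train")
  victim <- recs[[1]]$id
  file.remove(file.path(root, "train", "masks", paste0(victim, ".png")))
  expect_warning(remaining <- load_dataset(root, "train"), "skipped")
  expect_length(remaining, 2)

  # manifest-based exclusion of a Normal-ovary sample
  keep <- vapply(remaining, `[[`, "", "id")
  write.csv(data.frame(id = keep[1], category = "Normal ovary"),
            file.path(root, "classes.csv"), row.names = FALSE)
  filtered <- suppressWarnings(load_dataset(root, "train"))
  expect_length(filtered, 1)
  expect_identical(filtered[[1]]$id, keep[2])
})

test_that("preprocess resizes, standardizes, and keeps masks binary", {
  rec <- generate_phantom(phantom_config(image_size = 100, seed = 9))
  pp <- preprocess(rec, side = 96)
  expect_identical(dim(pp$image), c(96L, 96L, 3L))
  expect_identical(dim(pp$mask), c(96L, 96L))
  expect_true(all(pp$mask %in% c(0L, 1L)))
  # lesion topology survives the resize
  expect_identical(n_components(pp$mask), 1L)
  # all-zero mask survives as all zeros
  rec0 <- rec; rec0$mask[] <- 0L
  expect_true(all(preprocess(rec0, side = 96)$mask == 0))
  # already-at-size input keeps its geometry (mask unchanged by resize)
  sq <- rec
  sq$image <- rec$image[1:96, 1:96, , drop = FALSE]
  sq$mask <- rec$mask[1:96, 1:96]
  expect_identical(preprocess(sq, side = 96)$mask, sq$mask)
})

test_that("flip augmentation is an involution and conserves lesion area", {
  rec <- generate_phantom(phantom_config(image_size = 64, seed = 5))
  set.seed(1)
  # find a draw that applies both flips
  repeat {
    out <- augment(rec$image, rec$mask)
    if (all(out$flips)) break
  }
  expect_identical(sum(out$mask), sum(rec$mask))
  both <- out$image[rev(seq_len(nrow(rec$mask))),
                    rev(seq_len(ncol(rec$mask))), , drop = FALSE]
  expect_identical(both, rec$image)
  # image and mask flip together: lesion pixels still align
  g <- out$image[, , 1]
  expect_lt(mean(g[out$mask == 1]), mean(g[out$mask == 0]))
})

test_that("train/val split is seeded, disjoint and exhaustive", {
  recs <- lapply(1:820, function(i) {
    structure(list(id = paste0("r", i), image = NULL, mask = NULL,
                   subset = "train"), class = "sample_record")
  })
  sp <- split_train_val(recs, 0.8, seed = 3)
  expect_length(sp$train, 656)
  expect_length(sp$val, 164)
  ids <- c(vapply(sp$train, `[[`, "", "id"), vapply(sp$val, `[[`, "", "id"))
  expect_setequal(ids, paste0("r", 1:820))
  sp2 <- split_train_val(recs, 0.8, seed = 3)
  expect_identical(vapply(sp$train, `[[`, "", "id"),
                   vapply(sp2$train, `[[`, "", "id"))
  small <- split_train_val(recs[1:10], 0.8, seed = 1)
  expect_length(small$train, 8)
  expect_length(small$val, 2)
  expect_error(split_train_val(recs[1], 0.8, 1), "at least two")
})
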