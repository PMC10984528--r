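tiny_cfg <- pmffnet_config(widths = c(8L, 8L, 16L, 16L),
                           depths = c(1L, 1L, 1L, 1L),
                           heads = c(1L, 1L, 2L, 2L),
                           ffn_ratio = 2L, mfb_width = 8L)

tiny_phantoms <- function(n, seed0 = 500, size = 64) {
  lapply(seq_len(n), function(i) {
    generate_phantom(phantom_config(image_size = size, seed = seed0 + i))
  })
}

test_that("plateau scheduler halves exactly on schedule", {
  # flat metric: first epoch improves over -Inf, then 10 stagnant epochs
  s <- plateau_scheduler(1e-4, patience = 10L, factor = 0.5)
  lrs <- vapply(rep(0.5, 11), s$step, numeric(1))
  expect_identical(s$events, 11L)
  expect_equal(lrs, c(rep(1e-4, 10), 5e-5))

  # strictly improving metric: never drops
  s2 <- plateau_scheduler(1e-4, 10L, 0.5)
  for (m in seq(0.1, 0.9, length.out = 30)) s2$step(m)
  expect_length(s2$events, 0)
  expect_equal(s2$lr, 1e-4)

  # improvement resets the stagnation counter
  s3 <- plateau_scheduler(1e-3, 3L, 0.5)
  for (m in c(0.5, 0.5, 0.5, 0.6, 0.6, 0.6, 0.6)) s3$step(m)
  # stalls at epochs 2,3 then reset; stalls at 5,6,7 -> one event at epoch 7
  expect_identical(s3$events, 7L)
  expect_equal(s3$lr, 5e-4)

  # two consecutive plateaus halve twice
  s4 <- plateau_scheduler(1, 2L, 0.5)
  for (m in rep(0, 7)) s4$step(m)
  expect_identical(s4$events, c(3L, 5L, 7L))
  expect_equal(s4$lr, 0.125)
})

test_that("a stagnant training run halves the learning rate once at epoch 11", {
  set.seed(70)
  recs <- tiny_phantoms(2)
  model <- pmffnet_model(tiny_cfg, seed = 71)
  # learning rate small enough that the validation metric cannot move
  cfg <- train_config(epochs = 11L, batch_size = 2L, lr = 1e-30, side = 32L,
                      seed = 72, augment_flips = FALSE)
  log <- fit(model, recs, recs, cfg)
  expect_identical(attr(log, "lr_events"), 11L)
  expect_equal(log$lr, rep(1e-30, 11))       # drop applies from epoch 12
  expect_true(all(diff(log$lr) <= 0))
  expect_equal(var(log$val_dice), 0)         # frozen model, frozen metric
})

test_that("training is seeded and reproducible", {
  recs <- tiny_phantoms(4)
  run <- function() {
    model <- pmffnet_model(tiny_cfg, seed = 73)
    cfg <- train_config(epochs = 2L, batch_size = 2L, lr = 1e-3, side = 32L,
                        seed = 74)
    fit(model, recs, recs[1:2], cfg)
  }
  l1 <- run(); l2 <- run()
  expect_identical(l1$train_loss, l2$train_loss)
  expect_identical(l1$val_dice, l2$val_dice)
})

test_that("the saved best checkpoint reproduces the logged best validation mDice", {
  recs <- tiny_phantoms(4)
  model <- pmffnet_model(tiny_cfg, seed = 75)
  cfg <- train_config(epochs = 3L, batch_size = 2L, lr = 1e-3, side = 32L,
                      seed = 76, augment_flips = FALSE)
  ck <- withr::local_tempfile(fileext = ".rds")
  log <- fit(model, recs[1:2], recs[3:4], cfg, checkpoint = ck)
  best <- load_checkpoint(ck)
  ns <- asNamespace("pmffnet")
  redone <- ns$model_dice_on(best, recs[3:4], 32L, NULL)
  expect_lt(abs(redone - attr(log, "best_dice")), 1e-6)
  expect_identical(attr(best, "meta")$epoch, attr(log, "best_epoch"))
})

test_that("evaluate scores oracle and degenerate predictors correctly", {
  recs <- tiny_phantoms(3)
  # oracle fixture: feeds the ground truth back as the prediction
  oracle <- function(pp) pp$mask
  ev <- evaluate(oracle, recs, side = 64L)
  expect_equal(unname(unclass(ev$report)), rep(1, 5))

  # all-background predictor misses every lesion: recall collapses to 0
  blank <- function(pp) matrix(0, nrow(pp$mask), ncol(pp$mask))
  ev0 <- evaluate(blank, recs, side = 64L)
  expect_equal(unname(ev0$report["recall"]), 0)
  expect_equal(unname(ev0$report["precision"]), 0)

  # per-image rows keep input order; CSV carries the 2-decimal percent format
  expect_identical(ev$per_image$id, vapply(recs, `[[`, "", "id"))
  csv <- withr::local_tempfile(fileext = ".csv")
  evaluate(oracle, recs, side = 64L, csv = csv)
  got <- utils::read.csv(csv, colClasses = "character")
  expect_identical(got$dice, rep("100.00", 4))
  expect_error(evaluate(oracle, list(), side = 64L), "empty test set")
})

test_that("predict round-trips geometry and exports activation maps", {
  root <- withr::local_tempdir()
  rec <- generate_phantom(phantom_config(image_size = 70, seed = 901))
  img_path <- file.path(root, "in.png")
  png::writePNG(rec$image / 255, img_path)
  model <- pmffnet_model(tiny_cfg, seed = 77)
  out_path <- file.path(root, "mask.png")
  act_dir <- file.path(root, "acts")
  m1 <- predict_mask(model, img_path, out_path, side = 32L,
                     activations = act_dir)
  expect_identical(dim(m1), dim(rec$mask))
  stored <- png::readPNG(out_path)
  expect_true(all(stored %in% c(0, 1)))
  # one map per requested tap per scale: 4 backbone + 4 mfb + decoder
  expect_length(dir(act_dir, pattern = "\\.png$"), 9L)
  # deterministic inference: identical PNG bytes on a second run
  out2 <- file.path(root, "mask2.png")
  predict_mask(model, img_path, out2, side = 32L)
  expect_identical(readBin(out_path, "raw", 1e6), readBin(out2, "raw", 1e6))
  expect_error(predict_mask(model, file.path(root, "missing.png"), out_path),
               "cannot read")
})
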