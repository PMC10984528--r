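test_that("BCE loss matches closed forms", {
  # perfect prediction pinned at the clamp boundary
  gt <- matrix(c(1, 0, 1, 1), 2, 2)
  pred <- ifelse(gt == 1, 1, 0)
  expect_lt(bce_loss(gt, pred), 1e-6)
  # uninformative prediction: ln 2 regardless of the target
  expect_equal(bce_loss(matrix(1, 3, 3), matrix(0.5, 3, 3)), log(2))
  expect_equal(bce_loss(matrix(0, 3, 3), matrix(0.5, 3, 3)), log(2))
  # hand evaluation
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.2)), -(log(0.9) + log(0.8)) / 2)
  expect_error(bce_loss(matrix(0, 2, 2), matrix(0, 2, 3)), "dimensions")
})

test_that("Dice loss identities and empty-mask behaviour", {
  gt <- matrix(0, 8, 8); gt[2:4, 3:6] <- 1
  expect_equal(dice_loss(gt, gt), 0)
  # doubly-empty: the smooth term exists for exactly this case
  z <- matrix(0, 8, 8)
  expect_equal(dice_loss(z, z), 0)
  # all-wrong over N pixels: 1 - 1/(N+1) = N/(N+1)
  n <- 64
  expect_equal(dice_loss(z, matrix(1, 8, 8)), n / (n + 1))
  # range and total-loss dominance on random pairs
  set.seed(11)
  for (i in 1:20) {
    g <- matrix(rbinom(64, 1, 0.3), 8, 8)
    p <- matrix(runif(64), 8, 8)
    dl <- dice_loss(g, p)
    expect_gte(dl, 0); expect_lt(dl, 1)
    expect_gte(total_loss(g, p), max(dl, bce_loss(g, p)))
  }
})

test_that("confusion counts match a hand-counted toy grid", {
  gt <- matrix(0, 10, 10); gt[1:3, 1:3] <- 1          # 3x3 lesion
  pred <- matrix(0, 10, 10); pred[1:4, 1:4] <- 1      # 4x4 prediction, corner-aligned
  cc <- confusion(gt, pred)
  expect_identical(cc[c("TP", "FP", "FN", "TN")],
                   list(TP = 9L, FP = 7L, FN = 0L, TN = 84L))
  expect_identical(cc$TP + cc$FP + cc$FN + cc$TN, 100L)
  # identity and complement
  ident <- confusion(gt, gt)
  expect_identical(c(ident$FP, ident$FN), c(0L, 0L))
  comp <- confusion(gt, 1 - gt)
  expect_identical(c(comp$TP, comp$TN), c(0L, 0L))
})

test_that("metrics_from_counts matches direct arithmetic and conventions", {
  m <- metrics_from_counts(list(TP = 6, FP = 2, FN = 2, TN = 90))
  expect_equal(unname(m["acc"]), 0.96)
  expect_equal(unname(m["iou"]), 0.6)
  expect_equal(unname(m["dice"]), 13 / 17)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["recall"]), 0.75)
  # perfect prediction
  expect_equal(unname(metrics_from_counts(list(TP = 50, FP = 0, FN = 0, TN = 14))),
               rep(1, 5))
  # all-background truly predicted all-background
  expect_equal(unname(metrics_from_counts(list(TP = 0, FP = 0, FN = 0, TN = 64))),
               rep(1, 5))
  # lesion entirely missed: overlap metrics collapse to 0
  missed <- metrics_from_counts(list(TP = 0, FP = 0, FN = 9, TN = 91))
  expect_equal(unname(missed[c("iou", "precision", "recall")]), c(0, 0, 0))
})

test_that("metrics agree with a brute-force recount on random mask pairs", {
  set.seed(42)
  brute <- function(g, p) {
    # independent recount: loop over pixels, tally, then direct formulas
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_along(g)) {
      if (g[i] == 1 && p[i] == 1) tp <- tp + 1L
      else if (g[i] == 0 && p[i] == 1) fp <- fp + 1L
      else if (g[i] == 1 && p[i] == 0) fn <- fn + 1L
      else tn <- tn + 1L
    }
    list(TP = tp, FP = fp, FN = fn, TN = tn)
  }
  for (trial in 1:1000) {
    g <- matrix(rbinom(256, 1, runif(1)), 16, 16)
    p <- matrix(rbinom(256, 1, runif(1)), 16, 16)
    cb <- brute(g, p)
    cc <- confusion(g, p)
    expect_identical(cc[c("TP", "FP", "FN", "TN")], cb)
    expect_equal(metrics_from_counts(cc), metrics_from_counts(cb))
  }
})

test_that("Dice and IoU satisfy Dice = 2 IoU / (1 + IoU) without smoothing", {
  set.seed(7)
  for (trial in 1:50) {
    g <- matrix(rbinom(256, 1, 0.4), 16, 16)
    p <- matrix(rbinom(256, 1, 0.4), 16, 16)
    if (sum(g) == 0 || sum(p) == 0) next
    m <- metrics_from_counts(confusion(g, p), smooth = 0)
    expect_equal(unname(m["dice"]), unname(2 * m["iou"] / (1 + m["iou"])))
  }
})

test_that("mean_metrics averages per-image tuples and is order-invariant", {
  a <- c(acc = 0.9, iou = 0.4, dice = 0.5, precision = 0.6, recall = 0.7)
  b <- c(acc = 1.0, iou = 0.8, dice = 0.9, precision = 1.0, recall = 0.9)
  one <- mean_metrics(list(a))
  expect_equal(unclass(one), a)
  two <- mean_metrics(list(a, b))
  expect_equal(unname(two["iou"]), 0.6)
  expect_equal(unclass(mean_metrics(list(b, a))), unclass(two))
  expect_error(mean_metrics(list()), "no per-image")
})

test_that("metrics CSV writer emits percent rows plus a mean row", {
  df <- data.frame(id = c("p1", "p2"),
                   acc = c(0.9, 1), iou = c(0.4, 0.8), dice = c(0.5, 0.9),
                   precision = c(0.6, 1), recall = c(0.7, 0.9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(df, path)
  got <- utils::read.csv(path, colClasses = "character")
  expect_identical(got$id, c("p1", "p2", "mean"))
  expect_identical(got$iou, c("40.00", "80.00", "60.00"))
})
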