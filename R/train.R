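# Training loop: AdamW on the compound BCE+Dice loss, validation-mDice
# plateau scheduling, best-checkpoint selection, and the evaluation /
# prediction entry points.

#' Training configuration
#'
#' @param epochs training epochs (default 100).
#' @param batch_size minibatch size (default 8).
#' @param lr initial AdamW learning rate (default 1e-4).
#' @param weight_decay AdamW decoupled weight decay.
#' @param betas AdamW moment decay pair.
#' @param plateau_patience epochs without validation-mDice improvement before
#'   the learning rate is halved (default 10).
#' @param plateau_factor multiplicative learning-rate drop at a plateau
#'   (default 0.5).
#' @param side training resolution; images and masks are resized to
#'   `side x side` (must be a multiple of 32).
#' @param seed seed controlling shuffling, augmentation and initialization.
#' @param augment_flips apply the 50/50 horizontal/vertical flip augmentation
#'   to training samples.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 8L, lr = 1e-4,
                         weight_decay = 0.01, betas = c(0.9, 0.999),
                         plateau_patience = 10L, plateau_factor = 0.5,
                         side = 384L, seed = 1L, augment_flips = TRUE) {
  stopifnot(plateau_factor > 0, plateau_factor < 1, plateau_patience >= 1,
            side %% 32 == 0, batch_size >= 1, epochs >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, weight_decay = weight_decay, betas = betas,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor,
                 side = as.integer(side), seed = as.integer(seed),
                 augment_flips = isTRUE(augment_flips)),
            class = "train_config")
}

#' AdamW optimizer state
#'
#' Decoupled weight decay: parameters shrink by `lr * weight_decay` before
#' the Adam update of the gradient moments.
#'
#' @param params named list of parameter nodes.
#' @param lr learning rate.
#' @param betas moment decay pair.
#' @param weight_decay decoupled decay coefficient.
#' @param eps denominator stabilizer.
#' @return An optimizer object with `$step()` and mutable `$lr`.
#' @keywords internal
adamw <- function(params, lr = 1e-4, betas = c(0.9, 0.999),
                  weight_decay = 0.01, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p$v * 0)
  st$v <- lapply(params, function(p) p$v * 0)
  st$t <- 0L
  st$lr <- lr
  st$step <- function() {
    st$t <- st$t + 1L
    b1 <- betas[1]; b2 <- betas[2]
    bc1 <- 1 - b1^st$t
    bc2 <- 1 - b2^st$t
    for (nm in names(params)) {
      p <- params[[nm]]
      g <- p$grad
      if (is.null(g)) next
      if (weight_decay > 0) p$v <- p$v - st$lr * weight_decay * p$v
      st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
      st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
      mhat <- st$m[[nm]] / bc1
      vhat <- st$v[[nm]] / bc2
      p$v <- p$v - st$lr * mhat / (sqrt(vhat) + eps)
    }
    invisible(NULL)
  }
  st
}

#' Reduce-on-plateau learning-rate scheduler
#'
#' Tracks a maximized metric (validation mDice). When the metric fails to
#' improve strictly for `patience` consecutive epochs, the learning rate is
#' multiplied by `factor` and the stagnation counter resets.
#'
#' @param lr0 initial learning rate.
#' @param patience stagnant epochs tolerated before a drop.
#' @param factor multiplicative drop.
#' @return Scheduler object: call `$step(metric)` once per epoch; read `$lr`.
#' @export
plateau_scheduler <- function(lr0, patience = 10L, factor = 0.5) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr0
  st$best <- -Inf
  st$stall <- 0L
  st$events <- integer(0)
  st$epoch <- 0L
  st$step <- function(metric) {
    st$epoch <- st$epoch + 1L
    if (metric > st$best) {
      st$best <- metric
      st$stall <- 0L
    } else {
      st$stall <- st$stall + 1L
      if (st$stall >= patience) {
        st$lr <- st$lr * factor
        st$events <- c(st$events, st$epoch)
        st$stall <- 0L
      }
    }
    st$lr
  }
  st
}

prep_batch <- function(samples, side, stats, do_augment) {
  n <- length(samples)
  x <- array(0, c(side, side, 3L, n))
  y <- array(0, c(side, side, 1L, n))
  for (i in seq_len(n)) {
    pp <- preprocess(samples[[i]], side = side, stats = stats)
    if (do_augment) {
      fl <- augment(pp$image, pp$mask)
      pp$image <- fl$image
      pp$mask <- fl$mask
    }
    x[, , , i] <- pp$image
    y[, , 1, i] <- pp$mask
  }
  list(x = x, y = y)
}

model_dice_on <- function(model, records, side, stats) {
  scores <- vapply(records, function(rec) {
    pp <- preprocess(rec, side = side, stats = stats)
    logits <- pmffnet_forward(model, pp$image)
    pred <- binarize(1 / (1 + exp(-logits[, , 1, 1])))
    unname(metrics_from_counts(confusion(pp$mask, pred))["dice"])
  }, numeric(1))
  mean(scores)
}

#' Train the network
#'
#' Optimizes the compound BCE + Dice loss with AdamW, evaluates validation
#' mDice after every epoch, halves the learning rate after
#' `plateau_patience` stagnant epochs, and keeps the checkpoint with the best
#' validation mDice. Fully seeded: the same model seed, data and training
#' configuration reproduce the loss trajectory.
#'
#' @param model a [pmffnet_model()].
#' @param train_set,val_set lists of `sample_record`s.
#' @param cfg a [train_config()].
#' @param checkpoint optional path for the best-model checkpoint (RDS);
#'   defaults to a tempfile.
#' @param stats normalization statistics (see [corpus_stats()]).
#' @param verbose print one line per epoch.
#' @return A `run_log`: data.frame with per-epoch train loss, validation
#'   mDice and learning rate, plus attributes `best_epoch`, `best_dice` and
#'   `checkpoint`.
#' @export
fit <- function(model, train_set, val_set, cfg = train_config(),
                checkpoint = NULL, stats = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "pmffnet_model"), inherits(cfg, "train_config"),
            length(train_set) >= 1, length(val_set) >= 1)
  if (is.null(checkpoint)) checkpoint <- tempfile(fileext = ".rds")
  set.seed(cfg$seed)
  opt <- adamw(model$params, lr = cfg$lr, betas = cfg$betas,
               weight_decay = cfg$weight_decay)
  sched <- plateau_scheduler(cfg$lr, cfg$plateau_patience, cfg$plateau_factor)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_dice = numeric(0), lr = numeric(0))
  best <- -Inf
  best_epoch <- NA_integer_
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(length(train_set))
    losses <- numeric(0)
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      batch <- prep_batch(train_set[idx], cfg$side, stats, cfg$augment_flips)
      zero_grads(model$params)
      logits <- pmffnet_graph(model, ad_const(batch$x))
      loss <- ad_total_loss(logits, batch$y)
      if (!is.finite(ad_value(loss))) {
        stop(sprintf("training diverged: non-finite loss at epoch %d", ep),
             call. = FALSE)
      }
      ad_backward(loss)
      opt$lr <- sched$lr
      opt$step()
      losses <- c(losses, ad_value(loss))
    }
    vd <- model_dice_on(model, val_set, cfg$side, stats)
    if (vd > best) {
      best <- vd
      best_epoch <- ep
      save_checkpoint(model, checkpoint, val_dice = vd, epoch = ep)
    }
    lr_now <- sched$lr
    sched$step(vd)
    log <- rbind(log, data.frame(epoch = ep, train_loss = mean(losses),
                                 val_dice = vd, lr = lr_now))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val mDice %.4f  lr %.2e",
                      ep, mean(losses), vd, lr_now))
    }
  }
  structure(log, class = c("run_log", "data.frame"),
            best_epoch = best_epoch, best_dice = best,
            checkpoint = checkpoint, lr_events = sched$events)
}

#' Save / load model checkpoints
#'
#' The checkpoint embeds the configuration, seed and parameter values, plus
#' any metadata supplied; loading rebuilds the model and restores weights.
#'
#' @param model a model; `path` an RDS file path.
#' @param ... metadata stored alongside (e.g. `val_dice`).
#' @return `save_checkpoint` the path; `load_checkpoint` the model with a
#'   `meta` attribute.
#' @export
save_checkpoint <- function(model, path, ...) {
  saveRDS(list(config = unclass(model$config), seed = model$seed,
               values = lapply(model$params, `[[`, "v"),
               meta = list(...)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path checkpoint path.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  config <- do.call(pmffnet_config, ck$config[setdiff(names(ck$config), NULL)])
  model <- pmffnet_model(config, seed = ck$seed)
  stopifnot(identical(names(model$params), names(ck$values)))
  for (nm in names(ck$values)) model$params[[nm]]$v <- ck$values[[nm]]
  attr(model, "meta") <- ck$meta
  model
}

#' Evaluate a model on a test set
#'
#' Thresholds sigmoid predictions at 0.5 and reports the per-image pixel
#' metrics together with their dataset means; optionally writes the
#' per-image CSV (rows in input order, summary row last).
#'
#' @param model a trained model (or a function mapping a preprocessed image
#'   array to a probability map, used for oracle fixtures in tests).
#' @param test_set list of `sample_record`s.
#' @param side evaluation resolution.
#' @param stats normalization statistics.
#' @param csv optional path for the per-image metric CSV.
#' @return List with `report` (a `metric_report`) and `per_image`
#'   (data.frame).
#' @export
evaluate <- function(model, test_set, side = 384L, stats = NULL, csv = NULL) {
  if (length(test_set) == 0) stop("empty test set", call. = FALSE)
  rows <- lapply(test_set, function(rec) {
    pp <- preprocess(rec, side = side, stats = stats)
    prob <- if (is.function(model)) {
      model(pp)
    } else {
      logits <- pmffnet_forward(model, pp$image)
      1 / (1 + exp(-logits[, , 1, 1]))
    }
    m <- metrics_from_counts(confusion(pp$mask, binarize(prob)))
    data.frame(id = rec$id, t(m))
  })
  per_image <- do.call(rbind, rows)
  if (!is.null(csv)) write_metrics_csv(per_image, csv)
  list(report = mean_metrics(per_image), per_image = per_image)
}

#' Segment one image file
#'
#' Reads a PNG, runs the network at the model's inference side, thresholds at
#' 0.5 and writes the binary mask back at the original resolution
#' (nearest-neighbour upsampling). Optionally exports channel-mean activation
#' maps of the backbone, MFB and decoder taps as grayscale PNGs.
#'
#' @param model a trained model.
#' @param image_path input PNG path.
#' @param out_path output mask PNG path.
#' @param side inference resolution.
#' @param stats normalization statistics.
#' @param activations optional directory for activation-map PNGs.
#' @return Invisibly, the binary mask matrix at original resolution.
#' @export
predict_mask <- function(model, image_path, out_path, side = 384L,
                         stats = NULL, activations = NULL) {
  if (!file.exists(image_path)) {
    stop("cannot read image: ", image_path, call. = FALSE)
  }
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1))
  if (dim(img)[3] == 1) img <- img[, , c(1, 1, 1), drop = FALSE]
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  h0 <- dim(img)[1]; w0 <- dim(img)[2]
  rec <- structure(list(id = "query",
                        image = array(as.integer(round(img * 255)), dim(img)),
                        mask = matrix(0L, h0, w0), subset = "test"),
                   class = "sample_record")
  pp <- preprocess(rec, side = side, stats = stats)
  out <- pmffnet_forward(model, pp$image, taps = !is.null(activations))
  logits <- if (is.null(activations)) out else out$logits
  mask <- binarize(1 / (1 + exp(-logits[, , 1, 1])))
  full <- resize_nearest(mask, h0, w0)
  png::writePNG(full + 0, out_path)
  if (!is.null(activations)) {
    dir.create(activations, recursive = TRUE, showWarnings = FALSE)
    dump_tap <- function(map, name) {
      m <- apply(map[, , , 1, drop = FALSE], c(1, 2), mean)
      rng <- range(m)
      if (diff(rng) < 1e-12) m[] <- 0 else m <- (m - rng[1]) / diff(rng)
      png::writePNG(m, file.path(activations, paste0(name, ".png")))
    }
    for (s in 1:4) {
      dump_tap(out$pyramid[[s]], sprintf("backbone_scale%d", s))
      dump_tap(out$mfb[[s]], sprintf("mfb_scale%d", s))
    }
    dump_tap(out$decoder, "decoder")
  }
  invisible(full)
}
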