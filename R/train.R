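#' Training configuration
#'
#' Defaults follow the published recipe for the full-scale model: 128
#' epochs, batch size 64, SGD with learning rates 0.004 (backbone) and 0.4
#' (head), both halved every 32 epochs, with flips/rotations, paired color
#' exchange, and multi-scale resizing. The `"tiny"` preset scales the whole
#' recipe down to a desk-size CPU run (tiny backbone, 64 px inputs,
#' batch 8, lr 0.01/0.1, no multi-scale).
#'
#' @param epochs number of training epochs.
#' @param batch_size samples per optimizer step.
#' @param lr_backbone,lr_head initial learning rates of the two parameter
#'   groups.
#' @param decay_factor,decay_every learning-rate schedule: multiply by
#'   `decay_factor` every `decay_every` epochs.
#' @param momentum,nesterov SGD momentum settings.
#' @param val_fraction held-out fraction for per-epoch validation.
#' @param color_exchange_rate fraction of each batch recolored from a
#'   random partner.
#' @param multiscale apply multi-scale resizing per batch.
#' @param grad_clip gradient L2 clip threshold (`Inf` disables).
#' @param seed seed controlling shuffling, augmentation and the split.
#' @param preset `"paper"` or `"tiny"`; explicit arguments override preset
#'   values.
#' @return a `train_config` object.
#' @export
train_config <- function(epochs = 128L, batch_size = 64L,
                         lr_backbone = 0.004, lr_head = 0.4,
                         decay_factor = 0.5, decay_every = 32L,
                         momentum = 0.9, nesterov = TRUE,
                         val_fraction = 0.1, color_exchange_rate = 0.5,
                         multiscale = TRUE, grad_clip = Inf, seed = 1L,
                         preset = c("paper", "tiny")) {
  preset <- match.arg(preset)
  cfg <- list(epochs = epochs, batch_size = batch_size,
              lr_backbone = lr_backbone, lr_head = lr_head,
              decay_factor = decay_factor, decay_every = decay_every,
              momentum = momentum, nesterov = nesterov,
              val_fraction = val_fraction,
              color_exchange_rate = color_exchange_rate,
              multiscale = multiscale, grad_clip = grad_clip,
              seed = as.integer(seed))
  if (preset == "tiny") {
    defaults <- list(epochs = 128L, batch_size = 64L, lr_backbone = 0.004,
                     lr_head = 0.4)
    tiny <- list(epochs = 10L, batch_size = 8L, lr_backbone = 0.01,
                 lr_head = 0.1, multiscale = FALSE)
    for (nm in names(tiny)) {
      if (identical(cfg[[nm]], defaults[[nm]]) || nm == "multiscale") {
        cfg[[nm]] <- tiny[[nm]]
      }
    }
  }
  stopifnot(cfg$epochs >= 1, cfg$lr_backbone > 0 || cfg$lr_backbone == 0,
            cfg$lr_head >= 0, cfg$decay_every >= 1)
  structure(cfg, class = "train_config")
}

#' Learning rates at a given epoch
#'
#' Step decay: `base_lr * decay_factor ^ floor(epoch / decay_every)` for
#' each parameter group (epoch is 0-based).
#'
#' @param config a [train_config()].
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @return named numeric vector `c(lr_backbone, lr_head)`.
#' @export
lr_at_epoch <- function(config, epoch) {
  if (epoch < 0 || epoch >= config$epochs) {
    stop("epoch must be in [0, epochs)", call. = FALSE)
  }
  f <- config$decay_factor^floor(epoch / config$decay_every)
  c(lr_backbone = config$lr_backbone * f, lr_head = config$lr_head * f)
}

stack_batch <- function(samples) {
  d <- dim(samples[[1]]$image)
  n <- length(samples)
  x <- array(0, dim = c(n, d[1], d[2], 3L))
  y <- array(0, dim = c(n, d[1], d[2], 1L))
  for (i in seq_len(n)) {
    x[i, , , ] <- samples[[i]]$image
    y[i, , , 1] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

#' Train a segmentation model
#'
#' Seeded end-to-end: sample order, augmentation, color-exchange pairing
#' and scale draws for epoch `e` depend only on `(config$seed, e)`, so a
#' shorter run reproduces the prefix of a longer one. Each epoch shuffles
#' the training split, applies flip/rotation augmentation, recolors a
#' fraction of each batch from a random partner, optionally draws a batch
#' scale, and takes one SGD step per batch on the Dice + BCE objective.
#'
#' @param model an [sranet()] model.
#' @param samples list of `seg_sample` training pairs.
#' @param config a [train_config()].
#' @param start_epoch 0-based epoch to resume from (weights should then come
#'   from a checkpoint of the same run); epoch seeding keeps the schedule
#'   and data order aligned with an uninterrupted run, though optimizer
#'   momentum restarts at zero.
#' @param verbose print one line per epoch.
#' @return a list with `model` (trained, in place), `log` (data.frame with
#'   one row per epoch: mean total/Dice/BCE losses, learning rates,
#'   validation mDice/mIoU) and `val_index` (held-out indices).
#' @export
train <- function(model, samples, config = train_config(preset = "tiny"),
                  start_epoch = 0L, verbose = FALSE) {
  # force the promises now: building a model resets the RNG, which must not
  # happen lazily in the middle of a seeded epoch stream
  force(model); force(config)
  stopifnot(length(samples) > 0, start_epoch >= 0,
            start_epoch < config$epochs)
  set.seed(mix_seed(config$seed, 999983L))
  n <- length(samples)
  n_val <- max(0L, floor(config$val_fraction * n))
  val_idx <- if (n_val > 0) sort(sample.int(n, n_val)) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  log_rows <- list()
  for (epoch in seq.int(start_epoch, config$epochs - 1L)) {
    set.seed(mix_seed(config$seed, epoch))
    lrs <- lr_at_epoch(config, epoch)
    order_idx <- base::sample(train_idx)
    batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
    tot <- dic <- bce <- 0; nb <- 0
    for (bi in batches) {
      batch <- lapply(samples[bi], augment)
      if (config$color_exchange_rate > 0 && length(batch) > 1) {
        recolor <- which(stats::runif(length(batch)) < config$color_exchange_rate)
        for (i in recolor) {
          donor <- base::sample(setdiff(seq_along(batch), i), 1L)
          batch[[i]] <- color_exchange(batch[[i]], batch[[donor]])
        }
      }
      if (config$multiscale) {
        side <- base::sample(c(256L, 288L, 320L, 352L), 1L,
                             prob = c(0.1, 0.2, 0.3, 0.4))
        batch <- lapply(batch, multiscale_resize, force = side)
      }
      b <- stack_batch(batch)
      out <- sranet_forward(model, b$x, training = TRUE)
      loss <- nd_dice_bce(out$node, b$y)
      if (!is.finite(loss$value)) {
        warning("non-finite loss at epoch ", epoch, "; aborting", call. = FALSE)
        return(list(model = model, log = do.call(rbind, log_rows),
                    val_index = val_idx, aborted = TRUE))
      }
      nd_backward(loss)
      if (is.finite(config$grad_clip)) clip_grads(model$params, config$grad_clip)
      sgd_step(model$params, lrs[["lr_backbone"]], lrs[["lr_head"]],
               config$momentum, config$nesterov)
      tot <- tot + as.numeric(loss$value)
      dic <- dic + loss$dice
      bce <- bce + loss$bce
      nb <- nb + 1
    }
    val <- if (length(val_idx) > 0) {
      ev <- evaluate(model, samples[val_idx])
      c(ev$m_dice, ev$m_iou)
    } else c(NA_real_, NA_real_)
    row <- data.frame(epoch = epoch, loss_total = tot / nb,
                      loss_dice = dic / nb, loss_bce = bce / nb,
                      lr_backbone = lrs[["lr_backbone"]],
                      lr_head = lrs[["lr_head"]],
                      val_mdice = val[1], val_miou = val[2])
    log_rows[[epoch - start_epoch + 1L]] <- row
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f (dice %.4f bce %.4f)  val mDice %s",
                      epoch, row$loss_total, row$loss_dice, row$loss_bce,
                      ifelse(is.na(row$val_mdice), "-",
                             sprintf("%.4f", row$val_mdice))))
    }
  }
  list(model = model, log = do.call(rbind, log_rows), val_index = val_idx,
       aborted = FALSE)
}

clip_grads <- function(params, max_norm) {
  total <- sqrt(sum(vapply(params, function(p) sum(p$grad^2), numeric(1))))
  if (total > max_norm) {
    sc <- max_norm / total
    for (p in params) p$grad <- p$grad * sc
  }
  invisible(params)
}

#' Evaluate a model on a sample set
#'
#' Each sample is resized to the model's input size, predicted in
#' evaluation mode, the prediction is resized back to the mask's native
#' resolution, and all six metrics are averaged over samples.
#'
#' @param model an [sranet()] model.
#' @param samples list of `seg_sample`.
#' @return a `metrics_report` of means.
#' @export
evaluate <- function(model, samples) {
  sz <- model$config$input_size
  reports <- lapply(samples, function(s) {
    img <- s$image
    native <- dim(s$mask)
    if (!all(dim(img)[1:2] == sz)) img <- resize_image(img, sz[1], sz[2])
    p <- predict_mask(model, img)
    if (!all(dim(p) == native)) {
      p <- resize_image(array(p, dim = c(dim(p), 1L)), native[1], native[2])[, , 1]
    }
    metrics_report(s$mask, p)
  })
  mean_reports(reports)
}
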