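#' Preprocess a frame (and optionally its label map) for the network
#'
#' Resizes the single-channel frame to the working resolution with bilinear
#' interpolation and normalizes 8-bit values (0-255) to floating values in
#' `[0, 1]`.  A label map, when given, is resized with nearest-neighbor
#' interpolation, the only label-safe choice (no interpolated fractional
#' labels).
#'
#' @param frame numeric/integer matrix (one channel); values in 0-255, or
#'   already in `[0, 1]`.
#' @param mask optional integer label map of the same size.
#' @param size target (height, width), default 128x128.
#' @return list with `frame` (numeric matrix in `[0, 1]`) and `mask`
#'   (integer matrix or NULL).
#' @export
preprocess <- function(frame, mask = NULL, size = c(128L, 128L)) {
  if (is.array(frame) && length(dim(frame)) == 3) {
    if (dim(frame)[3] > 1)
      stop("frame must be single-channel")
    frame <- frame[, , 1]
  }
  if (!is.matrix(frame)) stop("frame must be a matrix")
  f <- frame
  if (max(f) > 1) f <- f / 255
  img <- EBImage::resize(EBImage::Image(f), w = size[1], h = size[2],
                         filter = "bilinear")
  out_f <- pmin(pmax(matrix(EBImage::imageData(img), size[1], size[2]), 0), 1)
  out_m <- NULL
  if (!is.null(mask)) {
    stopifnot(is.matrix(mask))
    mimg <- EBImage::resize(EBImage::Image(mask), w = size[1], h = size[2],
                            filter = "none")
    out_m <- matrix(as.integer(round(EBImage::imageData(mimg))),
                    size[1], size[2])
  }
  list(frame = out_f, mask = out_m)
}

#' Randomly split a dataset into train / validation / test
#'
#' Floor allocation: validation and test sizes are `floor(n * ratio)` and
#' the remainder goes to training, so 100 items under the default 80/10/10
#' ratios give sizes (80, 10, 10).  The split is disjoint, exhaustive and
#' deterministic per seed.
#'
#' @param items vector or list to split (at least 10 items).
#' @param ratios length-3 numeric summing to 1.
#' @param seed integer seed.
#' @return list with `train`, `val` and `test` subsets of `items`.
#' @export
split_dataset <- function(items, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  n <- length(items)
  if (n < 10) stop("need at least 10 items to split")
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three values summing to 1")
  n_val <- floor(n * ratios[2])
  n_test <- floor(n * ratios[3])
  n_train <- n - n_val - n_test
  perm <- with_seed(seed, sample.int(n))
  list(train = items[perm[seq_len(n_train)]],
       val = items[perm[n_train + seq_len(n_val)]],
       test = items[perm[n_train + n_val + seq_len(n_test)]])
}

#' Training configuration
#'
#' The default values are the reference training recipe: mini-batches of
#' eight, 50 epochs at a fixed learning rate of 1e-3 with the Adam
#' optimizer (moment decay 0.9/0.999, epsilon 1e-8), per-pixel multiclass
#' cross-entropy loss, and data shuffling in each training epoch.
#'
#' @param split_ratios train/val/test ratios (used by [split_dataset()]).
#' @param batch_size mini-batch size (>= 1).
#' @param epochs number of training epochs.
#' @param learning_rate fixed learning rate (> 0; 0 is allowed and performs
#'   no updates, useful for diagnostics).
#' @param shuffle_each_epoch reshuffle the training order every epoch.
#' @param seed integer seed; fans out to the per-epoch shuffles.
#' @return an object of class `train_config`.
#' @export
train_config <- function(split_ratios = c(0.8, 0.1, 0.1),
                         batch_size = 8L, epochs = 50L,
                         learning_rate = 1e-3,
                         shuffle_each_epoch = TRUE, seed = 0L) {
  if (abs(sum(split_ratios) - 1) > 1e-8) stop("split_ratios must sum to 1")
  if (!is_count(batch_size, min = 1)) stop("batch_size must be >= 1")
  if (!is_count(epochs, min = 0)) stop("epochs must be >= 0")
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  structure(list(split_ratios = split_ratios,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 optimizer = "adam",
                 loss = "cross_entropy",
                 shuffle_each_epoch = isTRUE(shuffle_each_epoch),
                 seed = as.integer(seed)),
            class = "train_config")
}

pack_samples <- function(samples, size) {
  h <- size[1]; w <- size[2]
  frames <- array(0, c(h, w, length(samples)))
  labels <- array(0L, c(h, w, length(samples)))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (!all(dim(s$frame) == size) || !all(dim(s$labels) == size))
      stop("samples must be preprocessed to the spec input size")
    frames[, , i] <- s$frame
    labels[, , i] <- s$labels
  }
  list(frames = frames, labels = labels)
}

#' Train the network
#'
#' Runs exactly `config$epochs` epochs of mini-batch Adam on the training
#' split; after each training epoch, computes the validation loss and the
#' validation Dice, IoU and mean pixel accuracy (macro, per image then
#' averaged).  Deterministic given the config seed (up to floating-point
#' reproducibility on one device).  Aborts with a diagnostic if the
#' training loss becomes non-finite.
#'
#' @param model a `unet_model` from [build_unet()].
#' @param data list with `train` and `val`: lists of samples, each a list
#'   with `frame` (matrix in `[0, 1]` at the spec input size) and `labels`
#'   (integer label map of the same size).
#' @param config a [train_config()].
#' @return a data frame of class `train_history` with one row per epoch:
#'   `epoch`, `train_loss`, `val_loss`, `val_dice`, `val_iou`, `val_mpa`.
#' @export
fit <- function(model, data, config = train_config()) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "train_config"))
  if (length(data$train) == 0 || length(data$val) == 0)
    stop("empty training or validation split")
  size <- model$spec$input_size
  tr <- pack_samples(data$train, size)
  va <- pack_samples(data$val, size)
  va_gts <- lapply(data$val, `[[`, "labels")
  n <- length(data$train)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_dice = numeric(0),
                     val_iou = numeric(0), val_mpa = numeric(0))
  for (ep in seq_len(config$epochs)) {
    order <- if (config$shuffle_each_epoch)
      with_seed(config$seed + 1000L * ep, sample.int(n)) else seq_len(n)
    tl <- cpp_unet_train_epoch(model$ptr, tr$frames, tr$labels,
                               as.integer(order), config$batch_size,
                               config$learning_rate)
    if (!is.finite(tl))
      stop(sprintf("non-finite training loss at epoch %d", ep))
    ev <- cpp_unet_eval(model$ptr, va$frames, va$labels)
    preds <- lapply(seq_along(va_gts), function(i)
      matrix(ev$labels[, , i], size[1], size[2]))
    rep_ <- metrics_report(preds, va_gts)
    hist[nrow(hist) + 1, ] <- list(ep, tl, ev$loss, rep_$dice, rep_$iou,
                                   rep_$mean_pixel_accuracy)
  }
  attr(hist, "config") <- config
  class(hist) <- c("train_history", class(hist))
  hist
}

#' Evaluate a trained model on a test split
#'
#' Predicts a label map for every test frame and reports the macro Dice,
#' IoU, mean pixel accuracy and per-chamber pixel accuracy.
#'
#' @param model a `unet_model`.
#' @param test_samples list of samples (`frame` + `labels`), preprocessed
#'   to the spec input size.
#' @return a [metrics_report()].
#' @export
evaluate_on_test <- function(model, test_samples) {
  stopifnot(inherits(model, "unet_model"))
  if (length(test_samples) == 0) stop("empty test set")
  te <- pack_samples(test_samples, model$spec$input_size)
  preds <- predict_labelmap(model, te$frames)
  metrics_report(preds, lapply(test_samples, `[[`, "labels"))
}
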