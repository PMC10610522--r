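#' Architecture description of the four-chamber segmentation U-Net
#'
#' The default values describe the reference network: a single-channel
#' 128x128 input, four contraction blocks of 16/32/64/128 channels (each
#' two 3x3 convolutions and a 2x2 max-pool), a 256-channel bottleneck, a
#' mirrored expansion path using 2x2 stride-2 transposed convolutions and
#' skip concatenations, an 8-channel penultimate 3x3 convolution and a 1x1
#' classification convolution.  Every convolution (including the final 1x1)
#' is followed by a rectifier and batch normalization; the transposed
#' convolutions carry a bias but no batch norm.  With 5 output classes the
#' network has 2,315,135 trainable parameters.
#'
#' @param input_size integer (height, width); must be divisible by
#'   `2^length(contraction_channels)` and at least 16.
#' @param contraction_channels channel widths of the contraction blocks.
#' @param bottleneck_channels bottleneck width.
#' @param expansion_channels must mirror `contraction_channels` (reversed).
#' @param final_intermediate_channels width of the penultimate 3x3 conv.
#' @param num_classes output classes (background + chambers).
#' @return an object of class `unet_spec`.
#' @export
unet_spec <- function(input_size = c(128L, 128L),
                      contraction_channels = c(16L, 32L, 64L, 128L),
                      bottleneck_channels = 256L,
                      expansion_channels = rev(contraction_channels),
                      final_intermediate_channels = 8L,
                      num_classes = 5L) {
  input_size <- as.integer(input_size)
  contraction_channels <- as.integer(contraction_channels)
  L <- length(contraction_channels)
  if (!identical(as.integer(expansion_channels),
                 rev(contraction_channels)))
    stop("expansion_channels must mirror contraction_channels")
  if (length(input_size) != 2 || any(input_size < 16))
    stop("input_size must be (height, width) with both >= 16")
  if (any(input_size %% 2^L != 0))
    stop(sprintf("input_size must be divisible by 2^%d so the spatial size
 can halve at each contraction", L))
  structure(list(input_size = input_size,
                 contraction_channels = contraction_channels,
                 bottleneck_channels = as.integer(bottleneck_channels),
                 expansion_channels = as.integer(expansion_channels),
                 final_intermediate_channels =
                   as.integer(final_intermediate_channels),
                 num_classes = as.integer(num_classes),
                 conv_kernel = 3L, final_kernel = 1L,
                 upsample_kernel = 2L, upsample_stride = 2L,
                 batch_norm = TRUE),
            class = "unet_spec")
}

#' Feature-map sizes of a U-Net spec
#'
#' Spatial size halves at each contraction and doubles at each expansion;
#' e.g. a 128x128 input reaches 8x8 at the bottleneck of the default
#' four-level network.
#'
#' @param spec a [unet_spec()].
#' @return data frame with stage name, height and width.
#' @export
unet_shapes <- function(spec) {
  stopifnot(inherits(spec, "unet_spec"))
  L <- length(spec$contraction_channels)
  h <- spec$input_size[1]; w <- spec$input_size[2]
  stage <- c(paste("Contraction", 1:L), "Bottleneck",
             paste("Expansion", L:1))
  hh <- c(h / 2^(0:(L - 1)), h / 2^L, h / 2^((L - 1):0))
  ww <- c(w / 2^(0:(L - 1)), w / 2^L, w / 2^((L - 1):0))
  data.frame(stage = stage, height = as.integer(hh), width = as.integer(ww))
}

#' Build the segmentation network
#'
#' Instantiates the network described by a [unet_spec()] with seeded
#' fan-in-uniform weight initialization (batch-norm scale 1 / shift 0).
#' 3x3 convolutions use stride 1 and zero padding so every block preserves
#' spatial size; per operation the order is convolution, rectifier, batch
#' normalization.
#'
#' @param spec a [unet_spec()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `unet_model`.
#' @export
build_unet <- function(spec = unet_spec(), seed = 0L) {
  stopifnot(inherits(spec, "unet_spec"))
  ptr <- cpp_unet_create(spec$contraction_channels,
                         spec$bottleneck_channels,
                         spec$final_intermediate_channels,
                         spec$num_classes, as.integer(seed))
  structure(list(ptr = ptr, spec = spec, seed = as.integer(seed)),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("U-Net (%dx%d input, %s contraction channels, %d bottleneck, %d classes)\n",
              x$spec$input_size[1], x$spec$input_size[2],
              paste(x$spec$contraction_channels, collapse = "/"),
              x$spec$bottleneck_channels, x$spec$num_classes))
  cat(sprintf("  trainable parameters: %s\n",
              format(cpp_unet_num_params(x$ptr), big.mark = ",")))
  invisible(x)
}

#' Per-block parameter audit of a built network
#'
#' Counts the trainable parameters of every parameter-bearing operation by
#' inspecting the actual tensor shapes of the model: each 3x3 or 1x1
#' convolution row includes its bias and the two affine batch-norm
#' parameters per channel; transposed-convolution rows include the bias
#' only.
#'
#' @param model a `unet_model` from [build_unet()].
#' @return data frame with `block`, `operation` and `params` columns; the
#'   grand total is in attribute `"total"`.
#' @export
audit_parameters <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  df <- cpp_unet_audit(model$ptr)
  attr(df, "total") <- sum(df$params)
  df
}

#' Closed-form parameter audit of a U-Net spec
#'
#' The analytic parameter counts implied by a [unet_spec()]:
#' `9*cin*cout + cout + 2*cout` for a 3x3 convolution + batch norm,
#' `cin*cout + cout + 2*cout` for the 1x1 convolution + batch norm and
#' `4*cin*cout + cout` for a 2x2 transposed convolution with bias.  Used as
#' an independent cross-check of [audit_parameters()].
#'
#' @param spec a [unet_spec()].
#' @return data frame shaped like [audit_parameters()].
#' @export
audit_reference <- function(spec = unet_spec()) {
  stopifnot(inherits(spec, "unet_spec"))
  conv3 <- function(cin, cout) 9 * cin * cout + cout + 2 * cout
  conv1 <- function(cin, cout) cin * cout + cout + 2 * cout
  convt <- function(cin, cout) 4 * cin * cout + cout
  enc <- spec$contraction_channels
  L <- length(enc)
  bott <- spec$bottleneck_channels
  op3 <- "Conv2d 3x3, ReLU, BatchNorm2d"
  rows <- list()
  cin <- 1L
  for (i in seq_len(L)) {
    blk <- paste("Contraction", i)
    rows[[length(rows) + 1]] <- data.frame(block = blk, operation = op3,
                                           params = conv3(cin, enc[i]))
    rows[[length(rows) + 1]] <- data.frame(block = blk, operation = op3,
                                           params = conv3(enc[i], enc[i]))
    cin <- enc[i]
  }
  rows[[length(rows) + 1]] <- data.frame(block = "Bottleneck", operation = op3,
                                         params = conv3(enc[L], bott))
  rows[[length(rows) + 1]] <- data.frame(block = "Bottleneck", operation = op3,
                                         params = conv3(bott, bott))
  rows[[length(rows) + 1]] <- data.frame(block = "Bottleneck",
                                         operation = "ConvTranspose2d",
                                         params = convt(bott, bott))
  for (j in seq_len(L)) {
    upch <- if (j == 1) bott else enc[L - j + 2]
    skch <- enc[L - j + 1]
    blk <- paste("Expansion", L - j + 1)
    rows[[length(rows) + 1]] <- data.frame(block = blk, operation = op3,
                                           params = conv3(upch + skch, skch))
    rows[[length(rows) + 1]] <- data.frame(block = blk, operation = op3,
                                           params = conv3(skch, skch))
    if (j < L)
      rows[[length(rows) + 1]] <- data.frame(block = blk,
                                             operation = "ConvTranspose2d",
                                             params = convt(skch, skch))
  }
  rows[[length(rows) + 1]] <- data.frame(
    block = "Final", operation = op3,
    params = conv3(enc[1], spec$final_intermediate_channels))
  rows[[length(rows) + 1]] <- data.frame(
    block = "Final", operation = "Conv2d 1x1, ReLU, BatchNorm2d",
    params = conv1(spec$final_intermediate_channels, spec$num_classes))
  df <- do.call(rbind, rows)
  attr(df, "total") <- sum(df$params)
  df
}

frames_to_array <- function(frames) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.array(frames) && length(dim(frames)) == 3) return(frames)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  arr <- array(0, c(h, w, length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
  arr
}

#' Predict a label map for one or more normalized frames
#'
#' Runs the network in inference mode (batch norm uses running statistics)
#' and assigns each pixel the class with the highest score; ties break to
#' the lowest class index, so a network with an all-zero final layer yields
#' a constant background map.
#'
#' @param model a `unet_model`.
#' @param frame a numeric matrix in `[0, 1]` whose size matches the spec's
#'   `input_size`, a list of such matrices, or an (H, W, N) array.
#' @return an integer label map (matrix), or a list of them for batched
#'   input.
#' @export
predict_labelmap <- function(model, frame) {
  stopifnot(inherits(model, "unet_model"))
  single <- is.matrix(frame)
  arr <- frames_to_array(frame)
  if (!all(dim(arr)[1:2] == model$spec$input_size))
    stop(sprintf("frame size %dx%d does not match the spec input size %dx%d",
                 dim(arr)[1], dim(arr)[2],
                 model$spec$input_size[1], model$spec$input_size[2]))
  if (min(arr) < 0 || max(arr) > 1)
    stop("frame values must be normalized to [0, 1]")
  labs <- cpp_unet_predict(model$ptr, arr)
  if (single) return(matrix(labs[, , 1], dim(arr)[1], dim(arr)[2]))
  lapply(seq_len(dim(arr)[3]), function(i)
    matrix(labs[, , i], dim(arr)[1], dim(arr)[2]))
}

#' Extract the weights of a model
#'
#' Named list of weight matrices (plus batch-norm running statistics),
#' suitable for [set_unet_weights()] and for checkpointing with
#' [save_unet()].
#'
#' @param model a `unet_model`.
#' @return named list.
#' @export
get_unet_weights <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  cpp_unet_get_weights(model$ptr)
}

#' Overwrite the weights of a model
#'
#' @param model a `unet_model`.
#' @param weights named list as returned by [get_unet_weights()].
#' @return the model, invisibly.
#' @export
set_unet_weights <- function(model, weights) {
  stopifnot(inherits(model, "unet_model"))
  cpp_unet_set_weights(model$ptr, weights)
  invisible(model)
}

#' Save / load a self-describing model checkpoint
#'
#' The checkpoint embeds the [unet_spec()] together with the weights, so a
#' loaded checkpoint rebuilds the exact architecture.
#'
#' @param model a `unet_model`.
#' @param path file path.
#' @return `save_unet` returns `path` invisibly; `load_unet` returns a
#'   `unet_model`.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(list(spec = model$spec, seed = model$seed,
               weights = get_unet_weights(model)), path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  ck <- readRDS(path)
  model <- build_unet(ck$spec, seed = ck$seed)
  set_unet_weights(model, ck$weights)
  model
}
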