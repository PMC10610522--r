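# shared internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Coerce a mask argument (logical / 0-1 numeric matrix) to a logical matrix.
as_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("'%s' must be a matrix", arg))
  if (is.logical(mask)) return(mask)
  matrix(mask != 0, nrow = nrow(mask))
}

# Largest 8-connected foreground component of a logical matrix; all-FALSE
# matrix if the mask is empty.  Ties broken by lowest component label.
largest_component <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(mask))
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# n x 2 matrix of 0-based (x = col, y = row) coordinates of TRUE pixels
mask_coords <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  cbind(x = w[, 2] - 1L, y = w[, 1] - 1L)
}

stopifnot_same_size <- function(a, b, what = "inputs") {
  if (!all(dim(a)[1:2] == dim(b)[1:2])) {
    stop(sprintf("%s must have identical dimensions (%s vs %s)", what,
                 paste(dim(a)[1:2], collapse = "x"),
                 paste(dim(b)[1:2], collapse = "x")))
  }
}

is_count <- function(x, min = 0) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= min &&
    x == round(x)
}
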