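#' Read and write frames and label-map masks as PNG
#'
#' Frames are written as 8-bit grayscale PNG.  Label maps are written as
#' 8-bit grayscale PNG with the raw class ids 0-4 as pixel values (they
#' look nearly black in a viewer; multiply by 60 for inspection) and read
#' back exactly.  Binary cone masks use 0/255.
#'
#' @param frame integer matrix, 0-255.
#' @param labels integer label map, values 0-255 (classes 0-4 in practice).
#' @param mask logical matrix.
#' @param path file path.
#' @return writers return `path` invisibly; readers return an integer or
#'   logical matrix.
#' @name png_io
NULL

#' @rdname png_io
#' @export
write_frame_png <- function(frame, path) {
  stopifnot(is.matrix(frame))
  png::writePNG(pmin(pmax(frame, 0), 255) / 255, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' @rdname png_io
#' @export
write_mask_png <- function(labels, path) {
  stopifnot(is.matrix(labels))
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' @rdname png_io
#' @export
write_binary_mask_png <- function(mask, path) {
  png::writePNG(as_mask(mask) * 1, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_binary_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(img > 0.5, nrow(img), ncol(img))
}
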