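#' Smooth a scan-cone mask
#'
#' Refines a raw cone (scan-sector) detection mask so that it keeps the
#' regular shape of the cone beam: the largest connected component is kept,
#' its boundary is low-pass filtered by a morphological closing followed by
#' an opening with a disc of diameter 5 px, and interior holes are filled.
#' The result is a single connected, hole-free component.
#'
#' @param mask binary matrix (logical or 0/1), nonempty.
#' @return logical matrix, the refined mask.
#' @export
smooth_cone_mask <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("cone mask is empty")
  m <- largest_component(mask)
  brush <- EBImage::makeBrush(5, shape = "disc")
  img <- EBImage::Image(m * 1)
  img <- EBImage::opening(EBImage::closing(img, brush), brush)
  img <- EBImage::fillHull(img)
  out <- as_mask(matrix(EBImage::imageData(img), nrow = nrow(mask)))
  if (!any(out)) {
    # degenerate input thinner than the structuring element: fall back to
    # the hole-filled largest component
    out <- as_mask(matrix(EBImage::imageData(
      EBImage::fillHull(EBImage::Image(m * 1))), nrow = nrow(mask)))
  }
  largest_component(out)
}

#' Dilate a cone mask
#'
#' Grows the mask with a 3x3 rectangular structuring element to improve the
#' corners of the cone beam.
#'
#' @param mask binary matrix, nonempty.
#' @param iterations number of dilation passes (>= 1).
#' @return logical matrix containing the input.
#' @export
dilate_cone_mask <- function(mask, iterations = 2L) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("cone mask is empty")
  if (!is_count(iterations, min = 1)) stop("iterations must be >= 1")
  brush <- EBImage::makeBrush(3, shape = "box")
  img <- EBImage::Image(mask * 1)
  for (i in seq_len(iterations)) img <- EBImage::dilate(img, brush)
  as_mask(matrix(EBImage::imageData(img), nrow = nrow(mask)))
}

#' Apply a cone mask to a frame
#'
#' Keeps pixel values inside the mask and zeroes everything outside,
#' removing on-screen annotations and other out-of-cone artifacts.
#'
#' @param frame numeric/integer matrix.
#' @param mask binary matrix of the same size, nonempty.
#' @return matrix of the same type as `frame`.
#' @export
apply_cone <- function(frame, mask) {
  if (!is.matrix(frame)) stop("frame must be a matrix")
  mask <- as_mask(mask)
  stopifnot_same_size(frame, mask, "frame and mask")
  if (!any(mask)) stop("cone mask is empty")
  out <- frame
  out[!mask] <- 0L
  out
}

# fill the convex polygon with 0-based vertex coordinates (x, y) by row scan
fill_convex_polygon <- function(verts, h, w) {
  out <- matrix(FALSE, h, w)
  vy <- verts[, "y"]; vx <- verts[, "x"]
  n <- length(vy)
  for (r in max(0, floor(min(vy))):min(h - 1, ceiling(max(vy)))) {
    xs <- numeric(0)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- vy[i]; y2 <- vy[j]
      if ((y1 <= r && y2 >= r) || (y2 <= r && y1 >= r)) {
        if (y1 == y2) {
          xs <- c(xs, vx[i], vx[j])
        } else {
          xs <- c(xs, vx[i] + (r - y1) / (y2 - y1) * (vx[j] - vx[i]))
        }
      }
    }
    if (length(xs) >= 1) {
      c0 <- max(0, ceiling(min(xs) - 1e-9))
      c1 <- min(w - 1, floor(max(xs) + 1e-9))
      if (c1 >= c0) out[r + 1, (c0:c1) + 1] <- TRUE
    }
  }
  out
}

#' Extract a cone mask geometrically from a frame
#'
#' A weight-free stand-in for a learned cone detector: the frame is
#' thresholded with Otsu's method, the largest connected bright component is
#' selected, and its filled convex hull is returned (the scan sector is
#' convex, so the hull recovers the full sector including dark cavities
#' inside it).  Deterministic and parameter-free.
#'
#' @param frame numeric/integer matrix with 8-bit values (0-255).
#' @return logical cone mask.
#' @export
extract_cone_geometric <- function(frame) {
  if (!is.matrix(frame)) stop("frame must be a matrix")
  img <- frame / 255
  th <- EBImage::otsu(EBImage::Image(img))
  bw <- img > th
  if (!any(bw)) stop("frame is entirely below the detection threshold")
  comp <- largest_component(bw)
  pts <- mask_coords(comp)
  hull <- pts[chull(pts[, "x"], pts[, "y"]), , drop = FALSE]
  filled <- fill_convex_polygon(hull, nrow(frame), ncol(frame))
  filled | comp
}
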