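#' Parameters of the heuristic overlap correction
#'
#' The cut thresholds are Euclidean distances, in pixels of a
#' `reference_size` (default 128x128) working frame, between the ventricle's
#' top extreme point and the atrium's bottom extreme point on one side.
#' Overlaps whose extreme distance is below the side's threshold are treated
#' as regular anatomical overlap and ignored; above it, the ventricle mask
#' is cut.  When a label map arrives at another resolution the thresholds
#' are rescaled proportionally to the frame diagonal.
#'
#' @param right_threshold cut threshold for the right-side pair (classes
#'   3/4), pixels.
#' @param left_threshold cut threshold for the left-side pair (classes 1/2),
#'   pixels.
#' @param erosion_kernel side length of the square structuring element used
#'   by [erode_for_display()].
#' @param erosion_iterations erosion passes for display (>= 0).
#' @param reference_size frame size at which the thresholds are defined.
#' @return an object of class `correction_params`.
#' @export
correction_params <- function(right_threshold = 68.5,
                              left_threshold = 76.5,
                              erosion_kernel = 3L,
                              erosion_iterations = 1L,
                              reference_size = c(128L, 128L)) {
  if (right_threshold <= 0 || left_threshold <= 0)
    stop("thresholds must be > 0")
  if (!is_count(erosion_iterations, min = 0))
    stop("erosion_iterations must be a non-negative integer")
  structure(list(right_threshold = right_threshold,
                 left_threshold = left_threshold,
                 erosion_kernel = as.integer(erosion_kernel),
                 erosion_iterations = as.integer(erosion_iterations),
                 reference_size = as.integer(reference_size)),
            class = "correction_params")
}

chamber_side <- function(class_id) if (class_id %in% c(1L, 2L)) "left" else "right"
chamber_role <- function(class_id) if (class_id %in% c(1L, 3L)) "ventricle" else "atrium"

# build a chamber_mask object from a logical mask; extremes are 0-based
# (x = col, y = row); ties on the extreme row resolved to the smallest column
new_chamber_mask <- function(class_id, mask) {
  pts <- which(mask, arr.ind = TRUE)
  rmin <- min(pts[, 1]); rmax <- max(pts[, 1])
  top <- c(x = min(pts[pts[, 1] == rmin, 2]) - 1, y = rmin - 1)
  bottom <- c(x = min(pts[pts[, 1] == rmax, 2]) - 1, y = rmax - 1)
  structure(list(class_id = as.integer(class_id),
                 side = chamber_side(class_id),
                 role = chamber_role(class_id),
                 mask = mask, top = top, bottom = bottom,
                 area = sum(mask)),
            class = "chamber_mask")
}

#' Extract per-chamber masks from a label map
#'
#' Returns one `chamber_mask` per class present in the map, each reduced to
#' its largest connected component (the remedy for predictions that emit
#' more than one mask fragment per chamber).  Absent classes are simply
#' omitted; downstream operations skip sides with a missing chamber.
#'
#' @param label_map integer matrix valued 0-4.
#' @return named list of `chamber_mask` objects, names `"1"`-`"4"`.
#' @export
extract_chambers <- function(label_map) {
  stopifnot(is.matrix(label_map))
  if (!all(label_map %in% 0:4)) stop("label map must be valued in 0..4")
  out <- list()
  for (cls in 1:4) {
    m <- label_map == cls
    if (!any(m)) next
    out[[as.character(cls)]] <- new_chamber_mask(cls, largest_component(m))
  }
  out
}

check_pair <- function(ventricle, atrium) {
  stopifnot(inherits(ventricle, "chamber_mask"), inherits(atrium, "chamber_mask"))
  if (ventricle$role != "ventricle" || atrium$role != "atrium")
    stop("arguments must be a ventricle mask and an atrium mask")
  if (ventricle$side != atrium$side)
    stop(sprintf("side mismatch: ventricle is %s-side, atrium is %s-side",
                 ventricle$side, atrium$side))
}

#' Test for anatomically impossible ventricle/atrium overlap
#'
#' TRUE when the ventricle mask extends strictly below the top of its
#' same-side atrium mask, i.e. the ventricle's maximum y exceeds the
#' atrium's minimum y (row index increases downward).
#'
#' @param ventricle,atrium `chamber_mask` objects of the same side.
#' @return logical.
#' @export
overlap_test <- function(ventricle, atrium) {
  check_pair(ventricle, atrium)
  unname(ventricle$bottom["y"] > atrium$top["y"])
}

extreme_point <- function(obj, which) {
  if (inherits(obj, "chamber_mask")) return(obj[[which]])
  if (is.numeric(obj) && length(obj) == 2)
    return(c(x = obj[[1]], y = obj[[2]]))
  stop("expected a chamber_mask or a length-2 (x, y) point")
}

#' Distance between the chamber-extreme points of a ventricle/atrium pair
#'
#' The Euclidean distance between the two most extreme points of the pair:
#' the ventricle's topmost pixel and the atrium's bottommost pixel.  This
#' spans the combined vertical extent of the two chambers and is what the
#' side thresholds of [correction_params()] are compared against.  Either
#' argument may also be given directly as a 0-based `(x, y)` point.
#'
#' @param ventricle `chamber_mask` (its top extreme is used) or `(x, y)`.
#' @param atrium `chamber_mask` (its bottom extreme is used) or `(x, y)`.
#' @return distance in pixels, full precision.
#' @export
extreme_distance <- function(ventricle, atrium) {
  p <- extreme_point(ventricle, "top")
  q <- extreme_point(atrium, "bottom")
  if (inherits(ventricle, "chamber_mask") && inherits(atrium, "chamber_mask"))
    check_pair(ventricle, atrium)
  sqrt(sum((p - q)^2))
}

#' Cut the overlapping part of a ventricle mask
#'
#' Removes every ventricle pixel with row index greater than or equal to
#' the atrium's top row (the reference line of the overlap test).  Raises
#' an error if this would erase the whole ventricle, which signals a
#' pathological prediction the heuristic cannot fix.
#'
#' @param ventricle,atrium `chamber_mask` objects of the same side;
#'   [overlap_test()] must be TRUE.
#' @return the cut ventricle `chamber_mask` (atrium is never modified).
#' @export
apply_cut <- function(ventricle, atrium) {
  check_pair(ventricle, atrium)
  if (!overlap_test(ventricle, atrium))
    stop("apply_cut called without a detected overlap")
  cut_rows <- (atrium$top[["y"]] + 1):nrow(ventricle$mask)  # 1-based rows
  m <- ventricle$mask
  m[cut_rows, ] <- FALSE
  if (!any(m))
    stop("cut would erase the whole ventricle mask (total erasure)")
  new_chamber_mask(ventricle$class_id, m)
}

empty_side_report <- function() {
  list(overlap_detected = FALSE, distance = NA_real_, cut_applied = FALSE,
       pixels_removed = 0L, total_erasure = FALSE)
}

#' Heuristically correct a predicted label map
#'
#' For each side (left pair 1/2, right pair 3/4) independently: if the
#' ventricle mask overlaps its atrium ([overlap_test()]) and the
#' chamber-extreme distance ([extreme_distance()]) exceeds the side's
#' threshold, the ventricle's largest connected component is cut at the
#' atrium's top row; smaller overlaps are assumed to be regular anatomical
#' overlap and left untouched.  A cut that would erase the whole ventricle
#' is not applied and is flagged in the report instead.  Classes on a side
#' where no cut fires are returned bit-identical.
#'
#' Thresholds are rescaled by the ratio of the map's diagonal to the
#' diagonal of `params$reference_size`.
#'
#' @param label_map integer matrix valued 0-4.
#' @param params a [correction_params()].
#' @return list with `labels` (corrected map) and `report` (per-side list
#'   with `overlap_detected`, `distance`, `cut_applied`, `pixels_removed`,
#'   `total_erasure`).
#' @export
correct_labelmap <- function(label_map, params = correction_params()) {
  stopifnot(is.matrix(label_map))
  scale <- sqrt(sum(dim(label_map)^2)) / sqrt(sum(params$reference_size^2))
  thresholds <- c(left = params$left_threshold * scale,
                  right = params$right_threshold * scale)
  chambers <- extract_chambers(label_map)
  out <- label_map
  report <- list(left = empty_side_report(), right = empty_side_report())
  for (side in c("left", "right")) {
    v_id <- if (side == "left") "1" else "3"
    a_id <- if (side == "left") "2" else "4"
    v <- chambers[[v_id]]; a <- chambers[[a_id]]
    if (is.null(v) || is.null(a)) next
    rep_ <- empty_side_report()
    rep_$overlap_detected <- overlap_test(v, a)
    rep_$distance <- extreme_distance(v, a)
    if (rep_$overlap_detected && rep_$distance > thresholds[[side]]) {
      cut_rows <- (a$top[["y"]] + 1):nrow(label_map)
      remove <- v$mask
      remove[-cut_rows, ] <- FALSE
      if (sum(v$mask) - sum(remove) == 0L) {
        rep_$total_erasure <- TRUE
      } else {
        out[remove] <- 0L
        rep_$cut_applied <- TRUE
        rep_$pixels_removed <- sum(remove)
      }
    }
    report[[side]] <- rep_
  }
  list(labels = out, report = report)
}

#' Erode all chamber masks for display
#'
#' Applies the same square-element binary erosion to every chamber mask,
#' growing the background; class identities are preserved.  Because every
#' mask is eroded with the same element, congruent chambers keep their area
#' ratio exactly.
#'
#' @param label_map integer matrix valued 0-4.
#' @param params a [correction_params()]; uses `erosion_kernel` and
#'   `erosion_iterations` (0 iterations returns the input unchanged).
#' @return the eroded label map.
#' @export
erode_for_display <- function(label_map, params = correction_params()) {
  stopifnot(is.matrix(label_map))
  if (params$erosion_iterations == 0L) return(label_map)
  brush <- EBImage::makeBrush(params$erosion_kernel, shape = "box")
  out <- matrix(0L, nrow(label_map), ncol(label_map))
  for (cls in 1:4) {
    m <- label_map == cls
    if (!any(m)) next
    img <- EBImage::Image(m * 1)
    for (i in seq_len(params$erosion_iterations))
      img <- EBImage::erode(img, brush)
    out[as_mask(matrix(EBImage::imageData(img), nrow = nrow(label_map)))] <- cls
  }
  out
}
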