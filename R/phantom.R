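#' Configuration for the synthetic echocardiogram phantom
#'
#' Describes the geometry and noise of a synthetic apical four-chamber
#' B-mode frame: a scan cone (sector) with its apex near the top of the
#' frame, four elliptical chamber cavities (ventricles above atria, one
#' ventricle/atrium pair per side), constant-intensity artifact bands above
#' the apex emulating on-screen text/trace burn-ins, and multiplicative
#' speckle.
#'
#' Chamber classes follow the package convention: 1 left ventricle, 2 left
#' atrium, 3 right ventricle, 4 right atrium.  "Left" chambers are drawn on
#' the image right, as in the clinical display convention; the sides are
#' pure class labels and can be mirrored via `left_on_image_right`.
#'
#' @param frame_size integer (height, width) in pixels, at least 64x64.
#' @param cone_apex 0-based (x, y) pixel coordinate of the sector apex;
#'   default top-center, `y = round(0.03 * height)`.
#' @param cone_half_angle half opening angle of the sector, degrees.
#' @param cone_depth sector radius in pixels; default reaches 4 px above the
#'   bottom edge.
#' @param speckle_scale dimensionless speckle strength in `[0, 1]`; 0 gives a
#'   noiseless piecewise-constant frame.
#' @param tissue_intensity myocardium/tissue intensity inside the cone, 0-1.
#' @param band_intensity intensity of the artifact bands, 0-1.
#' @param artifact_bands list of 0-based `c(row0, row1, col0, col1)`
#'   rectangles outside the cone, or `NULL` for the default two horizontal
#'   strips above the apex.
#' @param left_on_image_right logical; clinical display mirroring.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(frame_size = c(112L, 112L),
                           cone_apex = NULL,
                           cone_half_angle = 35,
                           cone_depth = NULL,
                           speckle_scale = 0.35,
                           tissue_intensity = 0.55,
                           band_intensity = 0.8,
                           artifact_bands = NULL,
                           left_on_image_right = TRUE) {
  frame_size <- as.integer(frame_size)
  if (length(frame_size) != 2 || any(frame_size < 64))
    stop("frame_size must be (height, width) with both >= 64")
  h <- frame_size[1]; w <- frame_size[2]
  if (is.null(cone_apex)) cone_apex <- c(x = (w - 1) / 2, y = round(0.03 * h))
  if (is.null(cone_depth)) cone_depth <- h - cone_apex[["y"]] - 4
  if (cone_half_angle <= 0 || cone_half_angle >= 90)
    stop("cone_half_angle must be in (0, 90) degrees")
  if (is.null(artifact_bands)) {
    r2 <- if (cone_apex[["y"]] >= 3) 2L else 1L
    c0 <- round(0.08 * w); c1 <- round(0.92 * w)
    artifact_bands <- list(c(0L, 0L, c0, c1), c(r2, r2, c0, c1))
  }
  structure(list(frame_size = frame_size,
                 cone_apex = cone_apex,
                 cone_half_angle = cone_half_angle,
                 cone_depth = cone_depth,
                 speckle_scale = speckle_scale,
                 tissue_intensity = tissue_intensity,
                 band_intensity = band_intensity,
                 artifact_bands = artifact_bands,
                 left_on_image_right = left_on_image_right),
            class = "phantom_config")
}

#' Read a phantom configuration from a YAML file
#'
#' Keys mirror the arguments of [phantom_config()].
#'
#' @param path path to a YAML file.
#' @return a `phantom_config` object.
#' @export
phantom_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(phantom_config)))
  do.call(phantom_config, vals[keep])
}

# logical cone-sector mask for a config (analytic ground truth)
cone_sector_mask <- function(config) {
  h <- config$frame_size[1]; w <- config$frame_size[2]
  ax <- config$cone_apex[["x"]]; ay <- config$cone_apex[["y"]]
  yy <- matrix(0:(h - 1), h, w)
  xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  dy <- yy - ay; dx <- xx - ax
  r <- sqrt(dx^2 + dy^2)
  ang <- atan2(abs(dx), dy)  # angle from downward vertical
  dy >= 0 & r <= config$cone_depth &
    ang <= config$cone_half_angle * pi / 180
}

# boundary points of a rotated ellipse, 0-based continuous (x, y)
ellipse_boundary <- function(center, semi_axes, rotation, n = 72) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  rot <- rotation * pi / 180
  bx <- semi_axes[1] * cos(t); by <- semi_axes[2] * sin(t)
  cbind(x = center[1] + bx * cos(rot) - by * sin(rot),
        y = center[2] + bx * sin(rot) + by * cos(rot))
}

# logical mask of an ellipse (pixel centers), clipped to the cone
ellipse_mask <- function(chamber, config) {
  h <- config$frame_size[1]; w <- config$frame_size[2]
  yy <- matrix(0:(h - 1), h, w)
  xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  rot <- chamber$rotation * pi / 180
  dx <- xx - chamber$center[1]; dy <- yy - chamber$center[2]
  xr <- dx * cos(rot) + dy * sin(rot)
  yr <- -dx * sin(rot) + dy * cos(rot)
  (xr / chamber$semi_axes[1])^2 + (yr / chamber$semi_axes[2])^2 <= 1
}

points_in_cone <- function(pts, config) {
  ax <- config$cone_apex[["x"]]; ay <- config$cone_apex[["y"]]
  dx <- pts[, "x"] - ax; dy <- pts[, "y"] - ay
  all(dy >= 0 &
        sqrt(dx^2 + dy^2) <= config$cone_depth &
        atan2(abs(dx), dy) <= config$cone_half_angle * pi / 180)
}

# one random chamber spec; geometry fractions chosen to mimic an apical
# four-chamber view in which the chambers span most of the sector depth
draw_chamber <- function(class_id, config) {
  h <- config$frame_size[1]; w <- config$frame_size[2]
  side_left <- class_id %in% c(1L, 2L)    # anatomical left
  on_right <- xor(!side_left, config$left_on_image_right)
  cx <- (if (on_right) 0.60 else 0.40) * w + runif(1, -0.02, 0.02) * w
  if (class_id %in% c(1L, 3L)) {          # ventricle
    cy <- runif(1, 0.42, 0.46) * h
    a <- runif(1, 0.075, 0.095) * w
    b <- runif(1, 0.120, 0.145) * h
  } else {                                # atrium
    cy <- runif(1, 0.74, 0.78) * h
    a <- runif(1, 0.070, 0.090) * w
    b <- runif(1, 0.085, 0.110) * h
  }
  list(class_id = class_id,
       center = c(x = cx, y = cy),
       semi_axes = c(a = a, b = b),
       rotation = runif(1, -10, 10),
       intensity = runif(1, 0.06, 0.18))
}

#' Generate a random phantom scene
#'
#' Draws four chamber ellipses inside the scan cone under the anatomical
#' constraints of the apical four-chamber view: each ventricle center lies
#' strictly above its same-side atrium center, every ellipse lies fully
#' inside the cone sector, and the rendered chamber regions are pairwise
#' disjoint (with at least one background pixel of separation).  Placement
#' is rejection-sampled; configurations that cannot satisfy the constraints
#' raise an error naming the first violated constraint.
#'
#' The same `(config, seed)` pair always yields the same scene.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @param max_attempts rejection-sampling budget.
#' @return an object of class `phantom_scene`.
#' @export
generate_scene <- function(config = phantom_config(), seed = 0L,
                           max_attempts = 300L) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is_count(seed, min = -Inf)) stop("seed must be a single integer")
  with_seed(seed, {
    last_fail <- "no attempt made"
    for (attempt in seq_len(max_attempts)) {
      chambers <- lapply(1:4, draw_chamber, config = config)
      ok <- TRUE
      for (ch in chambers) {
        if (!points_in_cone(ellipse_boundary(ch$center, ch$semi_axes,
                                             ch$rotation), config)) {
          last_fail <- sprintf("chamber %d ellipse not inside the cone sector",
                               ch$class_id)
          ok <- FALSE
          break
        }
      }
      if (ok) {
        for (side in list(c(1L, 2L), c(3L, 4L))) {
          v <- chambers[[side[1]]]; a <- chambers[[side[2]]]
          if (v$center[["y"]] >= a$center[["y"]]) {
            last_fail <- sprintf(
              "ventricle %d center not above atrium %d center",
              side[1], side[2])
            ok <- FALSE
          }
        }
      }
      if (ok) {
        masks <- lapply(chambers, ellipse_mask, config = config)
        grown <- lapply(masks, function(m)
          as_mask(EBImage::imageData(EBImage::dilate(
            EBImage::Image(m * 1), EBImage::makeBrush(3, "box")))))
        for (i in 1:3) for (j in (i + 1):4) {
          if (any(grown[[i]] & masks[[j]])) {
            last_fail <- sprintf("chambers %d and %d touch or overlap", i, j)
            ok <- FALSE
          }
        }
      }
      if (ok) {
        return(structure(list(frame_size = config$frame_size,
                              cone_apex = config$cone_apex,
                              cone_half_angle = config$cone_half_angle,
                              cone_depth = config$cone_depth,
                              chambers = chambers,
                              artifact_bands = config$artifact_bands,
                              speckle_scale = config$speckle_scale,
                              tissue_intensity = config$tissue_intensity,
                              band_intensity = config$band_intensity,
                              seed = as.integer(seed),
                              config = config),
                         class = "phantom_scene"))
      }
    }
    stop(sprintf("could not place chambers after %d attempts; last failure: %s",
                 max_attempts, last_fail))
  })
}

#' Render a phantom scene to a frame and its ground-truth label map
#'
#' Pixels outside the cone are 0 except the artifact bands.  Inside the
#' cone, tissue and chamber intensities are multiplied by a spatially
#' correlated speckle field: unit-mean Rayleigh noise mixed in with weight
#' `speckle_scale` and smoothed with a Gaussian of sigma 1 px.  With
#' `speckle_scale = 0` the frame is piecewise constant.
#'
#' @param scene a `phantom_scene` from [generate_scene()].
#' @return a list with `frame` (integer matrix, 0-255), `labels` (integer
#'   label map, 0-4) and `cone` (logical analytic sector mask).
#' @export
render_phantom <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  config <- scene$config
  h <- scene$frame_size[1]; w <- scene$frame_size[2]
  cone <- cone_sector_mask(config)
  labels <- matrix(0L, h, w)
  img <- matrix(0, h, w)
  img[cone] <- scene$tissue_intensity
  for (ch in scene$chambers) {
    m <- ellipse_mask(ch, config) & cone
    labels[m] <- ch$class_id
    img[m] <- ch$intensity
  }
  if (scene$speckle_scale > 0) {
    noise <- with_seed(scene$seed + 77777L, {
      u <- matrix(runif(h * w), h, w)
      r <- sqrt(-(4 / pi) * log(u))       # Rayleigh, unit mean
      1 + scene$speckle_scale * (r - 1)
    })
    noise <- EBImage::imageData(EBImage::gblur(EBImage::Image(noise),
                                               sigma = 1))
    noise <- pmax(matrix(noise, h, w), 0)
    img[cone] <- img[cone] * noise[cone]
  }
  for (b in scene$artifact_bands) {
    rows <- (b[1]:b[2]) + 1L; cols <- (b[3]:b[4]) + 1L
    sel <- matrix(FALSE, h, w); sel[rows, cols] <- TRUE
    img[sel & !cone] <- scene$band_intensity
  }
  frame <- matrix(as.integer(round(255 * pmin(pmax(img, 0), 1))), h, w)
  list(frame = frame, labels = labels, cone = cone)
}

#' Inject a segmentation "leak" defect into a label map
#'
#' Extends the `from_class` chamber region by a connected protrusion of
#' approximately `extent` rows toward (and possibly past) the adjacent
#' same-side chamber -- downward for a ventricle, upward for an atrium --
#' overwriting only background pixels.  This emulates the defect in which a
#' predicted ventricle mask wraps around its atrium.
#'
#' The protrusion is grown by geodesic dilation of the chamber mask inside
#' a background corridor that runs from the chamber's extreme point along
#' the adjacent chamber's nearest flank, so the result is always one
#' connected component that hugs (and can pass) the neighboring chamber.
#'
#' @param label_map integer label map (0-4).
#' @param from_class chamber class 1-4 whose mask leaks.
#' @param extent protrusion length in rows; 0 returns the input unchanged.
#' @param seed integer seed for the corridor-width jitter.
#' @return the modified label map.
#' @export
inject_leak <- function(label_map, from_class, extent, seed = 0L) {
  stopifnot(is.matrix(label_map))
  from_class <- as.integer(from_class)
  if (!from_class %in% 1:4) stop("from_class must be 1, 2, 3 or 4")
  if (extent < 0) stop("extent must be >= 0")
  if (extent == 0) return(label_map)
  adjacent <- c(2L, 1L, 4L, 3L)[from_class]
  if (!any(label_map == from_class))
    stop(sprintf("class %d not present in the label map", from_class))
  if (!any(label_map == adjacent))
    stop(sprintf("adjacent chamber (class %d) cannot be identified", adjacent))
  h <- nrow(label_map); w <- ncol(label_map)
  down <- from_class %in% c(1L, 3L)       # ventricles leak downward
  pts <- which(label_map == from_class, arr.ind = TRUE)
  r0 <- if (down) max(pts[, 1]) else min(pts[, 1])
  c0 <- min(pts[pts[, 1] == r0, 2])
  adj_pts <- which(label_map == adjacent, arr.ind = TRUE)
  adj_l <- min(adj_pts[, 2]); adj_r <- max(adj_pts[, 2])
  # run the corridor along the adjacent chamber's nearest flank; keeping
  # columns beyond that flank inside the corridor guarantees an open,
  # connected channel past the chamber
  edge <- if (abs(c0 - adj_l) <= abs(c0 - adj_r)) adj_l else adj_r
  jitter <- with_seed(seed, sample(0:2, 1))
  cl <- min(c0 - 2L, edge - 5L - jitter)
  cr <- max(c0 + 2L, edge + 5L + jitter)
  if (edge == adj_l) cr <- min(cr, max(c0 + 2L, adj_l + 2L))
  else cl <- max(cl, min(c0 - 2L, adj_r - 2L))
  cl <- max(1L, cl); cr <- min(w, cr)
  rows <- if (down) (r0 + 1L):min(h, r0 + extent)
          else max(1L, r0 - extent):(r0 - 1L)
  allowed <- matrix(FALSE, h, w)
  allowed[rows, cl:cr] <- TRUE
  allowed <- allowed & label_map == 0L
  grown <- label_map == from_class
  brush <- EBImage::makeBrush(3, "box")
  for (i in seq_len(extent + (cr - cl) + 8L)) {
    nxt <- as_mask(EBImage::imageData(EBImage::dilate(EBImage::Image(grown * 1),
                                                      brush)),
                   "grown")
    nxt <- (nxt & allowed) | grown
    if (identical(nxt, grown)) break
    grown <- nxt
  }
  out <- label_map
  out[grown & label_map == 0L] <- from_class
  out
}

#' Generate a batch of phantom frames with ground truth
#'
#' Convenience wrapper producing `n` independent scenes (seeds
#' `seed, seed+1, ...`), their rendered frames and label maps, and -- with
#' probability `leak_prob` -- a defective copy of the label map in which the
#' right ventricle (class 3) leaks past the top of the right atrium, as a
#' stand-in for a faulty prediction.
#'
#' @param n number of frames.
#' @param size frame side length in pixels.
#' @param seed integer seed.
#' @param leak_prob probability that a frame receives a defective copy.
#' @param leak_overshoot rows by which the leak crosses the atrium top.
#' @param config optional [phantom_config()]; overrides `size` when given.
#' @return list of samples, each with `frame`, `labels`, `scene` and (when
#'   leaked) `defect_labels`.
#' @export
generate_phantom_dataset <- function(n, size = 112L, seed = 0L,
                                     leak_prob = 0, leak_overshoot = 25L,
                                     config = NULL) {
  if (is.null(config)) config <- phantom_config(frame_size = c(size, size))
  lapply(seq_len(n), function(i) {
    sc <- generate_scene(config, seed = seed + i - 1L)
    rp <- render_phantom(sc)
    sample <- list(frame = rp$frame, labels = rp$labels, scene = sc)
    do_leak <- leak_prob > 0 &&
      with_seed(seed + i - 1L + 500000L, runif(1)) < leak_prob
    if (do_leak) {
      rv_rows <- which(rp$labels == 3L, arr.ind = TRUE)[, 1]
      ra_rows <- which(rp$labels == 4L, arr.ind = TRUE)[, 1]
      gap <- min(ra_rows) - max(rv_rows)
      sample$defect_labels <- inject_leak(rp$labels, from_class = 3L,
                                          extent = gap + leak_overshoot,
                                          seed = seed + i - 1L + 900000L)
    }
    sample
  })
}
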