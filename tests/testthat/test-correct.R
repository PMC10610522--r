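# build a label map containing rectangles with exactly known extreme points
rect_map <- function(..., h = 128, w = 128) {
  m <- matrix(0L, h, w)
  for (r in list(...)) m[r$rows + 1, r$cols + 1] <- r$class  # 0-based in
  m
}

test_that("extreme distance matches hand-computed values", {
  expect_equal(extreme_distance(c(54, 9), c(45, 80)), sqrt(9^2 + 71^2))
  expect_equal(round(extreme_distance(c(54, 9), c(45, 80)), 1), 71.6)
  expect_equal(extreme_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(extreme_distance(c(7, 7), c(7, 7)), 0)
})

test_that("chamber extremes use min row / max row with lowest-column ties", {
  m <- matrix(0L, 20, 20)
  m[5, 8:12] <- 3L        # several pixels share the top row
  m[6:15, 10] <- 3L
  m[15, 9:11] <- 3L       # several pixels share the bottom row
  ch <- extract_chambers(m)[["3"]]
  expect_equal(ch$top, c(x = 7, y = 4))      # 0-based, smallest column
  expect_equal(ch$bottom, c(x = 8, y = 14))
})

test_that("overlap test is a strict comparison of vertical extents", {
  v <- rect_map(h = 100, w = 100,
                list(rows = 5:40, cols = 20:40, class = 3))
  a40 <- rect_map(h = 100, w = 100,
                  list(rows = 50:90, cols = 20:40, class = 4))
  a_overlap <- rect_map(h = 100, w = 100,
                        list(rows = 30:90, cols = 50:70, class = 4))
  ch_v <- extract_chambers(v)[["3"]]
  expect_false(overlap_test(ch_v, extract_chambers(a40)[["4"]]))
  expect_true(overlap_test(ch_v, extract_chambers(a_overlap)[["4"]]))
  # boundary: ventricle bottom equals atrium top -> no overlap
  a_touch <- rect_map(h = 100, w = 100,
                      list(rows = 40:90, cols = 50:70, class = 4))
  expect_false(overlap_test(ch_v, extract_chambers(a_touch)[["4"]]))
  # side mismatch
  lv <- extract_chambers(rect_map(h = 100, w = 100,
                                  list(rows = 5:40, cols = 60:80,
                                       class = 1)))[["1"]]
  expect_error(overlap_test(lv, extract_chambers(a40)[["4"]]), "side")
})

test_that("apply_cut removes exactly the rows at/below the atrium top", {
  # ventricle extending one row past the atrium top: the cut line sits at
  # the atrium's top row, so that row and the one below it are removed
  v <- rect_map(list(rows = 10:51, cols = 20:30, class = 3))
  a <- rect_map(list(rows = 50:90, cols = 35:45, class = 4))
  cv <- extract_chambers(v)[["3"]]; ca <- extract_chambers(a)[["4"]]
  cut <- apply_cut(cv, ca)
  expect_equal(cut$bottom[["y"]], 49)
  expect_equal(sum(cv$mask) - sum(cut$mask), 22)  # two 11-px rows removed
  expect_lt(sum(cut$mask), sum(cv$mask))
  expect_identical(cut$mask[1:50, ], cv$mask[1:50, ])

  # cutting a ventricle entirely below the atrium top is refused
  v2 <- rect_map(list(rows = 60:80, cols = 20:30, class = 3))
  a2 <- rect_map(list(rows = 50:90, cols = 35:45, class = 4))
  expect_error(apply_cut(extract_chambers(v2)[["3"]],
                         extract_chambers(a2)[["4"]]), "erasure")
  # no overlap -> precondition violated
  expect_error(apply_cut(extract_chambers(rect_map(list(rows = 5:20,
                                                        cols = 20:30,
                                                        class = 3)))[["3"]],
                         ca), "overlap")
})

test_that("extract_chambers keeps the largest component per class", {
  m <- matrix(0L, 64, 64)
  m[10:21, 10:19] <- 3L                 # 120 px
  m[40:46, 40] <- 3L                    # 7 px satellite
  ch <- extract_chambers(m)
  expect_equal(ch[["3"]]$area, 120)
  expect_identical(names(ch), "3")
  expect_length(extract_chambers(matrix(0L, 16, 16)), 0)

  lab <- render_phantom(generate_scene(phantom_config(), seed = 2))$labels
  chs <- extract_chambers(lab)
  combined <- matrix(0L, nrow(lab), ncol(lab))
  for (ch in chs) combined[ch$mask] <- ch$class_id
  expect_identical(combined, lab)       # clean maps partition exactly
})

test_that("correct_labelmap applies the documented decision rule", {
  # right-side pair whose extreme points are (54, 9) and (45, 80):
  # distance 71.57 exceeds the right threshold 68.5 -> cut fires
  m <- rect_map(
    list(rows = 9:60, cols = 54:64, class = 3),
    list(rows = 50:80, cols = 45:55, class = 4))
  res <- correct_labelmap(m)
  expect_true(res$report$right$overlap_detected)
  expect_equal(res$report$right$distance, sqrt(9^2 + 71^2))
  expect_true(res$report$right$cut_applied)
  expect_gt(res$report$right$pixels_removed, 0)
  expect_equal(max(which(res$labels == 3, arr.ind = TRUE)[, 1]) - 1, 49)

  # same overlap geometry but vertical span 60 < 68.5 -> regular overlap,
  # ignored
  m2 <- rect_map(
    list(rows = 20:60, cols = 45:64, class = 3),
    list(rows = 50:80, cols = 45:55, class = 4))
  res2 <- correct_labelmap(m2)
  expect_true(res2$report$right$overlap_detected)
  expect_equal(res2$report$right$distance, 60)
  expect_false(res2$report$right$cut_applied)
  expect_identical(res2$labels, m2)

  # untouched map passes through bit-identical with an all-clear report
  clean <- render_phantom(generate_scene(phantom_config(), seed = 4))$labels
  res3 <- correct_labelmap(clean)
  expect_identical(res3$labels, clean)
  expect_equal(res3$report$left$pixels_removed, 0)
  expect_equal(res3$report$right$pixels_removed, 0)
})

test_that("thresholds rescale with the frame diagonal", {
  p <- correction_params()
  # at 64x64 the right threshold shrinks to half of its 128x128 value; a
  # span that would be ignored at 128 is cut at the same relative geometry
  m <- rect_map(h = 64, w = 64,
                list(rows = 5:30, cols = 27:32, class = 3),
                list(rows = 25:40, cols = 22:27, class = 4))
  d <- correct_labelmap(m, p)
  expect_equal(d$report$right$distance,
               extreme_distance(c(27, 5), c(22, 40)))
  expect_true(d$report$right$cut_applied)   # 35.4 > 68.5 * 0.5
})

test_that("correction is idempotent, monotone and side-local on leak phantoms", {
  ds <- leak_set()[1:20]
  for (s in ds) {
    res <- correct_labelmap(s$defect_labels)
    # monotone: no chamber gains pixels
    for (k in 1:4)
      expect_lte(sum(res$labels == k), sum(s$defect_labels == k))
    # locality: the left side never changes (leak was injected on the right)
    for (k in 1:2)
      expect_identical(res$labels == k, s$defect_labels == k)
    # idempotence
    res2 <- correct_labelmap(res$labels)
    expect_identical(res2$labels, res$labels)
    expect_false(res2$report$right$cut_applied)
  }
})

test_that("display erosion shrinks every chamber equally", {
  p <- correction_params(erosion_iterations = 0)
  lab <- render_phantom(generate_scene(phantom_config(), seed = 6))$labels
  expect_identical(erode_for_display(lab, p), lab)

  squares <- rect_map(h = 64, w = 64,
                      list(rows = 5:24, cols = 5:24, class = 1),
                      list(rows = 35:54, cols = 35:54, class = 2))
  er <- erode_for_display(squares, correction_params(erosion_iterations = 1))
  expect_equal(sum(er == 1), 18 * 18)
  expect_equal(sum(er == 2), 18 * 18)
  expect_equal(sum(er == 1) / sum(er == 2), 1)

  er2 <- erode_for_display(lab, correction_params(erosion_iterations = 1))
  for (k in 1:4) {
    expect_lte(sum(er2 == k), sum(lab == k))
    expect_true(all(lab[er2 == k] == k))  # erosion only shrinks in place
  }
})
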