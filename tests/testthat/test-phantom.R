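test_that("scene generation is deterministic and anatomically ordered", {
  cfg <- phantom_config()
  s1 <- generate_scene(cfg, seed = 0)
  s2 <- generate_scene(cfg, seed = 0)
  expect_identical(s1, s2)
  expect_length(s1$chambers, 4)

  r1 <- render_phantom(s1)
  r2 <- render_phantom(s2)
  expect_identical(r1$frame, r2$frame)
  expect_identical(r1$labels, r2$labels)

  for (seed in 0:9) {
    sc <- generate_scene(cfg, seed = seed)
    lab <- render_phantom(sc)$labels
    expect_true(all(lab %in% 0:4))
    expect_true(all(vapply(1:4, function(k) any(lab == k), logical(1))))
    rows <- function(k) which(lab == k, arr.ind = TRUE)[, 1]
    # ventricles strictly above their same-side atria
    expect_lt(min(rows(1)), min(rows(2)))
    expect_lt(min(rows(3)), min(rows(4)))
  }
})

test_that("rendered chamber regions are disjoint and equal ellipse-within-cone", {
  for (seed in 0:4) {
    sc <- generate_scene(phantom_config(), seed = seed)
    rp <- render_phantom(sc)
    areas <- vapply(1:4, function(k) sum(rp$labels == k), numeric(1))
    # single-valued map + per-chamber area accounting against the analytic
    # ellipse-within-cone region means no pixel carries two labels
    for (ch in sc$chambers) {
      analytic <- echoseg:::ellipse_mask(ch, sc$config) & rp$cone
      expect_equal(sum(rp$labels == ch$class_id), sum(analytic))
      expect_true(all(rp$labels[analytic] == ch$class_id))
    }
    expect_equal(sum(areas), sum(rp$labels > 0))
  }
})

test_that("speckle-free rendering is piecewise constant at the spec intensities", {
  cfg <- phantom_config(speckle_scale = 0)
  sc <- generate_scene(cfg, seed = 3)
  rp <- render_phantom(sc)
  for (ch in sc$chambers) {
    vals <- rp$frame[rp$labels == ch$class_id] / 255
    expect_equal(stats::sd(vals), 0)
    expect_lt(abs(mean(vals) - ch$intensity), 1 / 255)
  }
  tissue <- rp$frame[rp$cone & rp$labels == 0]
  expect_equal(stats::sd(tissue), 0)
})

test_that("speckle adds in-cone variance; out-of-cone stays clean", {
  sc <- generate_scene(phantom_config(speckle_scale = 0.35), seed = 3)
  rp <- render_phantom(sc)
  expect_gt(stats::var(rp$frame[rp$cone & rp$labels == 0]), 0)
  # outside the cone everything is 0 except the artifact bands
  outside <- rp$frame
  outside[rp$cone] <- 0L
  for (b in sc$artifact_bands)
    outside[(b[1]:b[2]) + 1, (b[3]:b[4]) + 1] <- 0L
  expect_true(all(outside == 0))
})

test_that("impossible cone geometry is rejected with a named constraint", {
  expect_error(
    generate_scene(phantom_config(cone_half_angle = 1), seed = 0,
                   max_attempts = 20),
    "cone sector")
})

test_that("leak injection extends the chamber without touching other classes", {
  sc <- generate_scene(phantom_config(frame_size = c(128, 128)), seed = 5)
  lab <- render_phantom(sc)$labels

  expect_identical(inject_leak(lab, 3, extent = 0), lab)

  gap <- min(which(lab == 4, arr.ind = TRUE)[, 1]) -
    max(which(lab == 3, arr.ind = TRUE)[, 1])
  leaked <- inject_leak(lab, 3, extent = gap + 25, seed = 1)

  # protrusion crosses the adjacent chamber's top and adds area
  expect_gt(max(which(leaked == 3, arr.ind = TRUE)[, 1]),
            min(which(leaked == 4, arr.ind = TRUE)[, 1]))
  expect_gt(sum(leaked == 3), sum(lab == 3))
  # only background pixels were overwritten; other classes bit-identical
  changed <- leaked != lab
  expect_true(all(lab[changed] == 0))
  expect_true(all(leaked[changed] == 3))
  for (k in c(1, 2, 4)) expect_identical(leaked == k, lab == k)

  expect_error(inject_leak(lab, 5, 10), "from_class")
  expect_error(inject_leak(matrix(0L, 64, 64), 3, 10), "not present")
})

test_that("dataset generation attaches defective copies with leaks", {
  ds <- generate_phantom_dataset(4, size = 112, seed = 2, leak_prob = 1,
                                 leak_overshoot = 20)
  for (s in ds) {
    expect_false(is.null(s$defect_labels))
    expect_gt(sum(s$defect_labels == 3), sum(s$labels == 3))
    expect_identical(s$defect_labels == 4, s$labels == 4)
  }
})

test_that("YAML config round-trips through phantom_config_from_yaml", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("frame_size: [96, 96]", "cone_half_angle: 30",
               "speckle_scale: 0.2"), path)
  cfg <- phantom_config_from_yaml(path)
  expect_s3_class(cfg, "phantom_config")
  expect_identical(cfg$frame_size, c(96L, 96L))
  expect_equal(cfg$cone_half_angle, 30)
  expect_equal(cfg$speckle_scale, 0.2)
})
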