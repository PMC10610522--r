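small_pp <- function(n, seed = 0, size = c(64L, 64L)) {
  ds <- generate_phantom_dataset(n, size = 112, seed = seed)
  lapply(ds, function(s) {
    r <- preprocess(s$frame, s$labels, size = size)
    list(frame = r$frame, labels = r$mask)
  })
}

test_that("preprocessing normalizes, resizes and preserves the label set", {
  out <- preprocess(matrix(128L, 112, 112))
  expect_equal(dim(out$frame), c(128, 128))
  expect_true(all(abs(out$frame - 128 / 255) < 1e-12))

  mask <- matrix(0L, 112, 112); mask[30:60, 40:70] <- 3L
  out2 <- preprocess(matrix(0L, 112, 112), mask)
  expect_equal(dim(out2$mask), c(128, 128))
  expect_true(all(out2$mask %in% c(0L, 3L)))  # nearest-neighbor: no new labels

  expect_error(preprocess(array(0, c(8, 8, 3))), "single-channel")
})

test_that("per-class pixel shares survive the resize within 5 percent", {
  for (seed in 0:4) {
    rp <- render_phantom(generate_scene(phantom_config(), seed = seed))
    resized <- preprocess(rp$frame, rp$labels)$mask
    for (k in 1:4) {
      before <- mean(rp$labels == k)
      after <- mean(resized == k)
      expect_lt(abs(after - before) / before, 0.05)
    }
  }
})

test_that("dataset splitting uses floor allocation with remainder to train", {
  sp <- split_dataset(1:100, c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(lengths(sp), c(train = 80L, val = 10L, test = 10L))
  expect_equal(sort(unname(unlist(sp))), 1:100)  # disjoint and exhaustive

  sp10 <- split_dataset(1:10, seed = 1)
  expect_equal(lengths(sp10), c(train = 8L, val = 1L, test = 1L))

  expect_identical(split_dataset(1:57, seed = 9), split_dataset(1:57, seed = 9))
  expect_false(identical(split_dataset(1:57, seed = 9)$train,
                         split_dataset(1:57, seed = 10)$train))
  expect_error(split_dataset(1:9), "at least 10")
  expect_error(split_dataset(1:20, c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("training configuration validates its fields", {
  cfg <- train_config()
  expect_equal(cfg$batch_size, 8L)
  expect_equal(cfg$epochs, 50L)
  expect_equal(cfg$learning_rate, 1e-3)
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(learning_rate = -1), "learning_rate")
  expect_error(train_config(split_ratios = c(0.6, 0.2, 0.1)), "sum to 1")
})

test_that("fit runs the requested epochs and handles degenerate configs", {
  pp <- small_pp(12)
  sp64 <- unet_spec(input_size = c(64L, 64L))
  data <- list(train = pp[1:8], val = pp[9:12])

  m0 <- build_unet(sp64, seed = 0)
  expect_identical(nrow(fit(m0, data, train_config(epochs = 0))), 0L)

  # zero learning rate: no weight updates, constant training loss
  # (shuffling disabled so each epoch sees identical batch statistics)
  m1 <- build_unet(sp64, seed = 0)
  w_before <- get_unet_weights(m1)
  h <- fit(m1, data, train_config(epochs = 3, learning_rate = 0,
                                  shuffle_each_epoch = FALSE))
  expect_equal(nrow(h), 3L)
  expect_equal(h$train_loss, rep(h$train_loss[1], 3))
  w_after <- get_unet_weights(m1)
  for (nm in c("c1a.W", "b2.W", "fin1.W"))
    expect_identical(w_before[[nm]], w_after[[nm]])

  expect_error(fit(m1, list(train = list(), val = pp[9:12]),
                   train_config(epochs = 1)), "empty")
})

test_that("training loss decreases on phantoms in a short seeded run", {
  pp <- small_pp(24, seed = 100)
  m <- build_unet(unet_spec(input_size = c(64L, 64L)), seed = 0)
  h <- fit(m, list(train = pp[1:20], val = pp[21:24]),
           train_config(epochs = 5, seed = 0))
  expect_equal(nrow(h), 5L)
  expect_lt(h$train_loss[5], h$train_loss[1])
  expect_true(all(is.finite(h$val_loss)))
  expect_true(all(h$val_dice >= 0 & h$val_dice <= 1))
})

test_that("evaluate_on_test scores predictions against ground truth", {
  pp <- small_pp(4, seed = 7)
  m <- build_unet(unet_spec(input_size = c(64L, 64L)), seed = 0)
  # all-background predictor: zero the final classification layer
  w <- get_unet_weights(m)
  w[["fin1.W"]][] <- 0; w[["fin1.b"]][] <- 0
  set_unet_weights(m, w)
  rep_ <- evaluate_on_test(m, pp)
  expect_equal(rep_$n_items, 4)
  expect_true(all(rep_$per_class$dice == 0))       # chambers all missed
  expect_true(all(rep_$per_class$pixel_accuracy == 0))
  expect_error(evaluate_on_test(m, list()), "empty")
})
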