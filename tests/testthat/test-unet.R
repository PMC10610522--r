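tiny_spec <- function() {
  unet_spec(input_size = c(16L, 16L), contraction_channels = c(2L, 3L),
            bottleneck_channels = 4L, final_intermediate_channels = 3L,
            num_classes = 3L)
}

test_that("parameter audit equals the closed-form counts", {
  m <- build_unet(unet_spec(), seed = 0)
  audit <- audit_parameters(m)
  ref <- audit_reference(unet_spec())
  expect_equal(audit$block, ref$block)
  expect_equal(audit$operation, ref$operation)
  expect_equal(as.integer(audit$params), as.integer(ref$params))
  expect_equal(attr(audit, "total"), attr(ref, "total"))

  # closed form also pins a non-default width configuration
  sp <- unet_spec(input_size = c(32L, 32L), contraction_channels = c(4L, 8L),
                  bottleneck_channels = 16L, final_intermediate_channels = 4L,
                  num_classes = 3L)
  m2 <- build_unet(sp, seed = 1)
  expect_equal(as.integer(audit_parameters(m2)$params),
               as.integer(audit_reference(sp)$params))
})

test_that("audit counts are only reachable with batch-norm affine parameters", {
  audit <- audit_parameters(build_unet(unet_spec(), seed = 0))
  # first operation: 1 -> 16 channels; without the 2 affine parameters per
  # batch-norm channel the count would be 160, not 192
  expect_equal(audit$params[1], 192)
  expect_equal(9 * 1 * 16 + 16, 160)
  expect_equal(9 * 1 * 16 + 16 + 2 * 16, 192)
  # final 1x1: 8 -> 5 with bias would be 45; 55 requires the 2*5 batch-norm
  expect_equal(audit$params[nrow(audit)], 55)
  expect_equal(8 * 5 + 5, 45)
  expect_equal(8 * 5 + 5 + 2 * 5, 55)
})

test_that("spatial contract: halving to the bottleneck, output same size as input", {
  sh <- unet_shapes(unet_spec())
  expect_equal(sh$height[sh$stage == "Bottleneck"], 8L)
  sh64 <- unet_shapes(unet_spec(input_size = c(64L, 64L)))
  expect_equal(sh64$height[sh64$stage == "Bottleneck"], 4L)

  for (n in c(32L, 64L)) {
    sp <- unet_spec(input_size = c(n, n))
    m <- build_unet(sp, seed = 0)
    out <- predict_labelmap(m, matrix(runif(n * n), n, n))
    expect_equal(dim(out), c(n, n))
    expect_true(all(out %in% 0:4))
  }

  m <- build_unet(unet_spec(), seed = 0)
  arr <- array(runif(128 * 128 * 2), c(128, 128, 2))
  preds <- predict_labelmap(m, arr)
  expect_length(preds, 2)
  expect_equal(dim(preds[[1]]), c(128, 128))
})

test_that("invalid architecture specs are rejected", {
  expect_error(unet_spec(expansion_channels = c(16, 32, 64, 128)), "mirror")
  expect_error(unet_spec(input_size = c(100L, 100L)), "divisible")
  expect_error(unet_spec(input_size = c(8L, 8L)), ">= 16")
  m <- build_unet(unet_spec(), seed = 0)
  expect_error(predict_labelmap(m, matrix(0.5, 64, 64)), "input size")
  expect_error(predict_labelmap(m, matrix(2, 128, 128)), "\\[0, 1\\]")
})

test_that("an all-zero final layer yields a constant background map", {
  m <- build_unet(unet_spec(), seed = 0)
  w <- get_unet_weights(m)
  w[["fin1.W"]][] <- 0
  w[["fin1.b"]][] <- 0
  set_unet_weights(m, w)
  out <- predict_labelmap(m, matrix(runif(128 * 128), 128, 128))
  expect_true(all(out == 0L))  # equal scores, argmax ties to lowest class
})

test_that("prediction and initialization are deterministic per seed", {
  f <- matrix(runif(64 * 64), 64, 64)
  sp <- unet_spec(input_size = c(64L, 64L))
  m <- build_unet(sp, seed = 3)
  expect_identical(predict_labelmap(m, f), predict_labelmap(m, f))
  m2 <- build_unet(sp, seed = 3)
  expect_identical(get_unet_weights(m), get_unet_weights(m2))
  m3 <- build_unet(sp, seed = 4)
  expect_false(identical(get_unet_weights(m)[["c1a.W"]],
                         get_unet_weights(m3)[["c1a.W"]]))
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(42)
  m <- build_unet(tiny_spec(), seed = 7)
  imgs <- array(runif(16 * 16 * 2), c(16, 16, 2))
  labs <- array(sample(0:2, 16 * 16 * 2, TRUE), c(16, 16, 2))
  grads <- echoseg:::cpp_unet_grads(m$ptr, imgs, labs)
  w <- get_unet_weights(m)
  eps <- 3e-3
  for (nm in c("c1a.W", "c2b.b", "b1.W", "up1.W", "e2a.W", "e1b.gamma",
               "fin3.beta", "fin1.W", "up2.b")) {
    i <- sample(length(w[[nm]]), 1)
    wp <- w; wp[[nm]][i] <- w[[nm]][i] + eps
    set_unet_weights(m, wp)
    lp <- echoseg:::cpp_unet_loss(m$ptr, imgs, labs, TRUE)
    wm <- w; wm[[nm]][i] <- w[[nm]][i] - eps
    set_unet_weights(m, wm)
    lm <- echoseg:::cpp_unet_loss(m$ptr, imgs, labs, TRUE)
    numeric_g <- (lp - lm) / (2 * eps)
    analytic_g <- grads[[nm]][i]
    rel <- abs(analytic_g - numeric_g) /
      max(0.05, abs(analytic_g) + abs(numeric_g))
    expect_lt(rel, 0.03, label = sprintf("gradient error of %s[%d]", nm, i))
    set_unet_weights(m, w)
  }
})

test_that("checkpoints are self-describing and round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".rds")
  sp <- unet_spec(input_size = c(32L, 32L))
  m <- build_unet(sp, seed = 5)
  f <- matrix(runif(32 * 32), 32, 32)
  save_unet(m, path)
  m2 <- load_unet(path)
  expect_equal(m2$spec, sp)
  expect_identical(predict_labelmap(m2, f), predict_labelmap(m, f))
})
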