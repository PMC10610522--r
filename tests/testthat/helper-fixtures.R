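# shared fixtures, built in code and cached for the duration of the session

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache, inherits = FALSE))
    assign(key, force(expr), envir = .test_cache)
  get(key, envir = .test_cache, inherits = FALSE)
}

# analytic filled sector (apex top-center), used as a clean cone mask
sector_mask <- function(h = 96, w = 96, half_angle = 35, apex_y = 4,
                        depth = h - 8) {
  cfg <- phantom_config(frame_size = c(h, w), cone_half_angle = half_angle,
                        cone_apex = c(x = (w - 1) / 2, y = apex_y),
                        cone_depth = depth)
  echoseg:::cone_sector_mask(cfg)
}

# 100 phantoms at the 128x128 working resolution, every frame carrying a
# defective copy in which the right ventricle leaks >= 20 rows past the top
# of the right atrium
leak_set <- function() cached("leak_set", {
  generate_phantom_dataset(100, size = 128L, seed = 11L, leak_prob = 1,
                           leak_overshoot = 25L)
})

# the seeded reference training experiment: 100 phantoms at 112x112,
# preprocessed to 128x128, 80/10/10 split, mini-batch 8, fixed learning
# rate 1e-3, 50 epochs of Adam on per-pixel cross-entropy
reference_run <- function() cached("reference_run", {
  ds <- generate_phantom_dataset(100, size = 112L, seed = 0L)
  pp <- lapply(ds, function(s) {
    r <- preprocess(s$frame, s$labels)
    list(frame = r$frame, labels = r$mask)
  })
  sp <- split_dataset(pp, c(0.8, 0.1, 0.1), seed = 0L)
  model <- build_unet(unet_spec(), seed = 0L)
  history <- fit(model, list(train = sp$train, val = sp$val),
                 train_config(epochs = 50L, seed = 0L))
  list(history = history, test_report = evaluate_on_test(model, sp$test),
       sizes = lengths(sp))
})

# binary masks with a fixed density, for metric property checks
random_mask <- function(h, w, p = 0.3) matrix(runif(h * w) < p, h, w)
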