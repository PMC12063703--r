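# Shared small fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# A small two-class phantom pair with a lightly trained source model:
# enough signal for contract tests, cheap enough to build in seconds.
small_fixture <- function() {
  memo("small", {
    spec <- phantom_spec(image_size = 32L, n_classes = 2L, n_slices = 16L,
                         seed = 11L)
    ph <- phantom_dataset(spec)
    model <- build_backbone("tiny", num_classes = 2L, seed = 3L)
    model <- train_source(model, ph$images_a[, , 1:12],
                          ph$labels[, , 1:12], epochs = 3L,
                          batch_size = 4L, lr = 2e-3, seed = 1L)
    list(spec = spec, ph = ph, model = model)
  })
}

# A tiny alignment model sized for gradient checks.
small_am <- function(mode = "specific", seed = 5L) {
  build_alignment_model(code_dim = 16L, blocks = 2L, width = 4L,
                        mode = mode, seed = seed)
}
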