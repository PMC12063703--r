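# The phantom benchmark protocol shared by the acceptance tests. One run
# per seed, memoised: source training on domain A, stage-1 prompting and
# the agnostic baseline on unlabeled domain B, pseudo-labeling, stage-2
# adaptation, and held-out evaluation of all four conditions.

benchmark_protocol <- function(seed) {
  spec <- phantom_spec(image_size = 64L, n_classes = 4L, n_slices = 200L,
                       seed = seed)
  ph <- phantom_dataset(spec)
  train_ids <- 1:50
  eval_ids <- 181:200
  adapt_ids <- 1:64

  src <- build_backbone("tiny", num_classes = 4L, seed = seed)
  src <- train_source(src, ph$images_a[, , train_ids],
                      ph$labels[, , train_ids], epochs = 14L,
                      batch_size = 4L, lr = 2e-3, seed = seed + 1L)

  am <- build_alignment_model(seed = seed + 1L)
  am <- train_alignment(src, am, ph$images_b, epochs = 2L, batch_size = 4L,
                        lr = 1e-3, seed = seed + 2L)

  ag <- make_agnostic_prompt(spec$image_size, spec$image_size)
  ag <- train_alignment(src, ag, ph$images_b, epochs = 2L, batch_size = 4L,
                        lr = 1e-3, seed = seed + 2L)

  tgt <- adapt(src, am, ph$images_b[, , adapt_ids], epochs = 2L,
               batch_size = 4L, lr = 5e-4, seed = seed + 3L)

  ev_imgs_b <- ph$images_b[, , eval_ids]
  ev_labs <- ph$labels[, , eval_ids]
  mse_of <- function(prompt) {
    bundles <- make_pseudo_labels(src, ev_imgs_b, am = prompt)
    mean(vapply(seq_along(bundles), function(i) {
      pseudo_label_mse(bundles[[i]], ev_labs[, , i])
    }, numeric(1)))
  }
  list(
    seed = seed,
    spec = spec,
    source = src,
    am = am,
    agnostic = ag,
    target = tgt,
    dice_source_heldout = mean_dice(src, ph$images_a[, , eval_ids], ev_labs),
    dice_source_only = mean_dice(src, ev_imgs_b, ev_labs),
    dice_prompted = mean_dice(src, ev_imgs_b, ev_labs, am = am),
    dice_agnostic = mean_dice(src, ev_imgs_b, ev_labs, am = ag),
    dice_adapted = mean_dice(tgt, ev_imgs_b, ev_labs, am = am),
    mse_raw = mse_of(NULL),
    mse_fused = mse_of(am),
    bnc_log = am$log
  )
}

benchmark_run <- function(seed) {
  memo(paste0("bench", seed), benchmark_protocol(seed))
}
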