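test_that("extracting BN statistics reflects initialization and layer count", {
  m <- build_backbone("tiny", num_classes = 3, seed = 0)
  st <- extract_source_bn_stats(m)
  expect_equal(length(st$layer_ids), length(bn_layer_indices(m)))
  for (j in seq_along(st$mean)) {
    expect_equal(st$mean[[j]], rep(0, length(st$mean[[j]])))
    expect_equal(st$var[[j]], rep(1, length(st$var[[j]])))
  }
  no_bn <- m
  no_bn$layers <- Filter(function(l) l$type != "bn", no_bn$layers)
  expect_error(extract_source_bn_stats(no_bn), "no batch-normalization")
})

test_that("captured batch statistics equal direct feature-map moments", {
  # identity first layer (1x1 conv, weight 1): first-layer features = input
  m <- build_backbone("tiny", num_classes = 1, seed = 1)
  m$layers[[1]] <- list(type = "conv", cin = 1L, cout = 1L, k = 1L,
                        pad = 0L, stride = 1L,
                        W = array(1, c(1, 1, 1, 1)), b = 0)
  m$layers[[2]] <- list(type = "bn", channels = 1L, gamma = 1, beta = 0,
                        rmean = 0, rvar = 1, eps = 1e-5, momentum = 0.1)
  m$layers <- m$layers[1:3]                # conv-id, bn, lrelu
  const <- array(5, c(8, 8, 3))
  st <- capture_batch_stats(m, const)
  expect_equal(st$mean[[1]], 5)
  expect_equal(st$var[[1]], 0)

  # brute-force recomputation on a real model and random batch
  m2 <- small_fixture()$model
  set.seed(8)
  xb <- array(rnorm(32 * 32 * 4), c(32, 32, 4))
  st2 <- capture_batch_stats(m2, xb)
  h <- vpsfda:::conv_fw(vpsfda:::as_image_stack(xb), m2$layers[[1]]$W,
                        m2$layers[[1]]$b, 1L, 1L)$out
  hm <- matrix(h, 32 * 32 * 4, dim(h)[4])
  expect_equal(st2$mean[[1]], colMeans(hm), tolerance = 1e-6)
  expect_equal(st2$var[[1]], colMeans(hm^2) - colMeans(hm)^2,
               tolerance = 1e-6)

  # duplication invariance of mean/variance
  dup <- xb[, , c(1:4, 1:4)]
  st3 <- capture_batch_stats(m2, dup)
  for (j in seq_along(st2$mean)) {
    expect_equal(st3$mean[[j]], st2$mean[[j]], tolerance = 1e-10)
    expect_equal(st3$var[[j]], st2$var[[j]], tolerance = 1e-10)
  }
  # capture is read-only
  expect_identical(model_params(m2, buffers = TRUE),
                   model_params(small_fixture()$model, buffers = TRUE))
})

test_that("bnc_loss matches hand arithmetic", {
  mk <- function(mean, var, ids = 1L) {
    structure(list(layer_ids = ids, mean = mean, var = var),
              class = "vps_bn_stats")
  }
  src <- mk(list(0), list(1))
  expect_equal(bnc_loss(src, src), 0)
  # one layer, one channel, mu = 1 vs 0, matched variance -> (1-0)^2 = 1
  expect_equal(bnc_loss(mk(list(1), list(1)), src), 1)
  # two layers each contributing 0.5 -> 1.0 (additivity over layers)
  src2 <- mk(list(0, 0), list(1, 1), ids = c(1L, 2L))
  bat2 <- mk(list(sqrt(0.5), sqrt(0.5)), list(1, 1), ids = c(1L, 2L))
  expect_equal(bnc_loss(bat2, src2), 1)
  # channel aggregation: mean vs sum
  src3 <- mk(list(c(0, 0)), list(c(1, 1)))
  bat3 <- mk(list(c(1, 1)), list(c(1, 1)))
  expect_equal(bnc_loss(bat3, src3, channel_agg = "mean"), 1)
  expect_equal(bnc_loss(bat3, src3, channel_agg = "sum"), 2)
  expect_error(bnc_loss(mk(list(0), list(1), ids = 2L), src), "different BN")
  expect_error(bnc_loss(mk(list(c(0, 0)), list(c(1, 1))), src),
               "channel count")
})

test_that("the in-training BNC loss equals the public loss computation", {
  fx <- small_fixture()
  am <- small_am()
  xb <- fx$ph$images_b[, , 1:4]
  sb <- vpsfda:::stage1_batch(fx$model, am, vpsfda:::as_image_stack(xb),
                              "mean", NULL, need_grads = FALSE)
  fused <- vpsfda:::as_image_stack(xb) +
    vpsfda:::am_forward(am, vpsfda:::as_image_stack(xb))$delta
  ref <- bnc_loss(capture_batch_stats(fx$model, array(fused, dim(fused)[1:3])),
                  extract_source_bn_stats(fx$model))
  expect_equal(sb$loss, ref, tolerance = 1e-8)
})

test_that("BNC gradients match finite differences through the whole chain", {
  fx <- small_fixture()
  am <- small_am()
  x <- vpsfda:::as_image_stack(fx$ph$images_b[, , 1:2])
  sb <- vpsfda:::stage1_batch(fx$model, am, x, "mean", NULL,
                              need_grads = TRUE)
  params <- vpsfda:::am_params(am)
  set.seed(77)
  for (nm in c("syn1.theta", "syn3.Ws", "fc.W", "enc2.W", "affine")) {
    i <- sample(length(params[[nm]]), 1)
    f <- function(v) {
      p2 <- params; p2[[nm]][i] <- v
      vpsfda:::stage1_batch(fx$model, vpsfda:::set_am_params(am, p2), x,
                            "mean", NULL, need_grads = FALSE)$loss
    }
    eps <- 1e-5
    fd <- (f(params[[nm]][i] + eps) - f(params[[nm]][i] - eps)) / (2 * eps)
    an <- sb$grads[[nm]][i]
    expect_equal(unname(an), fd, tolerance = 1e-3)
  }
})

test_that("stage-1 training never touches the source model", {
  fx <- small_fixture()
  before <- model_params(fx$model, buffers = TRUE)
  am <- small_am()
  am2 <- train_alignment(fx$model, am, fx$ph$images_b[, , 1:8],
                         epochs = 1, batch_size = 4, lr = 1e-3, seed = 2)
  expect_identical(model_params(fx$model, buffers = TRUE), before)
  expect_equal(nrow(am2$log), 2L)          # 8 images / batch 4
  # lr = 0 leaves the prompt parameters unchanged
  am3 <- train_alignment(fx$model, am, fx$ph$images_b[, , 1:8],
                         epochs = 1, batch_size = 4, lr = 0, seed = 2)
  expect_identical(vpsfda:::am_params(am3), vpsfda:::am_params(am))
  expect_error(train_alignment(fx$model, am, array(0, c(32, 32, 0))),
               "empty target")
  expect_error(capture_batch_stats(fx$model, array(0, c(32, 32, 0))),
               "empty batch")
})

test_that("the agnostic grid moves off zero after one training pass", {
  fx <- small_fixture()
  ag <- make_agnostic_prompt(32, 32)
  ag2 <- train_alignment(fx$model, ag, fx$ph$images_b[, , 1:4],
                         epochs = 1, batch_size = 4, lr = 1e-3, seed = 5)
  expect_gt(max(abs(ag2$grid)), 0)
  expect_equal(nrow(ag2$log), 1L)
})

test_that("matched-domain batches sit near the BNC floor", {
  # source-domain batches score far lower than target-domain batches
  # under a well-trained source model: the loss detects the domain shift
  run <- benchmark_run(0)
  ph <- phantom_dataset(run$spec)
  src_stats <- extract_source_bn_stats(run$source)
  ls <- bnc_loss(capture_batch_stats(run$source, ph$images_a[, , 181:200]),
                 src_stats)
  lt <- bnc_loss(capture_batch_stats(run$source, ph$images_b[, , 181:200]),
                 src_stats)
  expect_lt(ls, lt / 3)
})
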