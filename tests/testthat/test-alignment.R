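test_that("prompt code has the configured dimension and is deterministic", {
  am <- build_alignment_model(code_dim = 8, blocks = 1, width = 2, seed = 1)
  set.seed(1)
  x <- matrix(rnorm(32 * 32), 32, 32)
  code <- encode_prompt_code(am, x)
  expect_equal(dim(code), c(1L, 8L))
  expect_identical(code, encode_prompt_code(am, x))
  expect_true(all(is.finite(code)))
})

test_that("a zeroed encoder yields a zero prompt code", {
  am <- build_alignment_model(code_dim = 8, blocks = 1, width = 2, seed = 1)
  for (i in seq_along(am$enc)) {
    am$enc[[i]]$W[] <- 0; am$enc[[i]]$b[] <- 0
  }
  am$fc$W[] <- 0; am$fc$b[] <- 0
  x <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(as.vector(encode_prompt_code(am, x)), rep(0, 8))
})

test_that("images below the encoder's receptive needs are rejected", {
  am <- build_alignment_model(code_dim = 8, blocks = 1, width = 2, seed = 1)
  expect_error(encode_prompt_code(am, matrix(0, 8, 8)), "at least 16x16")
})

test_that("demodulation cancels a uniform kernel gain (closed form)", {
  # 1x1 kernel theta_hat = 2, eps -> 0: output = v * 2 / sqrt(4) = v
  m <- matrix(c(1, -2, 3, 0.5), 2, 2)
  out <- modulated_demodulated_conv(m, array(2, c(1, 1, 1, 1)),
                                    style = 0, eps = 1e-16)
  expect_equal(array(m, c(2, 2, 1)), out, tolerance = 1e-7)
  # all-zero effective kernel: output identically zero
  out0 <- modulated_demodulated_conv(m, array(1, c(1, 1, 1, 1)),
                                     style = -1, eps = 1e-8)
  expect_equal(max(abs(out0)), 0)
  expect_error(
    modulated_demodulated_conv(array(0, c(4, 4, 2)),
                               array(0, c(3, 3, 3, 1)), style = rep(0, 3)),
    "channel mismatch")
})

test_that("demodulated outputs keep roughly unit variance on iid inputs", {
  # style removal: output std stays near 1 regardless of style magnitude
  set.seed(99)
  for (rep in 1:3) {
    th <- array(rnorm(3 * 3 * 4 * 3), c(3, 3, 4, 3))
    s <- rnorm(4) * 10^(rep - 2)            # styles spanning magnitudes
    x <- array(rnorm(80 * 80 * 4), c(80, 80, 4))
    out <- modulated_demodulated_conv(x, th, s, eps = 1e-8)
    core <- out[9:72, 9:72, , drop = FALSE]  # interior: padding-free pixels
    stds <- apply(core, 3, stats::sd)
    expect_true(all(stds > 0.8 & stds < 1.2))
  }
})

test_that("prompts preserve shape and are input-specific", {
  am <- build_alignment_model(code_dim = 32, blocks = 5, width = 4, seed = 2)
  expect_equal(length(am$syn), 10L)        # 5 blocks x 2 conv layers
  set.seed(3)
  x1 <- matrix(rnorm(64 * 64), 64, 64)
  x2 <- matrix(rnorm(64 * 64), 64, 64)
  d1 <- generate_prompt(am, x1)
  expect_equal(dim(d1), c(64L, 64L))
  d2 <- generate_prompt(am, x2)
  expect_gt(max(abs(d1 - d2)), 0)          # different inputs, different prompts
  # the agnostic baseline applies one grid to every input
  ag <- make_agnostic_prompt(64, 64)
  ag$grid[] <- rnorm(64 * 64)
  f1 <- vpsfda:::fuse_stack(vpsfda:::as_image_stack(x1), ag) -
    vpsfda:::as_image_stack(x1)
  f2 <- vpsfda:::fuse_stack(vpsfda:::as_image_stack(x2), ag) -
    vpsfda:::as_image_stack(x2)
  expect_equal(f1, f2)
})

test_that("zeroing the final synthesis layer gives an identically zero prompt", {
  am <- build_alignment_model(code_dim = 16, blocks = 2, width = 4, seed = 4)
  n <- length(am$syn)
  am$syn[[n]]$theta[] <- 0
  am$syn[[n]]$b[] <- 0
  am$syn[[n]]$Ws[] <- 0
  am$syn[[n]]$bs[] <- 0
  x <- matrix(rnorm(32 * 32), 32, 32)
  d <- generate_prompt(am, x)
  expect_equal(max(abs(d)), 0)
  expect_equal(fuse(x, d), x)
})

test_that("additive fusion is exact and validates shapes", {
  x <- matrix(rnorm(16), 4, 4)
  d1 <- matrix(rnorm(16), 4, 4)
  d2 <- matrix(rnorm(16), 4, 4)
  expect_equal(fuse(x, matrix(0, 4, 4)), x)
  expect_equal(fuse(matrix(0, 4, 4), d1), d1)
  expect_equal(fuse(fuse(x, d1), d2), x + d1 + d2)
  expect_error(fuse(x, matrix(0, 4, 5)), "shape mismatch")
})

test_that("plain mode reduces each layer to the general convolution", {
  am <- build_alignment_model(code_dim = 16, blocks = 1, width = 3,
                              mode = "plain", seed = 6)
  x <- vpsfda:::as_image_stack(matrix(rnorm(24 * 24), 24, 24))
  got <- vpsfda:::am_forward(am, x)$delta
  # reference: chain ordinary convolutions + leaky ReLU by hand
  h <- x
  for (i in seq_along(am$syn)) {
    h <- vpsfda:::conv_fw(h, am$syn[[i]]$theta, am$syn[[i]]$b, 1L, 1L)$out
    if (i < length(am$syn)) h <- vpsfda:::lrelu_fw(h, 0.01)$out
  }
  expect_equal(got, h, tolerance = 1e-12)
})

test_that("the agnostic prompt is a zero-initialized trainable grid", {
  ag <- make_agnostic_prompt(24, 20)
  expect_equal(dim(ag$grid), c(24L, 20L))
  expect_equal(sum(ag$grid != 0), 0)
  expect_equal(length(ag$grid), 24 * 20)   # W*H trainable parameters
})
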