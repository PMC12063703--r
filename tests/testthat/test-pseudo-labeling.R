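make_soft <- function(fg) {
  # single-foreground-class softmax from a matrix of foreground probs
  p <- array(0, c(dim(fg), 2))
  p[, , 1] <- 1 - fg
  p[, , 2] <- fg
  p
}

test_that("category thresholds follow the top-k rule", {
  # channel-c values at c-argmax pixels {0.9, 0.8, 0.6, 0.4}: only the
  # first three have foreground argmax (> 0.5)
  fg <- matrix(c(0.9, 0.6, 0.8, 0.4), 2, 2)
  p <- make_soft(fg)
  expect_equal(category_thresholds(p, k = 2), 0.8)
  expect_equal(category_thresholds(p, k = 1), 0.9)   # k = 1 -> max
  expect_equal(category_thresholds(p, k = 10), 0.6)  # short set -> min value
  # no pixel with argmax c -> delta_c = 1
  p0 <- make_soft(matrix(0.2, 2, 2))
  expect_equal(category_thresholds(p0, k = 1), 1)
  expect_error(category_thresholds(p, k = 0), "k must be")
})

test_that("the printed 2x2 toy case is denoised as expected", {
  fg <- matrix(c(0.9, 0.6, 0.8, 0.4), 2, 2)   # [[0.9, 0.8], [0.6, 0.4]]
  p <- make_soft(fg)
  out <- denoise_double_threshold(p, k = 2, k_mode = "rank", lambda = 0.7)
  expect_equal(out$delta, 0.8)
  expect_equal(sum(out$r), 2)                 # 0.9 and 0.8 survive
  expect_equal(out$r, matrix(c(1L, 0L, 1L, 0L), 2, 2))
  expect_equal(out$y_hat[1, 1, 1], 1)
  expect_equal(out$y_hat[1, 2, 1], 1)
  expect_equal(sum(out$y_hat), 2)
})

test_that("degenerate global thresholds behave as bounds", {
  p <- random_soft_prediction(8, 8, 2, seed = 5)
  all_kept <- denoise_double_threshold(p, k = 64, k_mode = "rank", lambda = 0)
  pm <- matrix(p, 64, 3)
  n_fg <- sum(max.col(pm, ties.method = "first") > 1)
  expect_equal(sum(all_kept$r), n_fg)         # every foreground-argmax pixel
  none <- denoise_double_threshold(p, k = 1, k_mode = "rank", lambda = 1)
  expect_equal(sum(none$r), 0)                # nothing exceeds probability 1
})

test_that("vectorized denoising equals pixel-wise brute force exactly", {
  for (seed in 1:100) {
    p <- random_soft_prediction(8, 8, 2, seed = seed)
    k <- (seed %% 5) + 1L
    lambda <- c(0, 0.3, 0.5, 0.75)[(seed %% 4) + 1L]
    delta <- brute_force_thresholds(p, k)
    expect_identical(category_thresholds(p, k), delta)
    got <- denoise_double_threshold(p, k = k, k_mode = "rank",
                                    lambda = lambda)
    ref <- brute_force_denoise(p, delta, lambda)
    expect_identical(got$y_hat, ref$y_hat)
    expect_identical(got$r, ref$r)
  }
})

test_that("confident-pixel counts are monotone in the thresholds", {
  p <- random_soft_prediction(12, 12, 3, seed = 42)
  delta <- category_thresholds(p, k = 20)
  counts <- vapply(seq(0, 1, by = 0.1), function(lam) {
    sum(denoise_double_threshold(p, delta = delta, lambda = lam)$r)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))         # non-increasing in lambda
  counts_d <- vapply(seq(0, 1, by = 0.25), function(dd) {
    sum(denoise_double_threshold(p, delta = rep(dd, 3), lambda = 0.2)$r)
  }, numeric(1))
  expect_true(all(diff(counts_d) <= 0))       # non-increasing in delta
})

test_that("mask and label are consistent on every output", {
  for (seed in c(3, 14, 27)) {
    p <- random_soft_prediction(10, 10, 4, seed = seed)
    out <- denoise_double_threshold(p, k = 0.5, lambda = 0.4)
    nonzero <- apply(out$y_hat, c(1, 2), sum)
    expect_identical(out$r == 1L, nonzero != 0)     # r = 1 <=> labelled
    expect_lte(max(nonzero), 1)                     # at most one channel
  }
})

test_that("pseudo-label MSE matches hand arithmetic", {
  # exact agreement -> 0
  y <- array(0, c(1, 1, 4)); y[1, 1, 2] <- 1
  lab <- matrix(2L, 1, 1)
  expect_equal(pseudo_label_mse(y, lab), 0)
  # wrong class: (1^2 + 1^2)/4 = 0.5 for that pixel
  lab_b <- matrix(3L, 1, 1)
  expect_equal(pseudo_label_mse(y, lab_b), 0.5)
  # all-zero pseudo-label vs one-hot truth: 0.25 per labelled pixel
  y0 <- array(0, c(1, 1, 4))
  expect_equal(pseudo_label_mse(y0, lab), 0.25)
  # pixel averaging: one wrong pixel out of four
  y2 <- array(0, c(2, 2, 4)); y2[1, 1, 1] <- 1
  lab2 <- matrix(0L, 2, 2); lab2[1, 1] <- 2L
  expect_equal(pseudo_label_mse(y2, lab2), (1 + 1) / 4 / 4)
  expect_error(pseudo_label_mse(y, matrix(0L, 2, 2)), "shape mismatch")
})

test_that("the denoiser interface validates conformance", {
  p <- random_soft_prediction(6, 6, 2, seed = 9)
  direct <- denoise_double_threshold(p, k = 0.33, lambda = 0.5)
  via <- as_denoiser(function(q) {
    denoise_double_threshold(q, k = 0.33, lambda = 0.5)
  })(p)
  expect_identical(via$y_hat, direct$y_hat)
  expect_identical(via$r, direct$r)
  # argmax denoiser: every foreground-argmax pixel confident
  argmax_g <- as_denoiser(function(q) {
    denoise_double_threshold(q, k = 1, k_mode = "fraction", lambda = 0)
  })
  out <- argmax_g(p)
  pm <- matrix(p, 36, 3)
  expect_equal(sum(out$r), sum(max.col(pm, ties.method = "first") > 1))
  # nonconforming shapes are rejected
  bad <- as_denoiser(function(q) {
    list(y_hat = array(0, c(3, 3, 2)), r = matrix(0L, 3, 3))
  })
  expect_error(bad(p), "does not conform")
  # mask/label inconsistency is rejected
  lying <- as_denoiser(function(q) {
    o <- denoise_double_threshold(q, k = 1, k_mode = "fraction", lambda = 0)
    o$r[] <- 1L
    o
  })
  expect_error(lying(p), "consistency")
})
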