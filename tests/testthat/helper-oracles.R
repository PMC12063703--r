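# Independent oracles used across the suite. These deliberately use the
# dumbest possible formulations (pixel loops, all-pairs scans) so they
# cannot share bugs with the vectorized implementations they check.

# Pixel-by-pixel double-threshold denoiser: for each pixel, look at the
# argmax channel; assign the one-hot label iff it is foreground and passes
# both thresholds.
brute_force_denoise <- function(p, delta, lambda) {
  d <- dim(p)
  C <- d[3] - 1L
  y <- array(0, c(d[1], d[2], C))
  r <- matrix(0L, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      probs <- p[i, j, ]
      cm <- which.max(probs)
      if (cm == 1L) next                       # background argmax
      cc <- cm - 1L
      if (probs[cm] >= delta[cc] && probs[cm] > lambda) {
        y[i, j, cc] <- 1
        r[i, j] <- 1L
      }
    }
  }
  list(y_hat = y, r = r)
}

# Sort-based per-category threshold oracle.
brute_force_thresholds <- function(p, k) {
  d <- dim(p)
  C <- d[3] - 1L
  delta <- rep(1, C)
  for (cc in seq_len(C)) {
    vals <- c()
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (which.max(p[i, j, ]) == cc + 1L) vals <- c(vals, p[i, j, cc + 1L])
    }
    if (length(vals) == 0) next
    sv <- sort(vals, decreasing = TRUE)
    delta[cc] <- sv[min(k, length(sv))]
  }
  delta
}

# Exhaustive average surface distance: boundary pixels by 4-neighbourhood
# scan, then all-pairs nearest distances.
brute_force_asd <- function(a, b, spacing = 1) {
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  surf <- function(m) {
    out <- NULL
    d <- dim(m)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (!m[i, j]) next
      nb <- c(
        if (i > 1) m[i - 1, j] else FALSE,
        if (i < d[1]) m[i + 1, j] else FALSE,
        if (j > 1) m[i, j - 1] else FALSE,
        if (j < d[2]) m[i, j + 1] else FALSE
      )
      if (!all(nb)) out <- rbind(out, c(i, j))
    }
    out
  }
  sa <- surf(a != 0); sb <- surf(b != 0)
  dmin <- function(from, to) {
    mean(apply(from, 1, function(pt) {
      min(sqrt(((pt[1] - to[, 1]) * spacing[1])^2 +
                 ((pt[2] - to[, 2]) * spacing[2])^2))
    }))
  }
  (dmin(sa, sb) + dmin(sb, sa)) / 2
}

# Random softmax grid: H x W x (C+1) with rows drawn from a Dirichlet-like
# normalized-uniform distribution.
random_soft_prediction <- function(h, w, C, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(h * w * (C + 1L))^2, h * w, C + 1L)
  m <- m / rowSums(m)
  array(m, c(h, w, C + 1L))
}

# Central finite difference of f at x[i].
num_grad <- function(f, x, i, eps = 1e-5) {
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}
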