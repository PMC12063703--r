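test_that("anatomy masks are valid, disjoint, and deterministic", {
  spec <- phantom_spec(image_size = 48, n_classes = 4, n_slices = 10,
                       seed = 2)
  m1 <- generate_anatomy(spec, 3)
  expect_true(all(m1 %in% 0:4))
  expect_identical(m1, generate_anatomy(spec, 3))
  expect_false(identical(m1, generate_anatomy(spec, 4)))
  # one-hot disjointness is implied by the integer encoding; check the
  # one-hot view sums to at most 1 on foreground
  oh <- sapply(1:4, function(cc) as.integer(m1 == cc))
  expect_lte(max(rowSums(oh)), 1)
})

test_that("every class is present in at least 80% of slices", {
  spec <- phantom_spec(n_slices = 60, seed = 0)
  ph <- phantom_dataset(spec)
  presence <- sapply(1:4, function(cc) {
    mean(apply(ph$labels, 3, function(m) any(m == cc)))
  })
  expect_true(all(presence >= 0.8))
})

test_that("rendered slices are normalized and share geometry across domains", {
  spec <- phantom_spec(n_slices = 6, seed = 1)
  ph <- phantom_dataset(spec)
  for (i in 1:6) {
    v <- as.vector(ph$images_a[, , i])
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(mean(v^2) - mean(v)^2 - 1), 1e-6)  # population variance 1
  }
  # identical labels per slice index; different intensity renderings
  expect_identical(ph$labels, ph$labels)
  expect_gt(max(abs(ph$images_a - ph$images_b)), 0.5)
  # the intensity transfer is (near-)inverted between domains: within-slice
  # correlation of the two renderings is strongly negative
  cors <- sapply(1:6, function(i) {
    cor(as.vector(ph$images_a[, , i]), as.vector(ph$images_b[, , i]))
  })
  expect_true(all(cors < -0.5))
})

test_that("noise-free, bias-free rendering is piecewise constant", {
  spec <- phantom_spec(n_slices = 1, seed = 3)
  m <- generate_anatomy(spec, 1)
  img <- render_domain(m, list(intensities = c(0.1, 0.3, 0.5, 0.7, 0.9),
                               noise_sd = 0, bias_amp = 0),
                       seed = 1, normalize = FALSE)
  expect_lte(length(unique(as.vector(img))), 5)
  expect_equal(sort(unique(as.vector(img))),
               sort(unique(c(0.1, 0.3, 0.5, 0.7, 0.9)[sort(unique(m)) + 1])))
})

test_that("datasets regenerate bit-identically from the same spec", {
  spec <- phantom_spec(image_size = 32, n_classes = 2, n_slices = 3,
                       seed = 9)
  p1 <- phantom_dataset(spec)
  p2 <- phantom_dataset(spec)
  expect_identical(p1$images_a, p2$images_a)
  expect_identical(p1$images_b, p2$images_b)
  expect_identical(p1$labels, p2$labels)
})

test_that("make_dataset writes the full file tree with a faithful manifest", {
  spec <- phantom_spec(image_size = 32, n_classes = 2, n_slices = 3,
                       seed = 5)
  d1 <- file.path(tempdir(), "phantom_t1")
  d2 <- file.path(tempdir(), "phantom_t2")
  unlink(c(d1, d2), recursive = TRUE)
  make_dataset(spec, d1)
  make_dataset(spec, d2)
  for (dom in c("A", "B")) {
    expect_length(list.files(file.path(d1, paste0("domain_", dom),
                                       "images")), 3L)
    expect_length(list.files(file.path(d1, paste0("domain_", dom),
                                       "labels")), 3L)
  }
  man1 <- yaml::read_yaml(file.path(d1, "manifest.yaml"))
  man2 <- yaml::read_yaml(file.path(d2, "manifest.yaml"))
  expect_equal(man1$spec$seed, 5)
  expect_equal(man1$spec$domain_a$noise_sd, spec$domain_a$noise_sd)
  expect_identical(man1$checksums, man2$checksums)   # reproducible bytes
  # shared geometry on disk: label files identical across domains
  for (i in 1:3) {
    fa <- file.path(d1, "domain_A", "labels", sprintf("slice_%04d.png", i))
    fb <- file.path(d1, "domain_B", "labels", sprintf("slice_%04d.png", i))
    expect_identical(readBin(fa, "raw", file.info(fa)$size),
                     readBin(fb, "raw", file.info(fb)$size))
  }
  unlink(c(d1, d2), recursive = TRUE)
})
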