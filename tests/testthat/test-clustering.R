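test_that("spectral distances match hand computation on a toy grid", {
  grid <- seq(10, 12, length.out = 16)
  mk <- function(hot, id) {
    y <- numeric(16); y[hot] <- 1
    g4_spectrum(grid, y, id)
  }
  a <- mk(2, "a"); b <- mk(3, "b")
  d <- spectra_distance_matrix(list(a, b), "euclidean")
  expect_equal(d["a", "b"], sqrt(2))
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_equal(d, t(d))
  # identical spectra at distance zero
  d2 <- spectra_distance_matrix(list(a, mk(2, "a2")), "euclidean")
  expect_equal(d2["a", "a2"], 0)
  # mismatched grids rejected
  c_off <- g4_spectrum(seq(10, 12, length.out = 17), rep(0:1, length.out = 17), "c")
  expect_error(spectra_distance_matrix(list(a, c_off)), "common ppm grid")
})

test_that("correlation distance is invariant to affine intensity rescaling", {
  set.seed(201)
  grid <- seq(10, 12, length.out = 128)
  a <- g4_spectrum(grid, rnorm(128), "a")
  b <- g4_spectrum(grid, rnorm(128), "b")
  b2 <- g4_spectrum(grid, 3.7 * b$intensity + 2, "b")
  d1 <- spectra_distance_matrix(list(a, b), "correlation")["a", "b"]
  d2 <- spectra_distance_matrix(list(a, b2), "correlation")["a", "b"]
  expect_equal(d1, d2)
})

test_that("two well-separated synthetic groups split perfectly at k = 2", {
  grid <- seq(10, 12, length.out = 256)
  set.seed(211)
  mk <- function(center, id) {
    y <- exp(-(grid - center)^2 / 0.005) + rnorm(256, 0, 0.01)
    g4_spectrum(grid, y, id)
  }
  sp <- c(lapply(1:5, function(i) mk(10.5, paste0("g1_", i))),
          lapply(1:5, function(i) mk(11.5, paste0("g2_", i))))
  d <- spectra_distance_matrix(sp, "euclidean")
  cl <- hierarchical_cluster(d, "average", k = 2)
  truth <- rep(1:2, each = 5)
  expect_equal(cluster_class_agreement(cl$labels, truth)$ari, 1)
  # k = n gives singletons
  cln <- hierarchical_cluster(d, "average", k = 10)
  expect_equal(sort(cln$labels), 1:10)
  expect_error(hierarchical_cluster(d, "average", k = 1), "between 2")
  expect_error(hierarchical_cluster(d, "average", k = 11), "between 2")
})

test_that("clustering of equidistant points is deterministic across runs", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  dimnames(d) <- list(letters[1:3], letters[1:3])
  r1 <- hierarchical_cluster(d, "average", k = 2)
  r2 <- hierarchical_cluster(d, "average", k = 2)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$merge, r2$merge)
  # every cluster non-empty
  expect_setequal(unique(r1$labels), 1:2)
})

test_that("agreement statistics hit their closed-form values", {
  truth <- rep(c("x", "y"), each = 10)
  perfect <- cluster_class_agreement(rep(1:2, each = 10), truth)
  expect_equal(perfect$ari, 1)
  expect_equal(perfect$purity, 1)
  lumped <- cluster_class_agreement(rep(1, 20), truth)
  expect_equal(lumped$ari, 0)
  expect_equal(lumped$purity, 0.5)
  expect_error(cluster_class_agreement(1:3, c("x", "y")), "equal length")
  expect_error(cluster_class_agreement(1:3, rep("x", 3)), "two distinct")
})

test_that("random labels score near-zero adjusted Rand index", {
  set.seed(221)
  truth <- sample(rep(1:5, each = 100))
  aris <- replicate(100, {
    cluster_class_agreement(sample(truth), truth)$ari
  })
  expect_lt(max(abs(aris)), 0.05)
})

test_that("binning preserves the grid span and tolerates jitter", {
  s <- lorentzian_spectrum(at = 11, n = 2048)
  b <- bin_spectrum(s, width = 0.05)
  expect_lt(length(b$ppm), length(s$ppm))
  # bucket means never exceed the raw maximum, and the peak bucket is hot
  expect_lte(max(b$intensity), max(s$intensity))
  expect_equal(b$ppm[which.max(b$intensity)], 11, tolerance = 0.05)
  # two copies of a peak jittered within one bucket stay nearly identical
  s2 <- lorentzian_spectrum(at = 11.004, n = 2048)
  d_raw <- sqrt(sum((s$intensity - s2$intensity)^2))
  b2 <- bin_spectrum(s2, width = 0.05)
  d_bin <- sqrt(sum((b$intensity - b2$intensity)^2))
  expect_lt(d_bin / sqrt(length(b$ppm)), d_raw / sqrt(length(s$ppm)))
})

test_that("signal-free spectra never enter the distance matrix", {
  cfg <- g4_sim_config(seed = 231)
  labels <- c(rep("17.3", 5), rep("17.4", 5), rep("no_G4_signals", 5))
  sp <- simulate_spectra_cohort(labels, cfg)
  res <- cluster_spectra_cohort(sp, k = 2)
  noise_ids <- names(sp)[labels == "no_G4_signals"]
  expect_true(all(noise_ids %in% res$dropped))
  expect_false(any(noise_ids %in% res$clustering$seq_ids))
  # determinism of the full wrapper
  res2 <- cluster_spectra_cohort(sp, k = 2)
  expect_identical(res$clustering$labels, res2$clustering$labels)
})

test_that("silhouette selection finds the generating group count", {
  grid <- seq(10, 12, length.out = 256)
  set.seed(241)
  mk <- function(center, id) {
    y <- exp(-(grid - center)^2 / 0.005) + rnorm(256, 0, 0.02)
    g4_spectrum(grid, y, id)
  }
  sp <- unlist(lapply(c(10.4, 11.1, 11.8), function(ctr)
    lapply(1:6, function(i) mk(ctr, paste0(ctr, "_", i)))), recursive = FALSE)
  d <- spectra_distance_matrix(sp, "euclidean")
  expect_equal(choose_k_silhouette(d, 2:8), 3)
})
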