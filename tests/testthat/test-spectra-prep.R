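test_that("trimming restricts to the imino window and is idempotent", {
  s <- g4_spectrum(seq(0, 12, length.out = 1200), rnorm(1200), "x")
  t1 <- trim_region(s, 10, 12)
  expect_true(all(t1$ppm >= 10 & t1$ppm <= 12))
  expect_equal(t1$seq_id, "x")
  t2 <- trim_region(t1, 10, 12)
  expect_identical(t1$intensity, t2$intensity)
  # full-axis window is the identity
  full <- trim_region(s, 0, 12)
  expect_identical(full$intensity, s$intensity)
  expect_error(trim_region(s, 13, 14), "window error")
})

test_that("0-1 scaling maps extremes and is idempotent; constant input warns", {
  s <- g4_spectrum(seq(10, 12, length.out = 16), c(2, 4, 6, rep(4, 13)), "x")
  sc <- scale01(s)
  expect_equal(sc$intensity[1:3], c(0, 0.5, 1))
  expect_identical(scale01(sc)$intensity, sc$intensity)
  expect_warning(z <- scale01(flat_spectrum(value = 3)), "constant")
  expect_true(all(z$intensity == 0))
})

test_that("robust noise estimate recovers sigma and ignores sparse peaks", {
  set.seed(101)
  # Monte-Carlo: pure Gaussian noise at several sigmas
  for (sigma in c(0.01, 1, 7)) {
    est <- estimate_noise(noise_spectrum(sd = sigma))
    expect_lt(abs(est - sigma) / sigma, 0.15)
  }
  expect_equal(estimate_noise(flat_spectrum()), 0)
  # a noiseless Lorentzian contributes almost nothing
  lor <- lorentzian_spectrum(at = 11)
  expect_lt(estimate_noise(lor), 0.01 * max(lor$intensity))
  short <- g4_spectrum(seq(10, 12, length.out = 20), rnorm(20))
  expect_error(estimate_noise(short), "64 points")
})

test_that("signal filter separates flat noise from structured spectra", {
  set.seed(111)
  expect_false(has_g4_signals(noise_spectrum(sd = 0.01)))
  expect_false(has_g4_signals(flat_spectrum()))
  cfg <- g4_sim_config()
  s <- simulate_spectrum("17.3", cfg)
  expect_true(has_g4_signals(trim_region(s)))
  # cohort of signal-free spectra: at least 95/100 filtered
  cohort <- simulate_spectra_cohort(rep("no_G4_signals", 100),
                                    g4_sim_config(seed = 112))
  kept <- vapply(cohort, function(x) has_g4_signals(trim_region(x)),
                 logical(1))
  expect_gte(sum(!kept), 95L)
})

test_that("peak picking recovers generated peaks exactly without noise", {
  cfg <- g4_sim_config(noise_sd = 0)
  set.seed(121)
  for (label in c("17.3", "17.4", "17.63", "17.28", "17.180")) {
    s <- simulate_spectrum(label, cfg)
    truth <- attr(s, "truth")
    pk <- pick_peaks(trim_region(s))
    expect_equal(pk$n_signals, nrow(truth))
    # positions within half a linewidth of the generated ones
    if (nrow(truth) > 0) {
      err <- abs(sort(pk$positions_ppm) - sort(truth$position))
      expect_lt(max(err), cfg$linewidth_ppm / 2)
    }
  }
  flat <- pick_peaks(flat_spectrum())
  expect_equal(flat$n_signals, 0L)
  expect_equal(flat$span_ppm, 0)
})

test_that("no detected signals implies an empty peak list at the same threshold", {
  set.seed(131)
  for (i in 1:20) {
    s <- noise_spectrum(sd = runif(1, 0.005, 0.05))
    if (!has_g4_signals(s, k = 5))
      expect_equal(pick_peaks(s, k = 5)$n_signals, 0L)
  }
})

test_that("close peaks merge keeping the higher one", {
  ppm <- seq(10, 12, length.out = 4096)
  y <- 0.01^2 / ((ppm - 11)^2 + 0.01^2) + 0.5 * 0.01^2 / ((ppm - 11.02)^2 + 0.01^2)
  s <- g4_spectrum(ppm, y, "pair")
  pk <- pick_peaks(s, min_sep_ppm = 0.03)
  expect_equal(pk$n_signals, 1L)
  expect_lt(abs(pk$positions_ppm - 11), 0.005)
})

test_that("timepoint comparison scores spectral change in [0, 1]", {
  s <- lorentzian_spectrum(at = 11)
  expect_equal(compare_timepoints(s, s)$score, 0)
  # anti-correlated pattern clips to 1
  neg <- g4_spectrum(s$ppm, -s$intensity, s$seq_id)
  expect_equal(compare_timepoints(s, neg)$score, 1)
  expect_true(compare_timepoints(s, neg)$changed)
  # slow folder: noise-only early spectrum vs folded late spectrum
  set.seed(141)
  cfg <- g4_sim_config()
  early <- simulate_spectrum("no_G4_signals", cfg, seq_id = "sf", timepoint = "t0")
  late <- simulate_spectrum("17.28", cfg, seq_id = "sf", timepoint = "t2months")
  prep <- function(x) suppressWarnings(scale01(trim_region(x)))
  cmp <- compare_timepoints(prep(early), prep(late))
  expect_gt(cmp$score, 0.2)
  expect_true(cmp$changed)
  # disjoint axes error
  lo <- g4_spectrum(seq(0, 5, length.out = 64), rnorm(64))
  expect_error(compare_timepoints(s, lo), "overlap")
})

test_that("delimited and JCAMP-style spectrum files round-trip", {
  s <- lorentzian_spectrum(at = 10.8, n = 64)
  s$timepoint <- "t2months"
  f <- tempfile(fileext = ".tsv")
  write_spectrum(s, f)
  r <- read_spectrum(f)
  expect_equal(r$ppm, s$ppm)
  expect_equal(r$intensity, s$intensity)
  expect_equal(r$seq_id, s$seq_id)
  expect_equal(r$timepoint, "t2months")

  jf <- tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=fx", "##XUNITS=PPM", "##XYDATA=(XY..XY)",
               paste(s$ppm, s$intensity, sep = ", "), "##END="), jf)
  j <- read_jcamp(jf)
  expect_equal(j$intensity, s$intensity)
  expect_equal(j$seq_id, "fx")
  writeLines(c("##TITLE=bad", "##XUNITS=HZ", "##XYDATA=(XY..XY)", "##END="), jf)
  expect_error(read_jcamp(jf), "XUNITS")
})
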