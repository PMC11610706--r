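# shared fixtures built in code

# a spectrum with a single unit-height Lorentzian at `at`, no noise
lorentzian_spectrum <- function(at = 11, hwhm = 0.01, n = 2048,
                                lo = 10, hi = 12, id = "fx") {
  ppm <- seq(lo, hi, length.out = n)
  g4_spectrum(ppm, hwhm^2 / ((ppm - at)^2 + hwhm^2), seq_id = id)
}

flat_spectrum <- function(value = 0, n = 2048, lo = 10, hi = 12, id = "flat") {
  g4_spectrum(seq(lo, hi, length.out = n), rep(value, n), seq_id = id)
}

noise_spectrum <- function(sd = 1, n = 2048, lo = 10, hi = 12, id = "noise") {
  g4_spectrum(seq(lo, hi, length.out = n), rnorm(n, 0, sd), seq_id = id)
}

# minimal activity table with two classes and chosen means, zero spread
two_class_activity_table <- function(mean_a = 6, mean_b = 2, n = 4) {
  data.frame(
    seq_id = sprintf("s%02d", seq_len(2 * n)),
    class = rep(c("a", "b"), each = n),
    Flu = rep(c(mean_a, mean_b), each = n),
    Tet = rep(c(mean_a, mean_b), each = n),
    Dim = rep(c(mean_b, mean_a), each = n),
    Per = rep(c(3, 3), each = n),
    GTP = rep(c(mean_a, mean_b), each = n),
    stringsAsFactors = FALSE
  )
}

signal_classes <- setdiff(g4_class_labels(), c("no_pattern", "no_G4_signals"))
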