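#' Trim a spectrum to the G-quadruplex imino region
#'
#' Restricts a spectrum to the analysis window, by default the 10-12 ppm
#' region where G-quadruplex imino protons resonate. Metadata and, when
#' present, ground-truth peak annotations (restricted to the window) are
#' preserved. Idempotent.
#'
#' @param s A `g4_spectrum`.
#' @param lo,hi Window bounds in ppm.
#' @return The trimmed `g4_spectrum`.
#' @export
trim_region <- function(s, lo = 10, hi = 12) {
  stopifnot(inherits(s, "g4_spectrum"), lo < hi)
  keep <- s$ppm >= lo & s$ppm <= hi
  if (!any(keep))
    stop("window error: [", lo, ", ", hi, "] ppm does not overlap the axis",
         call. = FALSE)
  out <- g4_spectrum(s$ppm[keep], s$intensity[keep],
                     seq_id = s$seq_id, timepoint = s$timepoint)
  tr <- attr(s, "truth")
  if (!is.null(tr))
    attr(out, "truth") <- tr[tr$position >= lo & tr$position <= hi, ,
                             drop = FALSE]
  attr(out, "class_label") <- attr(s, "class_label")
  out
}

#' Scale a spectrum linearly onto [0, 1]
#'
#' Maps the minimum intensity to 0 and the maximum to 1. A constant
#' spectrum cannot be scaled; it is returned as all zeros with a warning.
#' Idempotent on non-degenerate input.
#'
#' @param s A `g4_spectrum`.
#' @return The scaled `g4_spectrum`.
#' @export
scale01 <- function(s) {
  stopifnot(inherits(s, "g4_spectrum"))
  rng <- range(s$intensity)
  if (diff(rng) == 0) {
    warning("constant spectrum cannot be scaled; returning all zeros")
    y <- numeric(length(s$intensity))
  } else {
    y <- (s$intensity - rng[1]) / diff(rng)
  }
  out <- g4_spectrum(s$ppm, y, seq_id = s$seq_id, timepoint = s$timepoint)
  attr(out, "truth") <- attr(s, "truth")
  attr(out, "class_label") <- attr(s, "class_label")
  out
}

#' Robust noise estimate for a 1D trace
#'
#' Estimates the noise SD as 1.4826 x the median absolute deviation of the
#' first differences divided by sqrt(2). Differencing removes smooth
#' baseline and peak structure; the MAD makes the estimate insensitive to
#' the sparse large differences contributed by peaks.
#'
#' @param s A `g4_spectrum` or `g4_chromatogram`, or a numeric vector.
#' @return Estimated noise SD (0 for a perfectly flat trace).
#' @export
estimate_noise <- function(s) {
  y <- if (is.numeric(s)) s else s$intensity %||% s$absorbance
  if (length(y) < 64L)
    stop("noise estimation requires at least 64 points", call. = FALSE)
  stats::mad(diff(y)) / sqrt(2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Does a trimmed spectrum contain G-quadruplex signals?
#'
#' A spectrum is considered to contain signals when its maximum intensity
#' in the window reaches `k` times the robust noise estimate. Spectra that
#' fail this test are filtered out before clustering.
#'
#' @param s A trimmed `g4_spectrum`.
#' @param k Detection threshold in noise-SD units (default 5).
#' @return Logical.
#' @export
has_g4_signals <- function(s, k = 5) {
  noise <- estimate_noise(s)
  mx <- max(s$intensity)
  if (noise == 0) mx > 0 else mx >= k * noise
}

# indices of strict local maxima of y
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
}

# greedy merge: keep highest peak, drop others within min_sep of a kept one
merge_close_peaks <- function(pos, height, min_sep) {
  ord <- order(height, decreasing = TRUE)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(pos[i] - pos[kept]) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Pick imino peaks in a trimmed spectrum
#'
#' Detects strict local maxima above `k` times the robust noise estimate
#' and merges maxima closer than `min_sep_ppm`, keeping the higher one.
#'
#' @param s A trimmed `g4_spectrum`.
#' @param k Detection threshold in noise-SD units (default 5).
#' @param min_sep_ppm Minimum separation between reported peaks (ppm).
#' @return An object of class `g4_peaklist`: list with `positions_ppm`,
#'   `heights`, `snr`, `n_signals` and `span_ppm` (0 when fewer than two
#'   peaks).
#' @export
pick_peaks <- function(s, k = 5, min_sep_ppm = 0.03) {
  stopifnot(inherits(s, "g4_spectrum"))
  y <- s$intensity
  noise <- estimate_noise(s)
  thr <- if (noise > 0) k * noise else 0
  idx <- local_maxima(y)
  idx <- idx[y[idx] > thr]
  if (length(idx) > 1L)
    idx <- idx[merge_close_peaks(s$ppm[idx], y[idx], min_sep_ppm)]
  pos <- s$ppm[idx]
  hts <- y[idx]
  structure(list(
    positions_ppm = pos,
    heights = hts,
    snr = if (noise > 0) hts / noise else rep(Inf, length(hts)),
    n_signals = length(pos),
    span_ppm = if (length(pos) >= 2L) diff(range(pos)) else 0
  ), class = "g4_peaklist")
}

#' @export
print.g4_peaklist <- function(x, ...) {
  cat(sprintf("<g4_peaklist> %d signal(s), span %.3f ppm\n",
              x$n_signals, x$span_ppm))
  invisible(x)
}

#' Compare two timepoints of the same sequence
#'
#' Quantifies spectral change between two measurements as
#' 1 - Pearson correlation of the intensities interpolated onto a common
#' grid (the coarser of the two axes, restricted to their overlap),
#' clipped to [0, 1]. Slow-folding sequences show large scores between an
#' early, signal-free spectrum and a late, folded one.
#'
#' @param a,b Trimmed, scaled `g4_spectrum` objects of the same sequence.
#' @param threshold Score above which the pair is flagged `changed`.
#' @return List with `score` in [0, 1] and logical `changed`.
#' @export
compare_timepoints <- function(a, b, threshold = 0.2) {
  stopifnot(inherits(a, "g4_spectrum"), inherits(b, "g4_spectrum"))
  lo <- max(min(a$ppm), min(b$ppm))
  hi <- min(max(a$ppm), max(b$ppm))
  if (lo >= hi)
    stop("ppm axes do not overlap", call. = FALSE)
  coarser <- if (mean(diff(a$ppm)) >= mean(diff(b$ppm))) a else b
  grid <- coarser$ppm[coarser$ppm >= lo & coarser$ppm <= hi]
  ya <- stats::approx(a$ppm, a$intensity, xout = grid)$y
  yb <- stats::approx(b$ppm, b$intensity, xout = grid)$y
  if (stats::sd(ya) == 0 || stats::sd(yb) == 0) {
    score <- if (stats::sd(ya) == 0 && stats::sd(yb) == 0) 0 else 1
  } else {
    score <- min(max(1 - stats::cor(ya, yb), 0), 1)
  }
  list(score = score, changed = score > threshold)
}
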