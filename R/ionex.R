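#' Elution-volume windows for ion-exchange peak types
#'
#' The diagnostic MonoQ elution windows for the five chromatographic peak
#' types, in mL: non-G4 species 5.1-5.4, heavily mutated sequences
#' 5.55-5.7, dimeric 6.1-6.7, tetrameric 6.8-7.4 and monomeric
#' G-quadruplexes 7.7-9.0. Windows are pairwise disjoint; bounds are
#' inclusive.
#'
#' @return data.frame with columns `type`, `lo`, `hi`.
#' @export
ionex_windows <- function() {
  data.frame(
    type = c("not_G4", "many_mutations", "dimeric", "tetrameric", "monomeric"),
    lo = c(5.1, 5.55, 6.1, 6.8, 7.7),
    hi = c(5.4, 5.7, 6.7, 7.4, 9.0),
    stringsAsFactors = FALSE
  )
}

#' Classify a chromatographic apex by elution volume
#'
#' @param v Elution volume(s), mL.
#' @param table Window table as from [ionex_windows()].
#' @return Character vector: the containing window's type, or
#'   `"unclassified"` for volumes in a gap.
#' @export
#' @examples
#' classify_peak(c(8.0, 6.4, 7.5))
classify_peak <- function(v, table = ionex_windows()) {
  stopifnot(all(v > 0))
  vapply(v, function(x) {
    hit <- which(x >= table$lo & x <= table$hi)
    if (length(hit) == 1L) table$type[hit] else "unclassified"
  }, character(1))
}

#' Detect peaks in an ion-exchange chromatogram
#'
#' Strict local maxima above `k` times the robust noise estimate (the same
#' estimator used for spectra), merged within `merge_ml` keeping the
#' higher apex.
#'
#' @param c A `g4_chromatogram`.
#' @param k Detection threshold in noise-SD units.
#' @param merge_ml Merge radius in mL.
#' @return data.frame with columns `apex_ml`, `height`, `type`.
#' @export
detect_chromatogram_peaks <- function(c, k = 5, merge_ml = 0.1) {
  stopifnot(inherits(c, "g4_chromatogram"))
  if (length(c$volume_ml) < 64L)
    stop("chromatogram must have at least 64 points", call. = FALSE)
  y <- c$absorbance
  noise <- estimate_noise(c)
  thr <- if (noise > 0) k * noise else 0
  idx <- local_maxima(y)
  idx <- idx[y[idx] > thr]
  if (length(idx) > 1L)
    idx <- idx[merge_close_peaks(c$volume_ml[idx], y[idx], merge_ml)]
  data.frame(
    apex_ml = c$volume_ml[idx],
    height = y[idx],
    type = if (length(idx)) classify_peak(c$volume_ml[idx]) else character(0),
    stringsAsFactors = FALSE
  )
}

#' Infer the multimeric states present in a chromatogram
#'
#' Detects apexes and returns the set of classified peak types
#' (unclassified apexes, i.e. those falling between windows, are not
#' states and are dropped from the set). Mixed states are allowed, e.g. a
#' sequence eluting as both monomer and tetramer.
#'
#' @param c A `g4_chromatogram`.
#' @param table Window table.
#' @param k,merge_ml Detection parameters.
#' @return Character vector (possibly empty) of distinct states.
#' @export
infer_multimeric_states <- function(c, table = ionex_windows(), k = 5,
                                    merge_ml = 0.1) {
  peaks <- detect_chromatogram_peaks(c, k = k, merge_ml = merge_ml)
  types <- peaks$type[peaks$type != "unclassified"]
  sort(unique(types))
}
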