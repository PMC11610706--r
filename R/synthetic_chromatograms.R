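#' Construct a chromatogram object
#'
#' @param volume_ml Monotone increasing elution-volume axis (mL).
#' @param absorbance Absorbance values, same length.
#' @param seq_id Sequence identifier.
#' @return An object of class `g4_chromatogram`.
#' @export
g4_chromatogram <- function(volume_ml, absorbance, seq_id = NA_character_) {
  if (length(volume_ml) != length(absorbance))
    stop("volume and absorbance must have equal length", call. = FALSE)
  if (any(diff(volume_ml) <= 0))
    stop("volume axis must be strictly increasing", call. = FALSE)
  if (!all(is.finite(absorbance)))
    stop("absorbance values must be finite", call. = FALSE)
  structure(list(volume_ml = as.numeric(volume_ml),
                 absorbance = as.numeric(absorbance), seq_id = seq_id),
            class = "g4_chromatogram")
}

#' Simulate an ion-exchange chromatogram for a set of multimeric states
#'
#' Places one Gaussian peak per requested state, with the apex centred
#' uniformly within that state's elution window (see [ionex_windows()]),
#' shrunk by `cfg$chrom_window_margin_ml` at both ends so the simulated
#' apex remains diagnostic of its window, plus white Gaussian noise.
#' The ground-truth state set and apex centres are attached as attribute
#' `"truth"`.
#'
#' Draws from the current RNG stream; seed at the caller.
#'
#' @param states Non-empty character vector of states among
#'   `not_G4`, `many_mutations`, `dimeric`, `tetrameric`, `monomeric`.
#' @param cfg A [g4_sim_config()].
#' @param seq_id Identifier carried on the chromatogram.
#' @return A `g4_chromatogram` with attribute `truth`.
#' @export
#' @examples
#' set.seed(1)
#' tr <- simulate_chromatogram("monomeric")
#' attr(tr, "truth")
simulate_chromatogram <- function(states, cfg = g4_sim_config(),
                                  seq_id = NA_character_) {
  states <- unique(states)
  if (length(states) == 0L)
    stop("states must be a non-empty set", call. = FALSE)
  win <- ionex_windows()
  unknown <- setdiff(states, win$type)
  if (length(unknown))
    stop("unknown multimeric state(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  vol <- seq(cfg$chrom_ml_min, cfg$chrom_ml_max,
             length.out = cfg$chrom_points)
  absb <- numeric(length(vol))
  m <- cfg$chrom_window_margin_ml
  centers <- vapply(states, function(st) {
    w <- win[win$type == st, ]
    stats::runif(1, w$lo + m, w$hi - m)
  }, numeric(1))
  heights <- stats::runif(length(states), 0.6, 1.0)
  for (j in seq_along(states))
    absb <- absb + heights[j] *
      exp(-(vol - centers[j])^2 / (2 * cfg$chrom_peak_sd_ml^2))
  if (cfg$chrom_noise_sd > 0)
    absb <- absb + stats::rnorm(length(vol), 0, cfg$chrom_noise_sd)

  tr <- g4_chromatogram(vol, absb, seq_id = seq_id)
  attr(tr, "truth") <- data.frame(state = states, center_ml = centers,
                                  height = heights)
  tr
}
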