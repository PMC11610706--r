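#' Construct a 1D spectrum object
#'
#' @param ppm Strictly monotone ppm axis.
#' @param intensity Intensity values, same length as `ppm`.
#' @param seq_id Sequence identifier.
#' @param timepoint Timepoint label (e.g. "t0", "t2months").
#' @return An object of class `g4_spectrum`.
#' @export
g4_spectrum <- function(ppm, intensity, seq_id = NA_character_,
                        timepoint = "t0") {
  if (length(ppm) != length(intensity))
    stop("ppm and intensity must have equal length", call. = FALSE)
  if (length(ppm) < 16L)
    stop("spectrum must have at least 16 points", call. = FALSE)
  d <- diff(ppm)
  if (!all(d > 0) && !all(d < 0))
    stop("ppm axis must be strictly monotone", call. = FALSE)
  if (!all(is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 seq_id = seq_id, timepoint = timepoint),
            class = "g4_spectrum")
}

#' @export
print.g4_spectrum <- function(x, ...) {
  cat(sprintf("<g4_spectrum> %s [%s]: %d points, %.2f-%.2f ppm\n",
              x$seq_id, x$timepoint, length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

lorentzian_mixture <- function(ppm, positions, heights, hwhm) {
  out <- numeric(length(ppm))
  for (j in seq_along(positions))
    out <- out + heights[j] * hwhm[j]^2 / ((ppm - positions[j])^2 + hwhm[j]^2)
  out
}

# draw realised peak positions for one spectrum from a class template;
# endpoints of the base fingerprint are always kept so the class span is
# stable, and a minimum separation is enforced so peaks stay resolvable
draw_template_peaks <- function(tpl, cfg, min_sep = 0.08) {
  if (!is.null(tpl$union_of)) {
    tpls <- class_spectrum_templates()[tpl$union_of]
    parts <- lapply(tpls, draw_template_peaks, cfg = cfg, min_sep = min_sep)
    pos <- sort(unlist(lapply(parts, `[[`, "positions")))
    snr <- max(vapply(parts, `[[`, numeric(1), "snr"))
    wf <- max(vapply(parts, `[[`, numeric(1), "width_factor"))
  } else if (isTRUE(tpl$random)) {
    n <- sample(tpl$n_range[1]:tpl$n_range[2], 1L)
    pos <- sort(stats::runif(n, cfg$ppm_min + 0.2, cfg$ppm_max - 0.1))
    snr <- stats::runif(1, tpl$snr_range[1], tpl$snr_range[2])
    wf <- 1
  } else {
    base <- tpl$positions
    n <- if (tpl$n_range[1] == tpl$n_range[2]) tpl$n_range[1] else
      sample(tpl$n_range[1]:tpl$n_range[2], 1L)
    n <- min(n, length(base))
    if (n == 0L)
      return(list(positions = numeric(0), snr = 1, width_factor = 1))
    if (n >= 2L && length(base) > 2L) {
      keep <- c(1L, length(base))
      mid <- setdiff(seq_along(base), keep)
      extra <- if (n > 2L) sort(sample(mid, n - 2L)) else integer(0)
      pos <- base[c(1L, extra, length(base))]
    } else {
      pos <- base[seq_len(n)]
    }
    pos <- pos + stats::rnorm(length(pos), 0, 0.008)
    snr <- stats::runif(1, tpl$snr_range[1], tpl$snr_range[2])
    wf <- if (is.null(tpl$width_factor)) 1 else tpl$width_factor
  }
  # drop any peak closer than min_sep to its left neighbour
  pos <- sort(pos)
  if (length(pos) > 1L) {
    keep <- c(TRUE, diff(pos) >= min_sep)
    while (!all(keep)) {
      pos <- pos[keep]
      keep <- c(TRUE, diff(pos) >= min_sep)
    }
  }
  pos <- pmin(pmax(pos, cfg$ppm_min + 0.05), cfg$ppm_max - 0.05)
  list(positions = pos, snr = snr, width_factor = wf)
}

#' Simulate a class-conditioned imino-region spectrum
#'
#' Generates one synthetic 1D proton spectrum of the 10-12 ppm
#' G-quadruplex imino region for a given spectral class: Lorentzian peaks
#' at jittered positions drawn from the class fingerprint template, plus
#' additive white Gaussian noise. The drawn ground-truth peak positions and
#' heights are attached as attribute `"truth"` for downstream validation.
#'
#' Draws from the current RNG stream; seed at cohort level (see
#' [simulate_spectra_cohort()]) for reproducibility.
#'
#' @param label A class label from [g4_class_labels()].
#' @param cfg A [g4_sim_config()].
#' @param seq_id,timepoint Metadata carried on the spectrum.
#' @return A `g4_spectrum` with attribute `truth`, a data.frame of
#'   ground-truth `position` and `height`.
#' @export
#' @examples
#' set.seed(1)
#' s <- simulate_spectrum("17.4", g4_sim_config(noise_sd = 0))
#' nrow(attr(s, "truth"))  # at most 6
simulate_spectrum <- function(label, cfg = g4_sim_config(),
                              seq_id = NA_character_, timepoint = "t0") {
  tpls <- class_spectrum_templates()
  if (!label %in% names(tpls))
    stop("no spectrum template for class '", label, "'", call. = FALSE)
  draw <- draw_template_peaks(tpls[[label]], cfg)
  ppm <- seq(cfg$ppm_min, cfg$ppm_max, length.out = cfg$points)

  npk <- length(draw$positions)
  if (npk > 0L) {
    rel <- stats::runif(npk, 0.6, 1.0)
    peak_scale <- if (cfg$noise_sd > 0) draw$snr * cfg$noise_sd else 1
    heights <- rel / max(rel) * peak_scale
    hwhm <- rep(cfg$linewidth_ppm * draw$width_factor / 2, npk)
    intensity <- lorentzian_mixture(ppm, draw$positions, heights, hwhm)
  } else {
    heights <- numeric(0)
    intensity <- numeric(cfg$points)
  }
  if (cfg$noise_sd > 0)
    intensity <- intensity + stats::rnorm(cfg$points, 0, cfg$noise_sd)

  s <- g4_spectrum(ppm, intensity, seq_id = seq_id, timepoint = timepoint)
  attr(s, "truth") <- data.frame(position = draw$positions, height = heights)
  attr(s, "class_label") <- label
  s
}

#' Simulate a cohort of class-conditioned spectra
#'
#' @param labels Character vector of class labels, one spectrum each.
#' @param cfg A [g4_sim_config()]; `cfg$seed` seeds the draw.
#' @param seq_ids Optional sequence ids (default `spec_001`, ...).
#' @return List of `g4_spectrum` objects, names = seq_ids.
#' @export
simulate_spectra_cohort <- function(labels, cfg = g4_sim_config(),
                                    seq_ids = NULL) {
  if (is.null(seq_ids))
    seq_ids <- sprintf("spec_%03d", seq_along(labels))
  set.seed(cfg$seed)
  out <- Map(function(lab, id) simulate_spectrum(lab, cfg, seq_id = id),
             labels, seq_ids)
  names(out) <- seq_ids
  out
}
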