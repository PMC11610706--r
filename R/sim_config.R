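#' Simulation configuration
#'
#' Central parameter block for the synthetic-data generators. The imino
#' region of interest is 10-12 ppm, sampled on a 2048-point grid; peaks are
#' Lorentzian with a default full width of 0.02 ppm; noise is additive white
#' Gaussian, and SNR is defined as peak height over noise SD.
#'
#' @param seed Integer seed consumed by the cohort-level generators.
#' @param ppm_min,ppm_max Bounds of the simulated imino window (ppm).
#' @param points Number of grid points.
#' @param linewidth_ppm Lorentzian full width at half maximum (ppm).
#' @param noise_sd Noise standard deviation (intensity units).
#' @param within_class_rsd Relative SD of activities within a class.
#' @param class_activity_means Class-by-activity mean table; defaults to
#'   [default_activity_means()].
#' @param chrom_ml_min,chrom_ml_max,chrom_points Chromatogram volume axis (mL).
#' @param chrom_peak_sd_ml Gaussian peak SD of chromatographic peaks (mL).
#' @param chrom_noise_sd Chromatogram noise SD (absorbance units).
#' @param chrom_window_margin_ml Margin kept between a simulated apex centre
#'   and its elution-window boundary (mL), so simulated apexes are
#'   diagnostic of their window.
#' @return A list of class `g4_sim_config`.
#' @export
g4_sim_config <- function(seed = 1L,
                          ppm_min = 10, ppm_max = 12, points = 2048L,
                          linewidth_ppm = 0.02, noise_sd = 0.01,
                          within_class_rsd = 0.1,
                          class_activity_means = default_activity_means(),
                          chrom_ml_min = 4.5, chrom_ml_max = 9.5,
                          chrom_points = 1001L,
                          chrom_peak_sd_ml = 0.04, chrom_noise_sd = 0.02,
                          chrom_window_margin_ml = 0.05) {
  stopifnot(ppm_min < ppm_max, points >= 16L, linewidth_ppm > 0,
            noise_sd >= 0, within_class_rsd >= 0)
  structure(list(
    seed = as.integer(seed),
    ppm_min = ppm_min, ppm_max = ppm_max, points = as.integer(points),
    linewidth_ppm = linewidth_ppm, noise_sd = noise_sd,
    within_class_rsd = within_class_rsd,
    class_activity_means = class_activity_means,
    chrom_ml_min = chrom_ml_min, chrom_ml_max = chrom_ml_max,
    chrom_points = as.integer(chrom_points),
    chrom_peak_sd_ml = chrom_peak_sd_ml, chrom_noise_sd = chrom_noise_sd,
    chrom_window_margin_ml = chrom_window_margin_ml
  ), class = "g4_sim_config")
}

#' Class-conditioned spectral fingerprint templates
#'
#' Each major spectral class is represented by a caricature fingerprint:
#' a set of base imino peak positions (ppm), a range for the number of
#' peaks realised in a given spectrum (draws always retain the outermost
#' base positions, so the ppm span of a class is stable), an SNR range and
#' a linewidth multiplier (broad, low-SNR classes correspond to multimeric
#' or exchange-broadened species). Class 17.4 spans ~0.8 ppm with up to six
#' peaks; Class 17.4s26 spans ~1.5 ppm with eleven or more; Class
#' 17.4+17.4s26 is the union of the two patterns; no_G4_signals has no
#' peaks; no_pattern draws unstructured per-sequence positions.
#'
#' @return Named list of templates, one per label in [g4_class_labels()].
#' @export
class_spectrum_templates <- function() {
  tpl <- function(positions, n_range, snr_range, width_factor = 1)
    list(positions = positions, n_range = n_range,
         snr_range = snr_range, width_factor = width_factor)
  list(
    "17.3"          = tpl(seq(10.45, 11.95, length.out = 12), c(12, 12), c(40, 60)),
    "17.63"         = tpl(c(11.00, 11.25, 11.50), c(2, 3), c(6, 10), width_factor = 2),
    "17.4"          = tpl(seq(10.90, 11.70, length.out = 6), c(3, 6), c(20, 30)),
    "17.4s26"       = tpl(seq(10.25, 11.75, length.out = 14), c(11, 14), c(8, 15)),
    "17.4+17.4s26"  = list(union_of = c("17.4", "17.4s26")),
    "17.49"         = tpl(seq(10.50, 11.90, length.out = 11), c(10, 11), c(30, 50)),
    "17.28"         = tpl(seq(10.50, 11.80, length.out = 11), c(6, 11), c(10, 18)),
    "17.36"         = tpl(seq(10.70, 11.60, length.out = 7), c(5, 7), c(10, 20)),
    "17.180"        = tpl(c(10.60, 11.00, 11.40, 11.80), c(3, 4), c(8, 15)),
    "17.154"        = tpl(c(10.75, 11.15, 11.55, 11.90), c(3, 4), c(6, 12)),
    "no_pattern"    = list(random = TRUE, n_range = c(3, 8), snr_range = c(8, 20)),
    "no_G4_signals" = tpl(numeric(0), c(0, 0), c(1, 1))
  )
}

#' Default class-by-activity mean table
#'
#' Encodes the qualitative activity landscape of the spectral classes in
#' arbitrary units (background ~1): Class 17.3 has the maximal intrinsic
#' fluorescence (Flu) and peroxidase (Per) activities; the tetramer-forming
#' Class 17.63 is high in tetramer formation (Tet) and GTP binding, with
#' mean GTP 12-fold above and mean Per 3-fold below Class 17.4; the
#' dimer-forming 17.4 family is high in dimer formation (Dim); sequences
#' without G4 signals sit at background.
#'
#' @return A data.frame with rownames = class labels and columns
#'   Flu, Tet, Dim, Per, GTP.
#' @export
default_activity_means <- function() {
  m <- rbind(
    "17.3"          = c(100,  5,  5, 100, 40),
    "17.63"         = c(  8, 80, 10,  10, 60),
    "17.4"          = c( 10,  5, 80,  30,  5),
    "17.4s26"       = c( 12,  8, 70,  28,  6),
    "17.4+17.4s26"  = c( 11,  6, 75,  29,  5.5),
    "17.49"         = c( 25,  8,  8,  30, 15),
    "17.28"         = c(  4, 12, 20,   8,  6),
    "17.36"         = c(  5, 10, 15,  10,  8),
    "17.180"        = c(  2,  2,  3,   3,  3),
    "17.154"        = c(  2,  3,  4,   3,  2.5),
    "no_pattern"    = c(  2,  2,  2,   2,  2),
    "no_G4_signals" = c(  1,  1,  1,   1,  1)
  )
  colnames(m) <- c("Flu", "Tet", "Dim", "Per", "GTP")
  as.data.frame(m)
}

#' Expected multimeric-state fingerprint per spectral class
#'
#' Maps each spectral class to the ion-exchange peak types its members
#' typically produce: monomer-forming classes elute in the monomeric
#' window, the dimer-forming 17.4 family in the dimeric window, the
#' tetramer-forming 17.63 in the tetrameric window; heavily mutated classes
#' fall in the many-mutations or non-G4 windows.
#'
#' @return Named list mapping class label to a character vector of states.
#' @export
class_state_map <- function() {
  list(
    "17.3"          = "monomeric",
    "17.63"         = "tetrameric",
    "17.4"          = "dimeric",
    "17.4s26"       = "dimeric",
    "17.4+17.4s26"  = "dimeric",
    "17.49"         = "monomeric",
    "17.28"         = "dimeric",
    "17.36"         = "dimeric",
    "17.180"        = "many_mutations",
    "17.154"        = "many_mutations",
    "no_pattern"    = "not_G4",
    "no_G4_signals" = "not_G4"
  )
}
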