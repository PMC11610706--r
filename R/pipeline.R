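#' Pipeline configuration
#'
#' Assembles and validates the configuration for the end-to-end run:
#' reference topology, simulation settings, preprocessing window and
#' thresholds, clustering parameters, ion-exchange settings and the
#' activity-profile permutation test. Unknown keys are rejected.
#'
#' @param seed Master seed; every stochastic stage derives from it.
#' @param reference 17-nt reference scaffold string.
#' @param simulation Named list overriding [g4_sim_config()] fields
#'   (e.g. `list(noise_sd = 0.02)`).
#' @param prep List with `window` (ppm pair), `k` (detection threshold),
#'   `min_sep_ppm`.
#' @param clustering List with `metric`, `linkage`, `k`
#'   (`"auto"` or integer, or `"n_classes"` to use the number of
#'   simulated signal classes).
#' @param ionex List with `k`, `merge_ml`.
#' @param profile List with `n_perm`.
#' @param n_per_class Spectra simulated per signal class.
#' @return Validated list of class `g4_config`.
#' @export
g4_config <- function(seed = 1L,
                      reference = "GGGTGGGTTGGGTGGGA",
                      simulation = list(),
                      prep = list(window = c(10, 12), k = 5,
                                  min_sep_ppm = 0.03),
                      clustering = list(metric = "euclidean",
                                        linkage = "ward",
                                        k = "n_classes",
                                        bin_width = 0.05),
                      ionex = list(k = 5, merge_ml = 0.1),
                      profile = list(n_perm = 500),
                      n_per_class = 10L) {
  cfg <- list(seed = as.integer(seed), reference = reference,
              simulation = simulation, prep = prep,
              clustering = clustering, ionex = ionex, profile = profile,
              n_per_class = as.integer(n_per_class))
  validate_config(cfg)
  structure(cfg, class = "g4_config")
}

config_schema <- list(
  seed = NULL, reference = NULL, n_per_class = NULL,
  simulation = c("seed", "ppm_min", "ppm_max", "points", "linewidth_ppm",
                 "noise_sd", "within_class_rsd", "class_activity_means",
                 "chrom_ml_min", "chrom_ml_max", "chrom_points",
                 "chrom_peak_sd_ml", "chrom_noise_sd",
                 "chrom_window_margin_ml"),
  prep = c("window", "k", "min_sep_ppm"),
  clustering = c("metric", "linkage", "k", "bin_width"),
  ionex = c("k", "merge_ml"),
  profile = c("n_perm")
)

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (block in names(config_schema)) {
    allowed <- config_schema[[block]]
    if (is.null(allowed) || is.null(cfg[[block]])) next
    bad <- setdiff(names(cfg[[block]]), allowed)
    if (length(bad))
      stop("unknown config key(s) in '", block, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match [g4_config()]
#'   arguments.
#' @return A validated `g4_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(g4_config, vals)
}

derive_seed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Run the full screening pipeline on synthetic data
#'
#' Executes the stages in order: (1) enumerate and classify the 496-member
#' library; (2) simulate class-conditioned spectra for every signal class;
#' (3) preprocess (trim, filter, scale) and cluster the spectra, scoring
#' agreement against the generating classes; (4) simulate and type
#' ion-exchange chromatograms, scoring state-set recovery; (5) simulate
#' activities across the library classes and compute renormalised class
#' profiles with the RSD permutation null. Writes per-stage outputs and a
#' manifest under `out_dir`.
#'
#' @param cfg A [g4_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly: a list with per-stage summaries, file
#'   paths and md5 hashes.
#' @export
run_pipeline <- function(cfg = g4_config(), out_dir = tempfile("g4run")) {
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("g4screen")),
                   seed = cfg$seed, stages = list())
  paths <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res
  }

  sim_cfg <- do.call(g4_sim_config,
                     c(list(seed = derive_seed(cfg$seed, 101L)),
                       cfg$simulation))

  # stage 1: library
  lib <- stage("library", {
    l <- assign_rule_class(enumerate_library(g4_reference(cfg$reference)))
    write_library(l, fasta = file.path(out_dir, "library.fasta"),
                  annot = file.path(out_dir, "library.tsv"))
    l
  })
  paths <- c(paths, file.path(out_dir, c("library.fasta", "library.tsv")))
  manifest$stages$library <- list(n_sequences = nrow(lib),
                                  classes = as.list(table(lib$class)))

  # stage 2+3: spectra, preprocessing, clustering
  signal_classes <- setdiff(g4_class_labels(), c("no_pattern", "no_G4_signals"))
  cohort_labels <- c(rep(signal_classes, each = cfg$n_per_class),
                     rep("no_G4_signals", cfg$n_per_class))
  spectra <- stage("simulate_spectra",
                   simulate_spectra_cohort(cohort_labels, sim_cfg))
  clus <- stage("cluster", {
    k <- cfg$clustering$k
    if (identical(k, "n_classes")) k <- length(signal_classes)
    cluster_spectra_cohort(spectra,
                           lo = cfg$prep$window[1], hi = cfg$prep$window[2],
                           k_signals = cfg$prep$k,
                           metric = cfg$clustering$metric,
                           linkage = cfg$clustering$linkage, k = k,
                           bin_width = cfg$clustering$bin_width)
  })
  truth <- cohort_labels[match(clus$kept, names(spectra))]
  agree <- cluster_class_agreement(clus$clustering$labels, truth)
  label_tab <- data.frame(seq_id = clus$kept, cluster = clus$clustering$labels,
                          rule_class = truth)
  utils::write.table(label_tab, file.path(out_dir, "clusters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(agree, file.path(out_dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, file.path(out_dir, c("clusters.tsv", "agreement.json")))
  manifest$stages$clustering <- list(
    n_simulated = length(spectra), n_clustered = length(clus$kept),
    n_filtered = length(clus$dropped), ari = agree$ari,
    purity = agree$purity)

  # stage 4: ion exchange
  ionex_res <- stage("ionex", {
    set.seed(derive_seed(cfg$seed, 202L))
    smap <- class_state_map()
    rows <- lapply(seq_along(signal_classes), function(i) {
      states <- smap[[signal_classes[i]]]
      tr <- simulate_chromatogram(states, sim_cfg,
                                  seq_id = sprintf("ix_%02d", i))
      inferred <- infer_multimeric_states(tr, k = cfg$ionex$k,
                                          merge_ml = cfg$ionex$merge_ml)
      data.frame(seq_id = tr$seq_id, class = signal_classes[i],
                 truth = paste(sort(states), collapse = "+"),
                 inferred = paste(inferred, collapse = "+"),
                 recovered = identical(sort(states), inferred))
    })
    do.call(rbind, rows)
  })
  utils::write.table(ionex_res, file.path(out_dir, "ionex_states.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, file.path(out_dir, "ionex_states.tsv"))
  manifest$stages$ionex <- list(recovery_rate = mean(ionex_res$recovered))

  # stage 5: activity profiles
  prof <- stage("profiles", {
    set.seed(derive_seed(cfg$seed, 303L))
    act <- simulate_activities(lib$class, sim_cfg, seq_ids = lib$seq_id)
    write_activity_table(act, file.path(out_dir, "activities.tsv"))
    p <- class_profiles(act)
    radar_export(p, file.path(out_dir, "profiles.json"))
    null_flu <- rsd_random_null(act, "17.3", "Flu",
                                n_perm = cfg$profile$n_perm,
                                seed = derive_seed(cfg$seed, 404L))
    list(profiles = p, act = act, null_p_17_3_flu = null_flu$p)
  })
  paths <- c(paths, file.path(out_dir, c("activities.tsv", "profiles.json")))
  g <- prof$profiles
  manifest$stages$profiles <- list(
    gtp_ratio_17_63_vs_17_4 =
      g$GTP_mean[g$class == "17.63"] / g$GTP_mean[g$class == "17.4"],
    per_ratio_17_63_vs_17_4 =
      g$Per_mean[g$class == "17.63"] / g$Per_mean[g$class == "17.4"],
    rsd_null_p_17_3_flu = prof$null_p_17_3_flu)

  manifest$files <- as.list(tools::md5sum(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
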