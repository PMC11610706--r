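#' Simulate per-sequence activity tables with class structure
#'
#' Draws the five biochemical activities (Flu = intrinsic fluorescence,
#' Tet = tetramer formation, Dim = dimer formation, Per = peroxidase
#' activity, GTP = GTP binding) for a list of sequences. Each value is
#' drawn around its class mean with relative SD `cfg$within_class_rsd`
#' (truncated at zero), so within-class spread is small compared to the
#' between-class spread encoded in the mean table.
#'
#' Draws from the current RNG stream; seed at the caller.
#'
#' @param labels Character vector of class labels, one row per sequence.
#' @param cfg A [g4_sim_config()]; class means come from
#'   `cfg$class_activity_means`.
#' @param seq_ids Optional ids (default `seq_001`, ...).
#' @return A data.frame with columns `seq_id`, `class`, `Flu`, `Tet`,
#'   `Dim`, `Per`, `GTP`.
#' @export
#' @examples
#' set.seed(1)
#' act <- simulate_activities(rep(c("17.3", "17.63"), each = 5))
#' aggregate(GTP ~ class, act, mean)
simulate_activities <- function(labels, cfg = g4_sim_config(),
                                seq_ids = NULL) {
  means <- cfg$class_activity_means
  missing_cls <- setdiff(unique(labels), rownames(means))
  if (length(missing_cls))
    stop("no activity means configured for class(es): ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  if (is.null(seq_ids))
    seq_ids <- sprintf("seq_%03d", seq_along(labels))
  n <- length(labels)
  acts <- colnames(means)
  vals <- sapply(acts, function(a) {
    mu <- means[labels, a]
    pmax(0, stats::rnorm(n, mean = mu, sd = cfg$within_class_rsd * mu))
  })
  vals <- matrix(vals, nrow = n, dimnames = list(NULL, acts))
  data.frame(seq_id = seq_ids, class = labels, vals,
             stringsAsFactors = FALSE, check.names = FALSE)
}
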