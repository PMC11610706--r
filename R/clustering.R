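#' Resample a spectrum onto a common ppm grid
#'
#' Linear interpolation onto `grid`; points outside the source axis are an
#' error (the clustering grid must lie within every spectrum's axis).
#'
#' @param s A `g4_spectrum`.
#' @param grid Target ppm grid.
#' @return A `g4_spectrum` on `grid`.
#' @export
resample_spectrum <- function(s, grid) {
  if (min(grid) < min(s$ppm) || max(grid) > max(s$ppm))
    stop("target grid extends beyond the spectrum axis", call. = FALSE)
  y <- stats::approx(s$ppm, s$intensity, xout = grid)$y
  out <- g4_spectrum(grid, y, seq_id = s$seq_id, timepoint = s$timepoint)
  attr(out, "class_label") <- attr(s, "class_label")
  out
}

#' Bin a spectrum into fixed-width ppm buckets
#'
#' Standard chemometric bucketing: the axis is divided into contiguous
#' buckets of `width` ppm and each bucket takes the mean intensity of the
#' points it contains (empty buckets are 0). Binning makes the spectral
#' distance tolerant to the small chemical-shift jitter between samples
#' that would otherwise decorrelate narrow lines.
#'
#' @param s A `g4_spectrum`.
#' @param width Bucket width in ppm.
#' @return A `g4_spectrum` on the bucket-centre grid.
#' @export
bin_spectrum <- function(s, width = 0.05) {
  stopifnot(inherits(s, "g4_spectrum"), width > 0)
  breaks <- seq(min(s$ppm), max(s$ppm) + width, by = width)
  g <- cut(s$ppm, breaks, include.lowest = TRUE)
  y <- as.numeric(tapply(s$intensity, g, mean))
  y[is.na(y)] <- 0
  centers <- breaks[-length(breaks)] + width / 2
  out <- g4_spectrum(centers, y, seq_id = s$seq_id, timepoint = s$timepoint)
  attr(out, "class_label") <- attr(s, "class_label")
  out
}

#' Pairwise distance matrix between spectra
#'
#' Spectra must already be trimmed, scaled and on one common grid.
#' Metrics: `euclidean` (L2 distance between intensity vectors) or
#' `correlation` (1 - Pearson r, invariant to affine intensity rescaling).
#'
#' @param spectra List of `g4_spectrum` objects on a common grid.
#' @param metric `"euclidean"` or `"correlation"`.
#' @return Symmetric distance matrix with seq_ids as dimnames.
#' @export
spectra_distance_matrix <- function(spectra,
                                    metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  grids <- lapply(spectra, `[[`, "ppm")
  if (!all(vapply(grids[-1], function(g) isTRUE(all.equal(g, grids[[1]])),
                  logical(1))))
    stop("all spectra must share one common ppm grid", call. = FALSE)
  x <- do.call(rbind, lapply(spectra, `[[`, "intensity"))
  rownames(x) <- vapply(spectra, `[[`, character(1), "seq_id")
  d <- if (metric == "euclidean") {
    as.matrix(stats::dist(x))
  } else {
    1 - stats::cor(t(x))
  }
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering of spectra
#'
#' Deterministic agglomerative clustering (via [stats::hclust()]) of a
#' precomputed distance matrix, cut into `k` groups.
#'
#' @param d Symmetric distance matrix (as from
#'   [spectra_distance_matrix()]).
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward D2).
#' @param k Number of clusters, `2 <= k <= n`.
#' @return A list of class `g4_clustering` with `seq_ids`, `labels`
#'   (integer cluster per sequence, 1..k, no empty cluster), `merge`,
#'   `height` and `params`.
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete", "ward"),
                                 k) {
  linkage <- match.arg(linkage)
  n <- nrow(d)
  if (k < 2 || k > n)
    stop("k must be between 2 and the number of spectra (", n, ")",
         call. = FALSE)
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::as.dist(d), method = method)
  labels <- stats::cutree(hc, k = k)
  structure(list(
    seq_ids = rownames(d),
    labels = unname(labels),
    merge = hc$merge,
    height = hc$height,
    params = list(linkage = linkage, k = k)
  ), class = "g4_clustering")
}

#' Choose the number of clusters by mean silhouette width
#'
#' @param d Distance matrix.
#' @param k_range Candidate cluster counts (default 2..15).
#' @param linkage Linkage passed to [hierarchical_cluster()].
#' @return The k with the highest mean silhouette width.
#' @export
choose_k_silhouette <- function(d, k_range = 2:15, linkage = "average") {
  k_range <- k_range[k_range >= 2 & k_range <= nrow(d) - 1]
  sil <- vapply(k_range, function(k) {
    cl <- hierarchical_cluster(d, linkage, k)
    mean(cluster::silhouette(cl$labels, stats::as.dist(d))[, 3])
  }, numeric(1))
  k_range[which.max(sil)]
}

#' Agreement between a clustering and reference class labels
#'
#' @param labels Integer (or factor) cluster labels.
#' @param truth Reference class labels, same length.
#' @return List with `ari` (adjusted Rand index) and `purity` (fraction of
#'   items in their cluster's majority class).
#' @export
cluster_class_agreement <- function(labels, truth) {
  if (length(labels) != length(truth))
    stop("labels and truth must have equal length", call. = FALSE)
  if (length(unique(truth)) < 2L)
    stop("need at least two distinct truth labels", call. = FALSE)
  ari <- mclust::adjustedRandIndex(labels, truth)
  tab <- table(labels, truth)
  purity <- sum(apply(tab, 1L, max)) / length(labels)
  list(ari = ari, purity = purity)
}

#' Filter, resample and cluster a cohort of spectra
#'
#' Convenience wrapper running the preprocessing contract ahead of
#' clustering: trim to the imino window, drop spectra without signals,
#' scale to [0, 1], resample to a common grid, bin into ppm buckets, and
#' cluster.
#'
#' @param spectra List of `g4_spectrum` objects.
#' @param lo,hi Imino window (ppm).
#' @param k_signals Signal-detection threshold for filtering.
#' @param metric,linkage Clustering parameters.
#' @param k Number of clusters, or `"auto"` for silhouette selection.
#' @param bin_width Bucket width in ppm for [bin_spectrum()]; `NULL`
#'   clusters the unbinned grid.
#' @return List with `clustering` (a `g4_clustering`), `kept` (seq_ids that
#'   entered clustering) and `dropped` (seq_ids filtered out).
#' @export
cluster_spectra_cohort <- function(spectra, lo = 10, hi = 12, k_signals = 5,
                                   metric = "euclidean", linkage = "ward",
                                   k = "auto", bin_width = 0.05) {
  trimmed <- lapply(spectra, trim_region, lo = lo, hi = hi)
  keep <- vapply(trimmed, has_g4_signals, logical(1), k = k_signals)
  kept <- trimmed[keep]
  if (length(kept) < 3L)
    stop("fewer than 3 spectra contain signals; nothing to cluster",
         call. = FALSE)
  scaled <- lapply(kept, function(s) suppressWarnings(scale01(s)))
  grid <- scaled[[1]]$ppm
  common <- lapply(scaled, resample_spectrum, grid = grid)
  if (!is.null(bin_width))
    common <- lapply(common, bin_spectrum, width = bin_width)
  d <- spectra_distance_matrix(common, metric = metric)
  if (identical(k, "auto")) k <- choose_k_silhouette(d, linkage = linkage)
  list(
    clustering = hierarchical_cluster(d, linkage = linkage, k = k),
    kept = names(spectra)[keep],
    dropped = names(spectra)[!keep]
  )
}
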