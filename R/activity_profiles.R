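activity_columns <- c("Flu", "Tet", "Dim", "Per", "GTP")

check_activity_table <- function(t) {
  miss <- setdiff(c("seq_id", "class", activity_columns), names(t))
  if (length(miss))
    stop("activity table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(t$seq_id))
    stop("activity table has duplicated seq_ids", call. = FALSE)
  if (any(!is.finite(as.matrix(t[activity_columns]))))
    stop("activity table has missing or non-finite activities", call. = FALSE)
  invisible(t)
}

#' Per-class activity profiles, renormalised to 0-100
#'
#' Computes the mean of each activity within each class and linearly
#' renormalises each activity across classes so that the class with the
#' maximal mean scores 100: `renorm = 100 * mean / max(class means)`.
#' Zero is anchored at zero activity (no minimum subtraction), so ratios
#' between classes are preserved.
#'
#' @param t Activity table with columns `seq_id`, `class`, `Flu`, `Tet`,
#'   `Dim`, `Per`, `GTP`.
#' @return data.frame of class `g4_profiles`: one row per class, columns
#'   `class`, `<activity>_mean` and `<activity>_renorm`.
#' @export
#' @examples
#' t <- data.frame(seq_id = c("a", "b"), class = c("x", "y"),
#'                 Flu = c(6, 2), Tet = 1:2, Dim = 2:1,
#'                 Per = c(3, 3), GTP = c(6, 2))
#' class_profiles(t)
class_profiles <- function(t) {
  check_activity_table(t)
  cls <- sort(unique(t$class))
  raw <- t(vapply(cls, function(cl)
    colMeans(t[t$class == cl, activity_columns, drop = FALSE]),
    numeric(length(activity_columns))))
  renorm <- raw
  for (a in seq_len(ncol(raw))) {
    mx <- max(raw[, a])
    if (mx == 0) {
      warning("activity '", activity_columns[a],
              "' has zero mean in every class; renormalised to 0")
      renorm[, a] <- 0
    } else {
      renorm[, a] <- 100 * raw[, a] / mx
    }
  }
  out <- data.frame(class = cls, raw, renorm, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("class", paste0(activity_columns, "_mean"),
                  paste0(activity_columns, "_renorm"))
  rownames(out) <- NULL
  class(out) <- c("g4_profiles", "data.frame")
  out
}

#' Relative standard deviation of an activity within a class
#'
#' @param t Activity table.
#' @param class Class label.
#' @param activity One of Flu, Tet, Dim, Per, GTP.
#' @return Sample SD divided by the mean.
#' @export
rsd_within_class <- function(t, class, activity) {
  stopifnot(activity %in% activity_columns)
  x <- t[t$class == class, activity]
  if (length(x) < 2L)
    stop("class '", class, "' has fewer than 2 members", call. = FALSE)
  m <- mean(x)
  if (m == 0)
    stop("class '", class, "' has zero mean ", activity, call. = FALSE)
  stats::sd(x) / m
}

#' Permutation null for within-class RSD
#'
#' Tests whether the activity RSD within a class is smaller than expected
#' for a randomly chosen group of sequences of the same size: draws
#' `n_perm` random groups (without replacement within each draw) from the
#' whole table, computes their RSD, and reports the one-sided add-one
#' smoothed p-value `p = (1 + #{null <= observed}) / (1 + n_perm)`.
#'
#' @param t Activity table.
#' @param class Class label whose homogeneity is tested.
#' @param activity Activity column.
#' @param n_perm Number of random groups (>= 100).
#' @param seed Optional seed for the draws.
#' @return List with `observed` RSD, `null_rsds` and `p`.
#' @export
rsd_random_null <- function(t, class, activity, n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- rsd_within_class(t, class, activity)
  size <- sum(t$class == class)
  x <- t[[activity]]
  null_rsds <- vapply(seq_len(n_perm), function(i) {
    g <- x[sample.int(length(x), size)]
    stats::sd(g) / mean(g)
  }, numeric(1))
  list(observed = obs, null_rsds = null_rsds,
       p = (1 + sum(null_rsds <= obs)) / (1 + n_perm))
}

#' Export / import activity profiles for radar plotting
#'
#' Lossless JSON serialisation of a profile table: one record per class
#' with the five renormalised axes (and raw means).
#'
#' @param profiles A `g4_profiles` table from [class_profiles()].
#' @param path Output JSON file; `NULL` returns the JSON string.
#' @return `radar_export()`: the path (or JSON string) invisibly;
#'   `radar_import()`: the profile table.
#' @export
radar_export <- function(profiles, path = NULL) {
  json <- jsonlite::toJSON(as.data.frame(profiles), digits = NA,
                           dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(invisible(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname radar_export
#' @param x Path or JSON string produced by [radar_export()].
#' @export
radar_import <- function(x) {
  df <- jsonlite::fromJSON(x)
  if (length(df) == 0L)
    df <- data.frame(class = character(0))
  class(df) <- c("g4_profiles", "data.frame")
  df
}
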