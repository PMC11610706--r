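#' Enumerate the 496-member variant library
#'
#' Builds the full variant library from the reference scaffold: the tetrad
#' sub-library (all 4^4 = 256 base combinations at the central-tetrad
#' positions 2, 6, 11, 15, with reference loops) and three loop sub-libraries
#' (all 3^4 = 81 combinations of A/C/T -- never G -- at loop positions
#' 4, 8, 9, 13), each in a fixed tetrad background: the reference GGGG
#' (monomer-forming), G-to-A at position 2 (AGGG, a representative
#' dimer-former) and G-to-A at position 11 (GGAG, a representative
#' tetramer-former).
#'
#' The raw enumeration has 499 records; the reference-loop member of each
#' loop sub-library duplicates a tetrad sub-library member, so exactly three
#' records are merged, leaving 496 unique sequences. Merged records keep the
#' tetrad sub-library id as canonical and accumulate all sub-library tags.
#'
#' @param ref A [g4_reference()] topology.
#' @param dedup Merge identical sequence strings (default `TRUE`). With
#'   `dedup = FALSE` the raw 499-row enumeration is returned.
#' @return A data.frame with one row per (unique) sequence and columns
#'   `seq_id`, `sequence`, `sublibrary` (comma-separated tags),
#'   `tetrad_pattern`, `loop_pattern`, `n_tetrad_mutations`,
#'   `mutated_tetrad_positions` (comma-separated), `n_loop_adenosines_489`.
#' @export
#' @examples
#' lib <- enumerate_library()
#' nrow(lib)                       # 496
#' table(lib$n_tetrad_mutations)
enumerate_library <- function(ref = g4_reference(), dedup = TRUE) {
  validate_reference(ref)
  ref_chars <- strsplit(ref$sequence, "")[[1]]
  tet_pos <- ref$central_tetrad_positions
  loop_pos <- ref$loop_positions

  build <- function(positions, alphabet, background, tag, id_prefix) {
    combos <- expand.grid(rep(list(alphabet), length(positions)),
                          stringsAsFactors = FALSE)
    # enumerate with the first listed position varying slowest
    combos <- combos[do.call(order, combos), , drop = FALSE]
    seqs <- apply(combos, 1L, function(b) {
      chars <- background
      chars[positions] <- b
      paste(chars, collapse = "")
    })
    pat <- apply(combos, 1L, paste, collapse = "")
    data.frame(
      seq_id = sprintf("%s_%s", id_prefix, pat),
      sequence = seqs,
      sublibrary = tag,
      stringsAsFactors = FALSE
    )
  }

  bases <- c("A", "C", "G", "T")
  h <- c("A", "C", "T")

  bg_17_4 <- ref_chars; bg_17_4[2L] <- "A"
  bg_17_10 <- ref_chars; bg_17_10[11L] <- "A"

  raw <- rbind(
    build(tet_pos, bases, ref_chars, "tetrad", "tet"),
    build(loop_pos, h, ref_chars, "loop_17_3", "l3"),
    build(loop_pos, h, bg_17_4, "loop_17_4", "l4"),
    build(loop_pos, h, bg_17_10, "loop_17_10", "l10")
  )

  if (dedup) {
    # merge identical strings; the tetrad sub-library record is canonical
    split_idx <- split(seq_len(nrow(raw)), raw$sequence)
    merged <- lapply(split_idx, function(i) {
      i <- i[order(match(raw$sublibrary[i],
                         c("tetrad", "loop_17_3", "loop_17_4", "loop_17_10")))]
      data.frame(
        seq_id = raw$seq_id[i[1L]],
        sequence = raw$sequence[i[1L]],
        sublibrary = paste(raw$sublibrary[i], collapse = ","),
        stringsAsFactors = FALSE
      )
    })
    raw <- do.call(rbind, merged)
    raw <- raw[order(raw$seq_id), , drop = FALSE]
    rownames(raw) <- NULL
  }

  ann <- annotate_sequences(raw$sequence, ref)
  out <- cbind(raw, ann[, setdiff(names(ann), "sequence"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Annotate a 17-nt sequence against the reference topology
#'
#' Fills the mutational-signature fields used by the rule classifier: the
#' base pattern at the central-tetrad positions (2, 6, 11, 15), the loop
#' pattern (4, 8, 9, 13), the number and location of central-tetrad
#' mutations, and the number of adenosines at the first three loop positions
#' (4, 8, 9), which separates the 17.4-family spectral classes.
#'
#' @param sequence A 17-character DNA string (vectorised).
#' @param ref A [g4_reference()] topology.
#' @return A data.frame with columns `sequence`, `tetrad_pattern`,
#'   `loop_pattern`, `n_tetrad_mutations`, `mutated_tetrad_positions`,
#'   `n_loop_adenosines_489`.
#' @export
annotate_sequences <- function(sequence, ref = g4_reference()) {
  sequence <- toupper(sequence)
  bad_len <- nchar(sequence) != 17L
  if (any(bad_len))
    stop("malformed sequence: length must be 17 (got ",
         paste(unique(nchar(sequence[bad_len])), collapse = ", "), ")",
         call. = FALSE)
  if (any(grepl("[^ACGT]", sequence)))
    stop("malformed sequence: alphabet must be A, C, G, T", call. = FALSE)

  tet_pos <- ref$central_tetrad_positions
  loop_pos <- ref$loop_positions
  mat <- do.call(rbind, strsplit(sequence, ""))

  tet <- mat[, tet_pos, drop = FALSE]
  tetrad_pattern <- apply(tet, 1L, paste, collapse = "")
  loop_pattern <- apply(mat[, loop_pos, drop = FALSE], 1L, paste, collapse = "")
  mut <- tet != "G"
  n_tet <- rowSums(mut)
  mut_pos <- apply(mut, 1L, function(m) paste(tet_pos[m], collapse = ","))
  n_a489 <- rowSums(mat[, c(4L, 8L, 9L), drop = FALSE] == "A")

  data.frame(
    sequence = sequence,
    tetrad_pattern = tetrad_pattern,
    loop_pattern = loop_pattern,
    n_tetrad_mutations = as.integer(n_tet),
    mutated_tetrad_positions = mut_pos,
    n_loop_adenosines_489 = as.integer(n_a489),
    stringsAsFactors = FALSE
  )
}

#' Count library members by number of central-tetrad mutations
#'
#' @param library The deduplicated enumeration from [enumerate_library()].
#' @param k Integer vector of mutation counts to include, e.g. `1` or `c(3, 4)`.
#' @return Number of unique library sequences with `n_tetrad_mutations` in `k`.
#' @export
#' @examples
#' lib <- enumerate_library()
#' count_by_tetrad_mutations(lib, 1)        # 172
#' count_by_tetrad_mutations(lib, c(3, 4))  # 189
count_by_tetrad_mutations <- function(library, k) {
  sum(library$n_tetrad_mutations %in% as.integer(k))
}

iupac_map <- c(A = "A", C = "C", G = "G", T = "T",
               N = "[ACGT]", H = "[ACT]", Y = "[CT]")

#' Select library members by central-tetrad IUPAC pattern
#'
#' Matches the 4-character base pattern at positions (2, 6, 11, 15) against
#' one or more degenerate patterns (codes A, C, G, T, N = any, H = not G,
#' Y = pyrimidine); several patterns are OR-combined.
#'
#' @param library Enumeration data.frame.
#' @param pattern Character vector of 4-character IUPAC patterns.
#' @return The matching rows of `library`.
#' @export
#' @examples
#' lib <- enumerate_library()
#' nrow(match_tetrad_pattern(lib, c("NAAA", "AAAN")))  # 7
match_tetrad_pattern <- function(library, pattern) {
  pattern <- toupper(pattern)
  if (any(nchar(pattern) != 4L))
    stop("pattern error: each pattern must have 4 characters", call. = FALSE)
  codes <- unique(strsplit(paste(pattern, collapse = ""), "")[[1]])
  unknown <- setdiff(codes, names(iupac_map))
  if (length(unknown))
    stop("pattern error: unknown IUPAC code(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  regexes <- vapply(strsplit(pattern, ""), function(p)
    paste0("^", paste(iupac_map[p], collapse = ""), "$"), character(1))
  hit <- Reduce(`|`, lapply(regexes, grepl, x = library$tetrad_pattern))
  library[hit, , drop = FALSE]
}

tetrad_matches <- function(tetrad_pattern, pattern) {
  p <- strsplit(toupper(pattern), "")[[1]]
  grepl(paste0("^", paste(iupac_map[p], collapse = ""), "$"), tetrad_pattern)
}

#' Spectral class labels
#'
#' The major spectral classes recognised by the rule classifier, in rule
#' priority order, plus the two catch-all labels.
#' @return Character vector of class names.
#' @export
g4_class_labels <- function() {
  c("17.3", "17.63", "17.4", "17.4s26", "17.4+17.4s26",
    "17.49", "17.28", "17.36", "17.180", "17.154",
    "no_pattern", "no_G4_signals")
}

#' Assign rule-based spectral classes from mutational signatures
#'
#' Implements the sequence-to-class rules observed in the NMR screen. The
#' dominant determinant is the mutation pattern at the central-tetrad
#' positions (2, 6, 11, 15):
#'
#' * both halves (2,6) and (11,15) unmutated (GGGG) -> Class 17.3
#'   (monomeric G-quadruplex);
#' * only the first half (2,6) unmutated -> Class 17.63 (tetramer-forming);
#' * only the second half (11,15) unmutated -> the dimer-forming 17.4
#'   family. For members of the 17.4 loop sub-library the family splits by
#'   the number of adenosines at loop positions 4, 8, 9: zero or one -> Class
#'   17.4s26, two or three -> Class 17.4, with the mixed Class 17.4+17.4s26
#'   recorded as the ambiguous alternative in the overlapping bands (one or
#'   two adenosines);
#' * cross-half two-mutation patterns: GHHG -> Class 17.49, HGGH -> Class
#'   17.28 (with 17.36 as ambiguous alternative; TGGT is reassigned to 17.36
#'   when `tggt_to_17_36 = TRUE`, the default), GHGH -> Class 17.36;
#' * NAAA or AAAN -> Class 17.180; HAHG -> Class 17.154 (the AAAG pattern
#'   matches both and is labelled 17.180 with 17.154 recorded as ambiguous);
#' * any other sequence with three or four central-tetrad mutations ->
#'   no_G4_signals; everything remaining -> no_pattern.
#'
#' The function is total and deterministic; ambiguity is recorded in the
#' `ambiguous_alternatives` column, never silently dropped.
#'
#' @param library Enumeration data.frame (or any data.frame with
#'   `tetrad_pattern`, `sublibrary`, `n_tetrad_mutations`,
#'   `n_loop_adenosines_489` columns).
#' @param tggt_to_17_36 Reassign the TGGT pattern from 17.28 to 17.36
#'   (default `TRUE`).
#' @return `library` with added columns `class` and
#'   `ambiguous_alternatives` (comma-separated, possibly empty).
#' @export
#' @examples
#' lib <- assign_rule_class(enumerate_library())
#' table(lib$class)
assign_rule_class <- function(library, tggt_to_17_36 = TRUE) {
  tp <- library$tetrad_pattern
  in_l4 <- grepl("loop_17_4", library$sublibrary, fixed = TRUE)
  n_a <- library$n_loop_adenosines_489
  nmut <- library$n_tetrad_mutations

  chars <- do.call(rbind, strsplit(tp, ""))
  g <- chars == "G"
  first_intact <- g[, 1L] & g[, 2L]
  second_intact <- g[, 3L] & g[, 4L]

  n <- length(tp)
  cls <- rep(NA_character_, n)
  amb <- rep("", n)

  set <- function(i, label, alt = NULL) {
    take <- i & is.na(cls)
    cls[take] <<- label
    if (!is.null(alt)) amb[take] <<- alt
  }

  # R1/R2: intact halves
  set(first_intact & second_intact, "17.3")
  set(first_intact & !second_intact, "17.63")

  # R3: 17.4 family, refined by loop adenosines inside the 17.4 loop library
  fam <- second_intact & !first_intact & is.na(cls)
  set(fam & in_l4 & n_a == 0L, "17.4s26")
  set(fam & in_l4 & n_a == 1L, "17.4s26", "17.4+17.4s26")
  set(fam & in_l4 & n_a == 2L, "17.4", "17.4+17.4s26")
  set(fam & in_l4 & n_a == 3L, "17.4")
  set(fam & !in_l4, "17.4")

  # R4: cross-half two-mutation signatures
  set(tetrad_matches(tp, "GHHG"), "17.49")
  if (tggt_to_17_36) set(tp == "TGGT", "17.36", "17.28")
  set(tetrad_matches(tp, "HGGH"), "17.28", "17.36")
  set(tetrad_matches(tp, "GHGH"), "17.36")

  # R5: near-complete tetrad replacement signatures
  nearA <- tetrad_matches(tp, "NAAA") | tetrad_matches(tp, "AAAN")
  hahg <- tetrad_matches(tp, "HAHG")
  set(nearA & hahg, "17.180", "17.154")
  set(nearA, "17.180")
  set(hahg, "17.154")

  # R6: catch-alls
  set(nmut >= 3L, "no_G4_signals")
  set(rep(TRUE, n), "no_pattern")

  library$class <- cls
  library$ambiguous_alternatives <- amb
  library
}
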