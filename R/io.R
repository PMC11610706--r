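#' Write / read a spectrum as two-column delimited text
#'
#' The format is a `# key: value` metadata header followed by
#' tab-separated (ppm, intensity) pairs.
#'
#' @param s A `g4_spectrum`.
#' @param path Output file.
#' @return `write_spectrum()` returns `path` invisibly; `read_spectrum()`
#'   returns a `g4_spectrum`.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "g4_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seq_id: %s", s$seq_id),
               sprintf("# timepoint: %s", s$timepoint),
               "# columns: ppm\tintensity"), con)
  utils::write.table(data.frame(s$ppm, s$intensity), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t")
  g4_spectrum(dat[[1]], dat[[2]],
              seq_id = meta$seq_id %||% NA_character_,
              timepoint = meta$timepoint %||% "t0")
}

#' Read a minimal JCAMP-DX-style spectrum file
#'
#' Supports the plain `(XY..XY)` dialect: `##TITLE=`, `##XUNITS=PPM`,
#' `##XYDATA=(XY..XY)` followed by `x, y` pairs, terminated by `##END=`.
#'
#' @param path Input file.
#' @return A `g4_spectrum` (title stored as `seq_id`).
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path)
  get_field <- function(key) {
    h <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(h)) return(NULL)
    trimws(sub(paste0("^##", key, "="), "", h[1]))
  }
  xunits <- get_field("XUNITS")
  if (!is.null(xunits) && toupper(xunits) != "PPM")
    stop("unsupported XUNITS '", xunits, "': expected PPM", call. = FALSE)
  start <- grep("^##XYDATA=", lines)
  if (!length(start))
    stop("no ##XYDATA block found", call. = FALSE)
  end <- grep("^##END", lines)
  end <- if (length(end)) end[1] else length(lines) + 1L
  body <- lines[(start[1] + 1L):(end - 1L)]
  body <- body[nzchar(trimws(body))]
  parts <- do.call(rbind, strsplit(trimws(body), "[,\\s]+"))
  g4_spectrum(as.numeric(parts[, 1]), as.numeric(parts[, 2]),
              seq_id = get_field("TITLE") %||% NA_character_)
}

#' Write / read a chromatogram as (mL, absorbance) text
#'
#' @param c A `g4_chromatogram`.
#' @param path File path.
#' @return `write_chromatogram()` returns `path` invisibly;
#'   `read_chromatogram()` returns a `g4_chromatogram`.
#' @export
write_chromatogram <- function(c, path) {
  stopifnot(inherits(c, "g4_chromatogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# seq_id: %s", c$seq_id),
               "# columns: volume_ml\tabsorbance"), con)
  utils::write.table(data.frame(c$volume_ml, c$absorbance), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path) {
  lines <- readLines(path)
  id <- NA_character_
  m <- grep("^#\\s*seq_id:", lines, value = TRUE)
  if (length(m)) id <- trimws(sub("^#\\s*seq_id:", "", m[1]))
  dat <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t")
  g4_chromatogram(dat[[1]], dat[[2]], seq_id = id)
}

#' Write / read an activity table
#'
#' Tab-separated with columns seq_id, class, Flu, Tet, Dim, Per, GTP.
#'
#' @param t Activity data.frame.
#' @param path File path.
#' @return `write_activity_table()` returns `path` invisibly;
#'   `read_activity_table()` returns the data.frame.
#' @export
write_activity_table <- function(t, path) {
  utils::write.table(t, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_activity_table
#' @export
read_activity_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Export the enumerated library as FASTA and annotation table
#'
#' @param library Enumeration data.frame from [enumerate_library()].
#' @param fasta,annot Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of written paths.
#' @export
write_library <- function(library, fasta = NULL, annot = NULL) {
  written <- list()
  if (!is.null(fasta)) {
    dna <- Biostrings::DNAStringSet(library$sequence)
    names(dna) <- library$seq_id
    Biostrings::writeXStringSet(dna, fasta)
    written$fasta <- fasta
  }
  if (!is.null(annot)) {
    utils::write.table(library, annot, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    written$annot <- annot
  }
  invisible(written)
}
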