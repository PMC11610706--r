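#' Reference G-quadruplex scaffold topology
#'
#' Describes the 17-nt monomeric reference G-quadruplex used as the starting
#' point for the variant library: three stacked guanine tetrads formed by the
#' four G-tracts, four loop positions connecting the tracts, and a single
#' 3' tail nucleotide. All positions are 1-based.
#'
#' The middle tetrad (the "central tetrad") is formed by positions 2, 6, 11
#' and 15; these are the positions varied in the tetrad sub-library. The loop
#' positions 4, 8, 9 and 13 are varied in the loop sub-libraries.
#'
#' @param sequence 17-character DNA string of the reference scaffold. The
#'   default carries G at every tetrad position, T at every loop position and
#'   A at the tail.
#' @return An object of class `g4_reference`: a list with `sequence`,
#'   `tetrad_layers` (three ordered 4-vectors of positions),
#'   `central_tetrad_positions`, `loop_positions` and `tail_position`.
#' @export
#' @examples
#' ref <- g4_reference()
#' substring(ref$sequence, ref$central_tetrad_positions,
#'           ref$central_tetrad_positions)
g4_reference <- function(sequence = "GGGTGGGTTGGGTGGGA") {
  ref <- structure(
    list(
      sequence = toupper(sequence),
      tetrad_layers = list(c(1L, 5L, 10L, 14L),
                           c(2L, 6L, 11L, 15L),
                           c(3L, 7L, 12L, 16L)),
      central_tetrad_positions = c(2L, 6L, 11L, 15L),
      loop_positions = c(4L, 8L, 9L, 13L),
      tail_position = 17L
    ),
    class = "g4_reference"
  )
  validate_reference(ref)
  ref
}

validate_reference <- function(ref) {
  seq <- ref$sequence
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) != 17L)
    stop("reference sequence must be a single 17-character string", call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("reference sequence may only contain A, C, G, T", call. = FALSE)
  tet <- sort(unlist(ref$tetrad_layers))
  if (!all(chars[tet] == "G"))
    stop("invalid reference: all tetrad positions must carry G", call. = FALSE)
  if (!identical(ref$central_tetrad_positions, ref$tetrad_layers[[2]]))
    stop("central tetrad must be the middle tetrad layer", call. = FALSE)
  covered <- sort(c(tet, ref$loop_positions, ref$tail_position))
  if (!identical(covered, 1:17))
    stop("tetrad, loop and tail positions must partition 1..17", call. = FALSE)
  invisible(ref)
}

#' @export
print.g4_reference <- function(x, ...) {
  cat("G-quadruplex reference scaffold (17 nt)\n")
  cat("  sequence:      ", x$sequence, "\n")
  cat("  central tetrad:", paste(x$central_tetrad_positions, collapse = ", "), "\n")
  cat("  loops:         ", paste(x$loop_positions, collapse = ", "), "\n")
  invisible(x)
}
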