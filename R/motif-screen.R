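# Consensus-motif grammars and the CN/CY partition.
#
# The SUMOylation consensus is psi-K-x-E(/D): a hydrophobic residue (psi)
# immediately before the lysine, any residue at K+1, and an acidic residue at
# K+2. Six grammar variants C1-C6 differ in the psi set and in whether D is
# allowed at K+2:
#
#   C1 (L,V,M,F)           K x (E,D)     C4 (L,V,M,F)           K x (E)
#   C2 (A,I,P,L,V,M,F)     K x (E,D)     C5 (A,I,P,L,V,M,F)     K x (E)
#   C3 (A,I,P,L,V,M,F,G,Y) K x (E,D)     C6 (A,I,P,L,V,M,F,G,Y) K x (E)
#
# Matching is evaluated on the padded window (positions 10, 12, 13 relative
# to window start), so behaviour at protein ends is uniform: a '-' at any
# motif position fails the motif, including the unconstrained x at K+1 (a gap
# is not an amino acid).

MOTIF_PSI <- list(
  C1 = c("L", "V", "M", "F"),
  C2 = c("A", "I", "P", "L", "V", "M", "F"),
  C3 = c("A", "I", "P", "L", "V", "M", "F", "G", "Y"),
  C4 = c("L", "V", "M", "F"),
  C5 = c("A", "I", "P", "L", "V", "M", "F"),
  C6 = c("A", "I", "P", "L", "V", "M", "F", "G", "Y")
)
MOTIF_TAIL <- list(
  C1 = c("E", "D"), C2 = c("E", "D"), C3 = c("E", "D"),
  C4 = "E", C5 = "E", C6 = "E"
)

#' Consensus-motif grammar definition
#'
#' Returns one of the six built-in psi-K-x-E(/D) grammar variants.
#'
#' @param id One of `"C1"` ... `"C6"` (default `"C1"`, the variant the
#'   screening system settles on).
#' @return An object of class `motif_def` with fields `id`, `psi` (allowed
#'   residues at K-1) and `tail` (allowed residues at K+2).
#' @export
#' @examples
#' motif_def("C3")
motif_def <- function(id = "C1") {
  if (inherits(id, "motif_def")) return(id)
  id <- as.character(id)
  if (length(id) != 1 || !id %in% names(MOTIF_PSI)) {
    abort("`id` must be one of C1, C2, C3, C4, C5, C6.")
  }
  structure(
    list(id = id, psi = MOTIF_PSI[[id]], tail = MOTIF_TAIL[[id]]),
    class = "motif_def"
  )
}

#' @export
print.motif_def <- function(x, ...) {
  cat(sprintf(
    "<motif %s> (%s) K x (%s)\n", x$id,
    paste(x$psi, collapse = ","), paste(x$tail, collapse = ",")
  ))
  invisible(x)
}

#' Classify windows as motif-conforming (CY) or not (CN)
#'
#' A window is CY iff the residue at K-1 (window index 10) is in the
#' grammar's psi set, K+1 (index 12) is a real residue (not a gap), and K+2
#' (index 13) is in the tail set. Only these three positions are consulted.
#'
#' @param windows A window tibble (needs a `window` column), or a character
#'   vector of 21-residue windows.
#' @param motif A [motif_def()] or its id.
#' @return For a tibble input, the tibble with a `motif_class` column
#'   (`"CY"`/`"CN"`) added; for a character input, the character vector of
#'   classes.
#' @export
#' @examples
#' classify_sites(paste0(strrep("-", 9), "LKAE", strrep("-", 8)), "C1")
classify_sites <- function(windows, motif = "C1") {
  motif <- motif_def(motif)
  win <- if (is.character(windows)) windows else windows$window
  if (is.null(win)) abort("`windows` must have a `window` column.")
  bad_len <- which(nchar(win) != WINDOW_SIZE)
  if (length(bad_len) > 0) {
    abort(paste0("Window of length != 21 at row ", bad_len[1]))
  }
  psi_res <- substring(win, WINDOW_CENTER - 1L, WINDOW_CENTER - 1L)
  x_res <- substring(win, WINDOW_CENTER + 1L, WINDOW_CENTER + 1L)
  tail_res <- substring(win, WINDOW_CENTER + 2L, WINDOW_CENTER + 2L)
  cls <- ifelse(
    psi_res %in% motif$psi & x_res != GAP_CHAR & tail_res %in% motif$tail,
    "CY", "CN"
  )
  if (is.character(windows)) return(cls)
  mutate(windows, motif_class = cls)
}

#' Partition labelled windows into CY_P / CY_N / CN_P / CN_N
#'
#' The four subsets are disjoint and jointly exhaust the input: rows are
#' assigned by (label, motif class). Windows labelled `unknown` are an error;
#' filter them out first.
#'
#' @param windows A labelled window tibble.
#' @param motif A [motif_def()] or its id.
#' @return The tibble with `motif_class` and a `subset` column taking values
#'   `CY_P`, `CY_N`, `CN_P`, `CN_N`.
#' @export
partition_windows <- function(windows, motif = "C1") {
  if (!all(windows$label %in% c("positive", "negative"))) {
    n_unk <- sum(!windows$label %in% c("positive", "negative"))
    abort(paste0(
      n_unk, " window(s) with label outside {positive, negative}; ",
      "filter unknowns before partitioning."
    ))
  }
  windows <- classify_sites(windows, motif)
  mutate(
    windows,
    subset = paste0(.data$motif_class, "_",
                    ifelse(.data$label == "positive", "P", "N"))
  )
}
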