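# Sequence input and lysine-window extraction.
#
# Proteins travel as a tibble with one row per protein:
#   protein_id <chr>, sequence <chr>, positive_sites <list of integer>
# Windows travel as a tibble with one row per candidate lysine:
#   protein_id <chr>, center_pos <int>, window <chr 21>, label <chr>

NONSTANDARD_AA <- c("B", "J", "O", "U", "X", "Z")

#' Read protein sequences from a FASTA file
#'
#' Records get their id from the FASTA header up to the first whitespace.
#' Sequences are upper-cased and validated against the 20 standard amino
#' acids. Under the strict default any other letter (B, J, O, U, X, Z, ...)
#' is an error; with `permissive = TRUE` the six non-standard codes are
#' mapped to `"-"` and treated as gaps by every encoder.
#'
#' @param path Path to a FASTA file.
#' @param permissive Map non-standard residue codes to `"-"` instead of
#'   erroring (default `FALSE`).
#' @param keep_ids Optional character vector of ids to keep (e.g. cluster
#'   representatives from an external redundancy-reduction run); other
#'   records are dropped.
#' @return A tibble with columns `protein_id`, `sequence`, and
#'   `positive_sites` (a list-column of integer vectors, empty until
#'   [read_site_annotations()] attaches annotations).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MKVLKTE"), fa)
#' read_fasta(fa)
read_fasta <- function(path, permissive = FALSE, keep_ids = NULL) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(paste0("Malformed FASTA in ", path, ": ", conditionMessage(e)))
  )
  if (length(set) == 0) abort(paste0("FASTA file is empty: ", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (anyDuplicated(ids)) {
    abort(paste0(
      "Duplicate FASTA ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  proteins <- tibble(
    protein_id = unname(ids),
    sequence = unname(seqs),
    positive_sites = rep(list(integer(0)), length(ids))
  )
  if (!is.null(keep_ids)) {
    proteins <- filter(proteins, .data$protein_id %in% keep_ids)
  }
  validate_sequences(proteins, permissive = permissive)
}

validate_sequences <- function(proteins, permissive = FALSE) {
  ok_chars <- c(AA_ALPHABET, GAP_CHAR)
  proteins$sequence <- purrr::map2_chr(
    proteins$sequence, proteins$protein_id,
    function(s, id) {
      if (!nzchar(s)) abort(paste0("Empty sequence for protein ", id))
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      bad <- setdiff(unique(chars), ok_chars)
      if (length(bad) == 0) return(s)
      if (permissive && all(bad %in% NONSTANDARD_AA)) {
        chars[chars %in% NONSTANDARD_AA] <- GAP_CHAR
        return(paste(chars, collapse = ""))
      }
      abort(paste0(
        "Protein ", id, " contains residues outside the 20-letter alphabet: ",
        paste(bad, collapse = ", "),
        if (!permissive) " (use permissive = TRUE to map B/J/O/U/X/Z to '-')"
      ))
    }
  )
  proteins
}

#' Attach SUMOylation-site annotations to protein records
#'
#' Reads a TSV of known sites (`protein_id<TAB>position`, 1-based; header row
#' optional; `#` comment lines skipped) and attaches each position to the
#' matching protein. Every annotated position must index a lysine. Duplicate
#' rows are deduplicated silently.
#'
#' @param proteins A protein tibble from [read_fasta()].
#' @param path Path to the annotation TSV.
#' @return The protein tibble with `positive_sites` filled in.
#' @export
read_site_annotations <- function(proteins, path) {
  if (!file.exists(path)) abort(paste0("Annotation file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) return(proteins)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad_rows <- which(lengths(fields) < 2)
  if (length(bad_rows) > 0) {
    abort(paste0("Annotation row without two tab-separated fields at data line ",
                 bad_rows[1]))
  }
  ann <- tibble(
    protein_id = purrr::map_chr(fields, 1),
    position = purrr::map_chr(fields, 2)
  )
  # optional header row
  if (suppressWarnings(is.na(as.integer(ann$position[1])))) ann <- ann[-1, ]
  pos_int <- suppressWarnings(as.integer(ann$position))
  if (anyNA(pos_int)) {
    abort(paste0("Non-integer position in annotation file: ",
                 ann$position[which(is.na(pos_int))[1]]))
  }
  ann$position <- pos_int
  ann <- distinct(ann)

  unknown <- setdiff(unique(ann$protein_id), proteins$protein_id)
  if (length(unknown) > 0) {
    abort(paste0("Annotations reference unknown protein ids: ",
                 paste(unknown, collapse = ", ")))
  }
  seq_by_id <- setNames(proteins$sequence, proteins$protein_id)
  res_at <- substring(seq_by_id[ann$protein_id], ann$position, ann$position)
  bad <- which(res_at != "K")
  if (length(bad) > 0) {
    abort(paste0(
      "Annotated position is not a lysine: ",
      paste(sprintf("%s:%d ('%s')", ann$protein_id[bad], ann$position[bad],
                    res_at[bad]), collapse = ", ")
    ))
  }
  sites <- split(ann$position, ann$protein_id)
  proteins$positive_sites <- purrr::map2(
    proteins$positive_sites, proteins$protein_id,
    function(cur, id) sort(unique(c(cur, sites[[id]])))
  )
  proteins
}

#' Extract 21-residue lysine-centred windows
#'
#' Emits one window per lysine in every protein: 10 residues either side of
#' the lysine, with positions beyond the sequence ends padded with `"-"`, so
#' every window has length 21 and a `K` at (1-based) window index 11.
#'
#' Labels: `positive` for annotated sites; other lysines are `negative` only
#' in proteins that carry at least one positive site and when
#' `negatives_rule` is on (the dataset rule that negatives come from proteins
#' with a known site), otherwise `unknown`.
#'
#' @param proteins An (annotated) protein tibble.
#' @param negatives_rule Logical; label unannotated lysines in annotated
#'   proteins as negatives (default `TRUE`).
#' @return A tibble with columns `protein_id`, `center_pos`, `window`,
#'   `label`.
#' @export
#' @examples
#' prot <- tibble::tibble(
#'   protein_id = "P1", sequence = "MKV", positive_sites = list(2L)
#' )
#' extract_windows(prot)
extract_windows <- function(proteins, negatives_rule = TRUE) {
  half <- (WINDOW_SIZE - 1L) %/% 2L
  rows <- purrr::pmap(
    list(proteins$protein_id, proteins$sequence, proteins$positive_sites),
    function(id, seq, pos_sites) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      ks <- which(chars == "K")
      if (length(ks) == 0) return(NULL)
      padded <- c(rep(GAP_CHAR, half), chars, rep(GAP_CHAR, half))
      windows <- vapply(
        ks,
        function(p) paste(padded[p:(p + 2L * half)], collapse = ""),
        character(1)
      )
      label <- if (length(pos_sites) > 0) {
        ifelse(ks %in% pos_sites, "positive",
               if (negatives_rule) "negative" else "unknown")
      } else {
        rep("unknown", length(ks))
      }
      tibble(
        protein_id = id, center_pos = as.integer(ks),
        window = windows, label = label
      )
    }
  )
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      protein_id = character(), center_pos = integer(),
      window = character(), label = character()
    )
  }
  out
}

#' Write extracted windows to a TSV file
#'
#' @param windows A window tibble from [extract_windows()].
#' @param path Output path.
#' @param seed Optional seed recorded in the file header.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path, seed = NULL) {
  write_tsv_with_header(windows, path, seed = seed)
}
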