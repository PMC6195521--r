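# The four-block, 903-dimensional feature encoding of a 21-residue window.
#
# Block layout (1-based, inclusive):
#   binary      1-420   21 positions x 20 one-hot amino-acid channels
#   physchem  421-630   21 positions x 10 physicochemical properties
#   structure 631-777   21 positions x 7 per-residue structure values
#   ptm       778-903   21 positions x 6 PTM confidence codes (0/10/50/100)
#
# Gaps ('-') and out-of-sequence window positions encode as zeros in every
# block; zero is also the "no modification" / "no profile" code, so the null
# providers for structure and PTM are all-zero blocks.

the <- new.env(parent = emptyenv())

#' The 20 x 10 physicochemical property table
#'
#' Ten values per amino acid: five factor-analytic consensus scores
#' (polarity, secondary-structure propensity, molecular size, codon
#' diversity, electrostatic charge) and five literature-survey properties
#' (hydropathy, side-chain heavy-atom count, alpha-helix propensity, codon
#' count, beta-strand propensity). Shipped as a versioned text file so
#' encodings are reproducible bit-for-bit; pass `path` to substitute a
#' custom table of the same shape.
#'
#' @param path Optional path to a replacement TSV (same columns, 20 rows).
#' @return A tibble with column `aa` plus the 10 property columns.
#' @export
#' @examples
#' physchem_table()
physchem_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the$physchem)) return(the$physchem)
    path <- system.file("extdata", "physchem_table.tsv", package = "sumoscreen")
    tab <- validate_physchem(read_tsv_skip_comments(path))
    the$physchem <- tab
    return(tab)
  }
  validate_physchem(read_tsv_skip_comments(path))
}

validate_physchem <- function(tab) {
  need <- c("aa", PHYSCHEM_CHANNELS)
  if (!all(need %in% names(tab))) {
    abort(paste0("Physicochemical table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  if (!setequal(tab$aa, AA_ALPHABET) || nrow(tab) != 20) {
    abort("Physicochemical table must have exactly one row per standard amino acid.")
  }
  tab <- arrange(tab[, need], match(.data$aa, AA_ALPHABET))
  if (anyNA(tab)) abort("Physicochemical table contains missing values.")
  tab
}

window_chars <- function(windows) {
  bad <- which(nchar(windows) != WINDOW_SIZE)
  if (length(bad) > 0) abort(paste0("Window of length != 21 at row ", bad[1]))
  matrix(
    unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
    ncol = WINDOW_SIZE, byrow = TRUE
  )
}

#' One-hot (binary) sequence block
#'
#' 20 indicator channels per window position, amino acids in fixed
#' alphabetical order (A, C, D, ..., Y); gaps encode as all zeros.
#'
#' @param windows Character vector of 21-residue windows (or a window
#'   tibble).
#' @return Numeric matrix, one row per window, 420 columns.
#' @export
encode_binary <- function(windows) {
  if (is.data.frame(windows)) windows <- windows$window
  chars <- window_chars(windows)
  out <- matrix(0, nrow = nrow(chars), ncol = 20L * WINDOW_SIZE)
  idx <- match(chars, AA_ALPHABET)        # NA for gaps
  hit <- which(!is.na(idx))
  rows <- ((hit - 1L) %% nrow(chars)) + 1L
  pos <- ((hit - 1L) %/% nrow(chars)) + 1L
  out[cbind(rows, (pos - 1L) * 20L + idx[hit])] <- 1
  colnames(out) <- feature_names()[1:420]
  out
}

#' Physicochemical property block
#'
#' The residue's 10 table values per window position; gaps contribute ten
#' zeros.
#'
#' @inheritParams encode_binary
#' @param table A table from [physchem_table()].
#' @return Numeric matrix, 210 columns.
#' @export
encode_physchem <- function(windows, table = physchem_table()) {
  if (is.data.frame(windows) && "window" %in% names(windows)) {
    windows <- windows$window
  }
  table <- validate_physchem(table)
  vals <- as.matrix(table[, PHYSCHEM_CHANNELS])
  chars <- window_chars(windows)
  bad <- setdiff(unique(as.vector(chars)), c(AA_ALPHABET, GAP_CHAR))
  if (length(bad) > 0) {
    abort(paste0("Residue absent from physicochemical table: ",
                 paste(bad, collapse = ", ")))
  }
  idx <- match(chars, AA_ALPHABET)
  dim(idx) <- dim(chars)
  n <- nrow(chars)
  out <- matrix(0, nrow = n, ncol = 10L * WINDOW_SIZE)
  for (p in seq_len(WINDOW_SIZE)) {
    ip <- idx[, p]
    ok <- !is.na(ip)
    if (any(ok)) out[ok, (p - 1L) * 10L + 1:10] <- vals[ip[ok], , drop = FALSE]
  }
  colnames(out) <- feature_names()[421:630]
  out
}

profile_block <- function(windows_tbl, profile, channels, block_name, offset) {
  n <- nrow(windows_tbl)
  k <- length(channels)
  out <- matrix(0, nrow = n, ncol = k * WINDOW_SIZE)
  colnames(out) <- feature_names()[offset + seq_len(k * WINDOW_SIZE)]
  if (is.null(profile) || n == 0) return(out)
  need <- c("protein_id", "position", channels)
  if (!all(need %in% names(profile))) {
    abort(paste0(block_name, " profile must have columns: ",
                 paste(need, collapse = ", ")))
  }
  key <- paste(profile$protein_id, profile$position)
  vals <- as.matrix(profile[, channels])
  half <- (WINDOW_SIZE - 1L) %/% 2L
  for (p in seq_len(WINDOW_SIZE)) {
    pos <- windows_tbl$center_pos + (p - WINDOW_CENTER)
    in_seq <- substring(windows_tbl$window, p, p) != GAP_CHAR
    wkey <- paste(windows_tbl$protein_id, pos)
    hit <- match(wkey, key)
    missing <- in_seq & is.na(hit)
    if (any(missing)) {
      i <- which(missing)[1]
      abort(paste0(
        block_name, " profile does not cover ", windows_tbl$protein_id[i],
        " position ", pos[i], " (profile shorter than sequence?)"
      ))
    }
    ok <- in_seq & !is.na(hit)
    if (any(ok)) {
      out[ok, (p - 1L) * k + seq_len(k)] <- vals[hit[ok], , drop = FALSE]
    }
  }
  out
}

#' Structure profile block
#'
#' Seven per-residue values (buried/exposed class, relative and absolute
#' surface accessibility, Z-score, helix/strand/coil probabilities) at each
#' window position. `profile = NULL` is the null provider: 147 zeros, for
#' runs without structure predictions.
#'
#' @param windows A window tibble (`protein_id`, `center_pos`, `window`).
#' @param profile A structure profile tibble from [parse_structure_file()],
#'   or `NULL`.
#' @return Numeric matrix, 147 columns.
#' @export
encode_structure <- function(windows, profile = NULL) {
  profile_block(windows, profile, STRUCTURE_CHANNELS, "Structure", 630L)
}

#' PTM confidence block
#'
#' Six ordered modification channels (acetylation, hydroxylation,
#' methylation, phosphorylation, sumoylation, ubiquitination) with
#' confidence codes 0/10/50/100 per window position. `profile = NULL` is the
#' null provider — 126 zeros — which is exactly the "No mod" ablation
#' configuration.
#'
#' @inheritParams encode_structure
#' @param profile A PTM profile tibble from [parse_ptm_file()], or `NULL`.
#' @param mask_center_sumo Zero out the sumoylation channel at the candidate
#'   lysine itself (window position 11), in case self-predictions should not
#'   inform the model. Default `FALSE` (included).
#' @return Numeric matrix, 126 columns.
#' @export
encode_ptm <- function(windows, profile = NULL, mask_center_sumo = FALSE) {
  if (!is.null(profile)) {
    vals <- unlist(profile[PTM_TYPES[PTM_TYPES %in% names(profile)]])
    bad <- setdiff(unique(vals), PTM_CODES)
    if (length(bad) > 0) {
      abort(paste0("PTM confidence codes outside {0, 10, 50, 100}: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  out <- profile_block(windows, profile, PTM_TYPES, "PTM", 777L)
  if (mask_center_sumo) {
    col <- (WINDOW_CENTER - 1L) * 6L + match("sumoylation", PTM_TYPES)
    out[, col] <- 0
  }
  out
}

#' Encode windows as 903-dimensional feature vectors
#'
#' Concatenates the four blocks in fixed layout order. The result keeps the
#' window bookkeeping columns so downstream steps can route rows by motif
#' class and recover per-site predictions.
#'
#' @param windows A window tibble from [extract_windows()].
#' @param table Physicochemical table (default the shipped one).
#' @param structure Structure profile tibble or `NULL` (null provider).
#' @param ptm PTM profile tibble or `NULL` (null provider; the "No mod"
#'   configuration).
#' @param mask_center_sumo See [encode_ptm()].
#' @return A tibble: `protein_id`, `center_pos`, `window`, `label`, then the
#'   903 feature columns named as in [feature_names()].
#' @export
encode_windows <- function(windows, table = physchem_table(),
                           structure = NULL, ptm = NULL,
                           mask_center_sumo = FALSE) {
  need <- c("protein_id", "center_pos", "window")
  if (!all(need %in% names(windows))) {
    abort("`windows` must have protein_id, center_pos and window columns.")
  }
  feats <- cbind(
    encode_binary(windows$window),
    encode_physchem(windows$window, table),
    encode_structure(windows, structure),
    encode_ptm(windows, ptm, mask_center_sumo = mask_center_sumo)
  )
  meta <- windows[, intersect(c(need, "label"), names(windows))]
  bind_cols(meta, as_tibble(feats))
}

# Extract the bare feature matrix (and labels) from an encoded tibble.
feature_matrix <- function(encoded) {
  cols <- intersect(feature_names(), names(encoded))
  if (length(cols) == 0) {
    # fall back: any non-bookkeeping numeric column (used by the selection
    # functions on generic feature tables)
    cols <- setdiff(names(encoded),
                    c("protein_id", "center_pos", "window", "label",
                      "motif_class", "subset"))
  }
  as.matrix(encoded[, cols])
}

#' Parse a per-residue structure profile file
#'
#' Expects a whitespace- or tab-separated table with columns `protein_id`,
#' `position` (1-based), then the seven structure values in fixed order:
#' `buried_exposed` (0/1), `rsa`, `asa`, `zscore`, `alpha_prob`,
#' `beta_prob`, `coil_prob`. Lines starting `#` are skipped. A header row
#' naming the columns is accepted in any order.
#'
#' @param path Path to the profile file.
#' @return A tibble with one row per (protein, residue).
#' @export
parse_structure_file <- function(path) {
  tab <- parse_profile_file(path, STRUCTURE_CHANNELS, "structure")
  probs <- as.matrix(tab[, c("alpha_prob", "beta_prob", "coil_prob")])
  if (any(probs < 0 | probs > 1)) {
    bad <- which(probs < 0 | probs > 1)[1]
    abort(paste0("Secondary-structure probability outside [0, 1]: ",
                 probs[bad]))
  }
  if (!all(tab$buried_exposed %in% c(0, 1))) {
    abort("buried_exposed must be a 0/1 class column.")
  }
  tab
}

#' Parse a per-residue PTM confidence profile file
#'
#' Same dialect as [parse_structure_file()] with the six ordered PTM
#' channels (`acetylation`, `hydroxylation`, `methylation`,
#' `phosphorylation`, `sumoylation`, `ubiquitination`), each coded
#' 0/10/50/100.
#'
#' @param path Path to the profile file.
#' @return A tibble with one row per (protein, residue).
#' @export
parse_ptm_file <- function(path) {
  tab <- parse_profile_file(path, PTM_TYPES, "PTM")
  vals <- unlist(tab[PTM_TYPES])
  bad <- setdiff(unique(vals), PTM_CODES)
  if (length(bad) > 0) {
    abort(paste0("PTM confidence codes outside {0, 10, 50, 100}: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  tab
}

parse_profile_file <- function(path, channels, what) {
  if (!file.exists(path)) abort(paste0(what, " profile file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) abort(paste0("Empty ", what, " profile file: ", path))
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- length(channels) + 2L
  if (any(lengths(fields) != ncols)) {
    abort(paste0(what, " profile rows must have ", ncols,
                 " whitespace-separated fields."))
  }
  header <- fields[[1]]
  expected <- c("protein_id", "position", channels)
  if (setequal(header, expected)) {
    order_idx <- match(expected, header)
    fields <- fields[-1]
  } else {
    order_idx <- seq_len(ncols)
  }
  mat <- matrix(unlist(fields), ncol = ncols, byrow = TRUE)[, order_idx, drop = FALSE]
  pos <- suppressWarnings(as.integer(mat[, 2]))
  if (anyNA(pos)) abort(paste0("Non-integer position in ", what, " profile."))
  vals <- suppressWarnings(apply(mat[, -(1:2), drop = FALSE], 2, as.numeric))
  if (anyNA(vals)) abort(paste0("Non-numeric value in ", what, " profile."))
  out <- bind_cols(
    tibble(protein_id = mat[, 1], position = pos),
    as_tibble(setNames(as.data.frame(vals), channels))
  )
  if (anyDuplicated(paste(out$protein_id, out$position))) {
    abort(paste0("Duplicate (protein, position) rows in ", what, " profile."))
  }
  out
}

# Profile coverage check against a protein tibble: every residue of every
# profiled protein must be present.
check_profile_coverage <- function(profile, proteins, what) {
  for (i in seq_len(nrow(proteins))) {
    id <- proteins$protein_id[i]
    rows <- profile[profile$protein_id == id, ]
    if (nrow(rows) == 0) next
    len <- nchar(proteins$sequence[i])
    if (!setequal(rows$position, seq_len(len))) {
      abort(paste0(what, " profile for ", id,
                   " does not cover positions 1..", len))
    }
  }
  ids <- setdiff(unique(profile$protein_id), proteins$protein_id)
  if (length(ids) > 0) {
    abort(paste0(what, " profile references unknown protein ids: ",
                 paste(ids, collapse = ", ")))
  }
  invisible(profile)
}

#' Write an encoded feature table to TSV
#'
#' @param encoded Tibble from [encode_windows()].
#' @param path Output path.
#' @param seed Optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_features <- function(encoded, path, seed = NULL) {
  write_tsv_with_header(encoded, path, seed = seed)
}
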