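# Shared constants and small helpers.

# The 20 standard amino acids, fixed alphabetical order. This order is frozen:
# it defines the channel order of the one-hot block and the row order of the
# physicochemical table, so changing it silently changes every encoding.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

GAP_CHAR <- "-"

WINDOW_SIZE <- 21L
WINDOW_CENTER <- 11L   # 1-based index of the candidate lysine inside the window

# Feature-vector layout (1-based, inclusive). Encoding layout version: bump if
# any block size, order or channel naming changes; persisted models refuse to
# load across versions.
BLOCK_SIZES <- c(binary = 420L, physchem = 210L, structure = 147L, ptm = 126L)
LAYOUT_VERSION <- "1"

PTM_TYPES <- c(
  "acetylation", "hydroxylation", "methylation",
  "phosphorylation", "sumoylation", "ubiquitination"
)
PTM_CODES <- c(0, 10, 50, 100)

STRUCTURE_CHANNELS <- c(
  "buried_exposed", "rsa", "asa", "zscore",
  "alpha_prob", "beta_prob", "coil_prob"
)

PHYSCHEM_CHANNELS <- c(
  "polarity", "secondary_structure", "molecular_size", "codon_diversity",
  "electrostatic_charge", "hydrophobicity", "side_chain_length",
  "alpha_helix_propensity", "num_codons", "beta_strand_propensity"
)

#' Column names of the 903-dimensional feature vector
#'
#' Names follow `<block>_<windowpos>_<channel>`: block one of `binary`,
#' `physchem`, `structure`, `ptm`; window position 1--21 (the lysine sits at
#' position 11); channel the amino-acid letter (binary block) or property /
#' profile / modification name.
#'
#' @return Character vector of length 903.
#' @export
#' @examples
#' head(feature_names())
feature_names <- function() {
  c(
    paste0("binary_", rep(1:21, each = 20), "_", rep(AA_ALPHABET, 21)),
    paste0("physchem_", rep(1:21, each = 10), "_", rep(PHYSCHEM_CHANNELS, 21)),
    paste0("structure_", rep(1:21, each = 7), "_", rep(STRUCTURE_CHANNELS, 21)),
    paste0("ptm_", rep(1:21, each = 6), "_", rep(PTM_TYPES, 21))
  )
}

# Seed scope: run `code` under a temporary RNG state seeded with `seed`
# (restores the caller's state). seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + 104729 * as.double(offset)) %% 2147483647)
}

# Parse a P/N ratio given as "1:2", ":2", 2, or 1.5 -> negatives per positive.
parse_ratio <- function(ratio) {
  if (is.numeric(ratio)) {
    if (length(ratio) != 1 || !is.finite(ratio) || ratio <= 0) {
      abort("`ratio` must be a single positive number or a string like \"1:2\".")
    }
    return(as.double(ratio))
  }
  if (is.character(ratio) && length(ratio) == 1) {
    parts <- strsplit(ratio, ":", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    num <- suppressWarnings(as.double(parts))
    if (length(num) == 1 && is.finite(num) && num > 0) return(num)
    if (length(num) == 2 && all(is.finite(num)) && all(num > 0)) {
      return(num[2] / num[1])
    }
  }
  abort("`ratio` must be a single positive number or a string like \"1:2\".")
}

# Stable content hash (used for config/table fingerprints in file headers and
# model archives).
hash_of <- function(x) rlang::hash(x)

# Header comment stamped on every TSV the package writes.
output_header <- function(seed = NULL, config = NULL) {
  paste0(
    "# sumoscreen ", as.character(utils::packageVersion("sumoscreen")),
    " layout=", LAYOUT_VERSION,
    if (!is.null(seed)) paste0(" seed=", seed),
    if (!is.null(config)) paste0(" config_hash=", hash_of(config))
  )
}

write_tsv_with_header <- function(x, path, seed = NULL, config = NULL) {
  writeLines(output_header(seed = seed, config = config), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_tsv_skip_comments <- function(path, col_types = NULL) {
  readr::read_tsv(
    path, comment = "#", col_types = col_types,
    progress = FALSE, show_col_types = FALSE
  )
}
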