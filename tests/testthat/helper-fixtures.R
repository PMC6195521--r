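# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# A window string from explicit K-1 / K+1 / K+2 context, all other positions
# filled with `fill`.
make_window <- function(psi = "A", x = "A", tail = "A", fill = "G") {
  chars <- rep(fill, 21)
  chars[11] <- "K"
  chars[10] <- psi
  chars[12] <- x
  chars[13] <- tail
  paste(chars, collapse = "")
}

# n random 21-residue windows (K fixed at the centre), optionally with gap
# runs at the ends as boundary windows would have.
random_windows <- function(n, gap_prob = 0.2, seed = NULL) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  run <- function() {
    chars <- sample(aa, 21, replace = TRUE)
    if (runif(1) < gap_prob) {
      k <- sample(1:9, 1)
      if (runif(1) < 0.5) chars[1:k] <- "-" else chars[(22 - k):21] <- "-"
    }
    chars[11] <- "K"
    paste(chars, collapse = "")
  }
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) run(), character(1))
}

# A window tibble wrapping bare window strings.
window_tbl <- function(windows, label = "unknown", protein_id = NULL) {
  tibble::tibble(
    protein_id = protein_id %||% paste0("P", seq_along(windows)),
    center_pos = 11L,
    window = windows,
    label = rep_len(label, length(windows))
  )
}

write_fasta_fixture <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(purrr::imap(entries, function(seq, id) c(paste0(">", id), seq))),
             path)
  path
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Encoded-tibble fixture with hand-planted signal, bypassing the sequence
# encoders: window strings control motif routing, feature columns carry the
# signal. Useful for classifier-level tests.
planted_encoded <- function(n_per_cell = 25, shift_cy = 2, shift_cn = 0,
                            n_features = 20, seed = 1) {
  set.seed(seed)
  cy_win <- make_window(psi = "L", x = "A", tail = "E")
  cn_win <- make_window(psi = "A", x = "A", tail = "A")
  # negatives twice as many as positives so a 1:2 draw needs no clamping
  cells <- rep(c(1L, 2L, 3L, 4L), n_per_cell * c(1, 2, 1, 2))
  meta <- tibble::tibble(
    protein_id = sprintf("P%04d", seq_along(cells)),
    center_pos = 11L,
    window = c(cy_win, cy_win, cn_win, cn_win)[cells],
    label = c("positive", "negative", "positive", "negative")[cells]
  )
  X <- matrix(rnorm(nrow(meta) * n_features), nrow(meta), n_features)
  is_cy_pos <- meta$window == cy_win & meta$label == "positive"
  is_cn_pos <- meta$window == cn_win & meta$label == "positive"
  X[is_cy_pos, 1:5] <- X[is_cy_pos, 1:5] + shift_cy
  X[is_cn_pos, 1:5] <- X[is_cn_pos, 1:5] + shift_cn
  colnames(X) <- paste0("f", seq_len(n_features))
  dplyr::bind_cols(meta, tibble::as_tibble(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fast_spec <- function() sumoscreen::classifier_spec(ntree = 50)
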