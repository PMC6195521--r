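# Seeded synthetic proteomes with planted SUMOylation sites.
#
# The generator emulates the statistical skeleton the pipeline is built for:
# background sequences drawn from residue frequencies, a fraction of lysines
# promoted to positives, a controllable fraction of positives whose context
# is rewritten to match the chosen consensus motif (the remainder guaranteed
# NOT to match), and matching per-residue structure / PTM provider tables
# with optional planted signal at positive sites. It makes no attempt to
# imitate real SUMO substrate statistics beyond the motif structure.

# Swiss-Prot-like background residue frequencies (percent, order AA_ALPHABET).
UNIPROT_FREQ <- c(
  A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86, G = 7.07, H = 2.27,
  I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06, P = 4.74, Q = 3.93,
  R = 5.53, S = 6.65, T = 5.36, V = 6.86, W = 1.10, Y = 2.92
)

#' Synthetic proteome configuration
#'
#' @param n_proteins Number of proteins (default 100).
#' @param min_length,max_length Protein length bounds, uniform (defaults
#'   80 and 250; lengths below 21 make every window boundary-padded and are
#'   not recommended).
#' @param positive_rate Probability that a lysine is promoted to a planted
#'   SUMOylation site (default 0.05, matching the roughly 1:20 positive
#'   fraction of curated site collections).
#' @param motif Consensus grammar the planted sites are measured against
#'   (default `"C1"`).
#' @param motif_conformance Fraction of planted positives whose K-1/K+2
#'   context is rewritten to match the motif; the rest are rewritten to
#'   guarantee a non-match (default 0.75, the conforming share reported for
#'   curated SUMO sites). `NULL` disables context rewriting altogether —
#'   positives keep their background context and carry no motif signal (the
#'   fully null condition).
#' @param ptm_signal Probability that a planted positive also gets planted
#'   high-confidence co-modification codes (acetylation/ubiquitination 100
#'   at the site, phosphorylation 50 next to it); 0 = none.
#' @param structure_signal Probability that a planted positive gets an
#'   exposed, high-accessibility structure context; 0 = none.
#' @param background `"uniform"` over the 20 amino acids (default) or
#'   `"uniprot"` for Swiss-Prot-like frequencies, or a named numeric vector
#'   of 20 weights.
#' @param seed Master seed; fixed seed gives byte-identical output files.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 100, min_length = 80,
                             max_length = 250, positive_rate = 0.05,
                             motif = "C1", motif_conformance = 0.75,
                             ptm_signal = 0, structure_signal = 0,
                             background = "uniform", seed = NULL) {
  fracs <- c(positive_rate, motif_conformance %||% 0, ptm_signal,
             structure_signal)
  if (any(fracs < 0 | fracs > 1)) {
    abort("Rates and signal strengths must lie in [0, 1].")
  }
  if (min_length < WINDOW_SIZE) {
    warn("Proteins shorter than 21 residues give fully padded windows.")
  }
  freq <- if (is.numeric(background)) {
    if (!setequal(names(background), AA_ALPHABET)) {
      abort("A numeric `background` must be named by the 20 amino acids.")
    }
    background[AA_ALPHABET]
  } else if (identical(background, "uniform")) {
    setNames(rep(1, 20), AA_ALPHABET)
  } else if (identical(background, "uniprot")) {
    UNIPROT_FREQ[AA_ALPHABET]
  } else {
    abort("`background` must be \"uniform\", \"uniprot\", or a named vector.")
  }
  structure(
    list(
      n_proteins = n_proteins, min_length = min_length,
      max_length = max_length, positive_rate = positive_rate,
      motif = motif_def(motif)$id, motif_conformance = motif_conformance,
      ptm_signal = ptm_signal, structure_signal = structure_signal,
      background = freq / sum(freq), seed = seed
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic proteome with planted SUMOylation sites
#'
#' See [synthetic_config()] for the dials. Context rewriting locks every
#' touched position so later sites can never undo an earlier site's planted
#' (non-)conformance; a site whose rewrite is infeasible (sequence end or a
#' locked/lysine position in the way) is skipped with a message. The ground
#' truth records each kept site's actual conformance (re-derived from the
#' final sequence) and whether PTM signal was planted.
#'
#' @param config A [synthetic_config()] (or arguments passed through to it).
#' @param ... Passed to [synthetic_config()] when `config` is missing.
#' @return A `synthetic_dataset` list of tibbles: `proteins` (with
#'   `positive_sites` attached), `annotations`, `structure`, `ptm`, `truth`,
#'   plus the `config`. Write to disk with [write_dataset()].
#' @export
#' @examples
#' ds <- generate_dataset(n_proteins = 4, seed = 1)
#' ds$truth
generate_dataset <- function(config = NULL, ...) {
  config <- config %||% synthetic_config(...)
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  motif <- motif_def(config$motif)
  non_psi <- setdiff(AA_ALPHABET, c(motif$psi, "K"))
  non_tail <- setdiff(AA_ALPHABET, c(motif$tail, "K"))

  proteins <- vector("list", config$n_proteins)
  truth_rows <- vector("list", config$n_proteins)
  n_skipped <- 0L

  for (i in seq_len(config$n_proteins)) {
    id <- sprintf("SYN%04d", i)
    len <- sample(config$min_length:config$max_length, 1)
    chars <- sample(AA_ALPHABET, len, replace = TRUE, prob = config$background)
    ks <- which(chars == "K")
    pos <- ks[runif(length(ks)) < config$positive_rate]
    locked <- pos   # planted lysines themselves must never be overwritten
    kept <- integer(0)
    conforming <- logical(0)
    for (k in pos) {
      if (is.null(config$motif_conformance)) {
        kept <- c(kept, k)
        conforming <- c(conforming, NA)
        next
      }
      want_cy <- runif(1) < config$motif_conformance
      targets <- if (want_cy) {
        if (k < 2 || k + 2 > len) NULL
        else list(c(k - 1, sample(motif$psi, 1)),
                  c(k + 2, sample(motif$tail, 1)))
      } else {
        # a missing K+2 already guarantees CN; otherwise break psi and tail
        tg <- list()
        if (k >= 2 && chars[k - 1] %in% motif$psi) {
          tg <- c(tg, list(c(k - 1, sample(non_psi, 1))))
        }
        if (k + 2 <= len && chars[k + 2] %in% motif$tail) {
          tg <- c(tg, list(c(k + 2, sample(non_tail, 1))))
        }
        tg
      }
      if (is.null(targets)) { n_skipped <- n_skipped + 1L; next }
      t_pos <- vapply(targets, function(t) as.integer(t[1]), integer(1))
      if (any(t_pos %in% locked)) { n_skipped <- n_skipped + 1L; next }
      for (t in targets) chars[as.integer(t[1])] <- t[2]
      # lock the whole motif context so later rewrites cannot disturb it
      locked <- c(locked, max(1, k - 1):min(len, k + 2))
      kept <- c(kept, k)
      conforming <- c(conforming, want_cy)
    }
    proteins[[i]] <- tibble(
      protein_id = id, sequence = paste(chars, collapse = ""),
      positive_sites = list(as.integer(kept))
    )
    if (length(kept) > 0) {
      truth_rows[[i]] <- tibble(
        protein_id = id, position = as.integer(kept),
        conforming = as.integer(conforming)
      )
    }
  }
  if (n_skipped > 0) {
    inform(paste0(n_skipped, " planted site(s) skipped (rewrite infeasible)."))
  }
  proteins <- bind_rows(proteins)
  truth <- bind_rows(truth_rows)
  if (nrow(truth) == 0) {
    truth <- tibble(protein_id = character(), position = integer(),
                    conforming = integer())
  }

  profiles <- make_profiles(proteins, truth, config)
  truth <- profiles$truth

  annotations <- select(truth, "protein_id", "position")
  structure(
    list(proteins = proteins, annotations = annotations,
         structure = profiles$structure, ptm = profiles$ptm,
         truth = truth, config = config),
    class = "synthetic_dataset"
  )
}

make_profiles <- function(proteins, truth, config) {
  lens <- nchar(proteins$sequence)
  n_res <- sum(lens)
  base <- tibble(
    protein_id = rep(proteins$protein_id, lens),
    position = unlist(lapply(lens, seq_len))
  )
  # background structure: coin-flip burial, uniform accessibility, Dirichlet
  # helix/strand/coil probabilities
  g <- matrix(stats::rgamma(n_res * 3, shape = 1), ncol = 3)
  probs <- g / rowSums(g)
  struct <- bind_cols(base, tibble(
    buried_exposed = rbinom(n_res, 1, 0.45),
    rsa = round(runif(n_res), 3),
    asa = NA_real_,
    zscore = round(rnorm(n_res), 3),
    alpha_prob = round(probs[, 1], 3),
    beta_prob = round(probs[, 2], 3),
    coil_prob = round(probs[, 3], 3)
  ))
  # background PTM confidence codes, identical for positives and negatives
  ptm_vals <- matrix(
    sample(PTM_CODES, n_res * 6, replace = TRUE,
           prob = c(0.93, 0.04, 0.02, 0.01)),
    ncol = 6
  )
  colnames(ptm_vals) <- PTM_TYPES
  ptm <- bind_cols(base, as_tibble(ptm_vals))

  truth$planted_ptm <- 0L
  if (nrow(truth) > 0) {
    key <- paste(base$protein_id, base$position)
    site_row <- match(paste(truth$protein_id, truth$position), key)
    lens_by_id <- setNames(lens, proteins$protein_id)
    if (config$ptm_signal > 0) {
      plant <- runif(nrow(truth)) < config$ptm_signal
      truth$planted_ptm <- as.integer(plant)
      for (j in which(plant)) {
        r <- site_row[j]
        ptm$acetylation[r] <- 100
        ptm$ubiquitination[r] <- 100
        if (truth$position[j] + 1 <= lens_by_id[truth$protein_id[j]]) {
          ptm$phosphorylation[r + 1] <- 50
        }
      }
    }
    if (config$structure_signal > 0) {
      plant <- runif(nrow(truth)) < config$structure_signal
      for (j in which(plant)) {
        r <- site_row[j]
        struct$buried_exposed[r] <- 1L
        struct$rsa[r] <- round(runif(1, 0.75, 1), 3)
      }
    }
  }
  struct$asa <- round(struct$rsa * 200, 1)
  list(structure = struct, ptm = ptm, truth = truth)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d proteins, %d planted positives (motif %s, conformance %s)\n",
    nrow(x$proteins), nrow(x$truth), x$config$motif,
    if (is.null(x$config$motif_conformance)) "off"
    else format(x$config$motif_conformance)
  ))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits `proteins.fasta`, `sites.tsv` (annotations), `structure.tsv`,
#' `ptm.tsv` and `truth.tsv` into `dir`. All TSVs carry the package/seed
#' header comment; rewriting with the same config and seed is
#' byte-identical.
#'
#' @param dataset A `synthetic_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "proteins.fasta"),
    annotations = file.path(dir, "sites.tsv"),
    structure = file.path(dir, "structure.tsv"),
    ptm = file.path(dir, "ptm.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  seqs <- Biostrings::AAStringSet(setNames(dataset$proteins$sequence,
                                           dataset$proteins$protein_id))
  Biostrings::writeXStringSet(seqs, paths["fasta"])
  seed <- dataset$config$seed
  write_tsv_with_header(dataset$annotations, paths["annotations"],
                        seed = seed, config = dataset$config)
  write_tsv_with_header(dataset$structure, paths["structure"],
                        seed = seed, config = dataset$config)
  write_tsv_with_header(dataset$ptm, paths["ptm"],
                        seed = seed, config = dataset$config)
  write_tsv_with_header(dataset$truth, paths["truth"],
                        seed = seed, config = dataset$config)
  invisible(paths)
}

#' Encode a synthetic dataset end to end
#'
#' Convenience wrapper: extract labelled windows from the generated proteins
#' and encode them with the dataset's own structure and PTM profiles.
#'
#' @param dataset A `synthetic_dataset`.
#' @param structure,ptm Override the providers: `TRUE` (default) uses the
#'   dataset's profile, `NULL`/`FALSE` the null provider.
#' @return An encoded window tibble ([encode_windows()]).
#' @export
encode_dataset <- function(dataset, structure = TRUE, ptm = TRUE) {
  windows <- extract_windows(dataset$proteins)
  windows <- filter(windows, .data$label != "unknown")
  encode_windows(
    windows,
    structure = if (isTRUE(structure)) dataset$structure else NULL,
    ptm = if (isTRUE(ptm)) dataset$ptm else NULL
  )
}
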