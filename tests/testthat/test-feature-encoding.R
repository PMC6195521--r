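test_that("binary block is a per-position one-hot with gaps as zeros", {
  all_gap <- paste(c(rep("-", 10), "K", rep("-", 10)), collapse = "")
  b <- encode_binary(c(all_gap, make_window()))
  expect_equal(dim(b), c(2L, 420L))
  expect_equal(sum(b[1, ]), 1)          # only the centre K is a residue
  expect_equal(sum(b[2, ]), 21)         # fully non-gap: exactly 21 ones
  expect_true(all(b %in% c(0, 1)))
  # ones sit in the right channels: centre K -> position 11, channel K
  k_col <- (11 - 1) * 20 + match("K", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(unname(b[1, k_col]), 1)
  # ones per window equal the non-gap count for arbitrary windows
  wins <- random_windows(50, seed = 3)
  ones <- rowSums(encode_binary(wins))
  expect_equal(unname(ones), 21 - stringr::str_count(wins, "-"))
})

test_that("physicochemical block repeats table rows and zeroes gaps", {
  tab <- physchem_table()
  all_a <- paste(c(rep("A", 10), "K", rep("A", 10)), collapse = "")
  p <- encode_physchem(all_a, tab)
  expect_equal(ncol(p), 210L)
  a_row <- unlist(tab[tab$aa == "A", -1])
  k_row <- unlist(tab[tab$aa == "K", -1])
  expect_equal(unname(p[1, 1:10]), unname(a_row))
  expect_equal(unname(p[1, 101:110]), unname(k_row))  # centre position
  gap_win <- paste(c(rep("-", 10), "K", rep("-", 10)), collapse = "")
  g <- encode_physchem(gap_win, tab)
  expect_equal(unname(g[1, 1:100]), rep(0, 100))
})

test_that("structure and PTM blocks pull profile rows; null providers zero", {
  prot <- tibble::tibble(protein_id = "P1",
                         sequence = paste(rep("A", 30), collapse = ""),
                         positive_sites = list(integer(0)))
  # make position 5 a K so there is an N-terminal window
  substr(prot$sequence, 5, 5) <- "K"
  substr(prot$sequence, 20, 20) <- "K"
  w <- extract_windows(prot, negatives_rule = FALSE)

  expect_equal(unname(encode_structure(w)), matrix(0, 2, 147))
  expect_equal(unname(encode_ptm(w)), matrix(0, 2, 126))

  struct <- tibble::tibble(
    protein_id = "P1", position = 1:30,
    buried_exposed = rep(1, 30), rsa = (1:30) / 30, asa = (1:30) * 2,
    zscore = rep(0.5, 30), alpha_prob = rep(0.2, 30),
    beta_prob = rep(0.3, 30), coil_prob = rep(0.5, 30)
  )
  s <- encode_structure(w, struct)
  # window at K=5 has 6 padded N-terminal positions -> 6 x 7 leading zeros
  expect_equal(unname(s[1, 1:42]), rep(0, 42))
  # window position 7 of that window is protein position 1
  expect_equal(unname(s[1, 43:49]),
               c(1, 1 / 30, 2, 0.5, 0.2, 0.3, 0.5))

  ptm <- tibble::tibble(protein_id = "P1", position = 1:30)
  for (t in c("acetylation", "hydroxylation", "methylation",
              "phosphorylation", "sumoylation", "ubiquitination")) {
    ptm[[t]] <- rep(0, 30)
  }
  # a high-confidence phosphorylation at protein position 14 = window
  # position 5 of the K=20 window
  ptm$phosphorylation[14] <- 100
  e <- encode_ptm(w, ptm)
  cols <- colnames(e)
  expect_equal(unname(e[2, cols == "ptm_5_phosphorylation"]), 100)
  expect_equal(sum(e[2, ]), 100)

  # masking the centre sumoylation channel zeroes exactly that entry
  ptm$sumoylation[20] <- 100
  e2 <- encode_ptm(w, ptm, mask_center_sumo = TRUE)
  expect_equal(unname(e2[2, cols == "ptm_11_sumoylation"]), 0)

  # a profile that does not cover the sequence is an error
  expect_error(encode_structure(w, struct[1:10, ]), "does not cover")
  # codes outside the four levels are rejected
  ptm$acetylation[3] <- 25
  expect_error(encode_ptm(w, ptm), "25")
})

test_that("encode_windows concatenates blocks at the fixed layout", {
  ds <- generate_dataset(n_proteins = 6, min_length = 40, max_length = 80,
                         positive_rate = 0.4, ptm_signal = 0.8,
                         structure_signal = 0.8, seed = 21)
  w <- extract_windows(ds$proteins)
  enc <- encode_windows(w, structure = ds$structure, ptm = ds$ptm)
  feats <- as.matrix(enc[, feature_names()])
  expect_equal(ncol(feats), 903L)

  # layout conservation: slicing at 420/630/777 reproduces each block
  expect_equal(unname(feats[, 1:420]), unname(encode_binary(w$window)))
  expect_equal(unname(feats[, 421:630]), unname(encode_physchem(w$window)))
  expect_equal(unname(feats[, 631:777]),
               unname(encode_structure(w, ds$structure)))
  expect_equal(unname(feats[, 778:903]), unname(encode_ptm(w, ds$ptm)))

  # swapping a provider for null changes only its own block
  enc_null_s <- encode_windows(w, structure = NULL, ptm = ds$ptm)
  f2 <- as.matrix(enc_null_s[, feature_names()])
  expect_equal(f2[, c(1:630, 778:903)], feats[, c(1:630, 778:903)])
  expect_true(all(f2[, 631:777] == 0))
  enc_null_p <- encode_windows(w, structure = ds$structure, ptm = NULL)
  f3 <- as.matrix(enc_null_p[, feature_names()])
  expect_equal(f3[, 1:777], feats[, 1:777])
  expect_true(all(f3[, 778:903] == 0))

  # determinism: same inputs, identical vectors
  enc_again <- encode_windows(w, structure = ds$structure, ptm = ds$ptm)
  expect_identical(enc, enc_again)
})

test_that("provider files parse, validate ranges, and round-trip", {
  struct_lines <- c(
    "# provider fixture",
    paste("protein_id", "position", "buried_exposed", "rsa", "asa", "zscore",
          "alpha_prob", "beta_prob", "coil_prob", sep = "\t"),
    "P1\t1\t0\t0.10\t20.0\t-1.2\t0.3\t0.3\t0.4",
    "P1\t2\t1\t0.90\t150.0\t0.8\t0.1\t0.2\t0.7",
    "P1\t3\t0\t0.50\t80.0\t0.0\t0.5\t0.1\t0.4"
  )
  prof <- parse_structure_file(write_tsv_fixture(struct_lines))
  expect_equal(nrow(prof), 3)
  expect_equal(prof$rsa, c(0.1, 0.9, 0.5))

  bad_prob <- struct_lines
  bad_prob[3] <- "P1\t1\t0\t0.10\t20.0\t-1.2\t1.2\t0.3\t0.4"
  expect_error(parse_structure_file(write_tsv_fixture(bad_prob)), "\\[0, 1\\]")

  ptm_lines <- c(
    "P1\t1\t0\t0\t10\t50\t0\t100",
    "P1\t2\t0\t0\t0\t0\t0\t0",
    "P1\t3\t100\t0\t0\t0\t10\t0"
  )
  prof <- parse_ptm_file(write_tsv_fixture(ptm_lines))
  expect_equal(prof$phosphorylation, c(50, 0, 0))
  expect_equal(prof$ubiquitination, c(100, 0, 0))

  bad_code <- sub("\t10\t50", "\t25\t50", ptm_lines)
  expect_error(parse_ptm_file(write_tsv_fixture(bad_code)), "25")
})

test_that("a custom physicochemical table must have the full 20-row shape", {
  tab <- physchem_table()
  expect_equal(dim(tab), c(20L, 11L))
  expect_error(validate_physchem(tab[-1, ]), "one row per")
})
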