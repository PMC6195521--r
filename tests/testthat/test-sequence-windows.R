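test_that("read_fasta parses records in file order with ids up to whitespace", {
  path <- write_fasta_fixture(list("P1 some description" = "MKV",
                                   "P2" = "AAKAA"))
  prot <- read_fasta(path)
  expect_equal(prot$protein_id, c("P1", "P2"))
  expect_equal(prot$sequence, c("MKV", "AAKAA"))
  expect_equal(prot$positive_sites, list(integer(0), integer(0)))
})

test_that("read_fasta rejects empty files and non-standard residues", {
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_fasta(empty), "empty")
  path <- write_fasta_fixture(list(P1 = "MKXV"))
  expect_error(read_fasta(path), "outside the 20-letter alphabet")
  # permissive mode maps the six non-standard codes to gaps
  prot <- read_fasta(path, permissive = TRUE)
  expect_equal(prot$sequence, "MK-V")
  # permissive does not excuse arbitrary characters
  bad <- write_fasta_fixture(list(P1 = "MK*V"))
  expect_error(read_fasta(bad, permissive = TRUE), "outside")
})

test_that("read_fasta keep_ids filters to cluster representatives", {
  path <- write_fasta_fixture(list(P1 = "MKV", P2 = "AKA", P3 = "KKK"))
  prot <- read_fasta(path, keep_ids = c("P1", "P3"))
  expect_equal(prot$protein_id, c("P1", "P3"))
})

test_that("site annotations attach, validate and deduplicate", {
  path <- write_fasta_fixture(list(P1 = "MKV", P2 = "AAKAAKA"))
  prot <- read_fasta(path)

  ann <- write_tsv_fixture(c("# comment", "P1\t2", "P2\t6", "P1\t2"))
  out <- read_site_annotations(prot, ann)
  expect_equal(out$positive_sites[[1]], 2L)
  expect_equal(out$positive_sites[[2]], 6L)

  # optional header row is tolerated
  with_header <- write_tsv_fixture(c("protein_id\tposition", "P1\t2"))
  expect_equal(read_site_annotations(prot, with_header)$positive_sites[[1]], 2L)

  # a position that is not a lysine names protein and position
  not_k <- write_tsv_fixture("P1\t1")
  expect_error(read_site_annotations(prot, not_k), "P1:1")

  unknown <- write_tsv_fixture("P9\t2")
  expect_error(read_site_annotations(prot, unknown), "P9")

  empty_ann <- write_tsv_fixture(character(0))
  out <- read_site_annotations(prot, empty_ann)
  expect_equal(lengths(out$positive_sites), c(0L, 0L))
})

test_that("extract_windows pads, centres and labels per the dataset rules", {
  prot <- tibble::tibble(protein_id = "P1", sequence = "MKV",
                         positive_sites = list(2L))
  w <- extract_windows(prot)
  expect_equal(w$window, paste0(strrep("-", 9), "MKV", strrep("-", 9)))
  expect_equal(w$label, "positive")
  expect_equal(w$center_pos, 2L)

  # 21-residue protein with K at 11: window is the unpadded sequence
  seq21 <- paste0(strrep("A", 10), "K", strrep("A", 10))
  prot <- tibble::tibble(protein_id = "P1", sequence = seq21,
                         positive_sites = list(11L))
  expect_equal(extract_windows(prot)$window, seq21)

  # no lysine -> no windows
  prot <- tibble::tibble(protein_id = "P1", sequence = "AAAA",
                         positive_sites = list(integer(0)))
  expect_equal(nrow(extract_windows(prot)), 0)

  # second K in an annotated protein: negative with the rule on, unknown off
  prot <- tibble::tibble(protein_id = "P1", sequence = "AKAAKAA",
                         positive_sites = list(2L))
  expect_equal(sort(extract_windows(prot, TRUE)$label),
               c("negative", "positive"))
  expect_equal(sort(extract_windows(prot, FALSE)$label),
               c("positive", "unknown"))

  # lysines in proteins without any positive are unknown either way
  prot <- tibble::tibble(protein_id = "P1", sequence = "AKA",
                         positive_sites = list(integer(0)))
  expect_equal(extract_windows(prot, TRUE)$label, "unknown")
})

test_that("windows reconstruct from the sequence and partition by label", {
  ds <- generate_dataset(n_proteins = 15, min_length = 25, max_length = 120,
                         positive_rate = 0.3, seed = 99)
  w <- extract_windows(ds$proteins)
  seqs <- setNames(ds$proteins$sequence, ds$proteins$protein_id)

  # offset reconstruction: window position i <-> protein position c + (i-11)
  rebuilt <- purrr::map2_chr(w$protein_id, w$center_pos, function(id, cp) {
    chars <- strsplit(seqs[[id]], "")[[1]]
    pos <- cp + (1:21) - 11
    out <- ifelse(pos >= 1 & pos <= length(chars), chars[pmax(pos, 1)], "-")
    paste(out, collapse = "")
  })
  expect_equal(w$window, rebuilt)
  expect_true(all(substr(w$window, 11, 11) == "K"))
  expect_true(all(nchar(w$window) == 21))

  # one window per K; labels partition the lysines
  k_counts <- stringr::str_count(ds$proteins$sequence, "K")
  expect_equal(nrow(w), sum(k_counts))
  n_pos <- sum(lengths(ds$proteins$positive_sites))
  expect_equal(sum(w$label == "positive"), n_pos)
  expect_equal(sum(w$label != "positive"), sum(k_counts) - n_pos)
})
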