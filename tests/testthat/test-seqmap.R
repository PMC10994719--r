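test_that("exact substring aligns with full identity at the right offset", {
  al <- smith_waterman("KLMNP", "AAKLMNPAA")
  expect_equal(al$score, 10)
  expect_equal(al$target_interval, c(3, 7))
  expect_equal(al$identity, 1.0)
  expect_equal(al$aligned_pairs[, 1], 1:5)
  expect_equal(al$aligned_pairs[, 2], 3:7)
})

test_that("sequences without a positive-scoring cell give the empty alignment", {
  al <- smith_waterman("AAAA", "GGGG")
  expect_equal(al$score, 0)
  expect_true(is.na(al$query_interval[1]))
  expect_equal(nrow(al$aligned_pairs), 0)
  expect_error(smith_waterman("", "ACD"), "non-empty")
})

test_that("alignment score is symmetric in its arguments", {
  set.seed(11)
  for (k in 1:100) {
    q <- random_peptide(sample(4:12, 1))
    t <- random_peptide(sample(4:25, 1))
    expect_equal(smith_waterman(q, t)$score, smith_waterman(t, q)$score)
  }
})

test_that("scores agree with an independent aligner on random pairs", {
  skip_if_not_installed("Biostrings")
  sm <- matrix(-1, 27, 27,
               dimnames = list(c(LETTERS, "*"), c(LETTERS, "*")))
  diag(sm) <- 2
  set.seed(12)
  for (k in 1:50) {
    q <- random_peptide(8)
    t <- random_peptide(30)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(t), type = "local",
      substitutionMatrix = sm, gapOpening = 4, gapExtension = 1)
    expect_equal(smith_waterman(q, t)$score, Biostrings::score(ref))
  }
})

test_that("aligned pairs are strictly increasing and identity is in [0,1]", {
  set.seed(13)
  for (k in 1:40) {
    al <- smith_waterman(random_peptide(10), random_peptide(40))
    if (nrow(al$aligned_pairs) > 1) {
      expect_true(all(diff(al$aligned_pairs[, 1]) > 0))
      expect_true(all(diff(al$aligned_pairs[, 2]) > 0))
    }
    expect_gte(al$identity, 0)
    expect_lte(al$identity, 1)
  }
})

test_that("peptide positions map to protein coordinates by offset", {
  prot <- toy_protein("T1", paste0(strrep("A", 10), "KLMNPQRST",
                                   strrep("A", 10)))
  m <- map_peptide_position("KLMNPQRST", 3, prot)
  expect_true(m$mappable)
  expect_equal(m$pos_in_protein, 13L)
})

test_that("a mismatch away from the link site still maps; at the site it does not", {
  prot <- toy_protein("T2", paste0(strrep("A", 10), "KLMNPQRST",
                                   strrep("A", 10)))
  # W at peptide position 1 is a mismatch, link site 5 is identical
  m <- map_peptide_position("WLMNPQRST", 5, prot)
  expect_true(m$mappable)
  expect_equal(m$pos_in_protein, 15L)
  # link site itself substituted -> unmappable
  m2 <- map_peptide_position("KLMNWQRST", 5, prot)
  expect_false(m2$mappable)
})

test_that("a peptide absent from the protein is unmappable", {
  prot <- toy_protein("T3", strrep("A", 30))
  m <- map_peptide_position("WYWYW", 3, prot)
  expect_false(m$mappable)
})

test_that("side-swapped duplicate rows collapse to one link with multiplicity 2", {
  prot <- paste0(strrep("A", 5), "KLMNPQRST", strrep("A", 5), "WYVTREHCD",
                 strrep("A", 5))
  proteins <- list(P1 = toy_protein("P1", prot))
  raw <- read_crosslink_table(write_links_csv(data.frame(
    protein1 = c("P1", "P1"), protein2 = c("P1", "P1"),
    peptide1 = c("KLMNPQRST", "WYVTREHCD"),
    peptide2 = c("WYVTREHCD", "KLMNPQRST"),
    pos_pep1 = c(3, 4), pos_pep2 = c(4, 3))))$links
  nl <- normalize_links(raw, proteins)
  expect_equal(nrow(nl$links), 1)
  expect_equal(nl$links$multiplicity, 2L)
  expect_equal(nl$links$link_type, "intra")
})

test_that("normalization is idempotent", {
  prot <- paste0(strrep("A", 5), "KLMNPQRST", strrep("A", 5), "WYVTREHCD")
  proteins <- list(P1 = toy_protein("P1", prot))
  raw <- read_crosslink_table(write_links_csv(data.frame(
    protein1 = "P1", protein2 = "P1",
    peptide1 = "KLMNPQRST", peptide2 = "WYVTREHCD",
    pos_pep1 = 3, pos_pep2 = 4)))$links
  once <- normalize_links(raw, proteins)$links
  twice <- normalize_links(once, proteins)$links
  expect_equal(as.data.frame(twice), as.data.frame(once))
})

test_that("an inconsistent given protein position loses to the mapped one", {
  prot <- paste0(strrep("A", 10), "KLMNPQRST")
  proteins <- list(P1 = toy_protein("P1", prot))
  raw <- read_crosslink_table(write_links_csv(data.frame(
    protein1 = "P1", protein2 = "P1",
    peptide1 = "KLMNPQRST", peptide2 = "KLMNPQRST",
    pos_pep1 = 3, pos_pep2 = 5, pos_prot1 = 2, pos_prot2 = 15)),
    xl_config())$links
  nl <- normalize_links(raw, proteins)
  expect_equal(nl$links$pos_prot_a, 13L)
  expect_equal(nl$links$pos_prot_b, 15L)
  expect_true(any(grepl("disagrees", nl$diagnostics$message)))
})

test_that("links to absent accessions are dropped with a diagnostic", {
  proteins <- list(P1 = toy_protein("P1", strrep("K", 20)))
  raw <- read_crosslink_table(write_links_csv(data.frame(
    protein1 = "P1", protein2 = "MISSING",
    peptide1 = "KKKKK", peptide2 = "KKKKK",
    pos_pep1 = 1, pos_pep2 = 1)))$links
  nl <- normalize_links(raw, proteins)
  expect_equal(nrow(nl$links), 0)
  expect_true(any(grepl("not in FASTA", nl$diagnostics$message)))
})

test_that("mapped peptides re-extract from the protein at full identity", {
  prot <- paste0(strrep("A", 7), "KLMNPQRST", strrep("C", 7), "WYVTREHID")
  proteins <- list(P1 = toy_protein("P1", prot))
  raw <- read_crosslink_table(write_links_csv(data.frame(
    protein1 = "P1", protein2 = "P1",
    peptide1 = "KLMNPQRST", peptide2 = "WYVTREHID",
    pos_pep1 = 2, pos_pep2 = 2)))$links
  nl <- normalize_links(raw, proteins)$links
  for (side in c("a", "b")) {
    pep <- nl[[paste0("peptide_", side)]]
    al <- smith_waterman(pep, prot)
    frag <- substr(prot, al$target_interval[1], al$target_interval[2])
    ident <- mean(strsplit(frag, "")[[1]] == strsplit(pep, "")[[1]])
    expect_gte(ident, al$identity)
  }
})
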