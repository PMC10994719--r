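norm_one <- function(seqs, acc, pos_a, pos_b) {
  proteins <- stats::setNames(list(toy_protein(acc, seqs)), acc)
  pa <- max(1, pos_a - 4); pb <- max(1, pos_b - 4)
  raw <- read_crosslink_table(write_links_csv(data.frame(
    protein1 = acc, protein2 = acc,
    peptide1 = substr(seqs, pa, pos_a + 4),
    peptide2 = substr(seqs, pb, pos_b + 4),
    pos_pep1 = pos_a - pa + 1, pos_pep2 = pos_b - pb + 1)))$links
  normalize_links(raw, proteins)$links[1, ]
}

test_that("assignment enumeration covers chains and deduplicates pairs", {
  seqs <- xlinkval:::random_protein(60, 71)
  p <- toy_protein("P", seqs)
  mono <- helix_structure(seqs)
  link <- norm_one(seqs, "P", 10, 30)
  cand_m <- select_structures(p, list(mono))[[1]]
  expect_equal(nrow(enumerate_assignments(link, cand_m, "same_chain")), 1)
  expect_equal(nrow(enumerate_assignments(link, cand_m, "cross_chain")), 0)

  dimer <- rbind(make_helix_chain(seqs, "A"),
                 make_helix_chain(seqs, "B", origin = c(10, 0, 0)))
  f <- tempfile(fileext = ".pdb")
  write_pdb_fixture(dimer, f, resolution = 2)
  cand_d <- find_complex_structures(p, p, list(read_structure(f)))[[1]]
  # symmetric link (i to i): the two cross-chain orientations coincide
  slink <- norm_one(seqs, "P", 10, 10)
  expect_equal(nrow(enumerate_assignments(slink, cand_d, "same_chain")), 2)
  expect_equal(nrow(enumerate_assignments(slink, cand_d, "cross_chain")), 1)
  expect_equal(nrow(enumerate_assignments(slink, cand_d, "all")), 3)
  # asymmetric link keeps both cross-chain orientations
  expect_equal(nrow(enumerate_assignments(link, cand_d, "cross_chain")), 2)
})

test_that("the best assignment minimizes topological distance", {
  # antiparallel dimer: residues 10 and 90 are far along one chain but
  # close across the interface
  seqs <- xlinkval:::random_protein(100, 421)
  dimer <- rbind(make_helix_chain(seqs, "A"),
                 make_helix_chain(seqs, "B", origin = c(10, 0, 148.5),
                                  orientation = diag(c(1, -1, -1))))
  f <- tempfile(fileext = ".pdb")
  write_pdb_fixture(dimer, f, resolution = 2)
  m <- read_structure(f)
  p <- toy_protein("P", seqs)
  cand <- find_complex_structures(p, p, list(m))[[1]]
  link <- norm_one(seqs, "P", 10, 90)
  asg <- enumerate_assignments(link, cand, "all")
  ev <- evaluate_link(link, asg, m)
  expect_true(ev$best$chain_a != ev$best$chain_b)
  expect_true(is.finite(ev$best$topological))
  # best is no worse than every individual assignment
  expect_true(all(ev$best$topological <= ev$results$topological + 1e-9))
  # same-chain interpretations exceed the search cap
  same <- ev$results[ev$results$chain_a == ev$results$chain_b, ]
  expect_true(all(!is.finite(same$topological)))
})

test_that("distances classify against the linker range with a lower bound", {
  lk <- linker_spec()
  expect_equal(classify_distance(20, lk), "within")
  expect_equal(classify_distance(40, lk), "out_of_range")
  expect_equal(classify_distance(4, lk), "out_of_range")
  expect_equal(classify_distance(Inf, lk), "out_of_range")
  # raising linker_max never moves a link from within to out of range
  ds <- c(4, 6, 20, 34.9, 40, 70)
  prev <- rep(FALSE, length(ds))
  for (mx in c(20, 35, 50, 80)) {
    now <- vapply(ds, function(d)
      classify_distance(d, linker_spec(max_distance = mx)) == "within",
      logical(1))
    expect_true(all(now[prev]))
    prev <- now
  }
})

test_that("every link receives exactly one category", {
  sc <- make_homodimer_scenario(tempfile("dim"))
  res <- run_pipeline(sc$crosslink_csv, sc$fasta, sc$structure_dir)
  cats <- c("intra_within_range", "intra_out_of_range", "ops_inter",
            "ops_inter_validated", "out_of_range_inter_validated",
            "inter_within_range", "inter_out_of_range", "unmapped")
  expect_equal(nrow(res$links), 2)
  expect_true(all(res$links$category %in% cats))
  # validated categories carry a within-range distance
  val <- res$links$category %in% c("ops_inter_validated",
                                   "out_of_range_inter_validated")
  expect_true(all(res$links$within_range[val]))
})

test_that("links without any usable structure are unmapped", {
  seqs <- xlinkval:::random_protein(60, 72)
  proteins <- list(P = toy_protein("P", seqs))
  link <- norm_one(seqs, "P", 10, 30)
  cls <- full_classify(link, NULL, proteins, list())
  expect_equal(cls$category, "unmapped")
  expect_null(cls$best)
})
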