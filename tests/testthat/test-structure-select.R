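test_that("chain sequences cover observed residues in author order", {
  m <- helix_structure(strrep("A", 20))
  cs <- chain_sequence(m, "A")
  expect_equal(cs$sequence, strrep("A", 20))
  expect_equal(cs$map$resno, 1:20)
})

test_that("author-numbering gaps do not insert gap characters", {
  seqs <- xlinkval:::random_protein(20, 41)
  a1 <- make_helix_chain(substr(seqs, 1, 10))
  a2 <- make_helix_chain(substr(seqs, 15, 20), start_resno = 15L,
                         origin = c(0, 0, 21))
  f <- tempfile(fileext = ".pdb")
  write_pdb_fixture(rbind(a1, a2), f, resolution = 2)
  m <- read_structure(f)
  cs <- chain_sequence(m, "A")
  expect_equal(nchar(cs$sequence), 16)
  expect_equal(cs$map$resno, c(1:10, 15:20))
  expect_equal(cs$sequence,
               paste0(substr(seqs, 1, 10), substr(seqs, 15, 20)))
})

test_that("selenomethionine maps to M by default and X otherwise", {
  at <- make_helix_chain("AMA")
  at$resname[at$resno == 2] <- "MSE"
  f <- tempfile(fileext = ".pdb")
  write_pdb_fixture(at, f, resolution = 2)
  m <- read_structure(f)
  expect_equal(chain_sequence(m, "A")$sequence, "AMA")
  expect_equal(chain_sequence(m, "A", mse_as_met = FALSE)$sequence, "AXA")
})

test_that("an exact-copy chain scores identity 1 and coverage 1", {
  seqs <- xlinkval:::random_protein(50, 42)
  m <- helix_structure(seqs)
  cm <- score_chain(toy_protein("P", seqs), m, "A")
  expect_equal(cm$identity, 1.0)
  expect_equal(cm$coverage, 1.0)
  expect_equal(nrow(cm$residue_map), 50)
})

test_that("a chain holding half the protein scores coverage 0.5", {
  seqs <- xlinkval:::random_protein(100, 43)
  m <- helix_structure(substr(seqs, 1, 50))
  cm <- score_chain(toy_protein("P", seqs), m, "A")
  expect_equal(cm$coverage, 0.5)
  expect_equal(cm$identity, 1.0)
})

test_that("a 20% point mutant scores identity near 0.8", {
  seqs <- xlinkval:::random_protein(100, 44)
  set.seed(45)
  mut <- mutate_sequence(seqs, 0.20)
  m <- helix_structure(mut)
  cm <- score_chain(toy_protein("P", seqs), m, "A")
  expect_gte(cm$identity, 0.75)
  expect_lte(cm$identity, 0.85)
})

test_that("predicted models are only a fallback and resolution gates experiments", {
  seqs <- xlinkval:::random_protein(60, 46)
  d <- tempfile("lib"); dir.create(d)
  write_pdb_fixture(make_helix_chain(seqs), file.path(d, "exp1.pdb"),
                    resolution = 3.0)
  write_pdb_fixture(make_helix_chain(seqs, bfactor = 90),
                    file.path(d, "model_p1.pdb"))
  lib <- structure_library(d)
  expect_equal(lib$model_p1$source, "predicted")
  cands <- select_structures(toy_protein("P", seqs), lib)
  expect_equal(vapply(cands, function(x) x$structure$structure_id,
                      character(1)), "exp1")
  # experimental structure beyond the resolution cutoff is rejected,
  # leaving the predicted model as fallback
  d2 <- tempfile("lib"); dir.create(d2)
  write_pdb_fixture(make_helix_chain(seqs), file.path(d2, "exp2.pdb"),
                    resolution = 4.5)
  write_pdb_fixture(make_helix_chain(seqs, bfactor = 90),
                    file.path(d2, "model_p2.pdb"))
  cands2 <- select_structures(toy_protein("P", seqs), structure_library(d2))
  expect_equal(vapply(cands2, function(x) x$structure$structure_id,
                      character(1)), "model_p2")
})

test_that("candidates rank by identity, then coverage, resolution, id", {
  seqs <- xlinkval:::random_protein(100, 47)
  set.seed(48)
  d <- tempfile("lib"); dir.create(d)
  write_pdb_fixture(make_helix_chain(mutate_sequence(seqs, 0.08)),
                    file.path(d, "a_worse.pdb"), resolution = 2)
  write_pdb_fixture(make_helix_chain(mutate_sequence(seqs, 0.05)),
                    file.path(d, "b_better.pdb"), resolution = 2)
  cands <- select_structures(toy_protein("P", seqs), structure_library(d))
  ids <- vapply(cands, function(x) x$structure$structure_id, character(1))
  idt <- vapply(cands, `[[`, numeric(1), "identity")
  expect_equal(ids[1], "b_better")
  expect_true(idt[1] > idt[2])
  # every returned candidate satisfies the cutoffs
  cfg <- xl_config()
  expect_true(all(idt >= cfg$identity_cutoff))
  # deterministic total order
  cands2 <- select_structures(toy_protein("P", seqs), structure_library(d))
  expect_equal(ids, vapply(cands2, function(x) x$structure$structure_id,
                           character(1)))
})

test_that("pLDDT trimming removes the designed residues and is monotone", {
  seqs <- xlinkval:::random_protein(100, 49)
  plddt <- c(rep(60, 10), rep(90, 90))
  at <- make_helix_chain(seqs, bfactor = plddt)
  f <- tempfile(fileext = ".pdb")
  write_pdb_fixture(at, f)
  m <- read_structure(f, source = "predicted")
  expect_equal(nrow(trim_by_plddt(m, 70)$residues), 90)
  expect_equal(nrow(trim_by_plddt(m, 0)$residues), 100)
  m2 <- helix_structure(seqs, source = "predicted", bfactor = 90)
  expect_equal(trim_by_plddt(m2, 70)$residues, m2$residues)
  # monotone: raising the cutoff never adds residues
  set.seed(50)
  m3 <- helix_structure(seqs, source = "predicted",
                        bfactor = runif(100, 40, 100))
  prev <- NULL
  for (cut in c(0, 50, 70, 90, 101)) {
    keys <- with(trim_by_plddt(m3, cut)$residues, paste(chain, resno))
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
  expect_error(trim_by_plddt(helix_structure(seqs), 70), "predicted")
})

test_that("homo-multimer queries need two matching chains", {
  seqs <- xlinkval:::random_protein(60, 51)
  dimer <- rbind(make_helix_chain(seqs, "A"),
                 make_helix_chain(seqs, "B", origin = c(10, 0, 0)))
  d <- tempfile("lib"); dir.create(d)
  write_pdb_fixture(dimer, file.path(d, "dim.pdb"), resolution = 2)
  write_pdb_fixture(make_helix_chain(seqs, "A"), file.path(d, "mono.pdb"),
                    resolution = 2)
  lib <- structure_library(d)
  p <- toy_protein("P", seqs)
  cands <- find_complex_structures(p, p, lib)
  expect_equal(vapply(cands, function(x) x$structure$structure_id,
                      character(1)), "dim")
  expect_length(cands[[1]]$chain_maps$P, 2)
})

test_that("hetero pairs need one matching chain per protein", {
  s1 <- xlinkval:::random_protein(60, 52)
  s2 <- xlinkval:::random_protein(60, 53)
  cplx <- rbind(make_helix_chain(s1, "A"),
                make_helix_chain(s2, "B", origin = c(12, 0, 0)))
  d <- tempfile("lib"); dir.create(d)
  write_pdb_fixture(cplx, file.path(d, "ab.pdb"), resolution = 2)
  lib <- structure_library(d)
  cands <- find_complex_structures(toy_protein("P1", s1),
                                   toy_protein("P2", s2), lib)
  expect_length(cands, 1)
  none <- find_complex_structures(toy_protein("P1", s1),
                                  toy_protein("P3", xlinkval:::random_protein(60, 54)),
                                  lib)
  expect_length(none, 0)
})

test_that("link residues map through the chain map, gaps stay unmapped", {
  seqs <- xlinkval:::random_protein(20, 55)
  a1 <- make_helix_chain(substr(seqs, 1, 10))
  a2 <- make_helix_chain(substr(seqs, 15, 20), start_resno = 15L,
                         origin = c(0, 0, 21))
  f <- tempfile(fileext = ".pdb")
  write_pdb_fixture(rbind(a1, a2), f, resolution = 2)
  m <- read_structure(f)
  cm <- score_chain(toy_protein("P", seqs), m, "A")
  expect_equal(map_link_residue(5, cm)$resno, 5)
  expect_false(map_link_residue(12, cm)$mapped)
  expect_error(map_link_residue(25, cm, protein_length = 20), "beyond")
})
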