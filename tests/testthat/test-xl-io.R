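test_that("header-only cross-link table yields empty links, no diagnostics", {
  f <- tempfile(fileext = ".csv")
  writeLines("protein1,protein2,peptide1,peptide2,pos_pep1,pos_pep2", f)
  r <- read_crosslink_table(f)
  expect_equal(nrow(r$links), 0)
  expect_equal(nrow(r$diagnostics), 0)
})

test_that("rows missing every position on one side are rejected per-row", {
  f <- write_links_csv(data.frame(
    protein1 = c("P1", "P1", "P2"), protein2 = c("P1", "P2", "P2"),
    peptide1 = c("ACDEFK", "KLMNP", "WYVTR"),
    peptide2 = c("KLMNPQ", "ACDEF", "ACDEF"),
    pos_pep1 = c(6, 1, 2), pos_pep2 = c(1, 2, NA)))
  r <- read_crosslink_table(f)
  expect_equal(nrow(r$links), 2)
  expect_equal(nrow(r$diagnostics), 1)
  expect_match(r$diagnostics$message, "side b")
  # totality: records + diagnostics = data rows
  expect_equal(nrow(r$links) + nrow(r$diagnostics), 3)
})

test_that("peptide modification annotations are stripped", {
  expect_equal(clean_peptide("ACDM[15.99]K"), "ACDMK")
  expect_equal(clean_peptide("AC(ox)DK"), "ACDK")
  expect_equal(clean_peptide("ACDKcmK"), "ACDKK")
  expect_equal(clean_peptide("acdefk"), "ACDEFK")
})

test_that("an unknown required column is fatal and names the found columns", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("prot_x,protein2,peptide1,peptide2", "a,b,c,d"), f)
  expect_error(read_crosslink_table(f), "protein1.*prot_x")
})

test_that("FASTA accessions follow UniProt pipe and bare-id conventions", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">sp|P04179|SODM_HUMAN", "MLSRAVCGT", ">toy1", "ACDEFG"), f)
  recs <- read_fasta(f)
  expect_setequal(names(recs), c("P04179", "toy1"))
  expect_equal(recs$toy1$sequence, "ACDEFG")
})

test_that("duplicate FASTA entries collapse; conflicting ones are fatal", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF", ">a", "ACDEF", ">b", "KLMNP"), f)
  expect_length(read_fasta(f), 2)
  g <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF", ">a", "ACDEG"), g)
  expect_error(read_fasta(g), "conflicting")
})

test_that("helix fixture reads back with expected chain and residues", {
  m <- helix_structure(strrep("A", 20))
  expect_s3_class(m, "xl_structure")
  expect_equal(unique(m$residues$chain), "A")
  expect_equal(nrow(m$residues), 20)
  expect_equal(m$resolution, 2.0)
  expect_equal(m$source, "experimental")
  # 20 residues x (N, CA, C, O, CB)
  expect_equal(nrow(m$atoms), 100)
})

test_that("PDB and mmCIF encodings parse to identical structure models", {
  seqs <- strrep("ADKLE", 4)
  at <- make_helix_chain(seqs)
  fp <- file.path(tempdir(), "fmt1.pdb")
  fc <- file.path(tempdir(), "fmt1.cif")
  write_pdb_fixture(at, fp, resolution = 3.1)
  write_cif_fixture(at, fc, resolution = 3.1)
  mp <- read_structure(fp)
  mc <- read_structure(fc)
  expect_equal(mp$atoms, mc$atoms)
  expect_equal(mp$residues, mc$residues)
  expect_equal(mp$resolution, mc$resolution)
})

test_that("only the first model of a multi-model file is kept", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00 10.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       9.000   9.000   9.000  1.00 10.00           C",
    "ENDMDL", "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x, c(0, 3.8))
})

test_that("altlocs resolve to highest occupancy; waters drop; ligands stay as volume", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00 10.00           C",
    "HETATM    4  O   HOH A 101       5.000   5.000   5.000  1.00 10.00           O",
    "HETATM    5 ZN    ZN A 102       6.000   6.000   6.000  1.00 10.00          ZN",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$residues), 2)
  expect_equal(m$atoms$x[m$atoms$resno == 1], 1.0)
  expect_equal(nrow(m$het_atoms), 1)
  expect_equal(m$het_atoms$element, "ZN")
})

test_that("result table writing requires classification and round-trips", {
  sc <- make_ops_scenario(tempfile("ops"))
  res <- run_pipeline(sc$crosslink_csv, sc$fasta, sc$structure_dir)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_result_table(res$links, f1)
  back <- read.csv(f1)
  expect_equal(nrow(back), nrow(res$links))
  expect_true(all(c("link_type_final", "topological_distance",
                    "evidence_class") %in% names(back)))
  expect_equal(back$overlap_length, res$links$overlap_length)
  write_result_table(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(write_result_table(res$links[, 1:4], tempfile()),
               "not fully classified")
})

test_that("structure library loads from a directory and honors the index", {
  d <- tempfile("lib")
  dir.create(d)
  write_pdb_fixture(make_helix_chain(strrep("K", 10)),
                    file.path(d, "s1.pdb"), resolution = 2.5)
  write_pdb_fixture(make_helix_chain(strrep("L", 10)),
                    file.path(d, "s2.pdb"))
  lib <- structure_library(d)
  expect_setequal(names(lib), c("s1", "s2"))
  idx <- file.path(d, "index.tsv")
  write.table(data.frame(structure_id = "only", path = file.path(d, "s2.pdb"),
                         resolution = 1.9, source = "experimental"),
              idx, sep = "\t", row.names = FALSE, quote = FALSE)
  lib2 <- structure_library(d, index = idx)
  expect_equal(names(lib2), "only")
  expect_equal(lib2$only$resolution, 1.9)
})
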