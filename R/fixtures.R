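# Synthetic structures, sequences and link tables with known ground truth.
# Fixtures are emitted as real files in standard formats (PDB, FASTA, CSV)
# so tests exercise the full I/O surface.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n, seed, exclude_gly = TRUE) {
  set.seed(seed)
  alpha <- if (exclude_gly) setdiff(AA20, "G") else AA20
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

#' Ideal helical chain coordinates
#'
#' Builds an idealized alpha-helical backbone (N, CA, C, O and CB except for
#' glycine) with analytically known geometry: alpha-carbons lie on a helix of
#' given radius, rise per residue and twist per residue; beta-carbons point
#' radially outward. Consecutive alpha-carbons are ~3.8 Angstrom apart under
#' the standard parameters.
#'
#' @param sequence one-letter amino-acid string (one residue per letter).
#' @param chain_id chain identifier.
#' @param rise rise per residue in Angstrom (default 1.5).
#' @param twist twist per residue in degrees (default 100).
#' @param radius alpha-carbon helix radius in Angstrom (default 2.3).
#' @param origin xyz translation applied after `orientation`.
#' @param orientation 3x3 rotation matrix applied to the canonical
#'   helix-along-z coordinates.
#' @param bfactor per-residue B-factor / pLDDT values (recycled).
#' @param start_resno author number of the first residue.
#' @return data frame of atoms (`chain`, `resno`, `insert`, `resname`,
#'   `atom_name`, `element`, `x`, `y`, `z`, `bfactor`).
#' @export
make_helix_chain <- function(sequence, chain_id = "A", rise = 1.5,
                             twist = 100, radius = 2.3, origin = c(0, 0, 0),
                             orientation = diag(3), bfactor = 30,
                             start_resno = 1L) {
  n <- nchar(sequence)
  stopifnot(n >= 3)
  aa1 <- strsplit(sequence, "")[[1]]
  aa3 <- unname(vapply(aa1, function(a) bio3d::aa123(a), character(1)))
  bfactor <- rep_len(bfactor, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    th <- (i - 1) * twist * pi / 180
    z <- (i - 1) * rise
    ca <- c(radius * cos(th), radius * sin(th), z)
    outv <- c(cos(th), sin(th), 0)
    tanv <- c(-sin(th), cos(th), 0)
    atoms <- list(
      N  = ca - 1.0 * tanv + c(0, 0, -0.9),
      CA = ca,
      C  = ca + 1.0 * tanv + c(0, 0, 0.9),
      O  = ca + 1.8 * tanv + c(0, 0, 1.3))
    if (aa1[i] != "G") atoms$CB <- ca + 1.53 * outv
    nm <- names(atoms)
    xyz <- t(vapply(atoms, function(p)
      as.numeric(orientation %*% p + origin), numeric(3)))
    dimnames(xyz) <- NULL
    rows[[i]] <- data.frame(
      chain = chain_id, resno = start_resno + i - 1L, insert = "",
      resname = aa3[i], atom_name = nm,
      element = substr(nm, 1, 1), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      bfactor = bfactor[i], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an atom table as a PDB file
#'
#' Minimal fixed-column PDB writer for fixture structures; optionally emits
#' a resolution header record.
#' @param atoms atom data frame as produced by [make_helix_chain()].
#' @param path output path.
#' @param resolution resolution in Angstrom for the `REMARK 2` record, or
#'   `NA` to omit it.
#' @return `path`, invisibly.
#' @export
write_pdb_fixture <- function(atoms, path, resolution = NA) {
  ln <- character()
  if (is.finite(resolution))
    ln <- c(ln, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    nm <- if (nchar(a$atom_name) < 4) paste0(" ", a$atom_name) else a$atom_name
    ln <- c(ln, sprintf(
      "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i %% 100000, nm, a$resname, a$chain, a$resno,
      ifelse(nzchar(a$insert), a$insert, " "),
      a$x, a$y, a$z, 1.00, a$bfactor, a$element))
  }
  writeLines(c(ln, "END"), path)
  invisible(path)
}

#' Write an atom table as a minimal mmCIF file
#'
#' Emits the same atoms as [write_pdb_fixture()] in an `atom_site` loop, used
#' to check that both encodings parse to identical structure models.
#' @inheritParams write_pdb_fixture
#' @return `path`, invisibly.
#' @export
write_cif_fixture <- function(atoms, path, resolution = NA) {
  id <- tools::file_path_sans_ext(basename(path))
  ln <- c(paste0("data_", id))
  if (is.finite(resolution))
    ln <- c(ln, sprintf("_refine.ls_d_res_high  %.2f", resolution))
  ln <- c(ln, "loop_",
          paste0("_atom_site.",
                 c("group_PDB", "id", "type_symbol", "label_atom_id",
                   "label_alt_id", "label_comp_id", "label_asym_id",
                   "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                   "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                   "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                   "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")))
  for (i in seq_len(nrow(atoms))) {
    a <- atoms[i, ]
    ln <- c(ln, sprintf(
      "ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f 1.00 %.2f %d %s %s %s 1",
      i, a$element, a$atom_name, a$resname, a$chain, a$resno,
      ifelse(nzchar(a$insert), a$insert, "?"),
      a$x, a$y, a$z, a$bfactor, a$resno, a$resname, a$chain, a$atom_name))
  }
  writeLines(ln, path)
  invisible(path)
}

write_fasta_fixture <- function(records, path) {
  ln <- unlist(lapply(records, function(r) c(paste0(">", r$accession),
                                             r$sequence)))
  writeLines(ln, path)
  invisible(path)
}

write_links_fixture <- function(links, path) {
  write.csv(links, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

peptide_at <- function(sequence, pos, flank = 4L) {
  start <- max(1L, pos - flank)
  end <- min(nchar(sequence), pos + flank)
  list(peptide = substr(sequence, start, end),
       pos_in_peptide = pos - start + 1L, interval = c(start, end))
}

assert_unique_peptide <- function(sequence, peptide) {
  hits <- gregexpr(peptide, sequence, fixed = TRUE)[[1]]
  if (length(hits[hits > 0]) != 1)
    xl_abort("fixture peptide %s not unique in protein", peptide)
}

# deterministically pick the first sub-seed whose random sequence keeps all
# fixture peptides unique (collisions are rare but must not abort a build)
pick_protein <- function(n, seed, intervals) {
  for (k in 0:49) {
    seqs <- random_protein(n, seed + k * 7919)
    ok <- all(vapply(intervals, function(iv) {
      p <- substr(seqs, iv[1], iv[2])
      h <- gregexpr(p, seqs, fixed = TRUE)[[1]]
      length(h[h > 0]) == 1
    }, logical(1)))
    if (ok) return(seqs)
  }
  xl_abort("could not generate a sequence with unique fixture peptides")
}

scenario <- function(name, dir, crosslink_csv, fasta, structure_dir, truth,
                     seed) {
  manifest <- list(name = name, seed = seed,
                   crosslink_csv = basename(crosslink_csv),
                   fasta = basename(fasta),
                   structure_dir = basename(structure_dir), truth = truth)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(name = name, dir = dir, crosslink_csv = crosslink_csv,
                 fasta = fasta, structure_dir = structure_dir, truth = truth,
                 seed = seed), class = "xl_scenario")
}

#' Homodimer remapping scenario
#'
#' A 100-residue protein whose structure is an antiparallel helical
#' homodimer (chains A and B). Two intra-links are designed so that one is
#' satisfied within a single chain (`intra_within_range`) while the other
#' spans residues far apart along the chain but close across the dimer
#' interface, so it can only be satisfied as a homo-multimeric inter-link
#' (`out_of_range_inter_validated`). With `monomer_only = TRUE` the library
#' holds only a single chain and the second link ends `intra_out_of_range`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed controlling the random sequence.
#' @param monomer_only write a monomer instead of the dimer.
#' @return an `xl_scenario` with a `truth` data frame.
#' @export
make_homodimer_scenario <- function(dir, seed = 421, monomer_only = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sdir <- file.path(dir, "structures")
  dir.create(sdir, showWarnings = FALSE)
  seqs <- pick_protein(100, seed, list(c(26, 34), c(36, 44), c(6, 14),
                                       c(86, 94)))
  prot <- list(accession = "DIMER1", sequence = seqs)

  chA <- make_helix_chain(seqs, "A")
  flip <- diag(c(1, -1, -1))  # antiparallel copy, 10 A away in x
  chB <- make_helix_chain(seqs, "B", origin = c(10, 0, 148.5),
                          orientation = flip)
  atoms <- if (monomer_only) chA else rbind(chA, chB)
  pdb <- file.path(sdir, if (monomer_only) "mono1.pdb" else "dimer1.pdb")
  write_pdb_fixture(atoms, pdb, resolution = 2.0)

  fasta <- file.path(dir, "proteins.fasta")
  write_fasta_fixture(list(prot), fasta)

  sites <- list(link1 = c(30L, 40L), link2 = c(10L, 90L))
  rows <- lapply(names(sites), function(nm) {
    s <- sites[[nm]]
    p1 <- peptide_at(seqs, s[1]); p2 <- peptide_at(seqs, s[2])
    assert_unique_peptide(seqs, p1$peptide)
    assert_unique_peptide(seqs, p2$peptide)
    data.frame(protein1 = "DIMER1", protein2 = "DIMER1",
               peptide1 = p1$peptide, peptide2 = p2$peptide,
               pos_pep1 = p1$pos_in_peptide, pos_pep2 = p2$pos_in_peptide,
               stringsAsFactors = FALSE)
  })
  csv <- file.path(dir, "links.csv")
  write_links_fixture(do.call(rbind, rows), csv)

  truth <- data.frame(
    link = c("link1", "link2"),
    pos_a = c(30L, 10L), pos_b = c(40L, 90L),
    is_ops = c(FALSE, FALSE), self_link = c(FALSE, FALSE),
    category = c("intra_within_range",
                 if (monomer_only) "intra_out_of_range"
                 else "out_of_range_inter_validated"),
    stringsAsFactors = FALSE)
  scenario("homodimer", dir, csv, fasta, sdir, truth, seed)
}

#' Overlapping-peptide scenario
#'
#' An 80-residue protein with five intra-links whose peptides overlap by 0,
#' 1, 5 and 9 residues plus one link joining a residue to itself. The
#' structure library is empty, so OPS links stay `ops_inter` and the
#' non-overlapping link is `unmapped`.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return an `xl_scenario`.
#' @export
make_ops_scenario <- function(dir, seed = 727) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sdir <- file.path(dir, "structures")
  dir.create(sdir, showWarnings = FALSE)
  seqs <- pick_protein(80, seed, list(c(1, 9), c(20, 28), c(30, 38),
                                      c(38, 46), c(50, 58), c(54, 62),
                                      c(65, 73), c(10, 18)))
  prot <- list(accession = "OPSPROT", sequence = seqs)
  fasta <- file.path(dir, "proteins.fasta")
  write_fasta_fixture(list(prot), fasta)

  mk <- function(i1, s1, i2, s2) {
    pep1 <- substr(seqs, i1[1], i1[2]); pep2 <- substr(seqs, i2[1], i2[2])
    assert_unique_peptide(seqs, pep1); assert_unique_peptide(seqs, pep2)
    data.frame(protein1 = "OPSPROT", protein2 = "OPSPROT",
               peptide1 = pep1, peptide2 = pep2,
               pos_pep1 = s1 - i1[1] + 1L, pos_pep2 = s2 - i2[1] + 1L,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    mk(c(1L, 9L), 5L, c(20L, 28L), 24L),    # k = 0
    mk(c(30L, 38L), 34L, c(38L, 46L), 42L), # k = 1 (share residue 38)
    mk(c(50L, 58L), 54L, c(54L, 62L), 58L), # k = 5
    mk(c(65L, 73L), 69L, c(65L, 73L), 70L), # full overlap (9)
    mk(c(10L, 18L), 14L, c(10L, 18L), 14L)) # self-link
  csv <- file.path(dir, "links.csv")
  write_links_fixture(rows, csv)

  truth <- data.frame(
    link = c("k0", "k1", "k5", "full", "self"),
    is_ops = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    overlap_length = c(0L, 1L, 5L, 9L, 9L),
    self_link = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    category = c("unmapped", "ops_inter", "ops_inter", "ops_inter",
                 "ops_inter"),
    stringsAsFactors = FALSE)
  scenario("ops", dir, csv, fasta, sdir, truth, seed)
}

#' Predicted-model pLDDT scenario
#'
#' A 100-residue protein whose only available structure is a single-chain
#' predicted model with a designed low-confidence segment (pLDDT 60 on
#' residues 1--10, 90 elsewhere). One link anchors inside the low-confidence
#' segment: at the default pLDDT cutoff of 70 the trimmed model cannot map
#' it (`unmapped`); at cutoff 0 it maps with a finite in-range distance.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return an `xl_scenario`.
#' @export
make_predicted_model_scenario <- function(dir, seed = 911) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sdir <- file.path(dir, "structures")
  dir.create(sdir, showWarnings = FALSE)
  seqs <- pick_protein(100, seed, list(c(1, 9), c(16, 24)))
  prot <- list(accession = "PREDPROT", sequence = seqs)
  fasta <- file.path(dir, "proteins.fasta")
  write_fasta_fixture(list(prot), fasta)

  plddt <- c(rep(60, 10), rep(90, 90))
  ch <- make_helix_chain(seqs, "A", bfactor = plddt)
  write_pdb_fixture(ch, file.path(sdir, "model_pred1.pdb"))

  p1 <- peptide_at(seqs, 5L); p2 <- peptide_at(seqs, 20L)
  assert_unique_peptide(seqs, p1$peptide)
  assert_unique_peptide(seqs, p2$peptide)
  csv <- file.path(dir, "links.csv")
  write_links_fixture(data.frame(
    protein1 = "PREDPROT", protein2 = "PREDPROT",
    peptide1 = p1$peptide, peptide2 = p2$peptide,
    pos_pep1 = p1$pos_in_peptide, pos_pep2 = p2$pos_in_peptide,
    stringsAsFactors = FALSE), csv)

  truth <- data.frame(
    link = "lowconf", pos_a = 5L, pos_b = 20L, is_ops = FALSE,
    category = "unmapped", category_at_cutoff0 = "intra_within_range",
    trimmed_residues = 10L, stringsAsFactors = FALSE)
  scenario("predicted_model", dir, csv, fasta, sdir, truth, seed)
}
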