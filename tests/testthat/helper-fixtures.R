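# Small structure builders shared across tests. Structures are written to
# temp files and read back so tests exercise the real I/O path.

helix_structure <- function(sequence, chain_id = "A", resolution = 2.0,
                            ext = "pdb", source = NULL, ...) {
  at <- make_helix_chain(sequence, chain_id, ...)
  f <- tempfile(fileext = paste0(".", ext))
  if (ext == "pdb") write_pdb_fixture(at, f, resolution = resolution)
  else write_cif_fixture(at, f, resolution = resolution)
  read_structure(f, source = source)
}

# mutate a fraction of positions to different residues (fixed rng state
# assumed set by the caller)
mutate_sequence <- function(seqs, frac) {
  v <- strsplit(seqs, "")[[1]]
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  idx <- sample(length(v), round(frac * length(v)))
  for (i in idx) v[i] <- sample(setdiff(alpha, v[i]), 1)
  paste(v, collapse = "")
}

write_links_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

toy_protein <- function(accession, sequence) {
  list(accession = accession, sequence = sequence)
}
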