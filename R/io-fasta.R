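#' Read protein sequences from FASTA
#'
#' Parses a FASTA file into a named list of protein records. Accessions are
#' taken from the UniProt pipe convention (`>db|ACCESSION|NAME`) when present,
#' otherwise from the first whitespace-delimited token of the header.
#' Duplicate headers with identical sequences collapse silently; duplicates
#' with conflicting sequences are an error.
#'
#' @param path FASTA file path.
#' @return named list (accession -> list with `accession`, `sequence`).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P04179|SODM_HUMAN", "MLSRAVCGT", ">toy1", "ACDEFG"), f)
#' names(read_fasta(f))
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) xl_abort("FASTA file not found: %s", path)
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0) return(list())
  acc <- vapply(names(ss), parse_accession, character(1), USE.NAMES = FALSE)
  seqs <- unname(toupper(as.character(ss)))
  out <- list()
  for (i in seq_along(acc)) {
    a <- acc[i]
    if (!nzchar(seqs[i])) xl_abort("empty sequence for %s in %s", a, path)
    if (!is.null(out[[a]])) {
      if (!identical(out[[a]]$sequence, seqs[i]))
        xl_abort("conflicting sequences for accession %s in %s", a, path)
    } else {
      out[[a]] <- list(accession = a, sequence = seqs[i])
    }
  }
  out
}

parse_accession <- function(header) {
  header <- sub("^>", "", trimws(header))
  first <- strsplit(header, "[ \t]")[[1]][1]
  if (grepl("\\|", first)) {
    parts <- strsplit(first, "\\|", fixed = FALSE)[[1]]
    if (length(parts) >= 2 && nzchar(parts[2])) return(parts[2])
  }
  first
}
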