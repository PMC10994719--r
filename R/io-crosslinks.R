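#' Read a cross-link table
#'
#' Reads a CSV of identified cross-links into a raw link table. Each row is a
#' cross-linked peptide pair; each side carries a protein accession, a peptide
#' sequence, and a link-site position given within the peptide and/or within
#' the full protein (both 1-based). Rows missing both positions on a side are
#' rejected with a per-row diagnostic rather than aborting the run. Peptide
#' strings are cleaned for alignment: bracketed modification annotations and
#' lowercase modification tags are stripped, and all-lowercase peptides are
#' uppercased.
#'
#' @param path path to the CSV file.
#' @param config an [xl_config()]; `config$columns` maps the canonical fields
#'   to the file's column names and `config$delimiter` sets the separator.
#' @return a list with elements `links` (data frame of class `xl_raw_links`,
#'   one row per accepted link: `row_id`, `protein_a`, `protein_b`,
#'   `peptide_a`, `peptide_b`, `pos_pep_a`, `pos_pep_b`, `pos_prot_a`,
#'   `pos_prot_b`, `source_tag`) and `diagnostics` (data frame of rejected
#'   rows and reasons).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("protein1,protein2,peptide1,peptide2,pos_pep1,pos_pep2",
#'              "P1,P1,ACDEFK,KLMNPQ,6,1"), f)
#' read_crosslink_table(f)$links
#' @export
read_crosslink_table <- function(path, config = xl_config()) {
  if (!file.exists(path)) xl_abort("cross-link table not found: %s", path)
  df <- tryCatch(
    read.csv(path, sep = config$delimiter, stringsAsFactors = FALSE,
             check.names = FALSE),
    error = function(e) xl_abort("cannot read %s: %s", path, conditionMessage(e)))
  cols <- config$columns
  required <- unlist(cols[c("protein_a", "protein_b", "peptide_a", "peptide_b")])
  missing <- setdiff(required, names(df))
  if (length(missing))
    xl_abort("missing required column(s) %s; file has: %s",
             paste(missing, collapse = ", "), paste(names(df), collapse = ", "))

  pick <- function(field, n) {
    nm <- cols[[field]]
    if (nm %in% names(df)) df[[nm]] else rep(NA, n)
  }
  n <- nrow(df)
  out <- data.frame(
    row_id = seq_len(n),
    protein_a = as.character(pick("protein_a", n)),
    protein_b = as.character(pick("protein_b", n)),
    peptide_a = clean_peptide(as.character(pick("peptide_a", n))),
    peptide_b = clean_peptide(as.character(pick("peptide_b", n))),
    pos_pep_a = suppressWarnings(as.integer(pick("pos_pep_a", n))),
    pos_pep_b = suppressWarnings(as.integer(pick("pos_pep_b", n))),
    pos_prot_a = suppressWarnings(as.integer(pick("pos_prot_a", n))),
    pos_prot_b = suppressWarnings(as.integer(pick("pos_prot_b", n))),
    source_tag = rep(basename(path), n),
    stringsAsFactors = FALSE)

  diags <- xl_diag()
  bad_side <- function(pp, pprot, pep) {
    (is.na(pp) & is.na(pprot)) | nchar(pep) == 0 |
      (!is.na(pp) & (pp < 1 | pp > nchar(pep)))
  }
  reason <- rep(NA_character_, n)
  ba <- bad_side(out$pos_pep_a, out$pos_prot_a, out$peptide_a)
  bb <- bad_side(out$pos_pep_b, out$pos_prot_b, out$peptide_b)
  reason[ba] <- "side a: no usable position or empty/inconsistent peptide"
  reason[bb & is.na(reason)] <-
    "side b: no usable position or empty/inconsistent peptide"
  drop <- !is.na(reason)
  if (any(drop))
    diags <- rbind(diags, xl_diag(out$row_id[drop], "read", reason[drop]))
  links <- out[!drop, , drop = FALSE]
  rownames(links) <- NULL
  class(links) <- c("xl_raw_links", "data.frame")
  list(links = links, diagnostics = diags)
}

#' Clean peptide strings for alignment
#'
#' Strips bracketed modification annotations (`[...]`, `(...)`) and lowercase
#' modification tags, leaving the plain uppercase amino-acid sequence.
#' Peptides written entirely in lowercase are uppercased instead.
#' @param x character vector of peptide strings.
#' @return cleaned character vector.
#' @export
clean_peptide <- function(x) {
  x <- gsub("\\[[^]]*\\]|\\([^)]*\\)", "", x)
  all_lower <- grepl("^[a-z]+$", x)
  x[all_lower] <- toupper(x[all_lower])
  gsub("[^A-Z]", "", x)
}

#' Write the extended results table
#'
#' Writes classified links as CSV: every input column is preserved and the
#' analysis columns are appended (`link_type_original`, `link_type_final`,
#' `ops_flag`, `overlap_length`, `self_link_flag`, `structure_id`,
#' `chain_pair`, `euclidean_distance`, `topological_distance`,
#' `within_range`, `evidence_class`). Reading the file back and writing it
#' again is byte-identical.
#'
#' @param links a classified link table (see [full_classify()] /
#'   [run_pipeline()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(links, path) {
  req <- c("link_type_original", "link_type_final", "ops_flag",
           "overlap_length", "self_link_flag", "structure_id", "chain_pair",
           "euclidean_distance", "topological_distance", "within_range",
           "evidence_class")
  miss <- setdiff(req, names(links))
  if (length(miss))
    xl_abort("links not fully classified; missing: %s",
             paste(miss, collapse = ", "))
  df <- as.data.frame(links)
  # deterministic text rendering so that write -> read -> write is stable
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.numeric(v) && !is.integer(v)) {
      s <- vapply(v, function(z) {
        if (is.na(z)) NA_character_
        else if (is.infinite(z)) "Inf"
        else format(z, digits = 17, scientific = FALSE, trim = TRUE)
      }, character(1))
      df[[nm]] <- s
    } else if (is.logical(v)) {
      df[[nm]] <- ifelse(is.na(v), NA, ifelse(v, "TRUE", "FALSE"))
    }
  }
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) xl_abort("cannot write results to %s", path)
  invisible(path)
}
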