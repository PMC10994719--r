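#' Smith-Waterman local alignment
#'
#' Optimal local alignment of two amino-acid sequences under an affine gap
#' scheme (a gap of length k costs `gap_open + k * gap_extend`). Ties are
#' broken deterministically: the end cell with the highest score and, among
#' equals, the smallest `(target_end, query_end)`; the traceback prefers
#' diagonal over vertical (query-consuming) over horizontal (target-consuming)
#' moves. When no cell scores above zero the empty alignment with score 0 is
#' returned.
#'
#' @param query,target amino-acid strings (non-empty).
#' @param scheme a [scoring_scheme()].
#' @param all_placements also return every distinct maximum-score placement
#'   (needed to handle peptides that occur more than once in a protein).
#' @return an object of class `xl_alignment`: `score`, `query_interval` and
#'   `target_interval` (1-based inclusive, `NA` for the empty alignment),
#'   `identity` (identical / aligned columns), `aligned_pairs` (two-column
#'   matrix of query/target positions for match and mismatch columns) and,
#'   if requested, `placements` (list of equal-score alternatives).
#' @examples
#' smith_waterman("KLMNP", "AAKLMNPAA")
#' @export
smith_waterman <- function(query, target, scheme = scoring_scheme(),
                           all_placements = FALSE) {
  stopifnot(is.character(query), is.character(target))
  if (!nzchar(query) || !nzchar(target))
    xl_abort("smith_waterman: sequences must be non-empty")
  r <- .sw_align_cpp(query, target, scheme$match, scheme$mismatch,
                     scheme$gap_open, scheme$gap_extend, all_placements)
  as_alignment <- function(z, score) {
    np <- nrow(z$pairs)
    structure(list(
      score = score,
      query_interval = c(z$qs, z$qe),
      target_interval = c(z$ts, z$te),
      identity = if (np > 0) z$n_ident / np else 0,
      aligned_pairs = z$pairs), class = "xl_alignment")
  }
  out <- as_alignment(r, r$score)
  if (all_placements) {
    pls <- lapply(r$placements, as_alignment, score = r$score)
    keys <- vapply(pls, function(p)
      paste(p$query_interval, p$target_interval, collapse = ","), character(1))
    out$placements <- pls[!duplicated(keys)]
  }
  out
}

#' @export
print.xl_alignment <- function(x, ...) {
  if (is.na(x$query_interval[1])) {
    cat("<xl_alignment> empty (score 0)\n")
  } else {
    cat(sprintf("<xl_alignment> score %g, query [%d,%d] -> target [%d,%d], identity %.3f\n",
                x$score, x$query_interval[1], x$query_interval[2],
                x$target_interval[1], x$target_interval[2], x$identity))
  }
  invisible(x)
}

#' Map a link position from peptide to protein coordinates
#'
#' Aligns the peptide to the full protein sequence and returns the protein
#' position paired with the peptide link site. The site is unmappable when it
#' falls in a gap, or when the alignment is imperfect (below full coverage or
#' full identity of the peptide) and the link-site column itself is not an
#' identical match: the linked residue must align to an identical residue.
#'
#' @param peptide peptide string.
#' @param pos_in_peptide 1-based link site within the peptide.
#' @param protein a protein record (list with `sequence`), or a string.
#' @param scheme a [scoring_scheme()].
#' @return list with `pos_in_protein` (integer or `NA`), `alignment`
#'   (`xl_alignment`), `ambiguous` (TRUE when equal-score placements map the
#'   site to different protein positions) and `mappable`.
#' @export
map_peptide_position <- function(peptide, pos_in_peptide, protein,
                                 scheme = scoring_scheme()) {
  seqs <- if (is.list(protein)) protein$sequence else protein
  stopifnot(pos_in_peptide >= 1, pos_in_peptide <= nchar(peptide))
  al <- smith_waterman(peptide, seqs, scheme, all_placements = TRUE)
  site_of <- function(a) {
    if (is.na(a$query_interval[1]) || nrow(a$aligned_pairs) == 0)
      return(NA_integer_)
    hit <- a$aligned_pairs[, 1] == pos_in_peptide
    if (!any(hit)) return(NA_integer_)
    tp <- a$aligned_pairs[hit, 2][1]
    perfect <- a$identity == 1 &&
      nrow(a$aligned_pairs) == nchar(peptide) &&
      a$query_interval[1] == 1 && a$query_interval[2] == nchar(peptide)
    site_ident <- substr(peptide, pos_in_peptide, pos_in_peptide) ==
      substr(seqs, tp, tp)
    if (perfect || site_ident) as.integer(tp) else NA_integer_
  }
  pos <- site_of(al)
  alts <- unique(stats::na.omit(vapply(al$placements, site_of, integer(1))))
  list(pos_in_protein = pos, alignment = al,
       ambiguous = length(alts) > 1,
       mappable = !is.na(pos))
}

#' Normalize raw cross-links to full-protein coordinates
#'
#' Fills in the protein-level link position on both sides of every raw link
#' (directly given, or mapped from the peptide via [map_peptide_position()];
#' when both are available and disagree, the mapped value wins and a
#' diagnostic is recorded), assigns the link type (`intra` when both
#' accessions are equal, `inter` otherwise), and collapses exact duplicates
#' under the canonical unordered key (protein pair + protein-position pair),
#' keeping the first occurrence and accumulating multiplicity. The operation
#' is idempotent.
#'
#' @param raw raw link table from [read_crosslink_table()] (the `links`
#'   element), or an already-normalized table.
#' @param proteins named list from [read_fasta()].
#' @param scheme a [scoring_scheme()].
#' @return list with `links` (data frame of class `xl_links` adding
#'   `pos_prot_a`, `pos_prot_b`, `link_type`, `unique_key`, `multiplicity`)
#'   and `diagnostics`.
#' @export
normalize_links <- function(raw, proteins, scheme = scoring_scheme()) {
  diags <- xl_diag()
  note <- function(id, msg) diags <<- rbind(diags, xl_diag(id, "normalize", msg))
  n <- nrow(raw)
  keep <- rep(TRUE, n)
  pos_a <- rep(NA_integer_, n)
  pos_b <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    row <- raw[i, ]
    for (side in c("a", "b")) {
      prot <- proteins[[row[[paste0("protein_", side)]]]]
      if (is.null(prot)) {
        note(row$row_id, sprintf("side %s: accession %s not in FASTA", side,
                                 row[[paste0("protein_", side)]]))
        keep[i] <- FALSE
        break
      }
      given <- row[[paste0("pos_prot_", side)]]
      pep_pos <- row[[paste0("pos_pep_", side)]]
      mapped <- NA_integer_
      if (!is.na(pep_pos)) {
        m <- map_peptide_position(row[[paste0("peptide_", side)]], pep_pos,
                                  prot, scheme)
        mapped <- m$pos_in_protein
        if (m$ambiguous)
          note(row$row_id, sprintf(
            "side %s: peptide has multiple equal-scoring placements; first used",
            side))
      }
      final <- if (!is.na(mapped)) {
        if (!is.na(given) && given != mapped)
          note(row$row_id, sprintf(
            "side %s: given protein position %d disagrees with mapped %d; mapped used",
            side, given, mapped))
        mapped
      } else if (!is.na(given)) {
        given
      } else {
        note(row$row_id, sprintf("side %s: peptide unmappable and no protein position",
                                 side))
        keep[i] <- FALSE
        NA_integer_
      }
      if (!keep[i]) break
      if (!is.na(final) && final > nchar(prot$sequence)) {
        note(row$row_id, sprintf("side %s: position %d beyond protein length",
                                 side, final))
        keep[i] <- FALSE
        break
      }
      if (side == "a") pos_a[i] <- final else pos_b[i] <- final
    }
  }
  out <- raw[keep, , drop = FALSE]
  out$pos_prot_a <- pos_a[keep]
  out$pos_prot_b <- pos_b[keep]
  out$link_type <- ifelse(out$protein_a == out$protein_b, "intra", "inter")
  swap <- out$protein_a > out$protein_b |
    (out$protein_a == out$protein_b & out$pos_prot_a > out$pos_prot_b)
  key_a <- ifelse(swap, paste(out$protein_b, out$pos_prot_b),
                  paste(out$protein_a, out$pos_prot_a))
  key_b <- ifelse(swap, paste(out$protein_a, out$pos_prot_a),
                  paste(out$protein_b, out$pos_prot_b))
  out$unique_key <- paste(key_a, key_b, sep = " -- ")
  mult <- if ("multiplicity" %in% names(out)) out$multiplicity else rep(1L, nrow(out))
  tot <- tapply(mult, out$unique_key, sum)
  first <- !duplicated(out$unique_key)
  out <- out[first, , drop = FALSE]
  out$multiplicity <- as.integer(tot[out$unique_key])
  rownames(out) <- NULL
  class(out) <- c("xl_links", "data.frame")
  list(links = out, diagnostics = diags)
}
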