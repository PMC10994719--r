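#' Overlap of two residue intervals
#'
#' Number of residues shared by two 1-based inclusive intervals on the same
#' protein sequence.
#' @param interval_a,interval_b integer vectors `c(start, end)`.
#' @return non-negative integer.
#' @examples
#' compute_overlap(c(5, 12), c(10, 20)) # 3
#' @export
compute_overlap <- function(interval_a, interval_b) {
  stopifnot(length(interval_a) == 2, length(interval_b) == 2,
            interval_a[1] <= interval_a[2], interval_b[1] <= interval_b[2])
  max(0L, min(interval_a[2], interval_b[2]) -
        max(interval_a[1], interval_b[1]) + 1L)
}

#' Overlapping-peptide-sequence (OPS) analysis of one intra-link
#'
#' Aligns the two peptides of an intra-link individually against the protein
#' sequence and computes the overlap of their mapped intervals. Two peptides
#' of one cross-link cannot overlap on a single chain (unless the sequence
#' itself is duplicated), so any overlap -- even a single residue -- is
#' evidence of a homo-multimer. A link joining a residue position to itself
#' is the extreme case (self-link).
#'
#' When a peptide has several equal-scoring placements, the placement pair
#' minimizing the overlap is used (a conservative call: peptides duplicated
#' within the sequence, which can overlap in one placement but not another,
#' do not produce false homo-multimer evidence); an ambiguity flag is set.
#'
#' @param link one row of a normalized link table (`link_type == "intra"`).
#' @param protein the matching protein record.
#' @param scheme a [scoring_scheme()].
#' @return an object of class `xl_ops`: `is_ops`, `overlap_length`,
#'   `self_link`, `interval_a`, `interval_b`, `ambiguous`.
#' @export
classify_ops <- function(link, protein, scheme = scoring_scheme()) {
  if (!identical(link$link_type, "intra"))
    xl_abort("classify_ops expects an intra-link")
  placements_for <- function(pep) {
    smith_waterman(pep, protein$sequence, scheme,
                   all_placements = TRUE)$placements
  }
  pa <- placements_for(link$peptide_a)
  pb <- placements_for(link$peptide_b)
  if (length(pa) == 0 || length(pb) == 0)
    xl_abort("classify_ops: peptide does not align to protein %s",
             protein$accession)
  best <- NULL
  for (a in pa) for (b in pb) {
    ov <- compute_overlap(a$target_interval, b$target_interval)
    if (is.null(best) || ov < best$ov)
      best <- list(ov = ov, ia = a$target_interval, ib = b$target_interval)
  }
  self <- !is.na(link$pos_prot_a) && !is.na(link$pos_prot_b) &&
    link$pos_prot_a == link$pos_prot_b
  structure(list(is_ops = best$ov >= 1, overlap_length = as.integer(best$ov),
                 self_link = self, interval_a = best$ia, interval_b = best$ib,
                 ambiguous = length(pa) > 1 || length(pb) > 1),
            class = "xl_ops")
}

#' Reclassify an OPS link as a homo-multimeric inter-link
#'
#' An intra-link whose peptides overlap is reclassified as an inter-link with
#' evidence tag `"OPS"`; the original type is preserved in
#' `link_type_original`.
#'
#' @param link one-row link data frame.
#' @param ops the [classify_ops()] result for that link.
#' @return the link row with `link_type_original`, `link_type_final`,
#'   `ops_flag`, `overlap_length`, `self_link_flag` set.
#' @export
ops_reclassify <- function(link, ops) {
  link$link_type_original <- link$link_type
  link$ops_flag <- isTRUE(ops$is_ops)
  link$overlap_length <- ops$overlap_length
  link$self_link_flag <- isTRUE(ops$self_link)
  link$link_type_final <- if (isTRUE(ops$is_ops)) "inter" else link$link_type
  link$evidence_class <- if (isTRUE(ops$is_ops)) "OPS" else NA_character_
  link
}

#' @export
print.xl_ops <- function(x, ...) {
  cat(sprintf("<xl_ops> is_ops=%s overlap=%d self_link=%s [%d,%d] vs [%d,%d]\n",
              x$is_ops, x$overlap_length, x$self_link,
              x$interval_a[1], x$interval_a[2], x$interval_b[1], x$interval_b[2]))
  invisible(x)
}
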