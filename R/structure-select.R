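#' One-letter sequence of a structure chain
#'
#' Extracts the chain sequence over the observed residues in author order.
#' Non-standard residues become `X` (selenomethionine becomes `M` by
#' default); gaps in the author numbering do not insert gap characters.
#'
#' @param structure an `xl_structure`.
#' @param chain_id chain identifier.
#' @param mse_as_met map MSE to `M` (default TRUE).
#' @return list with `sequence` and `map` (data frame: `ordinal`, `resno`,
#'   `insert`, `resname`), or error for a chain with no residues.
#' @export
chain_sequence <- function(structure, chain_id, mse_as_met = TRUE) {
  res <- structure$residues[structure$residues$chain == chain_id, , drop = FALSE]
  if (nrow(res) == 0) xl_abort("chain %s has no residues", chain_id)
  aa <- suppressWarnings(bio3d::aa321(res$resname))
  aa[is.na(aa) | !aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  aa[res$resname == "MSE"] <- if (mse_as_met) "M" else "X"
  list(sequence = paste(aa, collapse = ""),
       map = data.frame(ordinal = seq_len(nrow(res)), resno = res$resno,
                        insert = res$insert, resname = res$resname,
                        stringsAsFactors = FALSE))
}

#' Score a structure chain against a protein sequence
#'
#' Locally aligns the full protein sequence against the chain sequence and
#' summarizes the match: `identity` is the fraction of identical residues
#' over aligned columns, `coverage` the fraction of the protein covered by
#' aligned columns, and `residue_map` maps protein positions to structure
#' residues (author numbering) for every aligned column.
#'
#' @param protein protein record (list with `accession`, `sequence`).
#' @param structure an `xl_structure`.
#' @param chain_id chain identifier.
#' @param scheme a [scoring_scheme()].
#' @param mse_as_met passed to [chain_sequence()].
#' @return an object of class `xl_chain_map`: `structure_id`, `chain_id`,
#'   `identity`, `coverage`, `residue_map` (data frame: `pos`, `resno`,
#'   `insert`).
#' @export
score_chain <- function(protein, structure, chain_id,
                        scheme = scoring_scheme(), mse_as_met = TRUE) {
  cs <- chain_sequence(structure, chain_id, mse_as_met)
  al <- smith_waterman(protein$sequence, cs$sequence, scheme)
  np <- nrow(al$aligned_pairs)
  rmap <- if (np > 0) {
    ord <- al$aligned_pairs[, 2]
    data.frame(pos = al$aligned_pairs[, 1],
               resno = cs$map$resno[ord], insert = cs$map$insert[ord],
               stringsAsFactors = FALSE)
  } else {
    data.frame(pos = integer(), resno = integer(), insert = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(structure_id = structure$structure_id, chain_id = chain_id,
                 identity = al$identity,
                 coverage = np / nchar(protein$sequence),
                 residue_map = rmap), class = "xl_chain_map")
}

chain_passes <- function(cm, structure, config) {
  res_ok <- structure$source == "predicted" ||
    (is.finite(structure$resolution) &&
       structure$resolution <= config$resolution_cutoff)
  cm$identity >= config$identity_cutoff &&
    cm$coverage >= config$coverage_cutoff && res_ok
}

candidate_from <- function(structure, chain_maps_by_acc) {
  best_id <- max(vapply(unlist(chain_maps_by_acc, recursive = FALSE),
                        `[[`, numeric(1), "identity"))
  best_cov <- max(vapply(unlist(chain_maps_by_acc, recursive = FALSE),
                         `[[`, numeric(1), "coverage"))
  structure(list(structure = structure, chain_maps = chain_maps_by_acc,
                 identity = best_id, coverage = best_cov,
                 resolution = structure$resolution),
            class = "xl_candidate")
}

rank_candidates <- function(cands) {
  if (length(cands) == 0) return(cands)
  idt <- vapply(cands, `[[`, numeric(1), "identity")
  cov <- vapply(cands, `[[`, numeric(1), "coverage")
  res <- vapply(cands, function(x)
    if (is.finite(x$resolution)) x$resolution else Inf, numeric(1))
  ids <- vapply(cands, function(x) x$structure$structure_id, character(1))
  cands[order(-idt, -cov, res, ids)]
}

#' Select candidate structures for one protein
#'
#' Keeps library structures with at least one chain passing the identity,
#' coverage and (for experimental structures) resolution cutoffs, ranked by
#' identity, then coverage, then resolution, then structure id. Predicted
#' models are considered only as a fallback when no experimental structure
#' passes; they are exempt from the resolution cutoff and are trimmed by
#' pLDDT before use.
#'
#' @param protein protein record.
#' @param library list of `xl_structure` (see [structure_library()]).
#' @param config an [xl_config()].
#' @param scheme a [scoring_scheme()].
#' @return ranked list of `xl_candidate` objects (possibly empty).
#' @export
select_structures <- function(protein, library, config = xl_config(),
                              scheme = scoring_scheme()) {
  score_all <- function(models) {
    out <- list()
    for (m in models) {
      if (m$source == "predicted")
        m <- trim_by_plddt(m, config$plddt_cutoff)
      cms <- list()
      for (ch in unique(m$residues$chain)) {
        cm <- score_chain(protein, m, ch, scheme, config$mse_as_met)
        if (chain_passes(cm, m, config)) cms[[length(cms) + 1L]] <- cm
      }
      if (length(cms))
        out[[length(out) + 1L]] <- candidate_from(
          m, stats::setNames(list(cms), protein$accession))
    }
    out
  }
  exper <- Filter(function(m) m$source == "experimental", library)
  cands <- score_all(exper)
  if (length(cands) == 0) {
    pred <- Filter(function(m) m$source == "predicted", library)
    cands <- score_all(pred)
  }
  rank_candidates(cands)
}

#' Trim a predicted model by pLDDT
#'
#' Removes residues whose representative-atom (alpha-carbon) pLDDT -- stored
#' in the B-factor field -- is below the cutoff. Residue numbering is
#' preserved. Raising the cutoff never adds residues.
#'
#' @param model an `xl_structure` with `source == "predicted"`.
#' @param cutoff minimum pLDDT kept.
#' @return the trimmed `xl_structure`.
#' @export
trim_by_plddt <- function(model, cutoff) {
  if (!identical(model$source, "predicted"))
    xl_abort("trim_by_plddt expects a predicted model")
  at <- model$atoms
  ca <- at[at$atom_name == "CA", , drop = FALSE]
  keyv <- paste(at$chain, at$resno, at$insert, sep = "\r")
  cakey <- paste(ca$chain, ca$resno, ca$insert, sep = "\r")
  plddt <- stats::setNames(ca$bfactor, cakey)[keyv]
  plddt[is.na(plddt)] <- 0  # residues without CA are dropped
  model$atoms <- at[plddt >= cutoff, , drop = FALSE]
  model$residues <- residue_table(model$atoms)
  model
}

#' Find complex structures covering a protein pair
#'
#' Returns ranked candidates where both accessions have at least one passing
#' chain; for a homo-multimer query (both accessions equal) a structure needs
#' at least two distinct passing chains. Only experimental structures are
#' searched (predicted monomer models cannot carry a complex interface).
#'
#' @param protein_a,protein_b protein records (may be identical).
#' @param library list of `xl_structure`.
#' @param config an [xl_config()].
#' @param scheme a [scoring_scheme()].
#' @return ranked list of `xl_candidate` objects.
#' @export
find_complex_structures <- function(protein_a, protein_b, library,
                                    config = xl_config(),
                                    scheme = scoring_scheme()) {
  homo <- identical(protein_a$accession, protein_b$accession)
  cands <- list()
  for (m in Filter(function(m) m$source == "experimental", library)) {
    maps_for <- function(protein) {
      cms <- list()
      for (ch in unique(m$residues$chain)) {
        cm <- score_chain(protein, m, ch, scheme, config$mse_as_met)
        if (chain_passes(cm, m, config)) cms[[length(cms) + 1L]] <- cm
      }
      cms
    }
    ca <- maps_for(protein_a)
    if (homo) {
      if (length(ca) >= 2)
        cands[[length(cands) + 1L]] <- candidate_from(
          m, stats::setNames(list(ca), protein_a$accession))
    } else {
      cb <- maps_for(protein_b)
      if (length(ca) >= 1 && length(cb) >= 1)
        cands[[length(cands) + 1L]] <- candidate_from(
          m, stats::setNames(list(ca, cb),
                             c(protein_a$accession, protein_b$accession)))
    }
  }
  rank_candidates(cands)
}

#' Map a protein position onto a structure residue
#'
#' Looks the position up in a chain map; positions falling in unobserved or
#' unaligned regions are unmapped.
#'
#' @param pos_in_protein 1-based protein position.
#' @param chain_map an `xl_chain_map` from [score_chain()].
#' @param protein_length protein length, for the bounds check (optional).
#' @return list with `mapped`, `resno`, `insert`, `chain_id`.
#' @export
map_link_residue <- function(pos_in_protein, chain_map,
                             protein_length = NULL) {
  if (!is.null(protein_length) && pos_in_protein > protein_length)
    xl_abort("position %d beyond protein length %d", pos_in_protein,
             protein_length)
  stopifnot(pos_in_protein >= 1)
  i <- match(pos_in_protein, chain_map$residue_map$pos)
  if (is.na(i))
    return(list(mapped = FALSE, resno = NA_integer_, insert = NA_character_,
                chain_id = chain_map$chain_id))
  list(mapped = TRUE, resno = chain_map$residue_map$resno[i],
       insert = chain_map$residue_map$insert[i], chain_id = chain_map$chain_id)
}

#' @export
print.xl_candidate <- function(x, ...) {
  cat(sprintf("<xl_candidate> %s identity %.3f coverage %.3f%s; chains: %s\n",
              x$structure$structure_id, x$identity, x$coverage,
              if (is.finite(x$resolution))
                sprintf(" resolution %.2f A", x$resolution) else "",
              paste(unlist(lapply(x$chain_maps, function(l)
                vapply(l, `[[`, character(1), "chain_id"))), collapse = ",")))
  invisible(x)
}
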