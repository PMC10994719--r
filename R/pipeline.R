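#' Run the full cross-link validation pipeline
#'
#' Executes the complete workflow on local files: read the cross-link CSV,
#' FASTA sequences and structure library; normalize link positions to
#' full-protein coordinates; run the overlapping-peptide (OPS) analysis on
#' intra-links; select structures, compute Euclidean and topological
#' distances over chain-pair assignments; and classify every link. The run
#' is deterministic given identical inputs and configuration.
#'
#' @param crosslink_csv path to the cross-link table.
#' @param fasta path to the protein FASTA.
#' @param structure_dir directory with PDB/mmCIF files (may be empty or
#'   missing for sequence-only analyses).
#' @param config an [xl_config()].
#' @param linker a [linker_spec()].
#' @param scheme a [scoring_scheme()].
#' @param output_dir when not `NULL`, write `results.csv`, `summary.json`,
#'   `diagnostics.tsv` and one PyMOL viewer script per evaluated structure
#'   into this directory.
#' @return an object of class `xl_result`: `links` (classified table),
#'   `stats` ([summarize_links()]), `diagnostics`, `assignments` (all
#'   per-assignment distance results), `config`, `linker`.
#' @examples
#' \donttest{
#' sc <- make_ops_scenario(tempfile("ops"))
#' res <- run_pipeline(sc$crosslink_csv, sc$fasta, sc$structure_dir)
#' res$stats$n_ops
#' }
#' @export
run_pipeline <- function(crosslink_csv, fasta, structure_dir = NULL,
                         config = xl_config(), linker = linker_spec(),
                         scheme = scoring_scheme(), output_dir = NULL) {
  raw <- read_crosslink_table(crosslink_csv, config)
  proteins <- read_fasta(fasta)
  library <- if (!is.null(structure_dir) && dir.exists(structure_dir))
    structure_library(structure_dir) else list()

  norm <- normalize_links(raw$links, proteins, scheme)
  links <- norm$links
  diags <- rbind(raw$diagnostics, norm$diagnostics)

  n <- nrow(links)
  links$link_type_original <- links$link_type
  links$link_type_final <- links$link_type
  links$ops_flag <- rep(FALSE, n)
  links$overlap_length <- rep(NA_integer_, n)
  links$self_link_flag <- rep(FALSE, n)
  links$structure_id <- rep(NA_character_, n)
  links$chain_pair <- rep(NA_character_, n)
  links$euclidean_distance <- rep(NA_real_, n)
  links$topological_distance <- rep(NA_real_, n)
  links$within_range <- rep(NA, n)
  links$evidence_class <- rep(NA_character_, n)
  links$category <- rep(NA_character_, n)

  cache <- new.env(parent = emptyenv())
  assignments <- list()
  for (i in seq_len(n)) {
    link <- links[i, ]
    ops <- NULL
    if (identical(link$link_type, "intra")) {
      ops <- classify_ops(link, proteins[[link$protein_a]], scheme)
      links$ops_flag[i] <- ops$is_ops
      links$overlap_length[i] <- ops$overlap_length
      links$self_link_flag[i] <- ops$self_link
      if (ops$ambiguous)
        diags <- rbind(diags, xl_diag(link$row_id, "ops",
          "ambiguous peptide placement; minimal-overlap placement used"))
      link <- ops_reclassify(link, ops)
      links$link_type_final[i] <- link$link_type_final
    }
    cls <- full_classify(link, ops, proteins, library, config, linker,
                         scheme, cache)
    links$category[i] <- cls$category
    if (!is.na(cls$structure_id)) links$structure_id[i] <- cls$structure_id
    if (!is.null(cls$best)) {
      links$chain_pair[i] <- paste0(cls$best$chain_a, ":", cls$best$chain_b)
      links$euclidean_distance[i] <- cls$best$euclidean
      links$topological_distance[i] <- cls$best$topological
      links$within_range[i] <-
        classify_distance(cls$best$topological, linker) == "within"
    }
    if (links$category[i] %in%
        c("ops_inter_validated", "out_of_range_inter_validated"))
      links$link_type_final[i] <- "inter"
    ev <- switch(links$category[i],
                 ops_inter = "OPS",
                 ops_inter_validated = "OPS + structure",
                 out_of_range_inter_validated = "out-of-range intra remapped",
                 unmapped = NA_character_,
                 "structure")
    if (isTRUE(links$ops_flag[i]) && is.na(ev)) ev <- "OPS"
    links$evidence_class[i] <- ev
    if (!is.null(cls$all_results)) {
      ar <- cls$all_results
      ar$row_id <- link$row_id
      ar$structure_id <- cls$structure_id
      assignments[[length(assignments) + 1L]] <- ar
    }
  }
  assignments <- if (length(assignments)) do.call(rbind, assignments) else NULL

  stats <- summarize_links(links)
  out <- structure(list(links = links, stats = stats, diagnostics = diags,
                        assignments = assignments, config = config,
                        linker = linker, library = library),
                   class = "xl_result")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_table(links, file.path(output_dir, "results.csv"))
    jsonlite::write_json(unclass(stats), file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    write.table(diags, file.path(output_dir, "diagnostics.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    for (sid in unique(stats::na.omit(links$structure_id))) {
      write_viewer_script(out, sid,
                          file.path(output_dir, paste0(sid, "_links.pml")))
    }
  }
  out
}

#' Summary statistics of a classified link table
#'
#' Aggregate counts of the run: totals by original type, OPS and self-link
#' counts, how many links could be mapped onto a structure, how many fell
#' within the linker range, and the reclassification tallies.
#'
#' @param links classified link table (from [run_pipeline()]).
#' @return list of class `xl_stats`; `fraction_within_range` is `NULL` when
#'   nothing was mapped.
#' @export
summarize_links <- function(links) {
  n_mapped <- sum(!is.na(links$topological_distance))
  n_within <- sum(links$within_range %in% TRUE)
  validated <- c("ops_inter_validated", "out_of_range_inter_validated")
  structure(list(
    n_links_total = nrow(links),
    n_intra = sum(links$link_type_original == "intra"),
    n_inter = sum(links$link_type_original == "inter"),
    n_ops = sum(links$ops_flag %in% TRUE),
    n_self_links = sum(links$self_link_flag %in% TRUE),
    n_mapped = n_mapped,
    n_within_range = n_within,
    fraction_within_range = if (n_mapped > 0) n_within / n_mapped else NULL,
    n_reclassified_ops = sum(links$category %in%
                               c("ops_inter", "ops_inter_validated")),
    n_reclassified_out_of_range = sum(links$category %in%
                                        "out_of_range_inter_validated"),
    n_validated_homo_multimer = sum(links$category %in% validated),
    n_unmapped = sum(links$category %in% "unmapped"),
    n_proteins = length(unique(c(links$protein_a, links$protein_b))),
    n_proteins_with_ops = length(unique(links$protein_a[links$ops_flag %in% TRUE]))),
    class = "xl_stats")
}

#' Write a PyMOL viewer script for one structure
#'
#' Generates a script that loads the structure and draws one distance object
#' per evaluated chain-pair assignment between the two anchor atoms,
#' coloring within-range and out-of-range links differently and naming each
#' object with the link id and its topological distance. Self-links are
#' marked with a sphere on the residue.
#'
#' @param result an `xl_result` from [run_pipeline()].
#' @param structure_id which evaluated structure to script.
#' @param path output `.pml` path.
#' @param within_color,out_color PyMOL color names.
#' @return `path`, invisibly.
#' @export
write_viewer_script <- function(result, structure_id, path,
                                within_color = "teal", out_color = "red") {
  m <- result$library[[structure_id]]
  if (is.null(m)) xl_abort("structure %s not in result library", structure_id)
  obj <- m$structure_id
  ln <- c(sprintf("load %s, %s", m$path, obj),
          "hide everything", sprintf("show cartoon, %s", obj),
          sprintf("color grey80, %s", obj))
  asg <- result$assignments
  asg <- asg[!is.null(asg) & asg$structure_id %in% structure_id, , drop = FALSE]
  lk <- result$links
  anchor_name <- function(chain, resno) {
    at <- m$atoms
    has_cb <- any(at$chain == chain & at$resno == resno & at$atom_name == "CB")
    if (result$config$anchor == "CB" && has_cb) "CB" else "CA"
  }
  for (i in seq_len(nrow(asg))) {
    a <- asg[i, ]
    row <- lk[lk$row_id == a$row_id, ][1, ]
    within <- is.finite(a$topological) &&
      classify_distance(a$topological, result$linker) == "within"
    degenerate <- a$chain_a == a$chain_b && a$resno_a == a$resno_b
    dlab <- if (is.finite(a$topological))
      sprintf("%.1fA", a$topological) else "unreachable"
    name <- sprintf("xl%d_%s%d_%s%d_%s", a$row_id, a$chain_a, a$resno_a,
                    a$chain_b, a$resno_b, gsub("\\.", "p", dlab))
    col <- if (within) within_color else out_color
    if (!degenerate)
      ln <- c(ln, sprintf(
        "distance %s, %s and chain %s and resi %d and name %s, %s and chain %s and resi %d and name %s",
        name, obj, a$chain_a, a$resno_a, anchor_name(a$chain_a, a$resno_a),
        obj, a$chain_b, a$resno_b, anchor_name(a$chain_b, a$resno_b)),
        sprintf("color %s, %s", col, name))
    if (isTRUE(row$self_link_flag) || degenerate) {
      # self-links carry a residue marker (the "loop" case)
      for (sel in unique(c(
        sprintf("%s and chain %s and resi %d and name %s", obj, a$chain_a,
                a$resno_a, anchor_name(a$chain_a, a$resno_a)),
        sprintf("%s and chain %s and resi %d and name %s", obj, a$chain_b,
                a$resno_b, anchor_name(a$chain_b, a$resno_b)))))
        ln <- c(ln, sprintf("show spheres, %s", sel),
                sprintf("color %s, %s", col, sel))
    }
  }
  writeLines(ln, path)
  invisible(path)
}

#' @export
print.xl_result <- function(x, ...) {
  cat("Cross-link validation result\n")
  print(x$stats)
  invisible(x)
}

#' @export
print.xl_stats <- function(x, ...) {
  cat(sprintf("  %d links (%d intra, %d inter) over %d protein(s)\n",
              x$n_links_total, x$n_intra, x$n_inter, x$n_proteins))
  cat(sprintf("  OPS: %d (self-links %d) in %d protein(s)\n", x$n_ops,
              x$n_self_links, x$n_proteins_with_ops))
  cat(sprintf("  mapped to structures: %d; within linker range: %d (%s)\n",
              x$n_mapped, x$n_within_range,
              if (is.null(x$fraction_within_range)) "-"
              else sprintf("%.1f%%", 100 * x$fraction_within_range)))
  cat(sprintf("  reclassified: %d OPS, %d out-of-range; validated homo-multimer: %d; unmapped: %d\n",
              x$n_reclassified_ops, x$n_reclassified_out_of_range,
              x$n_validated_homo_multimer, x$n_unmapped))
  invisible(x)
}

#' @export
summary.xl_result <- function(object, ...) {
  print(object$stats)
  tab <- table(object$links$category)
  cat("  categories:\n")
  for (nm in names(tab)) cat(sprintf("    %-30s %d\n", nm, tab[[nm]]))
  invisible(object$stats)
}
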