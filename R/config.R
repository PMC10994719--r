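#' Run configuration
#'
#' Assembles and validates the tunable parameters of the validation pipeline.
#' The defaults are the tool's standard operating point: structures are
#' accepted at >= 90% sequence identity and >= 50% coverage, experimental
#' structures additionally need a resolution of at most 4 Angstrom, predicted
#' models are trimmed to residues with pLDDT >= 70, and a cross-link is
#' considered satisfied when its topological distance falls within the
#' 5--35 Angstrom linker range.
#'
#' @param identity_cutoff minimum fraction of identical residues over aligned
#'   columns for a chain to count as a match (default 0.90).
#' @param coverage_cutoff minimum fraction of the protein sequence covered by
#'   the chain alignment (default 0.50).
#' @param resolution_cutoff maximum resolution in Angstrom for experimental
#'   structures (default 4). Predicted models are exempt; experimental
#'   structures without resolution metadata fail this cutoff.
#' @param plddt_cutoff minimum per-residue pLDDT retained in predicted models
#'   (default 70).
#' @param linker_min,linker_max accepted topological-distance range of the
#'   cross-linker in Angstrom (default 5--35).
#' @param grid_spacing voxel edge length in Angstrom for the occupancy grid
#'   (default 1.0).
#' @param probe_radius probe radius in Angstrom added to atomic van der Waals
#'   radii when blocking voxels (default 1.4).
#' @param clearance_radius radius in Angstrom of the free sphere carved around
#'   each link endpoint so that anchors are never sealed inside the protein
#'   volume (default 4).
#' @param grid_padding padding in Angstrom around the structure's bounding box;
#'   must leave room for detours, so it defaults to `linker_max`.
#' @param topo_cap abandon the path search beyond this length in Angstrom
#'   (default `2 * linker_max`).
#' @param anchor `"CB"` (beta-carbon, alpha-carbon for glycine) or `"CA"`.
#' @param candidate_depth how many ranked candidate structures to evaluate per
#'   link (default 1; alternates are reported, not evaluated).
#' @param mse_as_met treat selenomethionine (MSE) as methionine when deriving
#'   chain sequences (default TRUE).
#' @param columns named list mapping the canonical cross-link table fields to
#'   the column names used in the input CSV; see [read_crosslink_table()].
#' @param delimiter field separator of the cross-link CSV (default `","`).
#' @param offline_mode reserved switch confirming that only local files are
#'   used; the analysis core never touches the network (default TRUE).
#'
#' @return an object of class `xl_config` (a validated named list).
#' @examples
#' cfg <- xl_config()
#' cfg$identity_cutoff
#' @export
xl_config <- function(identity_cutoff = 0.90,
                      coverage_cutoff = 0.50,
                      resolution_cutoff = 4.0,
                      plddt_cutoff = 70,
                      linker_min = 5,
                      linker_max = 35,
                      grid_spacing = 1.0,
                      probe_radius = 1.4,
                      clearance_radius = 4.0,
                      grid_padding = linker_max,
                      topo_cap = 2 * linker_max,
                      anchor = c("CB", "CA"),
                      candidate_depth = 1L,
                      mse_as_met = TRUE,
                      columns = default_columns(),
                      delimiter = ",",
                      offline_mode = TRUE) {
  anchor <- match.arg(anchor)
  stopifnot(identity_cutoff > 0, identity_cutoff <= 1,
            coverage_cutoff > 0, coverage_cutoff <= 1,
            resolution_cutoff > 0,
            linker_min >= 0, linker_min < linker_max,
            grid_spacing > 0, probe_radius >= 0, clearance_radius >= 0,
            grid_padding >= 0, topo_cap > 0, candidate_depth >= 1)
  cols <- default_columns()
  cols[names(columns)] <- columns
  structure(list(identity_cutoff = identity_cutoff,
                 coverage_cutoff = coverage_cutoff,
                 resolution_cutoff = resolution_cutoff,
                 plddt_cutoff = plddt_cutoff,
                 linker_min = linker_min, linker_max = linker_max,
                 grid_spacing = grid_spacing, probe_radius = probe_radius,
                 clearance_radius = clearance_radius,
                 grid_padding = grid_padding, topo_cap = topo_cap,
                 anchor = anchor, candidate_depth = as.integer(candidate_depth),
                 mse_as_met = mse_as_met, columns = cols,
                 delimiter = delimiter, offline_mode = offline_mode),
            class = "xl_config")
}

#' Default cross-link CSV column schema
#'
#' Canonical field -> input column name. Override individual entries through
#' the `columns` argument of [xl_config()] when the search engine export uses
#' different headers.
#' @return named list of column names.
#' @export
default_columns <- function() {
  list(protein_a = "protein1", protein_b = "protein2",
       peptide_a = "peptide1", peptide_b = "peptide2",
       pos_pep_a = "pos_pep1", pos_pep_b = "pos_pep2",
       pos_prot_a = "pos_prot1", pos_prot_b = "pos_prot2")
}

#' Cross-linker distance specification
#'
#' The accepted topological-distance interval for a cross-linking reagent.
#' The default 5--35 Angstrom range reflects common lysine-reactive linkers
#' (e.g. DSS/BS3) including side-chain flexibility.
#'
#' @param name linker name, free text.
#' @param min_distance,max_distance accepted range in Angstrom.
#' @return an object of class `linker_spec`.
#' @examples
#' linker_spec()
#' @export
linker_spec <- function(name = "default", min_distance = 5,
                        max_distance = 35) {
  stopifnot(min_distance >= 0, min_distance < max_distance)
  structure(list(name = name, min_distance = min_distance,
                 max_distance = max_distance), class = "linker_spec")
}

#' Alignment scoring scheme
#'
#' A simple identity-dominant scheme for local alignment of peptides and
#' protein/chain sequences: matches reward +2, mismatches cost -1, and a gap
#' of length k costs `gap_open + k * gap_extend`.
#'
#' @param match,mismatch per-column substitution scores.
#' @param gap_open one-off cost of opening a gap (<= 0).
#' @param gap_extend per-column gap cost (<= 0).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -1, gap_open = -4,
                           gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

#' @export
print.xl_config <- function(x, ...) {
  cat("Cross-link validation configuration\n")
  cat(sprintf("  identity >= %.2f, coverage >= %.2f, resolution <= %.1f A\n",
              x$identity_cutoff, x$coverage_cutoff, x$resolution_cutoff))
  cat(sprintf("  pLDDT >= %g; linker range [%g, %g] A\n",
              x$plddt_cutoff, x$linker_min, x$linker_max))
  cat(sprintf("  grid: %.2f A voxels, probe %.2f A, clearance %.2f A, cap %g A\n",
              x$grid_spacing, x$probe_radius, x$clearance_radius, x$topo_cap))
  cat(sprintf("  anchor atom: %s\n", x$anchor))
  invisible(x)
}
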