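---
title: "Validating cross-links against structures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating cross-links against structures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlinkval)
```

## The problem

Cross-linking mass spectrometry (XL-MS) identifies pairs of peptides joined
by a chemical cross-linker, together with the linked residue positions. Each
cross-link is a distance restraint: the two linked residues must lie within
the span the linker can bridge. When a structure of the protein (or complex)
is available, a cross-link can be validated geometrically; links whose two
peptides come from the same sequence (*intra-links*) that fail this test are
not necessarily wrong — they may join two *copies* of the protein in a
homo-multimer.

`xlinkval` automates this assessment on local files. It produces, for every
input link, a final category, the structure and chain pair it was evaluated
on, and two distances:

* the **Euclidean distance** $d_E$, the straight line between the two anchor
  atoms (the beta-carbon; alpha-carbon for glycine), and
* the **topological distance** $d_T$, the length of the shortest spatial
  path between the anchors that does not pass through the protein volume.

A link is *within range* when $d_{\min} \le d_T \le d_{\max}$ for the
linker's accepted interval (default 5–35 Å, typical of lysine-reactive
reagents such as DSS/BS3). $d_T$ rather than $d_E$ is compared against the
range because a linker cannot thread through a folded protein.

## Pipeline

1. **Normalization.** Peptides are cleaned of modification annotations and
   aligned to their full protein sequence by Smith–Waterman local alignment,
   converting link sites to full-protein coordinates. A site only maps when
   the alignment is perfect or the link-site column itself aligns to an
   identical residue. Exact duplicates under the unordered
   (protein, position) pair key are collapsed, accumulating multiplicity.
2. **Overlapping peptide sequences (OPS).** For each intra-link the two
   peptides are aligned to the protein independently. Unless the peptide
   sequence is duplicated in the protein, two overlapping peptides cannot
   come from one chain, so an overlap of even one residue is evidence of a
   homo-multimer; a residue linked to itself is the extreme case. OPS
   intra-links are reclassified as candidate inter-links.
3. **Structure selection.** Each protein is matched against a local library
   of coordinate files by local alignment of the UniProt sequence against
   each chain sequence. Chains pass at identity ≥ 90 % and coverage ≥ 50 %;
   experimental structures additionally need resolution ≤ 4 Å. Predicted
   models (pLDDT in the B-factor field) are used only when no experimental
   structure passes, after removing residues below pLDDT 70. Complex
   searches require both proteins on one structure; homo-multimer searches
   require at least two matching chains.
4. **Distances.** Anchors are mapped through the chain alignment to author
   residue numbers. The structure is voxelized (below) and $d_T$ computed
   per chain-pair assignment; for multi-chain structures all permutations of
   the link across chains are enumerated (same-chain, cross-chain, or both,
   deduplicated by unordered residue pair) and the assignment with the
   smallest finite $d_T$ is reported (ties: smaller $d_E$, then chain pair).
5. **Reclassification.** Non-OPS intra-links in range stay
   `intra_within_range`. Out-of-range intra-links are re-evaluated
   cross-chain on homo-complex structures; success yields
   `out_of_range_inter_validated`, otherwise `intra_out_of_range`. OPS links
   follow the same remapping independently (`ops_inter`,
   `ops_inter_validated`). Inter-links evaluate on common complex structures
   (`inter_within_range` / `inter_out_of_range`); links with no usable
   structure are `unmapped`.

## The topological distance

The protein volume is discretized on a cubic voxel grid (spacing 1 Å by
default) covering the atoms' bounding box plus padding (default
$d_{\max}$, so detours have room). A voxel is blocked when its center lies
within (van der Waals radius + probe radius, default probe 1.4 Å) of any
retained atom — residue atoms plus non-water heteroatoms. A clearance
sphere (default 4 Å) around each link anchor is carved free so anchors
buried by their own side chains are never sealed in.

$d_T$ is the shortest-path length on the 26-connected graph of free voxels,
with step costs spacing·{1, √2, √3} (Dijkstra). Two refinements:

* **Line of sight.** If the straight segment between the anchors crosses no
  blocked voxel, $d_T = d_E$ exactly; the voxel search only runs for
  obstructed pairs. This removes the metric anisotropy of the discrete
  graph in free space.
* **Cap.** The search is abandoned beyond a cap (default $2 d_{\max}$).
  Because a path is never shorter than the straight line, anchor pairs with
  $d_E$ above the cap are reported unreachable without searching. An
  unreachable $d_T$ is treated as *out of range* — positive evidence
  against the evaluated interpretation, not missing data.

The path is any volume-avoiding path, not one forced to hug the protein
surface; this is an approximation of exact Euclidean
shortest-paths-with-obstacles. Discretization guarantees
$d_T \ge d_E - s\sqrt{3}$ for spacing $s$, and adding obstacles can only
increase $d_T$ (both properties are under test).

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `identity_cutoff` | 0.90 | fraction | minimum chain sequence identity over aligned columns |
| `coverage_cutoff` | 0.50 | fraction | minimum fraction of the protein covered by the chain |
| `resolution_cutoff` | 4.0 | Å | maximum resolution for experimental structures |
| `plddt_cutoff` | 70 | score | minimum per-residue confidence kept in predicted models |
| `linker_min`, `linker_max` | 5, 35 | Å | accepted topological range of the linker |
| `grid_spacing` | 1.0 | Å | voxel edge; halving it roughly ×8 the search volume |
| `probe_radius` | 1.4 | Å | water-probe inflation of atomic radii |
| `clearance_radius` | 4.0 | Å | free sphere around each anchor |
| `topo_cap` | 70 | Å | path-search abandon threshold |
| `anchor` | `"CB"` | — | anchor atom (`"CA"` optional) |

Alignment scoring is identity-dominant (+2 match, −1 mismatch, a gap of
length $k$ costs $-4 - k$): with no substitution-matrix biology, identity
fractions are directly interpretable against the cutoffs. Identity is
computed over aligned (match/mismatch) columns; coverage over the full
protein length.

## Numerical choices and degenerate inputs

* Alignment traceback ties break deterministically (diagonal over vertical
  over horizontal; end cell with highest score, then smallest
  (target end, query end)), so repeated runs are identical. When no cell
  scores positive, the empty alignment with score 0 is returned.
* A peptide occurring at several equal-scoring positions is flagged
  ambiguous. Normalization uses the first placement; the OPS call uses the
  placement pair *minimizing* overlap — the conservative choice that keeps
  duplicated peptides from generating false homo-multimer evidence.
* Candidate ranking (identity desc, coverage desc, resolution asc,
  structure id asc) is a total order, making structure choice reproducible.
  Only the top-ranked candidate is evaluated by default
  (`candidate_depth`).
* Experimental entries without resolution metadata fail the resolution
  cutoff (predicted models are exempt — pLDDT is their quality gate). This
  deliberately rejects e.g. NMR entries unless the cutoff is disabled by
  raising it.
* Alternate locations resolve to highest occupancy then first seen; only
  the first model of multi-model files is read; waters are dropped while
  other heteroatoms still block voxels; MSE counts as methionine.

## What the synthetic scenarios do and do not show

The generator builds idealized helical chains with analytically known
geometry (CA–CA ≈ 3.8 Å along the chain), so every scenario's truth is
fixed by construction and independent of the random sequence:

* `make_homodimer_scenario()` — an antiparallel helical homodimer in which
  one link is satisfiable within a chain and another only across the
  interface; exercises out-of-range detection and chain-permutation
  remapping.
* `make_ops_scenario()` — peptide pairs overlapping by 0, 1, 5 and 9
  residues plus a self-link; exercises the OPS rules at their boundary.
* `make_predicted_model_scenario()` — a designed pLDDT profile whose
  low-confidence segment carries a link anchor; exercises model trimming.

These scenarios validate the machinery: parsing, alignment, mapping,
voxelization, search and the decision cascade. They do not emulate real
side-chain packing, conformational disorder, crystallographic versus
biological assemblies, search-engine identification errors, or isoform
ambiguity — passing them shows the pipeline computes what it defines, not
that a particular biological dataset is correct. Problem sizes are kept at
desk scale throughout (proteins of 60–100 residues, grids of a few million
voxels at most, a few hundred random cases per property).

## Known limitations

* The topological distance is a voxel-graph approximation, not an exact
  polyhedral shortest path; free-space values are exact via the
  line-of-sight short-cut, obstructed values carry discretization error of
  order one voxel diagonal plus metric anisotropy of the 26-neighborhood.
* Quaternary structure is taken as deposited; no assembly inference or
  stoichiometry reasoning is attempted.
* Structure search is alignment against a user-supplied local library;
  remote retrieval is out of the analysis core by design.
* Redundancy elimination is exact unordered-key deduplication; links
  differing by one residue are kept distinct.
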