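#' Enumerate chain-pair assignments of a link on a candidate structure
#'
#' Lists the ways the two sides of a link can be placed on the candidate's
#' chains. `same_chain` yields one assignment per chain on which both
#' residues are observed; `cross_chain` yields every ordered pair of distinct
#' chains (side a on the first, side b on the second), deduplicated by the
#' unordered residue pair; `all` is their union. Assignments with either
#' residue unobserved are dropped.
#'
#' @param link one-row normalized link.
#' @param candidate an `xl_candidate` from [select_structures()] /
#'   [find_complex_structures()].
#' @param mode `"same_chain"`, `"cross_chain"` or `"all"`.
#' @return data frame with one row per assignment: `chain_a`, `chain_b`,
#'   `resno_a`, `insert_a`, `resno_b`, `insert_b`.
#' @export
enumerate_assignments <- function(link, candidate,
                                  mode = c("same_chain", "cross_chain", "all")) {
  mode <- match.arg(mode)
  maps_a <- candidate$chain_maps[[link$protein_a]]
  maps_b <- candidate$chain_maps[[link$protein_b]]
  if (is.null(maps_a) || is.null(maps_b))
    xl_abort("candidate %s has no chain maps for the link's proteins",
             candidate$structure$structure_id)
  empty <- data.frame(chain_a = character(), chain_b = character(),
                      resno_a = integer(), insert_a = character(),
                      resno_b = integer(), insert_b = character(),
                      stringsAsFactors = FALSE)
  rows <- list()
  add <- function(ma, mb) {
    ra <- map_link_residue(link$pos_prot_a, ma)
    rb <- map_link_residue(link$pos_prot_b, mb)
    if (!ra$mapped || !rb$mapped) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      chain_a = ma$chain_id, chain_b = mb$chain_id,
      resno_a = ra$resno, insert_a = ra$insert,
      resno_b = rb$resno, insert_b = rb$insert, stringsAsFactors = FALSE)
  }
  if (mode %in% c("same_chain", "all"))
    for (ma in maps_a) for (mb in maps_b)
      if (ma$chain_id == mb$chain_id) add(ma, mb)
  if (mode %in% c("cross_chain", "all"))
    for (ma in maps_a) for (mb in maps_b)
      if (ma$chain_id != mb$chain_id) add(ma, mb)
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  # deduplicate by unordered residue pair
  e1 <- paste(out$chain_a, out$resno_a, out$insert_a)
  e2 <- paste(out$chain_b, out$resno_b, out$insert_b)
  key <- ifelse(e1 <= e2, paste(e1, e2, sep = " | "), paste(e2, e1, sep = " | "))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate a link's distances over its chain-pair assignments
#'
#' Computes the Euclidean and topological distance for every assignment and
#' selects the best one: the minimum finite topological distance, ties broken
#' by the smaller Euclidean distance, then by lexicographic chain pair. When
#' every assignment is unreachable, the assignment with the minimal Euclidean
#' distance is reported with an infinite topological distance.
#'
#' @param link one-row normalized link (used for labels only).
#' @param assignments data frame from [enumerate_assignments()].
#' @param structure the candidate's `xl_structure`.
#' @param config an [xl_config()].
#' @param base_grid optional pre-built occupancy grid for this structure
#'   without clearance carve-outs (a performance cache); when supplied,
#'   endpoint clearance is carved per assignment on a copy.
#' @return list with `best` (one-row data frame: `chain_a`, `chain_b`,
#'   `euclidean`, `topological`, `capped`) and `results` (all assignments).
#' @export
evaluate_link <- function(link, assignments, structure, config = xl_config(),
                          base_grid = NULL) {
  stopifnot(nrow(assignments) >= 1)
  res <- assignments
  res$euclidean <- NA_real_
  res$topological <- NA_real_
  res$capped <- FALSE
  for (i in seq_len(nrow(assignments))) {
    asg <- assignments[i, ]
    aa <- anchor_atom(structure, asg$chain_a, asg$resno_a, asg$insert_a,
                      config$anchor)
    ab <- anchor_atom(structure, asg$chain_b, asg$resno_b, asg$insert_b,
                      config$anchor)
    res$euclidean[i] <- euclidean_distance(aa, ab)
    if (res$euclidean[i] > config$topo_cap) {
      # the topological path cannot be shorter than the straight line
      res$topological[i] <- Inf
      res$capped[i] <- TRUE
      next
    }
    grid <- if (is.null(base_grid))
      build_occupancy_grid(structure, list(aa, ab), config)
    else
      carve_clearance(base_grid, list(aa, ab), config$clearance_radius)
    td <- topological_distance(grid, aa, ab, cap = config$topo_cap)
    res$topological[i] <- td$distance
    res$capped[i] <- td$capped
  }
  fin <- is.finite(res$topological)
  ord <- if (any(fin)) {
    order(!fin, res$topological, res$euclidean, res$chain_a, res$chain_b)
  } else {
    order(res$euclidean, res$chain_a, res$chain_b)
  }
  list(best = res[ord[1], , drop = FALSE], results = res)
}

# carve clearance spheres around endpoints on a copy of a cached base grid
carve_clearance <- function(grid, endpoints, clearance) {
  pts <- do.call(rbind, lapply(endpoints, function(e)
    if (is.list(e)) e$xyz else e))
  g <- grid
  carve <- carve_mask(grid, pts, clearance)
  g$blocked <- grid$blocked & !carve
  g
}

carve_mask <- function(grid, pts, clearance) {
  mask <- array(FALSE, dim = grid$dim)
  ax <- grid$origin[1] + (seq_len(grid$dim[1]) - 1) * grid$spacing
  ay <- grid$origin[2] + (seq_len(grid$dim[2]) - 1) * grid$spacing
  az <- grid$origin[3] + (seq_len(grid$dim[3]) - 1) * grid$spacing
  for (p in seq_len(nrow(pts))) {
    ix <- which(abs(ax - pts[p, 1]) <= clearance)
    iy <- which(abs(ay - pts[p, 2]) <= clearance)
    iz <- which(abs(az - pts[p, 3]) <= clearance)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ax[ix] - pts[p, 1])^2
    dy2 <- (ay[iy] - pts[p, 2])^2
    dz2 <- (az[iz] - pts[p, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    mask[ix, iy, iz] <- mask[ix, iy, iz] | (d2 <= clearance^2)
  }
  mask
}

#' Classify a distance against the linker range
#'
#' @param topological topological distance in Angstrom (may be `Inf`).
#' @param linker a [linker_spec()].
#' @return `"within"` or `"out_of_range"`; unreachable counts as out of
#'   range (positive evidence against the evaluated interpretation).
#' @examples
#' classify_distance(20, linker_spec()) # "within"
#' classify_distance(4, linker_spec())  # "out_of_range" (below minimum)
#' @export
classify_distance <- function(topological, linker = linker_spec()) {
  if (is.list(topological)) topological <- topological$distance
  if (is.finite(topological) && topological >= linker$min_distance &&
      topological <= linker$max_distance) "within" else "out_of_range"
}

#' Full decision cascade for one link
#'
#' Applies the complete classification logic:
#' 1. OPS intra-links are reclassified as inter-links and evaluated
#'    cross-chain on homo-complex candidates; a within-range distance
#'    upgrades them to `ops_inter_validated`, otherwise they stay
#'    `ops_inter`.
#' 2. Non-OPS intra-links are evaluated same-chain on the best candidate
#'    (experimental, else pLDDT-trimmed predicted model). Within range keeps
#'    `intra_within_range`; out of range triggers a cross-chain evaluation on
#'    homo-complex candidates: within range gives
#'    `out_of_range_inter_validated`, otherwise `intra_out_of_range`.
#' 3. Inter-links are evaluated on common complex structures:
#'    `inter_within_range` / `inter_out_of_range`.
#' 4. Links with no usable structure anywhere are `unmapped` (the OPS flag is
#'    still reported).
#'
#' @param link one-row normalized link.
#' @param ops [classify_ops()] result for intra-links, or `NULL`.
#' @param proteins named list from [read_fasta()].
#' @param library list of `xl_structure`.
#' @param config an [xl_config()].
#' @param linker a [linker_spec()].
#' @param scheme a [scoring_scheme()].
#' @param cache optional environment reusing candidate selections and grids
#'   across links.
#' @return list with `category`, `best` (one-row distance data frame or
#'   `NULL`), `structure_id`, `all_results`, `evidence`.
#' @export
full_classify <- function(link, ops, proteins, library,
                          config = xl_config(), linker = linker_spec(),
                          scheme = scoring_scheme(), cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  prot_a <- proteins[[link$protein_a]]
  prot_b <- proteins[[link$protein_b]]

  memo <- function(key, fn) {
    k <- paste0("k:", key)
    if (is.null(cache[[k]])) cache[[k]] <- list(value = fn())
    cache[[k]]$value
  }
  mono_cands <- function(p)
    memo(paste("mono", p$accession),
         function() select_structures(p, library, config, scheme))
  homo_cands <- function(p)
    memo(paste("homo", p$accession),
         function() find_complex_structures(p, p, library, config, scheme))
  pair_cands <- function(pa, pb)
    memo(paste("pair", pa$accession, pb$accession),
         function() find_complex_structures(pa, pb, library, config, scheme))
  grid_for <- function(structure)
    memo(paste("grid", structure$structure_id, structure$source),
         function() build_occupancy_grid(structure, list(), config))

  evaluate_on <- function(cands, mode) {
    depth <- min(config$candidate_depth, length(cands))
    for (d in seq_len(depth)) {
      cand <- cands[[d]]
      asg <- enumerate_assignments(link, cand, mode)
      if (nrow(asg) == 0) next
      ev <- evaluate_link(link, asg, cand$structure, config,
                          base_grid = grid_for(cand$structure))
      return(list(cand = cand, ev = ev))
    }
    NULL
  }

  done <- function(category, hit = NULL, evidence = NA_character_) {
    list(category = category,
         best = if (is.null(hit)) NULL else hit$ev$best,
         structure_id = if (is.null(hit)) NA_character_ else
           hit$cand$structure$structure_id,
         all_results = if (is.null(hit)) NULL else hit$ev$results,
         evidence = evidence)
  }

  if (identical(link$link_type, "intra")) {
    is_ops <- !is.null(ops) && isTRUE(ops$is_ops)
    if (is_ops) {
      hit <- evaluate_on(homo_cands(prot_a), "cross_chain")
      if (is.null(hit))
        return(done("ops_inter", evidence = "OPS"))
      verdict <- classify_distance(hit$ev$best$topological, linker)
      if (verdict == "within")
        return(done("ops_inter_validated", hit, "OPS + structure"))
      return(done("ops_inter", hit, "OPS"))
    }
    hit <- evaluate_on(mono_cands(prot_a), "same_chain")
    if (is.null(hit)) return(done("unmapped"))
    verdict <- classify_distance(hit$ev$best$topological, linker)
    if (verdict == "within")
      return(done("intra_within_range", hit, "structure"))
    cross <- evaluate_on(homo_cands(prot_a), "cross_chain")
    if (!is.null(cross) &&
        classify_distance(cross$ev$best$topological, linker) == "within")
      return(done("out_of_range_inter_validated", cross,
                  "out-of-range intra remapped"))
    return(done("intra_out_of_range", hit, "structure"))
  }

  hit <- evaluate_on(pair_cands(prot_a, prot_b), "cross_chain")
  if (is.null(hit)) return(done("unmapped"))
  verdict <- classify_distance(hit$ev$best$topological, linker)
  done(if (verdict == "within") "inter_within_range" else "inter_out_of_range",
       hit, "structure")
}
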