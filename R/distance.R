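# van der Waals radii (Angstrom) by element; the default covers carbon-like
# atoms of unknown element.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               FE = 1.60, ZN = 1.39, MG = 1.73, CA = 2.31, MN = 1.60,
               CU = 1.40, "NA" = 2.27, K = 2.75)
VDW_DEFAULT <- 1.70

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

#' Anchor atom of a linked residue
#'
#' The atom representing a residue for cross-link distance purposes: the
#' beta-carbon when present, the alpha-carbon for glycine or when the
#' beta-carbon is missing (or when `anchor = "CA"`); an error when neither
#' exists.
#'
#' @param structure an `xl_structure`.
#' @param chain_id chain identifier.
#' @param resno author residue number.
#' @param insert insertion code (default empty).
#' @param anchor `"CB"` or `"CA"`.
#' @return list with `chain_id`, `resno`, `insert`, `atom_name`, `xyz`.
#' @export
anchor_atom <- function(structure, chain_id, resno, insert = "",
                        anchor = c("CB", "CA")) {
  anchor <- match.arg(anchor)
  at <- structure$atoms
  sel <- at$chain == chain_id & at$resno == resno & at$insert == insert
  if (!any(sel)) xl_abort("residue %s/%s%s not in structure %s", chain_id,
                          resno, insert, structure$structure_id)
  res <- at[sel, , drop = FALSE]
  nm <- if (anchor == "CB" && "CB" %in% res$atom_name) "CB"
        else if ("CA" %in% res$atom_name) "CA"
        else xl_abort("residue %s/%s has neither CB nor CA", chain_id, resno)
  a <- res[res$atom_name == nm, , drop = FALSE][1, ]
  list(chain_id = chain_id, resno = resno, insert = insert, atom_name = nm,
       xyz = c(a$x, a$y, a$z))
}

#' Euclidean distance between two anchor atoms
#' @param a,b anchor atoms from [anchor_atom()], or bare xyz vectors.
#' @return distance in Angstrom.
#' @export
euclidean_distance <- function(a, b) {
  pa <- if (is.list(a)) a$xyz else a
  pb <- if (is.list(b)) b$xyz else b
  sqrt(sum((pa - pb)^2))
}

#' Build a voxel occupancy grid around a structure
#'
#' Discretizes space around the structure's atoms (residue atoms plus
#' non-water heteroatoms) into cubic voxels. A voxel is blocked when its
#' center lies within (van der Waals radius + probe radius) of any retained
#' atom, except inside clearance spheres carved around the link endpoints so
#' that anchors are never sealed inside the molecular volume. The grid covers
#' the atoms' bounding box plus padding on every side.
#'
#' @param structure an `xl_structure` (already pLDDT-trimmed if predicted).
#' @param endpoints list of anchor atoms (or xyz vectors) around which
#'   clearance spheres are carved; may be empty.
#' @param config an [xl_config()] supplying `grid_spacing`, `probe_radius`,
#'   `clearance_radius` and `grid_padding`.
#' @return an object of class `xl_grid`: `origin`, `spacing`, `dim`,
#'   `blocked` (logical array).
#' @export
build_occupancy_grid <- function(structure, endpoints = list(),
                                 config = xl_config()) {
  at <- rbind(structure$atoms[, c("x", "y", "z", "element")],
              structure$het_atoms[, c("x", "y", "z", "element")])
  coords <- as.matrix(at[, c("x", "y", "z")])
  pts <- do.call(rbind, lapply(endpoints, function(e)
    if (is.list(e)) e$xyz else e))
  if (is.null(pts)) pts <- matrix(numeric(), 0, 3)
  lo <- apply(rbind(coords, pts), 2, min) - config$grid_padding
  hi <- apply(rbind(coords, pts), 2, max) + config$grid_padding
  make_grid(lo, hi, config$grid_spacing, coords,
            vdw_radius(at$element) + config$probe_radius, pts,
            config$clearance_radius)
}

make_grid <- function(lo, hi, spacing, atom_xyz, radii, clear_pts,
                      clearance) {
  dim <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  blocked <- .grid_block_cpp(as.numeric(lo), spacing, dim,
                             as.matrix(atom_xyz), as.numeric(radii),
                             as.matrix(clear_pts), clearance)
  structure(list(origin = as.numeric(lo), spacing = spacing, dim = dim,
                 blocked = array(blocked, dim = dim)), class = "xl_grid")
}

#' Construct a grid directly from a blocked-voxel array
#'
#' Low-level constructor used for testing and for synthetic obstacle fields.
#' @param blocked 3-d logical array.
#' @param origin xyz of the voxel `[1,1,1]` center.
#' @param spacing voxel edge length in Angstrom.
#' @return an `xl_grid`.
#' @export
as_grid <- function(blocked, origin = c(0, 0, 0), spacing = 1) {
  stopifnot(is.array(blocked), length(dim(blocked)) == 3)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dim = dim(blocked), blocked = blocked), class = "xl_grid")
}

grid_voxel <- function(grid, xyz) {
  v <- as.integer(floor((xyz - grid$origin) / grid$spacing + 0.5))
  if (any(v < 0) || any(v >= grid$dim))
    xl_abort("point (%.1f, %.1f, %.1f) outside grid", xyz[1], xyz[2], xyz[3])
  v  # 0-based
}

#' Topological (volume-avoiding) distance between two anchors
#'
#' Length of the shortest path between the two anchor points that does not
#' pass through blocked voxels, measured on the 26-connected voxel graph with
#' step costs `spacing * {1, sqrt(2), sqrt(3)}` (Dijkstra search). When the
#' straight segment between the anchors touches no blocked voxel the
#' Euclidean distance is returned directly (`line_of_sight` short-cut). The
#' search is abandoned beyond `cap`; since the path length is bounded below
#' by the Euclidean distance, anchor pairs further apart than `cap` in a
#' straight line are reported capped without searching.
#'
#' @param grid an `xl_grid`.
#' @param a,b anchor atoms (or xyz vectors) inside the grid.
#' @param cap abandon the search beyond this length in Angstrom.
#' @param line_of_sight enable the straight-line short-cut (default TRUE).
#' @return list with `distance` (Angstrom; `Inf` when unreachable within the
#'   cap) and `capped` (TRUE when the search was cut off by `cap` rather than
#'   exhausting the reachable region).
#' @export
topological_distance <- function(grid, a, b, cap = 70, line_of_sight = TRUE) {
  pa <- if (is.list(a)) a$xyz else a
  pb <- if (is.list(b)) b$xyz else b
  va <- grid_voxel(grid, pa)
  vb <- grid_voxel(grid, pb)
  eu <- euclidean_distance(pa, pb)
  if (line_of_sight &&
      .segment_free_cpp(grid$blocked, grid$origin, grid$spacing, grid$dim,
                        as.numeric(pa), as.numeric(pb)))
    return(list(distance = eu, capped = FALSE))
  if (eu > cap) return(list(distance = Inf, capped = TRUE))
  r <- .grid_dijkstra_cpp(grid$blocked, grid$dim, va, vb, grid$spacing, cap)
  list(distance = r[1], capped = r[2] > 0)
}

#' @export
print.xl_grid <- function(x, ...) {
  cat(sprintf("<xl_grid> %d x %d x %d voxels at %.2f A (%.0f%% blocked)\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing,
              100 * mean(x$blocked)))
  invisible(x)
}
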