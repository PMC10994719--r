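#' Read a protein structure (PDB or mmCIF)
#'
#' Parses a coordinate file into a structure model. Only the first model of
#' multi-model (e.g. NMR-style) files is kept. Waters are discarded; other
#' heteroatoms are excluded from the residue list but retained as occupied
#' volume for the topological distance computation. Selenomethionine (MSE) is
#' kept as a regular residue. Alternate locations are resolved to the highest
#' occupancy, first seen. Resolution is read from the header when present.
#' For predicted models the B-factor column is interpreted as per-residue
#' pLDDT (0--100).
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`, `.mmcif`) file.
#' @param source `"experimental"` or `"predicted"`; when `NULL`, files whose
#'   name starts with `AF-`/`AF_` or contains `predicted` or `model` are
#'   taken as predicted models.
#' @param structure_id identifier; defaults to the file name without
#'   extension.
#' @return an object of class `xl_structure`: list with `structure_id`,
#'   `source`, `resolution` (Angstrom or `NA`), `path`, `atoms` (residue
#'   atoms), `het_atoms` (non-water heteroatoms kept as occupied volume) and
#'   `residues` (one row per residue: `chain`, `resno`, `insert`, `resname`).
#' @export
read_structure <- function(path, source = NULL, structure_id = NULL) {
  if (!file.exists(path)) xl_abort("structure file not found: %s", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(
      if (is_cif) bio3d::read.cif(path, rm.alt = FALSE)
      else bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE)),
    error = function(e) xl_abort("cannot parse %s: %s", path, conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) xl_abort("no coordinates in %s", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  if (anyNA(at$x) || anyNA(at$y) || anyNA(at$z))
    xl_abort("non-finite coordinates in %s", path)

  # resolve altlocs: highest occupancy, then first seen
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -at$o)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "\r"),
                       unique(paste(at$chain, at$resno, at$insert,
                                    sep = "\r")))), , drop = FALSE]

  water <- at$resid %in% c("HOH", "WAT", "DOD")
  at <- at[!water, , drop = FALSE]
  is_res <- at$type == "ATOM" | at$resid == "MSE"
  res_atoms <- at[is_res, , drop = FALSE]
  het_atoms <- at[!is_res, , drop = FALSE]
  if (nrow(res_atoms) == 0) xl_abort("no protein chains in %s", path)

  if (is.null(structure_id))
    structure_id <- tools::file_path_sans_ext(basename(path))
  if (is.null(source)) {
    source <- if (grepl("^AF[-_]|predicted|model", basename(path),
                        ignore.case = TRUE)) "predicted" else "experimental"
  }
  source <- match.arg(source, c("experimental", "predicted"))
  if (source == "predicted" &&
      (min(res_atoms$b) < 0 || max(res_atoms$b) > 100))
    xl_abort("predicted model %s has B-factor/pLDDT outside [0, 100]", path)

  resolution <- parse_resolution(path, is_cif)
  if (source == "predicted") resolution <- NA_real_

  m <- structure(list(structure_id = structure_id, source = source,
                      resolution = resolution, path = normalizePath(path),
                      atoms = tidy_atoms(res_atoms),
                      het_atoms = tidy_atoms(het_atoms)),
                 class = "xl_structure")
  m$residues <- residue_table(m$atoms)
  dup <- duplicated(paste(m$residues$chain, m$residues$resno,
                          m$residues$insert, sep = "\r"))
  if (any(dup)) xl_abort("duplicate residue identifiers in %s", path)
  m
}

tidy_atoms <- function(at) {
  if (nrow(at) == 0)
    return(data.frame(chain = character(), resno = integer(),
                      insert = character(), resname = character(),
                      atom_name = character(), element = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      bfactor = numeric(), stringsAsFactors = FALSE))
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  data.frame(chain = as.character(at$chain), resno = as.integer(at$resno),
             insert = as.character(at$insert),
             resname = as.character(at$resid),
             atom_name = trimws(as.character(at$elety)), element = elem,
             x = at$x, y = at$y, z = at$z, bfactor = at$b,
             stringsAsFactors = FALSE)
}

residue_table <- function(atoms) {
  k <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  first <- !duplicated(k)
  data.frame(chain = atoms$chain[first], resno = atoms$resno[first],
             insert = atoms$insert[first], resname = atoms$resname[first],
             stringsAsFactors = FALSE)
}

parse_resolution <- function(path, is_cif) {
  ln <- tryCatch(readLines(path, warn = FALSE), error = function(e) character())
  num <- function(x) suppressWarnings(as.numeric(x))
  if (is_cif) {
    for (tag in c("_refine\\.ls_d_res_high", "_reflns\\.d_resolution_high",
                  "_em_3d_reconstruction\\.resolution")) {
      hit <- grep(paste0("^", tag, "[ \t]"), ln, value = TRUE)
      if (length(hit)) {
        v <- num(strsplit(trimws(hit[1]), "[ \t]+")[[1]][2])
        if (is.finite(v)) return(v)
      }
    }
  } else {
    hit <- grep("^REMARK   2 RESOLUTION\\.", ln, value = TRUE)
    if (length(hit)) {
      v <- num(sub("^REMARK   2 RESOLUTION\\.[ \t]*([0-9.]+).*$", "\\1", hit[1]))
      if (is.finite(v)) return(v)
    }
  }
  NA_real_
}

#' Load a local structure library
#'
#' Reads every PDB/mmCIF file in a directory into structure models. An
#' optional tab-separated index (`structure_id`, `path`, `resolution`, and
#' optionally `source`) overrides per-file metadata and restricts the library
#' to the listed files.
#'
#' @param dir directory containing structure files.
#' @param index optional path to the index TSV.
#' @return list of `xl_structure` objects, named by `structure_id`.
#' @export
structure_library <- function(dir, index = NULL) {
  if (!is.null(index)) {
    idx <- read.delim(index, stringsAsFactors = FALSE)
    stopifnot(all(c("structure_id", "path") %in% names(idx)))
    models <- lapply(seq_len(nrow(idx)), function(i) {
      p <- idx$path[i]
      if (!file.exists(p)) p <- file.path(dir, idx$path[i])
      src <- if ("source" %in% names(idx)) idx$source[i] else NULL
      m <- read_structure(p, source = src, structure_id = idx$structure_id[i])
      if ("resolution" %in% names(idx) && is.finite(idx$resolution[i]) &&
          m$source == "experimental")
        m$resolution <- idx$resolution[i]
      m
    })
  } else {
    files <- list.files(dir, pattern = "\\.(pdb|ent|cif|mmcif)$",
                        full.names = TRUE, ignore.case = TRUE)
    models <- lapply(sort(files), read_structure)
  }
  stats::setNames(models, vapply(models, `[[`, character(1), "structure_id"))
}

#' @export
print.xl_structure <- function(x, ...) {
  cat(sprintf("<xl_structure> %s (%s)%s\n", x$structure_id, x$source,
              if (is.finite(x$resolution))
                sprintf(", %.2f A", x$resolution) else ""))
  ch <- unique(x$residues$chain)
  cat(sprintf("  %d chain(s) [%s], %d residues, %d atoms\n", length(ch),
              paste(ch, collapse = ","), nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}
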