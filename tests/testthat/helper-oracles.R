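# Independent oracles used to check the implementation.

# Exhaustive local-alignment score by enumeration of alignment paths.
# Every prefix of an optimal local alignment scores > 0 (otherwise dropping
# the prefix does at least as well), which makes the enumeration tractable
# for short sequences. Gap model: a gap of length k costs go + k * ge.
sw_enum_score <- function(q, t, match = 2, mismatch = -1, go = -4, ge = -1) {
  qv <- strsplit(q, "")[[1]]
  tv <- strsplit(t, "")[[1]]
  nq <- length(qv); nt <- length(tv)
  best <- 0
  rec <- function(i, j, score, state) {
    if (score > best) best <<- score
    if (i > nq || j > nt) return(invisible())
    if (score + match * min(nq - i + 1, nt - j + 1) <= best)
      return(invisible())
    s <- score + (if (qv[i] == tv[j]) match else mismatch)
    if (s > 0) rec(i + 1, j + 1, s, "M")
    su <- score + ge + (if (state == "U") 0 else go)
    if (su > 0) rec(i + 1, j, su, "U")
    sl <- score + ge + (if (state == "L") 0 else go)
    if (sl > 0) rec(i, j + 1, sl, "L")
    invisible()
  }
  for (i in seq_len(nq)) for (j in seq_len(nt))
    if (qv[i] == tv[j]) rec(i + 1, j + 1, match, "M")
  best
}

random_peptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Textbook Dijkstra on the 26-connected free-voxel graph, via igraph.
# blocked: 3-d logical array; va, vb: 1-based voxel index triples.
grid_oracle_distance <- function(blocked, va, vb, spacing = 1) {
  d <- dim(blocked)
  L <- array(seq_along(blocked), d)
  free <- !blocked
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[offs$di > 0 | (offs$di == 0 & (offs$dj > 0 |
           (offs$dj == 0 & offs$dk > 0))), ]
  from <- integer(); to <- integer(); w <- numeric()
  for (r in seq_len(nrow(offs))) {
    di <- offs$di[r]; dj <- offs$dj[r]; dk <- offs$dk[r]
    xr <- max(1, 1 - di):(d[1] - max(0, di))
    yr <- max(1, 1 - dj):(d[2] - max(0, dj))
    zr <- max(1, 1 - dk):(d[3] - max(0, dk))
    ok <- free[xr, yr, zr, drop = FALSE] &
      free[xr + di, yr + dj, zr + dk, drop = FALSE]
    if (!any(ok)) next
    from <- c(from, L[xr, yr, zr, drop = FALSE][ok])
    to <- c(to, L[xr + di, yr + dj, zr + dk, drop = FALSE][ok])
    w <- c(w, rep(spacing * sqrt(di^2 + dj^2 + dk^2), sum(ok)))
  }
  g <- igraph::make_empty_graph(n = prod(d), directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to), weight = w)
  ia <- L[va[1], va[2], va[3]]
  ib <- L[vb[1], vb[2], vb[3]]
  as.numeric(igraph::distances(g, v = ia, to = ib,
                               weights = igraph::E(g)$weight))
}

# voxel triple (1-based) of a point in an as_grid() grid
voxel_of <- function(grid, xyz) {
  as.integer(floor((xyz - grid$origin) / grid$spacing + 0.5)) + 1L
}

# a random obstacle field with guaranteed-free endpoint voxels
random_grid_case <- function(d = c(12, 12, 12), p_block = 0.25) {
  blocked <- array(stats::runif(prod(d)) < p_block, dim = d)
  repeat {
    va <- sapply(d, function(n) sample(n, 1))
    vb <- sapply(d, function(n) sample(n, 1))
    if (!all(va == vb)) break
  }
  blocked[va[1], va[2], va[3]] <- FALSE
  blocked[vb[1], vb[2], vb[3]] <- FALSE
  list(blocked = blocked, va = va, vb = vb)
}
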