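# Internal mask utilities shared by the phantom and the segmentation cascade.
# Masks are logical 3D arrays; connectivity is 8 in-plane and 26 in 3D.

# Run code with a temporary RNG state so callers' streams are untouched.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

as3d <- function(mask) {
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  mask
}

neighborOffsets <- function(dims) {
  dz <- if (dims[3] > 1L) -1:1 else 0L
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = dz)
  off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), , drop = FALSE]
}

# Linear indices of in-bounds neighbors for each of a set of voxel positions.
shiftIndex <- function(pos, off, dims) {
  p <- cbind(pos[, 1] + off[1], pos[, 2] + off[2], pos[, 3] + off[3])
  ok <- p[, 1] >= 1 & p[, 1] <= dims[1] &
        p[, 2] >= 1 & p[, 2] <= dims[2] &
        p[, 3] >= 1 & p[, 3] <= dims[3]
  lin <- rep(NA_integer_, nrow(p))
  lin[ok] <- p[ok, 1] + (p[ok, 2] - 1L) * dims[1] +
    (p[ok, 3] - 1L) * dims[1] * dims[2]
  lin
}

# Connected-component labelling of a logical mask via an adjacency graph.
# Returns an integer array: 0 outside the mask, component id inside.
connectedComponents <- function(mask) {
  mask <- as3d(mask)
  dims <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dims)
  if (!length(idx)) return(lab)
  pos <- arrayInd(idx, dims)
  inMask <- integer(prod(dims))
  inMask[idx] <- seq_along(idx)   # voxel -> vertex id
  off <- neighborOffsets(dims)
  half <- off[off$dx + 3 * off$dy + 9 * off$dz > 0, , drop = FALSE]
  edges <- vector("list", nrow(half))
  for (i in seq_len(nrow(half))) {
    nb <- shiftIndex(pos, as.numeric(half[i, ]), dims)
    ok <- !is.na(nb)
    ok[ok] <- inMask[nb[ok]] > 0L
    if (any(ok))
      edges[[i]] <- cbind(seq_along(idx)[ok], inMask[nb[ok]])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(em) && nrow(em))
    g <- igraph::add_edges(g, t(em))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# TRUE where a voxel (not in `mask`) touches `mask` under 8/26-connectivity,
# computed by shifting the mask one voxel in every neighbour direction.
neighborAny <- function(mask) {
  mask <- as3d(mask)
  dims <- dim(mask)
  out <- array(FALSE, dims)
  off <- neighborOffsets(dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  for (i in seq_len(nrow(off))) {
    dx <- off$dx[i]; dy <- off$dy[i]; dz <- off$dz[i]
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    zs <- max(1, 1 + dz):min(nz, nz + dz)
    out[xs, ys, zs] <- out[xs, ys, zs, drop = FALSE] |
      mask[xs - dx, ys - dy, zs - dz, drop = FALSE]
  }
  out
}

maskCentroid <- function(mask) {
  pos <- arrayInd(which(as3d(mask)), dim(as3d(mask)))
  colMeans(pos)
}

# Drop connected components smaller than minPx voxels.
dropSmallComponents <- function(mask, minPx) {
  cc <- connectedComponents(mask)
  if (!any(cc > 0L)) return(as3d(mask) & FALSE)
  keep <- as.integer(names(which(table(cc[cc > 0L]) >= minPx)))
  array(cc %in% keep, dim(cc))
}

stopifnotSameShape <- function(a, b, what = "masks") {
  if (!identical(dim(as3d(a)), dim(as3d(b))))
    stop(what, " must have identical shapes", call. = FALSE)
}
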