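# 26-connected component machinery shared by mask validation, segmentation
# and the zone/texture builders.

# The 13 unique positive offsets of the 26-neighbourhood; each offset and its
# negation together cover all 26 neighbours.
offsets26 <- function() {
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0 & off$dk == 0), ]
  keep <- off$dk > 0 | (off$dk == 0 & off$dj > 0) |
    (off$dk == 0 & off$dj == 0 & off$di > 0)
  as.matrix(off[keep, , drop = FALSE])
}

# For one offset, linear indices of all voxel pairs (a, b) with b = a + offset
# such that pred(a, b) holds; `lab` is a 3D array, 0 meaning background.
# Returns a 2-column matrix of linear indices.
.pairs_at_offset <- function(lab, off, same_level = FALSE) {
  d <- dim(lab)
  lo <- pmax(1, 1 - off)
  hi <- pmin(d, d - off)
  if (any(hi < lo)) return(matrix(integer(0), ncol = 2))
  i1 <- lo[1]:hi[1]
  j1 <- lo[2]:hi[2]
  k1 <- lo[3]:hi[3]
  a <- lab[i1, j1, k1, drop = FALSE]
  b <- lab[i1 + off[1], j1 + off[2], k1 + off[3], drop = FALSE]
  ok <- a > 0 & b > 0
  if (same_level) ok <- ok & a == b
  if (!any(ok)) return(matrix(integer(0), ncol = 2))
  idx_a <- as.vector(outer(outer(i1, (j1 - 1) * d[1], "+"),
                           (k1 - 1) * d[1] * d[2], "+"))
  shift <- off[1] + off[2] * d[1] + off[3] * d[1] * d[2]
  sel <- which(as.vector(ok))
  cbind(idx_a[sel], idx_a[sel] + shift)
}

# Label 26-connected components of lab > 0 (same_level = FALSE) or of
# equal-valued regions (same_level = TRUE, the GLSZM zone definition).
# Returns list(labels = integer vector parallel to `which(lab > 0)`,
#              voxels = linear indices, n = number of components).
label_components <- function(lab, same_level = FALSE) {
  vox <- which(lab > 0)
  if (!length(vox)) return(list(labels = integer(0), voxels = vox, n = 0L))
  edges <- lapply(seq_len(nrow(offsets26())), function(r) {
    .pairs_at_offset(lab, offsets26()[r, ], same_level = same_level)
  })
  edges <- do.call(rbind, edges)
  id <- integer(length(lab))
  id[vox] <- seq_along(vox)
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(id[edges[, 1]], id[edges[, 2]]))
  }
  comp <- igraph::components(g)
  list(labels = comp$membership, voxels = vox, n = comp$no)
}

# Number of 26-connected foreground components of a binary array.
count_components <- function(mask_arr) {
  label_components(array(as.integer(mask_arr != 0), dim(mask_arr)))$n
}

# Binary array of the component containing `seed` (linear index) in arr > 0.
component_containing <- function(bin, seed) {
  lab <- label_components(array(as.integer(bin != 0), dim(bin)))
  out <- array(0L, dim(bin))
  pos <- match(seed, lab$voxels)
  if (is.na(pos)) return(out)
  out[lab$voxels[lab$labels == lab$labels[pos]]] <- 1L
  out
}
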