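#' Geometrical shape features of a VOI
#'
#' Six shape descriptors computed on the binary mask in physical (mm)
#' coordinates, so anisotropic voxels are handled explicitly:
#'
#' * `SOLIDITY` — mask voxel count divided by the number of grid voxel
#'   centers lying inside or on the convex hull of the mask voxel centers;
#'   below 1 for lesions with concavities or surface irregularities.
#' * `SPHERICITY` — `pi^(1/3) * (6V)^(2/3) / A`, 1 for a perfect sphere.
#' * `COMPACTNESS` — `36 * pi * V^2 / A^3`.
#' * `SURFACE_AREA` — mm^2, sum of exposed voxel faces.
#' * `MAX_DIAMETER` — mm, largest distance between two voxel centers.
#' * `ELONGATION` — square root of the ratio of the second to the first
#'   principal-axis variance of the voxel centers (1 = equi-axed).
#'
#' If the voxel centers are collinear the hull degenerates; solidity falls
#' back to 1 with a warning. Planar (single-slice) masks use the 2D hull in
#' their plane.
#'
#' @param mask a [voi_mask()].
#' @return named numeric vector of the six features.
#' @export
compute_shape_features <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  sp <- mask$spacing
  d <- dim(mask$mask)
  vox <- which(mask$mask == 1L)
  idx <- arrayInd(vox, d)
  centers <- sweep(idx - 1, 2, sp, "*")  # physical voxel centers
  n_mask <- length(vox)

  vol_mm3 <- n_mask * prod(sp)
  area <- .surface_area(mask$mask, sp)
  sphericity <- pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / area
  compactness <- 36 * pi * vol_mm3^2 / area^3

  # pairwise distances over the axis-extreme subset (superset of hull vertices)
  ext <- .axis_extremes(idx, d)
  ext_centers <- sweep(ext - 1, 2, sp, "*")
  max_diam <- sqrt(max(.pairwise_sq(ext_centers)))

  cov <- stats::cov(centers)
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  elongation <- if (ev[1] > 1e-12) sqrt(ev[2] / ev[1]) else 1

  c(SOLIDITY = .solidity(idx, d, sp, n_mask),
    SPHERICITY = sphericity, COMPACTNESS = compactness,
    SURFACE_AREA = area, MAX_DIAMETER = max_diam, ELONGATION = elongation)
}

.pairwise_sq <- function(P) {
  g <- rowSums(P^2)
  outer(g, g, "+") - 2 * P %*% t(P)
}

# Exposed-face surface area in mm^2.
.surface_area <- function(m, sp) {
  d <- dim(m)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  total <- 0
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    nb <- pad[2:(d[1] + 1) + s[1], 2:(d[2] + 1) + s[2], 2:(d[3] + 1) + s[3],
              drop = FALSE]
    exposed <- sum(m == 1L & nb == 0L)
    total <- total + exposed * face_area[which(s != 0)]
  }
  total
}

# Per-(j,k), (i,k) and (i,j) line extremes of the mask voxels: a small
# superset of the convex-hull vertices.
.axis_extremes <- function(idx, d) {
  keys <- list(idx[, 2] + idx[, 3] * (d[2] + 2),
               idx[, 1] + idx[, 3] * (d[1] + 2),
               idx[, 1] + idx[, 2] * (d[1] + 2))
  sel <- logical(nrow(idx))
  for (ax in 1:3) {
    k <- keys[[ax]]
    v <- idx[, ax]
    mn <- tapply(v, k, min)[as.character(k)]
    mx <- tapply(v, k, max)[as.character(k)]
    sel <- sel | v == mn | v == mx
  }
  idx[sel, , drop = FALSE]
}

# Solidity with planar/collinear degeneracy handling.
.solidity <- function(idx, d, sp, n_mask) {
  centers <- sweep(idx - 1, 2, sp, "*")
  flat_axes <- which(apply(idx, 2, function(x) length(unique(x))) == 1)
  if (nrow(unique(idx)) < 3 ||
      (length(flat_axes) >= 2)) {
    return(1)  # collinear voxel centers: hull degenerates
  }
  rng <- apply(idx, 2, range)
  grid <- as.matrix(expand.grid(i = rng[1, 1]:rng[2, 1],
                                j = rng[1, 2]:rng[2, 2],
                                k = rng[1, 3]:rng[2, 3]))
  qcenters <- sweep(grid - 1, 2, sp, "*")
  if (length(flat_axes) == 1) {
    keep <- setdiff(1:3, flat_axes)
    inside <- in_hull_2d(centers[, keep, drop = FALSE],
                         qcenters[, keep, drop = FALSE])
    return(n_mask / sum(inside))
  }
  ext <- .axis_extremes(idx, d)
  hull <- convex_hull_3d(sweep(ext - 1, 2, sp, "*"))
  if (is.null(hull)) {
    # obliquely planar or collinear set
    cen <- sweep(centers, 2, colMeans(centers))
    eg <- eigen(crossprod(cen), symmetric = TRUE)
    if (eg$values[2] < 1e-9) return(1)  # collinear
    basis <- eg$vectors[, 1:2]
    normal <- eg$vectors[, 3]
    on_plane <- abs(sweep(qcenters, 2, colMeans(centers)) %*% normal) < 1e-6
    P2 <- cen %*% basis
    Q2 <- sweep(qcenters, 2, colMeans(centers)) %*% basis
    inside <- drop(on_plane) & in_hull_2d(P2, Q2)
    return(n_mask / sum(inside))
  }
  n_hull <- sum(in_hull_3d(hull, qcenters))
  n_mask / max(n_hull, n_mask)
}
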