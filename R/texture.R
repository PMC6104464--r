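# Quantization and the five 3D texture-matrix families (co-occurrence,
# size-zone, grey-tone-difference, grey-level-dependence), all built with
# 26-voxel connectivity on mask-restricted neighbourhoods: neighbours
# outside the VOI are ignored, never padded.

#' Quantize the in-VOI SUV range to N grey levels
#'
#' Equal-width binning over the in-VOI `[min, max]` range:
#' `level(v) = min(N, floor((v - min) / (max - min) * N) + 1)`. The minimum
#' maps to level 1 and the maximum is clamped into level `N`. A constant VOI
#' quantizes to level 1 everywhere.
#'
#' @param volume a [pet_volume()].
#' @param mask a [voi_mask()] on the same grid.
#' @param N number of grey levels (default 64).
#' @return a `quantized_voi`: list with `levels` (3D integer array, 0
#'   outside the mask), `N`, and the `range` used for binning.
#' @export
quantize <- function(volume, mask, N = 64) {
  check_pair(volume, mask)
  stopifnot(N >= 1)
  v <- volume$values[mask$mask == 1L]
  lev <- array(0L, dim(volume$values))
  rng <- range(v)
  if (rng[2] > rng[1]) {
    l <- pmin(N, floor((v - rng[1]) / (rng[2] - rng[1]) * N) + 1L)
  } else {
    l <- rep(1L, length(v))
  }
  lev[mask$mask == 1L] <- as.integer(l)
  structure(list(levels = lev, N = as.integer(N), range = rng),
            class = "quantized_voi")
}

# Accumulate symmetric co-occurrence counts over all ordered in-mask voxel
# pairs at the 26 neighbour offsets (13 unique offsets, both orientations).
.cooccurrence_counts <- function(q) {
  N <- q$N
  cnt <- matrix(0, N, N)
  off <- offsets26()
  for (r in seq_len(nrow(off))) {
    pr <- .pairs_at_offset(q$levels, off[r, ])
    if (!nrow(pr)) next
    a <- q$levels[pr[, 1]]
    b <- q$levels[pr[, 2]]
    t1 <- tabulate((a - 1L) * N + b, nbins = N * N)
    cnt <- cnt + matrix(t1, N, N, byrow = TRUE) +
      t(matrix(t1, N, N, byrow = TRUE))
  }
  cnt
}

# Shared feature set of a normalized co-occurrence matrix p (sums to 1).
.cooc_features <- function(p) {
  N <- nrow(p)
  i <- matrix(seq_len(N), N, N)
  j <- t(i)
  nz <- p > 0
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p))
  sd_j <- sqrt(sum((j - mu_j)^2 * p))
  corr <- if (sd_i > 1e-12 && sd_j > 1e-12) {
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
  } else 0  # constant VOI: correlation undefined, reported as 0
  list(entropy = -sum(p[nz] * log2(p[nz])),
       energy = sum(p^2),
       contrast = sum(p * (i - j)^2),
       homogeneity = sum(p / (1 + abs(i - j))),
       dissimilarity = sum(p * abs(i - j)),
       correlation = corr)
}

#' Grey level co-occurrence matrices and their features
#'
#' `compute_glcm()` and `compute_nglcm()` share one direction-aggregated
#' symmetric accumulation: counts over all ordered in-mask voxel pairs at
#' one-voxel distance in the 26-neighbourhood. `compute_nglcm()` exposes the
#' normalized (relative-frequency) matrix, whose entropy measures the
#' randomness of neighbouring grey-level pairs — zero only for a constant
#' VOI.
#'
#' @param q a [quantize()]d VOI.
#' @return a list with the matrix and named features (`GLCM_*` /
#'   `NGLCM_*`).
#' @export
compute_glcm <- function(q) {
  cnt <- .cooccurrence_counts(q)
  if (sum(cnt) == 0) stop("VOI has no in-mask neighbouring voxel pair")
  f <- .cooc_features(cnt / sum(cnt))
  list(matrix = cnt,
       features = c(GLCM_ENTROPY = f$entropy, GLCM_ENERGY = f$energy,
                    GLCM_CONTRAST = f$contrast,
                    GLCM_HOMOGENEITY = f$homogeneity,
                    GLCM_DISSIMILARITY = f$dissimilarity,
                    GLCM_CORRELATION = f$correlation))
}

#' @rdname compute_glcm
#' @export
compute_nglcm <- function(q) {
  cnt <- .cooccurrence_counts(q)
  if (sum(cnt) == 0) stop("VOI has no in-mask neighbouring voxel pair")
  p <- cnt / sum(cnt)
  f <- .cooc_features(p)
  list(matrix = p,
       features = c(NGLCM_ENTROPY = f$entropy, NGLCM_ENERGY = f$energy,
                    NGLCM_CONTRAST = f$contrast,
                    NGLCM_HOMOGENEITY = f$homogeneity,
                    NGLCM_CORRELATION = f$correlation))
}

#' Grey level size zone matrix and its features
#'
#' Zones are 26-connected components of equal-level in-mask voxels;
#' `glszm[n, s]` counts zones of grey level `n` and size `s`. The zone
#' percentage `ZP = (number of zones) / (number of in-mask voxels)` is low
#' for lesions whose wide uptake range produces large homogeneous regions
#' after quantization (heterogeneous lesions) and 1 when every voxel is its
#' own zone.
#'
#' @param q a [quantize()]d VOI.
#' @return list with `matrix` (N rows, max-zone-size columns) and features
#'   `GLSZM_ZP`, `GLSZM_SZE`, `GLSZM_LZE`, `GLSZM_GLN`, `GLSZM_ZSN`,
#'   `GLSZM_LGZE`, `GLSZM_HGZE`.
#' @export
compute_glszm <- function(q) {
  comp <- label_components(q$levels, same_level = TRUE)
  n_vox <- length(comp$voxels)
  sizes <- tabulate(comp$labels, nbins = comp$n)
  # grey level of each zone = level of its first voxel
  lev_of_zone <- integer(comp$n)
  lev_of_zone[comp$labels] <- q$levels[comp$voxels]
  S <- max(sizes)
  m <- matrix(0, q$N, S)
  for (z in seq_len(comp$n)) {
    m[lev_of_zone[z], sizes[z]] <- m[lev_of_zone[z], sizes[z]] + 1
  }
  nz <- as.integer(round(sum(m)))  # total zone count
  s_idx <- matrix(seq_len(S), q$N, S, byrow = TRUE)
  n_idx <- matrix(seq_len(q$N), q$N, S)
  p <- m / nz
  feats <- c(
    GLSZM_ZP = nz / n_vox,
    GLSZM_SZE = sum(p / s_idx^2),
    GLSZM_LZE = sum(p * s_idx^2),
    GLSZM_GLN = sum(rowSums(m)^2) / nz,
    GLSZM_ZSN = sum(colSums(m)^2) / nz,
    GLSZM_LGZE = sum(p / n_idx^2),
    GLSZM_HGZE = sum(p * n_idx^2))
  list(matrix = m, features = feats, n_zones = nz, n_voxels = n_vox)
}

# Sum and count of in-mask 26-neighbour levels for every in-mask voxel.
.neighbour_stats <- function(q) {
  d <- dim(q$levels)
  inm <- q$levels > 0
  nsum <- array(0, d)
  ncnt <- array(0L, d)
  nsame <- array(0L, d)
  off_all <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off_all <- off_all[!(off_all$di == 0 & off_all$dj == 0 & off_all$dk == 0), ]
  for (r in seq_len(nrow(off_all))) {
    off <- as.integer(off_all[r, ])
    lo <- pmax(1, 1 - off)
    hi <- pmin(d, d - off)
    if (any(hi < lo)) next
    i1 <- lo[1]:hi[1]
    j1 <- lo[2]:hi[2]
    k1 <- lo[3]:hi[3]
    src <- q$levels[i1 + off[1], j1 + off[2], k1 + off[3], drop = FALSE]
    ok <- src > 0
    nsum[i1, j1, k1] <- nsum[i1, j1, k1, drop = FALSE] + src * ok
    ncnt[i1, j1, k1] <- ncnt[i1, j1, k1, drop = FALSE] + ok
    nsame[i1, j1, k1] <- nsame[i1, j1, k1, drop = FALSE] +
      (ok & src == q$levels[i1, j1, k1, drop = FALSE])
  }
  list(sum = nsum, count = ncnt, same = nsame, inmask = inm)
}

#' Neighbourhood grey tone difference matrix and its features
#'
#' For every in-mask voxel with at least one in-mask 26-neighbour, the
#' absolute difference between its level and the mean level of those
#' neighbours is accumulated per grey level, giving occurrence counts
#' `n_i` and summed differences `s_i` from which the five Amadasun-King
#' features follow. On a constant VOI all `s_i` are 0 and coarseness is
#' capped at `1e6`.
#'
#' @param q a [quantize()]d VOI.
#' @return list with `table` (per-level `n_i`, `s_i`) and features
#'   `NGTDM_COARSENESS`, `NGTDM_CONTRAST`, `NGTDM_BUSYNESS`,
#'   `NGTDM_COMPLEXITY`, `NGTDM_STRENGTH`.
#' @export
compute_ngtdm <- function(q) {
  st <- .neighbour_stats(q)
  use <- st$inmask & st$count > 0
  if (!any(use)) stop("VOI has no voxel with an in-mask neighbour")
  lv <- q$levels[use]
  diffs <- abs(lv - st$sum[use] / st$count[use])
  n_i <- tabulate(lv, nbins = q$N)
  s_i <- vapply(seq_len(q$N), function(l) sum(diffs[lv == l]), numeric(1))
  Nv <- sum(n_i)
  p_i <- n_i / Nv
  act <- which(p_i > 0)
  Ng <- length(act)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 1e-12) 1 / coarse_den else 1e6
  contrast <- if (Ng > 1) {
    (sum(outer(p_i[act], p_i[act]) *
           outer(act, act, function(a, b) (a - b)^2)) /
       (Ng * (Ng - 1))) * (sum(s_i) / Nv)
  } else 0
  busy_den <- sum(abs(outer(act * p_i[act], act * p_i[act], "-")))
  busyness <- if (busy_den > 1e-12) sum(p_i * s_i) / busy_den else 0
  pi_a <- p_i[act]
  si_a <- s_i[act]
  complexity <- sum(outer(act, act, function(a, b) abs(a - b)) *
                      (outer(pi_a * si_a, pi_a * si_a, "+") /
                         (Nv * outer(pi_a, pi_a, "+"))))
  strength <- if (sum(s_i) > 1e-12) {
    sum(outer(pi_a, pi_a, "+") * outer(act, act, function(a, b) (a - b)^2)) /
      sum(s_i)
  } else 0
  list(table = data.frame(level = seq_len(q$N), n = n_i, s = s_i),
       features = c(NGTDM_COARSENESS = coarseness, NGTDM_CONTRAST = contrast,
                    NGTDM_BUSYNESS = busyness, NGTDM_COMPLEXITY = complexity,
                    NGTDM_STRENGTH = strength))
}

#' Neighbourhood grey level dependence matrix and its features
#'
#' The dependence of an in-mask voxel is the number of its in-mask
#' 26-neighbours with exactly the same grey level (coarseness parameter 0);
#' `ngldm[n, d+1]` counts voxels of level `n` with dependence `d`
#' (`d` in 0..26).
#'
#' @param q a [quantize()]d VOI.
#' @return list with `matrix` (N x 27) and features `NGLDM_SNE`,
#'   `NGLDM_LNE`, `NGLDM_NN`, `NGLDM_ENTROPY`.
#' @export
compute_ngldm <- function(q) {
  st <- .neighbour_stats(q)
  lv <- q$levels[st$inmask]
  dep <- st$same[st$inmask]
  m <- matrix(0, q$N, 27)
  t1 <- tabulate((lv - 1L) * 27L + dep + 1L, nbins = q$N * 27L)
  m <- matrix(t1, q$N, 27, byrow = TRUE)
  tot <- sum(m)
  p <- m / tot
  dmat <- matrix(0:26, q$N, 27, byrow = TRUE)
  nzp <- p[p > 0]
  feats <- c(NGLDM_SNE = sum(p / (dmat + 1)^2),
             NGLDM_LNE = sum(p * (dmat + 1)^2),
             NGLDM_NN = sum(colSums(m)^2) / tot,
             NGLDM_ENTROPY = -sum(nzp * log2(nzp)))
  list(matrix = m, features = feats)
}
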