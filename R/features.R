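#' SUV and volume features
#'
#' @param volume a [pet_volume()].
#' @param mask a [voi_mask()] on the same grid.
#' @return named vector: `SUVmax`, `SUVmean`, `MTV` (mL,
#'   voxel count x voxel volume / 1000) and `TLG` (`SUVmean * MTV`).
#' @export
compute_suv_features <- function(volume, mask) {
  check_pair(volume, mask)
  v <- volume$values[mask$mask == 1L]
  mtv <- length(v) * prod(volume$spacing) / 1000
  c(SUVmax = max(v), SUVmean = mean(v), MTV = mtv, TLG = mean(v) * mtv)
}

#' First-order grey-level histogram features
#'
#' Seven descriptors of the in-VOI SUV distribution: mean, population
#' standard deviation, skewness, excess kurtosis, coefficient of variation,
#' base-2 entropy over `n_bins` equal-width bins spanning the in-mask range,
#' and uniformity (sum of squared bin probabilities). A constant VOI is
#' degenerate: sd, skewness, kurtosis and CV are reported as 0, entropy 0
#' and uniformity 1.
#'
#' @param volume a [pet_volume()].
#' @param mask a [voi_mask()].
#' @param n_bins histogram bin count (default 64).
#' @return named numeric vector of the 7 features (`HIST_*`).
#' @export
compute_histogram_features <- function(volume, mask, n_bins = 64) {
  check_pair(volume, mask)
  v <- volume$values[mask$mask == 1L]
  n <- length(v)
  mu <- mean(v)
  s2 <- mean((v - mu)^2)  # population variance
  s <- sqrt(s2)
  if (s < 1e-12) {
    return(c(HIST_MEAN = mu, HIST_SD = 0, HIST_SKEWNESS = 0,
             HIST_KURTOSIS = 0, HIST_CV = 0, HIST_ENTROPY = 0,
             HIST_UNIFORMITY = 1))
  }
  skew <- mean((v - mu)^3) / s^3
  kurt <- mean((v - mu)^4) / s2^2 - 3
  cv <- s / mu
  br <- seq(min(v), max(v), length.out = n_bins + 1)
  cnt <- tabulate(pmin(n_bins, findInterval(v, br)), nbins = n_bins)
  p <- cnt / n
  nz <- p > 0
  c(HIST_MEAN = mu, HIST_SD = s, HIST_SKEWNESS = skew, HIST_KURTOSIS = kurt,
    HIST_CV = cv, HIST_ENTROPY = -sum(p[nz] * log2(p[nz])),
    HIST_UNIFORMITY = sum(p^2))
}

#' The frozen radiomic feature roster
#'
#' @return character vector of the 44 feature names produced by
#'   [extract_features()], in their fixed column order.
#' @export
feature_names <- function() {
  c("SUVmax", "SUVmean", "MTV", "TLG",
    "SOLIDITY", "SPHERICITY", "COMPACTNESS", "SURFACE_AREA", "MAX_DIAMETER",
    "ELONGATION",
    "HIST_MEAN", "HIST_SD", "HIST_SKEWNESS", "HIST_KURTOSIS", "HIST_CV",
    "HIST_ENTROPY", "HIST_UNIFORMITY",
    "GLCM_ENTROPY", "GLCM_ENERGY", "GLCM_CONTRAST", "GLCM_HOMOGENEITY",
    "GLCM_DISSIMILARITY", "GLCM_CORRELATION",
    "NGLCM_ENTROPY", "NGLCM_ENERGY", "NGLCM_CONTRAST", "NGLCM_HOMOGENEITY",
    "NGLCM_CORRELATION",
    "GLSZM_ZP", "GLSZM_SZE", "GLSZM_LZE", "GLSZM_GLN", "GLSZM_ZSN",
    "GLSZM_LGZE", "GLSZM_HGZE",
    "NGTDM_COARSENESS", "NGTDM_CONTRAST", "NGTDM_BUSYNESS",
    "NGTDM_COMPLEXITY", "NGTDM_STRENGTH",
    "NGLDM_SNE", "NGLDM_LNE", "NGLDM_NN", "NGLDM_ENTROPY")
}

#' Extract the full radiomic feature vector of a VOI
#'
#' Concatenates the SUV/volume, shape, histogram and texture feature groups
#' (44 features in total, see [feature_names()]): co-occurrence (GLCM and
#' its normalized variant NGLCM), size-zone (GLSZM), grey-tone-difference
#' (NGTDM) and grey-level-dependence (NGLDM) families, all computed in 3D
#' with 26-voxel connectivity after `N`-level quantization of the in-VOI
#' SUV range. Deterministic.
#'
#' @param volume a [pet_volume()].
#' @param mask a [voi_mask()].
#' @param N quantization level count (default 64).
#' @return named numeric vector, names exactly [feature_names()].
#' @export
extract_features <- function(volume, mask, N = 64) {
  check_pair(volume, mask)
  q <- quantize(volume, mask, N = N)
  out <- c(compute_suv_features(volume, mask),
           compute_shape_features(mask),
           compute_histogram_features(volume, mask, n_bins = N),
           compute_glcm(q)$features,
           compute_nglcm(q)$features,
           compute_glszm(q)$features,
           compute_ngtdm(q)$features,
           compute_ngldm(q)$features)
  out[feature_names()]
}
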