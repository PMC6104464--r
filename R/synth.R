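# Synthetic PET tumour and cohort generator. Emulates the data structure the
# downstream analysis assumes: ellipsoidal lesions with optional necrotic
# cores and focal hot spots (wide SUV range = regional heterogeneity),
# lobulated boundaries (reduced solidity), reconstruction-like Gaussian
# smoothing and additive noise, and per-patient visual-detection labels with
# configurable sensitivity/specificity.

# Evaluate expr with a private RNG stream; the caller's stream is untouched.
with_seed_local <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Parameters of one synthetic tumour
#'
#' Describes an ellipsoidal FDG-avid lesion: uniform uptake `base_suv`,
#' semi-axes `radius_mm`, an optional central necrotic core (a sub-ellipsoid
#' occupying `fraction` of the lesion volume at `suv_ratio` times the base
#' uptake), optional Gaussian hot spots, a lobulated boundary (low-order
#' spherical-harmonic radial perturbation of relative amplitude
#' `lobulation`), Gaussian post-smoothing of FWHM `psf_fwhm_mm` emulating
#' reconstruction filtering, and additive Gaussian noise `noise_sd` (SUV).
#'
#' @param base_suv baseline lesion uptake (SUV, > 0).
#' @param radius_mm semi-axes in mm, length 3.
#' @param necrotic_core `NULL` or `list(fraction=, suv_ratio=)` with
#'   `fraction` in (0,1) and `suv_ratio` in `[0,1)`.
#' @param hot_spots `NULL` or `list(count=, peak_suv_ratio=, radius_mm=)`;
#'   each spot adds a Gaussian bump of sd `radius_mm` peaking at
#'   `peak_suv_ratio * base_suv`.
#' @param lobulation boundary perturbation amplitude in `[0, 1)` (fraction of
#'   local radius).
#' @param noise_sd additive Gaussian noise sd in SUV (applied after
#'   smoothing, clipped at 0).
#' @param psf_fwhm_mm FWHM of the isotropic Gaussian smoothing filter, mm.
#' @return a `tumour_params` list.
#' @export
tumour_params <- function(base_suv = 10, radius_mm = c(15, 15, 15),
                          necrotic_core = NULL, hot_spots = NULL,
                          lobulation = 0, noise_sd = 0, psf_fwhm_mm = 5) {
  stopifnot(base_suv > 0, all(radius_mm > 0), length(radius_mm) == 3,
            lobulation >= 0, lobulation < 1, noise_sd >= 0, psf_fwhm_mm >= 0)
  if (!is.null(necrotic_core)) {
    stopifnot(necrotic_core$fraction > 0, necrotic_core$fraction < 1,
              necrotic_core$suv_ratio >= 0, necrotic_core$suv_ratio < 1)
  }
  if (!is.null(hot_spots)) {
    stopifnot(hot_spots$count >= 1, hot_spots$peak_suv_ratio > 1,
              hot_spots$radius_mm > 0)
  }
  structure(list(base_suv = base_suv, radius_mm = as.numeric(radius_mm),
                 necrotic_core = necrotic_core, hot_spots = hot_spots,
                 lobulation = lobulation, noise_sd = noise_sd,
                 psf_fwhm_mm = psf_fwhm_mm),
            class = "tumour_params")
}

# Real spherical harmonics of degree 2 and 3 (unnormalized Cartesian forms)
# evaluated at unit directions; rows = points, cols = basis functions.
.sh_basis <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  cbind(x * y, y * z, z * x, x^2 - y^2, 3 * z^2 - 1,
        z * (5 * z^2 - 3), x * (5 * z^2 - 1), y * (5 * z^2 - 1),
        z * (x^2 - y^2), x * y * z, x * (x^2 - 3 * y^2),
        y * (3 * x^2 - y^2))
}

# Separable Gaussian smoothing with edge-replicate padding.
.gauss_smooth <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 1e-8) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    idx_base <- seq_len(d[ax])
    out <- array(0, d)
    for (t in seq_along(k)) {
      shift <- t - r - 1L
      idx <- pmin(pmax(idx_base + shift, 1L), d[ax])
      sl <- switch(ax,
                   arr[idx, , , drop = FALSE],
                   arr[, idx, , drop = FALSE],
                   arr[, , idx, drop = FALSE])
      out <- out + k[t] * sl
    }
    arr <- out
  }
  arr
}

#' Generate one synthetic PET tumour
#'
#' Builds a volume/mask pair on a grid just large enough to hold the lesion
#' plus margin. The mask is the (lobulated) ellipsoid; uptake is `base_suv`
#' inside, modified by the necrotic core and hot spots, smoothed with a
#' Gaussian of FWHM `psf_fwhm_mm`, then perturbed with clipped Gaussian
#' noise. Background uptake is 5% of `base_suv`. Deterministic given `seed`.
#'
#' @param params a [tumour_params()].
#' @param grid_spacing voxel spacing `(dx, dy, dz)` in mm.
#' @param seed integer seed for lobulation shape, hot-spot placement and
#'   noise.
#' @return `list(volume = pet_volume, mask = voi_mask)`.
#' @examples
#' tp <- tumour_params(base_suv = 10, radius_mm = c(15, 15, 15),
#'                     noise_sd = 0, psf_fwhm_mm = 0)
#' tm <- generate_tumour(tp, seed = 1)
#' max(tm$volume$values)  # 10
#' @export
generate_tumour <- function(params, grid_spacing = c(2.73, 2.73, 3.27),
                            seed = 1) {
  stopifnot(inherits(params, "tumour_params"))
  with_seed_local(seed, {
    sp <- as.numeric(grid_spacing)
    r <- params$radius_mm * (1 + params$lobulation)
    sigma_vox <- (params$psf_fwhm_mm / 2.3548) / sp
    margin <- 3L + ceiling(3 * max(sigma_vox, 0))
    half <- ceiling(r / sp) + margin
    d <- 2L * half + 1L
    ctr <- half + 1L
    # physical coordinates relative to the lesion centre
    cx <- (seq_len(d[1]) - ctr[1]) * sp[1]
    cy <- (seq_len(d[2]) - ctr[2]) * sp[2]
    cz <- (seq_len(d[3]) - ctr[3]) * sp[3]
    X <- array(cx, d)
    Y <- aperm(array(cy, d[c(2, 1, 3)]), c(2, 1, 3))
    Z <- aperm(array(cz, d[c(3, 2, 1)]), c(3, 2, 1))
    ex <- X / params$radius_mm[1]
    ey <- Y / params$radius_mm[2]
    ez <- Z / params$radius_mm[3]
    rho <- sqrt(ex^2 + ey^2 + ez^2)
    limit <- array(1, d)
    if (params$lobulation > 0) {
      coefs <- rnorm(12) * rep(c(1, 1 / 1.5), c(5, 7))  # damp degree 3
      nz <- rho > 1e-12
      u <- cbind(as.vector(ex)[nz], as.vector(ey)[nz],
                 as.vector(ez)[nz]) / as.vector(rho)[nz]
      f <- drop(.sh_basis(u) %*% coefs)
      f <- f / max(abs(f))
      pert <- array(0, d)
      pert[nz] <- f
      limit <- 1 + params$lobulation * pert
    }
    inside <- rho <= limit
    if (sum(inside) < 2) stop("degenerate radii: lesion smaller than 2 voxels")
    mask_arr <- array(0L, d)
    mask_arr[inside] <- 1L
    # lobulation at high amplitude can pinch off satellites; keep the lesion
    if (count_components(mask_arr) > 1) {
      mask_arr <- component_containing(
        mask_arr, (ctr[3] - 1L) * d[1] * d[2] + (ctr[2] - 1L) * d[1] + ctr[1])
    }
    bg <- 0.05 * params$base_suv
    vals <- array(bg, d)
    vals[mask_arr == 1L] <- params$base_suv
    if (!is.null(params$necrotic_core)) {
      scale <- params$necrotic_core$fraction^(1 / 3)
      core <- (ex / scale)^2 + (ey / scale)^2 + (ez / scale)^2 <= 1
      vals[core & mask_arr == 1L] <-
        params$base_suv * params$necrotic_core$suv_ratio
    }
    if (!is.null(params$hot_spots)) {
      hs <- params$hot_spots
      for (s in seq_len(hs$count)) {
        # uniform position well inside the lesion
        repeat {
          p <- runif(3, -0.7, 0.7)
          if (sum(p^2) <= 0.49) break
        }
        cpos <- p * params$radius_mm
        d2 <- (X - cpos[1])^2 + (Y - cpos[2])^2 + (Z - cpos[3])^2
        vals <- vals + params$base_suv * (hs$peak_suv_ratio - 1) *
          exp(-0.5 * d2 / hs$radius_mm^2)
      }
    }
    # statistical noise enters before the reconstruction filter, so the
    # smoothed image carries spatially correlated noise as real PET does
    if (params$noise_sd > 0) {
      vals <- vals + rnorm(length(vals), 0, params$noise_sd)
      vals[vals < 0] <- 0
    }
    if (params$psf_fwhm_mm > 0) vals <- .gauss_smooth(vals, sigma_vox)
    list(volume = pet_volume(vals, spacing = sp),
         mask = voi_mask(mask_arr, spacing = sp))
  })
}

# Draw one scalar from a fixed value (length 1) or a uniform range (length 2).
.draw <- function(x) if (length(x) == 2) runif(1, x[1], x[2]) else x[1]

#' Distribution over tumour parameters for cohort simulation
#'
#' Each scalar field is either a fixed value or a `c(lo, hi)` uniform range.
#' `radius_mm` may be a length-2 range (each semi-axis drawn independently)
#' or a fixed length-3 triple. Cores and hot spots are attached with
#' probability `core_prob` / `hotspot_prob`. `noise_frac` sets the noise sd
#' as a fraction of the drawn `base_suv`.
#'
#' @param base_suv,radius_mm,lobulation,psf_fwhm_mm as in [tumour_params()],
#'   fixed or ranges.
#' @param core_prob,core_fraction,core_suv_ratio necrotic-core attachment
#'   probability and geometry.
#' @param hotspot_prob,hotspot_count,hotspot_peak_ratio,hotspot_radius_mm
#'   hot-spot attachment probability and shape.
#' @param noise_frac noise sd as a fraction of base SUV.
#' @return a `tumour_param_dist` list, for [cohort_config()].
#' @export
tumour_param_dist <- function(base_suv = c(6, 15), radius_mm = c(12, 18),
                              core_prob = 0, core_fraction = 0.3,
                              core_suv_ratio = 0.1, hotspot_prob = 0,
                              hotspot_count = c(1, 3),
                              hotspot_peak_ratio = c(1.6, 2.2),
                              hotspot_radius_mm = c(4, 7), lobulation = 0.05,
                              noise_frac = 0.05, psf_fwhm_mm = 9) {
  structure(as.list(environment()), class = "tumour_param_dist")
}

# Sample concrete tumour_params from a tumour_param_dist (uses current RNG).
sample_tumour_params <- function(dist) {
  stopifnot(inherits(dist, "tumour_param_dist"))
  base <- .draw(dist$base_suv)
  radius <- if (length(dist$radius_mm) == 3) dist$radius_mm
            else runif(3, dist$radius_mm[1], dist$radius_mm[2])
  core <- NULL
  if (runif(1) < dist$core_prob) {
    core <- list(fraction = .draw(dist$core_fraction),
                 suv_ratio = .draw(dist$core_suv_ratio))
  }
  spots <- NULL
  if (runif(1) < dist$hotspot_prob) {
    spots <- list(count = round(.draw(dist$hotspot_count)),
                  peak_suv_ratio = .draw(dist$hotspot_peak_ratio),
                  radius_mm = .draw(dist$hotspot_radius_mm))
  }
  tumour_params(base_suv = base, radius_mm = radius, necrotic_core = core,
                hot_spots = spots, lobulation = .draw(dist$lobulation),
                noise_sd = dist$noise_frac * base,
                psf_fwhm_mm = .draw(dist$psf_fwhm_mm))
}

#' Configuration of a synthetic cohort
#'
#' Defaults describe the simulated study condition used throughout the
#' package: 86 patients of whom 16 are LN-positive; LN-positive tumours are
#' heterogeneous — a necrotic core (volume fraction 0.3 at 10% of base
#' uptake) with probability 0.8, focal hot spots with probability 0.7, and
#' a strongly lobulated boundary (amplitude 0.3); LN-negative tumours are
#' homogeneous and nearly smooth (amplitude 0.05); noise sd is 5% of base
#' SUV; visual nodal detection has sensitivity 0.5 and specificity 0.99.
#' Lesion semi-axes are drawn uniformly from 12-18 mm (roughly 7-25 mL)
#' and the simulated image resolution is 9 mm FWHM, the effective
#' resolution of an OSEM-reconstructed, post-filtered whole-body PET image.
#'
#' @param n_patients,n_positive cohort size and exact LN-positive count.
#' @param params_positive,params_negative [tumour_param_dist()] for each
#'   class.
#' @param visual_sensitivity,visual_specificity operating point of the
#'   simulated visual PET reading of nodal status.
#' @param grid_spacing voxel spacing in mm.
#' @param scanners character vector; scanner ids assigned round-robin.
#' @param seed integer master seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 86, n_positive = 16,
                          params_positive = tumour_param_dist(
                            core_prob = 0.8, hotspot_prob = 0.7,
                            lobulation = 0.3),
                          params_negative = tumour_param_dist(
                            core_prob = 0, lobulation = 0.05),
                          visual_sensitivity = 0.5,
                          visual_specificity = 0.99,
                          grid_spacing = c(2.73, 2.73, 3.27),
                          scanners = c("scannerA", "scannerB"),
                          seed = 1) {
  stopifnot(n_positive > 0, n_positive < n_patients,
            visual_sensitivity >= 0, visual_sensitivity <= 1,
            visual_specificity >= 0, visual_specificity <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws `n_patients` tumours (exactly `n_positive` LN-positive), extracts
#' radiomic features from each, and simulates the visual nodal reading:
#' `Bernoulli(visual_sensitivity)` for LN-positive patients and
#' `Bernoulli(1 - visual_specificity)` for LN-negative ones. Reproducible
#' from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory; if given, per-patient NIfTI
#'   volumes/masks and the cohort CSV are written there.
#' @param extract if `TRUE` (default) compute the radiomic feature vector of
#'   every tumour and attach it as cohort columns.
#' @param levels quantization levels for texture features.
#' @param keep_images if `TRUE`, attach the generated volumes and masks as
#'   attribute `"images"` (a list per patient).
#' @return a cohort data frame (class `rad_cohort`).
#' @export
generate_cohort <- function(config, out_dir = NULL, extract = TRUE,
                            levels = 64, keep_images = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  with_seed_local(config$seed, {
    status <- integer(n)
    status[sample.int(n, config$n_positive)] <- 1L
    tumour_seeds <- sample.int(.Machine$integer.max - 1L, n)
    visual <- ifelse(status == 1L,
                     rbinom(n, 1, config$visual_sensitivity),
                     rbinom(n, 1, 1 - config$visual_specificity))
    params <- lapply(seq_len(n), function(i) {
      sample_tumour_params(
        if (status[i] == 1L) config$params_positive else config$params_negative)
    })
    ids <- sprintf("p%03d", seq_len(n))
    scanner <- rep_len(config$scanners, n)
    images <- vector("list", n)
    feat_rows <- vector("list", n)
    for (i in seq_len(n)) {
      tm <- generate_tumour(params[[i]], config$grid_spacing,
                            seed = tumour_seeds[i])
      if (extract) {
        feat_rows[[i]] <- extract_features(tm$volume, tm$mask, N = levels)
      }
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_volume(tm$volume, file.path(out_dir,
                                          paste0(ids[i], "_pet.nii.gz")))
        write_mask(tm$mask, file.path(out_dir,
                                      paste0(ids[i], "_mask.nii.gz")))
      }
      if (keep_images) images[[i]] <- tm
    }
    df <- data.frame(patient_id = ids, ln_histology = status,
                     visual_detection = as.integer(visual),
                     scanner_id = scanner, stringsAsFactors = FALSE)
    if (extract) {
      df <- cbind(df, as.data.frame(do.call(rbind, feat_rows)))
    }
    cohort <- as_cohort(df)
    if (!is.null(out_dir)) {
      write_cohort_table(cohort, file.path(out_dir, "cohort.csv"))
    }
    if (keep_images) {
      names(images) <- ids
      attr(cohort, "images") <- images
    }
    cohort
  })
}
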