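#' PET volume and VOI mask containers
#'
#' A `pet_volume` holds a 3D array of body-weight SUV values together with
#' the physical voxel spacing (mm) and origin; a `voi_mask` holds a binary
#' tumour mask on the same grid. All downstream feature definitions assume a
#' single lesion, so a valid mask is one 26-connected foreground component
#' with at least two voxels.
#'
#' @param values 3D numeric array of SUV values (finite, non-negative).
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm.
#' @param origin numeric length-3, physical origin in mm.
#' @return `pet_volume()` returns an object of class `pet_volume`;
#'   `voi_mask()` an object of class `voi_mask`.
#' @examples
#' vol <- pet_volume(array(3, c(4, 4, 4)), spacing = c(2.73, 2.73, 3.27))
#' msk <- voi_mask(array(1, c(4, 4, 4)), spacing = c(2.73, 2.73, 3.27))
#' @export
pet_volume <- function(values, spacing = c(2.73, 2.73, 3.27),
                       origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("expected 3 dimensions, got ", length(dim(values)))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values))[1]
    stop("non-finite voxel at linear index ", bad,
         " (index ", paste(arrayInd(bad, dim(values)), collapse = ","), ")")
  }
  if (any(values < 0)) stop("negative SUV values are not allowed")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("spacing must be 3 positive values in mm")
  }
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "pet_volume")
}

#' @param mask 3D binary array (values 0/1).
#' @param check if `FALSE`, skip the single-component check (internal use).
#' @rdname pet_volume
#' @export
voi_mask <- function(mask, spacing = c(2.73, 2.73, 3.27), check = TRUE) {
  if (!is.array(mask) || length(dim(mask)) != 3) {
    stop("expected 3 dimensions, got ", length(dim(mask)))
  }
  m <- array(as.integer(round(mask)), dim(mask))
  if (max(abs(mask - m)) > 1e-6) stop("mask values must be binary (0/1)")
  if (!any(m != 0)) stop("empty mask")
  n_fg <- sum(m != 0)
  if (n_fg < 2) stop("mask must contain at least 2 foreground voxels")
  if (check) {
    nc <- count_components(m)
    if (nc != 1) stop(nc, " connected components (expected 1)")
  }
  structure(list(mask = m, spacing = as.numeric(spacing)),
            class = "voi_mask")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("PET volume:", paste(dim(x$values), collapse = " x "),
      "voxels, spacing", paste(format(x$spacing), collapse = " x "), "mm\n")
  cat("  SUV range [", format(min(x$values)), ",", format(max(x$values)),
      "]\n")
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("VOI mask:", sum(x$mask), "foreground voxels on a",
      paste(dim(x$mask), collapse = " x "), "grid\n")
  invisible(x)
}

# Assert that a mask and volume share grid and spacing.
check_pair <- function(volume, mask) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "voi_mask"))
  if (!identical(dim(volume$values), dim(mask$mask))) {
    stop("mask grid ", paste(dim(mask$mask), collapse = "x"),
         " does not match volume grid ",
         paste(dim(volume$values), collapse = "x"))
  }
  if (max(abs(volume$spacing - mask$spacing)) > 1e-9) {
    stop("mask spacing does not match volume spacing")
  }
  invisible(TRUE)
}

#' Read and write volumes and masks in NIfTI-1 format
#'
#' Volumes are stored as standard NIfTI-1 images (`.nii` / `.nii.gz`); voxel
#' spacing is carried in `pixdim`. `read_mask()` validates the image against
#' a reference volume and enforces the single-lesion mask invariants.
#'
#' @param path file path to a NIfTI image.
#' @return `read_volume()` a [pet_volume()]; `read_mask()` a [voi_mask()].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(pet_volume(array(3, c(4, 4, 4))), f)
#' v <- read_volume(f)
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(as.array(img)), dim = dim(img))
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) {
    stop("expected 3 dimensions, got ", length(dim(arr)))
  }
  hdr <- RNifti::niftiHeader(img)
  pet_volume(arr, spacing = RNifti::pixdim(img)[1:3],
             origin = c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
}

#' @param volume a [pet_volume()] to write.
#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param reference the [pet_volume()] the mask must align with.
#' @rdname read_volume
#' @export
read_mask <- function(path, reference) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(inherits(reference, "pet_volume"))
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(as.array(img)), dim = dim(img))
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) {
    stop("expected 3 dimensions, got ", length(dim(arr)))
  }
  if (!identical(dim(arr), dim(reference$values))) {
    stop("mask grid ", paste(dim(arr), collapse = "x"),
         " does not match reference grid ",
         paste(dim(reference$values), collapse = "x"))
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (max(abs(sp - reference$spacing)) > 1e-4) {
    stop("mask spacing does not match reference spacing")
  }
  voi_mask(arr, spacing = reference$spacing)
}

#' @param mask a [voi_mask()] to write.
#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voi_mask"))
  img <- RNifti::asNifti(mask$mask)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write cohort tables
#'
#' A cohort is a data frame with one row per patient: columns `patient_id`,
#' `ln_histology` (1 = nodal metastases at histology), `visual_detection`
#' (1 = PET-positive nodes at visual reading), `scanner_id`, plus optionally
#' one numeric column per extracted radiomic feature. Histology is the
#' reference standard against which every prediction mode is evaluated.
#'
#' @param path CSV file with a header row.
#' @return a `data.frame` of class `rad_cohort`, rows in file order.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_cohort(df)
}

#' @param cohort a cohort data frame.
#' @rdname read_cohort_table
#' @export
write_cohort_table <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_cohort_table
#' @param df a data frame with the required cohort columns.
#' @export
as_cohort <- function(df) {
  req <- c("patient_id", "ln_histology", "visual_detection", "scanner_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  dup <- unique(df$patient_id[duplicated(df$patient_id)])
  if (length(dup)) {
    stop("duplicate patient_id: ", paste(dup, collapse = ", "))
  }
  for (col in c("ln_histology", "visual_detection")) {
    bad <- which(!(df[[col]] %in% c(0, 1)))
    if (length(bad)) {
      stop("column ", col, " must be 0/1; offending row(s): ",
           paste(bad, collapse = ", "))
    }
    df[[col]] <- as.integer(df[[col]])
  }
  class(df) <- c("rad_cohort", "data.frame")
  df
}

# Names of the non-feature columns in a cohort table.
cohort_meta_cols <- function() {
  c("patient_id", "ln_histology", "visual_detection", "scanner_id")
}

#' Extracted feature columns of a cohort
#'
#' @param cohort a cohort data frame.
#' @return numeric matrix, one row per patient, one column per feature.
#' @export
cohort_features <- function(cohort) {
  feats <- setdiff(names(cohort), cohort_meta_cols())
  m <- as.matrix(as.data.frame(cohort)[, feats, drop = FALSE])
  rownames(m) <- cohort$patient_id
  m
}
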