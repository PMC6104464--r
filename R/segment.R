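#' Iterative-threshold tumour segmentation
#'
#' Delineates a tumour VOI from a PET volume by mask-mean-driven iterative
#' thresholding, a documented stand-in for clinical iterative contouring
#' tools (whose exact algorithms are proprietary). Starting from the
#' 26-connected component around `seed_point` above
#' `init_fraction * SUVmax`, the threshold is repeatedly reset to
#' `threshold_fraction` times the current in-mask mean SUV (background
#' corrected when `background_suv` is given:
#' `T = f * (mean - bg) + bg`), keeping the component containing the seed,
#' until the voxel set repeats. All downstream modules accept externally
#' supplied masks, so this stage is bypassable.
#'
#' @param volume a [pet_volume()].
#' @param seed_point integer voxel index `(i, j, k)` inside the lesion
#'   (SUV > 0 required).
#' @param config a [segmentation_config()].
#' @return a [voi_mask()]. If the iteration oscillates past
#'   `max_iterations`, the last mask is returned with attribute
#'   `converged = FALSE` and a warning.
#' @export
segment_tumour <- function(volume, seed_point, config = segmentation_config()) {
  stopifnot(inherits(volume, "pet_volume"), length(seed_point) == 3)
  d <- dim(volume$values)
  if (any(seed_point < 1) || any(seed_point > d)) {
    stop("seed_point outside the volume")
  }
  seed_lin <- seed_point[1] + (seed_point[2] - 1) * d[1] +
    (seed_point[3] - 1) * d[1] * d[2]
  if (volume$values[seed_lin] <= 0) {
    stop("seed_point has SUV <= 0; it must lie inside the lesion")
  }
  v <- volume$values
  threshold_for <- function(mask_arr) {
    m <- mean(v[mask_arr == 1L])
    if (!is.null(config$background_suv)) {
      config$threshold_fraction * (m - config$background_suv) +
        config$background_suv
    } else {
      config$threshold_fraction * m
    }
  }
  t0 <- min(config$init_fraction * max(v), v[seed_lin])
  cur <- component_containing(array(as.integer(v >= t0), d), seed_lin)
  if (!any(cur == 1L)) stop("empty mask at initialization")
  seen <- list()
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    thr <- threshold_for(cur)
    nxt <- component_containing(array(as.integer(v >= thr), d), seed_lin)
    if (!any(nxt == 1L)) stop("empty mask at iteration ", it)
    if (identical(nxt, cur)) {
      converged <- TRUE
      cur <- nxt
      break
    }
    key <- paste(which(nxt == 1L), collapse = ",")
    if (key %in% seen) {  # oscillation between states
      cur <- nxt
      break
    }
    seen[[length(seen) + 1]] <- key
    cur <- nxt
  }
  if (!converged) {
    warning("segmentation did not converge within ", config$max_iterations,
            " iterations; returning last mask")
  }
  out <- voi_mask(cur, spacing = volume$spacing)
  attr(out, "converged") <- converged
  out
}

#' @param threshold_fraction fraction of the current in-mask mean SUV used
#'   as the next threshold (default 0.42).
#' @param init_fraction fraction of the volume SUVmax for the initial mask
#'   (default 0.4).
#' @param max_iterations iteration cap.
#' @param background_suv optional background SUV for background-corrected
#'   thresholding.
#' @rdname segment_tumour
#' @export
segmentation_config <- function(threshold_fraction = 0.42,
                                init_fraction = 0.4,
                                max_iterations = 100,
                                background_suv = NULL) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1,
            init_fraction > 0, init_fraction < 1, max_iterations >= 1)
  structure(list(threshold_fraction = threshold_fraction,
                 init_fraction = init_fraction,
                 max_iterations = max_iterations,
                 background_suv = background_suv),
            class = "segmentation_config")
}
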