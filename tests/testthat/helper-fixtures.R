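# In-code fixtures shared across test files.

mk_vol <- function(arr, spacing = c(1, 1, 1)) {
  pet_volume(arr, spacing = spacing)
}

mk_mask <- function(arr, spacing = c(1, 1, 1)) {
  voi_mask(arr, spacing = spacing)
}

# A quantized VOI built directly from a 3D integer level array (0 = outside).
mk_quant <- function(levels, N = max(levels)) {
  structure(list(levels = array(as.integer(levels), dim(levels)),
                 N = as.integer(N), range = c(1, N)),
            class = "quantized_voi")
}

# Box volume+mask of given dims, constant value.
mk_box <- function(d, value = 5, spacing = c(1, 1, 1)) {
  list(volume = mk_vol(array(value, d), spacing),
       mask = mk_mask(array(1L, d), spacing))
}

# Volume+mask with prescribed in-mask values along a 1 x 1 x n line embedded
# in a zero background (mask is 26-connected by construction).
mk_line <- function(values, spacing = c(1, 1, 1)) {
  n <- length(values)
  arr <- array(0, c(n, 1, 1))
  arr[, 1, 1] <- values
  m <- array(0L, c(n, 1, 1))
  m[, 1, 1] <- 1L
  list(volume = mk_vol(arr, spacing), mask = mk_mask(m, spacing))
}

# Random single-component VOI inside a small grid with random levels in 1..N.
# Returns a quantized_voi. Used by the oracle fuzz suites.
random_quant <- function(dmax = 4, N = 4) {
  repeat {
    d <- c(sample(2:dmax, 1), sample(2:dmax, 1), sample(2:dmax, 1))
    m <- array(sample(0:1, prod(d), replace = TRUE, prob = c(0.4, 0.6)), d)
    if (sum(m) < 2) next
    lab <- petrad:::label_components(m)
    big <- which.max(tabulate(lab$labels))
    keep <- lab$voxels[lab$labels == big]
    if (length(keep) < 2) next
    m2 <- array(0L, d)
    m2[keep] <- 1L
    lev <- array(0L, d)
    lev[m2 == 1L] <- sample.int(N, sum(m2), replace = TRUE)
    return(mk_quant(lev, N))
  }
}

# Small labelled cohort with feature columns drawn from shifted normals.
mk_toy_cohort <- function(n = 30, n_pos = 10, sep = c(F1 = 3, F2 = 3),
                          noise_features = 0, seed = 1) {
  withr_seed <- function(code) petrad:::with_seed_local(seed, code)
  withr_seed({
    y <- rep(c(1L, 0L), c(n_pos, n - n_pos))
    df <- data.frame(patient_id = sprintf("p%02d", seq_len(n)),
                     ln_histology = y, visual_detection = 0L,
                     scanner_id = "s1", stringsAsFactors = FALSE)
    for (f in names(sep)) df[[f]] <- rnorm(n) + sep[[f]] * y
    if (noise_features > 0) {
      for (i in seq_len(noise_features)) {
        df[[paste0("N", i)]] <- rnorm(n)
      }
    }
    as_cohort(df)
  })
}
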