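test_that("SUV and volume features follow their definitions", {
  # 100-voxel mask (5x5x4) at PET spacing, constant SUV 5
  b <- mk_box(c(5, 5, 4), value = 5, spacing = c(2.73, 2.73, 3.27))
  f <- compute_suv_features(b$volume, b$mask)
  expect_equal(unname(f["MTV"]), 100 * 2.73^2 * 3.27 / 1000, tolerance = 1e-9)
  expect_equal(unname(f["SUVmean"]), 5)
  expect_equal(unname(f["TLG"]), unname(f["SUVmean"] * f["MTV"]),
               tolerance = 1e-12)
  expect_equal(round(unname(f["MTV"]), 4), 2.4371)

  l <- mk_line(c(2, 4, 6))
  f2 <- compute_suv_features(l$volume, l$mask)
  expect_equal(unname(f2["SUVmax"]), 6)
  expect_equal(unname(f2["SUVmean"]), 4)
})

test_that("TLG = SUVmean x MTV on arbitrary random VOIs", {
  set.seed(21)
  for (i in 1:20) {
    q <- random_quant(4, 4)
    vol <- pet_volume(array(runif(length(q$levels), 0, 30), dim(q$levels)),
                      spacing = runif(3, 1, 4))
    msk <- voi_mask(array(as.integer(q$levels > 0), dim(q$levels)),
                    spacing = vol$spacing)
    f <- compute_suv_features(vol, msk)
    expect_equal(unname(f["TLG"]), unname(f["SUVmean"] * f["MTV"]),
                 tolerance = 1e-9)
  }
})

test_that("histogram features match closed-form moments and conventions", {
  l <- mk_line(c(1, 1, 1, 5))
  f <- compute_histogram_features(l$volume, l$mask)
  expect_equal(unname(f["HIST_MEAN"]), 2)
  expect_equal(unname(f["HIST_SD"]), sqrt(3), tolerance = 1e-12)  # population
  expect_equal(unname(f["HIST_SKEWNESS"]), 2 / sqrt(3), tolerance = 1e-12)

  # constant VOI: degenerate conventions
  cst <- mk_box(c(3, 3, 3), value = 7)
  fc <- compute_histogram_features(cst$volume, cst$mask)
  expect_equal(unname(fc[c("HIST_SD", "HIST_SKEWNESS", "HIST_KURTOSIS",
                           "HIST_CV", "HIST_ENTROPY")]),
               rep(0, 5))
  expect_equal(unname(fc["HIST_UNIFORMITY"]), 1)

  # 64 voxels in 64 distinct bins: 6 bits, uniformity 1/64
  arr <- array(0, c(4, 4, 4))
  arr[] <- 0:63
  vol <- mk_vol(arr)
  msk <- mk_mask(array(1L, c(4, 4, 4)))
  fu <- compute_histogram_features(vol, msk, n_bins = 64)
  expect_equal(unname(fu["HIST_ENTROPY"]), 6)
  expect_equal(unname(fu["HIST_UNIFORMITY"]), 1 / 64)
})

test_that("quantization maps the in-VOI range onto 1..N", {
  vals <- c(0, 1.0, 32, 63.9)
  l <- mk_line(vals)
  q <- quantize(l$volume, l$mask, N = 64)
  lev <- q$levels[l$mask$mask == 1L]
  expect_identical(lev[1], 1L)   # minimum -> level 1
  expect_identical(lev[2], 2L)   # 1.0 on a [0, 63.9) span -> level 2
  expect_identical(lev[4], 64L)  # maximum clamps into level N

  cst <- mk_box(c(2, 2, 2), value = 3)
  qc <- quantize(cst$volume, cst$mask)
  expect_true(all(qc$levels[cst$mask$mask == 1L] == 1L))

  set.seed(5)
  for (i in 1:20) {
    q2 <- random_quant(4, 4)
    vol <- pet_volume(array(runif(length(q2$levels), 0, 9), dim(q2$levels)))
    msk <- voi_mask(array(as.integer(q2$levels > 0), dim(q2$levels)))
    qq <- quantize(vol, msk, N = 16)
    v <- vol$values[msk$mask == 1L]
    lv <- qq$levels[msk$mask == 1L]
    expect_identical(lv[which.min(v)], 1L)
    expect_identical(lv[which.max(v)], 16L)
    expect_true(all(lv >= 1 & lv <= 16))
  }
})

test_that("solidity is 1 on boxes and 8/9 on the notched slab", {
  expect_equal(unname(compute_shape_features(
    mk_mask(array(1L, c(3, 3, 3))))["SOLIDITY"]), 1)

  slab <- array(0L, c(3, 3, 1))
  slab[, , 1] <- 1L
  slab[1, 2, 1] <- 0L  # remove an edge-midpoint voxel
  f <- compute_shape_features(mk_mask(slab))
  expect_equal(unname(f["SOLIDITY"]), 8 / 9, tolerance = 1e-9)
})

test_that("solidity agrees with an independent point-in-hull oracle", {
  set.seed(31)
  for (i in 1:5) {
    # random blocky single-component mask
    m <- array(0L, c(5, 5, 4))
    m[2:4, 2:4, 2:3] <- 1L
    drop_n <- sample(3:6, 1)
    fg <- which(m == 1L)
    m[sample(fg, drop_n)] <- 0L
    lab <- petrad:::label_components(m)
    if (lab$n != 1 || length(lab$voxels) < 5) next
    sp <- c(1.2, 1, 0.8)
    sol <- compute_shape_features(voi_mask(m, spacing = sp))[["SOLIDITY"]]
    centers <- sweep(arrayInd(which(m == 1L), dim(m)) - 1, 2, sp, "*")
    if (qr(sweep(centers, 2, colMeans(centers)))$rank < 3) next
    grid <- as.matrix(expand.grid(1:5, 1:5, 1:4))
    qcent <- sweep(grid - 1, 2, sp, "*")
    n_hull <- sum(vapply(seq_len(nrow(qcent)), function(r) {
      oracle_in_hull(centers, qcent[r, ])
    }, logical(1)))
    expect_equal(sol, sum(m) / n_hull, tolerance = 1e-9)
  }
})

test_that("sphericity ranks a sphere above a matched lobulated lesion", {
  wins <- vapply(1:10, function(s) {
    sm <- generate_tumour(tumour_params(radius_mm = c(14, 14, 14),
                                        noise_sd = 0, psf_fwhm_mm = 0),
                          seed = s)
    lb <- generate_tumour(tumour_params(radius_mm = c(14, 14, 14),
                                        lobulation = 0.3, noise_sd = 0,
                                        psf_fwhm_mm = 0), seed = s)
    compute_shape_features(sm$mask)[["SPHERICITY"]] >
      compute_shape_features(lb$mask)[["SPHERICITY"]]
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("surface area and elongation are exact on analytic shapes", {
  f <- compute_shape_features(mk_mask(array(1L, c(3, 3, 3))))
  expect_equal(unname(f["SURFACE_AREA"]), 54)  # 6 faces x 9 unit squares
  expect_equal(unname(f["MAX_DIAMETER"]), 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(unname(f["ELONGATION"]), 1, tolerance = 1e-9)

  rod <- array(0L, c(9, 2, 2))
  rod[, 1:2, 1:2] <- 1L
  fr <- compute_shape_features(mk_mask(rod))
  expect_lt(unname(fr["ELONGATION"]), 0.5)
})

test_that("extract_features returns the frozen 44-feature roster, deterministically", {
  tm <- generate_tumour(tumour_params(radius_mm = c(10, 10, 10),
                                      necrotic_core = list(fraction = 0.3,
                                                           suv_ratio = 0.1),
                                      noise_sd = 0.5), seed = 2)
  f1 <- extract_features(tm$volume, tm$mask)
  f2 <- extract_features(tm$volume, tm$mask)
  expect_identical(names(f1), feature_names())
  expect_identical(f1, f2)
  expect_true(all(is.finite(f1)))
  expect_true(f1[["GLSZM_ZP"]] > 0 && f1[["GLSZM_ZP"]] <= 1)
  expect_true(f1[["SOLIDITY"]] > 0 && f1[["SOLIDITY"]] <= 1)
})

test_that("a wide-uptake-range lesion has lower GLSZM ZP than a matched narrow one", {
  zp <- vapply(1:20, function(s) {
    wide <- generate_tumour(tumour_params(radius_mm = c(15, 15, 15),
                                          necrotic_core = list(
                                            fraction = 0.3, suv_ratio = 0.1),
                                          hot_spots = list(
                                            count = 2, peak_suv_ratio = 2,
                                            radius_mm = 5),
                                          noise_sd = 0.5, psf_fwhm_mm = 9),
                            seed = s)
    narrow <- generate_tumour(tumour_params(radius_mm = c(15, 15, 15),
                                            noise_sd = 0.5, psf_fwhm_mm = 9),
                              seed = s)
    c(extract_features(wide$volume, wide$mask)[["GLSZM_ZP"]],
      extract_features(narrow$volume, narrow$mask)[["GLSZM_ZP"]])
  }, numeric(2))
  expect_lt(median(zp[1, ]), median(zp[2, ]))
})
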