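# ---- first-order ------------------------------------------------------------

test_that("constant VOI first-order degeneracies: zero entropy, zero sd", {
  vol <- tiny_volume(array(5, c(4, 4, 4)))
  m <- full_mask(c(4, 4, 4))
  fo <- first_order_features(vol, m)
  expect_equal(fo[["fo_entropy"]], 0)
  expect_equal(fo[["suv_sd"]], 0)
  expect_equal(fo[["suv_mean"]], fo[["suv_max"]])
})

test_that("equally occupied 64 levels give 6 bits of histogram entropy", {
  vals <- rep(seq(0, 63) + 0.5, each = 2) / 64
  vol <- volume_from_values(vals, c(8, 4, 4))
  fo <- first_order_features(vol, full_mask(c(8, 4, 4)))
  expect_equal(fo[["fo_entropy"]], 6)
  expect_equal(fo[["fo_uniformity"]], 1 / 64)
})

test_that("MATV and TLG follow from the voxel volume arithmetic", {
  # 100 voxels of 4.7 x 4.7 x 3.27 mm = 0.0722... ml each at SUVmean 5
  dims <- c(10, 5, 2)
  vol <- tiny_volume(array(5, dims), spacing = c(4.7, 4.7, 3.27))
  m <- voi_mask(array(TRUE, dims), spacing_mm = c(4.7, 4.7, 3.27))
  fo <- first_order_features(vol, m)
  vox_ml <- 4.7 * 4.7 * 3.27 / 1000
  expect_equal(fo[["matv_ml"]], 100 * vox_ml, tolerance = 1e-12)
  expect_equal(fo[["matv_ml"]], 7.22, tolerance = 1e-2)
  expect_equal(fo[["tlg"]], 5 * 100 * vox_ml, tolerance = 1e-12)
  expect_equal(fo[["tlg"]], 36.11, tolerance = 1e-2)
})

# ---- GLCM -------------------------------------------------------------------

test_that("constant VOI GLCM: entropy 0, homogeneity 1, dissimilarity 0", {
  vol <- tiny_volume(array(3, c(3, 3, 3)))
  q <- quantize_voi(vol, full_mask(c(3, 3, 3)))
  g <- glcm_features(q)
  expect_equal(g[["glcm_entropy"]], 0)
  expect_equal(g[["glcm_homogeneity"]], 1)
  expect_equal(g[["glcm_dissimilarity"]], 0)
  expect_equal(g[["glcm_energy"]], 1)
})

test_that("GLCM features match exhaustive pair enumeration on a 2x2x1 block", {
  lv <- array(NA_integer_, c(2, 2, 1))
  lv[, , 1] <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  mask <- !is.na(lv)
  q <- structure(list(levels = lv, mask = mask, n_bins = 2L,
                      calibration = c(0, 1), spacing_mm = c(1, 1, 1),
                      constant = FALSE), class = "quantized_voi")
  got <- glcm_features(q)
  want <- oracle_glcm_features(lv, mask, 2L)
  expect_equal(got, want[names(got)], tolerance = 1e-12)
})

test_that("direction-averaged GLCM features are 90-degree rotation invariant", {
  set.seed(5)
  dims <- c(5, 5, 5)
  vol <- tiny_volume(array(runif(125, 1, 9), dims))
  q1 <- quantize_voi(vol, full_mask(dims), n_bins = 8)
  rot <- aperm(vol$values, c(2, 1, 3))[dims[2]:1, , ]  # 90 deg about z
  q2 <- quantize_voi(tiny_volume(rot), full_mask(dims), n_bins = 8)
  expect_equal(glcm_features(q1), glcm_features(q2), tolerance = 1e-12)
})

# ---- GLRLM / GLSZM / NGTDM --------------------------------------------------

test_that("constant VOI higher-order degeneracies", {
  vol <- tiny_volume(array(2, c(4, 4, 4)))
  q <- quantize_voi(vol, full_mask(c(4, 4, 4)))
  ho <- higher_order_features(q)
  # a single 26-connected zone covering the VOI
  expect_equal(ho[["glszm_zone_percentage"]], 1 / 64)
  expect_equal(ho[["glszm_intensity_variability"]], 64^2)
  expect_equal(ho[["ngtdm_contrast"]], 0)
  expect_equal(ho[["ngtdm_coarseness"]], 1e6)  # capped reciprocal
})

test_that("GLSZM of the 4-voxel strip 1,1,2,2 follows the stated formula", {
  lv <- array(c(1L, 1L, 2L, 2L), c(4, 1, 1))
  q <- structure(list(levels = lv, mask = array(TRUE, c(4, 1, 1)),
                      n_bins = 2L, calibration = c(0, 1),
                      spacing_mm = c(1, 1, 1), constant = FALSE),
                 class = "quantized_voi")
  z <- glszm_features(q)
  # two zones of size 2 -> intensity variability (2^2 + 2^2) / 2 = 4
  expect_equal(z[["glszm_intensity_variability"]], 4)
  expect_equal(z[["glszm_zone_percentage"]], 2 / 4)
  expect_equal(z[["glszm_size_zone_variability"]], 4 / 2)
})

test_that("GLSZM zone sizes always sum to the voxel count", {
  for (s in 1:5) {
    set.seed(s)
    dims <- c(6, 6, 6)
    vol <- tiny_volume(array(runif(prod(dims), 1, 5), dims))
    mask <- array(runif(prod(dims)) < 0.7, dims)
    if (!any(mask)) next
    q <- quantize_voi(vol, voi_mask(mask, allow_empty = FALSE), n_bins = 4)
    zones <- petsegtex:::glszm_zones(q)
    expect_equal(sum(zones$size), sum(mask))
  }
})

test_that("GLRLM runs cover every voxel exactly once per direction", {
  set.seed(7)
  dims <- c(5, 5, 5)
  vol <- tiny_volume(array(runif(125, 1, 5), dims))
  q <- quantize_voi(vol, full_mask(dims), n_bins = 4)
  runs <- petsegtex:::runs_along(q, c(1, 0, 0))
  expect_equal(sum(runs$length), 125)
  runs_d <- petsegtex:::runs_along(q, c(1, 1, -1))
  expect_equal(sum(runs_d$length), 125)
})

# ---- fractal ----------------------------------------------------------------

test_that("box-counting dimension of a solid cube is close to 3", {
  dims <- c(64, 64, 64)
  vol <- tiny_volume(array(1, dims))
  fr <- fractal_features(vol, full_mask(dims))
  expect_gte(fr[["fractal_fd_mask"]], 2.8)
  expect_lte(fr[["fractal_fd_mask"]], 3.0 + 1e-6)
})

test_that("boundary dimension of a thin slab is close to 2", {
  dims <- c(32, 32, 9)
  m <- array(FALSE, dims); m[, , 4:7] <- TRUE   # 32 x 32 x 4 slab
  vol <- tiny_volume(array(1, dims))
  fr <- fractal_features(vol, voi_mask(m))
  expect_gte(fr[["fractal_fd_boundary"]], 1.8)
  expect_lte(fr[["fractal_fd_boundary"]], 2.2)
})

test_that("differential box-counting dimension ignores intensity scale", {
  set.seed(8)
  dims <- c(16, 16, 16)
  vol <- tiny_volume(array(runif(prod(dims), 1, 9), dims))
  f1 <- fractal_features(vol, full_mask(dims))
  f2 <- fractal_features(tiny_volume(vol$values * 12.5), full_mask(dims))
  expect_equal(f1[["fractal_fd_dbc"]], f2[["fractal_fd_dbc"]],
               tolerance = 1e-12)
})

# ---- panel assembly ---------------------------------------------------------

test_that("the panel always has 83 features in families 20/22/35/6", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 83)
  expect_equal(as.integer(table(reg$family)[c("first_order", "glcm",
                                              "higher_order", "fractal")]),
               c(20L, 22L, 35L, 6L))
  ph <- generate_phantom(phantom_config(seed = 21))
  fv <- extract_features(ph$volume, ph$truth)
  expect_equal(ncol(fv), 83)
  expect_identical(names(fv), reg$feature)
  expect_true(all(screen_features() %in% reg$feature))
})

test_that("features are translation invariant and out-of-mask independent", {
  set.seed(9)
  dims <- c(14, 14, 14)
  base <- array(2, dims)
  blob <- array(runif(5 * 5 * 5, 4, 9), c(5, 5, 5))
  v1 <- base; v1[3:7, 3:7, 3:7] <- blob
  m1 <- array(FALSE, dims); m1[3:7, 3:7, 3:7] <- TRUE
  v2 <- base; v2[8:12, 7:11, 6:10] <- blob
  m2 <- array(FALSE, dims); m2[8:12, 7:11, 6:10] <- TRUE
  f1 <- extract_features(tiny_volume(v1), voi_mask(m1))
  f2 <- extract_features(tiny_volume(v2), voi_mask(m2))
  expect_equal(unlist(f1), unlist(f2), tolerance = 1e-12)
  # altering voxels outside the mask changes nothing
  v3 <- v1; v3[!m1] <- runif(sum(!m1), 0, 50)
  f3 <- extract_features(tiny_volume(v3), voi_mask(m1))
  expect_equal(unlist(f1), unlist(f3), tolerance = 1e-12)
})

test_that("quantized families ignore affine intensity maps; SUV family scales", {
  set.seed(10)
  dims <- c(8, 8, 8)
  vol <- tiny_volume(array(runif(prod(dims), 2, 9), dims))
  f1 <- extract_features(vol, full_mask(dims))
  f2 <- extract_features(tiny_volume(vol$values * 2), full_mask(dims))
  for (f in c("fo_entropy", "glcm_entropy", "glcm_homogeneity",
              "glszm_intensity_variability", "ngtdm_coarseness"))
    expect_equal(f1[[f]], f2[[f]], tolerance = 1e-10)
  expect_equal(f2[["suv_mean"]], 2 * f1[["suv_mean"]])
  expect_equal(f2[["suv_sd"]], 2 * f1[["suv_sd"]])
  expect_equal(f2[["tlg"]], 2 * f1[["tlg"]])
  expect_equal(f2[["matv_ml"]], f1[["matv_ml"]])
})

test_that("a constant VOI still yields a complete 83-value row", {
  vol <- tiny_volume(array(4, c(6, 6, 6)))
  fv <- extract_features(vol, full_mask(c(6, 6, 6)))
  expect_equal(ncol(fv), 83)
  expect_equal(fv[["fo_entropy"]], 0)
  expect_equal(fv[["glcm_homogeneity"]], 1)
  expect_equal(fv[["ngtdm_coarseness"]], 1e6)
})
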