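test_that("5-voxel expansion of a point is the 515-voxel Euclidean ball", {
  m <- array(FALSE, c(15, 15, 15)); m[8, 8, 8] <- TRUE
  ex <- expand_mask(voi_mask(m), 5)
  # brute-force enumeration of offsets with squared distance <= 25
  offs <- as.matrix(expand.grid(-5:5, -5:5, -5:5))
  expect_equal(sum(ex$mask), sum(rowSums(offs^2) <= 25))
  expect_equal(sum(ex$mask), 515)
})

test_that("expansion by zero is the identity and corners clip safely", {
  m <- array(FALSE, c(6, 6, 6)); m[1, 1, 1] <- TRUE
  expect_identical(expand_mask(voi_mask(m), 0)$mask, m)
  ex <- expand_mask(voi_mask(m), 5)
  expect_equal(dim(ex$mask), c(6, 6, 6))
  expect_true(ex$mask[1, 1, 1])
  expect_false(ex$mask[6, 6, 6])
})

test_that("40P keeps exactly the voxels at or above 40% of the VOI max", {
  vals <- c(1, 3, 4, 5, 10)
  vol <- tiny_volume(array(c(vals, rep(0, 3)), c(2, 2, 2)))
  m <- array(FALSE, c(2, 2, 2)); m[1:5] <- TRUE
  seg <- segment_40p(vol, voi_mask(m, provenance = "expanded"))
  # threshold 4.0; >= keeps the boundary value 4 -> {4, 5, 10}
  expect_equal(sum(seg$mask$mask), 3)
  expect_setequal(vol$values[seg$mask$mask], c(4, 5, 10))
})

test_that("40P on a constant VOI keeps the whole VOI", {
  vol <- tiny_volume(array(5, c(4, 4, 4)))
  seg <- segment_40p(vol, full_mask(c(4, 4, 4)))
  expect_equal(sum(seg$mask$mask), 64)
})

test_that("40P is nested in the fraction and invariant to positive rescaling", {
  set.seed(1)
  vol <- tiny_volume(array(runif(125, 1, 10), c(5, 5, 5)))
  ex <- full_mask(c(5, 5, 5))
  m40 <- segment_40p(vol, ex, 0.4)$mask$mask
  m50 <- segment_40p(vol, ex, 0.5)$mask$mask
  expect_true(all(m50 <= m40))
  vol2 <- tiny_volume(vol$values * 7.3)
  expect_identical(segment_40p(vol2, ex, 0.4)$mask$mask, m40)
})

test_that("FLAB recovers three well-separated constant blocks", {
  bp <- block_phantom(nx = 12, m = c(1, 5, 10), noise_sd = 0.1, seed = 2)
  seg <- segment_flab(bp$volume, bp$mask)
  expect_true(all(abs(seg$class_means - c(1, 5, 10)) < 0.2))
  # mask should be exactly the 5- and 10-blocks
  want <- bp$labels >= 2
  agree <- mean(seg$mask$mask == want)
  expect_gte(agree, 0.99)
})

test_that("non-spatial FLAB labels match the pointwise posterior argmax", {
  # oracle: density-times-prior argmax at the converged parameters
  set.seed(4)
  n <- c(400, 300, 300)
  vals <- c(rnorm(n[1], 2, 0.3), rnorm(n[2], 5, 0.5), rnorm(n[3], 9, 0.8))
  vals <- pmax(sample(vals), 0)
  dims <- c(10, 10, 10)
  vol <- tiny_volume(array(vals, dims))
  seg <- segment_flab(vol, full_mask(dims),
                      flab_params(spatial_weight = 0))
  x <- as.vector(vol$values)  # VOI covers the full grid, column-major
  dens <- vapply(1:3, function(k)
    seg$class_priors[k] * dnorm(x, seg$class_means[k], seg$class_sds[k]),
    numeric(length(x)))
  oracle_keep <- max.col(dens) >= 2
  expect_equal(as.vector(seg$mask$mask), oracle_keep)
})

test_that("automatic masks are contained in the expanded VOI", {
  ph <- generate_phantom(phantom_config(seed = 12))
  fh <- simulate_reader_mask(ph$truth, reader_model(2.5, 6, 0, seed = 1))
  ex <- expand_mask(fh, 5)
  s40 <- segment_40p(ph$volume, ex)
  sfl <- suppressWarnings(segment_flab(ph$volume, ex))
  expect_true(all(s40$mask$mask <= ex$mask))
  expect_true(all(sfl$mask$mask <= ex$mask))
})

test_that("FLAB is deterministic for a fixed configuration", {
  ph <- generate_phantom(phantom_config(seed = 13))
  ex <- expand_mask(ph$truth, 5)
  a <- suppressWarnings(segment_flab(ph$volume, ex))
  b <- suppressWarnings(segment_flab(ph$volume, ex))
  expect_identical(a$mask$mask, b$mask$mask)
  expect_identical(a$class_means, b$class_means)
})

test_that("degenerate VOIs are rejected with informative errors", {
  vol <- tiny_volume(array(0, c(5, 5, 5)))
  expect_error(segment_40p(vol, full_mask(c(5, 5, 5))), "positive activity")
  vol2 <- tiny_volume(array(rep(c(1, 2), length.out = 125), c(5, 5, 5)))
  expect_error(segment_flab(vol2, full_mask(c(5, 5, 5))), "distinct")
})

test_that("median volumes order 40P <= FLAB <= positively biased freehand", {
  vols <- t(vapply(1:20, function(s) {
    set.seed(s)
    diam <- runif(1, 15, 60)
    cfg <- phantom_config(lesion_radii_mm = diam / 2 * runif(3, 0.8, 1.2),
                          tumour_suv_mean = runif(1, 5, 12), seed = s)
    ph <- generate_phantom(cfg)
    fh <- simulate_reader_mask(ph$truth, reader_model(2.5, 8, 0.05,
                                                      seed = s + 100))
    res <- suppressWarnings(segment_all(ph$volume, fh))
    vapply(res, function(x) x$volume_ml, numeric(1))
  }, numeric(3)))
  expect_lte(median(vols[, "40P"]), median(vols[, "FLAB"]))
  expect_lte(median(vols[, "FLAB"]), median(vols[, "FH"]))
  # the ordering also holds for a clear majority of individual lesions
  expect_gte(mean(vols[, "40P"] <= vols[, "FLAB"]), 0.7)
  expect_gte(mean(vols[, "FLAB"] <= vols[, "FH"]), 0.7)
})
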