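test_that("quantization maps the endpoints to levels 1 and n_bins", {
  vals <- seq(0, 1 - 1e-9, length.out = 64)
  vol <- volume_from_values(c(vals, rep(0.5, 64)), c(4, 4, 8))
  q <- quantize_voi(vol, full_mask(c(4, 4, 8)))
  lv <- q$levels[q$mask]
  x <- vol$values[q$mask]
  expect_equal(lv[which.min(x)], 1L)
  expect_equal(lv[which.max(x)], 64L)
  expect_true(all(lv >= 1 & lv <= 64))
})

test_that("quantized levels are invariant to positive affine rescaling", {
  set.seed(2)
  dims <- c(6, 6, 6)
  vol <- tiny_volume(array(runif(prod(dims), 1, 9), dims))
  q1 <- quantize_voi(vol, full_mask(dims))
  vol2 <- tiny_volume(vol$values * 3.7 + 11)
  q2 <- quantize_voi(vol2, full_mask(dims))
  expect_identical(q1$levels, q2$levels)
})

test_that("uniform intensities fill the 64 bins approximately uniformly", {
  set.seed(3)
  n <- 1e5
  dims <- c(50, 50, 40)
  vol <- tiny_volume(array(runif(prod(dims)), dims))
  q <- quantize_voi(vol, full_mask(dims))
  counts <- tabulate(q$levels[q$mask], nbins = 64)
  chi <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(chi$p.value, 0.01)
})

test_that("a constant VOI is flagged and collapses to level 1", {
  vol <- tiny_volume(array(4, c(4, 4, 4)))
  q <- quantize_voi(vol, full_mask(c(4, 4, 4)))
  expect_true(q$constant)
  expect_true(all(q$levels[q$mask] == 1L))
})
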