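test_that("noise-free homogeneous phantom is exactly two-level", {
  cfg <- phantom_config(heterogeneity_amplitude = 0, psf_fwhm_mm = 0,
                        noise_sigma_suv = 0, tumour_suv_mean = 8,
                        background_suv_mean = 2, seed = 1)
  ph <- generate_phantom(cfg)
  expect_true(all(ph$volume$values[ph$truth$mask] == 8))
  expect_true(all(ph$volume$values[!ph$truth$mask] == 2))
})

test_that("phantom generation is a pure function of its config", {
  cfg <- phantom_config(seed = 42)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$truth$mask, b$truth$mask)
})

test_that("generated activity is never negative", {
  for (s in 1:5) {
    cfg <- phantom_config(noise_sigma_suv = 2, background_suv_mean = 0.5,
                          tumour_suv_mean = 4, seed = s)
    ph <- generate_phantom(cfg)
    expect_true(all(ph$volume$values >= 0))
  }
})

test_that("most truth voxels stay above the 40% threshold despite blur", {
  # brute-force count on the generated array
  cfg <- phantom_config(tumour_suv_mean = 8, background_suv_mean = 2,
                        psf_fwhm_mm = 7, noise_sigma_suv = 0.2, seed = 5)
  ph <- generate_phantom(cfg)
  thr <- 0.4 * max(ph$volume$values)
  frac <- mean(ph$volume$values[ph$truth$mask] >= thr)
  expect_gte(frac, 0.5)
})

test_that("a lesion that violates the 5-voxel margin is rejected", {
  expect_error(phantom_config(grid_shape = c(10, 10, 10),
                              lesion_radii_mm = c(15, 15, 15)),
               "margin")
})

test_that("an unperturbed reader reproduces the truth mask exactly", {
  ph <- generate_phantom(phantom_config(seed = 2))
  rd <- reader_model(0, 0, 0, seed = 9)
  out <- simulate_reader_mask(ph$truth, rd)
  expect_identical(out$mask, ph$truth$mask)
})

test_that("a purely positive bias strictly dilates the truth", {
  ph <- generate_phantom(phantom_config(seed = 3))
  rd <- reader_model(0, 2 * 4.7, 0, seed = 9)  # +2 pixels equivalent
  out <- simulate_reader_mask(ph$truth, rd)
  expect_true(all(ph$truth$mask <= out$mask))
  expect_gt(sum(out$mask), sum(ph$truth$mask))
})

test_that("jittered readers give distinct masks that still overlap truth well", {
  ph <- generate_phantom(phantom_config(seed = 4))
  masks <- lapply(1:3, function(s)
    simulate_reader_mask(ph$truth, reader_model(1, 0, 0, seed = s)))
  jsis <- vapply(masks, function(m) {
    inter <- sum(m$mask & ph$truth$mask)
    100 * inter / sum(m$mask | ph$truth$mask)
  }, numeric(1))
  expect_gt(jsis[1], 60)
  expect_gt(jsis[2], 60)
  expect_gt(jsis[3], 60)
  expect_false(identical(masks[[1]]$mask, masks[[2]]$mask))
  expect_false(identical(masks[[2]]$mask, masks[[3]]$mask))
})

test_that("reader masks are 26-connected and deterministic under a seed", {
  ph <- generate_phantom(phantom_config(seed = 6))
  rd <- reader_model(2.5, 6, 0.05, seed = 77)
  a <- simulate_reader_mask(ph$truth, rd)
  b <- simulate_reader_mask(ph$truth, rd)
  expect_identical(a$mask, b$mask)
  lab <- petsegtex:::label_components26(a$mask)
  expect_equal(length(unique(lab[a$mask])), 1)
})

test_that("survival times are independent of the feature under a null effect", {
  ft <- tibble::tibble(patient_id = 1:500, fo_entropy = rnorm(500, 5, 1))
  sv <- simulate_survival(ft, log_hazard_coeff = 0, censor_rate = 0, seed = 8)
  kt <- suppressWarnings(
    stats::cor.test(ft$fo_entropy, sv$time_months, method = "kendall"))
  expect_gt(kt$p.value, 0.01)
})

test_that("zero censoring yields only observed events, all times positive", {
  ft <- tibble::tibble(patient_id = 1:50, fo_entropy = rnorm(50, 5, 1))
  sv <- simulate_survival(ft, censor_rate = 0, seed = 3)
  expect_true(all(sv$event))
  expect_true(all(sv$time_months > 0))
})

test_that("event proportion decreases as the censoring rate grows", {
  ft <- tibble::tibble(patient_id = 1:1000, fo_entropy = rnorm(1000, 5, 1))
  props <- vapply(c(0, 0.01, 0.05, 0.2), function(cr)
    mean(simulate_survival(ft, censor_rate = cr, seed = 5)$event), numeric(1))
  expect_true(all(diff(props) < 0))
})

test_that("a zero-variance driver feature is rejected", {
  ft <- tibble::tibble(patient_id = 1:20, fo_entropy = rep(3, 20))
  expect_error(simulate_survival(ft), "zero-variance")
})

test_that("Cox recovery: simulated effect sits inside the fit's 95% CI", {
  # scaled-down Monte-Carlo coverage check of the survival simulator
  hits <- vapply(1:20, function(r) {
    ft <- tibble::tibble(patient_id = 1:400,
                         fo_entropy = rnorm(400, 5, 1))
    sv <- simulate_survival(ft, log_hazard_coeff = 0.7,
                            censor_rate = 0.001, seed = 100 + r)
    d <- dplyr::inner_join(ft, sv, by = "patient_id")
    d$z <- scale(d$fo_entropy)[, 1]
    fit <- survival::coxph(survival::Surv(time_months, event) ~ z, data = d)
    ci <- stats::confint(fit)
    ci[1] <= 0.7 && 0.7 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
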