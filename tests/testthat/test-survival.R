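surv_data <- function(n, beta = 0, seed = 1, censor = 0.01) {
  set.seed(seed)
  x <- rnorm(n, 5, 1)
  lambda <- 0.03 * exp(beta * (x - mean(x)) / sd(x))
  t_ev <- rexp(n, lambda)
  t_c <- if (censor > 0) rexp(n, censor) else Inf
  tibble::tibble(patient_id = seq_len(n), f = x,
                 time_months = pmin(t_ev, t_c), event = t_ev <= t_c)
}

test_that("Cox coefficient matches grid-search partial likelihood to 1e-4", {
  # hand-made no-ties datasets, n = 6..8
  for (s in 1:5) {
    set.seed(s)
    n <- sample(6:8, 1)
    d <- tibble::tibble(
      patient_id = seq_len(n),
      f = c(rep(0, floor(n / 2)), rep(1, ceiling(n / 2))),
      time_months = sample(seq(1, 40, length.out = n)),
      event = TRUE)
    d10 <- dplyr::bind_rows(d, dplyr::mutate(d, patient_id = patient_id + n,
                                             time_months = time_months + 0.5,
                                             f = f + 0.01 * patient_id))
    fit <- cox_univariate(d10, "f")
    oracle <- oracle_cox_beta(d10$time_months, as.integer(d10$event), d10$f)
    expect_equal(fit$beta, oracle, tolerance = 1e-3)
  }
})

test_that("the partial likelihood is location invariant in the covariate", {
  d <- surv_data(60, beta = 0.5, seed = 2)
  f1 <- tidy(cox_univariate(d, "f"))
  d$f <- d$f + 100
  f2 <- tidy(cox_univariate(d, "f"))
  expect_equal(f1$hr, f2$hr, tolerance = 1e-8)
  expect_equal(f1$wald_p, f2$wald_p, tolerance = 1e-8)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
})

test_that("rescaling the covariate rescales beta but not p or AIC", {
  d <- surv_data(80, beta = 0.6, seed = 3)
  f1 <- cox_univariate(d, "f")
  d$f <- d$f * 4
  f2 <- cox_univariate(d, "f")
  expect_equal(f2$beta, f1$beta / 4, tolerance = 1e-6)
  expect_equal(f2$wald_p, f1$wald_p, tolerance = 1e-6)
  expect_equal(f2$aic, f1$aic, tolerance = 1e-6)
  expect_equal(exp(f2$beta_per_sd), exp(f1$beta_per_sd), tolerance = 1e-6)
})

test_that("AIC difference to the null model equals the LR statistic minus 2", {
  d <- surv_data(100, beta = 0.7, seed = 4)
  fit <- cox_univariate(d, "f")
  lr <- 2 * (fit$loglik[2] - fit$loglik[1])
  aic_null <- -2 * fit$loglik[1]
  expect_equal(aic_null - fit$aic, lr - 2, tolerance = 1e-8)
})

test_that("Wald p values are uniform under the null", {
  ps <- vapply(1:150, function(r) {
    d <- surv_data(300, beta = 0, seed = 1000 + r, censor = 0.005)
    cox_univariate(d, "f")$wald_p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate survival inputs are rejected", {
  d <- surv_data(50, seed = 5)
  d$f <- 3
  expect_error(cox_univariate(d, "f"), "zero-variance")
  d2 <- surv_data(50, seed = 6)
  d2$event <- FALSE
  expect_error(cox_univariate(d2, "f"), "events")
})

test_that("AIC bootstrap interval is seed-deterministic and stable", {
  d <- surv_data(80, beta = 0.4, seed = 7)
  ci1 <- aic_bootstrap_ci(d, "f", n_boot = 200, seed = 11)
  ci2 <- aic_bootstrap_ci(d, "f", n_boot = 200, seed = 11)
  expect_identical(ci1, ci2)
  fit <- cox_univariate(d, "f")
  ci_big <- aic_bootstrap_ci(d, "f", n_boot = 400, seed = 12)
  expect_lte(ci_big["lo"], fit$aic)
  expect_gte(ci_big["hi"], fit$aic)
})

test_that("the survival screen emits 12 features x all algorithms", {
  ft <- simulate_feature_table(60, seed = 8)
  sv <- simulate_survival(dplyr::filter(ft, algorithm == "FLAB"),
                          log_hazard_coeff = -0.7, seed = 9)
  scr <- run_survival_screen(ft, sv)
  expect_equal(nrow(scr), 12 * 3)
  expect_setequal(unique(scr$feature), screen_features())
  expect_setequal(unique(scr$algorithm), c("FH", "FLAB", "40P"))
  expect_true(all(c("hr", "wald_p", "aic", "significant",
                    "log_transformed") %in% names(scr)))
})

test_that("screen errors are propagated as flagged rows, never aborts", {
  ft <- simulate_feature_table(40, seed = 10)
  ft$matv_ml <- 7.5  # zero variance under every algorithm
  sv <- simulate_survival(dplyr::filter(ft, algorithm == "FLAB"),
                          driver_feature = "fo_entropy", seed = 11)
  scr <- run_survival_screen(ft, sv)
  bad <- dplyr::filter(scr, feature == "matv_ml")
  expect_true(all(!is.na(bad$error)))
  expect_true(all(is.na(bad$hr)))
  good <- dplyr::filter(scr, feature != "matv_ml")
  expect_true(all(is.na(good$error)))
})
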