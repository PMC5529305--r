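#' Univariate Cox proportional-hazards fit for one feature
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) for a single
#' covariate; reports the hazard ratio with Wald 95% CI and p value, and the
#' model AIC (`-2 logPL + 2` for the one estimated coefficient). Because HR
#' units depend on the feature's scale, the per-standard-deviation hazard
#' ratio is reported alongside the per-unit one.
#'
#' @param data Data frame holding the feature and survival columns, one row
#'   per patient.
#' @param feature Name of the covariate column.
#' @param time_col,event_col Names of the survival time (months) and event
#'   indicator (logical or 0/1) columns.
#' @return A `petx_cox_fit`; [tidy()] it for the screen row, [glance()] for
#'   fit-level statistics.
#' @export
cox_univariate <- function(data, feature, time_col = "time_months",
                           event_col = "event") {
  x <- data[[feature]]
  stopifnot(!is.null(x), length(x) >= 10)
  if (anyNA(x) || !all(is.finite(x))) stop("non-finite feature values")
  if (sd(x) == 0) stop("zero-variance feature: Cox fit undefined")
  if (sum(data[[event_col]]) < 3) stop("need at least 3 events")
  d <- data.frame(time = data[[time_col]], event = as.integer(data[[event_col]]),
                  x = x)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "efron")
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || se > 50 * max(1, abs(beta)) + 1e3)
    stop("monotone-likelihood separation: coefficient diverges")
  z <- qnorm(0.975)
  aic <- -2 * fit$loglik[2] + 2
  structure(list(fit = fit, feature = feature, beta = beta, se = se,
                 hr = exp(beta), hr_ci95 = exp(beta + c(-1, 1) * z * se),
                 wald_p = 2 * pnorm(-abs(beta / se)),
                 aic = aic, loglik = fit$loglik,
                 beta_per_sd = beta * sd(x),
                 n = nrow(d), n_events = sum(d$event)),
            class = "petx_cox_fit")
}

#' @export
print.petx_cox_fit <- function(x, ...) {
  cat("<petx_cox_fit> ", x$feature, ": HR ", signif(x$hr, 3), " (",
      signif(x$hr_ci95[1], 3), "-", signif(x$hr_ci95[2], 3), "), p = ",
      signif(x$wald_p, 3), ", AIC ", round(x$aic, 2), "\n", sep = "")
  invisible(x)
}

#' Tidy a univariate Cox fit into a screen row
#'
#' @param x A `petx_cox_fit`.
#' @param ... Unused.
#' @return One-row tibble: `feature`, `hr`, `hr_lo`, `hr_hi`, `hr_per_sd`,
#'   `wald_p`, `aic`, `n`, `n_events`.
#' @export
tidy.petx_cox_fit <- function(x, ...) {
  tibble::tibble(feature = x$feature, hr = x$hr,
                 hr_lo = x$hr_ci95[1], hr_hi = x$hr_ci95[2],
                 hr_per_sd = exp(x$beta_per_sd),
                 wald_p = x$wald_p, aic = x$aic,
                 n = x$n, n_events = x$n_events)
}

#' @export
#' @rdname tidy.petx_cox_fit
#' @param x A `petx_cox_fit`.
glance.petx_cox_fit <- function(x, ...) {
  tibble::tibble(logLik_null = x$loglik[1], logLik = x$loglik[2],
                 aic = x$aic, n = x$n, n_events = x$n_events)
}

#' Bootstrap confidence interval of a Cox model's AIC
#'
#' Patient-level resampling with replacement; the univariate model is refit
#' on each replicate and the percentile 2.5/97.5 quantiles of the replicate
#' AICs form the interval. Non-convergent replicates are redrawn (capped).
#'
#' @inheritParams cox_univariate
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @return Named numeric `c(lo, hi)`.
#' @export
aic_bootstrap_ci <- function(data, feature, time_col = "time_months",
                             event_col = "event", n_boot = 1000, seed = 1L) {
  set.seed(seed)
  n <- nrow(data)
  aics <- numeric(n_boot)
  draws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      draws <- draws + 1L
      if (draws > 10L * n_boot) stop("too many non-convergent replicates")
      idx <- sample.int(n, n, replace = TRUE)
      a <- tryCatch(cox_univariate(data[idx, , drop = FALSE], feature,
                                   time_col, event_col)$aic,
                    error = function(e) NA_real_)
      if (!is.na(a)) break
    }
    aics[b] <- a
  }
  q <- quantile(aics, c(0.025, 0.975), type = 7)
  c(lo = unname(q[1]), hi = unname(q[2]))
}

#' Univariate Cox screen of the 12 selected features per algorithm
#'
#' For each algorithm present in the feature table: the configured skewness
#' rule decides which of the screen features are log10-transformed (applied
#' consistently before fitting), then each feature is fit in its own
#' univariate Cox model against overall survival. Per-fit failures are
#' propagated as flagged rows; the screen never aborts.
#'
#' @param features Feature table keyed by `patient_id` and `algorithm` (one
#'   reader's dataset), wide.
#' @param survival_data Data frame `patient_id`, `time_months`, `event`.
#' @param feature_names The screened features; default [screen_features()].
#' @param skew_cutoff Passed to [select_log_transform()].
#' @param n_boot Bootstrap replicates for the AIC CI; 0 skips the interval.
#' @param seed Integer seed.
#' @return A tibble with one row per (algorithm, feature): the
#'   [tidy.petx_cox_fit()] columns plus `log_transformed`, `aic_lo`,
#'   `aic_hi`, `significant` (Wald p < 0.05) and `error` (message of a
#'   failed fit, `NA` otherwise).
#' @export
run_survival_screen <- function(features, survival_data,
                                feature_names = screen_features(),
                                skew_cutoff = 1.0, n_boot = 0, seed = 1L) {
  missing_f <- setdiff(feature_names, names(features))
  if (length(missing_f) > 0)
    stop("screen features absent from table: ",
         paste(missing_f, collapse = ", "))
  algos <- unique(features$algorithm)
  out <- list()
  for (alg in algos) {
    sub <- dplyr::filter(features, .data$algorithm == alg)
    sub <- dplyr::inner_join(sub, survival_data, by = "patient_id")
    tr <- suppressWarnings(
      select_log_transform(sub, feature_names, skew_cutoff = skew_cutoff))
    for (f in feature_names) {
      row <- tryCatch({
        cf <- cox_univariate(tr$data, f)
        r <- tidy(cf)
        if (n_boot > 0) {
          ci <- aic_bootstrap_ci(tr$data, f, n_boot = n_boot,
                                 seed = seed + match(f, feature_names))
          r$aic_lo <- ci["lo"]; r$aic_hi <- ci["hi"]
        } else {
          r$aic_lo <- NA_real_; r$aic_hi <- NA_real_
        }
        r$error <- NA_character_
        r
      }, error = function(e) {
        tibble::tibble(feature = f, hr = NA_real_, hr_lo = NA_real_,
                       hr_hi = NA_real_, hr_per_sd = NA_real_,
                       wald_p = NA_real_, aic = NA_real_,
                       n = nrow(tr$data), n_events = sum(tr$data$event),
                       aic_lo = NA_real_, aic_hi = NA_real_,
                       error = conditionMessage(e))
      })
      row$algorithm <- alg
      row$log_transformed <- f %in% tr$transformed
      out[[length(out) + 1L]] <- row
    }
  }
  dplyr::bind_rows(out) %>%
    dplyr::mutate(significant = !is.na(.data$wald_p) & .data$wald_p < 0.05) %>%
    dplyr::relocate("algorithm", "feature")
}
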