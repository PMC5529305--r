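#' Jaccard similarity index of two masks (percent)
#'
#' Voxel-by-voxel agreement: `100 * |A intersect B| / |A union B|`. 100 iff
#' the masks are identical, 0 iff disjoint.
#'
#' @param a,b Two [voi_mask()]s on the same grid, not both empty.
#' @return JSI in percent.
#' @export
#' @examples
#' m1 <- array(FALSE, c(4, 4, 4)); m1[1:2, 1:2, 1:2] <- TRUE
#' m2 <- array(FALSE, c(4, 4, 4)); m2[1:2, 1:2, 1] <- TRUE
#' jaccard_index(voi_mask(m1), voi_mask(m2))  # 50
jaccard_index <- function(a, b) {
  stopifnot(inherits(a, "voi_mask"), inherits(b, "voi_mask"))
  check_same_grid(a, b)
  uni <- sum(a$mask | b$mask)
  if (uni == 0) stop("both masks are empty: JSI undefined (0/0)")
  100 * sum(a$mask & b$mask) / uni
}

#' Pairwise JSI of a cohort's segmentations against a reference algorithm
#'
#' @param segmentations Named list of `petx_segmentation` lists (one per
#'   patient, as returned by [segment_all()]).
#' @param reference Reference algorithm (default `"FLAB"`).
#' @return A tibble `patient_id`, `algo_pair`, `jsi_percent`.
#' @export
jsi_table <- function(segmentations, reference = "FLAB") {
  purrr::imap_dfr(segmentations, function(segs, pid) {
    others <- setdiff(names(segs), reference)
    tibble::tibble(patient_id = pid,
                   algo_pair = paste(others, reference, sep = "/"),
                   jsi_percent = purrr::map_dbl(others, function(a)
                     jaccard_index(segs[[a]]$mask, segs[[reference]]$mask)))
  })
}

#' Compare two sets of JSI values (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test between two sets of percent-agreement
#' values; exact when both sets are small and tie-free, normal approximation
#' with tie correction otherwise.
#'
#' @param jsi1,jsi2 Numeric vectors of JSI percentages (non-empty).
#' @return One-row tibble with `u_statistic`, `p_value`, `n1`, `n2`,
#'   `median1`, `median2`.
#' @export
compare_jsi <- function(jsi1, jsi2) {
  stopifnot(length(jsi1) > 0, length(jsi2) > 0)
  wt <- suppressWarnings(wilcox.test(jsi1, jsi2, exact = NULL))
  tibble::tibble(u_statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 n1 = length(jsi1), n2 = length(jsi2),
                 median1 = median(jsi1), median2 = median(jsi2))
}

#' Regression of JSI on delineated volume
#'
#' Ordinary least squares of percent-agreement on tumour volume, used to ask
#' whether segmentation mismatch depends on lesion size.
#'
#' @param data Data frame with the volume and JSI columns.
#' @param volume_col,jsi_col Column names.
#' @return One-row tibble with `slope`, `intercept`, `r_squared`, `n`.
#' @export
jsi_volume_regression <- function(data, volume_col = "volume_ml",
                                  jsi_col = "jsi_percent") {
  v <- data[[volume_col]]
  j <- data[[jsi_col]]
  stopifnot(length(v) >= 3)
  if (sd(v) == 0) stop("zero-variance volumes: regression undefined")
  fit <- lm(j ~ v)
  r2 <- if (var(j) == 0) 0 else summary(fit)$r.squared
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 n = length(v))
}

#' Intraclass correlation coefficient for inter-reader agreement
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' (ICC(2,1)): readers are treated as a random sample of interchangeable
#' raters. ICC(3,1) (two-way mixed, consistency) is available via `type`.
#' The 95% CI is F-based. Bands follow the conventional cut-offs: high
#' (> 0.85), moderate (0.7-0.85), low (< 0.7).
#'
#' @param values Numeric matrix, subjects in rows, readers in columns
#'   (>= 3 subjects, >= 2 readers, no missing cells).
#' @param type `"ICC2"` (default, absolute agreement) or `"ICC3"`
#'   (consistency).
#' @param conf_level Confidence level of the interval.
#' @return A `petx_icc` object; see [tidy.petx_icc()].
#' @export
icc <- function(values, type = c("ICC2", "ICC3"), conf_level = 0.95) {
  type <- match.arg(type)
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  stopifnot(n >= 3, k >= 2)
  if (anyNA(values)) stop("ICC requires a complete subjects x readers matrix")
  if (var(as.vector(values)) == 0) stop("zero total variance: ICC undefined")
  d <- data.frame(y = as.vector(values),
                  subject = factor(rep(seq_len(n), times = k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(y ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  alpha <- 1 - conf_level
  if (type == "ICC2") {
    est <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    fl <- fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  }
  structure(list(icc = est, ci95 = c(lo = lo, hi = hi),
                 band = icc_band(est), type = type,
                 mean_squares = c(msr = msr, msc = msc, mse = mse),
                 n_subjects = n, n_raters = k, conf_level = conf_level),
            class = "petx_icc")
}

#' Reproducibility band of an ICC value
#'
#' @param x ICC value(s).
#' @return `"high"` (> 0.85), `"moderate"` (0.7-0.85) or `"low"` (< 0.7);
#'   the three bands tile the real line.
#' @export
icc_band <- function(x) {
  dplyr::case_when(x > 0.85 ~ "high",
                   x >= 0.7 ~ "moderate",
                   TRUE ~ "low")
}

#' @export
print.petx_icc <- function(x, ...) {
  cat("<petx_icc> ", x$type, " = ", signif(x$icc, 4), " [",
      signif(x$ci95[1], 4), ", ", signif(x$ci95[2], 4), "] (", x$band,
      ")\n", sep = "")
  invisible(x)
}

#' Tidy an ICC fit
#'
#' @param x A `petx_icc` from [icc()].
#' @param ... Unused.
#' @return One-row tibble: `icc`, `ci_lo`, `ci_hi`, `band`, `type`.
#' @export
tidy.petx_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_lo = unname(x$ci95[1]),
                 ci_hi = unname(x$ci95[2]), band = x$band, type = x$type)
}

#' Model-level summary of an ICC fit
#'
#' @param x A `petx_icc`.
#' @param ... Unused.
#' @return One-row tibble with the ANOVA mean squares and design size.
#' @export
glance.petx_icc <- function(x, ...) {
  tibble::tibble(ms_subjects = unname(x$mean_squares["msr"]),
                 ms_raters = unname(x$mean_squares["msc"]),
                 ms_error = unname(x$mean_squares["mse"]),
                 n_subjects = x$n_subjects, n_raters = x$n_raters)
}

# subjects x readers matrix of one feature under one algorithm
feature_matrix <- function(features, feature, algorithm) {
  sub <- dplyr::filter(features, .data$algorithm == !!algorithm)
  wide <- tidyr::pivot_wider(sub[, c("patient_id", "reader_id", feature)],
                             names_from = "reader_id",
                             values_from = dplyr::all_of(feature))
  as.matrix(wide[, -1])
}

#' Per-feature, per-algorithm ICC table
#'
#' Computes the inter-reader ICC of every feature under every algorithm in a
#' feature table, with CI and reproducibility band.
#'
#' @param features Feature table keyed by `patient_id`, `reader_id`,
#'   `algorithm` (wide, one column per feature).
#' @param feature_names Features to assess; default every registry feature
#'   present.
#' @param type ICC form, see [icc()].
#' @return A tibble `feature`, `algorithm`, `icc`, `ci_lo`, `ci_hi`, `band`.
#'   Features whose ICC is undefined on this table (zero variance) are
#'   returned as `NA` with band `"low"`.
#' @export
icc_table <- function(features, feature_names = NULL, type = "ICC2") {
  if (is.null(feature_names))
    feature_names <- intersect(feature_registry()$feature, names(features))
  algos <- unique(features$algorithm)
  tidyr::expand_grid(feature = feature_names, algorithm = algos) %>%
    dplyr::mutate(purrr::map2_dfr(.data$feature, .data$algorithm,
                                  function(f, a) {
      m <- feature_matrix(features, f, a)
      res <- tryCatch(tidy(icc(m, type = type))[, c("icc", "ci_lo", "ci_hi")],
                      error = function(e)
                        tibble::tibble(icc = NA_real_, ci_lo = NA_real_,
                                       ci_hi = NA_real_))
      res
    })) %>%
    dplyr::mutate(band = ifelse(is.na(.data$icc), "low", icc_band(.data$icc)))
}

#' Bootstrap comparison of two algorithms' ICC for one feature
#'
#' Resamples patients with replacement — the same resample applied to both
#' algorithms, preserving the pairing — recomputes both ICCs per replicate,
#' and forms the percentile 95% CI of the ICC difference. The difference is
#' flagged significant when the interval excludes zero. Degenerate
#' (zero-variance) resamples are redrawn, up to `10 * n_boot` draws.
#'
#' @param features Feature table as in [icc_table()].
#' @param feature Feature name.
#' @param algo_a,algo_b The two algorithms (difference is `a - b`).
#' @param n_boot Bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @param type ICC form.
#' @return One-row tibble: `feature`, `algo_pair`, `delta_icc` (point
#'   estimate), `ci_lo`, `ci_hi`, `significant`, `n_boot`, `seed`.
#' @export
icc_diff_bootstrap <- function(features, feature, algo_a, algo_b,
                               n_boot = 100, seed = 1L, type = "ICC2") {
  ma <- feature_matrix(features, feature, algo_a)
  mb <- feature_matrix(features, feature, algo_b)
  stopifnot(nrow(ma) == nrow(mb))
  n <- nrow(ma)
  point <- icc(ma, type = type)$icc - icc(mb, type = type)$icc
  set.seed(seed)
  deltas <- numeric(n_boot)
  draws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      draws <- draws + 1L
      if (draws > 10L * n_boot)
        stop("too many degenerate bootstrap resamples")
      idx <- sample.int(n, n, replace = TRUE)
      d <- tryCatch(icc(ma[idx, , drop = FALSE], type = type)$icc -
                      icc(mb[idx, , drop = FALSE], type = type)$icc,
                    error = function(e) NA_real_)
      if (!is.na(d)) break
    }
    deltas[b] <- d
  }
  ci <- unname(quantile(deltas, c(0.025, 0.975), type = 7))
  tibble::tibble(feature = feature,
                 algo_pair = paste(algo_a, algo_b, sep = "-"),
                 delta_icc = point, ci_lo = ci[1], ci_hi = ci[2],
                 significant = ci[1] > 0 | ci[2] < 0,
                 n_boot = n_boot, seed = seed)
}

#' Log10-transform skewed features
#'
#' Reproducible replacement for visual Q-Q screening: any feature whose
#' sample skewness exceeds `skew_cutoff` is log10-transformed. Features with
#' nonpositive values are never transformed (skipped with a warning),
#' whatever their skewness.
#'
#' @param features Wide feature table.
#' @param feature_names Candidate columns; default every registry feature
#'   present.
#' @param skew_cutoff Skewness threshold (default 1.0).
#' @return List with `data` (transformed table) and `transformed` (character
#'   vector of the columns that were log10-transformed).
#' @export
select_log_transform <- function(features, feature_names = NULL,
                                 skew_cutoff = 1.0) {
  if (is.null(feature_names))
    feature_names <- intersect(feature_registry()$feature, names(features))
  transformed <- character(0)
  for (f in feature_names) {
    x <- features[[f]]
    if (anyNA(x) || sd(x) == 0) next
    sk <- e1071::skewness(x, type = 2)
    if (is.na(sk) || sk <= skew_cutoff) next
    if (min(x) <= 0) {
      warning("feature `", f, "` is skewed but has nonpositive values; ",
              "log10 transform skipped")
      next
    }
    features[[f]] <- log10(x)
    transformed <- c(transformed, f)
  }
  list(data = features, transformed = transformed)
}
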