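#' First-order (histogram and SUV) features
#'
#' Twenty features of the in-mask intensity distribution: raw-SUV summary
#' statistics, volume measures (MATV in ml; TLG = SUVmean x MATV), and
#' histogram measures (entropy, uniformity) computed on the quantized-level
#' histogram.
#'
#' Degenerate constant VOIs give entropy 0, sd 0, skewness/kurtosis 0.
#'
#' @param volume A [pet_volume()].
#' @param mask A non-empty [voi_mask()].
#' @param q The matching [quantize_voi()] result (recomputed when omitted).
#' @return Named numeric vector of the 20 first-order features.
#' @export
first_order_features <- function(volume, mask, q = NULL) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "voi_mask"))
  if (is.null(q)) q <- quantize_voi(volume, mask)
  x <- volume$values[mask$mask]
  n <- length(x)
  vox_ml <- prod(mask$spacing_mm) / 1000
  m <- mean(x)
  s <- sd(x)
  cm <- x - m
  m2 <- mean(cm^2)
  skew <- if (m2 > 0) mean(cm^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean(cm^4) / m2^2 else 0
  p <- tabulate(q$levels[q$mask], nbins = q$n_bins)
  p <- p / sum(p)
  p_nz <- p[p > 0]
  c(suv_min = min(x),
    suv_max = max(x),
    suv_mean = m,
    suv_median = median(x),
    suv_sd = if (n > 1) s else 0,
    suv_variance = if (n > 1) s^2 else 0,
    suv_skewness = skew,
    suv_kurtosis = kurt,
    suv_energy = sum(x^2),
    fo_entropy = -sum(p_nz * log2(p_nz)),
    fo_uniformity = sum(p^2),
    suv_range = max(x) - min(x),
    suv_mad = mean(abs(cm)),
    suv_rms = sqrt(mean(x^2)),
    suv_p10 = unname(quantile(x, 0.10)),
    suv_p90 = unname(quantile(x, 0.90)),
    suv_iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)),
    suv_cov = if (m != 0) (if (n > 1) s else 0) / m else 0,
    matv_ml = n * vox_ml,
    tlg = m * n * vox_ml)
}
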