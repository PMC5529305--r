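#' The frozen 83-feature registry
#'
#' The texture panel consists of exactly 83 named features in four families:
#' 20 first-order, 22 second-order (GLCM), 35 higher-order (16 GLRLM + 14
#' GLSZM + 5 NGTDM) and 6 model-based (fractal). The family totals are fixed
#' by design; the member rosters are this package's documented completion of
#' those totals, since no universal roster exists.
#'
#' @return A tibble with columns `feature` and `family`
#'   (`first_order`, `glcm`, `higher_order`, `fractal`).
#' @export
#' @examples
#' dplyr::count(feature_registry(), family)
feature_registry <- function() {
  fo <- c("suv_min", "suv_max", "suv_mean", "suv_median", "suv_sd",
          "suv_variance", "suv_skewness", "suv_kurtosis", "suv_energy",
          "fo_entropy", "fo_uniformity", "suv_range", "suv_mad", "suv_rms",
          "suv_p10", "suv_p90", "suv_iqr", "suv_cov", "matv_ml", "tlg")
  glcm <- c("glcm_autocorrelation", "glcm_cluster_prominence",
            "glcm_cluster_shade", "glcm_cluster_tendency", "glcm_contrast",
            "glcm_correlation", "glcm_difference_average",
            "glcm_difference_entropy", "glcm_difference_variance",
            "glcm_dissimilarity", "glcm_energy", "glcm_entropy",
            "glcm_homogeneity", "glcm_idm", "glcm_idmn", "glcm_idn",
            "glcm_imc1", "glcm_imc2", "glcm_inverse_variance",
            "glcm_max_probability", "glcm_sum_average", "glcm_sum_entropy")
  ho <- c("glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_glnn", "glrlm_rln",
          "glrlm_rlnn", "glrlm_rp", "glrlm_glv", "glrlm_rv", "glrlm_re",
          "glrlm_lglre", "glrlm_hglre", "glrlm_srlgle", "glrlm_srhgle",
          "glrlm_lrlgle", "glrlm_lrhgle",
          "glszm_intensity_variability", "glszm_size_zone_variability",
          "glszm_zone_percentage", "glszm_small_area_emphasis",
          "glszm_large_area_emphasis", "glszm_low_gl_emphasis",
          "glszm_high_gl_emphasis", "glszm_small_area_low_gl",
          "glszm_small_area_high_gl", "glszm_large_area_low_gl",
          "glszm_large_area_high_gl", "glszm_gl_variance",
          "glszm_zone_variance", "glszm_zone_entropy",
          "ngtdm_coarseness", "ngtdm_contrast", "ngtdm_busyness",
          "ngtdm_complexity", "ngtdm_strength")
  fr <- c("fractal_fd_mask", "fractal_fd_boundary", "fractal_fd_dbc",
          "fractal_lacunarity_mean", "fractal_lacunarity_slope",
          "fractal_lacunarity_2")
  tibble::tibble(
    feature = c(fo, glcm, ho, fr),
    family = rep(c("first_order", "glcm", "higher_order", "fractal"),
                 times = c(length(fo), length(glcm), length(ho), length(fr))))
}

#' The 12 survival-screen features
#'
#' The commonly reported subset used for the univariate Cox screen: MATV,
#' TLG, SUVmean, SUVmax, SUV standard deviation, first-order entropy, GLCM
#' entropy / homogeneity / dissimilarity, GLSZM intensity variability, and
#' NGTDM coarseness and contrast.
#'
#' @return Character vector of 12 registry feature names.
#' @export
screen_features <- function() {
  c("matv_ml", "tlg", "suv_mean", "suv_max", "suv_sd", "fo_entropy",
    "glcm_entropy", "glcm_homogeneity", "glcm_dissimilarity",
    "glszm_intensity_variability", "ngtdm_coarseness", "ngtdm_contrast")
}

#' Extract the full 83-feature panel from one VOI
#'
#' Quantizes the VOI to `n_bins` grey levels and computes all four feature
#' families, asserting the 20/22/35/6 family counts before returning.
#' Degenerate inputs propagate as `NA` values for the affected family; no
#' column is ever dropped.
#'
#' @param volume A [pet_volume()].
#' @param mask A non-empty [voi_mask()] on the same grid.
#' @param n_bins Grey levels for quantization (default 64).
#' @param patient_id,reader_id,algorithm Optional identifiers carried into
#'   the output row.
#' @return A one-row tibble: identifier columns (when given) followed by the
#'   83 feature columns in registry order.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_config(seed = 3))
#' fv <- extract_features(ph$volume, ph$truth)
#' ncol(fv)  # 83
extract_features <- function(volume, mask, n_bins = 64, patient_id = NULL,
                             reader_id = NULL, algorithm = NULL) {
  q <- quantize_voi(volume, mask, n_bins = n_bins)
  fo <- first_order_features(volume, mask, q)
  g2 <- glcm_features(q)
  ho <- higher_order_features(q)
  fr <- fractal_features(volume, mask)
  stopifnot(length(fo) == 20, length(g2) == 22, length(ho) == 35,
            length(fr) == 6)
  vals <- c(fo, g2, ho, fr)
  reg <- feature_registry()
  stopifnot(identical(names(vals), reg$feature), length(vals) == 83)
  out <- tibble::as_tibble(as.list(vals))
  ids <- tibble::tibble(.rows = 1)
  if (!is.null(patient_id)) ids$patient_id <- patient_id
  if (!is.null(reader_id)) ids$reader_id <- reader_id
  if (!is.null(algorithm)) ids$algorithm <- algorithm
  dplyr::bind_cols(ids, out)
}
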