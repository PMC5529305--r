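#' Simulate a phantom cohort with multiple readers
#'
#' Draws `n_patients` lesions spanning the configured diameter range, builds
#' each phantom, and has each reader of the panel contour it. Per-patient
#' seeds are derived deterministically from the cohort seed (`seed + index`),
#' so the cohort is a pure function of its arguments.
#'
#' @param n_patients Number of patients.
#' @param seed Cohort seed.
#' @param readers Named list of [reader_model()]s; default [default_readers()].
#' @param lesion_diameter_range_mm Range (mm) from which each lesion's mean
#'   diameter is drawn uniformly; default 15-60 mm.
#' @param tumour_suv_range Range of the tumour mean SUV, drawn uniformly.
#' @param background_suv_mean,heterogeneity_amplitude,psf_fwhm_mm,noise_sigma_suv
#'   Passed to [phantom_config()].
#' @param voxel_spacing_mm Grid spacing.
#' @return A tibble with one row per patient: `patient_id`, `config`,
#'   `volume`, `truth` (list-columns) and `readers` (named list of freehand
#'   [voi_mask()]s per row).
#' @export
simulate_cohort <- function(n_patients, seed = 1L,
                            readers = default_readers(seed = seed),
                            lesion_diameter_range_mm = c(15, 60),
                            tumour_suv_range = c(5, 12),
                            background_suv_mean = 2,
                            heterogeneity_amplitude = 1.5,
                            psf_fwhm_mm = 7,
                            noise_sigma_suv = 0.3,
                            voxel_spacing_mm = c(4.7, 4.7, 3.27)) {
  stopifnot(n_patients >= 1)
  rows <- purrr::map(seq_len(n_patients), function(i) {
    pseed <- as.integer(seed + i)
    set.seed(pseed)
    diam <- runif(1, lesion_diameter_range_mm[1], lesion_diameter_range_mm[2])
    radii <- diam / 2 * runif(3, 0.8, 1.2)   # mild anisotropy
    suv <- runif(1, tumour_suv_range[1], tumour_suv_range[2])
    cfg <- phantom_config(voxel_spacing_mm = voxel_spacing_mm,
                          lesion_radii_mm = radii,
                          tumour_suv_mean = suv,
                          background_suv_mean = background_suv_mean,
                          heterogeneity_amplitude = heterogeneity_amplitude,
                          psf_fwhm_mm = psf_fwhm_mm,
                          noise_sigma_suv = noise_sigma_suv,
                          seed = pseed)
    ph <- generate_phantom(cfg)
    rmasks <- purrr::imap(readers, function(r, nm) {
      r$seed <- as.integer(r$seed + 1000L * i)
      simulate_reader_mask(ph$truth, r)
    })
    list(patient_id = sprintf("P%03d", i), config = cfg,
         volume = ph$volume, truth = ph$truth, readers = rmasks)
  })
  tibble::tibble(patient_id = purrr::map_chr(rows, "patient_id"),
                 config = purrr::map(rows, "config"),
                 volume = purrr::map(rows, "volume"),
                 truth = purrr::map(rows, "truth"),
                 readers = purrr::map(rows, "readers"))
}

#' Run the three segmentation algorithms on one freehand VOI
#'
#' Freehand ingestion, then 5-voxel expansion feeding the 40%-of-maximum
#' threshold and the three-class Bayesian segmenter.
#'
#' @param volume A [pet_volume()].
#' @param fh The reader's freehand [voi_mask()].
#' @param expand_voxels Expansion radius fed to the automatic algorithms.
#' @param fraction Threshold fraction of [segment_40p()].
#' @param flab A [flab_params()].
#' @return Named list of `petx_segmentation` results: `FH`, `40P`, `FLAB`.
#' @export
segment_all <- function(volume, fh, expand_voxels = 5, fraction = 0.40,
                        flab = flab_params()) {
  expanded <- expand_mask(fh, expand_voxels)
  list(FH = segment_freehand(fh),
       `40P` = segment_40p(volume, expanded, fraction = fraction),
       FLAB = segment_flab(volume, expanded, params = flab))
}

#' Extract the feature table of a simulated cohort
#'
#' For every (patient, reader, algorithm) cell: segment the reader's
#' freehand VOI with all three algorithms and extract the 83-feature panel.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param n_bins Grey levels for quantization.
#' @param expand_voxels,fraction,flab Segmentation settings, see
#'   [segment_all()].
#' @return A list with `features` (tibble keyed by `patient_id`, `reader_id`,
#'   `algorithm`, one column per registry feature) and `segmentations`
#'   (tibble of per-cell delineated volumes in ml).
#' @export
cohort_features <- function(cohort, n_bins = 64, expand_voxels = 5,
                            fraction = 0.40, flab = flab_params()) {
  feats <- list(); segs <- list()
  for (i in seq_len(nrow(cohort))) {
    vol <- cohort$volume[[i]]
    for (rd in names(cohort$readers[[i]])) {
      res <- segment_all(vol, cohort$readers[[i]][[rd]],
                         expand_voxels = expand_voxels, fraction = fraction,
                         flab = flab)
      for (alg in names(res)) {
        feats[[length(feats) + 1L]] <-
          extract_features(vol, res[[alg]]$mask, n_bins = n_bins,
                           patient_id = cohort$patient_id[i],
                           reader_id = rd, algorithm = alg)
        segs[[length(segs) + 1L]] <-
          dplyr::mutate(tidy(res[[alg]]),
                        patient_id = cohort$patient_id[i], reader_id = rd,
                        .before = 1)
      }
    }
  }
  list(features = dplyr::bind_rows(feats),
       segmentations = dplyr::bind_rows(segs))
}

#' Simulate a feature table statistically (no images)
#'
#' Draws a plausible per-patient table of the 12 survival-screen features
#' directly from a latent-trait model: a lognormal lesion size (driving MATV
#' and TLG), a positive uptake level (driving the SUV statistics) and a
#' heterogeneity trait (driving the entropy/texture features), replicated
#' across algorithms with algorithm-specific measurement noise. Used for
#' power and calibration experiments on the Cox screen, where image-based
#' extraction at hundreds of patients would be gratuitous.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed.
#' @param algorithms Algorithm labels replicated per patient.
#' @param algo_noise_sd Between-algorithm measurement noise, in units of each
#'   feature's patient-level standard deviation.
#' @return A tibble keyed by `patient_id`, `algorithm` with the 12 screen
#'   feature columns.
#' @export
simulate_feature_table <- function(n_patients, seed = 1L,
                                   algorithms = c("FH", "FLAB", "40P"),
                                   algo_noise_sd = 0.15) {
  set.seed(seed)
  n <- n_patients
  size <- rnorm(n)         # latent lesion size
  uptake <- rnorm(n)       # latent uptake level
  het <- rnorm(n)          # latent heterogeneity
  base <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    matv_ml = exp(2.5 + 0.8 * size),
    suv_mean = 6 + 1.5 * uptake + 0.3 * size,
    suv_max = 9 + 2.2 * uptake + 0.8 * het,
    suv_sd = exp(0.3 + 0.4 * het + 0.2 * uptake),
    fo_entropy = 4.5 + 0.6 * het + 0.2 * size,
    glcm_entropy = 7 + 0.8 * het + 0.2 * size,
    glcm_homogeneity = plogis(0.5 - 0.5 * het),
    glcm_dissimilarity = exp(1 + 0.5 * het),
    glszm_intensity_variability = exp(3 + 0.9 * size + 0.3 * het),
    ngtdm_coarseness = exp(-2 - 0.7 * size - 0.3 * het),
    ngtdm_contrast = exp(-1 + 0.6 * het))
  base$tlg <- base$matv_ml * base$suv_mean
  base <- base[, c("patient_id", screen_features())]
  purrr::map_dfr(algorithms, function(alg) {
    out <- base
    for (f in screen_features()) {
      s <- sd(base[[f]])
      out[[f]] <- base[[f]] + rnorm(n, sd = algo_noise_sd * s)
      if (min(base[[f]]) > 0) out[[f]] <- pmax(out[[f]], 1e-6)
    }
    dplyr::mutate(out, algorithm = alg, .after = "patient_id")
  })
}
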