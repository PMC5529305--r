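#' Experiment configuration
#'
#' One object controlling the full comparison experiment: cohort simulation,
#' per-reader segmentation with the three algorithms, feature extraction,
#' reproducibility reporting and the survival screen. With a fixed
#' `seed` every stage is deterministic.
#'
#' @param n_patients Cohort size (default 50).
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory; `NULL` disables file output.
#' @param n_bins Grey levels for quantization.
#' @param expand_voxels Freehand expansion radius.
#' @param fraction 40P threshold fraction.
#' @param flab [flab_params()] of the Bayesian segmenter.
#' @param lesion_diameter_range_mm,tumour_suv_range,background_suv_mean,heterogeneity_amplitude,psf_fwhm_mm,noise_sigma_suv,voxel_spacing_mm
#'   Cohort generator settings, see [simulate_cohort()].
#' @param reader_jitter_mm Contour jitter of the three-reader panel.
#' @param primary_reader Reader whose dataset feeds JSI and survival
#'   analyses (the "single most experienced observer" dataset).
#' @param jsi_reference Reference algorithm of the JSI comparison.
#' @param icc_n_boot Bootstrap resamples for pairwise ICC differences.
#' @param icc_diff_features Features compared across algorithms by bootstrap;
#'   default the 12 screen features.
#' @param survival_driver,survival_coeff,survival_baseline_hazard,survival_censor_rate
#'   Survival simulator settings, see [simulate_survival()].
#' @param aic_n_boot Bootstrap replicates of the AIC CIs in the screen
#'   (0 skips them).
#' @param write_nifti Write per-patient volumes and masks as NIfTI-1.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_patients = 50, seed = 1L, out_dir = NULL,
                              n_bins = 64, expand_voxels = 5, fraction = 0.40,
                              flab = flab_params(),
                              lesion_diameter_range_mm = c(15, 60),
                              tumour_suv_range = c(5, 12),
                              background_suv_mean = 2,
                              heterogeneity_amplitude = 1.5,
                              psf_fwhm_mm = 7,
                              noise_sigma_suv = 0.3,
                              voxel_spacing_mm = c(4.7, 4.7, 3.27),
                              reader_jitter_mm = 2.5,
                              primary_reader = "A",
                              jsi_reference = "FLAB",
                              icc_n_boot = 100,
                              icc_diff_features = screen_features(),
                              survival_driver = "fo_entropy",
                              survival_coeff = -0.7,
                              survival_baseline_hazard = 0.03,
                              survival_censor_rate = 0.01,
                              aic_n_boot = 0,
                              write_nifti = !is.null(out_dir)) {
  cfg <- as.list(environment())
  structure(cfg, class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Any field of [experiment_config()] can appear as a top-level YAML key;
#' `flab` may be a mapping of [flab_params()] fields.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$flab)) y$flab <- do.call(flab_params, y$flab)
  do.call(experiment_config, y)
}

#' Run the full comparison experiment
#'
#' Simulates the cohort, segments every (patient, reader) freehand VOI with
#' the three algorithms, extracts the 83-feature panel, computes the JSI
#' overlap report against the reference algorithm, the per-feature ICC table
#' with bootstrap pairwise differences, and the univariate Cox screen on
#' survival simulated from the primary reader's features. If `out_dir` is
#' set, each report is written as CSV (and masks as NIfTI when
#' `write_nifti`). A stage failure keeps already-written outputs and raises
#' an error naming the stage.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress the per-patient progress log.
#' @return A list: `cohort_manifest`, `features`, `segmentations`,
#'   `jsi`, `jsi_summary`, `jsi_test`, `jsi_regression`, `icc`,
#'   `icc_diff`, `survival_data`, `survival_screen`, `config`.
#' @export
run_experiment <- function(config = experiment_config(), quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("experiment stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  readers <- default_readers(spacing_mm = config$voxel_spacing_mm,
                             jitter_mm = config$reader_jitter_mm,
                             seed = config$seed)
  cohort <- stage("simulate", simulate_cohort(
    config$n_patients, seed = config$seed, readers = readers,
    lesion_diameter_range_mm = config$lesion_diameter_range_mm,
    tumour_suv_range = config$tumour_suv_range,
    background_suv_mean = config$background_suv_mean,
    heterogeneity_amplitude = config$heterogeneity_amplitude,
    psf_fwhm_mm = config$psf_fwhm_mm,
    noise_sigma_suv = config$noise_sigma_suv,
    voxel_spacing_mm = config$voxel_spacing_mm))

  feats <- list(); segs <- list(); ref_masks <- list()
  manifest <- list()
  stage("segment_features", for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    vol <- cohort$volume[[i]]
    paths <- list(volume_path = NA_character_)
    if (!is.null(out_dir) && config$write_nifti) {
      paths$volume_path <- file.path(out_dir, paste0(pid, ".nii.gz"))
      write_nifti_volume(vol, paths$volume_path)
      write_nifti_volume(cohort$truth[[i]],
                         file.path(out_dir, paste0(pid, "_truth.nii.gz")))
    }
    for (rd in names(cohort$readers[[i]])) {
      t0 <- Sys.time()
      res <- segment_all(vol, cohort$readers[[i]][[rd]],
                         expand_voxels = config$expand_voxels,
                         fraction = config$fraction, flab = config$flab)
      if (!is.null(out_dir) && config$write_nifti) {
        mp <- file.path(out_dir, sprintf("%s_reader%s.nii.gz", pid, rd))
        write_nifti_volume(cohort$readers[[i]][[rd]], mp)
        paths[[paste0("mask_reader", rd)]] <- mp
        for (alg in names(res))
          write_nifti_volume(res[[alg]]$mask,
            file.path(out_dir, sprintf("%s_reader%s_%s.nii.gz", pid, rd, alg)))
      }
      if (rd == config$primary_reader) ref_masks[[pid]] <- res
      for (alg in names(res)) {
        feats[[length(feats) + 1L]] <-
          extract_features(vol, res[[alg]]$mask, n_bins = config$n_bins,
                           patient_id = pid, reader_id = rd, algorithm = alg)
        segs[[length(segs) + 1L]] <- dplyr::mutate(
          tidy(res[[alg]]), patient_id = pid, reader_id = rd, .before = 1)
        if (!quiet)
          message(sprintf("[%s reader %s %-4s] %5d voxels %7.2f ml %5.2fs",
                          pid, rd, alg, sum(res[[alg]]$mask$mask),
                          res[[alg]]$volume_ml,
                          as.numeric(Sys.time() - t0, units = "secs")))
      }
    }
    manifest[[i]] <- tibble::as_tibble(paths[!vapply(paths, is.null, TRUE)])
  })
  features <- dplyr::bind_rows(feats)
  segmentations <- dplyr::bind_rows(segs)

  jsi <- stage("jsi", jsi_table(ref_masks, reference = config$jsi_reference))
  jsi_summary <- jsi %>%
    dplyr::group_by(.data$algo_pair) %>%
    dplyr::summarise(mean_jsi = mean(.data$jsi_percent),
                     sd_jsi = sd(.data$jsi_percent),
                     min_jsi = min(.data$jsi_percent),
                     max_jsi = max(.data$jsi_percent), n = dplyr::n())
  pairs <- unique(jsi$algo_pair)
  jsi_test <- if (length(pairs) == 2)
    compare_jsi(jsi$jsi_percent[jsi$algo_pair == pairs[1]],
                jsi$jsi_percent[jsi$algo_pair == pairs[2]]) else NULL
  ref_vol <- segmentations %>%
    dplyr::filter(.data$reader_id == config$primary_reader,
                  .data$algorithm == config$jsi_reference) %>%
    dplyr::select("patient_id", "volume_ml")
  jsi_regression <- jsi %>%
    dplyr::inner_join(ref_vol, by = "patient_id") %>%
    dplyr::group_by(.data$algo_pair) %>%
    dplyr::group_modify(~ jsi_volume_regression(.x)) %>%
    dplyr::ungroup()

  transformed <- stage("log_transform", select_log_transform(features))
  icc_report <- stage("icc", icc_table(transformed$data))
  algos <- unique(features$algorithm)
  icc_diff <- stage("icc_boot", purrr::map_dfr(
    utils::combn(algos, 2, simplify = FALSE), function(pr)
      purrr::map_dfr(config$icc_diff_features, function(f)
        icc_diff_bootstrap(transformed$data, f, pr[1], pr[2],
                           n_boot = config$icc_n_boot,
                           seed = config$seed + 101L))))

  primary <- features %>%
    dplyr::filter(.data$reader_id == config$primary_reader)
  driver_tab <- primary %>%
    dplyr::filter(.data$algorithm == config$jsi_reference)
  survival_data <- stage("simulate_survival", simulate_survival(
    driver_tab, driver_feature = config$survival_driver,
    log_hazard_coeff = config$survival_coeff,
    baseline_hazard = config$survival_baseline_hazard,
    censor_rate = config$survival_censor_rate,
    seed = config$seed + 202L))
  screen <- stage("survival_screen", run_survival_screen(
    primary, survival_data, n_boot = config$aic_n_boot,
    seed = config$seed + 303L))

  result <- list(cohort_manifest = dplyr::bind_cols(
                   tibble::tibble(patient_id = cohort$patient_id),
                   dplyr::bind_rows(manifest)),
                 features = features, segmentations = segmentations,
                 jsi = jsi, jsi_summary = jsi_summary, jsi_test = jsi_test,
                 jsi_regression = jsi_regression,
                 icc = icc_report, icc_diff = icc_diff,
                 survival_data = survival_data, survival_screen = screen,
                 config = config)
  if (!is.null(out_dir)) {
    wr <- function(x, f) if (!is.null(x))
      readr::write_csv(x, file.path(out_dir, f))
    wr(result$cohort_manifest, "manifest.csv")
    wr(features, "features.csv")
    wr(segmentations, "segmentations.csv")
    wr(jsi, "jsi.csv")
    wr(jsi_summary, "jsi_summary.csv")
    wr(jsi_regression, "jsi_regression.csv")
    wr(icc_report, "icc_report.csv")
    wr(icc_diff, "icc_diff.csv")
    wr(survival_data, "survival.csv")
    wr(screen, "survival_screen.csv")
    writeLines(experiment_summary_text(result),
               file.path(out_dir, "summary.txt"))
  }
  result
}

# human-readable comparison of the three algorithms
experiment_summary_text <- function(result) {
  med <- result$icc %>%
    dplyr::group_by(.data$algorithm) %>%
    dplyr::summarise(median_icc = median(.data$icc, na.rm = TRUE)) %>%
    dplyr::arrange(dplyr::desc(.data$median_icc))
  vols <- result$segmentations %>%
    dplyr::group_by(.data$algorithm) %>%
    dplyr::summarise(median_ml = median(.data$volume_ml))
  nsig <- result$survival_screen %>%
    dplyr::group_by(.data$algorithm) %>%
    dplyr::summarise(n_significant = sum(.data$significant))
  c(sprintf("Cohort: %d patients, %d readers, seed %d",
            result$config$n_patients, 3, result$config$seed),
    "",
    "Median delineated volume (ml) per algorithm:",
    sprintf("  %-5s %8.2f", vols$algorithm, vols$median_ml),
    "",
    "Median inter-reader ICC across the 83-feature panel:",
    sprintf("  %-5s %6.3f", med$algorithm, med$median_icc),
    "",
    sprintf("Mean JSI vs %s:", result$config$jsi_reference),
    sprintf("  %-9s %6.1f%% (sd %4.1f)", result$jsi_summary$algo_pair,
            result$jsi_summary$mean_jsi, result$jsi_summary$sd_jsi),
    "",
    "Significant survival features (Wald p < 0.05) per algorithm:",
    sprintf("  %-5s %d", nsig$algorithm, nsig$n_significant))
}
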