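#' Phantom configuration
#'
#' Parameters of a synthetic focal-uptake PET phantom: an ellipsoidal lesion
#' of elevated SUV on a low-uptake background, with a within-tumour correlated
#' Gaussian heterogeneity field, Gaussian point-spread blur emulating
#' partial-volume averaging, and additive reconstruction-style noise.
#'
#' Defaults follow the scale of locally advanced NSCLC primaries imaged on a
#' clinical PET grid (4.7 x 4.7 mm pixels, 3.27 mm slices): lesion diameters
#' of 15-60 mm, tumour SUV well above a ~2 SUV mediastinal/lung background,
#' and a ~7 mm FWHM reconstructed resolution.
#'
#' @param grid_shape Integer length-3, voxels per axis. `NULL` sizes the grid
#'   automatically to the lesion plus a 5-voxel margin and blur padding.
#' @param voxel_spacing_mm Numeric length-3 spacing (mm).
#' @param lesion_center Voxel coordinates of the lesion centre; `NULL` centres
#'   it on the grid.
#' @param lesion_radii_mm Ellipsoid semi-axes (mm).
#' @param tumour_suv_mean,background_suv_mean Mean SUV inside / outside the
#'   lesion; tumour must exceed background and both must be positive.
#' @param heterogeneity_amplitude SUV standard deviation of the within-tumour
#'   Gaussian random field (0 = homogeneous lesion).
#' @param heterogeneity_corr_len_mm Correlation length of that field (mm).
#' @param psf_fwhm_mm Full width at half maximum of the Gaussian point-spread
#'   function (mm); 0 disables blurring.
#' @param noise_sigma_suv Standard deviation of additive Gaussian noise (SUV),
#'   applied after blurring and clipped at zero activity.
#' @param seed Integer seed; the phantom is a pure function of its config.
#'
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = NULL,
                           voxel_spacing_mm = c(4.7, 4.7, 3.27),
                           lesion_center = NULL,
                           lesion_radii_mm = c(15, 15, 15),
                           tumour_suv_mean = 8,
                           background_suv_mean = 2,
                           heterogeneity_amplitude = 1.5,
                           heterogeneity_corr_len_mm = 8,
                           psf_fwhm_mm = 7,
                           noise_sigma_suv = 0.3,
                           seed = 1L) {
  stopifnot(length(voxel_spacing_mm) == 3, length(lesion_radii_mm) == 3)
  if (!(tumour_suv_mean > background_suv_mean && background_suv_mean > 0))
    stop("need tumour_suv_mean > background_suv_mean > 0")
  if (any(lesion_radii_mm <= 0)) stop("lesion radii must be > 0")
  margin_vox <- 5
  pad_vox <- ceiling(3 * (psf_fwhm_mm / 2.3548) / voxel_spacing_mm)
  need <- 2 * (ceiling(lesion_radii_mm / voxel_spacing_mm) + margin_vox +
                 pad_vox) + 1
  if (is.null(grid_shape)) grid_shape <- need
  grid_shape <- as.integer(grid_shape)
  if (is.null(lesion_center)) lesion_center <- (grid_shape + 1) / 2
  r_vox <- lesion_radii_mm / voxel_spacing_mm
  if (any(lesion_center - r_vox < 1 + margin_vox) ||
      any(lesion_center + r_vox > grid_shape - margin_vox))
    stop("lesion does not fit inside the grid with a 5-voxel margin")
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = voxel_spacing_mm,
                 lesion_center = lesion_center,
                 lesion_radii_mm = lesion_radii_mm,
                 tumour_suv_mean = tumour_suv_mean,
                 background_suv_mean = background_suv_mean,
                 heterogeneity_amplitude = heterogeneity_amplitude,
                 heterogeneity_corr_len_mm = heterogeneity_corr_len_mm,
                 psf_fwhm_mm = psf_fwhm_mm,
                 noise_sigma_suv = noise_sigma_suv,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

voxel_coords <- function(dims) {
  list(x = array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dims),
       y = array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]), dims),
       z = array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims))
}

#' Generate a PET phantom
#'
#' Builds `background + ellipsoidal lesion (+ correlated heterogeneity
#' field inside the lesion)`, convolves with the Gaussian PSF, adds Gaussian
#' noise and clips at zero. The truth mask is the pre-blur ellipsoid support,
#' so the partial-volume effect of the PSF on boundary voxels is visible to
#' downstream segmenters exactly as it would be on a reconstructed image.
#'
#' @param config A [phantom_config()].
#' @return A list with elements `volume` ([pet_volume()]) and `truth`
#'   ([voi_mask()] with provenance `"truth"`).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_config(seed = 7))
#' ph$volume
#' ph$truth
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$grid_shape
  sp <- config$voxel_spacing_mm
  co <- voxel_coords(dims)
  inside <- ((co$x - config$lesion_center[1]) * sp[1] / config$lesion_radii_mm[1])^2 +
    ((co$y - config$lesion_center[2]) * sp[2] / config$lesion_radii_mm[2])^2 +
    ((co$z - config$lesion_center[3]) * sp[3] / config$lesion_radii_mm[3])^2 <= 1
  img <- array(config$background_suv_mean, dims)
  img[inside] <- config$tumour_suv_mean
  withr_seed <- config$seed
  set.seed(withr_seed)
  if (config$heterogeneity_amplitude > 0) {
    field <- array(rnorm(prod(dims)), dims)
    field <- gaussian_blur3d(field, config$heterogeneity_corr_len_mm / sp)
    s <- sd(field)
    if (s > 0) field <- field / s * config$heterogeneity_amplitude
    img[inside] <- img[inside] + field[inside]
  }
  if (config$psf_fwhm_mm > 0)
    img <- gaussian_blur3d(img, (config$psf_fwhm_mm / 2.3548) / sp)
  if (config$noise_sigma_suv > 0)
    img <- img + array(rnorm(prod(dims), sd = config$noise_sigma_suv), dims)
  img[img < 0] <- 0
  list(volume = pet_volume(img, spacing_mm = sp),
       truth = voi_mask(inside, spacing_mm = sp, provenance = "truth"))
}

#' Reader model
#'
#' A stochastic model of one human reader drawing freehand axial contours
#' around the lesion: smooth per-slice radial jitter, a systematic in-plane
#' over- or under-contouring bias, and occasional omission of the marginal
#' (first/last) slices where uptake is faint.
#'
#' @param boundary_jitter_mm Scale (mm) of the smooth radial contour
#'   perturbation per slice; must be >= 0.
#' @param dilation_bias_mm Signed systematic radial offset (mm): positive
#'   readers over-contour, negative readers under-contour.
#' @param slice_dropout_prob Probability that each marginal slice is omitted.
#' @param seed Integer seed.
#' @return A `reader_model` list.
#' @export
reader_model <- function(boundary_jitter_mm = 1,
                         dilation_bias_mm = 0,
                         slice_dropout_prob = 0.1,
                         seed = 1L) {
  stopifnot(boundary_jitter_mm >= 0,
            slice_dropout_prob >= 0, slice_dropout_prob < 1)
  structure(list(boundary_jitter_mm = boundary_jitter_mm,
                 dilation_bias_mm = dilation_bias_mm,
                 slice_dropout_prob = slice_dropout_prob,
                 seed = as.integer(seed)),
            class = "reader_model")
}

#' Default three-reader panel
#'
#' All three readers contour the *apparent* lesion — the blurred halo that
#' extends roughly half the PSF FWHM beyond the true edge — so their margins
#' are all positive, centred near +6 mm (half-FWHM halo plus about one
#' display pixel) with a +5/+6/+8 mm spread and 2.5 mm contour jitter
#' (around half a display pixel of slice-wise wobble). This puts the
#' freehand delineations outside the automatic ones on average and yields
#' moderate freehand inter-reader ICCs alongside high ICCs for the
#' semi-automatic algorithms, the regime reported for freehand PET
#' delineation panels.
#'
#' @param spacing_mm Grid spacing (kept for interface symmetry).
#' @param jitter_mm Contour jitter shared by the three readers.
#' @param seed Base seed; readers get `seed`, `seed + 1`, `seed + 2`.
#' @return Named list of three [reader_model()]s (A, B, C); A (the median
#'   margin) is the conventional primary reader.
#' @export
default_readers <- function(spacing_mm = c(4.7, 4.7, 3.27), jitter_mm = 2.5,
                            seed = 1L) {
  list(A = reader_model(jitter_mm, 6, 0.05, seed = seed),
       B = reader_model(jitter_mm, 8, 0.05, seed = seed + 1L),
       C = reader_model(jitter_mm, 5, 0.05, seed = seed + 2L))
}

# smooth periodic radial perturbation: low-order random Fourier series,
# approximately unit variance
periodic_noise <- function(theta, n_harmonics = 3) {
  g <- numeric(length(theta))
  for (k in seq_len(n_harmonics)) {
    g <- g + rnorm(1) * cos(k * theta) + rnorm(1) * sin(k * theta)
  }
  g / sqrt(n_harmonics)
}

perturb_slice <- function(slice, delta_fun, spacing_xy, n_bins = 16) {
  idx <- which(slice, arr.ind = TRUE)
  if (nrow(idx) == 0) return(slice)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  dims <- dim(slice)
  gx <- rep(seq_len(dims[1]), times = dims[2])
  gy <- rep(seq_len(dims[2]), each = dims[1])
  r <- sqrt(((gx - cx) * spacing_xy[1])^2 + ((gy - cy) * spacing_xy[2])^2)
  th <- atan2((gy - cy) * spacing_xy[2], (gx - cx) * spacing_xy[1])
  bin <- pmin(n_bins, 1L + as.integer(floor((th + pi) / (2 * pi) * n_bins)))
  inside <- as.vector(slice)
  # per-bin boundary radius of the current contour (max in-mask radius)
  Rb <- rep(0, n_bins)
  tb <- tapply(r[inside], bin[inside], max)
  Rb[as.integer(names(tb))] <- tb
  mid <- (-pi + (seq_len(n_bins) - 0.5) * 2 * pi / n_bins)
  delta <- delta_fun(mid)            # mm, per bin
  if (all(delta == 0)) return(slice) # exact identity when unperturbed
  dvox <- delta[bin]
  keep <- inside & (r <= Rb[bin] + pmin(dvox, 0) + 1e-9)
  add <- (!inside) & (r <= Rb[bin] + dvox) & (Rb[bin] > 0)
  array(keep | add, dims)
}

#' Simulate a reader's freehand mask
#'
#' Applies the reader model slice by slice to a truth mask: the axial contour
#' is perturbed radially by `dilation_bias_mm + boundary_jitter_mm * g(theta)`
#' with `g` a smooth periodic noise, and marginal slices are dropped with the
#' configured probability. The result is restricted to its largest
#' 26-connected component. If the perturbation empties the mask the draw is
#' retried with halved jitter, up to 3 attempts.
#'
#' @param truth A non-empty [voi_mask()].
#' @param reader A [reader_model()].
#' @return A [voi_mask()] with provenance `"freehand"`.
#' @export
simulate_reader_mask <- function(truth, reader) {
  stopifnot(inherits(truth, "voi_mask"), inherits(reader, "reader_model"))
  if (!any(truth$mask)) stop("truth mask is empty")
  jitter <- reader$boundary_jitter_mm
  for (attempt in 1:3) {
    set.seed(reader$seed + (attempt - 1L) * 7919L)
    out <- truth$mask
    # an over-contouring reader traces the blurred halo in 3D: positive bias
    # is a physical (mm) dilation, so marginal slices with faint uptake are
    # included too; under-contouring stays an in-plane radial retraction
    b_inplane <- reader$dilation_bias_mm
    if (reader$dilation_bias_mm > 0) {
      out <- dilate_mm(out, reader$dilation_bias_mm, truth$spacing_mm)
      b_inplane <- 0
    }
    zs <- which(apply(out, 3, any))
    for (z in zs) {
      j <- jitter
      b <- b_inplane
      out[, , z] <- perturb_slice(out[, , z], function(th) {
        if (j == 0 && b == 0) rep(0, length(th))
        else b + j * periodic_noise(th)
      }, truth$spacing_mm[1:2])
    }
    if (reader$slice_dropout_prob > 0 && length(zs) > 2) {
      if (runif(1) < reader$slice_dropout_prob) out[, , zs[1]] <- FALSE
      if (runif(1) < reader$slice_dropout_prob) out[, , zs[length(zs)]] <- FALSE
    }
    out <- largest_component26(out)
    if (any(out)) {
      return(voi_mask(out, spacing_mm = truth$spacing_mm,
                      provenance = "freehand"))
    }
    jitter <- jitter / 2
  }
  stop("reader perturbation emptied the mask after 3 attempts")
}

# anisotropic Euclidean dilation by a physical radius (mm)
dilate_mm <- function(mask, radius_mm, spacing_mm) {
  dims <- dim(mask)
  rv <- floor(radius_mm / spacing_mm)
  offs <- as.matrix(expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2],
                                dz = -rv[3]:rv[3]))
  d2 <- (offs[, 1] * spacing_mm[1])^2 + (offs[, 2] * spacing_mm[2])^2 +
    (offs[, 3] * spacing_mm[3])^2
  offs <- offs[d2 <= radius_mm^2 & rowSums(abs(offs)) > 0, , drop = FALSE]
  out <- mask
  for (i in seq_len(nrow(offs))) {
    s <- offset_slabs(dims, offs[i, ])
    out[s[[1]]$to, s[[2]]$to, s[[3]]$to] <-
      out[s[[1]]$to, s[[2]]$to, s[[3]]$to] |
      mask[s[[1]]$from, s[[2]]$from, s[[3]]$from, drop = FALSE]
  }
  out
}

# keep the largest 26-connected component of a logical array
largest_component26 <- function(mask) {
  n_in <- sum(mask)
  if (n_in == 0) return(mask)
  lab <- label_components26(mask)
  tab <- tabulate(lab[mask])
  keep <- which.max(tab)
  mask & (lab == keep)
}

# 26-connected component labelling via igraph on the in-mask voxel graph
label_components26 <- function(mask) {
  dims <- dim(mask)
  id <- array(0L, dims)
  id[mask] <- seq_len(sum(mask))
  edges <- list()
  for (i in seq_len(nrow(offsets13()))) {
    off <- offsets13()[i, ]
    p <- shifted_pairs(id, off)
    ok <- p$a > 0L & p$b > 0L
    if (any(ok)) edges[[length(edges) + 1L]] <- cbind(p$a[ok], p$b[ok])
  }
  g <- igraph::make_empty_graph(n = sum(mask), directed = FALSE)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  lab <- array(0L, dims)
  lab[mask] <- comp
  lab
}

#' Simulate survival outcomes from a feature table
#'
#' Draws overall-survival records from an exponential proportional-hazards
#' model in which the log hazard is
#' `log(baseline_hazard) + log_hazard_coeff * z`, with `z` the standardized
#' driver feature, plus independent exponential censoring. This provides
#' parameter-recovery ground truth for the Cox feature screen.
#'
#' @param features A data frame with one row per patient (one algorithm's
#'   rows of a feature table) containing `patient_id` and the driver column.
#' @param driver_feature Name of the feature column driving the hazard.
#' @param log_hazard_coeff Effect of the standardized feature on the log
#'   hazard (negative = protective).
#' @param baseline_hazard Baseline event rate, events/month (> 0).
#' @param censor_rate Exponential censoring rate, events/month (>= 0;
#'   0 disables censoring so every record is an observed death).
#' @param seed Integer seed.
#' @return A tibble with columns `patient_id`, `time_months` (> 0), `event`
#'   (logical: death observed).
#' @export
simulate_survival <- function(features, driver_feature = "fo_entropy",
                              log_hazard_coeff = -0.7,
                              baseline_hazard = 0.03,
                              censor_rate = 0.01,
                              seed = 1L) {
  stopifnot(is.data.frame(features), baseline_hazard > 0, censor_rate >= 0)
  if (!driver_feature %in% names(features))
    stop("driver feature `", driver_feature, "` not present for every patient")
  x <- features[[driver_feature]]
  if (anyNA(x)) stop("driver feature contains missing values")
  if (sd(x) == 0) stop("zero-variance driver feature: standardization undefined")
  z <- (x - mean(x)) / sd(x)
  set.seed(seed)
  lambda <- baseline_hazard * exp(log_hazard_coeff * z)
  t_event <- rexp(length(z), rate = lambda)
  t_cens <- if (censor_rate > 0) rexp(length(z), rate = censor_rate) else Inf
  tibble::tibble(patient_id = features$patient_id %||% seq_along(z),
                 time_months = pmax(pmin(t_event, t_cens), 1e-6),
                 event = t_event <= t_cens)
}
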