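#' Expand a freehand VOI
#'
#' Morphological dilation of the mask by Euclidean voxel distance
#' `<= n_voxels`, isotropic in index space and clipped to the grid. The
#' freehand template is expanded this way (default 5 voxels) before the
#' automatic segmenters run, so that the working region covers the whole
#' tumour plus surrounding background.
#'
#' @param fh A non-empty [voi_mask()].
#' @param n_voxels Dilation radius in voxels (0 = identity).
#' @return A [voi_mask()] with provenance `"expanded"`.
#' @export
#' @examples
#' m <- array(FALSE, c(15, 15, 15)); m[8, 8, 8] <- TRUE
#' expanded <- expand_mask(voi_mask(m, provenance = "freehand"), 5)
#' sum(expanded$mask)  # digital Euclidean ball of radius 5: 515 voxels
expand_mask <- function(fh, n_voxels = 5) {
  stopifnot(inherits(fh, "voi_mask"), n_voxels >= 0)
  if (!any(fh$mask)) stop("cannot expand an empty mask")
  n_voxels <- as.integer(n_voxels)
  if (n_voxels == 0L)
    return(voi_mask(fh$mask, spacing_mm = fh$spacing_mm, provenance = "expanded"))
  dims <- dim(fh$mask)
  offs <- as.matrix(expand.grid(dx = -n_voxels:n_voxels,
                                dy = -n_voxels:n_voxels,
                                dz = -n_voxels:n_voxels))
  offs <- offs[rowSums(offs^2) <= n_voxels^2, , drop = FALSE]
  # dilate on a padded grid with linear-index arithmetic, then crop
  dp <- dims + 2L * n_voxels
  padded <- array(FALSE, dp)
  core <- lapply(1:3, function(a) (n_voxels + 1L):(n_voxels + dims[a]))
  padded[core[[1]], core[[2]], core[[3]]] <- fh$mask
  idx <- which(padded)
  deltas <- offs[, 1] + dp[1] * offs[, 2] + dp[1] * dp[2] * offs[, 3]
  padded[as.vector(outer(idx, deltas, "+"))] <- TRUE
  out <- padded[core[[1]], core[[2]], core[[3]]]
  voi_mask(out, spacing_mm = fh$spacing_mm, provenance = "expanded")
}

new_segmentation <- function(mask, algorithm, n_iterations = NA_integer_,
                             class_means = NULL, converged = NA) {
  structure(list(mask = mask, algorithm = algorithm,
                 volume_ml = mask_volume_ml(mask),
                 n_iterations = n_iterations, class_means = class_means,
                 converged = converged),
            class = "petx_segmentation")
}

#' @export
print.petx_segmentation <- function(x, ...) {
  cat("<segmentation:", x$algorithm, "> ", sum(x$mask$mask), " voxels, ",
      signif(x$volume_ml, 4), " ml\n", sep = "")
  if (!is.null(x$class_means))
    cat("  class means (SUV): ", paste(signif(x$class_means, 4),
                                       collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a segmentation result
#'
#' @param x A segmentation result from [segment_40p()], [segment_flab()] or
#'   [segment_freehand()].
#' @param ... Unused.
#' @return One-row tibble with `algorithm`, `n_voxels`, `volume_ml`,
#'   `n_iterations`.
#' @export
tidy.petx_segmentation <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, n_voxels = sum(x$mask$mask),
                 volume_ml = x$volume_ml, n_iterations = x$n_iterations)
}

#' Freehand delineation (ingestion)
#'
#' Freehand masks are inputs (drawn by readers or simulated); this wraps one
#' as a segmentation result so the three algorithms share a result type.
#'
#' @param fh A [voi_mask()] drawn freehand.
#' @return A `petx_segmentation` with algorithm `"FH"`.
#' @export
segment_freehand <- function(fh) {
  stopifnot(inherits(fh, "voi_mask"))
  m <- voi_mask(fh$mask, spacing_mm = fh$spacing_mm, provenance = "freehand")
  new_segmentation(m, "FH")
}

#' 40%-of-maximum threshold segmentation
#'
#' Retains the voxels of the expanded VOI whose activity is equal to or
#' greater than `fraction` times the maximum-activity voxel inside the VOI.
#' The threshold is relative, so the result is invariant to positive
#' rescaling of the image.
#'
#' @param volume A [pet_volume()].
#' @param expanded The expanded template [voi_mask()].
#' @param fraction Threshold fraction in (0, 1); default 0.40.
#' @return A `petx_segmentation` with algorithm `"40P"`; its mask is always a
#'   subset of `expanded`.
#' @export
segment_40p <- function(volume, expanded, fraction = 0.40) {
  stopifnot(inherits(volume, "pet_volume"), inherits(expanded, "voi_mask"),
            fraction > 0, fraction < 1)
  check_same_grid(volume, expanded)
  if (!any(expanded$mask)) stop("expanded VOI is empty")
  vmax <- max(volume$values[expanded$mask])
  if (vmax <= 0) stop("degenerate result: VOI contains no positive activity")
  keep <- expanded$mask & (volume$values >= fraction * vmax)
  m <- voi_mask(keep, spacing_mm = volume$spacing_mm, provenance = "40P")
  stopifnot(all(m$mask <= expanded$mask))  # containment invariant
  new_segmentation(m, "40P")
}

#' Parameters of the three-class Bayesian segmenter
#'
#' The segmenter models VOI intensities as a three-class Gaussian mixture —
#' background, partial-volume transition shell, and tumour core — with the
#' class prior of each voxel locally adapted to the labels of its
#' 26-neighbourhood, and fits it by expectation-maximization-style
#' alternation.
#'
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance: maximum relative change of the class
#'   means between iterations.
#' @param spatial_weight Blend weight in `[0, 1)` between the global class
#'   proportions and the 26-neighbourhood label frequencies from the previous
#'   iteration; 0 gives a plain (non-spatial) Gaussian mixture.
#' @param init_strategy `"range"` (default; class means anchored at 1/6, 1/2
#'   and 5/6 of the VOI intensity *range*, i.e. near background, transition
#'   and core levels), `"quantile"` (means at the 1/6, 1/2, 5/6 intensity
#'   quantiles — poorly conditioned when background dominates the expanded
#'   VOI, since two classes then start inside the background mode) or
#'   `"kmeans"`.
#' @param seed Seed used only by the k-means initializer.
#' @return A `flab_params` list.
#' @export
flab_params <- function(max_iter = 100, tol = 1e-4, spatial_weight = 0.5,
                        init_strategy = c("range", "quantile", "kmeans"),
                        seed = 1L) {
  init_strategy <- match.arg(init_strategy)
  stopifnot(max_iter >= 1, tol > 0, spatial_weight >= 0, spatial_weight < 1)
  structure(list(n_classes = 3L, max_iter = as.integer(max_iter), tol = tol,
                 spatial_weight = spatial_weight,
                 init_strategy = init_strategy, seed = as.integer(seed)),
            class = "flab_params")
}

# Per-voxel neighbour label frequencies (26-neighbourhood, restricted to the
# VOI), as an n_vox x 3 matrix of counts. Works on a 1-voxel-padded copy so
# neighbour lookups are plain linear-index arithmetic.
neighbour_label_counts <- function(labels_voi, pad_ctx) {
  lab_p <- pad_ctx$zero
  lab_p[pad_ctx$idx] <- labels_voi
  nl <- lab_p[pad_ctx$nbr_idx]          # n_vox x 26 neighbour labels
  dim(nl) <- dim(pad_ctx$nbr_idx)
  cbind(rowSums(nl == 1L), rowSums(nl == 2L), rowSums(nl == 3L))
}

# padded linear-index context for a VOI: indices of VOI voxels in the padded
# grid and the n_vox x 26 matrix of their neighbour indices
make_pad_ctx <- function(voi) {
  dims <- dim(voi)
  dp <- dims + 2L
  zero <- array(0L, dp)
  inner <- array(FALSE, dp)
  inner[2:(dp[1] - 1), 2:(dp[2] - 1), 2:(dp[3] - 1)] <- voi
  idx <- which(inner)
  offs <- offsets26()
  deltas <- offs[, 1] + dp[1] * offs[, 2] + dp[1] * dp[2] * offs[, 3]
  nbr_idx <- outer(idx, deltas, "+")
  list(zero = zero, idx = idx, nbr_idx = nbr_idx)
}

#' Three-class Bayesian segmentation of a PET VOI
#'
#' Classifies the voxels of the expanded VOI into background, partial-volume
#' shell and tumour core with a spatially regularized three-class Gaussian
#' mixture; the background class is discarded and the union of the two
#' higher-mean classes is returned as the tumour delineation.
#'
#' @param volume A [pet_volume()].
#' @param expanded The expanded template [voi_mask()]; must hold at least 9
#'   voxels and at least 3 distinct intensity values.
#' @param params A [flab_params()].
#' @return A `petx_segmentation` with algorithm `"FLAB"`, recording the
#'   number of iterations, the converged class means (sorted ascending) and a
#'   convergence flag. The mask is always a subset of `expanded`.
#' @export
segment_flab <- function(volume, expanded, params = flab_params()) {
  stopifnot(inherits(volume, "pet_volume"), inherits(expanded, "voi_mask"),
            inherits(params, "flab_params"))
  check_same_grid(volume, expanded)
  voi <- expanded$mask
  n <- sum(voi)
  if (n < 3 * params$n_classes) stop("expanded VOI too small (need >= 9 voxels)")
  x <- volume$values[voi]
  if (length(unique(x)) < 3)
    stop("fewer than 3 distinct intensity levels inside the VOI")
  dims <- dim(voi)
  rng <- diff(range(x))
  sd_floor <- max(1e-8, 1e-4 * rng)

  if (params$init_strategy == "range") {
    mu <- min(x) + rng * c(1/6, 1/2, 5/6)
  } else if (params$init_strategy == "quantile") {
    mu <- as.numeric(quantile(x, c(1/6, 1/2, 5/6)))
    if (any(duplicated(mu))) mu <- mu + rng * c(-1e-3, 0, 1e-3)
  } else {
    set.seed(params$seed)
    mu <- sort(kmeans(x, centers = 3, nstart = 3)$centers[, 1])
  }
  sigma <- rep(max(sd(x) / 2, sd_floor), 3)
  pi_g <- rep(1 / 3, 3)
  lab <- max.col(-abs(outer(x, mu, "-")))  # nearest-mean init labels
  converged <- FALSE
  it <- 0L
  w <- params$spatial_weight
  dens <- matrix(0, n, 3)
  pad_ctx <- if (w > 0) make_pad_ctx(voi) else NULL
  for (it in seq_len(params$max_iter)) {
    # local priors: blend of global proportions and neighbour frequencies
    if (w > 0) {
      nb <- neighbour_label_counts(lab, pad_ctx)
      tot <- rowSums(nb)
      freq <- (nb + 1e-9) / (tot + 3e-9)
      prior <- (1 - w) * matrix(pi_g, n, 3, byrow = TRUE) + w * freq
    } else {
      prior <- matrix(pi_g, n, 3, byrow = TRUE)
    }
    for (k in 1:3) dens[, k] <- prior[, k] * dnorm(x, mu[k], sigma[k])
    rs <- rowSums(dens)
    rs[rs == 0] <- .Machine$double.xmin
    resp <- dens / rs
    nk <- colSums(resp)
    mu_new <- colSums(resp * x) / nk
    sigma_new <- sqrt(pmax(colSums(resp * (x - rep(mu_new, each = n))^2) / nk,
                           sd_floor^2))
    pi_g <- nk / n
    lab <- max.col(resp)
    delta <- max(abs(mu_new - mu) / pmax(abs(mu), sd_floor))
    mu <- mu_new
    sigma <- sigma_new
    if (delta < params$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("FLAB did not converge within max_iter; returning best-so-far")
  # final E-step so labels correspond exactly to the converged parameters
  if (w > 0) {
    nb <- neighbour_label_counts(lab, pad_ctx)
    freq <- (nb + 1e-9) / (rowSums(nb) + 3e-9)
    prior <- (1 - w) * matrix(pi_g, n, 3, byrow = TRUE) + w * freq
  } else {
    prior <- matrix(pi_g, n, 3, byrow = TRUE)
  }
  for (k in 1:3) dens[, k] <- prior[, k] * dnorm(x, mu[k], sigma[k])
  rs <- rowSums(dens)
  rs[rs == 0] <- .Machine$double.xmin
  resp <- dens / rs
  lab <- max.col(resp)
  ord <- order(mu)
  # keep the two highest-mean classes (tumour core + partial-volume shell)
  keep_classes <- ord[2:3]
  keep <- array(FALSE, dims)
  keep[voi] <- lab %in% keep_classes
  if (!any(keep)) stop("degenerate FLAB result: no voxel above background class")
  m <- voi_mask(keep, spacing_mm = volume$spacing_mm, provenance = "FLAB")
  stopifnot(all(m$mask <= expanded$mask))  # containment invariant
  res <- new_segmentation(m, "FLAB", n_iterations = it,
                          class_means = sort(mu), converged = converged)
  res$class_sds <- sigma[ord]
  res$class_priors <- pi_g[ord]
  res$posterior <- resp
  res
}
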