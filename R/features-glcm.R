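# Grey-level co-occurrence features.
#
# A symmetric co-occurrence matrix is accumulated per offset from all
# in-mask voxel pairs at unit distance along that offset; the 22 features are
# computed per direction and averaged over the 13 unique 3D directions
# (directions with no valid pair are skipped).

# co-occurrence counts for one offset; ng x ng, symmetric
glcm_matrix <- function(q, off) {
  p <- shifted_pairs(q$levels, off)
  ok <- !is.na(p$a) & !is.na(p$b)
  if (!any(ok)) return(NULL)
  a <- p$a[ok]; b <- p$b[ok]
  ng <- q$n_bins
  counts <- tabulate((a - 1L) * ng + b, nbins = ng * ng) +
    tabulate((b - 1L) * ng + a, nbins = ng * ng)
  matrix(counts, ng, ng)
}

# the 22 Haralick-derived features of one normalized symmetric GLCM
glcm_feature_set <- function(P, ng) {
  p <- P / sum(P)
  nz <- which(p > 0, arr.ind = TRUE)
  pv <- p[nz]
  i <- nz[, 1]; j <- nz[, 2]
  px <- rowSums(p)
  mu <- sum(seq_len(ng) * px)          # symmetric: mu_x = mu_y
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  # diagonal and cross-diagonal marginals
  pxmy <- vapply(0:(ng - 1), function(k) sum(pv[abs(i - j) == k]), numeric(1))
  pxpy <- vapply(2:(2 * ng), function(k) sum(pv[(i + j) == k]), numeric(1))
  k_d <- 0:(ng - 1)
  k_s <- 2:(2 * ng)
  da <- sum(k_d * pxmy)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hxy <- -sum(pv * log2(pv))
  # joint entropy terms against the product of marginals
  pm <- outer(px, px)[nz]
  hxy1 <- -sum(pv * log2(pm))
  pm_all <- outer(px, px)
  hxy2 <- -sum(pm_all[pm_all > 0] * log2(pm_all[pm_all > 0]))
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sig2 > 0) (sum(i * j * pv) - mu^2) / sig2 else 1
  pd_nz <- pxmy[pxmy > 0]
  ps_nz <- pxpy[pxpy > 0]
  c(glcm_autocorrelation = sum(i * j * pv),
    glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * pv),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * pv),
    glcm_cluster_tendency = sum((i + j - 2 * mu)^2 * pv),
    glcm_contrast = sum((i - j)^2 * pv),
    glcm_correlation = corr,
    glcm_difference_average = da,
    glcm_difference_entropy = -sum(pd_nz * log2(pd_nz)),
    glcm_difference_variance = sum((k_d - da)^2 * pxmy),
    glcm_dissimilarity = sum(abs(i - j) * pv),
    glcm_energy = sum(pv^2),
    glcm_entropy = hxy,
    glcm_homogeneity = sum(pv / (1 + abs(i - j))),
    glcm_idm = sum(pv / (1 + (i - j)^2)),
    glcm_idmn = sum(pv / (1 + (i - j)^2 / ng^2)),
    glcm_idn = sum(pv / (1 + abs(i - j) / ng)),
    glcm_imc1 = imc1,
    glcm_imc2 = imc2,
    glcm_inverse_variance = sum(ifelse(i == j, 0, pv / (i - j)^2)),
    glcm_max_probability = max(pv),
    glcm_sum_average = sum(k_s * pxpy),
    glcm_sum_entropy = -sum(ps_nz * log2(ps_nz)))
}

#' Grey-level co-occurrence matrix (GLCM) features
#'
#' Computes 22 second-order texture features from 3D co-occurrence matrices
#' at distance 1 voxel over the 13 unique directions of the
#' 26-neighbourhood, restricted to in-mask voxel pairs. Each direction's
#' symmetric normalized matrix yields one feature set; the sets are averaged.
#'
#' A constant VOI yields the single-cell degenerate matrix: entropy 0,
#' homogeneity 1, dissimilarity 0. If no direction holds a valid voxel pair
#' all features are `NA`.
#'
#' @param q A [quantize_voi()] result.
#' @return Named numeric vector of the 22 GLCM features.
#' @export
glcm_features <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  if (sum(q$mask) < 2) {  # degenerate: no voxel pair can exist
    nm <- feature_registry()$feature[feature_registry()$family == "glcm"]
    return(setNames(rep(NA_real_, length(nm)), nm))
  }
  offs <- offsets13()
  sets <- list()
  for (d in seq_len(nrow(offs))) {
    G <- glcm_matrix(q, offs[d, ])
    if (!is.null(G)) sets[[length(sets) + 1L]] <- glcm_feature_set(G, q$n_bins)
  }
  if (length(sets) == 0) {
    nm <- feature_registry()$feature[feature_registry()$family == "glcm"]
    return(setNames(rep(NA_real_, length(nm)), nm))
  }
  Reduce(`+`, sets) / length(sets)
}
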