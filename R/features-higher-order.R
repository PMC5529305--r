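# Higher-order texture families: grey-level run-length (16), size-zone (14)
# and neighbourhood grey-tone difference (5) features — 35 in all.

# ---- GLRLM -----------------------------------------------------------------

# runs of equal grey level along one direction, restricted to the mask;
# returns data frame (level, length)
runs_along <- function(q, off) {
  idx <- which(q$mask, arr.ind = TRUE)
  lev <- q$levels[q$mask]
  # parameter along the line: coordinate of the first nonzero (+1) component
  ax <- which(off != 0)[1]
  t_par <- idx[, ax]
  line <- idx - outer(t_par, off)
  o <- order(line[, 1], line[, 2], line[, 3], t_par)
  t_o <- t_par[o]
  lev_o <- lev[o]
  line_o <- line[o, , drop = FALSE]
  n <- length(t_o)
  if (n == 0) return(NULL)
  new_run <- if (n == 1) TRUE else
    c(TRUE,
      (diff(t_o) != 1) |
        (diff(lev_o) != 0) |
        (rowSums(abs(diff(line_o))) != 0))
  run_id <- cumsum(new_run)
  data.frame(level = lev_o[!duplicated(run_id)] * 1L,
             length = as.integer(tabulate(run_id)))
}

glrlm_feature_set <- function(runs, n_voxels) {
  r <- runs$length
  i <- runs$level
  nr <- length(r)
  # aggregated matrix margins
  gl_tab <- tapply(rep(1L, nr), i, sum)
  rl_tab <- tapply(rep(1L, nr), r, sum)
  p_i <- as.numeric(gl_tab) / nr
  lv_i <- as.numeric(names(gl_tab))
  p_l <- as.numeric(rl_tab) / nr
  ln_l <- as.numeric(names(rl_tab))
  mu_i <- sum(lv_i * p_i)
  mu_l <- sum(ln_l * p_l)
  pr <- rep(1 / nr, nr)
  c(glrlm_sre = sum(1 / r^2) / nr,
    glrlm_lre = sum(r^2) / nr,
    glrlm_gln = sum(as.numeric(gl_tab)^2) / nr,
    glrlm_glnn = sum(as.numeric(gl_tab)^2) / nr^2,
    glrlm_rln = sum(as.numeric(rl_tab)^2) / nr,
    glrlm_rlnn = sum(as.numeric(rl_tab)^2) / nr^2,
    glrlm_rp = nr / n_voxels,
    glrlm_glv = sum(p_i * (lv_i - mu_i)^2),
    glrlm_rv = sum(p_l * (ln_l - mu_l)^2),
    glrlm_re = -sum(table_p_log(i, r, nr)),
    glrlm_lglre = sum(1 / i^2) / nr,
    glrlm_hglre = sum(i^2) / nr,
    glrlm_srlgle = sum(1 / (i^2 * r^2)) / nr,
    glrlm_srhgle = sum(i^2 / r^2) / nr,
    glrlm_lrlgle = sum(r^2 / i^2) / nr,
    glrlm_lrhgle = sum(i^2 * r^2) / nr)
}

# entropy term of the (level, length) run distribution
table_p_log <- function(i, r, nr) {
  tab <- table(i, r)
  p <- as.numeric(tab[tab > 0]) / nr
  p * log2(p)
}

#' Grey-level run-length matrix (GLRLM) features
#'
#' Sixteen run-length features; runs are maximal sequences of equal-level
#' in-mask voxels along one of the 13 unique 3D directions (a gap in the
#' mask breaks the run). Features are computed per direction and averaged.
#'
#' @param q A [quantize_voi()] result.
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  n_voxels <- sum(q$mask)
  offs <- offsets13()
  sets <- lapply(seq_len(nrow(offs)), function(d) {
    runs <- runs_along(q, offs[d, ])
    glrlm_feature_set(runs, n_voxels)
  })
  Reduce(`+`, sets) / length(sets)
}

# ---- GLSZM -----------------------------------------------------------------

# 26-connected constant-level zones: (level, size) per zone
glszm_zones <- function(q) {
  mask <- q$mask
  dims <- dim(mask)
  id <- array(0L, dims)
  id[mask] <- seq_len(sum(mask))
  lev <- q$levels
  edges <- list()
  offs <- offsets13()
  for (d in seq_len(nrow(offs))) {
    pa <- shifted_pairs(id, offs[d, ])
    pl <- shifted_pairs(lev, offs[d, ])
    ok <- pa$a > 0L & pa$b > 0L & !is.na(pl$a) & !is.na(pl$b) & pl$a == pl$b
    if (any(ok)) edges[[length(edges) + 1L]] <- cbind(pa$a[ok], pa$b[ok])
  }
  g <- igraph::make_empty_graph(n = sum(mask), directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  lv <- lev[mask]
  data.frame(level = as.integer(tapply(lv, comp, function(v) v[1])),
             size = as.integer(tabulate(comp)))
}

#' Grey-level size-zone matrix (GLSZM) features
#'
#' Fourteen features of the distribution of 26-connected constant-level
#' zones. `glszm_intensity_variability` is the level-wise sum of squared
#' voxel counts divided by the number of zones (so a 4-voxel strip with
#' levels 1,1,2,2 gives (2^2 + 2^2)/2 = 4); `glszm_size_zone_variability` is
#' the classical size-wise zone-count analogue.
#'
#' @param q A [quantize_voi()] result.
#' @return Named numeric vector of 14 features.
#' @export
glszm_features <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  zones <- glszm_zones(q)
  i <- zones$level
  z <- zones$size
  nz <- nrow(zones)
  np <- sum(q$mask)
  vox_per_level <- tapply(z, i, sum)          # voxels at each level
  zones_per_size <- tapply(rep(1L, nz), z, sum)
  p <- rep(1 / nz, nz)
  lv <- as.numeric(names(vox_per_level))
  mu_i <- sum(i) / nz
  mu_z <- sum(z) / nz
  tab <- table(i, z)
  pz <- as.numeric(tab[tab > 0]) / nz
  c(glszm_intensity_variability = sum(as.numeric(vox_per_level)^2) / nz,
    glszm_size_zone_variability = sum(as.numeric(zones_per_size)^2) / nz,
    glszm_zone_percentage = nz / np,
    glszm_small_area_emphasis = sum(1 / z^2) / nz,
    glszm_large_area_emphasis = sum(z^2) / nz,
    glszm_low_gl_emphasis = sum(1 / i^2) / nz,
    glszm_high_gl_emphasis = sum(i^2) / nz,
    glszm_small_area_low_gl = sum(1 / (i^2 * z^2)) / nz,
    glszm_small_area_high_gl = sum(i^2 / z^2) / nz,
    glszm_large_area_low_gl = sum(z^2 / i^2) / nz,
    glszm_large_area_high_gl = sum(i^2 * z^2) / nz,
    glszm_gl_variance = sum((i - mu_i)^2) / nz,
    glszm_zone_variance = sum((z - mu_z)^2) / nz,
    glszm_zone_entropy = -sum(pz * log2(pz)))
}

# ---- NGTDM -----------------------------------------------------------------

#' Neighbourhood grey-tone difference matrix (NGTDM) features
#'
#' Five features built from the per-level summed absolute difference between
#' each in-mask voxel and the mean level of its in-mask 26-neighbourhood
#' (voxels with no in-mask neighbour are excluded). Coarseness is
#' `1 / (eps + sum(p_i * s_i))` with `eps = 1e-6`, capped at `1e6` — the cap
#' is reached by a perfectly homogeneous VOI. Contrast and busyness are 0 for
#' a single-level VOI.
#'
#' @param q A [quantize_voi()] result.
#' @param eps Numerical guard of the coarseness reciprocal.
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(q, eps = 1e-6) {
  stopifnot(inherits(q, "quantized_voi"))
  dims <- dim(q$mask)
  lev <- q$levels
  lev0 <- lev
  lev0[is.na(lev0)] <- 0
  inm <- array(as.numeric(q$mask), dims)
  nb_sum <- array(0, dims)
  nb_cnt <- array(0, dims)
  offs <- offsets26()
  for (d in seq_len(nrow(offs))) {
    off <- offs[d, ]
    s <- offset_slabs(dims, off)
    nb_sum[s[[1]]$to, s[[2]]$to, s[[3]]$to] <-
      nb_sum[s[[1]]$to, s[[2]]$to, s[[3]]$to] +
      lev0[s[[1]]$from, s[[2]]$from, s[[3]]$from]
    nb_cnt[s[[1]]$to, s[[2]]$to, s[[3]]$to] <-
      nb_cnt[s[[1]]$to, s[[2]]$to, s[[3]]$to] +
      inm[s[[1]]$from, s[[2]]$from, s[[3]]$from]
  }
  use <- q$mask & nb_cnt > 0
  if (!any(use)) {  # isolated voxel(s): no in-mask neighbourhood exists
    return(c(ngtdm_coarseness = NA_real_, ngtdm_contrast = NA_real_,
             ngtdm_busyness = NA_real_, ngtdm_complexity = NA_real_,
             ngtdm_strength = NA_real_))
  }
  lv <- lev[use]
  abar <- nb_sum[use] / nb_cnt[use]
  dev <- abs(lv - abar)
  n <- length(lv)
  ni <- tapply(rep(1L, n), lv, sum)
  si <- tapply(dev, lv, sum)
  levels_present <- as.numeric(names(ni))
  p_i <- as.numeric(ni) / n
  s_i <- as.numeric(si)
  ngp <- length(levels_present)
  coarse <- min(1 / (eps + sum(p_i * s_i)), 1e6)
  if (ngp > 1) {
    dif2 <- outer(levels_present, levels_present, function(a, b) (a - b)^2)
    pp <- outer(p_i, p_i)
    contrast <- sum(pp * dif2) / (ngp * (ngp - 1)) * sum(s_i) / n
    ipn <- levels_present * p_i
    busy_den <- sum(abs(outer(ipn, ipn, "-")))
    busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
    psps <- outer(p_i * s_i, p_i * s_i, "+")
    pps <- outer(p_i, p_i, "+")
    difa <- abs(outer(levels_present, levels_present, "-"))
    complexity <- sum(difa * psps / pps) / n
    strength <- sum(pps * dif2) / (eps + sum(s_i))
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(ngtdm_coarseness = coarse,
    ngtdm_contrast = contrast,
    ngtdm_busyness = busyness,
    ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

#' Higher-order texture features
#'
#' The 35 higher-order features: 16 run-length ([glrlm_features()]), 14
#' size-zone ([glszm_features()]) and 5 neighbourhood grey-tone difference
#' ([ngtdm_features()]) features.
#'
#' @param q A [quantize_voi()] result.
#' @return Named numeric vector of 35 features.
#' @export
higher_order_features <- function(q) {
  c(glrlm_features(q), glszm_features(q), ngtdm_features(q))
}
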