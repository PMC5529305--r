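# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately written from first principles (dense loops,
# explicit formulas, enumeration) and share no code with the package paths
# they check.

# ---- fixtures ---------------------------------------------------------------

tiny_volume <- function(values, spacing = c(1, 1, 1)) {
  pet_volume(values, spacing_mm = spacing)
}

full_mask <- function(dims, spacing = c(1, 1, 1)) {
  voi_mask(array(TRUE, dims), spacing_mm = spacing)
}

# a volume whose in-mask values are exactly `vals` (filled column-major into
# a full mask), padded into a dims grid
volume_from_values <- function(vals, dims, spacing = c(1, 1, 1)) {
  stopifnot(length(vals) == prod(dims))
  tiny_volume(array(vals, dims), spacing)
}

# three constant intensity blocks along x (means m1, m2, m3) plus noise
block_phantom <- function(nx = 12, m = c(1, 5, 10), noise_sd = 0.1,
                          seed = 1) {
  set.seed(seed)
  dims <- c(3 * nx, 8, 8)
  arr <- array(rep(m, each = nx), dims)
  arr <- arr + array(rnorm(prod(dims), sd = noise_sd), dims)
  arr[arr < 0] <- 0
  labels <- array(rep(1:3, each = nx), dims)
  list(volume = tiny_volume(arr), mask = full_mask(dims), labels = labels)
}

# ---- GLCM oracle ------------------------------------------------------------

# dense enumeration of all in-mask ordered voxel pairs at unit offsets;
# features computed from the standard definitions with explicit loops
oracle_glcm_features <- function(levels_arr, mask, n_bins) {
  dims <- dim(mask)
  dirs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0),
                c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1),
                c(1,1,-1), c(1,-1,1), c(1,-1,-1))
  per_dir <- list()
  for (d in seq_len(nrow(dirs))) {
    M <- matrix(0, n_bins, n_bins)
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      if (!mask[x, y, z]) next
      p2 <- c(x, y, z) + dirs[d, ]
      if (any(p2 < 1) || any(p2 > dims)) next
      if (!mask[p2[1], p2[2], p2[3]]) next
      i <- levels_arr[x, y, z]; j <- levels_arr[p2[1], p2[2], p2[3]]
      M[i, j] <- M[i, j] + 1
      M[j, i] <- M[j, i] + 1
    }
    if (sum(M) > 0) per_dir[[length(per_dir) + 1]] <- oracle_glcm_set(M, n_bins)
  }
  Reduce(`+`, per_dir) / length(per_dir)
}

oracle_glcm_set <- function(M, ng) {
  p <- M / sum(M)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum((1:ng) * px)
  var_x <- sum(((1:ng) - mu_x)^2 * px)
  f <- setNames(numeric(22),
                c("glcm_autocorrelation", "glcm_cluster_prominence",
                  "glcm_cluster_shade", "glcm_cluster_tendency",
                  "glcm_contrast", "glcm_correlation",
                  "glcm_difference_average", "glcm_difference_entropy",
                  "glcm_difference_variance", "glcm_dissimilarity",
                  "glcm_energy", "glcm_entropy", "glcm_homogeneity",
                  "glcm_idm", "glcm_idmn", "glcm_idn", "glcm_imc1",
                  "glcm_imc2", "glcm_inverse_variance",
                  "glcm_max_probability", "glcm_sum_average",
                  "glcm_sum_entropy"))
  pd <- numeric(ng); ps <- numeric(2 * ng)
  hxy <- 0; hxy1 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + v
    ps[i + j] <- ps[i + j] + v
    if (v > 0) {
      f["glcm_autocorrelation"] <- f["glcm_autocorrelation"] + i * j * v
      f["glcm_cluster_prominence"] <-
        f["glcm_cluster_prominence"] + (i + j - 2 * mu_x)^4 * v
      f["glcm_cluster_shade"] <-
        f["glcm_cluster_shade"] + (i + j - 2 * mu_x)^3 * v
      f["glcm_cluster_tendency"] <-
        f["glcm_cluster_tendency"] + (i + j - 2 * mu_x)^2 * v
      f["glcm_contrast"] <- f["glcm_contrast"] + (i - j)^2 * v
      f["glcm_dissimilarity"] <- f["glcm_dissimilarity"] + abs(i - j) * v
      f["glcm_energy"] <- f["glcm_energy"] + v^2
      hxy <- hxy - v * log2(v)
      if (px[i] * py[j] > 0) hxy1 <- hxy1 - v * log2(px[i] * py[j])
      f["glcm_homogeneity"] <- f["glcm_homogeneity"] + v / (1 + abs(i - j))
      f["glcm_idm"] <- f["glcm_idm"] + v / (1 + (i - j)^2)
      f["glcm_idmn"] <- f["glcm_idmn"] + v / (1 + (i - j)^2 / ng^2)
      f["glcm_idn"] <- f["glcm_idn"] + v / (1 + abs(i - j) / ng)
      if (i != j)
        f["glcm_inverse_variance"] <-
          f["glcm_inverse_variance"] + v / (i - j)^2
    }
  }
  f["glcm_entropy"] <- hxy
  f["glcm_correlation"] <- if (var_x > 0)
    (f[["glcm_autocorrelation"]] - mu_x^2) / var_x else 1
  kd <- 0:(ng - 1)
  f["glcm_difference_average"] <- sum(kd * pd)
  f["glcm_difference_entropy"] <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  f["glcm_difference_variance"] <-
    sum((kd - f[["glcm_difference_average"]])^2 * pd)
  ks <- seq_along(ps)
  f["glcm_sum_average"] <- sum(ks * ps)
  f["glcm_sum_entropy"] <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng)
    if (px[i] * py[j] > 0)
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
  f["glcm_imc1"] <- if (hx > 0) (hxy - hxy1) / hx else 0
  f["glcm_imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  f["glcm_max_probability"] <- max(p)
  f
}

# ---- ICC oracle -------------------------------------------------------------

# two-way ANOVA mean squares from explicit sums of squares, then the
# ICC(2,1) variance-components formula
oracle_icc2 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# ---- Cox oracle -------------------------------------------------------------

# explicit log partial likelihood (no ties assumed), maximized by two-stage
# grid search over [-5, 5] to 1e-4
oracle_cox_beta <- function(time, event, x) {
  logpl <- function(beta) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    s
  }
  grid <- seq(-5, 5, by = 0.01)
  best <- grid[which.max(vapply(grid, logpl, numeric(1)))]
  fine <- seq(best - 0.01, best + 0.01, by = 1e-4)
  fine[which.max(vapply(fine, logpl, numeric(1)))]
}

# ---- Mann-Whitney enumeration oracle ---------------------------------------

# exact two-sided p by enumerating all assignments of the pooled sample
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  combs <- utils::combn(length(pooled), n1)
  ustat <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- ustat(a, b)
  us <- apply(combs, 2, function(ix) ustat(pooled[ix], pooled[-ix]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}
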