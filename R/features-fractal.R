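# Model-based (fractal) features: box-counting dimensions of the mask and of
# its boundary, a differential box-counting dimension of the in-mask
# intensity surface, and gliding-free (tiled) box-mass lacunarity summaries.

dyadic_sizes <- function(extent) {
  k <- max(1L, floor(log2(max(2, extent / 2))))
  2^(0:k)
}

box_ids <- function(coords, s, minc) {
  b <- floor(sweep(coords, 2, minc, "-") / s)
  b[, 1] + 4096 * b[, 2] + 4096^2 * b[, 3]
}

box_count_dimension <- function(coords, sizes, minc) {
  n_boxes <- vapply(sizes, function(s) length(unique(box_ids(coords, s, minc))),
                    numeric(1))
  fit <- lm(log(n_boxes) ~ log(1 / sizes))
  unname(coef(fit)[2])
}

#' Fractal (model-based) features
#'
#' Six features describing the scaling behaviour of the VOI:
#' `fractal_fd_mask` and `fractal_fd_boundary` — box-counting dimensions of
#' the mask support and of its 6-connected boundary shell; `fractal_fd_dbc` —
#' differential box-counting dimension of the in-mask intensity surface with
#' relative height normalization (invariant to positive intensity scaling);
#' and three tiled box-mass lacunarity summaries (mean, log-log slope, and
#' value at box size 2). Slopes are least-squares fits over the dyadic box
#' sizes that fit the mask's bounding box.
#'
#' @param volume A [pet_volume()].
#' @param mask A [voi_mask()] spanning at least 4 voxels per axis.
#' @return Named numeric vector of 6 features (all `NA` when the mask extent
#'   is insufficient).
#' @export
fractal_features <- function(volume, mask) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "voi_mask"))
  check_same_grid(volume, mask)
  nm <- c("fractal_fd_mask", "fractal_fd_boundary", "fractal_fd_dbc",
          "fractal_lacunarity_mean", "fractal_lacunarity_slope",
          "fractal_lacunarity_2")
  idx <- which(mask$mask, arr.ind = TRUE)
  extent <- apply(idx, 2, function(v) diff(range(v)) + 1)
  if (any(extent < 4)) return(setNames(rep(NA_real_, 6), nm))
  minc <- apply(idx, 2, min)
  sizes <- dyadic_sizes(min(extent))
  fd_mask <- box_count_dimension(idx, sizes, minc)

  # boundary: in-mask voxels with an out-of-mask 6-neighbour
  dims <- dim(mask$mask)
  inner <- mask$mask
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
    s <- offset_slabs(dims, off)
    nb <- array(FALSE, dims)
    nb[s[[1]]$to, s[[2]]$to, s[[3]]$to] <-
      mask$mask[s[[1]]$from, s[[2]]$from, s[[3]]$from]
    # grid edge counts as outside
    edge <- array(TRUE, dims)
    edge[s[[1]]$to, s[[2]]$to, s[[3]]$to] <- FALSE
    inner <- inner & (nb | edge) & !edge  # neighbour exists and is in-mask
  }
  boundary <- mask$mask & !inner
  bidx <- which(boundary, arr.ind = TRUE)
  fd_boundary <- if (nrow(bidx) >= 8)
    box_count_dimension(bidx, sizes, minc) else NA_real_

  # differential box counting on relative-height-normalized intensities
  x <- volume$values[mask$mask]
  rngx <- diff(range(x))
  L <- max(extent)
  h <- if (rngx > 0) (x - min(x)) / rngx * L else rep(0, length(x))
  n_dbc <- vapply(sizes, function(s) {
    ids <- box_ids(idx, s, minc)
    zmax <- tapply(h, ids, max)
    zmin <- tapply(h, ids, min)
    sum(floor((zmax - zmin) / s) + 1)
  }, numeric(1))
  fd_dbc <- unname(coef(lm(log(n_dbc) ~ log(1 / sizes)))[2])

  # tiled box-mass lacunarity: E[M^2]/E[M]^2 over occupied boxes
  lac <- vapply(sizes, function(s) {
    ids <- box_ids(idx, s, minc)
    m <- tabulate(as.integer(factor(ids)))
    mean(m^2) / mean(m)^2
  }, numeric(1))
  lac_slope <- unname(coef(lm(log(lac) ~ log(sizes)))[2])
  lac2 <- if (2 %in% sizes) lac[sizes == 2] else lac[length(lac)]
  setNames(c(fd_mask, fd_boundary, fd_dbc, mean(lac), lac_slope, lac2), nm)
}
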