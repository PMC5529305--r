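#' Quantize a VOI to discrete grey levels
#'
#' Fixed-bin-number resampling of the in-mask SUV values into `n_bins`
#' (default 64) grey levels over the in-mask minimum-maximum range:
#' `level = 1 + floor(n_bins * (x - min) / (max - min))`, clipped to
#' `n_bins` at `x = max`. Quantized levels are invariant to any positive
#' affine rescaling of the intensities.
#'
#' @param volume A [pet_volume()].
#' @param mask A non-empty [voi_mask()] on the same grid.
#' @param n_bins Number of grey levels (default 64).
#' @return A `quantized_voi`: list with `levels` (3D integer array, `NA`
#'   outside the mask), `mask`, `n_bins`, `calibration` (`c(min, max)` SUV),
#'   `spacing_mm`, and `constant` flag (all levels forced to 1 when the VOI
#'   has zero intensity range; matrix features then take their degenerate
#'   values).
#' @export
quantize_voi <- function(volume, mask, n_bins = 64) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "voi_mask"),
            n_bins >= 2)
  check_same_grid(volume, mask)
  if (!any(mask$mask)) stop("mask is empty")
  x <- volume$values[mask$mask]
  lo <- min(x); hi <- max(x)
  lv <- array(NA_integer_, dim(mask$mask))
  constant <- hi == lo
  if (constant) {
    lv[mask$mask] <- 1L
  } else {
    lev <- 1L + as.integer(floor(n_bins * (x - lo) / (hi - lo)))
    lev[lev > n_bins] <- as.integer(n_bins)
    lv[mask$mask] <- lev
  }
  structure(list(levels = lv, mask = mask$mask, n_bins = as.integer(n_bins),
                 calibration = c(min_suv = lo, max_suv = hi),
                 spacing_mm = mask$spacing_mm, constant = constant),
            class = "quantized_voi")
}

#' @export
print.quantized_voi <- function(x, ...) {
  cat("<quantized_voi> ", sum(x$mask), " voxels, ", x$n_bins, " bins, SUV [",
      signif(x$calibration[1], 4), ", ", signif(x$calibration[2], 4), "]",
      if (x$constant) " (constant)", "\n", sep = "")
  invisible(x)
}
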