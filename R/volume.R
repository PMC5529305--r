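#' PET activity volume
#'
#' A 3D grid of tracer activity in standardized uptake value (SUV) units with
#' physical voxel spacing. This is the raw-image container every other
#' function in the package consumes.
#'
#' @param values Numeric 3D array of non-negative SUV values.
#' @param spacing_mm Numeric length-3 vector, voxel spacing in mm along
#'   (x, y, z). PET grids are typically anisotropic, e.g. `c(4.7, 4.7, 3.27)`.
#' @param origin_mm Numeric length-3 vector, physical position of the first
#'   voxel centre (mm). Cosmetic for analysis; kept for NIfTI round-trips.
#'
#' @return An object of class `pet_volume`: a list with elements `values`,
#'   `spacing_mm`, `origin_mm`.
#' @export
#' @examples
#' v <- pet_volume(array(2, c(8, 8, 8)), spacing_mm = c(4.7, 4.7, 3.27))
#' dim(v$values)
pet_volume <- function(values, spacing_mm = c(4.7, 4.7, 3.27),
                       origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3, length(spacing_mm) == 3)
  if (any(spacing_mm <= 0)) stop("voxel spacing components must be > 0")
  if (any(values < 0)) stop("PET activity must be non-negative (SUV >= 0)")
  structure(list(values = values, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "pet_volume")
}

#' Volume of interest (binary mask)
#'
#' A boolean 3D mask on the grid of a [pet_volume()], tagged with its
#' provenance: `"truth"` (simulated ground truth), `"freehand"` (a reader's
#' contour), `"expanded"` (dilated freehand template), `"40P"` or `"FLAB"`
#' (automatic delineations).
#'
#' @param mask Logical 3D array (coerced with `as.logical`).
#' @param spacing_mm Voxel spacing in mm, as for [pet_volume()].
#' @param provenance One of `"truth"`, `"freehand"`, `"expanded"`, `"40P"`,
#'   `"FLAB"`.
#' @param allow_empty Permit an all-`FALSE` mask (flagged degenerate).
#'
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask, spacing_mm = c(4.7, 4.7, 3.27),
                     provenance = c("truth", "freehand", "expanded", "40P", "FLAB"),
                     allow_empty = FALSE) {
  provenance <- match.arg(provenance)
  mask <- as.array(mask)
  stopifnot(length(dim(mask)) == 3)
  storage.mode(mask) <- "logical"
  if (!allow_empty && !any(mask)) stop("VOI mask is empty")
  structure(list(mask = mask, spacing_mm = as.numeric(spacing_mm),
                 provenance = provenance),
            class = "voi_mask")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("<pet_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing_mm, 4), collapse = " x "),
      " mm\n  SUV range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("<voi_mask> [", x$provenance, "] ", sum(x$mask), " / ",
      length(x$mask), " voxels (", signif(mask_volume_ml(x), 4), " ml)\n",
      sep = "")
  invisible(x)
}

#' Physical volume of a mask in millilitres
#'
#' Voxel count times physical voxel volume; the metabolically active tumour
#' volume (MATV) when applied to a tumour delineation.
#'
#' @param mask A [voi_mask()].
#' @return Volume in ml.
#' @export
mask_volume_ml <- function(mask) {
  sum(mask$mask) * prod(mask$spacing_mm) / 1000
}

# grid-compatibility check used before any voxelwise comparison
check_same_grid <- function(a, b) {
  if (!identical(dim(a$mask %||% a$values), dim(b$mask %||% b$values)))
    stop("objects are not on the same voxel grid")
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# The 13 unique (half-space) unit offsets of the 26-neighbourhood: each
# unordered 3D direction once, first nonzero component +1.
.petx_offsets <- local({
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  keep <- apply(d, 1, function(o) o[o != 0][1] > 0)
  half <- unname(d[keep, , drop = FALSE])
  list(half = half, full = rbind(half, -half))
})

offsets13 <- function() .petx_offsets$half

offsets26 <- function() .petx_offsets$full

# For an offset (dx,dy,dz), index slabs such that A[i1,j1,k1] and
# A[i1+dx, ...] enumerate every in-grid voxel pair at that offset.
offset_slabs <- function(dims, off) {
  lapply(1:3, function(ax) {
    d <- off[ax]
    n <- dims[ax]
    lo <- max(1L, 1L - d); hi <- min(n, n - d)
    if (hi < lo) return(list(from = integer(0), to = integer(0)))
    list(from = lo:hi, to = (lo + d):(hi + d))
  })
}

# Values of `arr` at the offset-shifted positions of the base slab, together
# with the base slab values. Returns a list(a = ..., b = ...) of equal-length
# vectors covering all in-grid pairs.
shifted_pairs <- function(arr, off) {
  dims <- dim(arr)
  s <- offset_slabs(dims, off)
  list(a = arr[s[[1]]$from, s[[2]]$from, s[[3]]$from, drop = FALSE],
       b = arr[s[[1]]$to,   s[[2]]$to,   s[[3]]$to,   drop = FALSE])
}

# Separable Gaussian blur with per-axis sigma in voxels. Kernel rows are
# renormalized at the array edges so constant fields stay constant.
gaussian_blur3d <- function(arr, sigma_vox) {
  dims <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-r, r), sd = s)
    n <- dims[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- (i - r):(i + r)
      ok <- idx >= 1 & idx <= n
      K[i, idx[ok]] <- k[ok] / sum(k[ok])
    }
    arr <- apply_along(arr, ax, K)
  }
  arr
}

# multiply matrix K (n_ax x n_ax) along axis `ax` of a 3D array
apply_along <- function(arr, ax, K) {
  dims <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, nrow = dims[ax])
  a <- array(m, dim = dims[perm])
  aperm(a, order(perm))
}

#' Write a volume or mask as NIfTI-1
#'
#' Spacing is recorded in the NIfTI header (`pixdim`); masks are written as
#' `uint8`. Use the `_truth` / `_readerK` filename suffix convention for
#' cohort masks.
#'
#' @param x A [pet_volume()] or [voi_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  arr <- if (inherits(x, "voi_mask")) x$mask + 0L else x$values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path,
                     datatype = if (inherits(x, "voi_mask")) "uint8" else "float")
  invisible(path)
}

#' Read a NIfTI-1 volume or mask
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param as One of `"volume"` or `"mask"`.
#' @param provenance Provenance tag applied when `as = "mask"`.
#' @return A [pet_volume()] or [voi_mask()].
#' @export
read_nifti_volume <- function(path, as = c("volume", "mask"),
                              provenance = "freehand") {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  if (as == "volume") pet_volume(arr, spacing_mm = sp)
  else voi_mask(arr > 0.5, spacing_mm = sp, provenance = provenance)
}
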