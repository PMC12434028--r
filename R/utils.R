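#' @useDynLib striatparc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm anova p.adjust rnorm runif rlnorm sd coef model.matrix
#'   quantile setNames complete.cases
#' @importFrom utils write.table read.table head packageVersion
NULL

# ---- grid / affine helpers -------------------------------------------------
# Volumes are plain 3D arrays; the geometry travels alongside as a "grid"
# list: dim (3 ints), voxel size in mm (isotropic), and a RAS affine mapping
# 0-based voxel indices to world mm. Axes are ordered right-anterior-superior,
# so "rostral" is +y and "ventral" is -z.

#' Define a voxel grid
#'
#' @param dim integer vector of length 3, voxels per axis.
#' @param voxel_mm isotropic voxel edge length in mm.
#' @param origin world-mm coordinate of voxel (0,0,0); defaults to centring
#'   the grid on the world origin.
#' @return a `voxel_grid` list with `dim`, `voxel_mm` and a 4x4 `affine`.
#' @export
voxel_grid <- function(dim, voxel_mm = 1, origin = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L), voxel_mm > 0)
  if (is.null(origin)) origin <- -voxel_mm * (dim - 1L) / 2
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- origin
  structure(list(dim = dim, voxel_mm = voxel_mm, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %dx%dx%d, %.3g mm iso>\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_mm))
  invisible(x)
}

voxel_volume <- function(grid) grid$voxel_mm^3

# 1-based array index matrix (n x 3) -> world mm (n x 3)
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  ijk0 <- cbind(ijk - 1, 1)
  t(grid$affine %*% t(ijk0))[, 1:3, drop = FALSE]
}

# logical array -> n x 3 matrix of 1-based indices (column-major order)
mask_indices <- function(mask) {
  which(mask, arr.ind = TRUE)
}

new_volume <- function(grid, value = 0) {
  array(value, dim = grid$dim)
}

# mid-sagittal split; left hemisphere is x below the midline
hemisphere_masks <- function(grid) {
  mid <- grid$dim[1] / 2
  xs <- slice.index(array(0L, grid$dim), 1)
  list(left = xs <= mid, right = xs > mid)
}

mirror_x <- function(mask) {
  mask[rev(seq_len(dim(mask)[1])), , , drop = FALSE]
}

# ---- connected components --------------------------------------------------

#' Label connected components of a 3D mask
#'
#' @param mask logical 3D array.
#' @param connectivity one of 6, 18, 26 (face / face+edge / face+edge+corner).
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  connectivity <- match.arg(as.character(connectivity), c("6", "18", "26"))
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  lab <- label_components_cpp(as.logical(mask), dim(mask),
                              as.integer(connectivity))
  array(lab, dim = dim(mask))
}

component_sizes <- function(labels) {
  tab <- tabulate(labels[labels > 0])
  tab[tab > 0]
}

# ---- seeds -----------------------------------------------------------------
# One global seed spawns per-stage substreams so that stages are individually
# reproducible; the derivation stays below 2^31 - 1.
spawn_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.double(seed) * 2654435761 + 97 * as.double(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- small report helpers --------------------------------------------------

#' Percent difference of a group mean relative to a reference mean
#'
#' Expresses how much smaller (positive result) or larger (negative result)
#' `x` is relative to `ref`, as the percentage `100 * (ref - x) / ref`.
#'
#' @param x group mean (e.g. a patient-group mean volume in mm^3).
#' @param ref reference mean (e.g. the control-group mean).
#' @return signed percentage.
#' @export
percent_smaller <- function(x, ref) {
  stopifnot(is.finite(x), is.finite(ref), ref != 0)
  100 * (ref - x) / ref
}

#' Fold difference between two quantities
#'
#' @param a,b positive quantities; returns `a / b`.
#' @return fold ratio.
#' @export
fold_difference <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b), b > 0)
  a / b
}
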