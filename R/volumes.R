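#' Voxelised image volume
#'
#' The basic image container used throughout the package: a 2D or 3D numeric
#' array of voxel values together with the physical voxel size in mm per axis.
#' Activity images, attenuation maps, kappa weight images, sensitivity images
#' and binary masks (stored as 0/1) are all `image_volume` objects.
#'
#' @param values numeric matrix (2D) or 3D array of finite voxel values.
#' @param voxel_size positive numeric vector of voxel pitch in mm, one entry
#'   per axis (recycled from a scalar).
#' @return An object of class `image_volume` with fields `values`, `dims`
#'   and `voxel_size`.
#' @examples
#' img <- image_volume(matrix(1, 8, 8), voxel_size = 2)
#' dim(img$values)
#' @export
image_volume <- function(values, voxel_size = 1) {
  if (is.vector(values)) values <- matrix(values, nrow = length(values))
  dims <- dim(values)
  if (is.null(dims) || !(length(dims) %in% c(2L, 3L)))
    stop("values must be a 2D matrix or 3D array")
  if (!all(is.finite(values))) stop("image values must be finite")
  voxel_size <- rep(as.numeric(voxel_size), length.out = length(dims))
  if (any(voxel_size <= 0)) stop("voxel sizes must be strictly positive")
  structure(list(values = values, dims = dims, voxel_size = voxel_size),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s, voxel %s mm, range [%.4g, %.4g]>\n",
              paste(x$dims, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

is_image_volume <- function(x) inherits(x, "image_volume")

#' Replace the values of an image volume, keeping its grid metadata
#' @param img an `image_volume` template.
#' @param values replacement array, same extent as `img$values`.
#' @return A new `image_volume`.
#' @keywords internal
#' @export
with_values <- function(img, values) {
  v <- array(values, dim = img$dims)
  image_volume(v, img$voxel_size)
}

same_grid <- function(a, b) {
  identical(a$dims, b$dims) && isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

stopifnot_same_grid <- function(a, b, what = "images") {
  if (!same_grid(a, b)) stop("dimension mismatch between ", what)
}

#' Physical voxel-centre coordinates of a grid
#'
#' Centres the grid on the origin; axis k of voxel index i has coordinate
#' (i - (n_k + 1) / 2) * voxel_size[k] mm.
#' @param dims integer vector of grid extents.
#' @param voxel_size mm per axis.
#' @return A list of coordinate vectors, one per axis.
#' @keywords internal
grid_axes <- function(dims, voxel_size) {
  voxel_size <- rep(voxel_size, length.out = length(dims))
  lapply(seq_along(dims), function(k)
    (seq_len(dims[k]) - (dims[k] + 1) / 2) * voxel_size[k])
}
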