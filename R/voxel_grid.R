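#' 3D scalar field with physical voxel size
#'
#' A `voxel_grid` wraps a 3D numeric array together with an isotropic physical
#' voxel size in nanometres. It is the container for tomograms and detection
#' probability maps. Physical coordinates are in nm, origin at the volume
#' corner: the centre of voxel `(i, j, k)` (1-based) is at
#' `((i - 1) * voxel_size, (j - 1) * voxel_size, (k - 1) * voxel_size)`,
#' with axis order (x, y, z) matching MRC column/row/section.
#'
#' @param data 3D numeric array.
#' @param voxel_size isotropic voxel size in nm (> 0). Anisotropic voxel
#'   sizes are rejected: pass a single value.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, voxel_size) {
  if (length(dim(data)) != 3L) {
    stop("voxel_grid data must be a 3D array")
  }
  if (length(voxel_size) != 1L || !is.finite(voxel_size) || voxel_size <= 0) {
    stop("voxel_size must be a single positive number (isotropic voxels only)")
  }
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "voxel_grid")
}

#' Binary mask on a voxel grid geometry
#'
#' A `binary_mask` is a logical 3D field sharing the `voxel_grid` geometry;
#' it represents structure segmentations, lamella masks and label masks.
#'
#' @param data 3D logical array (numeric input is binarized at > 0.5).
#' @param voxel_size isotropic voxel size in nm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, voxel_size) {
  if (length(dim(data)) != 3L) {
    stop("binary_mask data must be a 3D array")
  }
  if (!is.logical(data)) {
    data <- array(data > 0.5, dim = dim(data))
  }
  if (length(voxel_size) != 1L || !is.finite(voxel_size) || voxel_size <= 0) {
    stop("voxel_size must be a single positive number (isotropic voxels only)")
  }
  structure(list(data = data, voxel_size = as.numeric(voxel_size)),
            class = "binary_mask")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %.4g nm/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %.4g nm/voxel, %d TRUE (%.2f%%)\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$data),
              100 * mean(x$data)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' @export
dim.binary_mask <- function(x) dim(x$data)

# internal: check that two grid-like objects share geometry
check_same_geometry <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) {
    stop("geometry mismatch: grid dimensions differ (",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"), ")")
  }
  if (abs(a$voxel_size - b$voxel_size) > 1e-9 * a$voxel_size) {
    stop("geometry mismatch: voxel sizes differ (", a$voxel_size, " vs ",
         b$voxel_size, " nm)")
  }
  invisible(TRUE)
}

# internal: physical coordinates (nm) of all voxel centres along each axis
axis_coords <- function(n, voxel_size) (seq_len(n) - 1) * voxel_size

# internal: convert nm coordinates to fractional 1-based voxel indices
nm_to_index <- function(x_nm, voxel_size) x_nm / voxel_size + 1

#' Exact Euclidean distance transform of a mask
#'
#' For each voxel, the distance in nm to the centre of the nearest TRUE voxel
#' of `mask`. Computed exactly with a separable squared-distance transform.
#'
#' @param mask a [binary_mask] with at least one TRUE voxel.
#' @return A [voxel_grid] of distances in nm.
#' @export
distance_to_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) {
    stop("distance_to_mask: mask is empty")
  }
  d2 <- edt_squared_cpp(as.logical(mask$data), dim(mask$data))
  voxel_grid(array(sqrt(d2) * mask$voxel_size, dim = dim(mask$data)),
             mask$voxel_size)
}

#' Label connected components of a mask
#'
#' @param mask a [binary_mask].
#' @param connectivity `"face"` (6-neighbourhood) or `"face+edge+corner"`
#'   (26-neighbourhood, the default: diagonal voxels of one blob stay merged).
#' @return Integer 3D array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = c("face+edge+corner", "face")) {
  stopifnot(inherits(mask, "binary_mask"))
  connectivity <- match.arg(connectivity)
  conn <- if (connectivity == "face") 6L else 26L
  lab <- label_components_cpp(as.logical(mask$data), dim(mask$data), conn)
  array(lab, dim = dim(mask$data))
}

# internal: trilinear interpolation of a 3D array at continuous 1-based
# fractional indices (matrix idx with columns i, j, k). Points are clamped
# to the valid interpolation domain [1, n].
trilinear_sample <- function(arr, idx) {
  d <- dim(arr)
  i <- pmin(pmax(idx[, 1], 1), d[1])
  j <- pmin(pmax(idx[, 2], 1), d[2])
  k <- pmin(pmax(idx[, 3], 1), d[3])
  i0 <- pmin(floor(i), d[1] - 1); j0 <- pmin(floor(j), d[2] - 1)
  k0 <- pmin(floor(k), d[3] - 1)
  fi <- i - i0; fj <- j - j0; fk <- k - k0
  at <- function(ii, jj, kk) arr[cbind(ii, jj, kk)]
  v000 <- at(i0,     j0,     k0)
  v100 <- at(i0 + 1, j0,     k0)
  v010 <- at(i0,     j0 + 1, k0)
  v110 <- at(i0 + 1, j0 + 1, k0)
  v001 <- at(i0,     j0,     k0 + 1)
  v101 <- at(i0 + 1, j0,     k0 + 1)
  v011 <- at(i0,     j0 + 1, k0 + 1)
  v111 <- at(i0 + 1, j0 + 1, k0 + 1)
  (v000 * (1 - fi) * (1 - fj) * (1 - fk) +
   v100 * fi       * (1 - fj) * (1 - fk) +
   v010 * (1 - fi) * fj       * (1 - fk) +
   v110 * fi       * fj       * (1 - fk) +
   v001 * (1 - fi) * (1 - fj) * fk +
   v101 * fi       * (1 - fj) * fk +
   v011 * (1 - fi) * fj       * fk +
   v111 * fi       * fj       * fk)
}
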