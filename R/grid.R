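#' Isotropic Cartesian voxel grid
#'
#' One lattice is shared by the mechanics neighbour search and the diffusion
#' solver. Construction enforces that the voxel side is at least the nominal
#' maximum cell-cell interaction distance, so the 27-voxel force gather is
#' exhaustive.
#'
#' @param dx voxel side length (um), identical along all three axes.
#' @param dim integer length-3 voxel counts (nx, ny, nz).
#' @param origin length-3 corner coordinate (um).
#' @param max_interaction optional distance (um) that `dx` must not undercut.
#' @return an object of class `Grid` with empty voxel ranges.
#' @export
newGrid <- function(dx, dim, origin = c(0, 0, 0), max_interaction = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1), dx > 0)
  if (!is.null(max_interaction) && dx < max_interaction)
    stop(sprintf(paste0("voxel side %.4g um is shorter than the maximum ",
                        "cell-cell interaction distance %.4g um"),
                 dx, max_interaction))
  structure(list(origin = as.numeric(origin), dx = dx,
                 nx = dim[1], ny = dim[2], nz = dim[3],
                 voxel_start = NULL, voxel_end = NULL),
            class = "Grid")
}

#' @export
print.Grid <- function(x, ...) {
  cat(sprintf("<Grid> %d x %d x %d voxels, dx = %g um, origin (%g, %g, %g)\n",
              x$nx, x$ny, x$nz, x$dx,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Number of voxels / voxel volume
#' @param grid a `Grid`.
#' @return scalar.
#' @export
nVoxels <- function(grid) grid$nx * grid$ny * grid$nz

#' @rdname nVoxels
#' @export
voxelVolume <- function(grid) grid$dx^3

#' Voxel indices of points
#'
#' Containment follows the floor convention: a point `1 nm` inside a voxel
#' face belongs to that voxel, not to its neighbour. Indices are 0-based.
#'
#' @param x n-by-3 matrix of positions (um), or a `CellPopulation`.
#' @param grid a `Grid`.
#' @return list with integer vectors `i`, `j`, `k` and the linear id
#'   `linear = i + nx*(j + ny*k)` (0-based).
#' @export
voxelIndex <- function(x, grid) {
  if (inherits(x, "CellPopulation")) x <- x$position
  i <- as.integer(floor((x[, 1] - grid$origin[1]) / grid$dx))
  j <- as.integer(floor((x[, 2] - grid$origin[2]) / grid$dx))
  k <- as.integer(floor((x[, 3] - grid$origin[3]) / grid$dx))
  if (length(i) > 0 &&
      (min(i, j, k) < 0 || any(i >= grid$nx) || any(j >= grid$ny) ||
       any(k >= grid$nz)))
    stop("position outside the grid domain")
  list(i = i, j = j, k = k, linear = i + grid$nx * (j + grid$ny * k))
}

#' Morton (Z-order) key from voxel indices
#'
#' Interleaves the bits of the three indices: bit b of `i` goes to position
#' 3b, of `j` to 3b+1, of `k` to 3b+2. The key is returned as a double and is
#' exact for indices up to 17 bits per axis.
#'
#' @param i,j,k integer voxel indices (0-based).
#' @param grid optional `Grid`; when given, indices are checked against its
#'   extent.
#' @return numeric vector of keys.
#' @export
mortonEncode <- function(i, j, k, grid = NULL) {
  i <- as.integer(i); j <- as.integer(j); k <- as.integer(k)
  if (!is.null(grid) &&
      (any(i < 0 | i >= grid$nx) || any(j < 0 | j >= grid$ny) ||
       any(k < 0 | k >= grid$nz)))
    stop("voxel index out of domain")
  morton_encode_cpp(i, j, k)
}
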