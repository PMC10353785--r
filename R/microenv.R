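#' A diffusible substance field on the grid
#'
#' Holds the per-voxel concentration together with its transport constants
#' and boundary specification. Boundaries follow the finite-volume zero-flux
#' (Neumann) closure by default; Dirichlet conditions are realized as pinned
#' voxel sets whose values are re-imposed after every operator application
#' (domain faces for the spheroid scenario, the duct-wall shell for the duct
#' scenario, or any interior mask).
#'
#' @param grid a `Grid`.
#' @param value initial uniform concentration, or a full array (mmHg for
#'   oxygen).
#' @param D diffusion coefficient (um^2/min).
#' @param lam decay rate (1/min).
#' @param rho_star saturation concentration for the supply term (mmHg).
#' @param S supply rate: scalar or per-voxel array (1/min).
#' @param pinned integer linear voxel ids (1-based) held at fixed values.
#' @param pinned_value values for the pinned voxels (recycled).
#' @return an object of class `Field`.
#' @export
newField <- function(grid, value, D = 1e5, lam = 0.1, rho_star = value[1],
                     S = 0, pinned = integer(0), pinned_value = numeric(0)) {
  dims <- c(grid$nx, grid$ny, grid$nz)
  rho <- if (length(value) == 1) array(value, dims) else array(value, dims)
  pinned <- as.integer(pinned)
  pinned_value <- rep_len(as.numeric(pinned_value), length(pinned))
  f <- structure(list(rho = rho, D = D, lam = lam, rho_star = rho_star,
                      S = S, U = array(0, dims),
                      pinned = pinned, pinned_value = pinned_value),
                 class = "Field")
  f$rho[pinned] <- pinned_value
  f
}

#' @export
print.Field <- function(x, ...) {
  cat(sprintf(paste0("<Field> %s voxels, D = %g um^2/min, lambda = %g/min, ",
                     "%d pinned\n  rho in [%g, %g]\n"),
              paste(dim(x$rho), collapse = " x "), x$D, x$lam,
              length(x$pinned), min(x$rho), max(x$rho)))
  invisible(x)
}

#' Linear ids of all domain-face voxels
#'
#' Convenience mask for pinning a Dirichlet condition on the whole boundary.
#'
#' @param grid a `Grid`.
#' @return integer vector of 1-based linear voxel ids.
#' @export
faceVoxels <- function(grid) {
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  idx <- array(seq_len(nx * ny * nz), c(nx, ny, nz))
  face <- array(FALSE, c(nx, ny, nz))
  face[c(1, nx), , ] <- TRUE
  face[, c(1, ny), ] <- TRUE
  face[, , c(1, nz)] <- TRUE
  idx[face]
}

#' Per-voxel oxygen uptake map from the discrete cells
#'
#' `U_v = sum over living cells in v of (V_cell / V_voxel) * U_o`; dead
#' cells do not consume. The uptake rate is the relative concentration
#' decrease rate, 1/min.
#'
#' @param pop a `CellPopulation`.
#' @param grid a `Grid`.
#' @param uparams a [microenvParams()].
#' @return array of uptake rates, one per voxel.
#' @export
computeUptake <- function(pop, grid, uparams) {
  dims <- c(grid$nx, grid$ny, grid$nz)
  if (pop$n == 0) return(array(0, dims))
  vox <- voxelIndex(pop, grid)
  U <- compute_uptake_cpp(vox$linear, pop$V, isLiving(pop$phase),
                          nVoxels(grid), voxelVolume(grid), uparams$U_o)
  array(U, dims)
}

#' Implicit supply/uptake update
#'
#' Per voxel, `rho <- (rho + dt * S * rho_star) / (1 + dt * (S + U))` --
#' the implicit first-order form of the supply/uptake operator; pinned
#' voxels are re-imposed afterwards.
#'
#' @param field a `Field` with current `U` (see [computeUptake()]) and `S`.
#' @param dt diffusion time step (min).
#' @return the updated `Field`.
#' @export
supplyUptakeStep <- function(field, dt) {
  dims <- dim(field$rho)
  rho <- supply_uptake_cpp(as.vector(field$rho), as.vector(field$U),
                           as.numeric(field$S), field$rho_star, dt,
                           field$pinned - 1L, field$pinned_value)
  field$rho <- array(rho, dims)
  field
}

#' Finite-volume tridiagonal system for one 1-D diffusion-decay sweep
#'
#' Interior rows have diagonal `1 + dt*lam/3 + 2*dt*D/dx^2` and off-diagonals
#' `-dt*D/dx^2`; the first and last rows carry a single flux term (zero-flux
#' closure), so interior row sums equal `1 + dt*lam/3`. A single-voxel axis
#' reduces to pure decay.
#'
#' @param n number of voxels along the axis.
#' @param D diffusion coefficient (um^2/min).
#' @param lam full decay rate (1/min); each sweep applies a third of it.
#' @param dt time step (min).
#' @param dx voxel side (um).
#' @return list with `sub`, `diag`, `super` (lengths n-1, n, n-1).
#' @export
buildTridiagonal <- function(n, D, lam, dt, dx) {
  stopifnot(n >= 1)
  q <- dt * D / dx^2
  lam3 <- dt * lam / 3
  dg <- rep(1 + lam3 + 2 * q, n)
  if (n == 1) dg <- 1 + lam3
  else dg[c(1, n)] <- 1 + lam3 + q
  list(sub = rep(-q, max(n - 1, 0)), diag = dg, super = rep(-q, max(n - 1, 0)))
}

#' Solve a tridiagonal linear system with the Thomas algorithm
#'
#' O(n) forward elimination and back substitution; valid for the diagonally
#' dominant systems produced by [buildTridiagonal()] (a zero pivot raises an
#' error).
#'
#' @param sub,diag,super the three bands (lengths n-1, n, n-1).
#' @param rhs right-hand side (length n).
#' @return solution vector.
#' @export
thomasSolve <- function(sub, diag, super, rhs) {
  thomas_solve_cpp(as.numeric(sub), as.numeric(diag), as.numeric(super),
                   as.numeric(rhs))
}

#' One locally-one-dimensional diffusion-decay step
#'
#' Three sequential implicit sweeps (x, then y, then z), each solving one
#' tridiagonal system per perpendicular strip with a third of the decay rate;
#' pinned Dirichlet voxels are re-imposed after every sweep. With the
#' operator splitting used by the scheduler this step precedes the
#' supply/uptake update.
#'
#' @param field a `Field`.
#' @param grid the `Grid`.
#' @param dt diffusion time step (min).
#' @param reverse sweep z, then y, then x instead (the splitting orders
#'   differ at second order in `dt`).
#' @return the updated `Field`.
#' @export
lodDiffusionStep <- function(field, grid, dt, reverse = FALSE) {
  rho <- lod_step_cpp(as.vector(field$rho), grid$nx, grid$ny, grid$nz,
                      field$D, field$lam, dt, grid$dx,
                      field$pinned - 1L, field$pinned_value, reverse)
  field$rho <- array(rho, dim(field$rho))
  field
}

#' Oxygen seen by each cell
#'
#' Nearest-voxel sampling without interpolation: each cell reads the
#' concentration of its containing voxel (floor convention).
#'
#' @param pop a `CellPopulation`.
#' @param field a `Field`.
#' @param grid the `Grid`.
#' @return numeric vector, one value per cell (mmHg).
#' @export
sampleConcentration <- function(pop, field, grid) {
  if (pop$n == 0) return(numeric(0))
  vox <- voxelIndex(pop, grid)
  field$rho[vox$linear + 1L]
}
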