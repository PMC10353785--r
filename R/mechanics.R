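#' Sort a population by Morton key and index the voxel occupancy
#'
#' Cells are reordered by ascending Morton key (stable sort), so cells
#' sharing a voxel occupy a contiguous index range; the grid gains
#' `voxel_start` / `voxel_end` (0-based, half-open) per linear voxel id,
#' with `start == end` for empty voxels. Equivalent in contract to the
#' radix-sorted GPU layout; here the stable radix sort of `order()` does the
#' work.
#'
#' @param pop a `CellPopulation` with all positions inside the grid.
#' @param grid a `Grid`.
#' @return list with elements `population` (permuted) and `grid` (ranges
#'   filled in).
#' @export
sortByVoxel <- function(pop, grid) {
  vox <- voxelIndex(pop, grid)
  key <- morton_encode_cpp(vox$i, vox$j, vox$k)
  ord <- order(key, method = "radix")
  pop <- subsetPopulation(pop, ord)
  pop$sort_key <- key[ord]
  rng <- voxel_ranges_cpp(vox$linear[ord], nVoxels(grid))
  grid$voxel_start <- rng$start
  grid$voxel_end <- rng$end
  list(population = pop, grid = grid)
}

#' Pairwise cell-cell force
#'
#' Force on cell i from cell j: adhesion `C_cca (1 - d/R_A)^2` directed
#' toward j inside the adhesive reach `R_A = factor * (R_i + R_j)`, plus
#' repulsion `C_ccr (1 - d/R_R)^2` directed away inside the contact distance
#' `R_R = R_i + R_j`; zero beyond `R_A`; antisymmetric under i <-> j.
#' Coincident centers get a pure repulsion of magnitude `C_ccr` along the
#' deterministic fallback axis (-x for i).
#'
#' @param xi,xj length-3 positions (um).
#' @param Ri,Rj cell radii (um).
#' @param params a [mechanicsParams()].
#' @return length-3 force vector on i (um/min after drag normalization).
#' @export
pairwiseForce <- function(xi, xj, Ri, Rj, params) {
  r <- xj - xi
  d <- sqrt(sum(r * r))
  RR <- Ri + Rj
  RA <- params$adhesion_distance_factor * RR
  if (d == 0) {
    warning("coincident cell centers; fallback axis repulsion applied")
    return(c(-params$C_ccr, 0, 0))
  }
  if (d > RA) return(c(0, 0, 0))
  m <- params$C_cca * (1 - d / RA)^2
  if (d <= RR) m <- m - params$C_ccr * (1 - d / RR)^2
  m * r / d
}

#' Aggregate short-range forces over the 27-voxel neighbourhood
#'
#' For each cell, sums [pairwiseForce()] over every other cell in the 3x3x3
#' block of voxels around its own (clipped at domain faces) and adds the
#' motile force. Requires [sortByVoxel()] to have been applied this step.
#'
#' @param pop the sorted `CellPopulation`.
#' @param grid the `Grid` carrying current voxel ranges.
#' @param params a [mechanicsParams()].
#' @return n-by-3 matrix of total forces.
#' @export
aggregateForces <- function(pop, grid, params) {
  if (is.null(grid$voxel_start))
    stop("grid has no voxel ranges; call sortByVoxel() first")
  vox <- voxelIndex(pop, grid)
  fmot <- matrix(params$F_mot, nrow = pop$n, ncol = 3, byrow = TRUE)
  aggregate_forces_cpp(pop$position, cellRadius(pop), vox$i, vox$j, vox$k,
                       grid$voxel_start, grid$voxel_end,
                       grid$nx, grid$ny, grid$nz,
                       params$C_ccr, params$C_cca,
                       params$adhesion_distance_factor, fmot)
}

#' Velocities in the overdamped (inertialess) limit
#'
#' With zero acceleration the drag balances the total force, so
#' `v = F / eta`; at the default `eta = 1` velocity equals force numerically.
#'
#' @param forces n-by-3 matrix of total forces (motile force included).
#' @param params a [mechanicsParams()].
#' @return n-by-3 velocity matrix (um/min).
#' @export
cellVelocities <- function(forces, params) forces / params$eta

#' Advance positions with the two-step Adams-Bashforth scheme
#'
#' `x <- x + dt/2 * (3 v_now - v_prev)`; afterwards `previous_velocity`
#' holds `v_now`. The first mechanics step of a run has no previous velocity
#' and falls back to forward Euler (`bootstrap = TRUE` sets `v_prev = v_now`).
#'
#' @param pop a `CellPopulation`.
#' @param v n-by-3 matrix of current velocities.
#' @param dt mechanics time step (min).
#' @param bootstrap use forward Euler for this step.
#' @return the updated `CellPopulation`.
#' @export
updatePositions <- function(pop, v, dt, bootstrap = FALSE) {
  v_prev <- if (bootstrap) v else pop$previous_velocity
  pop$position <- pop$position + (dt / 2) * (3 * v - v_prev)
  pop$velocity <- v
  pop$previous_velocity <- v
  pop
}

#' Confine cells to the domain box and, optionally, a duct lumen
#'
#' Cell centers are clamped into the grid box (a hair inside the faces so
#' voxel lookup stays valid). With a duct, centers are additionally projected
#' so the whole cell fits in the lumen: radial distance at most
#' `R_duct - R_cell` and axial coordinate at least `closed_end + R_cell`.
#' `previous_velocity` is left untouched.
#'
#' @param pop a `CellPopulation`.
#' @param grid a `Grid`.
#' @param duct optional [ductGeometry()].
#' @return the projected `CellPopulation`.
#' @export
applyConfinement <- function(pop, grid, duct = NULL) {
  if (pop$n == 0) return(pop)
  eps <- 1e-6 * grid$dx
  lo <- grid$origin + eps
  hi <- grid$origin + c(grid$nx, grid$ny, grid$nz) * grid$dx - eps
  for (a in 1:3)
    pop$position[, a] <- pmin(pmax(pop$position[, a], lo[a]), hi[a])
  if (!is.null(duct)) {
    R <- cellRadius(pop)
    cyz <- duct$center_yz
    if (is.null(cyz))
      cyz <- grid$origin[2:3] + c(grid$ny, grid$nz) * grid$dx / 2
    dy <- pop$position[, 2] - cyz[1]
    dz <- pop$position[, 3] - cyz[2]
    rad <- sqrt(dy^2 + dz^2)
    rmax <- pmax(duct$radius - R, 0)
    out <- rad > rmax
    if (any(out)) {
      scale <- ifelse(rad[out] > 0, rmax[out] / rad[out], 0)
      pop$position[out, 2] <- cyz[1] + dy[out] * scale
      pop$position[out, 3] <- cyz[2] + dz[out] * scale
    }
    xmin <- duct$closed_end + R
    pop$position[, 1] <- pmax(pop$position[, 1], xmin)
  }
  pop
}
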