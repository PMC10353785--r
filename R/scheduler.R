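#' Initialize the free-floating spheroid scenario
#'
#' Seeds `n_cells` quiescent cells at the standard volume, uniformly placed
#' in a sphere centered in the domain. Unless an explicit `cluster_radius`
#' is given, the sphere is sized so the seeds sit at the configured packing
#' fraction (random close packing, 0.64, by default). Phase clocks start
#' uniform in `[0, 1/r_pro_max]` so the colony is not artificially
#' synchronized. The oxygen field starts uniform at the boundary value with
#' all domain faces pinned (Dirichlet).
#'
#' @param config a [simulationConfig()] with scenario `"HDS"`.
#' @return list with `population`, `field`, `grid`, `duct = NULL`.
#' @export
initHDS <- function(config) {
  grid <- newGrid(config$grid_dx, config$grid_dim, config$grid_origin,
                  max_interaction = maxInteractionDistance(config))
  vp <- config$volume
  V_std <- standardVolume(vp)
  n <- config$hds$n_cells
  r_cl <- config$hds$cluster_radius
  if (is.null(r_cl))
    r_cl <- (n * V_std / (config$hds$packing_fraction * 4 / 3 * pi))^(1 / 3)
  center <- grid$origin + c(grid$nx, grid$ny, grid$nz) * grid$dx / 2
  if (r_cl > min(c(grid$nx, grid$ny, grid$nz)) * grid$dx / 2)
    stop("seed cluster does not fit in the domain")
  pos <- .sampleBall(n, r_cl)
  pos <- sweep(pos, 2, center, "+")
  pop <- .seedPopulation(pos, vp, config$phase)
  u <- config$microenv
  faces <- faceVoxels(grid)
  field <- newField(grid, u$boundary_value, D = u$D, lam = u$lam,
                    rho_star = u$rho_star, pinned = faces,
                    pinned_value = rep(u$boundary_value, length(faces)))
  list(population = pop, field = field, grid = grid, duct = NULL)
}

#' Initialize the duct-confined (DCIS) scenario
#'
#' A cluster of `n_seed` quiescent cells is packed in a plug at the closed
#' end of the duct lumen; the duct wall -- the one-voxel-thick shell of
#' non-lumen voxels touching the lumen, including the cap behind the closed
#' end -- is pinned at the wall oxygen value (Dirichlet), while the open end
#' on the +x domain face keeps the zero-flux closure. The field starts
#' uniform at the wall value.
#'
#' @param config a [simulationConfig()] with scenario `"DCIS"`.
#' @return list with `population`, `field`, `grid`, `duct`.
#' @export
initDCIS <- function(config) {
  grid <- newGrid(config$grid_dx, config$grid_dim, config$grid_origin,
                  max_interaction = maxInteractionDistance(config))
  duct <- config$dcis$duct
  if (is.null(duct$center_yz))
    duct$center_yz <- grid$origin[2:3] + c(grid$ny, grid$nz) * grid$dx / 2
  if (duct$radius + grid$dx > min(grid$ny, grid$nz) * grid$dx / 2)
    stop("duct (plus its wall shell) does not fit in the domain cross-section")
  vp <- config$volume
  V_std <- standardVolume(vp)
  R_std <- cellRadius(V_std)
  n <- config$dcis$n_seed
  if (n > 0) {
    r_eff <- duct$radius - R_std
    L0 <- n * V_std / (config$dcis$packing_fraction * pi * r_eff^2)
    ang <- stats::runif(n, 0, 2 * pi)
    rad <- r_eff * sqrt(stats::runif(n))
    x <- stats::runif(n, duct$closed_end + R_std,
                      duct$closed_end + R_std + L0)
    pos <- cbind(x, duct$center_yz[1] + rad * cos(ang),
                 duct$center_yz[2] + rad * sin(ang))
    pop <- .seedPopulation(pos, vp, config$phase)
  } else {
    pop <- emptyPopulation()
  }
  shell <- ductWallShell(grid, duct)
  u <- config$microenv
  field <- newField(grid, duct$wall_value, D = u$D, lam = u$lam,
                    rho_star = u$rho_star, pinned = shell,
                    pinned_value = rep(duct$wall_value, length(shell)))
  list(population = pop, field = field, grid = grid, duct = duct)
}

# Uniform sample inside a ball of radius r centered at the origin.
.sampleBall <- function(n, r) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  rr <- r * stats::runif(n)^(1 / 3)
  s <- sqrt(1 - z^2)
  cbind(rr * s * cos(phi), rr * s * sin(phi), rr * z)
}

# Quiescent seeds at the standard volume with desynchronized clocks.
.seedPopulation <- function(pos, vparams, pparams) {
  n <- nrow(pos)
  V_NS <- vparams$V_NS_target[QUIESCENT]
  V_CS <- vparams$V_CS_target[QUIESCENT]
  V_F <- vparams$f_F / (1 - vparams$f_F) * (V_NS + V_CS)
  clock <- stats::runif(n, 0, 60 / pparams$r_pro_max)
  newCellPopulation(pos, phase = QUIESCENT, V_F = V_F, V_NS = V_NS,
                    V_CS = V_CS, phase_clock = clock)
}

#' Voxels forming the duct-wall Dirichlet shell
#'
#' Lumen voxels are those whose center lies inside the cylinder and past the
#' closed end; the shell is every non-lumen voxel sharing a face with a lumen
#' voxel (this includes the cap behind the closed end and is topologically
#' closed around the lumen except at the open domain face).
#'
#' @param grid a `Grid`.
#' @param duct a [ductGeometry()] with `center_yz` resolved.
#' @return integer vector of 1-based linear voxel ids.
#' @export
ductWallShell <- function(grid, duct) {
  L <- ductLumenMask(grid, duct)
  nb <- array(FALSE, dim(L))
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  if (nx > 1) {
    nb[-nx, , ] <- nb[-nx, , ] | L[-1, , ]
    nb[-1, , ] <- nb[-1, , ] | L[-nx, , ]
  }
  if (ny > 1) {
    nb[, -ny, ] <- nb[, -ny, ] | L[, -1, ]
    nb[, -1, ] <- nb[, -1, ] | L[, -ny, ]
  }
  if (nz > 1) {
    nb[, , -nz] <- nb[, , -nz] | L[, , -1]
    nb[, , -1] <- nb[, , -1] | L[, , -nz]
  }
  which(!L & nb)
}

#' @rdname ductWallShell
#' @export
ductLumenMask <- function(grid, duct) {
  xc <- grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$dx
  yc <- grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$dx
  zc <- grid$origin[3] + (seq_len(grid$nz) - 0.5) * grid$dx
  inx <- xc > duct$closed_end & xc <= duct$closed_end + duct$length
  r2 <- outer((yc - duct$center_yz[1])^2, (zc - duct$center_yz[2])^2, "+")
  inr <- r2 <= duct$radius^2
  outer(inx, inr, "&")
}

#' Run a full multiscale simulation
#'
#' Validates the configuration, seeds the scenario, then loops over
#' diffusion ticks. Every tick: uptake map, LOD diffusion-decay, implicit
#' supply/uptake. At the mechanics cadence: Morton sort, 27-voxel force
#' gather, overdamped velocities, Adams-Bashforth positions, confinement. At
#' the phase cadence: oxygen sampling, stochastic phase transitions,
#' component-volume relaxation, division and array compaction. Metrics are
#' recorded at the output cadence; a run with a fixed seed is bit-for-bit
#' reproducible. The run stops early (with a final record) if the population
#' dies out.
#'
#' @param config a [simulationConfig()].
#' @param init optional list with `population`, `field`, `grid` and
#'   optionally `duct` (required for the custom scenario; overrides the
#'   scenario initializer otherwise).
#' @param store_snapshots keep a copy of the population at every output time
#'   (memory-heavy; off by default).
#' @param snapshot_dir if non-NULL, write CSV snapshots there at the output
#'   cadence via [writeSnapshot()].
#' @param verbose print a progress line at every output time.
#' @return a `SimulationResult`: `metrics` data.frame (time, population and
#'   phase counts, radius, necrotic core radius, front), final `population`,
#'   `field`, `grid`, `duct`, `config`, `counters` of module invocations,
#'   and `snapshots` (list of populations) when requested.
#' @export
runSimulation <- function(config, init = NULL, store_snapshots = FALSE,
                          snapshot_dir = NULL, verbose = FALSE) {
  viol <- validateConfig(config)
  if (length(viol) > 0)
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  set.seed(config$seed)
  if (is.null(init)) {
    init <- switch(config$scenario,
      HDS = initHDS(config),
      DCIS = initDCIS(config),
      custom = stop("custom scenario requires an explicit `init`"))
  }
  pop <- init$population
  field <- init$field
  grid <- init$grid
  duct <- init$duct
  pparams <- config$phase
  vparams <- config$volume
  mparams <- config$mechanics
  uparams <- config$microenv
  dt_diff <- config$dt_diff
  mech_every <- round(config$dt_mech / dt_diff)
  phase_every <- round(config$dt_phase / dt_diff)
  out_every <- max(1, round(config$output_every / dt_diff))
  n_ticks <- floor(config$t_end / dt_diff + 1e-9)
  counters <- c(diffusion = 0L, mechanics = 0L, phases = 0L)
  first_mech <- TRUE
  rows <- list(.metricsRow(0, pop, duct))
  snaps <- if (store_snapshots) list(`0` = pop) else NULL
  if (!is.null(snapshot_dir))
    writeSnapshot(pop, field, grid, 0, snapshot_dir)
  tick <- 0L
  pop_dirty <- TRUE  # uptake map is stale only when cells changed
  while (tick < n_ticks) {
    tick <- tick + 1L
    t <- tick * dt_diff
    if (pop_dirty) {
      field$U <- computeUptake(pop, grid, uparams)
      pop_dirty <- FALSE
    }
    field <- lodDiffusionStep(field, grid, dt_diff)
    field <- supplyUptakeStep(field, dt_diff)
    counters["diffusion"] <- counters["diffusion"] + 1L
    if (tick %% mech_every == 0 && pop$n > 0) {
      sv <- sortByVoxel(pop, grid)
      pop <- sv$population
      forces <- aggregateForces(pop, sv$grid, mparams)
      v <- cellVelocities(forces, mparams)
      pop <- updatePositions(pop, v, config$dt_mech, bootstrap = first_mech)
      pop <- applyConfinement(pop, grid, duct)
      first_mech <- FALSE
      pop_dirty <- TRUE
      counters["mechanics"] <- counters["mechanics"] + 1L
    }
    if (tick %% phase_every == 0 && pop$n > 0) {
      p_oxy <- sampleConcentration(pop, field, grid)
      up <- updatePhases(pop, p_oxy, config$dt_phase, pparams, vparams)
      pop <- updateVolumes(up$population, config$dt_phase, vparams)
      daughters <- divideCells(pop, up$divisions)
      pop <- applyBirthDeath(pop, up$divisions, daughters, up$removals)
      pop_dirty <- TRUE
      counters["phases"] <- counters["phases"] + 1L
    }
    if (tick %% out_every == 0 || pop$n == 0) {
      rows[[length(rows) + 1]] <- .metricsRow(t, pop, duct)
      if (store_snapshots) snaps[[as.character(t)]] <- pop
      if (!is.null(snapshot_dir))
        writeSnapshot(pop, field, grid, t, snapshot_dir)
      if (verbose)
        message(sprintf("t = %8.1f min  n = %d", t, pop$n))
      if (pop$n == 0) break
    }
  }
  structure(list(metrics = do.call(rbind, rows), population = pop,
                 field = field, grid = grid, duct = duct, config = config,
                 counters = counters, snapshots = snaps),
            class = "SimulationResult")
}

#' @export
print.SimulationResult <- function(x, ...) {
  m <- x$metrics
  cat("<SimulationResult>", x$config$scenario, "scenario,",
      nrow(m), "records over", max(m$time), "min\n")
  cat("  final cells:", x$population$n,
      " radius:", format(m$radius[nrow(m)], digits = 5), "um\n")
  invisible(x)
}

.metricsRow <- function(t, pop, duct) {
  counts <- tabulate(pop$phase, nbins = 6)
  names(counts) <- c("n_premitotic", "n_postmitotic", "n_quiescent",
                     "n_apoptotic", "n_early_necrotic", "n_late_necrotic")
  data.frame(time = t, n_total = pop$n, t(counts),
             radius = if (pop$n > 0) spheroidRadius(pop) else NA_real_,
             necrotic_radius = if (pop$n > 0) necroticCoreRadius(pop)
                               else NA_real_,
             front = if (!is.null(duct) && pop$n > 0) dcisFront(pop, duct)
                     else NA_real_)
}
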