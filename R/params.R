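#' Phase-transition parameters
#'
#' Durations are in hours and rates in 1/hour, the units of the reference
#' parameter table (the engine converts to minutes once at run start).
#' Defaults are the Ki67-advanced reference set: deterministic premitotic and
#' postmitotic durations, a constant apoptosis rate, an oxygen-dependent
#' proliferation ramp between `Th_pro` and `Sa_pro`, and an oxygen-dependent
#' necrosis ramp between `Th_nec` and `Sa_nec` (all oxygen levels in mmHg).
#'
#' @param T_prem,T_postm premitotic / postmitotic phase durations (hour).
#' @param r_apop apoptosis rate (1/hour).
#' @param r_pro_max,Sa_pro,Th_pro max proliferation rate (1/hour), oxygen at
#'   which it is reached, and oxygen below which it is zero (mmHg).
#' @param r_nec_max,Sa_nec,Th_nec max necrosis rate (1/hour), oxygen at which
#'   it is reached, and oxygen above which it is zero (mmHg).
#' @return a `PhaseParams` list.
#' @export
phaseParams <- function(T_prem = 13, T_postm = 2.5, r_apop = 0.0060,
                        r_pro_max = 0.1176, Sa_pro = 10, Th_pro = 5,
                        r_nec_max = 0.1667, Sa_nec = 2.5, Th_nec = 5) {
  structure(list(T_prem = T_prem, T_postm = T_postm, r_apop = r_apop,
                 r_pro_max = r_pro_max, Sa_pro = Sa_pro, Th_pro = Th_pro,
                 r_nec_max = r_nec_max, Sa_nec = Sa_nec, Th_nec = Th_nec),
            class = "PhaseParams")
}

#' Component-volume parameters
#'
#' Per-phase relaxation targets and rates for the three cell components
#' (fluid, nuclear solid, cytoplasmic solid), in the order premitotic,
#' postmitotic, quiescent, apoptotic, early necrotic, late necrotic. The
#' fluid target is `f_F * V` in living phases, the current total volume `V`
#' during early necrosis (oncotic swelling), and zero for apoptotic and late
#' necrotic cells; `fluid_mode` encodes this (0 fraction-of-V, 1 current V,
#' 2 zero). Rates are 1/hour, volumes um^3.
#'
#' @param f_F fluid fraction target of living cells.
#' @param r_F,r_NS,r_CS per-phase rates (1/hour), length 6.
#' @param V_NS_target,V_CS_target per-phase solid targets (um^3), length 6.
#' @param fluid_mode per-phase fluid-target mode, length 6.
#' @param rupture_ratio early necrotic cells burst (enter the late necrotic
#'   stage) once `V >= rupture_ratio * V_std`.
#' @param removal_fraction dead cells are deleted once
#'   `V < removal_fraction * V_std`.
#' @return a `VolumeParams` list.
#' @export
volumeParams <- function(f_F = 0.7502,
                         r_F = c(3, 3, 3, 3, 0.67, 0.05),
                         V_NS_target = c(270, 135, 135, 0, 0, 0),
                         r_NS = c(0.33, 0.33, 0.33, 0.35, 0.013, 0.013),
                         V_CS_target = c(976, 488, 488, 0, 0, 0),
                         r_CS = c(0.27, 0.33, 0.33, 1, 0.0032, 0.0032),
                         fluid_mode = c(0L, 0L, 0L, 2L, 1L, 2L),
                         rupture_ratio = 2.0,
                         removal_fraction = 0.02) {
  structure(list(f_F = f_F, r_F = r_F,
                 V_NS_target = V_NS_target, r_NS = r_NS,
                 V_CS_target = V_CS_target, r_CS = r_CS,
                 fluid_mode = as.integer(fluid_mode),
                 rupture_ratio = rupture_ratio,
                 removal_fraction = removal_fraction),
            class = "VolumeParams")
}

#' Quiescent standard volume implied by the volume parameters
#'
#' V_std = (V_NS^q + V_CS^q) / (1 - f_F), about 2494 um^3 at the defaults.
#'
#' @param vparams a [volumeParams()] object.
#' @return volume in um^3.
#' @export
standardVolume <- function(vparams) {
  (vparams$V_NS_target[QUIESCENT] + vparams$V_CS_target[QUIESCENT]) /
    (1 - vparams$f_F)
}

#' Mechanics parameters
#'
#' The drag coefficient eta is 1 with the force constants expressed directly
#' in um/min, so velocity equals total force numerically; the maximum
#' adhesive interaction distance of a pair is
#' `adhesion_distance_factor * (R_i + R_j)`.
#'
#' @param C_cca,C_ccr cell-cell adhesion / repulsion strengths (um/min).
#' @param adhesion_distance_factor dimensionless, >= 1.
#' @param eta fluid-drag coefficient.
#' @param F_mot locomotive force, a length-3 vector applied to every cell
#'   (zero by default; motility models are out of scope).
#' @param dt_mech mechanics time step (min).
#' @return a `MechanicsParams` list.
#' @export
mechanicsParams <- function(C_cca = 0.4, C_ccr = 10.0,
                            adhesion_distance_factor = 1.25, eta = 1,
                            F_mot = c(0, 0, 0), dt_mech = 0.1) {
  structure(list(C_cca = C_cca, C_ccr = C_ccr,
                 adhesion_distance_factor = adhesion_distance_factor,
                 eta = eta, F_mot = as.numeric(F_mot), dt_mech = dt_mech),
            class = "MechanicsParams")
}

#' Microenvironment parameters
#'
#' @param U_o default oxygen consumption rate of a living cell (1/min): the
#'   per-voxel uptake rate contributed by one cell scales as
#'   `(V_cell / V_voxel) * U_o`.
#' @param D oxygen diffusion coefficient (um^2/min).
#' @param lam oxygen decay rate (1/min).
#' @param dt_diff diffusion-reaction time step (min).
#' @param boundary_value Dirichlet oxygen level at the domain boundary (mmHg).
#' @param rho_star saturation concentration used by the supply term (mmHg);
#'   defaults to `boundary_value`.
#' @return a `MicroenvParams` list.
#' @export
microenvParams <- function(U_o = 10, D = 1e5, lam = 0.1, dt_diff = 0.1,
                           boundary_value = 38, rho_star = boundary_value) {
  structure(list(U_o = U_o, D = D, lam = lam, dt_diff = dt_diff,
                 boundary_value = boundary_value, rho_star = rho_star),
            class = "MicroenvParams")
}

#' Duct geometry for the duct-confined (DCIS) scenario
#'
#' A cylinder along +x, closed by a flat cap at `closed_end`, open where it
#' meets the +x domain face.
#'
#' @param radius lumen radius R_duct (um).
#' @param length lumen length from the closed end to the open end (um).
#' @param closed_end x coordinate of the closed end (um).
#' @param center_yz length-2 vector, the axis position in y,z (um).
#' @param wall_value Dirichlet oxygen level on the duct wall (mmHg).
#' @return a `DuctGeometry` list.
#' @export
ductGeometry <- function(radius = 150, length = 750, closed_end = 50,
                         center_yz = NULL, wall_value = 7.2) {
  stopifnot(radius > 0, length > 0)
  structure(list(radius = radius, length = length, closed_end = closed_end,
                 center_yz = center_yz, wall_value = wall_value),
            class = "DuctGeometry")
}

#' Simulation configuration
#'
#' Bundles every parameter block with the multiscale time steps, domain
#' geometry and scenario selection. The three cadences must nest:
#' `dt_diff <= dt_mech <= dt_phase` with integer ratios; diffusion runs every
#' tick, mechanics and phase updates at their own multiples.
#'
#' @param scenario `"HDS"` (free-floating spheroid), `"DCIS"` (duct-confined),
#'   or `"custom"` (caller supplies the initial state to [runSimulation()]).
#' @param seed RNG seed for the whole run.
#' @param t_end simulated duration (min).
#' @param dt_diff,dt_mech,dt_phase time steps (min).
#' @param output_every metrics/snapshot cadence (min).
#' @param grid_dx voxel side length (um), shared by mechanics and diffusion.
#' @param grid_dim integer length-3 vector of voxel counts.
#' @param grid_origin length-3 vector (um).
#' @param phase,volume,mechanics,microenv parameter blocks.
#' @param hds list: `n_cells` seeded, `packing_fraction` of the seed cluster,
#'   optional explicit `cluster_radius` (um).
#' @param dcis list: `duct` ([ductGeometry()]), `n_seed`,
#'   `packing_fraction` of the seed plug.
#' @param initial_population optional CSV path of a starting population
#'   (columns x,y,z,phase,V,V_F,V_NS,V_CS) used by the custom scenario.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(scenario = c("HDS", "DCIS", "custom"),
                             seed = 1L, t_end = 4320,
                             dt_diff = 0.1, dt_mech = 0.1, dt_phase = 6,
                             output_every = 60,
                             grid_dx = 25, grid_dim = c(60L, 60L, 60L),
                             grid_origin = c(0, 0, 0),
                             phase = phaseParams(),
                             volume = volumeParams(),
                             mechanics = mechanicsParams(dt_mech = dt_mech),
                             microenv = microenvParams(dt_diff = dt_diff),
                             hds = list(n_cells = 2347,
                                        packing_fraction = 0.64,
                                        cluster_radius = NULL),
                             dcis = list(duct = ductGeometry(),
                                         n_seed = 500,
                                         packing_fraction = 0.64),
                             initial_population = NULL) {
  scenario <- match.arg(scenario)
  mechanics$dt_mech <- dt_mech
  microenv$dt_diff <- dt_diff
  structure(list(scenario = scenario, seed = as.integer(seed), t_end = t_end,
                 dt_diff = dt_diff, dt_mech = dt_mech, dt_phase = dt_phase,
                 output_every = output_every,
                 grid_dx = grid_dx, grid_dim = as.integer(grid_dim),
                 grid_origin = as.numeric(grid_origin),
                 phase = phase, volume = volume, mechanics = mechanics,
                 microenv = microenv, hds = hds, dcis = dcis,
                 initial_population = initial_population),
            class = "SimulationConfig")
}

#' Largest nominal cell-cell interaction distance
#'
#' `adhesion_distance_factor * 2 * R(V_std)`: the adhesive reach of a pair of
#' standard-volume cells. The grid voxel must be at least this long so the
#' 27-voxel gather sees every interacting neighbour. (A swollen early
#' necrotic cell can transiently exceed the nominal radius; as in the
#' reference setup, such rare longer-reach pairs are truncated at one voxel.)
#'
#' @param config a [simulationConfig()].
#' @return distance in um.
#' @export
maxInteractionDistance <- function(config) {
  R_std <- cellRadius(standardVolume(config$volume))
  config$mechanics$adhesion_distance_factor * 2 * R_std
}

.isMultiple <- function(big, small, tol = 1e-9) {
  r <- big / small
  abs(r - round(r)) < tol
}

#' Validate a configuration
#'
#' Checks every type invariant and returns the violations as a character
#' vector (empty when the configuration is consistent); it reports rather
#' than throws so a config can be fully audited in one pass.
#'
#' @param config a [simulationConfig()].
#' @return character vector of violation messages, possibly empty.
#' @export
validateConfig <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  p <- config$phase
  for (f in names(p)) if (!is.finite(p[[f]]) || p[[f]] <= 0)
    add(paste0("phase$", f, ": must be positive"))
  if (p$Th_pro >= p$Sa_pro) add("phase: Th_pro must be < Sa_pro")
  if (p$Sa_nec >= p$Th_nec) add("phase: Sa_nec must be < Th_nec")
  vol <- config$volume
  if (any(vol$r_F < 0) || any(vol$r_NS < 0) || any(vol$r_CS < 0))
    add("volume: component rates must be >= 0")
  if (any(vol$V_NS_target < 0) || any(vol$V_CS_target < 0))
    add("volume: component targets must be >= 0")
  if (vol$f_F <= 0 || vol$f_F >= 1)
    add("volume$f_F: must lie in (0, 1)")
  if (vol$rupture_ratio <= 1)
    add("volume$rupture_ratio: must exceed 1")
  if (vol$removal_fraction <= 0 || vol$removal_fraction >= 1)
    add("volume$removal_fraction: must lie in (0, 1)")
  m <- config$mechanics
  if (m$C_cca < 0 || m$C_ccr < 0)
    add("mechanics: C_cca and C_ccr must be >= 0")
  if (m$adhesion_distance_factor < 1)
    add("mechanics$adhesion_distance_factor: must be >= 1")
  if (m$eta <= 0) add("mechanics$eta: must be positive")
  u <- config$microenv
  for (f in c("U_o", "D", "boundary_value"))
    if (u[[f]] < 0) add(paste0("microenv$", f, ": must be >= 0"))
  if (u$lam < 0) add("microenv$lam: must be >= 0")
  if (config$grid_dx <= 0) add("grid_dx: must be positive")
  if (any(config$grid_dim < 1)) add("grid_dim: voxel counts must be >= 1")
  rmax <- if (vol$f_F > 0 && vol$f_F < 1) maxInteractionDistance(config)
          else NA_real_
  if (is.finite(rmax) && config$grid_dx < rmax)
    add(sprintf(paste0("grid_dx: voxel side %.4g um is shorter than the ",
                       "maximum cell-cell interaction distance %.4g um"),
                config$grid_dx, rmax))
  dts <- c(diff = config$dt_diff, mech = config$dt_mech,
           phase = config$dt_phase)
  if (any(dts <= 0)) add("time steps must be positive")
  if (config$dt_diff > config$dt_mech)
    add("dt_diff must be <= dt_mech")
  if (config$dt_mech > config$dt_phase)
    add("dt_mech must be <= dt_phase")
  if (!.isMultiple(config$dt_mech, config$dt_diff))
    add("dt_mech must be an integer multiple of dt_diff")
  if (!.isMultiple(config$dt_phase, config$dt_mech))
    add("dt_phase must be an integer multiple of dt_mech")
  if (config$t_end < 0) add("t_end: must be >= 0")
  if (config$output_every <= 0) add("output_every: must be positive")
  if (config$scenario == "DCIS") {
    d <- config$dcis$duct
    if (is.null(d)) add("dcis$duct: missing")
    else if (d$radius <= 0) add("dcis$duct$radius: must be positive")
  }
  v
}
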