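#' Benchmark scenario configurations
#'
#' Ready-made configurations for the two study scenarios at two problem
#' sizes.
#'
#' `scale = "scaled"` is the desk-scale variant used by the package's own
#' acceptance experiments: the spheroid starts from 500 cells in a 60^3
#' lattice of 25-um voxels and runs 72 h at time steps 0.1 / 0.1 / 6 min
#' (diffusion / mechanics / phases); the duct scenario uses a 32 x 20 x 20
#' lattice, a duct reaching the +x face (open end), a 7.2 mmHg wall
#' Dirichlet condition, a seed plug of about 75 um packed at random close
#' packing, and 48 h at steps 0.01 / 0.1 / 6 min (the duct lattice is small
#' enough to afford the reference diffusion step, which matters here because
#' the wall oxygen sits close to the proliferation threshold).
#'
#' `scale = "paper"` reproduces the full-size setup: 2347 seed cells in a
#' million-voxel lattice run for 450 h with diffusion every 0.01 min and
#' mechanics/phases every 0.1 min. These runs involve ~10^6 cells and are
#' not desk-scale; they are provided for completeness and for accelerated
#' hardware. The full-size duct run's domain and duration are nominal (the
#' source setup prints only radii and rates).
#'
#' @param seed RNG seed.
#' @param scale `"scaled"` or `"paper"`.
#' @param duct_radius duct lumen radius in um (typically 100-200).
#' @return a [simulationConfig()].
#' @export
hdsScenarioConfig <- function(seed = 1L, scale = c("scaled", "paper")) {
  scale <- match.arg(scale)
  if (scale == "scaled") {
    simulationConfig("HDS", seed = seed, t_end = 72 * 60,
                     dt_diff = 0.1, dt_mech = 0.1, dt_phase = 6,
                     output_every = 60, grid_dim = c(60, 60, 60),
                     hds = list(n_cells = 500, packing_fraction = 0.64,
                                cluster_radius = NULL))
  } else {
    simulationConfig("HDS", seed = seed, t_end = 450 * 60,
                     dt_diff = 0.01, dt_mech = 0.1, dt_phase = 0.1,
                     output_every = 600, grid_dim = c(100, 100, 100),
                     hds = list(n_cells = 2347, packing_fraction = 0.64,
                                cluster_radius = NULL))
  }
}

#' @rdname hdsScenarioConfig
#' @export
dcisScenarioConfig <- function(duct_radius = 150, seed = 1L,
                               scale = c("scaled", "paper")) {
  scale <- match.arg(scale)
  V_std <- standardVolume(volumeParams())
  R_std <- cellRadius(V_std)
  plug <- function(len) {
    round(0.64 * pi * (duct_radius - R_std)^2 * len / V_std)
  }
  if (scale == "scaled") {
    simulationConfig("DCIS", seed = seed, t_end = 48 * 60,
                     dt_diff = 0.01, dt_mech = 0.1, dt_phase = 6,
                     output_every = 120, grid_dim = c(32, 20, 20),
                     dcis = list(duct = ductGeometry(radius = duct_radius,
                                                     length = 750,
                                                     closed_end = 50,
                                                     wall_value = 7.2),
                                 n_seed = plug(75),
                                 packing_fraction = 0.64))
  } else {
    simulationConfig("DCIS", seed = seed, t_end = 10 * 24 * 60,
                     dt_diff = 0.01, dt_mech = 0.1, dt_phase = 6,
                     output_every = 720, grid_dim = c(80, 24, 24),
                     dcis = list(duct = ductGeometry(radius = duct_radius,
                                                     length = 1950,
                                                     closed_end = 50,
                                                     wall_value = 7.2),
                                 n_seed = plug(100),
                                 packing_fraction = 0.64))
  }
}
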