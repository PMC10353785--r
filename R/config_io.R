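#' Write / read a simulation configuration as YAML
#'
#' The file is a flat mapping whose keys mirror the parameter tables
#' (`phase_T_prem`, `volume_r_F`, `mech_C_cca`, `duct_radius`, ...); vector
#' parameters are YAML sequences. Numbers are written with 17 significant
#' digits so that a serialize/parse round trip reproduces every double
#' bit-for-bit.
#'
#' @param config a [simulationConfig()].
#' @param path file path.
#' @return `writeConfig` returns `path` invisibly; `readConfig` returns a
#'   `SimulationConfig`.
#' @export
writeConfig <- function(config, path) {
  p <- config$phase; vol <- config$volume; m <- config$mechanics
  u <- config$microenv
  flat <- list(
    scenario = config$scenario, seed = config$seed, t_end = config$t_end,
    dt_diff = config$dt_diff, dt_mech = config$dt_mech,
    dt_phase = config$dt_phase, output_every = config$output_every,
    grid_dx = config$grid_dx, grid_dim = config$grid_dim,
    grid_origin = config$grid_origin,
    phase_T_prem = p$T_prem, phase_T_postm = p$T_postm,
    phase_r_apop = p$r_apop, phase_r_pro_max = p$r_pro_max,
    phase_Sa_pro = p$Sa_pro, phase_Th_pro = p$Th_pro,
    phase_r_nec_max = p$r_nec_max, phase_Sa_nec = p$Sa_nec,
    phase_Th_nec = p$Th_nec,
    volume_f_F = vol$f_F, volume_r_F = vol$r_F,
    volume_V_NS_target = vol$V_NS_target, volume_r_NS = vol$r_NS,
    volume_V_CS_target = vol$V_CS_target, volume_r_CS = vol$r_CS,
    volume_fluid_mode = vol$fluid_mode,
    volume_rupture_ratio = vol$rupture_ratio,
    volume_removal_fraction = vol$removal_fraction,
    mech_C_cca = m$C_cca, mech_C_ccr = m$C_ccr,
    mech_adhesion_distance_factor = m$adhesion_distance_factor,
    mech_eta = m$eta, mech_F_mot = m$F_mot,
    microenv_U_o = u$U_o, microenv_D = u$D, microenv_lam = u$lam,
    microenv_boundary_value = u$boundary_value,
    microenv_rho_star = u$rho_star,
    hds_n_cells = config$hds$n_cells,
    hds_packing_fraction = config$hds$packing_fraction,
    dcis_n_seed = config$dcis$n_seed,
    dcis_packing_fraction = config$dcis$packing_fraction,
    duct_radius = config$dcis$duct$radius,
    duct_length = config$dcis$duct$length,
    duct_closed_end = config$dcis$duct$closed_end,
    duct_wall_value = config$dcis$duct$wall_value
  )
  if (!is.null(config$hds$cluster_radius))
    flat$hds_cluster_radius <- config$hds$cluster_radius
  if (!is.null(config$dcis$duct$center_yz))
    flat$duct_center_yz <- config$dcis$duct$center_yz
  if (!is.null(config$initial_population))
    flat$initial_population <- config$initial_population
  writeLines(yaml::as.yaml(flat, precision = 17), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(key, default = NULL)
    if (!is.null(y[[key]])) y[[key]] else default
  simulationConfig(
    scenario = y$scenario, seed = y$seed, t_end = y$t_end,
    dt_diff = y$dt_diff, dt_mech = y$dt_mech, dt_phase = y$dt_phase,
    output_every = y$output_every,
    grid_dx = y$grid_dx, grid_dim = y$grid_dim, grid_origin = y$grid_origin,
    phase = phaseParams(T_prem = y$phase_T_prem, T_postm = y$phase_T_postm,
                        r_apop = y$phase_r_apop,
                        r_pro_max = y$phase_r_pro_max,
                        Sa_pro = y$phase_Sa_pro, Th_pro = y$phase_Th_pro,
                        r_nec_max = y$phase_r_nec_max,
                        Sa_nec = y$phase_Sa_nec, Th_nec = y$phase_Th_nec),
    volume = volumeParams(f_F = y$volume_f_F, r_F = y$volume_r_F,
                          V_NS_target = y$volume_V_NS_target,
                          r_NS = y$volume_r_NS,
                          V_CS_target = y$volume_V_CS_target,
                          r_CS = y$volume_r_CS,
                          fluid_mode = y$volume_fluid_mode,
                          rupture_ratio = y$volume_rupture_ratio,
                          removal_fraction = y$volume_removal_fraction),
    mechanics = mechanicsParams(C_cca = y$mech_C_cca, C_ccr = y$mech_C_ccr,
                                adhesion_distance_factor =
                                  y$mech_adhesion_distance_factor,
                                eta = y$mech_eta, F_mot = y$mech_F_mot,
                                dt_mech = y$dt_mech),
    microenv = microenvParams(U_o = y$microenv_U_o, D = y$microenv_D,
                              lam = y$microenv_lam, dt_diff = y$dt_diff,
                              boundary_value = y$microenv_boundary_value,
                              rho_star = y$microenv_rho_star),
    hds = list(n_cells = y$hds_n_cells,
               packing_fraction = y$hds_packing_fraction,
               cluster_radius = pick("hds_cluster_radius")),
    dcis = list(duct = ductGeometry(radius = y$duct_radius,
                                    length = y$duct_length,
                                    closed_end = y$duct_closed_end,
                                    center_yz = pick("duct_center_yz"),
                                    wall_value = y$duct_wall_value),
                n_seed = y$dcis_n_seed,
                packing_fraction = y$dcis_packing_fraction),
    initial_population = pick("initial_population")
  )
}
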