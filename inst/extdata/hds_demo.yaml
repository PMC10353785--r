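scenario: HDS
seed: 7
t_end: 1440.0
dt_diff: 0.10000000000000001
dt_mech: 0.10000000000000001
dt_phase: 6.0
output_every: 360.0
grid_dx: 25.0
grid_dim:
- 24
- 24
- 24
grid_origin:
- 0.0
- 0.0
- 0.0
phase_T_prem: 13.0
phase_T_postm: 2.5
phase_r_apop: 0.006
phase_r_pro_max: 0.1176
phase_Sa_pro: 10.0
phase_Th_pro: 5.0
phase_r_nec_max: 0.16669999999999999
phase_Sa_nec: 2.5
phase_Th_nec: 5.0
volume_f_F: 0.75019999999999998
volume_r_F:
- 3.0
- 3.0
- 3.0
- 3.0
- 0.67000000000000004
- 0.05
volume_V_NS_target:
- 270.0
- 135.0
- 135.0
- 0.0
- 0.0
- 0.0
volume_r_NS:
- 0.33000000000000002
- 0.33000000000000002
- 0.33000000000000002
- 0.34999999999999998
- 0.013
- 0.013
volume_V_CS_target:
- 976.0
- 488.0
- 488.0
- 0.0
- 0.0
- 0.0
volume_r_CS:
- 0.27000000000000002
- 0.33000000000000002
- 0.33000000000000002
- 1.0
- 0.0032
- 0.0032
volume_fluid_mode:
- 0
- 0
- 0
- 2
- 1
- 2
volume_rupture_ratio: 2.0
volume_removal_fraction: 0.02
mech_C_cca: 0.40000000000000002
mech_C_ccr: 10.0
mech_adhesion_distance_factor: 1.25
mech_eta: 1.0
mech_F_mot:
- 0.0
- 0.0
- 0.0
microenv_U_o: 10.0
microenv_D: 100000.0
microenv_lam: 0.10000000000000001
microenv_boundary_value: 38.0
microenv_rho_star: 38.0
hds_n_cells: 200.0
hds_packing_fraction: 0.64000000000000001
dcis_n_seed: 500.0
dcis_packing_fraction: 0.64000000000000001
duct_radius: 150.0
duct_length: 750.0
duct_closed_end: 50.0
duct_wall_value: 7.20000000000000018

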