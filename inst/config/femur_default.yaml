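# Default femur defect experiment: 1000 MPa implant, 20-day degradation.
# Keys map to remodel_config() arguments.
c: 0.02
rho_max: 1.8
rho_min: 0.01
convergence_tol: 0.001
density_modulus_coeff: 2315
density_modulus_exp: 3
poisson: 0.3
new_bone_theta: 0.9
refill_threshold_frac: 0.5
femur:
  elem_cm: 0.5
  defect_nx: 6
  defect_ny: 6
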