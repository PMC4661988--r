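# Example flowfusion experiment configuration (values shown are the defaults
# for a synthetic pipe study; velocities in cm/s at the file boundary).
mode: cfd_3d
lambda:
  u: 1
  v: 1
  w: 1
fluid:
  rho: 1100      # kg/m^3 (carotid phantom fluid)
  mu: 0.005      # Pa s
solver:
  dt: 0.002      # pseudo-time step, s
  eps: 0.001     # steady-state rate tolerance, (m/s)/s
  div_tol: 0.0001
  max_outer: 3000
  max_inner: 30
  lin_tol: 1.0e-8
  relax_u: 0.7
  relax_p: 0.3
noise:
  sigma_cm_s: 8
  venc_cm_s: 50
  seed: 1
phantom:
  kind: pipe
  n: [16, 16, 48]
  spacing_mm: [0.5, 0.5, 1.0]
  radius_mm: 3.5
  w_max_cm_s: 45
  blunt: 4
paths:
  out_dir: out
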