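# Shared heavy fixtures: the binding-energy angle scans of the study
# conditions (C-25 on the 3-unit (6,5) tube, both end-constraint modes) and
# the 20-mer binding energy at the scan optimum. Computed once per test run
# and reused by the scan and acceptance test files.

acc_tube <- build_nanotube(nanotube_spec(6, 5, n_units = 3))
acc_params <- ff_params()
acc_grid <- seq(10, 80, by = 5)

acc_scan_fixed <- suppressWarnings(scan_binding_vs_angle(
  strrep("C", 25), acc_tube, acc_grid, fixed_ends = TRUE,
  params = acc_params, seed = 1, max_iter = 3000))

acc_scan_free <- suppressWarnings(scan_binding_vs_angle(
  strrep("C", 25), acc_tube, acc_grid, fixed_ends = FALSE,
  params = acc_params, seed = 1, max_iter = 3000))

acc_hyb20 <- suppressWarnings(generate_initial_configs(
  "GAGAAGAGAGCAGAAGGAGA", acc_tube,
  angle_grid = acc_scan_fixed$minimum$initial_angle, seed = 1))[[1]]
acc_be20 <- binding_energy(acc_hyb20, acc_params, fixed_ends = TRUE,
                           max_iter = 4000, seed = 1)
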