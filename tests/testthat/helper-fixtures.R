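# Small shared fixtures, built in code at load time. Kept deliberately tiny;
# anything heavier is constructed inside the test that needs it.

fix_sphere_mesh <- function(n = 162, radius = 70, seed = 1)
  gen_mesh(n, fold_amplitude = 0, radius = radius, seed = seed)

fix_folded_mesh <- function(n = 162, amp = 5, freq = 8, seed = 3)
  gen_mesh(n, fold_amplitude = amp, fold_frequency = freq, radius = 70,
           seed = seed)

fix_sensors <- function(C = 32, seed = 2)
  gen_sensor_array(C, cap_radius = 110, conductor_radius = 95, seed = seed)

# a micro run_config for pipeline-level tests (not the acceptance conditions)
fix_micro_config <- function() {
  tiny_config(
    mesh = list(n_vertices = 162),
    sensors = list(n_channels = 16),
    sim = list(duration_s = 10, n_states = 2, sources_per_state = 2),
    wfs = list(L_max = 2),
    hmm = list(K = 2, n_pca = 8, n_restarts = 1, n_dominant = 2),
    inversion = list(R = 4, msp_patches = 16),
    cv = list(n_folds = 2),
    stats = list(bmc_draws = 2000))
}
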