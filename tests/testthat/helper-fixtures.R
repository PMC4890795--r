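# shared fixtures: the reference animal, its steady-state-constrained
# variant, and a coarse integration step used where a test only needs
# qualitative trajectories (step-halving convergence is itself under test)
ref_fix <- reference_animal()
ref_ss <- apply_steady_state(ref_fix$params)

# fast simulation defaults for unit tests
sim_fast <- function(params = ref_fix$params, z = ref_fix$z, ...) {
  simulate_gi(params, z, dt = 0.01, ...)
}

# random marker-subsystem instance for property tests (rates within the
# fitting bounds, random Z over a 30-min grid)
random_ac_instance <- function() {
  k2 <- runif(1, 1e-4, 0.01)
  params <- update_parameters(
    ref_fix$params,
    iAc_S = runif(1, 500, 5000), iAc_P = runif(1, 0, 50),
    k_SP2 = k2, k_SP3 = k2 * runif(1, 1, 5),
    k_Ac_UAc = runif(1, 1e-4, 0.05))
  z <- z_schedule(seq(0, 420, by = 30), sample(0:2, 14, replace = TRUE))
  list(params = params, z = z)
}
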