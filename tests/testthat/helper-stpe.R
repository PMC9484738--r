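# Shared fixtures, built in code. Expensive suites are computed lazily and
# cached for the duration of the test run.

.fixtures <- new.env(parent = emptyenv())

# small sphere phantom with a 10 s inclusion time constant on a coarse grid
small_phantom <- function(grid_mm = 0.5, duration_s = 60, dt_s = 0.1) {
  lp <- function(tau, E, nu) 1 / (tau * aggregate_modulus(E, nu) * 2e4)
  bg <- material_params(3e4, 0.3, Lp = lp(15, 3e4, 0.3), k = 1e-14)
  inc <- material_params(6e4, 0.4, Lp = lp(10, 6e4, 0.4), k = 1e-14)
  phantom_spec(inc, bg, grid_mm = grid_mm, duration_s = duration_s,
               dt_s = dt_s)
}

# window-of-observation suite on noise-free scenarios (shared by several
# acceptance checks); four phantoms, windows in units of the pilot tau
ideal_woo_suite <- function() {
  if (!is.null(.fixtures$ideal_woo)) return(.fixtures$ideal_woo)
  out <- lapply(c("A", "B", "E", "F"), function(sc)
    run_stpe_experiment(list(scenario = sc, condition = "ideal",
                             woo_multiples = c(0.5, 1, 2, 2.5, 3),
                             grid_mm = 0.5, seed = 1)))
  names(out) <- c("A", "B", "E", "F")
  .fixtures$ideal_woo <- out
  out
}

# RF-chain suite: one spherical phantom at 40 and 20 dB SNR, half-size
# field, ~60 frames
rf_woo_suite <- function() {
  if (!is.null(.fixtures$rf_woo)) return(.fixtures$rf_woo)
  out <- lapply(c(40, 20), function(snr)
    run_stpe_experiment(list(scenario = "A", condition = "rf", snr_db = snr,
                             woo_multiples = 2, n_reps = 1, grid_mm = 0.4,
                             seed = 7)))
  names(out) <- c("snr40", "snr20")
  .fixtures$rf_woo <- out
  out
}
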