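# Shared fixtures: small protocols and deterministic cohorts built in code.

# 1 kHz-sampled standard protocol: same voltages/durations, 3x fewer
# samples than the 3 kHz default, enough for all non-kinetic checks.
fast_protocol <- function(steps_mV = seq(-80, 60, by = 20),
                          step_ms = 2000) {
  step_protocol(steps_mV = steps_mV, step_ms = step_ms, dt_ms = 1)
}

# Zero-noise, zero-variance cohort whose parameters are known exactly.
noiseless_config <- function(group = "ctrl", n_cells = 3,
                             g_sustained = 400, g_transient = 0,
                             g_leak = 0, v_half = 40, slope = 17.6,
                             rmp = -34.2, seed = 7L, ...) {
  cohort_config(group = group, n_cells = n_cells,
                capacitance = c(40, 0),
                g_sustained = c(g_sustained, 0),
                g_transient = c(g_transient, 0),
                g_leak = c(g_leak, 0),
                v_half = c(v_half, 0), slope = c(slope, 0),
                rmp = c(rmp, 0),
                fraction_transient = if (g_transient > 0) 1 else 0,
                noise_sd_pA = 0, seed = seed, ...)
}

# Recording with prescribed per-step plateau currents (pA), no noise:
# convenient for arithmetic oracles on the analysis stage.
flat_recording <- function(step_pA, steps_mV = seq(-80, 60, by = 20),
                           capacitance_pF = 10, id = "mock",
                           group = "control", rmp_mV = -34.2) {
  protocol <- fast_protocol(steps_mV)
  lay <- flsephys:::protocol_layout(protocol)
  sweeps <- vapply(step_pA, function(i) {
    x <- rep(0, lay$n_total)
    x[lay$step_idx] <- i
    x
  }, numeric(lay$n_total))
  colnames(sweeps) <- sprintf("%g", steps_mV)
  structure(
    list(id = id, group = group, capacitance_pF = capacitance_pF,
         rmp_mV = rmp_mV, time_ms = lay$time_ms, sweeps = sweeps,
         protocol = protocol, truth = NULL),
    class = "fls_recording")
}

E_K_294 <- nernst(141, 5, z = 1, temp_K = 294)
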