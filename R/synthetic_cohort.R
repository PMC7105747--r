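#' Ground-truth parameters of one synthetic FLS cell
#'
#' The forward model of a whole-cell recording is the sum of three
#' conductances, each expressed as a density (pS/pF) so that currents scale
#' with the cell's capacitance:
#' \itemize{
#'   \item a linear leak, `g_leak * (V - e_leak)`;
#'   \item a sustained, Boltzmann-gated potassium conductance
#'     `g_sustained * Po(V) * (V - e_rev)` with
#'     `Po(V) = 1/(1 + exp(-(V - v_half)/slope))`, activating
#'     instantaneously on the step;
#'   \item a transient (A-type-like) component
#'     `g_transient * Pt(V) * (V - e_rev) * (1 - exp(-t/tau_act)) * exp(-t/tau_inact)`,
#'     which peaks early in the step and then inactivates.
#' }
#' Gaussian recording noise of standard deviation `noise_sd_pA` is added
#' per sample. The stored `rmp_mV` is the *measured* (uncorrected) resting
#' potential; the junction-potential correction is applied at analysis
#' time.
#'
#' @param capacitance_pF cell capacitance (pF), > 0.
#' @param g_sustained,g_transient,g_leak maximal conductance densities
#'   (pS/pF), >= 0.
#' @param v_half_mV,slope_mV Boltzmann midpoint and slope of the sustained
#'   conductance (mV).
#' @param v_half_t_mV,slope_t_mV activation midpoint and slope of the
#'   transient conductance (mV).
#' @param tau_act_ms,tau_inact_ms transient activation and inactivation
#'   time constants (ms).
#' @param e_rev_mV reversal potential of the gated conductances (mV),
#'   normally the potassium equilibrium potential.
#' @param e_leak_mV leak reversal potential (mV).
#' @param rmp_mV measured (junction-uncorrected) resting potential (mV).
#' @param noise_sd_pA recording noise standard deviation (pA).
#'
#' @return An object of class `cell_truth`.
#' @export
cell_truth <- function(capacitance_pF = 45,
                       g_sustained = 480, g_transient = 0, g_leak = 3,
                       v_half_mV = 40, slope_mV = 17.6,
                       v_half_t_mV = -10, slope_t_mV = 14,
                       tau_act_ms = 20, tau_inact_ms = 150,
                       e_rev_mV = -84.6, e_leak_mV = -30,
                       rmp_mV = -34.2, noise_sd_pA = 5) {
  if (capacitance_pF <= 0) stopf("capacitance must be > 0")
  if (any(c(g_sustained, g_transient, g_leak) < 0))
    stopf("conductance densities must be >= 0")
  if (noise_sd_pA < 0) stopf("noise_sd must be >= 0")
  if (slope_mV <= 0 || slope_t_mV <= 0) stopf("Boltzmann slopes must be > 0")
  if (tau_act_ms <= 0 || tau_inact_ms <= 0) stopf("time constants must be > 0")
  structure(as.list(environment()), class = "cell_truth")
}

#' Predicted baseline-subtracted sustained current density
#'
#' Closed-form value the analysis stage should recover for a noiseless
#' cell: the step-end current minus the pre-step holding current, per pF.
#'
#' @param truth a [cell_truth()].
#' @param v_mV step potential(s) (mV).
#' @param holding_mV holding potential (mV).
#' @return density in pA/pF.
#' @export
predict_sustained_density <- function(truth, v_mV, holding_mV = -80) {
  po_s <- boltzmann(v_mV, truth$v_half_mV, truth$slope_mV)
  po_h <- boltzmann(holding_mV, truth$v_half_mV, truth$slope_mV)
  (truth$g_sustained * (po_s * (v_mV - truth$e_rev_mV) -
                          po_h * (holding_mV - truth$e_rev_mV)) +
      truth$g_leak * (v_mV - holding_mV)) / 1000
}

#' Predicted transient peak current density
#'
#' Peak of the transient envelope `(1 - exp(-t/tau_act)) * exp(-t/tau_inact)`
#' (attained at `t* = tau_act * log(1 + tau_inact/tau_act)`) times the
#' voltage-dependent driving term, per pF. The sustained and leak terms
#' cancel because the analysis subtracts the sustained level from the peak.
#'
#' @inheritParams predict_sustained_density
#' @return density in pA/pF.
#' @export
predict_transient_peak_density <- function(truth, v_mV) {
  ta <- truth$tau_act_ms; ti <- truth$tau_inact_ms
  tstar <- ta * log(1 + ti / ta)
  peak <- (1 - exp(-tstar / ta)) * exp(-tstar / ti)
  truth$g_transient * boltzmann(v_mV, truth$v_half_t_mV, truth$slope_t_mV) *
    (v_mV - truth$e_rev_mV) * peak / 1000
}

#' Simulate one whole-cell voltage-clamp recording
#'
#' Generates the sweep family evoked by a [step_protocol()] from a
#' [cell_truth()]: leak + transient + sustained components plus white
#' Gaussian noise. Currents are in pA (`density (pS/pF) x capacitance (pF)
#' x driving force (mV) / 1000`). Identical `(truth, protocol, seed)`
#' triples produce identical output.
#'
#' @param truth a [cell_truth()].
#' @param protocol a [step_protocol()].
#' @param seed integer seed for the recording noise, or `NULL` to use the
#'   current RNG state.
#' @param id cell identifier.
#' @param group group label (e.g. `"control"`).
#'
#' @return An object of class `fls_recording`: a list with elements
#'   `id`, `group`, `capacitance_pF`, `rmp_mV`, `time_ms`,
#'   `sweeps` (time x step matrix of currents, pA), `protocol`, `truth`.
#' @export
gen_recording <- function(truth, protocol = step_protocol(), seed = NULL,
                          id = "cell", group = "control") {
  if (!inherits(truth, "cell_truth")) stopf("truth must be a cell_truth")
  if (!inherits(protocol, "step_protocol"))
    stopf("protocol must be a step_protocol")
  lay <- protocol_layout(protocol)
  t_in_step <- (seq_len(lay$n_step) - 0.5) * protocol$dt_ms
  cm <- truth$capacitance_pF
  hold <- protocol$holding_mV

  hold_current <- cm / 1000 * (
    truth$g_leak * (hold - truth$e_leak_mV) +
      truth$g_sustained * boltzmann(hold, truth$v_half_mV, truth$slope_mV) *
        (hold - truth$e_rev_mV))

  sweeps <- vapply(protocol$steps_mV, function(v) {
    i <- rep(hold_current, lay$n_total)
    step_level <- cm / 1000 * (
      truth$g_leak * (v - truth$e_leak_mV) +
        truth$g_sustained * boltzmann(v, truth$v_half_mV, truth$slope_mV) *
          (v - truth$e_rev_mV))
    envelope <- (1 - exp(-t_in_step / truth$tau_act_ms)) *
      exp(-t_in_step / truth$tau_inact_ms)
    trans <- cm / 1000 * truth$g_transient *
      boltzmann(v, truth$v_half_t_mV, truth$slope_t_mV) *
      (v - truth$e_rev_mV) * envelope
    i[lay$step_idx] <- step_level + trans
    i
  }, numeric(lay$n_total))

  if (truth$noise_sd_pA > 0) {
    noise <- with_seed(seed,
      matrix(stats::rnorm(length(sweeps), 0, truth$noise_sd_pA),
             nrow = nrow(sweeps)))
    sweeps <- sweeps + noise
  }
  colnames(sweeps) <- sprintf("%g", protocol$steps_mV)

  structure(
    list(id = id, group = group, capacitance_pF = cm,
         rmp_mV = truth$rmp_mV, time_ms = lay$time_ms, sweeps = sweeps,
         protocol = protocol, truth = truth),
    class = "fls_recording")
}

#' @export
print.fls_recording <- function(x, ...) {
  cat(sprintf(
    "<fls_recording %s> group=%s, Cm=%.1f pF, %d sweeps x %d samples\n",
    x$id, x$group, x$capacitance_pF, ncol(x$sweeps), nrow(x$sweeps)))
  invisible(x)
}

#' Cohort configuration for the synthetic generator
#'
#' Population distributions for every [cell_truth()] field. Positive-only
#' quantities (capacitance and conductance densities) are drawn from
#' log-normal distributions parameterised by their arithmetic mean and sd;
#' potentials and Boltzmann parameters are Gaussian. A stated fraction of
#' cells carries the transient component; the rest have
#' `g_transient = 0`, matching the mixed phenotypes seen in FLS cohorts.
#'
#' @param group group label.
#' @param n_cells number of cells (>= 1).
#' @param capacitance,g_sustained,g_transient,g_leak,v_half,slope,rmp
#'   two-element `c(mean, sd)` vectors of the respective truth fields
#'   (units as in [cell_truth()]; `rmp` is the *measured*, junction-
#'   uncorrected resting potential).
#' @param fraction_transient probability in \[0, 1\] that a cell expresses
#'   the transient component.
#' @param tau_act_ms,tau_inact_ms,v_half_t_mV,slope_t_mV,e_rev_mV,e_leak_mV
#'   scalar transient kinetics / reversal settings shared by all cells.
#' @param noise_sd_pA recording noise sd (pA), shared.
#' @param seed master RNG seed for the cohort.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group, n_cells,
                          capacitance = c(45, 10),
                          g_sustained = c(480, 440),
                          g_transient = c(250, 120),
                          g_leak = c(3, 1),
                          v_half = c(40, 2),
                          slope = c(17.6, 0.5),
                          rmp = c(-34.2, 8.3),
                          fraction_transient = 0.75,
                          tau_act_ms = 20, tau_inact_ms = 150,
                          v_half_t_mV = -10, slope_t_mV = 14,
                          e_rev_mV = -84.6, e_leak_mV = -30,
                          noise_sd_pA = 5,
                          seed = 1L) {
  if (n_cells < 1) stopf("n_cells must be >= 1")
  if (fraction_transient < 0 || fraction_transient > 1)
    stopf("fraction_transient must lie in [0, 1]")
  two <- function(x, nm) {
    if (length(x) != 2) stopf("%s must be c(mean, sd)", nm)
    if (x[2] < 0) stopf("%s sd must be >= 0", nm)
    x
  }
  capacitance <- two(capacitance, "capacitance")
  g_sustained <- two(g_sustained, "g_sustained")
  g_transient <- two(g_transient, "g_transient")
  g_leak <- two(g_leak, "g_leak")
  v_half <- two(v_half, "v_half")
  slope <- two(slope, "slope")
  rmp <- two(rmp, "rmp")
  structure(as.list(environment())[
    c("group", "n_cells", "capacitance", "g_sustained", "g_transient",
      "g_leak", "v_half", "slope", "rmp", "fraction_transient",
      "tau_act_ms", "tau_inact_ms", "v_half_t_mV", "slope_t_mV",
      "e_rev_mV", "e_leak_mV", "noise_sd_pA", "seed")],
    class = "cohort_config")
}

#' Generate a seeded cohort of synthetic recordings
#'
#' Draws `n_cells` ground truths from the configured population
#' distributions and simulates one recording per cell. The master seed
#' fixes the per-cell parameter draws and the per-cell noise seeds, so the
#' whole cohort is reproducible bit for bit.
#'
#' @param config a [cohort_config()].
#' @param protocol a [step_protocol()].
#' @return list of [gen_recording()] objects.
#' @export
gen_cohort <- function(config, protocol = step_protocol()) {
  if (!inherits(config, "cohort_config")) stopf("config must be a cohort_config")
  n <- config$n_cells
  truths <- with_seed(config$seed, {
    cm <- rlnorm_mean_sd(n, config$capacitance[1], config$capacitance[2])
    gs <- rlnorm_mean_sd(n, config$g_sustained[1], config$g_sustained[2])
    gt <- rlnorm_mean_sd(n, config$g_transient[1], config$g_transient[2])
    gl <- rlnorm_mean_sd(n, config$g_leak[1], config$g_leak[2])
    vh <- stats::rnorm(n, config$v_half[1], config$v_half[2])
    sl <- pmax(stats::rnorm(n, config$slope[1], config$slope[2]), 1)
    rp <- stats::rnorm(n, config$rmp[1], config$rmp[2])
    has_t <- stats::runif(n) < config$fraction_transient
    noise_seeds <- sample.int(.Machine$integer.max, n)
    lapply(seq_len(n), function(i) {
      list(truth = cell_truth(
        capacitance_pF = cm[i],
        g_sustained = gs[i],
        g_transient = if (has_t[i]) gt[i] else 0,
        g_leak = gl[i],
        v_half_mV = vh[i], slope_mV = sl[i],
        v_half_t_mV = config$v_half_t_mV, slope_t_mV = config$slope_t_mV,
        tau_act_ms = config$tau_act_ms, tau_inact_ms = config$tau_inact_ms,
        e_rev_mV = config$e_rev_mV, e_leak_mV = config$e_leak_mV,
        rmp_mV = rp[i], noise_sd_pA = config$noise_sd_pA),
        seed = noise_seeds[i])
    })
  })
  lapply(seq_along(truths), function(i) {
    gen_recording(truths[[i]]$truth, protocol, seed = truths[[i]]$seed,
                  id = sprintf("%s_%02d", config$group, i),
                  group = config$group)
  })
}

#' Study-calibrated cohort configurations
#'
#' Returns control and cytokine-treated cohort configurations plus the
#' standard step protocol, calibrated so that in expectation the analysis
#' chain reproduces the study-level electrophysiological phenotype:
#' sustained current density at +20 mV of 12.5 (control) vs 3.8 pA/pF
#' (treated); junction-corrected resting potentials of -48.6 vs -38.6 mV
#' (with LJP = -14.4 mV, measured values of -34.2 and -24.2 mV); and a
#' control-minus-treated difference conductance that is Boltzmann with
#' midpoint +40 mV and slope 17.6 mV when referenced to the potassium
#' reversal potential of the recording solutions (-84.6 mV at 294 K).
#'
#' Both groups share the sustained activation curve (V1/2 = +40 mV,
#' k = 17.6 mV) and differ in conductance amplitude, so the group
#' difference of the chord conductance is itself Boltzmann with the same
#' midpoint and slope. Conductance means solve
#' `density(+20) = g * Po(+20) * (20 - E_K)/1000 + g_leak * 100/1000`;
#' population sds are set from the published SEMs times `sqrt(n)`
#' (n = 24 control, 20 treated). The transient component is present in
#' ~75% (control) and ~55% (treated) of cells with equal amplitude
#' distributions, since no group difference in the transient was found.
#'
#' @param seed_control,seed_treated master seeds of the two cohorts.
#' @param n_control,n_treated cohort sizes.
#' @param ljp_mV liquid junction potential assumed when back-computing the
#'   measured resting potentials (mV).
#' @return list with elements `control`, `treated` (both
#'   [cohort_config()]) and `protocol` ([step_protocol()]).
#' @export
paper_calibrated_config <- function(seed_control = 101L, seed_treated = 202L,
                                    n_control = 24L, n_treated = 20L,
                                    ljp_mV = -14.4) {
  e_k <- nernst(141, 5, z = 1, temp_K = 294)       # -84.60 mV
  po20 <- boltzmann(20, 40, 17.6)
  dens_per_g <- po20 * (20 - e_k) / 1000           # pA/pF per pS/pF
  g_leak_mean <- 3
  leak20 <- g_leak_mean * (20 - (-80)) / 1000
  g_ctrl <- (12.5 - leak20) / dens_per_g           # 480.0 pS/pF
  g_trt <- (3.8 - leak20) / dens_per_g             # 137.7 pS/pF
  sd_ctrl <- 2.3 * sqrt(n_control) / dens_per_g
  sd_trt <- 0.8 * sqrt(n_treated) / dens_per_g
  control <- cohort_config(
    group = "control", n_cells = n_control,
    g_sustained = c(g_ctrl, sd_ctrl),
    g_leak = c(g_leak_mean, 1),
    v_half = c(40, 2), slope = c(17.6, 0.5),
    rmp = c(-48.6 - ljp_mV, 1.7 * sqrt(n_control)),
    fraction_transient = 0.75,
    e_rev_mV = e_k, seed = seed_control)
  treated <- cohort_config(
    group = "treated", n_cells = n_treated,
    g_sustained = c(g_trt, sd_trt),
    g_leak = c(g_leak_mean, 1),
    v_half = c(40, 2), slope = c(17.6, 0.5),
    rmp = c(-38.6 - ljp_mV, 2.8 * sqrt(n_treated)),
    fraction_transient = 0.55,
    e_rev_mV = e_k, seed = seed_treated)
  list(control = control, treated = treated, protocol = step_protocol())
}
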