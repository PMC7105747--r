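#' Separate transient and sustained current components
#'
#' For each voltage step, measures the plateau ("sustained") current as
#' the mean over the final fraction of the step, and the transient peak as
#' the maximum of the lightly smoothed trace within an early search
#' window, minus the sustained level. Both are baseline-subtracted using
#' the mean holding current immediately preceding the step. All values in
#' pA.
#'
#' @param rec an `fls_recording`.
#' @param transient_window_ms search window for the transient peak,
#'   measured from step onset (ms).
#' @param sustained_frac final fraction of the step averaged for the
#'   sustained level.
#' @param baseline_ms length of pre-step segment averaged as baseline
#'   (ms); 0 disables baseline subtraction (useful for leak-free
#'   synthetic data).
#' @param smooth_ms boxcar width applied before peak detection (ms); 0
#'   disables smoothing. Smoothing suppresses the upward bias that taking
#'   a pointwise maximum of thousands of noisy samples would otherwise add
#'   to the peak estimate.
#'
#' @return data.frame with columns `step_mV`, `transient_pA`,
#'   `sustained_pA`.
#' @export
split_transient_sustained <- function(rec, transient_window_ms = 500,
                                      sustained_frac = 0.25,
                                      baseline_ms = 100,
                                      smooth_ms = 5) {
  if (!inherits(rec, "fls_recording")) stopf("rec must be an fls_recording")
  p <- rec$protocol
  lay <- protocol_layout(p)
  if (transient_window_ms > p$step_ms)
    stopf("transient window (%g ms) exceeds step duration (%g ms)",
          transient_window_ms, p$step_ms)
  if (baseline_ms > p$pre_ms)
    stopf("baseline window (%g ms) exceeds pre-step segment (%g ms)",
          baseline_ms, p$pre_ms)
  n_base <- round(baseline_ms / p$dt_ms)
  base_idx <- if (n_base > 0)
    lay$pre_idx[(lay$n_pre - n_base + 1):lay$n_pre]
  else integer(0)
  n_win <- round(transient_window_ms / p$dt_ms)
  win_idx <- lay$step_idx[seq_len(n_win)]
  n_sus <- max(round(sustained_frac * lay$n_step), 1)
  sus_idx <- lay$step_idx[(lay$n_step - n_sus + 1):lay$n_step]
  w <- max(round(smooth_ms / p$dt_ms), 1)

  out <- t(apply(rec$sweeps, 2, function(i) {
    baseline <- if (length(base_idx)) mean(i[base_idx]) else 0
    sustained <- mean(i[sus_idx]) - baseline
    seg <- i[win_idx] - baseline
    if (w > 1) seg <- stats::filter(seg, rep(1 / w, w), sides = 2)
    peak <- max(seg, na.rm = TRUE) - sustained
    c(transient_pA = peak, sustained_pA = sustained)
  }))
  data.frame(step_mV = p$steps_mV, transient_pA = out[, "transient_pA"],
             sustained_pA = out[, "sustained_pA"], row.names = NULL)
}

#' Capacitance-normalised current-voltage curve
#'
#' Divides each cell's component current by its capacitance and summarises
#' the cohort per voltage as mean +/- SEM current density (pA/pF).
#'
#' @param recs non-empty list of `fls_recording` objects sharing one
#'   protocol.
#' @param phase `"sustained"` or `"transient"`.
#' @param ... passed to [split_transient_sustained()].
#' @return An object of class `iv_curve`: data.frame with columns `v_mV`,
#'   `mean_pA_pF`, `sem_pA_pF`, `n`; attributes `phase` and
#'   `junction_corrected`.
#' @export
iv_curve <- function(recs, phase = c("sustained", "transient"), ...) {
  phase <- match.arg(phase)
  if (length(recs) == 0) stopf("iv_curve needs at least one recording")
  if (!all(vapply(recs, inherits, logical(1), "fls_recording")))
    stopf("all elements must be fls_recording objects")
  proto <- recs[[1]]$protocol
  for (r in recs[-1])
    if (!protocols_identical(r$protocol, proto))
      stopf("recordings use different protocols")
  col <- paste0(phase, "_pA")
  dens <- vapply(recs, function(r) {
    split_transient_sustained(r, ...)[[col]] / r$capacitance_pF
  }, numeric(length(proto$steps_mV)))
  dens <- matrix(dens, nrow = length(proto$steps_mV))
  sems <- if (ncol(dens) == 1) {
    warning("SEM of a single-cell curve is reported as 0", call. = FALSE)
    rep(0, nrow(dens))
  } else apply(dens, 1, sem)
  curve <- data.frame(
    v_mV = proto$steps_mV,
    mean_pA_pF = rowMeans(dens),
    sem_pA_pF = sems,
    n = ncol(dens))
  structure(curve, class = c("iv_curve", "data.frame"),
            phase = phase, junction_corrected = FALSE)
}

#' Difference current between two I-V curves
#'
#' Pointwise `control - treated` current density on identical voltage
#' grids, isolating the conductance lost after treatment. SEMs are
#' propagated as `sqrt(sem_c^2 + sem_t^2)`; no interpolation is
#' attempted on mismatched grids.
#'
#' @param control,treated `iv_curve` objects on the same voltage grid.
#' @return An `iv_curve` with `n` set to the smaller group size per point.
#' @export
difference_current <- function(control, treated) {
  if (!inherits(control, "iv_curve") || !inherits(treated, "iv_curve"))
    stopf("inputs must be iv_curve objects")
  if (length(control$v_mV) != length(treated$v_mV) ||
      any(abs(control$v_mV - treated$v_mV) > 1e-9))
    stopf("voltage grids differ; difference_current does not interpolate")
  curve <- data.frame(
    v_mV = control$v_mV,
    mean_pA_pF = control$mean_pA_pF - treated$mean_pA_pF,
    sem_pA_pF = sqrt(control$sem_pA_pF^2 + treated$sem_pA_pF^2),
    n = pmin(control$n, treated$n))
  structure(curve, class = c("iv_curve", "data.frame"),
            phase = attr(control, "phase"), junction_corrected = FALSE)
}

#' Chord conductance-voltage curve
#'
#' Converts current density to chord conductance density,
#' `g(V) = 1000 * I(V) / (V - E_rev)` (I in pA/pF, V in mV, g in pS/pF).
#' Points within `exclude_mV` of the reversal potential are dropped (and
#' recorded in the `dropped_mV` attribute) because the chord quotient is
#' numerically unstable there.
#'
#' @param iv an `iv_curve`.
#' @param e_rev_mV reversal potential used as the chord reference (mV).
#'   This is a required, explicit choice: for potassium-dominated FLS
#'   currents the Nernst potassium potential of the recording solutions
#'   (about -84.6 mV at 294 K) is the natural value.
#' @param exclude_mV half-width of the exclusion zone around `e_rev_mV`.
#' @return An object of class `gv_curve`: data.frame with columns `v_mV`,
#'   `g_pS_pF`, `sem_pS_pF`, `n`; attributes `e_rev_mV`, `dropped_mV`.
#' @export
chord_conductance <- function(iv, e_rev_mV, exclude_mV = 2) {
  if (!inherits(iv, "iv_curve")) stopf("iv must be an iv_curve")
  keep <- abs(iv$v_mV - e_rev_mV) >= exclude_mV
  if (!any(keep))
    stopf("all voltages lie within %g mV of E_rev = %g mV", exclude_mV,
          e_rev_mV)
  df <- iv$v_mV[keep] - e_rev_mV
  curve <- data.frame(
    v_mV = iv$v_mV[keep],
    g_pS_pF = 1000 * iv$mean_pA_pF[keep] / df,
    sem_pS_pF = 1000 * iv$sem_pA_pF[keep] / abs(df),
    n = iv$n[keep])
  structure(curve, class = c("gv_curve", "data.frame"),
            e_rev_mV = e_rev_mV, dropped_mV = iv$v_mV[!keep])
}

#' Fit a Boltzmann activation curve to a G-V relation
#'
#' Non-linear least squares fit of
#' `g(V) = Gmax / (1 + exp(-(V - V1/2)/k))` by Levenberg-Marquardt.
#' Default starting values: `Gmax = max(g)`, `V1/2` at the voltage where
#' the curve first crosses half its maximum, `k = 10 mV`. A fit that does
#' not converge, or converges to a non-positive slope or amplitude, is
#' returned with `converged = FALSE` rather than raising an error.
#'
#' @param gv a `gv_curve`, or any data.frame with columns `v_mV` and
#'   `g_pS_pF`.
#' @param init optional named list/vector with starting values `gmax`,
#'   `v_half`, `k`.
#' @return An object of class `boltzmann_fit`: list with `gmax`, `v_half`,
#'   `k` (mV), `rss`, `converged`, `se` (named parameter standard errors,
#'   `NA` on failure), `n_points`.
#' @export
fit_boltzmann <- function(gv, init = NULL) {
  v <- gv$v_mV
  g <- gv$g_pS_pF
  ok <- is.finite(v) & is.finite(g)
  v <- v[ok]; g <- g[ok]
  failure <- function() structure(
    list(gmax = NA_real_, v_half = NA_real_, k = NA_real_, rss = NA_real_,
         converged = FALSE, se = c(gmax = NA_real_, v_half = NA_real_,
                                   k = NA_real_), n_points = length(v)),
    class = "boltzmann_fit")
  if (length(v) < 4) stopf("Boltzmann fit needs at least 4 points")
  if (diff(range(g)) <= .Machine$double.eps * max(abs(g), 1))
    return(failure())                      # flat curve: midpoint undefined
  if (is.null(init)) {
    gmax0 <- max(g)
    above <- which(g >= gmax0 / 2)
    init <- list(gmax = gmax0,
                 v_half = v[above[1]],
                 k = 10)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      g ~ gmax / (1 + exp(-(v - v_half) / k)),
      data = data.frame(v = v, g = g),
      start = list(gmax = init$gmax, v_half = init$v_half, k = init$k),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(failure())
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["k"]] <= 0 || cf[["gmax"]] <= 0)
    return(failure())
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  names(se) <- c("gmax", "v_half", "k")
  structure(
    list(gmax = cf[["gmax"]], v_half = cf[["v_half"]], k = cf[["k"]],
         rss = sum(stats::resid(fit)^2), converged = TRUE, se = se,
         n_points = length(v)),
    class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "Boltzmann fit: Gmax = %.3g pS/pF, V1/2 = %.2f mV, k = %.2f mV (RSS %.3g, %d points)\n",
      x$gmax, x$v_half, x$k, x$rss, x$n_points))
  else cat("Boltzmann fit: did not converge\n")
  invisible(x)
}
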