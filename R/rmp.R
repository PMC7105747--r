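#' Apply the liquid-junction-potential correction
#'
#' `v_corrected = v_measured + ljp`, with the junction potential carrying
#' its own sign: an LJP of -14.4 mV makes reported potentials more
#' negative. Corrected values are tagged with a `junction_corrected`
#' attribute; correcting an already-corrected vector raises an error, a
#' guard against accidentally applying the offset twice.
#'
#' @param v_measured_mV measured potential(s) (mV).
#' @param ljp_mV junction potential (mV), signed.
#' @return corrected potentials (mV) with attribute
#'   `junction_corrected = TRUE`.
#' @examples
#' correct_junction(-34.2, -14.4)  # -48.6
#' @export
correct_junction <- function(v_measured_mV, ljp_mV) {
  if (isTRUE(attr(v_measured_mV, "junction_corrected")))
    stopf("values are already junction-corrected")
  out <- v_measured_mV + ljp_mV
  attr(out, "junction_corrected") <- TRUE
  out
}

#' Resting-membrane-potential group comparison
#'
#' Junction-corrects the measured resting potentials of both groups and
#' compares them with a two-sided unpaired Welch t-test (the
#' unequal-variance form of the unpaired t-test).
#'
#' @param control,treated measured (uncorrected) resting potentials (mV),
#'   each of length >= 2.
#' @param ljp_mV junction potential applied via [correct_junction()].
#' @return An object of class `rmp_stats`: list with per-group `mean`,
#'   `sem`, `n` (junction-corrected, mV), plus `t`, `df`, `p_value`,
#'   `ljp_mV`.
#' @export
rmp_stats <- function(control, treated, ljp_mV) {
  if (length(control) < 2 || length(treated) < 2)
    stopf("each group needs at least 2 cells")
  c_corr <- as.numeric(correct_junction(control, ljp_mV))
  t_corr <- as.numeric(correct_junction(treated, ljp_mV))
  if (stats::sd(c_corr) == 0 && stats::sd(t_corr) == 0) {
    # degenerate zero-variance groups: t.test() refuses constant data
    d <- mean(c_corr) - mean(t_corr)
    tt <- list(statistic = if (d == 0) 0 else sign(d) * Inf,
               parameter = NA_real_,
               p.value = if (d == 0) 1 else 0)
  } else {
    tt <- stats::t.test(c_corr, t_corr, var.equal = FALSE)
  }
  structure(
    list(control = list(mean = mean(c_corr), sem = sem(c_corr),
                        n = length(c_corr)),
         treated = list(mean = mean(t_corr), sem = sem(t_corr),
                        n = length(t_corr)),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, ljp_mV = ljp_mV),
    class = "rmp_stats")
}

#' @export
print.rmp_stats <- function(x, ...) {
  cat(sprintf(
    "RMP (junction corrected, LJP %+.1f mV):\n  control %.1f +/- %.1f mV (n = %d)\n  treated %.1f +/- %.1f mV (n = %d)\n  Welch t = %.2f, df = %.1f, p = %.3g\n",
    x$ljp_mV, x$control$mean, x$control$sem, x$control$n,
    x$treated$mean, x$treated$sem, x$treated$n, x$t, x$df, x$p_value))
  invisible(x)
}
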