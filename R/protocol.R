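#' Voltage-step protocol
#'
#' Describes a family of rectangular voltage steps delivered from a fixed
#' holding potential, as used for whole-cell voltage clamp of
#' fibroblast-like synoviocytes: a pre-step holding segment, a long
#' depolarising (or hyperpolarising) step, and a post-step return to
#' holding. The default protocol holds at -80 mV and applies 2 s steps
#' from -80 to +60 mV in 20 mV increments, sampled at 3 kHz.
#'
#' @param holding_mV holding potential (mV).
#' @param steps_mV strictly increasing vector of step potentials (mV).
#' @param step_ms step duration (ms).
#' @param pre_ms pre-step holding segment duration (ms).
#' @param post_ms post-step holding segment duration (ms).
#' @param dt_ms sampling interval (ms); must divide all segment durations.
#'
#' @return An object of class `step_protocol`.
#' @examples
#' p <- step_protocol()
#' p$steps_mV
#' @export
step_protocol <- function(holding_mV = -80,
                          steps_mV = seq(-80, 60, by = 20),
                          step_ms = 2000,
                          pre_ms = 100,
                          post_ms = 100,
                          dt_ms = 1000 / 3000) {
  if (length(steps_mV) < 1) stopf("protocol needs at least one step level")
  if (any(diff(steps_mV) <= 0))
    stopf("step_levels must be strictly increasing")
  for (d in c(step_ms, pre_ms, post_ms)) {
    if (d <= 0) stopf("protocol durations must be > 0")
    r <- d / dt_ms
    if (abs(r - round(r)) > 1e-8)
      stopf("sample interval %g ms does not divide segment duration %g ms",
            dt_ms, d)
  }
  if (dt_ms <= 0) stopf("sample interval must be > 0")
  structure(
    list(holding_mV = holding_mV, steps_mV = as.numeric(steps_mV),
         step_ms = step_ms, pre_ms = pre_ms, post_ms = post_ms,
         dt_ms = dt_ms),
    class = "step_protocol")
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf(
    "Voltage-step protocol: hold %g mV; %d steps %g..%g mV; %g ms step (%g ms pre, %g ms post); dt %.4g ms\n",
    x$holding_mV, length(x$steps_mV), min(x$steps_mV), max(x$steps_mV),
    x$step_ms, x$pre_ms, x$post_ms, x$dt_ms))
  invisible(x)
}

# Sample counts and index ranges of the three protocol segments.
protocol_layout <- function(protocol) {
  n_pre <- round(protocol$pre_ms / protocol$dt_ms)
  n_step <- round(protocol$step_ms / protocol$dt_ms)
  n_post <- round(protocol$post_ms / protocol$dt_ms)
  list(n_pre = n_pre, n_step = n_step, n_post = n_post,
       n_total = n_pre + n_step + n_post,
       step_idx = n_pre + seq_len(n_step),
       pre_idx = seq_len(n_pre),
       time_ms = (seq_len(n_pre + n_step + n_post) - 0.5) * protocol$dt_ms)
}

protocols_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}
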