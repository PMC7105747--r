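---
title: "Methods: quantifying cytokine-driven potassium-channel deregulation in synovial fibroblasts"
author: "flsephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cytokine-driven potassium-channel deregulation in synovial fibroblasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flsephys)
```

## Scientific context

Fibroblast-like synoviocytes (FLS) line the synovial joint and set the
composition of synovial fluid. Their membrane potential is dominated by
potassium conductances, in particular the large-conductance
calcium-activated potassium channel BK (gene *Kcnma1*, with modulatory
β-subunits *Kcnmb1–4*). Treating cultured FLS for 72 h with the
pro-inflammatory cytokines TNF-α and IL-1β — an established in vitro
model of inflammatory arthritis — depolarises the cells, reduces the
sustained outward current density, and remodels the ion-channel
("channelome") transcriptome.

`flsephys` packages the full quantitative chain needed to study this
phenotype at the desk: a seeded forward model of whole-cell
voltage-clamp cohorts, the patch-clamp analysis pipeline
(transient/sustained separation, I–V and difference currents, chord
conductance, Boltzmann fits, Nernst/Henderson potentials, resting-
potential statistics), a steady-state whole-cell membrane model that
maps BK calcium sensitivity (Kd) to the activation midpoint, and a
channelome stage for FPKM tables.

## The forward model of a recording

Each synthetic cell is a `cell_truth` with three conductance densities
(pS/pF), so currents scale with capacitance:

* **leak**: $I = g_{leak}(V - E_{leak})$;
* **sustained**: $I = g_s\,P_o(V)\,(V - E_K)$ with Boltzmann gating
  $P_o(V) = [1 + e^{-(V - V_{1/2})/k}]^{-1}$, activating instantaneously
  on the step;
* **transient**: a Hodgkin–Huxley-style $m\cdot h$ product with fixed
  exponents $1\cdot 1$,
  $I = g_t\,P_t(V)\,(V-E_K)\,(1 - e^{-t/\tau_{act}})\,e^{-t/\tau_{inact}}$,
  which peaks early and inactivates.

White Gaussian noise is added per sample. The recording filter chain
(1 kHz low-pass before 3 kHz digitisation) is *not* emulated: filtering
affects kinetics estimation, while every quantity this package reports
is a plateau mean or a smoothed peak, which the filter leaves
essentially unchanged. The transient's Boltzmann
($V_{1/2,t} = -10$ mV, $k_t = 14$ mV) and kinetics
($\tau_{act} = 20$ ms, $\tau_{inact} = 150$ ms) are field-typical
A-type-like values; only the envelope's existence matters for the
sustained-phase statistics, because by the final quarter of a 2 s step
the envelope has decayed below $10^{-4}$.

Between-cell variability is log-normal for positive-only quantities
(capacitance, conductances) and Gaussian for potentials and Boltzmann
parameters, the conventional choice for biophysical population spread.

## Calibrated study conditions

`paper_calibrated_config()` encodes the studied cohorts: 24 control and
20 treated cells, 2 s steps from −80 mV holding to −80…+60 mV in 20 mV
increments (the step count and spacing are a package default — the
source experiments show a step family without stating its grid), 3 kHz
sampling. The group-level targets are:

| quantity | control | treated |
|---|---|---|
| sustained density at +20 mV | 12.5 ± 2.3 pA/pF | 3.8 ± 0.8 pA/pF |
| corrected resting potential | −48.6 ± 1.7 mV | −38.6 ± 2.8 mV |

Both groups share the sustained activation curve
($V_{1/2} = +40$ mV, $k = 17.6$ mV, with small per-cell scatter of 2 and
0.5 mV); they differ only in conductance amplitude. The
control-minus-treated difference of the chord conductance is then itself
a Boltzmann with the same midpoint and slope, which is exactly the
analysis the difference-current pipeline performs. Conductance means
solve $d(+20) = g\,P_o(+20)\,(20-E_K)/1000 + g_{leak}\cdot 0.1$ with
$E_K = -84.60$ mV (Nernst, 141/5 mM, 294 K), giving 480.0 and
137.7 pS/pF. Population sds are the published SEMs times $\sqrt n$
(e.g. $2.3\sqrt{24} \approx 11.3$ pA/pF — the real cohorts are highly
variable, and the generator reproduces that variability rather than
shrinking it). Measured resting potentials are stored uncorrected
(−34.2 / −24.2 mV) and the −14.4 mV junction correction is applied at
analysis time, as in the experimental workflow. The transient component
is present in 75% of control and 55% of treated cells (the fractions of
cells contributing transient I–V data in the source cohorts), with
identical amplitude distributions, since no group difference in the
transient was found. Capacitance (45 ± 10 pF), leak (3 ± 1 pS/pF,
$E_{leak} = -30$ mV) and recording noise (5 pA) are field-typical
values chosen once.

## Analysis-chain conventions

* **Windows.** Sustained = mean over the final 25% of the step;
  transient peak = maximum within the first 500 ms minus the sustained
  level. The source experiments never state windows; these separate a
  sub-second transient from a 2 s plateau and are arguments, not
  constants.
* **Baseline.** The mean holding current over the 100 ms before the
  step is subtracted from both components. `baseline_ms = 0` disables
  this for leak-free synthetic data, where exact parameter recovery is
  then attainable (the baseline itself carries a small sustained
  holding current, $P_o(-80) \approx 10^{-3}$, which otherwise
  contaminates recovery at the $10^{-3}$ level).
* **Peak smoothing.** The transient peak is read from a 5 ms boxcar-
  smoothed trace; a raw pointwise maximum over ~1500 noisy samples
  would be biased upward by roughly $3.3\sigma$.
* **Chord conductance.** $g = 1000\,I/(V - E_{rev})$; points within
  2 mV of $E_{rev}$ are dropped as numerically unstable. $E_{rev}$ is a
  *required explicit argument*: the published chord conductances at
  +20 mV (271 and 120 pS/pF) are mutually inconsistent with any single
  reversal potential given the printed densities (they imply ≈ −26 and
  ≈ −12 mV respectively), so the package never guesses. The calibrated
  pipeline uses Nernst $E_K$.
* **Boltzmann fits.** Levenberg–Marquardt least squares
  (`minpack.lm::nlsLM`), initialised at $G_{max} = \max g$, $V_{1/2}$
  at the half-maximum crossing, $k = 10$ mV. Non-convergence or a
  non-positive slope/amplitude at the optimum sets a failure flag
  instead of raising; a flat G–V is flagged immediately (its midpoint
  is undefined).
* **Junction potential.** Henderson equation over a built-in relative-
  mobility table (K⁺, Na⁺, Cl⁻, Ca²⁺, Mg²⁺, gluconate⁻, HEPES⁻,
  EGTA²⁻, …); unknown species are a hard error, never silently
  defaulted. The standard FLS pipette/bath pair gives −13.3 mV at
  294 K, within the stated band of the −14.4 mV value used
  experimentally; the residual reflects mobility-table and ionisation
  choices (HEPES and EGTA are entered at nominal concentration as
  mono-/di-anions). Corrections are additive
  (`corrected = measured + LJP`) and tagged, so a vector cannot be
  corrected twice.
* **Statistics.** Group comparison by Welch's unequal-variance t-test
  (the safer reading of "unpaired t-test"); SEM of a single observation
  is 0 with a warning rather than `NaN`; no multiple-testing correction
  anywhere in the ephys chain.

## The membrane model and the Kd → V½ map

The steady-state model is
$$I(V) = g_{BK} P_o(V, Ca)(V - E_K) + g_{Kir}\,r(V)(V - E_K) +
g_{leak}(V - E_{leak}),$$
with textbook inward rectification
$r(V) = [1 + e^{(V - E_K - 10)/10}]^{-1}$ and $\sqrt{K_o/5}$ scaling of
$g_{Kir}$. BK gating is a Boltzmann whose midpoint moves leftward with
calcium through a Hill function:
$V_h(Ca) = V_{h0} - \Delta V_{max}\,Ca^h/(Ca^h + K_d^h)$. Voltage clamp
is simulated at steady state only — every reported quantity is a
plateau measure, so gating ODEs would add cost without information.

No independently fitted values for the BK gating parameters and the
resting calcium level of FLS are available to ship. The package
therefore uses an openly-stated anchor calibration:
fix $Ca_i = 0.35$ µM and $h = 1$, then solve $(V_{h0}, \Delta V_{max})$
from the two anchors $V_{1/2}(K_d{=}0.46\,\mu M) = +40$ mV and
$V_{1/2}(K_d{=}1.05\,\mu M) = +80$ mV, giving $V_{h0} = 134.9$ mV and
$\Delta V_{max} = 219.7$ mV (a calcium-free BK midpoint well above
+100 mV, consistent with BK behaviour in near-zero calcium). Under this
calibration `kd_for_shift(p, 40)` returning ≈ 1.05 µM is a
*self-consistency check of the sweep/inversion machinery*, not an
independent prediction — the anchors are built in by construction.
Replacing the calibration with externally fitted
$(V_{h0}, \Delta V_{max}, h, Ca_i)$ turns the same machinery into a
real inference.

`bk_gv_midpoint()` computes the midpoint two ways — analytically
($V_h(Ca_i)$) and by Boltzmann fit to the sampled G–V on a
−100…+320 mV grid — and the test suite requires agreement to $10^{-6}$
mV. `kd_sweep()` demands strict monotonicity (raising Kd must
depolarise the midpoint) and `kd_for_shift()` inverts it by bisection
to 0.01 µM.

## Channelome stage

FPKM tables (gene × sample TSV/CSV) are filtered to a curated
channel-gene list of ~270 symbols covering pore-forming and auxiliary
subunits of the major families plus connexins, pannexins, VDACs and
aquaporins, excluding channel-interacting and regulatory proteins. The
published study identified 190 channel genes with its own unpublished
list; the shipped list is independently curated, so counts on real data
may differ — the generator and tests therefore validate the *machinery*
(a table configured with 190 channel genes filters to exactly 190), not
the biological count. Matching is case-insensitive with transcript
suffixes stripped (`Kcnma1-203` → `kcnma1`).

Differential records use
$\log_2[(\bar x_t + \varepsilon)/(\bar x_c + \varepsilon)]$ with
pseudocount $\varepsilon = 0.05$ FPKM for stability near zero. A gene is
*detected* in a group when its mean FPKM exceeds 0.1 and it is non-zero
in at least half the replicates; this single rule drives the
appeared/disappeared classification (detected in exactly one group),
with up/down/unchanged decided by the ±1.5 log₂ cutoff among genes
detected in both. The 36 published per-gene log₂ values ship as a
plain-text resource and split 15 down / 21 up at that cutoff.

Confidence intervals: the default is a bias-corrected percentile
bootstrap over replicates (2000 resamples, seeded); a Welch t-interval
on per-replicate log₂ values is available via `method = "t"`.
**Known limitation:** at the study's own 4 + 4 replicate design the
bias-corrected bootstrap undercovers — measured coverage is ≈ 0.84 at
n = 4 and ≈ 0.91 at n = 8 against a nominal 0.95, the familiar
small-sample behaviour of percentile-type bootstraps — while the
t-interval holds ≈ 0.95 at both sizes. The acceptance suite therefore
checks bootstrap coverage at n = 8 (where first-order bootstrap
accuracy applies) and t-interval coverage at n = 4; for 4-replicate
designs the t-interval is the better default in practice. This may also
be read as a caution against over-interpreting bootstrap CIs on
4-replicate RNA-seq contrasts in general.

The synthetic generator draws a log-normal baseline per gene
(meanlog = log 20, sdlog = 1.5), multiplies treated means by
$2^{effect}$, adds replicate noise (sdlog 0.3), applies 2% random
dropout, and forces 20 "appeared" and 7 "disappeared" channel genes —
the structural scale of the studied channelome. It does **not** emulate
count-based dispersion (CuffDiff's model), library-size effects or
correlated genes; passing recovery tests show the thresholding and
classification machinery is correct, not that these settings match any
particular sequencing pipeline's error model.

## Problem sizes and numerical settings

The default test and acceptance workloads are sized for interactive
use: cohorts of 24 + 20 cells at 3 kHz (≈ 6600 samples × 8 steps per
cell) generate and analyse in under a second; property suites use a
1 kHz grid where kinetics are irrelevant; the CLT check uses 500 cells
on a 3-step protocol; coverage simulations use 400 genes × 1000
resamples. Root finding uses bracketed `uniroot` (resting potential to
$10^{-9}$ mV, bracketed between the extreme reversal potentials ± 1 mV;
Kd inversion to $10^{-3}$ µM). All randomness flows through explicit
seeds; identical seeds reproduce every output bit for bit, and seeded
helpers restore the caller's RNG state.

## What passing tests do and do not show

The synthetic cohorts reproduce the *statistical structure* the
analysis assumes: group means, SEM-scaled variability, a shared
activation curve, mixed transient phenotypes. They do not contain
series-resistance artefacts, seal drift, capacitive transients, P/N
leak-subtraction residues, or cell-to-cell correlation in time — so
green tests certify the analysis chain and calibration arithmetic, not
robustness to those experimental artefacts. Likewise the membrane model
contains only BK + Kir + leak; TRP-mediated calcium entry, calcium
dynamics and pharmacology (NS1619, paxilline) are out of scope, and the
`driving_force()` helper exists precisely to reason qualitatively about
the calcium-entry consequences of a depolarised resting potential
(`Vm − E_Ca < 0` means inward drive).
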