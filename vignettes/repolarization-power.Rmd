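---
title: "Repolarization power from time-dilated AP-clamp recordings: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repolarization power from time-dilated AP-clamp recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement and the correction

The repolarization power of a hERG-expressing cell is the time integral of
the current evoked by an action-potential voltage clamp,
$P = \int I_{\mathrm{hERG}}(t)\,\mathrm{d}t$, in pA·s (pA/pF·s for
capacitance-normalized recordings). It summarizes the net repolarizing
charge a channel variant delivers during one AP, which is what matters for
QT-interval phenotypes. The reference condition is 37 °C; automated patch
clamp is far more reliable at room temperature, where gating is slower and
the integral smaller.

The package implements the dilation/correction procedure that maps a
room-temperature measurement onto the physiological reference:

1. command the cell with the AP waveform whose time axis is stretched by a
   factor $f$ (`dilate()`), giving the slowed channel time to develop its
   current;
2. correct the recording by $t \mapsto t/f$, $I \mapsto f \cdot I$
   (`correct_trace()`).

The correction is an exact change of variables: the integral of the
corrected trace equals the raw integral of the dilated recording, for every
trace and every $f > 0$ (this substitution identity is tested to 1e-10
relative). If cooling slowed *every* rate **and** the conductance by the
same factor $f$, the corrected trace would equal the reference pointwise —
the time-rescaling identity that anchors the whole analysis, and the
strongest oracle in the test suite (uniform Q10 equal to the dilation
factor, 10 °C gap, maximum pointwise error < 1e-3 of the peak).

Real temperature sensitivities are not uniform, so a single factor can only
be a compromise; `scan_factors()` selects, from a candidate set, the factor
whose corrected repolarization power is closest to the reference (absolute
discrepancy; ties go to the smaller factor, since shorter protocols are
cheaper to record; the RMS trace discrepancy is reported alongside but does
not drive selection). Under the packaged model and Q10 values, a 10 °C gap
(27 → 37 °C, or 22 → 32 °C) selects $f = 2$ from
$\{1, 1.5, 2, 3, 5\}$.

Because kinetic compensation can hide kinetic distortion in an integral, a
second indicator, `time_of_peak()`, records when the current is maximal:
two traces with equal integrals but shifted current time courses are
distinguished by it.

## The gating model

No recordings ship with the package; a simulator stands in for them. The
current is a two-gate Hodgkin–Huxley formulation,

$$I(t) = g_{\max}\, a(t)^{4}\, i(t)\,\bigl(V(t) - E_{\mathrm{rev}}\bigr),$$

with a slow activation gate $a$ and a fast inactivation gate $i$ (fraction
of non-inactivated channels), each obeying
$\dot x = \alpha(V)(1-x) - \beta(V)x$ with exponential rate laws
$\alpha(V) = A e^{BV}$, $\beta(V) = C e^{-DV}$ (ms⁻¹, mV⁻¹). The defaults
(`default_wt_model()`), all overridable:

| quantity | default | meaning |
|---|---|---|
| activation $V_{1/2}$, slope | −30 mV, 9 mV | per-subunit steady-state activation |
| per-subunit activation τ at +20 mV | 500 ms | far-from-equilibrium activation within one AP |
| activation exponent | 4 | four subunit transitions, sigmoidal onset |
| inactivation $V_{1/2}$, slope | −55 mV, 25 mV | shallow, strongly inactivated at plateau |
| inactivation τ at 0 mV | 4 ms | fast inactivation/recovery |
| $E_{\mathrm{rev}}$ | −88 mV | physiological K⁺ gradient |
| $g_{\max}$ | 3200 nS | effective scale, see below |
| Q10 conductance | 1.4 | published whole-cell estimate |
| Q10 activation / deactivation / inactivation / recovery | 2.2 / 2.6 / 1.9 / 2.2 | within the published 1.7–2.6 band |

Temperature enters only through `scale_for_temperature()`:
$x(T) = x(t_{\mathrm{ref}})\,Q_{10}^{(T-t_{\mathrm{ref}})/10}$ applied to
each named process and to $g_{\max}$, guarded to 15–40 °C. Scaling is
transitive to 1e-10, and scaling by ΔT = −10 with a uniform Q10 of 2 halves
every rate exactly.

Three modelling choices deserve explanation:

* **Fourth-power activation.** hERG activates through several closed
  states; an $a^4$ Hodgkin–Huxley gate reproduces the sigmoidal onset and,
  more importantly here, makes the AP-clamp integral steeply (superlinearly)
  sensitive to kinetic speed. That steepness is a property the AP-clamp
  temperature data themselves demand: cooling by 10 °C slows whole-cell
  conductance only ~1.4-fold, so for a ×2 time dilation to *compensate* a
  10 °C gap (rather than overshoot by 2/1.4), the kinetic deficit left at
  effective speed $2/2.2 \approx 0.91$ must cost roughly the same ~30 % of
  the integral. A first-power gate is nearly linear in rate under this
  protocol and cannot produce that behaviour for any realistic rate
  constants — it would select 1.5 instead. `activation_exponent = 1`
  recovers the single-gate form, which the analytic step-response oracle in
  the test suite uses.
* **Calibration target.** The default kinetics were calibrated once against
  the AP-clamp temperature behaviour the method is built around (the
  collapse of the 27 °C factor-1 integral and the factor-2 optimum), not
  against isolated step-protocol time constants. As a consequence the
  per-subunit activation is slower than literature step-protocol estimates
  at 37 °C; macroscopic activation stays far from steady state within one
  300-ms AP. Users fitting their own cells should replace these constants.
* **Effective conductance.** Because open probability stays low during an
  AP in this far-from-equilibrium regime, $g_{\max} = 3200$ nS is an
  effective scale chosen so the wild-type 37 °C repolarization power is
  ≈ 22 pA·s (the order of magnitude reported for stable hERG lines); it is
  not a literature whole-cell conductance.

The per-process Q10 assignment is likewise an assumption, not measured
ground truth: published work brackets hERG gating-rate Q10s between 1.7 and
2.6 without a universally agreed per-process mapping. The defaults place
activation — the dominant, fourth-power process — at the band centre
(2.2), deactivation at the top (2.6, deactivation is the most
temperature-sensitive process in published estimates) and inactivation
slightly below its recovery (1.9 vs 2.2), which reproduces two observed
signatures at once: the factor-2 optimum under the packaged defaults and
the late shift of corrected room-temperature current in
inactivation-attenuated variants. All four are ordinary model fields.

## Variant presets

Variants are phenomenological (`variant_preset()`): a conductance scale,
per-process rate scales, and a shift of the inactivation voltage
dependence. Packaged presets:

* `R328C` — loss of function: conductance scaled to 0.3 (expression
  deficit); repolarization power ≈ 6.6 pA·s at 37 °C, below wild type.
* `D591H` — gain of function: inactivation half-voltage shifted +30 mV and
  recovery doubled (attenuated inactivation); ≈ 60.7 pA·s at 37 °C, above
  wild type, and its corrected 22 °C current peaks measurably later than
  the 32 °C reference — the kinetic fingerprint the secondary indicator is
  for.

These presets are calibrated to reproduce the qualitative loss/gain
ordering, not structural biophysics.

## The synthetic-data generator

`simulate_current()` integrates the gate ODEs with `deSolve::lsoda`
(rel/abs tolerances 1e-8/1e-10; gates initialized at holding-potential
steady state; the command voltage is piecewise-linear in time), sampling on
the protocol grid. Tightening tolerances tenfold moves the repolarization
power by < 0.01 %.

`simulate_population()` adds cell-to-cell variability: per-cell $g_{\max}$
from a log-normal parameterized to have mean $g_{\max}$
($\sigma^2 = \log(1+\mathrm{cv}^2)$, meanlog $= \log g_{\max} - \sigma^2/2$),
with per-cell seeds derived from one master seed. The current is exactly
linear in $g_{\max}$, so the ODEs are solved once per condition and scaled
per cell. `add_artifacts()` models what automated patch clamp adds on top
of the channel current: seeded Gaussian noise, ohmic leak, and a late
inward contamination ramp (a smooth descent to −amplitude over the terminal
sweep fraction) mimicking intracellular-solution contamination during cell
catch. The artifact defaults are deliberately conservative placeholders:
nothing quantitative is published about the contamination component, so it
exists to test analysis robustness, and it is excluded from any calibrated
claim.

What the generator does *not* emulate: series-resistance and capacitive
transients, seal instability, endogenous background currents, trafficking
(temperature-dependent surface expression), or channel noise. Passing tests
therefore validate the analysis pipeline and its internal consistency on a
plausible current generator — they do not certify behaviour on real
recordings with uncompensated instrumentation artifacts.

The default AP waveform (`ap_shape_params()`) is a stylized human
ventricular AP: hold −80 mV, 2-ms upstroke to +40 mV, plateau +20 mV,
APD90 300 ms, 100-ms pre/post-hold, 0.5-ms sampling, cosine-smoothed
repolarization (a piecewise-linear variant is available). The true
command waveform of any given rig can be substituted via
`read_protocol_csv()`; every analysis is waveform-agnostic. Dilation
stretches the *entire* command, holds included — integrals over the hold
segments are ≈ 0, so this choice is inert, and it matches how a slowed
sweep is actually commanded.

## Numerical and design choices

* **Integration window.** Default is the full sweep (explicit in every
  `repower_result`); window endpoints between samples are linearly
  interpolated. For clean traces the holding segments contribute ≈ 0; with
  leak they do not, which is why the window is user-settable and recorded.
* **Signed integration.** Negative excursions (the contamination dip)
  integrate with sign — recordings are integrated as-is. An optional
  `blank_late_artifact()` zeroes late sub-threshold samples; it is off in
  every default path.
* **Trace comparison.** `trace_discrepancy()` resamples both traces
  linearly onto a uniform grid over their overlap at the finer of the two
  native sampling intervals and returns the RMS difference.
* **Degenerate inputs.** An all-equal trace has no peak: `time_of_peak()`
  returns the window start with a warning. `normalize_to_peak()` refuses
  non-positive maxima. A zero-conductance model yields an identically zero
  current.
* **Statistics.** The usual ns / \* / \*\* convention (thresholds 0.05,
  0.01) is applied on top of rank tests by default — Mann–Whitney for
  independent groups, Wilcoxon signed-rank for paired — appropriate for the
  n = 6–9 cells of typical per-variant comparisons; Welch/paired t-tests
  are available. Pairwise comparisons are uncorrected by default (a Holm
  adjustment can be applied to the returned p-values with `p.adjust`).
  Group summaries are Tukey box-plot statistics: type-7 quartiles, whiskers
  at the most extreme data within 1.5×IQR fences.
* **Configuration.** Run configuration is YAML (`load_config()`): R has a
  mature YAML parser available everywhere this package runs, and the
  config structure (protocol / model / population / analysis / stats
  sections, strict unknown-key rejection, defaults for everything but the
  seed) is format-agnostic.
* **Determinism.** Every stochastic element — conductance draws, artifact
  noise, fixture generation — flows from explicit integer seeds;
  `make_fixtures()` output is bitwise reproducible.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is meaningful: single-condition
simulations on the default 0.5-ms grid (1001 samples), factor scans over
{1, 1.5, 2, 3, 5}, populations of 9–50 cells, 20 seed replicates for the
statistical-pattern check, and a reduced fixture grid in the IO tests. The
full fixture grid (3 variants × 4 temperatures × 6 factors × 8 cells) is
generated on demand by `make_fixtures()`.

## Known limitations

* The activation kinetics are calibrated to AP-clamp temperature behaviour,
  not to step-protocol data; do not reuse the default constants for
  voltage-step predictions.
* A single dilation factor is a compromise across processes with different
  Q10s; the residual kinetic mismatch is visible as a late shift of
  corrected traces (diagnosed by `time_of_peak`, quantified by
  `trace_discrepancy`) and grows with the temperature gap.
* Drug-block studies are out of scope: binding kinetics need not share the
  channel's temperature sensitivities, so time dilation is not a validated
  surrogate for temperature there.
* The statistical module reproduces the qualitative ns / \*\* patterns at
  matched seeds and n = 9; it makes no claim about the exact tests behind
  any published figure.
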