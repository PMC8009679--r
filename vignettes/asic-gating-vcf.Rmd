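---
title: "Modelling ASIC1a gating and voltage-clamp fluorometry signals"
author: "asicvcf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ASIC1a gating and voltage-clamp fluorometry signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asicvcf)
```

## The scientific problem

Acid-sensing ion channels (ASIC1a) are trimeric proton-gated Na⁺ channels.
Extracellular acidification evokes a transient inward current: the channel
opens and then desensitizes. Voltage-clamp fluorometry (VCF) records, next
to the current, the fluorescence of a dye attached to an engineered
cysteine; placing a quenching residue (Trp/Tyr) near the dye converts the
fluorescence change ΔF/F into a readout of whether two residues approach
(negative ΔF, increased quenching) or separate (positive ΔF) during a
gating transition. This package implements the computational layer of such
a study: a kinetic model of gating, a model of the fluorescence signal,
the kinetics metrics used to attribute ΔF components to transitions, and
the concordance analysis against residue-pair distances measured on
structural models of the closed, open, and desensitized conformations.

## The two-gate kinetic model

The channel is described by two independent first-order gates in the
Hodgkin–Huxley tradition: an activation gate $a$ and a sensitization gate
$s$. Their product rule defines four states,

$$P_C = (1-a)(1-s), \quad P_O = a(1-s), \quad P_{CD} = (1-a)s, \quad
P_{OD} = a\,s,$$

closed, open, closed-desensitized and open-desensitized; only O conducts,
so the current is $I = \pm\,g\,P_O$. Because the gates are independent,
$P_O P_{CD} = P_C P_{OD}$ holds identically, and O+OD tracks the
activation gate while CD+OD tracks the sensitization gate.

Each gate relaxes toward a pH-dependent steady state
$a_\infty(\mathrm{pH}) = x^n/(x^n + K^n)$ with $x = 10^{-\mathrm{pH}}$ and
$K = 10^{-\mathrm{pH}_{50}}$ — a Hill function of proton concentration —
with a time constant interpolated between an alkaline and an acidic limit
by a second Hill transition. The published rate set of the antecedent
wild-type model is deposited externally and is not transcribed here; the
module reproduces its *structure* and exposes every parameter through
`gate_parameters()` and JSON configs. The defaults were chosen once,
against the qualitative behaviour of the channel:

| parameter | activation gate | sensitization gate | why |
|---|---|---|---|
| pH50 | 6.60 | 7.05 | steady-state desensitization sits alkaline of activation |
| Hill n | 3.0 | 4.5 | steep proton dependence of both processes |
| τ alkaline | 0.30 s | 8 s | slow recovery from desensitization at pH 7.4 |
| τ acidic | 0.02 s | 1.2 s | ~10 ms-scale activation, seconds-scale desensitization |
| τ midpoint / n | 6.6 / 3 | 7.0 / 3 | transition between the limits around the gating range |

With these values the model produces transient pH 6.0 currents, an SSD
midpoint ~0.5 pH units alkaline of the activation midpoint, and a
biphasic peak occupancy of the CD state — the three qualitative
signatures the defaults are calibrated to. They are defaults, not fitted
constants.

### pH protocols and numerics

Bath pH follows a piecewise protocol (`ph_protocol()`); within a segment
the pH relaxes exponentially toward the target with time constant
`fall_time / ln 9`, so the 10–90% transit of the solution exchange equals
the nominal fall time (200 ms by default, the speed of the recording
chamber being emulated; `fall_time = 0` gives ideal steps). The ramp is
applied in pH rather than proton concentration — a deliberate and
isolated choice in `ph_value()`; the original simulations do not state
which convention they used.

The integrator (`integrate_gates()`) advances each gate with the exact
exponential update $a \leftarrow a_\infty + (a - a_\infty)e^{-\Delta t/\tau}$,
freezing $a_\infty$ and $\tau$ at the midpoint pH of each step. The
update is exact for constant pH, second-order accurate through ramps, and
unconditionally stable; gates start at the analytic steady state of the
conditioning pH, so no burn-in is simulated. At the default 1 kHz
sampling the trajectory agrees with an adaptive ODE solution to better
than $10^{-5}$ in every state probability (the test suite enforces
$10^{-3}$), and halving the step changes probabilities by under
$10^{-4}$.

## The fluorescence model and factor estimation

The modelled fluorescence is a state-probability-weighted sum,

$$\Delta F \sim F(C)P_C + F(O)P_O + F(CD)P_{CD} + F(OD)P_{OD},$$

with scaling factors in $[-1, +1]$ (`synthesize_dF()`). Traces are zeroed
on the pre-stimulus window; the factors are therefore identifiable only
up to this baseline convention, matching the proportional definition of
the model.

`estimate_factors()` reproduces the empirical decision tree used to fit
measured traces:

* **Transient signals** (|peak| > 1.1·|sustained| — the classification
  threshold is this package's choice, the source gives no numeric rule):
  $F(O) = \pm 1$ by the polarity of the signal; $|F(OD)|$ is solved
  (1-D search, tolerance $10^{-3}$) so the model reproduces the measured
  sustained/peak ratio.
* **Sustained signals**: $F(OD) = \pm 1$ by polarity, and $F(O)$ is read
  off a model-derived calibration curve mapping $F(O)$ to the statistic
  $(RT_F - RT_{AI})/(RT_{DI} - RT_{AI})$, built once per
  (model, protocol) pair at stimulation pH 6.0 (`calibrate_FO()`). The
  statistic is ~0 when ΔF tracks the activation gate and ~1 when it
  tracks desensitization. Onset kinetics depend almost exclusively on
  F(O) and F(OD), which the test suite verifies.
* **F(CD)** comes from a second calibration (`calibrate_FCD()`) relating
  the F(CD)/F(OD) ratio to the off-relaxation time after return to the
  conditioning pH; the off kinetics depend only on that ratio, so the
  curve is scale-invariant in the overall factor magnitude.
* **F(C)** stays 0 unless the three-factor model leaves a normalized RMS
  residual above 10% of the peak; only then is it fitted within
  $[-1, 1]$. F(C) is a compensatory, weakly identifiable parameter under
  the baseline convention: its fitted value should be read as "the trace
  needs a closed-state contribution", not as a precise weight.

Calibration curves are inverted by monotone piecewise-linear
interpolation; statistics outside the calibrated branch clip to the
nearest endpoint and set a warning flag rather than failing.

## Trace kinetics

Rise time is the time to pass from 10% to 90% of the amplitude (first
passages, linearly interpolated between samples); decay time mirrors it
on the falling phase from the peak. Two estimator details matter on noisy
data and are deliberate design choices:

* the amplitude at an extremum is re-estimated by a local linear fit
  around the argmax — the raw maximum of a noisy trace is biased high by
  the largest noise excursion, which would inflate rise times
  proportionally to the trace time constant;
* each threshold crossing is the midpoint of the first passage from one
  side and the last passage from the other; on a clean monotone trace the
  two coincide, under noise the first passage alone is biased early
  (markedly so on shallow decays).

Traces are pre-smoothed with a short *centered* moving average. A
centered window keeps the estimator symmetric under time reversal, so
the identity `decay_time(x) == rise_time(reverse(x))` holds by
construction. A saturating rise and a pure relaxation are sign-mirrors of
each other, so no polarity-free rule can both flag the former as
"no decay" and measure the latter; the tie is broken by signal magnitude:
a window whose signal moves monotonically away from baseline without
returning (the non-desensitizing pattern) yields an undefined (`NA`)
decay, while a window starting at an extremum that relaxes toward the end
level is measured. Undefined kinetics are always flagged `NA`, never
thrown, so cohort tables stay rectangular.

pH-response curves are fitted with the Hill equation
$I = I_{max}/(1 + (10^{-\mathrm{pH}_{50}}/10^{-\mathrm{pH}})^{n_H})$
(activation) or its decreasing analogue (steady-state desensitization),
by Levenberg–Marquardt least squares with $n_H \in (0, 10]$ and the
midpoint initialized at half-maximal response.

ΔF and current kinetics are classified as *correlated* when the ordinary
least-squares slope of $RT_F$ on $RT_I$ across cells lies in
$[0.75, 1.33]$. The regression keeps an intercept (the defining wording —
"linear regression" — does not force the origin) and the boundaries are
inclusive; both are documented decisions.

## Structure concordance

`cbeta_distances()` measures Cβ–Cβ distances of a residue pair in all
three subunits (or across the three cyclic subunit interfaces for primed,
intersubunit partners) of a trimeric structure, and
`state_distance_record()` averages them per state and forms the
differences with the convention that negative values mean approaching
(open vs closed; desensitized vs open). Classification
(`classify_pair()`): a negative ΔF polarity predicts approaching, a
positive one separation; agreement with the structural change of the
associated transition (closed–open for `o`-type components,
open–desensitized for `i`/`d`) is *consistent*, disagreement
*contradicts*, and changes below 1 Å are *indeterminate* (equality at the
threshold counts as interpretable — the legend's "< 1 Å" wording leaves
the boundary open). The `< o` association (movement faster than opening)
maps to the closed–open transition. Pairs with an average distance above
20 Å, or whose mutant does not desensitize, are excluded from
interpretation.

The packaged `table1.csv`/`table2.csv` fixtures are verbatim
transcriptions of the study's annotation and distance tables (plus a
`printed_font` column recording the printed classification), and the
default analysis path classifies against these printed distances.
Recomputing distances from coordinate files is supported but opt-in: the
human/chicken residue-numbering mapping is non-uniform and the homology
models behind the printed table are not bit-reproducible, so printed
deltas are the ground truth of record.

## The synthetic-data generator

`generate_recording()` inverts the analysis: it simulates the trajectory,
renders current and factor-weighted ΔF, applies an optional linear bleach
to the raw fluorescence, adds i.i.d. Gaussian noise per channel, and
re-normalizes to ΔF/F over the conditioning baseline. Defaults (current
noise 2% of a unit peak, ΔF/F noise 5·10⁻⁴, no bleach) emulate the visual
quality of published oocyte recordings; no noise statistics are reported
for the original data, so white noise is an explicit simplification —
real recordings have 50 Hz-filtered colored noise, perfusion artifacts
and slow drifts that the generator does not emulate. Passing tests
therefore demonstrate correctness of the estimators under the stated
noise model, not robustness to every experimental artifact.

`generate_cohort()` emulates per-oocyte variability: each cell draws a
lognormal multiplier (sd 0.3) on its gate time constants, and the
fluorescence kinetics are planted so that the cell's noise-free ΔF onset
rise time equals `target_slope` times its own noise-free current rise
time (a slope below 1 reads as "the reported conformational change is
faster than pore opening"). The regression of RT_F on RT_I then has the
planted slope in expectation, which the suite verifies to ±0.05.

Structure fixtures (`generate_structure_fixture()`) place Cβ atoms on
isolated rows and planes so that every planted per-interface distance is
realized exactly; they are labelled synthetic and carry no stereochemical
realism beyond the atom naming the PDB readers require.

All generators are pure functions of their inputs and seed; the session
RNG stream is saved and restored around every draw.

## Problem sizes and known limitations

The shipped analyses use 1 kHz sampling, 10–20 s pulses with 40 s
recovery windows (52 001 samples per trajectory), 13–15-point pH grids,
8-cell cohorts with 100 replicate cohorts per planted slope, 50 noisy
replicates for factor recovery, and 200 replicates for Hill-fit recovery
— sizes chosen so the full suite and the acceptance script each run in
about a minute on one core while keeping Monte-Carlo error well below the
tolerances tested.

Limitations worth knowing: the model has no intermediate states, no
voltage dependence beyond a fixed scale, and a single fluorophore
environment per recording; genuinely two-component ΔF signals (distinct
early/late components of some double mutants) must be annotated and
estimated one component at a time — the package does not auto-segment
them. Factor estimates inherit the identifiability limits of the
empirical procedure: in the transient branch |F(O)| is pinned to 1, in
the sustained branch |F(OD)| is, and recordings violating those
conventions are recovered only up to them.
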