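# asicvcf

Kinetic modelling and voltage-clamp fluorometry (VCF) analysis of ASIC1a
gating.

Acid-sensing ion channels (ASIC1a) are trimeric proton-gated Na⁺ channels
that open transiently upon extracellular acidification and then
desensitize. VCF pairs the membrane current with the fluorescence of a
dye docked at an engineered cysteine; a nearby quenching residue turns
the fluorescence change ΔF/F into a direction-of-movement readout for a
residue pair (negative ΔF = approaching, positive = separating). This
package is for channel biophysicists who want to analyse — or simulate —
such experiments end to end.

## What it implements

**Kinetic model.** A two-gate Hodgkin–Huxley-style model: an activation
gate *a* and a sensitization gate *s*, independent first-order processes
whose product rule spans the four states

    P_C = (1−a)(1−s),  P_O = a(1−s),  P_CD = (1−a)s,  P_OD = a·s

(closed, open, closed-desensitized, open-desensitized); only the open
state conducts, `I = ±g·P_O`. Gate steady states are Hill functions of
proton concentration, `a∞ = x^n/(x^n + K^n)` with `x = 10^−pH`,
`K = 10^−pH50`; time constants interpolate between alkaline and acidic
limits. Arbitrary piecewise pH protocols with a finite solution-exchange
fall time drive the exact-exponential integrator.

**Fluorescence model.** `ΔF ~ F(C)·P(C) + F(O)·P(O) + F(CD)·P(CD) +
F(OD)·P(OD)` with per-state scaling factors in [−1, +1], plus the
empirical estimation procedures that recover the factors from measured
trace kinetics (peak/sustained ratio, onset-statistic calibration,
off-relaxation calibration).

**Trace metrics.** 10–90 % rise times and 90–10 % decay times, peak vs
sustained amplitudes, ΔF/F normalization, Hill fits of pH-response
curves (`I = Imax/(1 + (10^−pH50/10^−pH)^nH)`), the RT_F-vs-RT_I
regression rule (correlated iff slope ∈ [0.75, 1.33]), and the
signal-specificity ratio.

**Structure concordance.** Cβ–Cβ distances of fluorophore–quencher pairs
across the three subunits (or cyclic interfaces) of trimeric structures
in the closed, open and desensitized states; classification of each
VCF-predicted movement as consistent / contradicting / indeterminate
(|Δ| < 1 Å) against the distance change of its associated transition,
with exclusion rules (> 20 Å pairs, non-desensitizing mutants). The
study's annotation and distance tables ship as packaged fixtures.

**Synthetic data.** Ground-truthed recordings (Gaussian noise, optional
bleach drift), multi-cell cohorts with planted RT_F/RT_I slopes, and
trimeric structure fixtures with planted distances — everything the test
suite needs is generated in code.

## Worked example

Simulate a recording whose fluorescence is dominated by the
open-desensitized state, extract its kinetics, and recover the scaling
factors:

```r
library(asicvcf)

model    <- channel_model()                 # defaults documented in the vignette
protocol <- pulse_protocol()                # 2 s pH 7.4 | 10 s pH 6.0 | 40 s pH 7.4

truth <- fluorescence_factors(F_O = -0.4, F_CD = -0.3, F_OD = -1)
rec   <- generate_recording(model, truth, protocol, noise_spec(seed = 42))

(metrics <- analyze_recording(rec))
#> Kinetics: RT_I 0.102 s, DT_I 2.73 s, RT_F_on 2.1 s, RT_F_off 8.28 s
#>   peak dF/F -0.981, sustained -0.9795 (sustained)

cal <- vcf_calibrations(model, protocol)    # model-derived calibration curves
estimate_factors(metrics, cal)
#> F(C) = +0.000  F(O) = -0.419  F(CD) = -0.300  F(OD) = -1.000
#> pattern: sustained
```

The current rises in ~0.1 s and decays (desensitizes) in ~2.7 s; the ΔF
onset sits between the two, so the signal is attributed mostly to the
open-desensitized state: the estimator pins F(OD) at −1 (sustained
pattern, negative polarity), places F(O) at −0.42 from the onset
statistic, and reads F(CD) = −0.30 off the off-relaxation calibration —
recovering the planted truth to within 0.02.

The packaged tables reproduce the study's concordance bookkeeping:

```r
summarize_table(read_table1(), read_table2())
#> VCF / structure concordance summary
#>   closed-open changes: 6 (2 intra-, 4 intersubunit)
#>   open-desensitized changes: 16 (14 retained, 2 excluded overall)
#>   retained open-desensitized: 5 consistent, 3 contradicting, 6 indeterminate
```

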