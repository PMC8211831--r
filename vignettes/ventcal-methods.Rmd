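---
title: "ventcal: methods, corrections, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ventcal: methods, corrections, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventcal)
```

## The measurement model

`ventcal` computes metabolic rates for a mechanically ventilated subject
from three measured ingredients:

1. **The molar ratio R = VI/VE**, measured mechanically: exhalation is
   collected into a non-permeable gasbag for a timed `te` seconds, then a
   constant-rate piston pump empties the bag in `ti` seconds. Since the
   same molecules fill and leave a bag of fixed content, `VI·ti = VE·te`,
   so `R = te/ti`. The only assumptions are that the pump rate is the same
   in both directions and that the bag's temperature and pressure are
   equilibrated to ambient during both counts (the ideal-gas condition);
   records violating the latter are dismissed, which
   `ratio_from_timing()` enforces via the `equilibrated` flag.
2. **Dry gas fractions** FIO2, FEO2, FECO2 after sensor corrections.
3. **The expired minute volume VE**, measured by water displacement and
   converted to dry STPD.

These combine as `VO2 = (R·FIO2 − FEO2)·VE`, `VCO2 = FECO2·VE` (the supply
gas is CO2-free), `RQ = VCO2/VO2`. Unlike the Haldane estimate
`VI/VE = (1 − FEO2 − FECO2)/(1 − FIO2)`, nothing here is singular at FIO2
1.0, and `haldane_ratio()` exists precisely so the two routes can be
compared where both are defined.

## Psychrometrics

Exhalation is water-saturated; all metabolic bookkeeping is dry-molar. The
water mole fraction of a sample at temperature `T`, relative humidity `rh`
and pressure `P` is `x_w = rh·es(T)/P`, and dry quantities are humid ones
times `1/(1 − x_w)`.

**Choice of saturation-vapor-pressure formula.** The Arden Buck (1981)
over-water form (constants 6.1121 hPa, 18.678, 234.5 °C, 257.14 °C) is
used throughout. On the twelve reference measurements taken under
intravenous anesthesia, multiplying each printed humid ratio by the Buck
humid-to-dry factor reproduces the printed dry ratio to ≤ 2×10⁻⁵ —
roughly six times tighter than the Magnus form on the same rows. The
enhancement factor for moist air (≤ 0.5% of `es`) is omitted; it is far
below the method's ±0.003 accuracy. Ice-phase formulas are out of scope
(all gases here are near room temperature).

**Dew point** is the closed-form inverse of the Buck formula: with
`y = ln(p_w/6.1121)`, solving `es(Td) = p_w` reduces to the quadratic
`Td²/c + (y − b)Td + y·d = 0`, whose physical root the package evaluates
directly. The test suite checks it against an independent bisection oracle
to < 0.01 °C.

**Units at boundaries.** Relative humidity enters files in percent (as
instruments report it) and is converted to a 0–1 fraction at parse time;
pressures are hPa internally, with gauge mmHg converted at parse
(1 mmHg = 1.333224 hPa).

## Sensor corrections and their order

Three distortions affect the raw fraction readings, inverted in this
order by `correct_reading()`:

1. **Pressure standardization.** Both sensors respond to partial pressure
   and are calibrated at ambient, but read in a circuit 10–15 mmHg above
   ambient (PEEP, circuit resistance, lung compliance), so raw readings
   are inflated by `p_circuit/p_calib`. The standardized fraction is
   `reading × p_calib/p_circuit`. The direction is a design choice — the
   source material states that standardization is needed but not the
   sign — and is the one under which readings taken above calibration
   pressure are lowered back to physical fractions.
2. **CO2/O2 cross-sensitivity.** The infrared CO2 reading falls linearly
   with O2 concentration; the empirical correction is
   `CO2 = CO2m/(1 − 0.00072·O2m)` with both operands **in percent** (the
   coefficient then gives the stated 7.2% effect at 100% O2). The O2 value
   used is the pressure-standardized one: each correction consumes
   already-physical inputs. Whether the original procedure used the raw or
   standardized O2 here is not documented; the difference is second-order
   (≈1.5% of a 7% correction).
3. **Humid → dry.** Expired fractions divide by `(1 − x_w)` at the
   exhalation line's temperature and humidity.

A raw `gas_reading` may legitimately exceed 1.0 (100% O2 read 12 mmHg
above calibration pressure ≈ 1.016); the strict `[0, 1]`/sum-to-1
contracts therefore apply to *corrected* fractions, where small
(percent-level) overshoots of the sum are tolerated as sensor noise — at
FIO2 1.0 the true dry expired fractions already sum to exactly 1, so any
positive noise realization overshoots.

Inspired O2 is recorded on a dried circuit before and after the expired
block; `interpolate_fio2()` supplies the linear time series in between.
One-second records are averaged over 60 s windows (`average_window()`).

## STPD convention and test-lung QC

"Standard temperature and pressure" is taken as the metabolic-physiology
STPD convention: 273.15 K, 1013.25 hPa, dry. `ve_to_stpd()` applies
`(1 − x_w)·(P/1013.25)·(273.15/(273.15 + T))` to the humid
water-displacement volume.

The test lung (a rubber balloon, no gas exchange) has true R = 1; its
measurements QC each experiment day. The pass band `|R − 1| ≤ 0.005` is a
package choice: the observed day-to-day test-lung spread is
0.99643–1.00465, and the method's stated accuracy is ±0.003; no numeric
band is given in the source material.

## Error budget

The O2 sensor's random error is ±0.2% of reading and the R measurement's
is ±0.3%; they are independent. Both "±x%" figures are interpreted as
**1-sigma relative errors** — a modelling choice, documented rather than
asserted. With VE constant and FIO2 fixed by the calibrated supply gas,
first-order propagation through `VO2 = (R·FIO2 − FEO2)·VE` gives

```
δVO2/VO2 = sqrt((σR·R·FIO2)² + (σO2·FEO2)²) / (R·FIO2 − FEO2)
```

σO2 is applied to the *expired* O2 reading only: FIO2 comes from a
calibrated gas supply and is treated as exact. Under this reading the
high-FIO2 operating point (extraction 0.048, σR = 0.003, σO2 = 0.002)
evaluates to ≈7.5%, the order of the published figure; attributing σO2 to
both O2 readings would give ≈8.6%. The exact operating point behind the
published ±7.5%/±2.5% figures is unstated, so they are treated as
order-of-magnitude anchors, not reproduction targets. A seeded Monte Carlo
(`monte_carlo_vo2_error()`, multiplicative Gaussian perturbations of R and
FEO2) checks the delta-method answer; they agree within 5% at these
sigmas with 10⁵ draws.

## The simulator: what it emulates, and what it does not

`forward_model()` is an exact molecule balance at dry STPD:

```
vo2_total = mass·(vo2_mito + k_p450·FIO2 + k_skin·max(0, FIO2 − 0.21))
vco2      = mass·rq_tissue·vo2_mito
VE        = VI − vo2_total + vco2 + dn2
FEO2      = (VI·FIO2 − vo2_total)/VE ;  FECO2 = vco2/VE ;  R = VI/VE
```

Design choices, made once:

- **Sinks are linear** in FIO2 (enzymatic, cytochrome-P450-like oxidation
  of intravenous anesthetics) and in FIO2 − 0.21 (cutaneous diffusion,
  zero at room air). These are the simplest forms consistent with the
  qualitative "O2-concentration-dependent" mechanisms hypothesized for
  the hyperoxia VO2 rise; no mechanistic dose-response is available to do
  better. Whether cutaneous loss should follow the skin-surface rather
  than inspired O2 gradient is unresolved; the linear surrogate is a
  stand-in.
- **The Haldane violation is one number.** Observed R exceeds the Haldane
  prediction with no known mechanism, so the simulator exposes a single
  net N2 flux `dn2` rather than inventing one. `dn2 = 0` recovers an
  exactly N2-conserving world in which direct R and the Haldane estimate
  provably coincide — a property test, not an assumption.
- **Defaults are the experimental conditions**: 180 mL/min minute
  ventilation, 45 breaths/min, PEEP 2, 0.40–0.50 kg subjects, exhalation
  RH 0.92 at room temperature (circuits equilibrate to ~0.90–0.93),
  ambient 22.4–23.5 °C and 995–1025 hPa, te = 600 s with noise on ti only
  (te is a controlled duration).
- **Noise enters where the physics says**: humidification, inverse
  cross-sensitivity distortion and pressure inflation are applied in the
  order the pipeline inverts them; multiplicative Gaussian noise then
  perturbs the expired O2 reading and ti. With zero noise the pipeline is
  the exact inverse of the forward model (round-trip residual ~1e-16,
  asserted at 1e-9).

The 2×2 cohort presets (`cohort_preset_2x2()`) place group-mean recovered
VO2 at 15.4/21.0 (intravenous arm, enzymatic sink `k_p450 = 8.0`
mL/kg/min per unit FIO2) and 15.4/17.2 (volatile arm, cutaneous sink
`k_skin = 2.571`), with VCO2 near 12.1–12.5 via
`rq_tissue = vco2_target/vo2_mito`, a 7% between-animal CV (the reference
group SD/mean ratio), and per-animal `dn2` solved so the dry molar ratio
lands at the observed group means (~1.007–1.011). The attribution of each
arm's O2-dependence to a single sink is illustrative — the source offers
both mechanisms without apportioning them.

The simulator does **not** emulate: breath-by-breath waveforms or
capnogram shapes (the mixing chamber averages them away), the empirical
decline of R toward 1.0 at high minute ventilation (no mechanistic basis
to simulate honestly), or sensor drift beyond the linear pre/post FIO2
interpolation. A green parameter-recovery test therefore establishes that
the correction chain inverts the modelled distortions at the modelled
noise level — not that the model captures every behaviour of a live
preparation.

## Statistics

Group summaries report the **population SD** (n denominator): it
reproduces three of the four reference ±values exactly at 4 decimals
(0.0018, 0.0017, 0.0029). The fourth (volatile-anesthetic group) computes
to 0.0024 against a printed 0.0023 under either denominator; it is
reported as computed. Display rounding is half-up at 4 decimals
(`round_half_up()`), and comparisons against published values are made on
the rounded display values.

`mann_whitney_u_exact()` computes the exact two-sided p-value over the
full permutation null with mid-rank ties, via dynamic programming on the
doubled-rank multiset — numerically identical to enumerating all
`C(nx+ny, nx)` labelings (the test oracle does exactly that for sizes
≤ 5) but feasible at 12 vs 12. The comparison is unpaired; whether the
original analysis paired animals across FIO2 levels is unstated.

## Known limitations

- The twelve volatile-anesthetic reference rows deviate from the
  humid→dry correction applied to their own printed bag conditions by up
  to 1.6×10⁻³ — under any standard vapor-pressure formula. A 2.5%
  isoflurane vapor correction or a different effective measurement
  temperature would explain it, but the source does not say. These rows'
  printed dry values are therefore treated as given data for group
  summaries, and the looser 2×10⁻³ tolerance on them is documented, not
  hidden.
- The published per-group VO2/VCO2/RQ values are not desk-reproducible
  (the per-animal gas readings are not printed); the cohort presets
  emulate their means but are not a reproduction.
- The supplementary correction diagram referenced by the source is hosted
  externally; the correction order implemented here is a documented
  package choice consistent with the text, not a verbatim transcription.
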