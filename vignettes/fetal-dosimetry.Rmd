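---
title: "Foetal dosimetry and risk estimation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Foetal dosimetry and risk estimation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetaldose)
```

## The problem

Inadvertent or clinically necessary X-ray examinations of pregnant patients
generate requests for a retrospective estimate of the dose absorbed by the
embryo/foetus and the radiation risks that dose implies. Simply looking up
an average uterus dose for the examination type can badly over- or
under-estimate the individual dose, because the dose depends on the
technique factors actually used, on the maternal anteroposterior (AP)
thickness, and on how deep the foetus lies. `fetaldose` implements the
individualised reconstruction: technique factors in, absorbed dose and
per-endpoint risk out, with a full audit trail.

## The dose model

All pathways reduce to a product of three factors: an *exposure quantity*
(entrance surface dose, dose-area product, or CT dose index), a *normalized
uterus dose* (NUD) coefficient converting that quantity to uterus dose at
the patient's foetal depth, and a *foetal size factor* (SF) converting
uterus dose to foetal dose at the patient's gestational age.

**Radiographs.** When a measured entrance surface dose (ESD) is supplied it
is used directly. Otherwise ESD is reconstructed from the QA tube-output
calibration:

$$\mathrm{ESD} = \left[\frac{\mathrm{FSD}_{QA}}{\mathrm{FSD}_{EX}}
\cdot \frac{\mathrm{kVp}_{EX}}{\mathrm{kVp}_{QA}}\right]^2
\cdot \mathrm{output} \cdot \mathrm{mAs},$$

i.e. the inverse-square distance correction and the empirical quadratic
dependence of tube output on potential. The quadratic rule is an
approximation; the package applies it as stated for any gap but emits a
warning when the exposure potential is more than 30 kV from the calibration
potential. The contract fixes the measurement geometry of both `output`
(mGy/mAs) and `output_rate` (mGy · min⁻¹ · mA⁻¹) at the QA focus-to-surface
distance; screening runs then contribute
`output_rate × mA × time(minutes)` under the same corrections. When a
record carries both a measured ESD and complete QA technique data, the
measured value wins and the conflict is logged — a supplied measurement is
better evidence than a reconstruction.

**Dose-area product.** DAP records (Gy·cm²) use a separate NUD table in
mGy per Gy·cm²; no distance correction applies because DAP is invariant
along the beam.

**CT.** A helical acquisition contributes

$$D_f = \mathrm{NUD}_V \cdot \mathrm{CTDI}_{soft} \cdot
\frac{\mathrm{mAs}/100}{\mathrm{pitch}},$$

with $\mathrm{CTDI}_{soft} = 1.07 \cdot \mathrm{CTDI}_{air}$ (air to ICRU
muscle). $\mathrm{NUD}_V$ sums per-slab normalized uterus doses over the
scan volume of a 208-slab, 5 mm-resolution reference phantom; the slab
tables are normalized per 100 mAs, hence the mAs/100 factor. Two readings
of the pitch term are arithmetically possible from the conventional layout
of this formula; we divide by pitch, consistent with helical-CT physics
(higher pitch means fewer rotations per unit length and proportionally less
dose). No size factor is applied to CT doses: the slab coefficients already
describe uterus dose in a whole-body phantom geometry.

**Totals.** Doses add across records and examinations; per-foetus totals
group records by `patient_id`, covering multiple and repeat examinations.
Nothing is rounded internally — presentation rounding lives entirely in the
risk and cohort layers.

## Lookup conventions

*Interpolation.* NUD-versus-depth and SF-versus-gestational-age tables are
interpolated piecewise-linearly. Linear interpolation is exact at grid
points, bounded by neighbouring grid values (no overshoot), and easy to
verify against an independent polyline evaluation, which the tests do.
Outside the grid the nearest endpoint is used and a warning emitted:
extrapolating a fitted trend beyond tabulated Monte Carlo data would
manufacture precision the tables do not have.

*Slab inclusion.* A slab belongs to the scan volume iff its **midpoint**
lies in the half-open interval `[scan_start, scan_end)`. The midpoint rule
keeps the slab sum additive over abutting ranges and order-independent;
fractional-overlap weighting was considered and rejected because the CT
dose formula is a pure sum of tabulated slab values, and a weighting scheme
would silently change the quantity being summed. The phantom frame puts the
origin at slab 0's lower edge, in millimetres, increasing toward the head.

*Beam quality.* Radiographic NUD tables are banded by kVp; a record's kVp
selects the band containing it, with shared edges resolving to the lower
band. Published compilations sometimes index by half-value layer instead of
(or in addition to) kVp; the CSV dialect reserves room for an HVL column
extension but the current matcher uses kVp only. CT tables require an exact
scanner-model match — interpolating organ-dose profiles between scanner
models has no physical basis.

*Defaults.* When the measurements are missing, foetal depth defaults to
9 cm and maternal AP thickness to 25 cm — the population averages used in
clinical practice when patient-specific values are unavailable. When no
size-factor table is supplied, SF = 1 with a warning. SF is evaluated once
per foetus from the gestational age at examination; per-record gestational
ages would only matter for examinations spread over weeks, which the record
schema does not attempt to represent.

## Risk model and the "1 in N" convention

Stochastic risk is linear no-threshold, $R = D_f \cdot RC$, with default
coefficients:

| endpoint | coefficient | unit |
|---|---|---|
| childhood cancer | 8.0 × 10⁻⁵ | per mGy |
| hereditary effects | 0.5 × 10⁻⁵ | per mGy |
| IQ decline | 25 × 10⁻³ | IQ points per mGy |
| severe mental retardation | 43 × 10⁻⁵ | per mGy |

All four are user-overridable. No dose threshold is applied to stochastic
endpoints. The gestational-age windows in which the mental-retardation and
IQ endpoints are biologically plausible (roughly weeks 8–15, attenuated to
week 25) are *not* gated by default — the report presents the coefficients
as published and leaves clinical interpretation to the physicist; a
gestational-age-aware report was considered and deliberately left out of
the default path to keep the arithmetic transparent.

Formatting: the risk is rounded **half-up** to one significant figure
$d \times 10^k$, and the denominator is taken from the reciprocal grid
$N = M(d) \times 10^{-k-1}$ with mantissa map

$$M = \{10,\; 5,\; 3.3,\; 2.5,\; 2,\; 1.7,\; 1.4,\; 1.25,\; 1.1\}
\quad (d = 1 \ldots 9),$$

so $2\times10^{-3}$ → "1 in 500", $3\times10^{-4}$ → "1 in 3300",
$8\times10^{-5}$ → "1 in 12500". Two details matter and are easy to get
wrong:

* **Half-up, not half-to-even.** A risk of $2.5\times10^{-7}$ must round to
  $3\times10^{-7}$ ("1 in 3300000"); R's `signif()` would round it to
  $2\times10^{-7}$ ("1 in 5000000"). The package implements explicit
  half-up rounding.
* **The map, not generic rounding.** Two-significant-figure reciprocal
  rounding would print "1 in 13000" where the convention prints
  "1 in 12500". The grid keeps denominators on the familiar clinical scale
  (..., 1000, 1250, 1400, 1700, 2000, 2500, 3300, 5000, 10000, ...), and
  its worst-case deviation from the exact reciprocal of the rounded risk is
  about 2% (at leading digit 7).

An alternative seen in some published tables reports the exact reciprocal
of the *unrounded* risk for isolated cells (e.g. 1/(2.5 × 10⁻⁴) = 4000
rather than the rounded 3300). The package applies the one-significant-
figure convention uniformly; mixing conventions cell-by-cell is not
reproducible.

`consequence_report()` adds the remaining presentations: safety
($1 - R$), equivalent number of chest examinations (reference foetal dose
0.001 mGy per chest film, the population mean), and equivalent period of
natural background exposure (default 2.4 mGy/year — a representative
worldwide average; the value is configurable because local background
varies several-fold). The deterministic-effect advisory trips at
100 mGy, the accepted threshold below which tissue reactions
(death, malformation, growth or mental retardation) are not expected;
it is an advisory flag, not a computed risk.

## Cohort layer

`summarize_cohort()` totals dose per foetus and bins on the half-open
intervals `[0, 0.1)`, `[0.1, 1)`, `[1, 10)`, `[10, 50)` mGy; a dose of
exactly 1.0 mGy falls in the `1–<10` bin. Doses of 50 mGy or more go to an
overflow bin with a warning — a properly conducted diagnostic workup should
not reach them. Range/mean tables aggregate *per examination* while
histograms and risk bands aggregate *per foetus*, matching how survey
results are conventionally reported. Headline shares ("x% received less
than 1 mGy") are integer-rounded percentages derived from the histogram
alone. Band risk strings take the bin edges through the one-in-N pipeline,
rendering the excluded upper edge as a strict bound
(`1 in 125000–<1 in 12500`).

## Synthetic generators

The NUD compilations used in practice are licensed publications and cannot
ship with the package, so both ends of the pipeline have deterministic
synthetic stand-ins, seeded and reproducible to the byte.

`simulate_coefficient_tables()` emulates the *structure* of the real
tables: NUD falling off exponentially with foetal depth (attenuation
through overlying tissue; decay constants 0.18–0.28 cm⁻¹, slower for harder
beams), per-projection surface values spanning pelvis-field magnitudes
(~0.3 per mGy ESD) down to chest-scatter magnitudes (floored at
1.2 × 10⁻⁵), three contiguous kVp bands over 50–120 kVp, Gaussian 208-slab
CT profiles peaking at a configurable uterus position (default 300 mm, peak
0.005–0.03 per slab, spread 60–120 mm), and a smooth size-factor curve
rising from ~1 early in gestation to ~1.5 near term. What it does **not**
emulate: real tables derive from Monte Carlo transport in anthropomorphic
phantoms and carry projection-specific shapes, field-size dependence and
statistical noise that no smooth parametric family reproduces. Tests
passing on these fixtures therefore validate the *lookup, interpolation and
arithmetic machinery*, not the dosimetric accuracy of any real coefficient
set — accuracy against a licensed table is inherited from that table, not
from this package.

`simulate_cohort()` emulates a referral cohort: gestational ages uniform on
2–38 weeks, foetal depths on 4.9–9.3 cm, maternal AP thicknesses on
16.5–31.0 cm (the ranges seen in multinational referral data); a mix of
measured-ESD, DAP, QA-reconstruction, fluoroscopy (spot films plus
screening) and CT examinations; 25% of patients with multi-examination
workups (2–4 examinations) and 10% of examinations repeated 2–3 times.
Magnitudes are chosen so cohort dose distributions look like practice:
mostly below 1 mGy, a small tail above 10 mGy, nothing near 50 mGy. The
generator guarantees every row resolves a dose pathway, so end-to-end runs
have zero schema rejects by construction.

## Numerical choices

* Coefficient CSVs are written by `readr` (shortest round-trippable
  representation) and read back with base R's correctly-rounded `strtod`
  parser, so generate → write → load → lookup round-trips bit-identically.
* Interpolation delegates to `stats::approx` after the package's own
  clamping and validation; the tests compare it against an independent
  polyline evaluation at 10⁻¹² relative tolerance.
* Totals are plain sums; contributions are non-negative by construction, so
  no compensated summation is needed at cohort sizes (hundreds of records).
* Degenerate inputs: an empty record set gives an empty result with a zero
  total; a CT range covering no slab midpoint gives 0 mGy with a warning;
  zero dose gives zero risk, safety 1, and a "negligible" sentinel below a
  configurable 10⁻⁹ risk floor.
* Test and example problem sizes — cohorts of tens to a few hundred
  patients, 50-draw property loops — were chosen as the smallest sizes that
  exercise every pathway and bin; the pipeline is linear in the number of
  records, and nothing in the method is stochastic except the synthetic
  generators.

## Known limitations

* Beam quality is matched on kVp alone; half-value-layer indexing is a
  schema extension, not yet a matcher feature.
* CT requires an exact scanner-model key; there is no fallback to a
  "similar" scanner.
* Organ doses other than uterus/foetus, shielding modifications, automatic
  exposure control, and radiotherapy or occupational exposure pathways are
  out of scope.
* The risk coefficients derive mainly from high-dose, high-dose-rate data;
  their linear extrapolation to the sub-mGy range is the standard
  radiation-protection convention, not a verified dose-response claim, and
  the package inherits that caveat wholesale.
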