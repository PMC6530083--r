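---
title: "Models and methods in scoil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in scoil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scoil)
```

scoil analyses chemical-mutagenesis screening campaigns for oleaginous
yeasts. This vignette documents the models it implements, the choices made
where the design was genuinely open, and what the synthetic-data tests do
and do not demonstrate.

## FAME profiles and mass conventions

A FAME profile is a weight-percent composition over identified fatty acids
in the `C<carbons>:<double_bonds>` notation. Profiles are always
renormalized to sum to exactly 100: gas-chromatography panels report percent
of *identified* peaks, and the unidentified remainder is not carried.
Mole-percent input is not supported.

Component molecular masses are computed from atomic masses (C 12.011,
H 1.008, O 15.999) for the free acid CnH(2n−2d)O2; a methyl-ester basis
(+CH2, 14.027 g/mol) is selectable because part of the biodiesel
correlation literature is calibrated on ester masses. The free-acid basis
is the default, matching the usual reading of "molecular mass of each fatty
acid component" in the correlation sources.

The viscosity and density correlations consume mixture-level terms ΣM and
ΣDB. scoil implements these as **percent-weighted means** of component mass
and double-bond count. This is a deliberate interpretation: taken as raw
sums over components they would be two orders of magnitude too large and
produce physically absurd viscosities, while weighted means yield the
3.5–4.4 mm²/s range reported for single-cell-oil biodiesel.

## Fuel indices

The ten indices are empirical correlations (see the README for the
formulas). Numerical conventions:

* **Iodine constant.** The default is 254, the constant used by the
  empirical-correlation literature; 245 appears in some secondary sources
  and is selectable (`iv_constant = 245`). Cetane number and heating value
  are computed from SV and IV and are unaffected by this choice when SV/IV
  are supplied directly.
* **LCSF** uses the saturated species C16:0 and C18:0 only — it is a
  long-chain *saturation* factor; unsaturated C16/C18 species do not
  contribute to cold-filter plugging in this correlation.
* **Oxidative stability** diverges as C18:2 + C18:3 → 0. A profile without
  these acids gets an `Inf` value flagged `unbounded` rather than an error,
  so a report is always produced.
* "Ln" in the viscosity correlation is the natural logarithm (the only
  reading that reproduces realistic kv), and reports print two decimals,
  matching the precision of published fuel panels.

Compliance checking encodes EN 14214 (IV ≤ 120, CN ≥ 51, kv 3.5–5,
density 0.86–0.9, OS ≥ 6), ASTM D6751 (CN ≥ 47, kv 1.9–6) and IS 15607
(CN ≥ 51, kv 3.5–5, density 0.86–0.9); unconstrained indices are reported
as such, and the overall verdict passes iff no constrained index fails.

## Survival statistics

Survival is computed against the untreated control (time 0), not the first
exposure point: the published abstract rates (e.g. 23/205 = 11.22%) confirm
this convention. Survival and mortality are stored at full precision and
rounded to two decimals only for reporting, with round-half-even; published
tables occasionally truncate instead, so comparisons elsewhere tolerate
±0.01. A dash in a colony table means "no colony on the plate" and is read
as a structural zero with a lethal flag — distinct from absent data. The
lethal time is the earliest zero-count exposure.

Tukey letter grouping computes the one-way ANOVA pooled variance, all-pairs
studentized-range statistics (`stats::ptukey`; no table lookups), and
assigns letters by scanning groups in descending mean order and merging
maximal runs of mutually non-significant groups. Zero pooled variance falls
back to exact-equality grouping. The pairwise p-values are cross-checked
against `stats::TukeyHSD` in the test suite; the letter-display algorithm
itself is the package's own.

## Response surfaces

The design is the full 3×3 cross of EMS concentration and volume; when the
levels are the study defaults, run ids follow the published experiment
numbering so fixtures line up. Factors are used in **natural units**
(mM, µl) — the published equation magnitudes make clear no −1/0/+1 coding
was applied — and the "3 blocks" of the design are treated as 3 replicates
with no block term, since the published equations contain none.

Fitting is OLS via QR (`stats::lm`), never explicit normal equations; the
tests carry an independent normal-equations oracle. ANOVA uses sequential
(type I) sums of squares in the term order x, y, x², y², xy — with unequally
spaced levels the linear and quadratic columns are not orthogonal, so order
matters and is fixed. p-values are upper-tail F probabilities with no
multiplicity correction, matching standard screening practice. Negative
fitted CFU predictions are legitimate quadratic extrapolations and are
returned flagged, not clipped.

Refitting the transcribed design table reproduces the published equations'
curvature terms within two units of the last printed digit, but intercept
and linear terms deviate beyond printed rounding (and one interaction sign
flips). This is expected: the source table is typographically garbled in
places (ambiguous cells are flagged `uncertain` in the fixture and excluded
from fitting tests), and the published fit may have used per-replicate data
whose means differ from the printed ones. `rsm_compare()` therefore
*reports* the full coefficient comparison rather than asserting it; tests
assert only the curvature agreement on the clean column.

## Productivity metrics

`BP = (final − initial)/time`, `L = 100(w1 − w2)/wB`, `LC = 100·lipid/biomass`,
`LP = BP·L/100`, implemented exactly as stated. The packaged lipid panel
carries an explicit `lp_consistent` flag because the reported LP values are
not reproducible from the reported BP and L via the stated formula (wild
YlTun15: 0.37 × 10.32/100 = 0.038 vs reported 0.090 mg/ml/h); whether the
published LP used lipid content or a different BP is undeterminable, so the
package implements the formula as written and preserves the evidence. The
wet- versus dry-biomass basis is the caller's responsibility; no implicit
conversion is made.

## Synthetic studies

The generator emulates the statistical structure the analyses assume, with
the minimal noise model for each data type:

* **Colony counts**: Poisson draws around `exp(a0 + a1x + a2x² + a3y +
  a4y² + a5xy)`. The strain-named presets fit this log-quadratic to the
  packaged design table, take the control expectation n0 from the control
  plates (205–311 CFU), and set the survival decay rate k so that expected
  60-min survival equals the strain's observed rate (11.22% for YlTun15).
  The generator's defaults are thus the study's own magnitudes.
* **Growth**: logistic OD600 curves (carrying capacities 21.9–28.2, maxima
  around 96–120 h) with additive Gaussian noise truncated at zero.
* **Compositions**: hierarchical Dirichlet draws (built on `rgamma`) —
  class shares around SFA/MUFA/PUFA targets, then acids within class —
  with a single concentration parameter; dispersion → ∞ recovers the target
  composition exactly.

All generators are pure functions of (parameters, seed): reruns are
bit-identical and the caller's RNG stream is restored.

**Recovery targets.** For a surface refit on Poisson data the estimand is
the *population OLS projection* of the expected-count surface onto the
quadratic model space (the exponential mean is not itself quadratic, so the
model-space projection is the only well-defined truth). The acceptance
check "coefficients within 3 SE of truth in ≥ 99% of repetitions" is
evaluated per coefficient across 1,000 seeded repetitions of the default
preset (9 runs × 3 replicates): under ideal Gaussian theory the joint
all-six-within-3-SE event has probability about 0.993⁶ < 0.99, so the
per-coefficient reading is the one the criterion's own arithmetic admits.
In practice coverage is conservative because the model-based residual
variance includes lack-of-fit of the quadratic to the exponential surface.

**What passing synthetic tests does not show.** The generator reproduces
magnitudes and noise families, not real screening data: plate counts may be
over-dispersed relative to Poisson, growth curves can show death phases the
logistic lacks, real FAME compositions have covariance structure a single
Dirichlet concentration cannot express, and dose–response surfaces need not
be log-quadratic. Recovery results certify the estimators, not the biology.

## Problem sizes

The test suite fits 9-run designs with 3 replicates (the study geometry),
uses 1,000 repetitions for coefficient-recovery rates, 300–400 seeds for
survival Monte-Carlo means, and 1,000 Dirichlet draws for compositional
means — sizes at which the Monte-Carlo error of each check is well below
its assertion tolerance. The whole suite runs in well under a minute.

## Known limitations

* No cis/trans or positional isomer distinctions; fuel correlations that
  depend on them are outside scope.
* Compliance limits cover the indices the screening literature reports;
  full standards include further assays (flash point, sulfur, glycerides)
  that cannot be predicted from FAME profiles.
* LD50-style dose–response curve fitting is deliberately not included; the
  lethal-time statistic is the screening-level summary.
* The quadratic surface is a local screening model: predictions far outside
  the design region are extrapolations and are flagged only for sign.
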