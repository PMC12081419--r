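---
title: "Counting statistics and method verification for asbestos burden analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting statistics and method verification for asbestos burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberburden)
```

## The measurement and its model

Lung tissue is freeze-dried, a known dry mass is oxidised in an oxygen
plasma asher, the mineral ash is suspended in water and an aliquot is
drawn through a polycarbonate membrane. The filter is examined at the SEM
at ×12,000, field by field, and every asbestos fiber longer than 1 µm is
recorded. `fiberburden` starts where the physics ends: it owns the
arithmetic and the statistics, not the preparation.

Two assumptions carry the whole extrapolation:

1. **Homogeneous deposition.** Fibers land on the active filtration area
   uniformly at random, so the fields examined are an equiprobable sample
   of the deposit and field counts are Poisson.
2. **Proportional loading.** Filtering `V_f` of `V_s` millilitres of a
   well-mixed suspension of `m` grams of dry tissue deposits
   `p_TS = m · V_f / V_s` grams of tissue-equivalent on the filter.

Under these, with `n_f` countable fibers over `N_fields` fields,

$$C = \frac{n_f \, A}{N_{fields}\, a \, p_{TS}} \quad \text{[ff/g dry]},$$

with `A` the active filtration area and `a` the calibrated field area,
both in mm². The *analytical sensitivity* `AS = A/(N_fields · a · p_TS)`
is the concentration a single fiber represents, so `C = n_f · AS` exactly
— an identity the tests enforce, because every uncertainty statement
below is a statement about `n_f` rescaled by `AS`.

Counting uncertainty is Poisson: `sd(n_f) = √n_f`, hence a relative
standard uncertainty of `100/√n_f` percent. At the 50-fiber stop this is
14.1% (reported rounded as 14%), 28.3% expanded with coverage factor 2 —
which is also why a 50-fiber cap is a sensible stopping rule: beyond it,
extra counting barely narrows the result while the preparation
uncertainty dominates.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `active_area_mm2` (`A`) | mm² | 222 | 2.22 cm², the active area of a 25 mm membrane in a standard funnel |
| `field_area_mm2` (`a`) | mm² | none — required | an instrument calibration value; deliberately never assumed |
| `ash_load` advisory limit | mg/cm² | 15 | above it, particulate buries fibers; flagged, never enforced |
| counting cut-off | µm | 1, strict `>` | the certification basis of the available CRMs is fibers > 1 µm; a fiber of exactly 1 µm is not counted |
| `as_requirement` | ff/g dry | 1e5 (0.1 mil) | the routine sensitivity requirement; `fiber_burden()` flags, `plan_fields()` plans for it |
| `fiber_cap` | fibers | 50 | the stop rule; counting past it is wasted effort (see CV above) |
| `ci_level` | — | 0.95 | convention |
| working range upper bound | ff/g dry | 3e8 (300 mil) | a reporting constant; extendable by loading less tissue per filter |

Concentrations are stored in ff/g dry and reported in "mil ff/g dry"
(10⁶ ff/g), the scale certificates use; the conversion factor is fixed.

## Confidence intervals and degenerate inputs

The interval is the exact Garwood interval: gamma quantiles
`[qgamma(α/2, n), qgamma(1−α/2, n+1)]` for the Poisson mean, rescaled by
`AS`. The paper-and-pencil alternative `C ± z√n·AS` is available as
`interval = "normal"` for comparison with legacy reports; it is anti-
conservative below roughly 20 fibers.

Two zero-related conventions deserve a note:

* `poisson_interval()` is strictly central: at `n = 0` the upper bound
  keeps the `α/2` tail (`qgamma(1−α/2, 1) ≈ 3.69` at 95%). Any other
  choice breaks the guaranteed-coverage property of the exact interval —
  with a one-sided upper limit at `n = 0`, coverage at true means just
  above 3 drops to ≈0.94. The tests verify coverage ≥ nominal at several
  means precisely because this is easy to get subtly wrong.
* A zero-count *result* is still reported: concentration 0, sd 0, a
  below-sensitivity flag, and a one-sided upper limit
  `−log(1−level)·AS`. That is the natural summary for blanks and clean
  samples, where the question is "how much could we have missed", not a
  central interval. The two conventions live in different functions and
  both are tested.

`plan_fields()` returns the smallest integer field count whose
sensitivity meets the target; the closed-form ceiling is guarded on both
sides against floating-point effects at exact boundaries, and a target
needing more fields than the filter has area for raises a typed
infeasible-plan error rather than a silent cap. Preparations with no
tissue (`p_TS = 0`, a procedural blank) are representable, but asking for
a per-gram concentration from one is an error.

## Reference-material verification

Precision and trueness are assessed against the two certified lung-tissue
materials (amosite + crocidolite at 49.0 mil ff/g, anthophyllite at
5.1 mil ff/g), each measured eight times:

* **Precision**: `χ²_c = (s_w/σ_w0)²` against `χ²(0.95, n−1)/(n−1)`
  (2.01 at n = 8), strict `<`.
* **Trueness**: `|x̄ − x_cert| ≤ k·√(u_meas² + u_CRM²)` with `k = 2`,
  boundary equality passing — mirroring the direction of the printed
  comparisons.

Three quantities are *supplied*, not derived, and
`validate_against_crm()` refuses to run without them:

* `σ_w0`, the specified within-laboratory SD. The published columns are
  consistent with different derivations (the Poisson reference
  `5.1/√50 = 0.72` matches the anthophyllite column; `49.0/√50 = 6.93`
  does not match the printed 7.0). `poisson_reference_sd()` makes the
  Poisson convention available explicitly; it is never invoked silently.
* `u_meas`, the standard uncertainty of the measurement result. The
  printed 7.4 is neither `s_w` (7.5) nor `s_w/√8` (2.65), so its formula
  is unstated; it stays an input.
* `t_factor = 2.45` for recovering `u_CRM = U/t` from the certificate
  (numerically the two-sided 95% Student t with 6 df), configurable.

Two printed cells of the anthophyllite column are internally
inconsistent with their own inputs: `(0.92/0.72)² = 1.63` (printed 1.56,
consistent with an unrounded SD near 0.90) and `2√(0.87²+0.61²) = 2.13`
(printed 2.26). The package computes from the stated inputs, asserts the
computed values, and documents the mismatch in its tests; both verdicts
pass under either value, so no conclusion changes.

## What the simulator emulates — and what it does not

`simulate_session()` draws per-field countable-fiber counts at
`λ = C · p_TS · a / A`, walks fields in order over the planned count from
`plan_fields(target_as)`, applies the 50-fiber cap, and attaches lengths
(log-normal, `meanlog = log 3`, `sdlog = 0.8`, truncated just above 1 µm
— a realistic right-skewed tissue-fiber length distribution, purely
cosmetic for count statistics) and amphibole classes. Design choices:

* **The cap completes the current field.** The field is the atomic unit
  of examination at the microscope; stopping mid-field would require
  partial-area bookkeeping with no statistical benefit.
* **Overdispersion** is a single-parameter gamma-mixed Poisson: per-field
  variance `λ(1 + d·λ)`. It models filter inhomogeneity, the failure
  mode the homogeneity requirement exists for. The default is 0: the
  verification argument assumes the filter passed visual homogeneity
  inspection. Note that because the mixing is independent across fields,
  the inflation `d·λ²` is negligible at small per-field rates; the
  coverage-degradation property is therefore demonstrated at `λ = 1`
  over 20 fields, where it actually expresses.
* A configurable **sub-micrometre fraction** adds fibers below 1 µm so
  the counting rule's filter can be shown to remove them.

What it does **not** emulate: spatial structure on the filter (counts are
drawn directly, not placed), EDS misclassification, inter-batch variance
between CRM bottles (replicates are i.i.d.), losses in preparation, and
fiber breakup. Passing simulation-based tests therefore demonstrates the
statistical machinery under the model the uncertainty treatment assumes —
not the field performance of the laboratory method, which is what the
CRM verification is for.

### Known limitation: stopping-rule bias

The ratio estimator `n_f/N_fields` is exactly unbiased under a fixed
field count, but the fiber cap makes `N_fields` a stopping time and
introduces a small upward Jensen-type bias of order `1/cap` (≈2% at
cap 50). Simulation at 2×10⁵ sessions puts it at ≈1.9% at 5 fibers per
field and ≈2.05% at 0.44 fibers per field. This is a property of the
field-completing stop rule itself, not of the implementation; it is well
inside the 14% counting CV at the cap, and the bias assertion in the
test suite is anchored at λ ≥ 5 where the bound holds with margin.

## Problem sizes and reproducibility

All simulations are seeded and bit-reproducible; every entry point that
draws random numbers accepts a seed, and one seed drives a whole
campaign. The shipped checks use 500 eight-replicate campaigns for the
verification pass rate (observed ≈0.91–0.92 under the pure-Poisson
model), 10⁴ sessions for interval coverage (binomial SE < 0.0025;
observed ≈0.955–0.96, inside the conservative band expected of exact
intervals), 10⁴ sessions for the capped-bias check, and 10⁴ pooled
sessions for the index-of-dispersion property. These sizes keep each
Monte-Carlo standard error a factor of a few below the tolerance it is
checked against.
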