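---
title: "Auditing the carbon footprint of dental nitrous oxide: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the carbon footprint of dental nitrous oxide: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2oaudit)
```

## The model

An episode of inhalation sedation delivers a nitrous-oxide/oxygen mix at a
total flow rate $f$ (L/min) with the N₂O fraction titrated up to a maximum
$c \in (0, 1]$ over an administration time $t$ (min). The audit convention
treats the maximum titration as applying over the whole administration, and
ignores the brief initial up-titration increments (their contribution to the
total volume is minimal). The administered N₂O volume, mass and footprint are

$$V = f \, c \, t, \qquad m = \rho V, \qquad E = G \, m,$$

with gas density $\rho = 0.001984467$ kg/L and global warming potential
$G = 265$ (the AR5-era 100-year figure; the current assessment's $G = 273$
is selectable via `gas_constants(gwp = 273)`, and rescales every footprint
by exactly $273/265$, i.e. +3%). Everything is linear, so full precision is
carried internally and rounding happens only at report formatting.

**Assumptions.** No ramp model of titration is offered: the maximum-fraction
simplification deliberately overstates each episode slightly, and is the
convention a service can actually audit from its notes. The footprint covers
administered gas only — not wasted gas, consumables, equipment, surgery
energy or travel.

A note on rounding: $30\,\mathrm{L} \times \rho \times 265 = 15.7765\ldots$,
which rounds to 15.78 under round-half-up, while audit reports conventionally
print 15.77. The package does not guess a rounding convention for other
people's printed numbers; tests compare within ±0.01 kg.

## Wastage estimation

Cylinder procurement is converted to a weekly available volume through a
capacity registry. The defaults, size E = 1,800 L and size G = 9,000 L of
gas, are the unique round-number capacities consistent with the standard
conversions "10 size-E cylinders/year = 346 L/week" and "6 size-G
cylinders/year = 1,038 L/week". Those conversions only reproduce under a
**52-week year**: `period_weeks()` therefore maps 364–366-day periods to
exactly 52 weeks and any other period to `days / 7`. (Under 365/7 = 52.14
weeks, 10 × 1800 L would print as 345 L/week, not 346.)

Wastage is the shortfall fraction
$w = 1 - \text{administered}/\text{procured}$. Three numerical choices
matter:

- **Negative values are preserved.** If the audit week was unusually busy,
  administered volume can exceed the pro-rata procured volume; $w < 0$ is
  reported verbatim and flagged `negative_anomaly`, never truncated, because
  truncation would bias any group mean upward.
- **The investigation threshold defaults to 0.20** ("investigate wastage over
  20%"), with the stricter in-study trigger of 0.25 available by
  configuration. Flagging is a pure function of $(w, \text{threshold})$; the
  threshold never alters the estimate itself.
- **Shared manifolds are ineligible**: when a piped supply also feeds
  theatres or other specialties, the procured volume is not attributable to
  dental sedation and no estimate is made.

Dividing the size-E capacity by the mean per-episode volume implied by the
national mean footprint ($28.62 / (\rho G) = 54.42$ L) gives
$1800 / 54.42 \approx 33.1$ episodes per cylinder. Audit reports quote
"approximately 32"; the gap is consistent with the (unpublished) capacity
value used there, and is documented rather than tuned away.

## The synthetic cohort generator

The national dataset behind the published audit (891 episodes, 31 services,
128 sites) is available only on request, so the generator emulates its
printed statistical structure and makes every pipeline stage testable.

**Marginals.** Flow, maximum titration and duration are positive,
right-skewed clinical quantities, so each is drawn from a log-normal
truncated to its printed range, with the log-scale location solved
(closed-form truncated mean, monotone root-find) so the truncated mean hits
the printed national mean:

| factor | mean | range | log-sd (default) |
|---|---|---|---|
| flow (LPM) | 5.84 | 1–13 | 0.35 |
| titration (fraction) | 0.345 | 0.10–0.55 | 0.35 |
| duration (min) | 28 | 3–99 | 0.55 |

The log-sds are the one free shape choice; they were fixed once at values
giving coefficients of variation typical of clinical audit data (≈0.3 for
machine settings, ≈0.5 for procedure time) and are not calibration dials.
The single 70% titration outlier observed nationally is reproducible only by
explicit injection (`inject_outlier = TRUE`, off by default), since it lies
outside the truncation range.

**Dependence and calibration.** Under independence the expected per-episode
footprint is the product of the means,
$5.84 \times 0.345 \times 28 \times \rho G = 29.67$ kg CO₂e, which
overshoots the printed per-episode mean of 28.62. The joint distribution is
therefore *not* independent: the generator couples the three factors through
an equicorrelated Gaussian copula with a single correlation parameter
$\theta \in (-0.5, 1)$ (marginals untouched). `calibrate_dependence()` finds
$\theta$ by seeded Monte-Carlo root-finding: one fixed matrix of standard
normals is reused across evaluations (common random numbers), making the
objective smooth and the result deterministic given the seed. The calibrated
value is mildly negative, $\theta \approx -0.086$ at the defaults —
operationally plausible: longer or higher-flow administrations tend to be
titrated a little lower. If the target is unreachable within the admissible
correlation range the calibration aborts with the achievable bracket; if
independence is already within tolerance, 0 is returned unchanged.

**Demographics and outcomes.** Ages are a two-component mixture: paediatric
(≤ 15 years) with probability 0.83, adult otherwise. The within-band
distributions and the ASA mix are not printed anywhere, so they were chosen
once: paediatric ages uniform on 4–15 (dental sedation is rarely attempted
below ~4), adult ages uniform on 16–80, ASA grades 1–3 with weights
0.65/0.25/0.10. Under these choices the implied standard-IVS eligibility
(age ≥ 12 and ASA ≤ II) is ≈40%, consistent with the published soft figure —
a consequence of the stated assumptions, not a fitted target. 19 of 31
services offer routine acclimatisation; episode success is Bernoulli with
probability 0.91 in offering and 0.94 in non-offering services (pooled ≈92%).
Sites split 84%/16% cylinder/manifold, and half of manifolds are shared with
other specialties (the published audit could estimate wastage at only 10 of
20 piped sites, suggesting roughly half were shared).

**Procurement.** Given a per-site administered volume and a target wastage
$w^\ast \in (-1, 1)$, the generator buys the whole-cylinder count closest to
$\text{administered}/(1 - w^\ast)$ per week (size E at cylinder sites, G at
manifold sites). Recovered wastage therefore differs from the target by at
most the single-cylinder quantisation step divided by the procured volume;
the nearest attainable value is reported per site.

**What a green test does and does not establish.** The generator reproduces
printed *marginal* summaries and one calibrated joint moment. It does not
reproduce real per-service case-mix heterogeneity, procedure-specific
durations, seasonal variation, or the correlated site/service structure of a
real national audit. Consequently the published service-level observables
(518.25 kg CO₂e mean weekly footprint, the exact 92% on the real 891
episodes, the exact 40% eligibility) are emulated, not desk-reproduced — the
underlying data are unpublished.

## Aggregation conventions

- The national per-episode mean is **episode-weighted**: total CO₂e divided
  by total episodes ("average footprint per appointment").
- The acclimatisation success comparison pools by the **unweighted mean of
  per-service rates** ("average success rate in services offering..."), with
  episode weighting available as an option. An empty group is `NA`, never 0.
- A printed per-episode range can be read over episodes or over per-service
  means; the ambiguity is real, so the rollup reports the per-service-mean
  range and the episode-level range remains available from
  `episode_footprint()`.
- Services are anonymised with stable pseudonyms assigned in sorted-id order.
- In `run_audit()`, a service counts as "offering routine acclimatisation"
  iff any of its audited episodes is an acclimatisation procedure — the
  episode template carries no policy field, so policy is inferred from
  observed practice.

## Degenerate inputs and numerics

Empty episode collections are errors, not silent zeros. Ingest validation is
total (valid rows + enumerated exclusions = input rows) and rows missing a
core numeric field are excluded with a warning rather than imputed — the
footprint formula has no missing-data procedure. The truncated-log-normal
mean uses tail-stable normal-CDF differences so the location solver cannot
lose precision at extreme brackets. CSV round-trips apply percent↔fraction
normalisation exactly once and are byte-stable on a second pass.

## Known limitations

- The maximum-titration convention overstates individual episodes by design;
  the package offers no ramp model because audit records contain no ramp.
- Wastage estimates from one-week windows are noisy by construction (the
  observed negative estimates are the visible symptom); they are screening
  estimates, not stock accounting.
- The copula family (equicorrelated Gaussian) is an assumption; any
  single-parameter family matching the marginals and one product moment
  would serve, and only that moment is calibrated.
- JSON is the only config format (no YAML dependency in the supported
  environment).
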