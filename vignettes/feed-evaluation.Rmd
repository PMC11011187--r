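---
title: "Feed evaluation by difference-method digestibility trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feed evaluation by difference-method digestibility trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feedeval)
```

## The problem

Novel feed ingredients — here, protein meals rendered from bovine
slaughterhouse by-products (rumen content, ears, blood, cheeks) — cannot be
fed as a complete diet, so their nutritional value cannot be measured
directly. The standard workaround is the *difference (indirect) method*: a
reference feed that can be fed alone (barley meal, in the bundled study) is
measured directly in a metabolic-cage trial; the test ingredient is then
mixed into the reference diet at a known inclusion (20 % here), the mixed
diet is measured the same way, and the ingredient's digestibility is
obtained by subtracting the reference's known contribution. feedeval
implements that whole chain for the canonical design — nine animals per
treatment, a seven-day total-collection period — together with the
downstream energy evaluation and the treatment comparisons trial reports
print.

## The model

**Apparent digestibility.** For each animal and proximate component
(DM, CP, EE, CF, NFE), intake $I$ and fecal output $F$ are accumulated over
the collection period and

$$D = \frac{I - F}{I} \times 100 .$$

Intakes come from daily offered minus refused feed (refusal is assumed
non-selective: a ground mash cannot be sorted) converted through the diet's
composition; fecal outputs from daily fresh feces, its measured DM
fraction, and the animal's pooled fecal composition. $D$ is *apparent*
(endogenous fecal losses are not corrected) and is never clamped: values
outside $[0, 100]$ are legitimate noise outcomes, are flagged, and
propagate — silent clamping would bias every downstream energy number.

**The difference method.** Writing $s_k$ for the reference diet's share of
the mixed diet's intake of nutrient $k$, the mixed-diet coefficient is the
blend $D_{diet,k} = s_k D_{ref,k} + (1-s_k) D_{ing,k}$, and the method
inverts it:

$$D_{ing,k} = \frac{D_{diet,k} - s_k\, D_{ref,k}}{1 - s_k}.$$

The share is *nutrient-wise* —
$s_k = f\,c_{ref,k} / \bigl(f\,c_{ref,k} + (1-f)\,c_{ing,k}\bigr)$
with $f$ the as-fed reference fraction and $c$ the as-fed nutrient
concentrations — not the raw 80/20 mass proportions, which are
dimensionally wrong whenever the two feeds differ in concentration (the
two weightings coincide only for DM). For a nutrient the ingredient lacks
entirely, $s_k = 1$ and the ingredient coefficient is unidentifiable; it
is reported absent rather than invented. This is exactly the case of the
fiber-free animal meals, whose CF and NFE columns stay empty.

The inversion is applied per animal (with the reference treatment *means*
as $D_{ref}$), and the treatment mean and between-animal sd are taken over
the inverted values — the mean-of-ratios convention that matches reporting
a per-treatment sd over $n = 9$ animals. A pooled-ratio alternative
(one ratio of summed masses) is available via `method = "pooled"`.

**Energy chain.** Digestible components are composition × digestibility;
total digestible nutrients weight fat by its energy density,

$$\mathrm{TDN}\,\% = dCP + 2.25\,dEE + dCF + dNFE,$$

with absent components contributing zero; and energy follows as
$\mathrm{DE} = \mathrm{TDN}\,\% \times 44.09$ kcal/kg,
$\mathrm{ME} = 0.82 \times \mathrm{DE}$. The three constants live in
`energy_constants()` and are logged with every pipeline run; the
N-to-protein factor (6.25, with 5.7 as a literature alternative) is
carried for provenance only.

**Intake and growth.** Voluntary intake is scaled to the mean of initial
and final body weight (the choice is explicit and configurable: the study
design records both weights without saying which to use) — as a percent of
live weight and as g per kg metabolic weight, $W^{0.75}$ (kg basis).
Test-ingredient intake is attributed by inclusion fraction on an as-fed
basis and converted with the ingredient's own DM, so reference plus test
attribution reproduces total DM intake exactly.

**Treatment comparison.** One-way ANOVA (via `stats::lm`) followed by
Duncan's multiple range test. Critical values are computed from
studentized-range quantiles (`stats::qtukey`) at Duncan's protection
levels $\alpha_p = 1-(1-\alpha)^{p-1}$, never from hard-coded tables, so
any error df is supported. Spans are tested widest-first with the standard
shielding rule, and maximal non-significant spans become the compact
letter display (lowercase, contiguous from "a", largest mean carrying
"a"). The test is *unprotected* by default (no ANOVA-F gate), matching
common animal-science practice; `protected = TRUE` collapses the display
whenever the overall F is non-significant. Both modes are provided because
trial reports rarely state which was used. Ties in means are broken by
input order.

## Composition conventions

Component percentages are interpreted on the analysed (air-dry) fraction
unless a profile declares `basis = "dry_matter"`; conversion is always
explicit (`as_dry_matter()` / `as_analyzed()`), never guessed. Components
plus ash are expected to close to 100 within ±2 percentage points; closure
failure is a logged warning, never an error, because published composition
tables do not always close — the bundled blood-meal row sums to 76.9 and
must remain loadable for the rest of its column to be usable. In CSV
files, "†", "NA" or an empty cell mark an absent component, legal only in
the CF and NFE columns; absent components are carried as exact zeros plus
a flag so mass-balance arithmetic stays total.

## The simulator

`simulate_trial()` is the forward model of the same mass balance:
offered and refused feed are drawn per animal-day; nutrient intakes follow
from the blended diet; true fecal output per nutrient is
$I_k (1 - D_k/100)$ with the animal's true mixed-diet coefficient built
from the reference and ingredient truths via the same nutrient shares the
analyser uses; fresh fecal mass and pooled fecal composition are
back-computed; and measurement noise is applied last. The hidden truth is
returned alongside the observable dataset, so
`analyze(simulate(truth, noise = 0)) == truth` is a testable identity —
the suite verifies it to ten significant digits across random truth
configurations, and verifies small bias and faithful between-animal spread
under noise.

Noise model, and the defaults taken as the canonical study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_animals`, `n_days` | 9, 7 | design size |
| `inclusion_fraction` | 0.2 | as-fed test-ingredient inclusion |
| `offered_g_mean`, `offered_g_cv` | 60 g, 0.10 | daily as-fed offer |
| `refusal_frac_mean`, `refusal_frac_cv` | 0.15, 0.30 | daily refusals |
| `animal_dev_sd_pp` | 3 pp | per-animal deviation of true ingredient digestibility |
| `fecal_noise_cv` | 0.05 | multiplicative daily fecal-mass measurement noise (unit-mean lognormal) |
| `fecal_comp_noise_sd_pp` | 0.3 pp | additive noise on pooled fecal composition, truncated to [0, 100] |
| `feces_dm_frac_mean`, `feces_dm_frac_sd` | 0.35, 0.02 | fecal DM fraction |
| `bw_mean_g`, `bw_sd_g` | 822, 60 | initial body weight |
| `daily_gain_mean_g`, `daily_gain_sd_g` | 6, 1 | true daily gain |

Body-weight and intake scales are guinea-pig realistic: ~820 g animals
offered ~60 g as-fed daily with modest refusals give roughly 45 g DM
intake per day, and a between-group initial-weight sd of ~60 g matches
what 9-animal treatment groups of this size typically show.

Three modelling choices deserve a note:

* **Per-animal variation enters through the varying feed only.** Deviations
  are applied to the test ingredient's true coefficients (to the
  reference's own when it is fed alone), while the reference's
  indigestibility is held constant across animals in mixed diets — which is
  precisely the assumption the difference method rests on. Applying
  deviations to the reference in mixed diets would make the method's
  estimand itself animal-dependent and the share-amplified reference noise
  would swamp the ingredient signal.
* **The DM deviation is induced, not drawn.** DM is the aggregate of its
  components, so an animal's DM deviation is the composition-weighted sum
  of its component deviations. Drawing it independently can imply a fecal
  component exceeding total fecal DM — an unphysical dataset the package
  would rightly refuse to construct. Any `dm` entry in `animal_dev_sd_pp`
  is therefore ignored.
* **Truth feasibility is enforced.** Configurations implying digestibility
  outside $[0, 100]$ or a fecal component above fecal DM (i.e. negative
  masses somewhere in the balance) are rejected with a diagnostic rather
  than silently truncated. Only per-nutrient feasibility is enforced,
  however: the generated fecal profile's components need not jointly close
  with ash to 100, which apparent-digestibility bookkeeping never needs.

What the generator does *not* emulate: selective refusal (sorting),
cecotrophy and other physiological digestion dynamics, day-to-day
autocorrelation in intake, nonlinear growth, and drift in fecal
composition over the collection week. Passing recovery tests therefore
show the *analysis chain* is correct and well-calibrated for this noise
model — not that real trials are free of the biases those phenomena can
introduce.

`biowaste_scenarios()` packages the bundled study as five simulation
configurations (reference diet alone plus four 80/20 test diets), with the
published composition rows as profiles, the published coefficient means as
simulation truths and the published sds as per-animal deviations. The
reference diet's own coefficients were never published, so
`barley_reference_digestibility()` supplies clearly-labelled stand-in
truths (DM 83, CP 75, EE 80, CF 40, NFE 85 %); every simulated recovery
claim is conditional on them. Because the analyser inverts exactly what
the generator blends, the noise-free closure test — simulate every
scenario, analyse, compare with the configured truths — passes to at least
six significant digits regardless of the stand-in values.

## Numerical choices

* All computation is in full double precision; rounding happens only at
  rendering. Comparisons against published table cells use ±0.02
  percentage points for percent columns and ±2 kcal/kg for energy columns,
  because the source tables round their intermediates.
* Sds of digestible components are the same linear map as the means
  (component × sd/100). Sds of TDN/DE/ME are taken from the per-animal
  chain when per-animal coefficients exist (exact under between-animal
  correlation); with only summary inputs they combine in quadrature, which
  assumes independent coefficients and is labelled as such.
* Degenerate ANOVA inputs are reported, not errored: no variation at all
  gives F undefined with p = 1 (no evidence of difference); zero
  within-group variance with distinct means gives F = ∞, p = 0. An epsilon
  guard (1e-12, scale-aware) absorbs floating-point residue in exactly
  degenerate data.
* Unequal group sizes use the harmonic-mean n in Duncan's ranges (logged).
* The multiplicative fecal-mass noise is unit-mean lognormal
  ($\mu = -\sigma^2/2$), so measured output is unbiased by construction.

## Known limitations

* One published energy cell is not reproducible from its own inputs: the
  blood-meal digestible EE printed in the source table (0.35) does not
  equal composition × digestibility (0.50 × 65.25 % = 0.33), so the TDN
  and DE that the package computes for blood meal from the composition and
  coefficient tables differ from the printed 71.46 / 3151 by 0.04 pp /
  2.2 kcal/kg. No basis conversion reconciles it (a DM-basis EE matches
  0.35 but breaks the CP column). The package reports its own arithmetic.
* The published intake table is internally inconsistent (its %LW and
  g/kg$W^{0.75}$ columns imply different intakes); the package computes
  self-consistent intake metrics and does not attempt to reproduce those
  numbers.
* Apparent digestibility confounds endogenous losses; marker-based and
  true (ileal) digestibility, nitrogen balance, and NRC-style net-energy
  systems are out of scope.

## Problem sizes used in the test suite

The suite validates the inversion identity on 100 random truth
configurations, noise calibration on 500 simulated trials of the canonical
9 × 7 design, the letter display against an exhaustive-span oracle on
1,000 random 2–6-group instances, and the published daily-gain pattern on
200 replicates at the published means and sds — sizes at which the
Monte-Carlo error of each check is far below its decision threshold.
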