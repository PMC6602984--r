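---
title: "Attributing disease burden to food-group intake: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing disease burden to food-group intake: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodcra)
```

## The problem

How much of the national burden of coronary heart disease (CHD), stroke,
type 2 diabetes (T2D) and colorectal cancer (CRC) could be avoided if a
population shifted its intake of major food groups — whole grains, nuts,
fruit, vegetables, fish, legumes, dairy, eggs, refined grains, red meat,
processed meat, sugar-sweetened beverages — to the level associated with
the lowest risk? `foodcra` implements the comparative risk assessment (CRA)
answer to that question for non-linear diet–disease relationships, from
four separately derived inputs:

1. **National intake distributions**: per-country percentile summaries of
   individual intake (g/day) from food-consumption surveys.
2. **Dose–response relative-risk curves**: tabulated RR(x) with a 95% CI
   band per food group and disease, as produced by non-linear
   dose–response meta-analysis of prospective cohorts.
3. **Optimal intakes (TMRELs)**: theoretical minimum risk exposure levels
   derived from those curves.
4. **National disease burden**: DALYs (mean and 95% uncertainty interval)
   per country and disease.

Real inputs of this kind come from consumption databases, meta-analyses
and burden-of-disease studies that cannot be bundled; the package
therefore ships a synthetic-data generator that emulates their
statistical structure with known ground truth, so that every stage is
testable end to end.

## Exposure model

Each country × food intake distribution $E(x)$ is a two-parameter gamma
density fitted to the reported percentiles (defaults: 2.5, 5, 10, 25, 50,
75, 90, 95, 97.5%). The fit minimises the unweighted sum of squared
differences between observed and fitted percentiles with the Nelder–Mead
simplex, run on $(\log k, \log\theta)$ so positivity needs no
constraints. Starting values come from the median and the top percentile
(a lognormal-exact shape heuristic, then the scale set so the median
matches); a restart from $(k=1, \theta=\mathrm{median})$ guards against
non-convergence, which is flagged on the result rather than raised. The
fit is scale-equivariant: multiplying all percentiles by $c$ multiplies
the scale by $c$ and leaves the shape alone.

The gamma is fitted as reported — no measurement-error deconvolution or
usual-intake modelling. Survey summaries based on a few recording days
are wider than usual-intake distributions; that width is part of the
evidence this model consumes, not something it corrects.

```{r fit-example}
probs <- default_percentile_probs()
fit <- fit_gamma_percentiles(qgamma(probs, shape = 2, scale = 50), probs)
c(shape = fit$shape, scale = fit$scale, loss = fit$fit_loss)
```

## Dose–response curves

Curves enter as dose grids with point RR and CI bounds. Evaluation is
linear interpolation; beyond the maximum observed dose the RR is held
constant (clamped) rather than extrapolated — the conservative convention
when a meta-analytic curve runs out of evidence. An association is
**significant** when its CI band strictly excludes 1 at some non-reference
dose; a band that exactly touches 1 (RR 1.06, 95% CI 1.00–1.13) is
treated as non-significant, which is why borderline associations drop out
of the significant-only scenarios. Direction is classified from grid
monotonicity with a $10^{-6}$ tolerance; a perfectly flat curve ties to
"inverse", a label with no numerical consequence since its attributable
fraction is zero.

## TMRELs

**Disease-specific rule.** For a monotonically decreasing (protective)
association the TMREL is the cross-country mean of the P97.5 intake —
the observed maximum consumption, since the curve never turns upward
within the evidence range. For every other shape the TMREL is the
minimum-risk dose from one-dimensional bounded optimization (Brent),
guarded by a 0.5 g/day grid scan and a local polish because tabulated
piecewise-linear curves can have flat stretches and multiple local
minima. A monotone-increasing (harmful) association optimises to zero
intake. The cross-country P97.5 mean is unweighted, and survey-weighted
percentiles are not modelled.

**Single cross-disease rule.** One TMREL per food group, chosen to
maximise the total attributable DALYs summed over diseases and countries,
$\sum_d \sum_c \mathrm{PAF}(c,d,t)\,\mathrm{DALY}(c,d)$ — the maximum
possible health gain from a single recommended intake. Because the
denominator integral $E[RR(X)]$ does not involve $t$, the objective
reduces to minimising $\sum_d w_d RR_d(t)$ with fixed weights
$w_d = \sum_c \mathrm{DALY}(c,d)/E[RR_d(X_c)]$, which makes the bounded
search essentially free. The search interval is
$[0, \min(D_{\max}, \overline{P97.5})]$: like the disease-specific rule,
the single counterfactual is capped at observed maximum consumption. This
cap is what makes a food with only monotone-protective associations get
the same value in both modes, and it is required for the design ordering
that disease-specific TMRELs attribute at least as much burden as the
single TMREL. The objective uses DALY point means only — no Monte Carlo
inside the optimiser — so the TMREL is deterministic given its inputs.
When the significant-only filter is active the eligible curve set
shrinks, and the single TMREL is re-optimised on the survivors, so it can
genuinely move between scenarios C and D.

## Attributable fractions and burden

The population attributable fraction compares observed exposure with a
counterfactual population at the TMREL:

$$
\mathrm{PAF} \;=\;
\frac{\int E(x)RR(x)\,dx - \int E'(x)RR(x)\,dx}{\int E(x)RR(x)\,dx}
\;=\; 1 - \frac{RR(t)}{E[RR(X)]},
$$

the counterfactual $E'$ being a point mass at the TMREL $t$ (the standard
CRA counterfactual of shifting everyone to the optimum), which collapses
its integral to $RR(t)$. PAFs can be negative when observed intake sits
closer to the optimum than the counterfactual implies.

**Quadrature.** $E[RR(X)]$ is integrated over $[0, Q(0.9999)]$ of the
fitted gamma on 2001 equispaced doses augmented with the curve's knots.
On every resulting cell the interpolated RR is exactly linear,
$a + bx$, so the cell integral is evaluated in closed form from gamma
distribution functions ($\int x f_k = k\theta\,[F_{k+1}]$) rather than by
a sampled rule. Two practical consequences: the integral stays exact when
the fitted shape is below 1 and the density diverges at zero intake
(common for rarely-consumed foods such as nuts), and step-like tabulated
curves are handled without smearing. The 0.01% of exposure mass beyond
the upper limit contributes the clamped RR at the limit; truncation error
is below $10^{-4}$ because RR is bounded.

**Combination.** Food-group PAFs combine multiplicatively under
independence, $\mathrm{PAF}_{comb} = 1 - \prod_i (1 - \mathrm{PAF}_i)$.
Intercorrelation of food intakes is a recognised source of overestimation
that this model, like standard CRA practice, does not correct.

**Uncertainty.** Only DALY uncertainty is propagated: each national DALY
estimate gets a gamma uncertainty distribution whose mean equals the
point estimate exactly and whose 2.5/97.5% quantiles best match the
reported interval (one-dimensional least-squares in the shape; a
degenerate interval becomes a point mass). Attribution multiplies fixed
PAFs by 100,000 Monte Carlo draws (configurable) and reports the
2.5th/97.5th percentiles of the products. RR-curve and exposure
uncertainty are deliberately not propagated. Every country × disease cell
draws from its own RNG substream keyed by the *labels*, so results are
reproducible cell by cell and removing a country leaves all other draws
untouched.

## Scenarios and ranking

Four scenarios cross the TMREL mode with the association filter:
A (disease-specific, all), B (disease-specific, significant-only),
C (single, all), D (single, significant-only). Under the filter,
non-significant pairs contribute PAF 0. For synthetic worlds with
non-negative PAFs the design implies
$A \ge B$, $C \ge D$, $A \ge C$, $B \ge D$ in total attributable DALYs,
which the test suite asserts on randomly generated worlds.

Proportions divide attributable DALYs by the four-disease DALY total (not
all-cause burden); pooled proportions sum numerators and denominators
across countries, i.e. they are DALY-weighted. The health-impact ranking
averages each food's attributable DALYs (and proportion) unweighted over
the four scenarios and sorts descending, ties alphabetical.

## The synthetic world

`synthetic_world()` is first-class, tested code, not a fixture. Its
ground truth:

* **Exposures.** Per country × food, gamma parameters anchored to
  cross-country mean and P97.5 intakes typical of European surveys
  (e.g. vegetables 152/412 g/day, fish 26/131 g/day), with lognormal
  between-country variation (CV 0.15 on the mean, 0.05 on the
  P97.5/mean ratio). The shape is solved from the P97.5/mean ratio by a
  1-D root-find; that ratio peaks at ≈11.45 for a gamma, so heavier
  requested tails are capped — a pure gamma cannot carry them.
* **Surveys.** The world's (shape, scale) define the distribution of an
  individual's intake averaged over `survey_days` (default 3). Per-day
  intakes are iid gamma(shape/d, scale·d), so the d-day mean is
  *exactly* gamma(shape, scale): percentiles, medians and expected
  relative risks all have closed forms for the oracle tests, while the
  per-day distribution is √d wider in CV — the widening that few-day
  food records impose relative to usual intake. An optional
  never-consumer share adds a point mass at zero that the gamma exposure
  model deliberately does not represent, for studying that
  misspecification. National percentiles are unweighted.
* **Curves.** Four families — monotone decreasing/increasing
  (saturating exponential in dose), J/U-shaped (quadratic with interior
  minimum $d^\*$, included in the grid so the tabulated curve attains it
  exactly), and flat. CI bands are constructed to be consistent with the
  requested significance flag: significant bands hug the point curve and
  exclude 1 wherever the effect is non-null; non-significant bands cross
  1 at every non-reference dose. The default association map follows the
  qualitative epidemiology of the twelve groups: protective whole
  grains, vegetables, fruit, nuts, legumes, fish, dairy; harmful eggs
  (T2D), red and processed meat, sugar-sweetened beverages; refined
  grains carry non-significant harmful curves so the significant-only
  filter visibly bites.
* **Burden.** Per-country DALY means scale disease baselines
  (CHD 620k, stroke 310k, T2D 170k, CRC 140k DALYs/year — the order of
  magnitude of mid-size European countries) by a lognormal country-size
  factor; envelopes attach a symmetric relative interval.

What passing tests on this world do **not** show: robustness to real
surveys' weighting and non-gamma shapes, to correlated food intakes, to
RR-curve estimation error, or to DALY envelopes whose uncertainty is
asymmetric in ways a gamma cannot match. Those belong to the data, not
the machinery.

## Numerical choices and degenerate inputs

* Percentile fit: Nelder–Mead `reltol` $10^{-12}$, up to 2000 iterations,
  one restart; all-zero percentile sets are rejected as degenerate,
  non-convergence is flagged, never thrown.
* Monotonicity tolerance $10^{-6}$ on grid differences; curves failing
  strict monotone decrease go to the optimizer branch.
* 1-D optimization: Brent plus 0.5 g/day grid scan plus local polish;
  interior minima are recovered to well under 0.1 g/day on grids that
  contain them.
* Missing curves (no dose–response function available) contribute
  PAF 0 with a logged notice and are excluded from TMREL optimization.
* A flat curve has $E[RR] = 1$ exactly under the closed-form quadrature,
  so its PAF is exactly 0, not merely small.
* Combined PAF is computed before draw multiplication, so per-draw
  combined attribution is exactly $\mathrm{PAF}_{comb}\times$ draw and
  totals decompose exactly across countries per simulation.

## Problem sizes

The default test suite exercises compact worlds (2–4 countries, 2–4
foods) with 1000–2000 Monte Carlo draws; the end-to-end check runs the
full 16 × 12 × 4 study with 4000 survey participants per country and
10,000 draws, and verifies the scenario-A total against an
individual-level simulation from the world's true parameters (200,000
draws per cell) within 1%. The bundled analysis script uses the same
study at the method's native 100,000 draws. These sizes were chosen so
Monte Carlo error sits well below the tolerances being asserted.

## A worked run

```{r worked, eval = FALSE}
world <- synthetic_world(seed = 1)
survey <- gen_intake_survey(world, n_participants = 4000)
exposures <- fit_exposures(survey$summary)
curves <- build_curves(world)
dalys <- gen_daly_envelope(world, rel_ui_width = 0.1)

scenarios <- lapply(c("A", "B", "C", "D"), function(lb)
  run_scenario(lb, exposures, curves, dalys, n_sim = 1e5, seed = 1))
rank_food_groups(scenarios)
```

The same pipeline is available from a YAML config via `cra_run_config()`
(see `simulate_inputs()` for writing a ready-made config from a synthetic
world), and from the thin command-line wrapper in `inst/cli/cra-daly.R`.

## Known limitations

* Causal interpretation of PAFs inherits all confounding and
  measurement-error caveats of the underlying meta-analyses.
* Multiplicative combination assumes independent food effects.
* The exposure model has no point mass at zero and no usual-intake
  correction; both shift PAFs for rarely-consumed foods.
* TMREL optimization is per food; no joint optimization across foods.
* RR uncertainty is not propagated, so reported uncertainty intervals
  reflect DALY uncertainty only and are narrower than full-model
  uncertainty would be.
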