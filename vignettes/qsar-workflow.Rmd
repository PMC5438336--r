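---
title: "Methods: linear QSAR modelling with GFA selection and a leverage applicability domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear QSAR modelling with GFA selection and a leverage applicability domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarlm)
```

`qsarlm` packages the classical linear QSAR workflow — activity
conversion, descriptor selection, MLR fitting, validation, applicability
domain, screening — for the small-sample regime typical of published
kinase-inhibitor series: a few dozen compounds described by hundreds of
correlated topological descriptors. This vignette records the model, the
conventions and tunables, the design decisions taken where the
literature leaves the procedure open, and what the synthetic testbed
does and does not establish.

## Activity scale

Activities arrive as IC50 in micromolar and are modelled on the pIC50
scale. `ic50_to_pic50()` uses the molar convention, `pIC50 =
6 - log10(IC50_uM)`, so that 1 uM maps to 6. Reports sometimes write
"`-log IC50`" while actually tabulating the molar form: an inhibitor
series with IC50 between 1 nM and about 3 uM lands on a printed pIC50
range of roughly 5.5–9, which only the molar convention produces. The
literal `-log10(uM)` form is available via `molar = FALSE` for data
genuinely on that scale.

## Descriptor tables

`read_descriptors()` consumes the common PaDEL-style CSV: first column
the compound identifier, the rest numeric descriptors. At n ≈ 25 there
is no sensible imputation, so any column with a missing or unparseable
entry is dropped, as are constant columns (they carry no information and
break scaling-free diagnostics such as VIF); every drop is reported in a
warning. Descriptor values are consumed as-is — the package never
computes descriptors from structures, and models operate on raw
(uncentred, unscaled) descriptor values so fitted coefficients read
directly as published equations do.

## Descriptor selection: GFA with a lack-of-fit fitness

With hundreds of candidate descriptors and ~19 training compounds,
subset selection is the scientifically dangerous step. We use a genetic
function algorithm over *fixed-size* descriptor subsets (default k = 3,
following the rule of thumb of at least five compounds per descriptor;
`gfa_select()` warns when `n < 5k`). Variable-length genomes and spline
terms of classical GFA are deliberately out of scope: the target use
case is a plain interpretable linear equation.

The fitness is Friedman's lack-of-fit score

$$\mathrm{LOF} = \frac{\mathrm{SSE}/n}{\bigl(1 - \lambda\,(p + 1 + d\,p)/n\bigr)^2},$$

with smoothing parameter `d = 1` and `λ = 1` by default; the count
`p + 1` is the regression parameters including the intercept, and the
`d·p` term charges extra for each basis function, so LOF penalises model
size relative to the sample. The GA itself uses operators chosen for
simplicity and strict seed-determinism: uniform random initial
k-subsets, size-2 tournament selection, uniform-exchange crossover
(probability 1) with duplicate genes repaired by random replacement,
single-gene mutation (probability 0.5) that swaps one member for a
random non-member, elitism of 1, and termination after 200 generations
or 30 without improvement. Population size (100) and generation count
are search budget, not science; with elitism the best LOF is
non-increasing by construction, which the tests assert.

Because the GA is a heuristic, the package also ships
`exhaustive_subset()`, a full enumeration of all `choose(p, k)` subsets
(refused above 10^6) with ties broken lexicographically by descriptor
name. It is the oracle the GA is tested against: on 20-descriptor
problems with a planted signal, the GA matches the enumeration optimum
on ≥ 90 % of seeds, and in practice on all of them.

## The fitted model object

`fit_mlr()` / `qsar_mlr()` return a single `qsar_mlr` object holding the
equation, OLS statistics, VIF table, leave-one-out Q², and the
applicability-domain context, with the usual `print`, `summary`, `coef`,
`predict`, `residuals`, `plot` (Williams plot) and `simulate` methods.
Conventions worth stating:

* **MSE.** Published QSAR tables rarely say whether MSE is `SSE/n` or
  `SSE/(n-k-1)`; the two differ by ~20 % at n = 19, k = 3. We report
  `SSE/n` as `mse` (primary) and the unbiased `SSE/(n-k-1)` as `mse_df`,
  and the summary prints both.
* **F and p.** `F = (R²/k) / ((1-R²)/(n-k-1))` with the p-value from the
  F(k, n-k-1) distribution; tests verify both against `summary.lm()` to
  1e-8.
* **Rank.** A rank-deficient design is an error naming the collinear
  columns, not a silent drop.
* **VIF.** `VIF_j = 1/(1 - R_j²)` from regressing descriptor j on the
  others; verdicts follow the conventional bands — acceptable in [1, 4],
  caution in (4, 5], unstable above 5.

## Validation

* **Internal.** `loo_q2()` computes `Q² = 1 - PRESS/SST` (SST about the
  full-sample mean). The default path uses the exact OLS shortcut
  `e_(i) = e_i/(1 - h_ii)`; a brute-force refit path exists purely so the
  shortcut can be verified (they agree to 1e-10 on random instances). A
  leverage of exactly 1 makes the deleted residual undefined and is an
  error. The acceptance rule is strict: `Q² > 0.5` passes, 0.5 exactly
  does not.
* **External.** `external_r2()` reports the squared Pearson correlation
  of observed vs predicted as the primary `R²test`, because the
  convention behind published values is often unrecoverable; the
  `1 - SSE/SST` form is reported alongside. The Pearson form is
  shift-invariant (a uniformly biased model can still score 1), the SS
  form is not — exposing both avoids silently comparing different
  statistics. With only ~6 test compounds either number is volatile, a
  limitation of the design being emulated, not of the implementation.
* **Y-randomization.** `y_randomize()` shuffles the response
  (Fisher–Yates via `sample()` under the run seed), refits, and records
  R² and Q² per iteration (default 10, matching common reporting). By
  default the model's own descriptor subset is refitted — the cheaper
  protocol that mirrors published randomization tables; `reselect =
  TRUE` reruns the GFA per shuffle, the stricter variant. The chance
  correlation flag raises if any shuffled R² reaches the original or the
  mean shuffled R² exceeds 0.5. An explicit `permutations` argument
  makes the test reproducible-by-construction (the identity permutation
  must return the original R² exactly).

## Applicability domain

Leverage of a (possibly new) compound is
`h = x'(X'X)^{-1}x` on the intercept-augmented design, computed from the
QR decomposition of the training design (and verified in tests against
the explicit inverse to 1e-10). The threshold is `h* = 3(k+1)/n` — for
k = 3 descriptors and n = 19 training compounds, `h* = 0.6316`, the 0.63
of standard Williams plots. Classification: training compounds are
leverage outliers when `h > h*` and response outliers when their
standardized residual exceeds ±2; both thresholds are strict, so a
compound exactly at the boundary is in-domain. Standardized residuals
are raw residuals over `sqrt(SSE/(n-k-1))` — the common Williams-plot
convention; leverage-corrected (studentized) residuals are reported as
an extra column but deliberately not used for classification. Test and
screening compounds have no training residual and are classified by
leverage only. `write_williams()`/`read_williams()` round-trip the plot
data with `h*` and the band limits in comment headers.

## Screening

`screen_candidates()` marks a candidate's prediction reliable exactly
when `h ≤ h*`. Candidates may carry descriptor columns (predictions and
leverages computed from the fit) or — as with literature candidate sets
whose descriptor values were never published — precomputed leverages and
predictions that are passed through unchanged. The shipped PIM candidate
table is of the second kind: descriptor values for those twelve PubChem
analogues are not public, so the package replicates the published
reliability flags from the published leverages and never pretends to
recompute the predictions. Lipinski filtering collects violations of
MW > 500, LogP > 5, HBD > 5, HBA > 10 with *inclusive* boundaries
(a value exactly at a cutoff passes, per the rule's original
violations-above-threshold reading); Veber flags (PSA > 140 Å²,
rotatable bonds > 10) are reported separately and do not affect the
Lipinski verdict.

## Reference fixtures

Two published three-descriptor PIM-kinase equations ship as
`qsar_equation` objects for worked examples and prediction-only use. One
printed coefficient (GATS8v in the PIM1 equation, printed as 1072) is
stored as 1.072: GATS8v is an order-one Geary autocorrelation and the
printed magnitude would push predictions three orders off the pIC50
scale; the original printed value is retained in the fixture metadata.
The 25-compound activity listing is shipped as opaque worked-example
numbers: its single observed column cannot be attributed to one assay
with certainty, so nothing asserts that those values reproduce the
equations' statistics.

## Synthetic testbed

Because the descriptor values behind the motivating study were never
published, every statistical claim is exercised on synthetic data whose
generating process matches what the analysis assumes:

* 25 compounds, 19/6 train/test split, 3 true descriptors — the scale of
  the emulated design; 200 descriptors by default (60 in the pinned
  fixture, for compactness).
* descriptors standard normal in blocks of 5 sharing a latent factor,
  within-block correlation 0.5, independence across blocks; the three
  true descriptors sit in distinct blocks so each carries correlated
  decoys — the failure mode GFA and VIF must handle;
* `pic50 = 7 + 1.5·x₁ - 1.2·x₂ + 0.8·x₃ + ε`, `ε ~ N(0, 0.9²)`, putting
  the population training R² near 0.84 so that small-sample fits land in
  the 0.6–0.95 band typical of published small-n QSAR models.

One dataset (generator seed 20170519, 60 descriptors) is frozen as CSV
under `inst/extdata/` and exposed as `study_fixture()`, so examples and
checks do not move if the generator evolves; its files are labelled
synthetic. What passing on this testbed shows: correct arithmetic,
selection consistency against enumeration, honest behaviour of Q²,
Y-randomization and the applicability domain under a known truth. What
it does not show: performance on real descriptor distributions (heavy
tails, discreteness, block structures far messier than exchangeable
blocks), nor robustness to activity measurement error correlated with
structure — real PaDEL output is not being simulated, only the
statistical skeleton the methods assume.

## Problem sizes and determinism

All randomness flows through explicit seeds (`synth_spec(seed=)`,
`gfa_control(seed=)`, `y_randomize(seed=)`, the pipeline's global seed
from which stage seeds derive), and seeded calls restore the caller's
RNG stream. The shipped checks use the sizes of the emulated design —
n = 25, p = 10–60 for selection tests (p = 20 for the 20-replicate
GA-vs-enumeration comparison), 50 random instances at n = 19, k = 3 for
the cross-validation identities — sizes at which the full enumeration
oracle stays exact and the whole suite runs in seconds. `run_pipeline()`
writes every artifact plus a manifest (seed, config hash) and is
byte-identical under a repeated config + seed.

## Known limitations

* Fixed-size subsets only; no spline/nonlinear GFA terms and no
  regularised alternatives — by design, to keep the model an equation a
  chemist can read.
* Golbraikh–Tropsha slope/intercept criteria and Roy's r²m metrics are
  not implemented; Q², external R², VIF and Y-randomization form the
  validation battery.
* The applicability domain is the leverage/Williams definition only; no
  distance-to-model or density-based alternatives.
* With 6 test compounds the external R² has large variance; treat it as
  a sanity check, not a precise estimate.
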