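---
title: "Edge co-fluctuation dynamics: models and methods"
author: "coflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge co-fluctuation dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coflux)
```

## The measurement model

Edge-centric functional connectivity unwraps an ordinary correlation in
time. Given a parcellated BOLD recording — a timepoints × nodes matrix with
repetition time TR — each node signal is z-scored (sample-SD convention,
applied once over the whole recording; runs are concatenated *before*
z-scoring, so run-specific offsets are removed jointly). For every node pair
$(i, j)$, $i < j$, the *edge time series* is the per-timepoint product

$$e_{ij}(t) = z_i(t)\, z_j(t),$$

whose time average is (up to the $(T-1)/T$ factor of the SD convention) the
Pearson correlation $r_{ij}$: the edge time series shows *when* the
correlation is earned. With $n$ nodes there are $n(n-1)/2$ edges — 35,778
for a 268-node parcellation. Correlating edge time series with one another
gives the eFC matrix (`computeEFC`); collapsing them per timepoint gives the
root-sum-square amplitude

$$\mathrm{RSS}(t) = \sqrt{\sum_{i<j} \big(z_i(t)\,z_j(t)\big)^2},$$

a single whole-brain (or subnetwork) co-fluctuation trace. `computeRSS`
uses the algebraic identity
$2\,\mathrm{RSS}(t)^2 = \big(\sum_i z_i^2\big)^2 - \sum_i z_i^4$, which
avoids materializing the edge matrix (the explicit edge path is retained
behind `explicitEdges = TRUE` and the two are required to agree to 1e-10 in
the test suite). A node subset (e.g. a 51-node default-mode-network list)
restricts the sum to within-subset pairs.

## Troughs, peaks, and magnitude criteria

Network reconfiguration events are read off the RSS trace. A *trough* is a
strict local minimum (ties disqualify); the *peak* between two consecutive
troughs is the maximum of the open interval, earliest index on ties. The
first and last samples are never extrema, and partial intervals at the ends
contribute neither peaks nor durations. Per subject we summarize the mean
trough-to-trough duration (index difference × TR, in seconds) and the mean
peak height (the absolute RSS value at the peak, not a prominence).

Shallow local minima are pruned by a percent-magnitude criterion
$\theta \in \{0.01, 0.02, 0.05\}$: a trough must be at least $\theta$ lower
than its *reference values*. Because "reference" is genuinely ambiguous, the
package implements both readings as first-class modes, always reported with
the mode name:

* **adjacent-sample** (default): keep trough $t$ iff
  $x_t \le (1-\theta)\,x_{t-1}$ and $x_t \le (1-\theta)\,x_{t+1}$. A single
  pass; trough sets are nested across increasing $\theta$.
* **adjacent-peak**: on the alternating trough/peak sequence, repeatedly
  remove the shallowest trough that is less than $\theta$ below the lower
  of its flanking peaks, merging its two segments (the higher peak
  survives). Removals only raise remaining flanking peaks, so valid troughs
  stay valid and the procedure terminates at a maximum-cardinality valid
  set; the test suite checks this against an exhaustive subset-enumeration
  oracle. The maximum set need not be unique (symmetric configurations can
  admit several); the implementation's deterministic removal order picks
  one, and the oracle check asserts validity and maximal size rather than
  uniqueness.

The percent comparison is boundary-inclusive and evaluated with a 1e-12
relative tolerance, so a value sitting exactly on the boundary in decimal
(2.97 against $0.99 \times 3$) is kept despite the binary representation of
$1-\theta$. Both criteria are scale-free: rescaling the RSS trace by any
positive constant leaves the extrema unchanged. No smoothing is applied to
the RSS trace before detection.

Subjects with fewer than two troughs under a strict criterion have
undefined means; they are flagged (`analyzable = FALSE`) and counted in the
pipeline manifest, never silently dropped.

## Group comparison

Group differences in the per-subject summaries are tested with an ordinary
least-squares model, one outcome per fit:

$$y = \beta_0 + \beta_g\,\mathbb{1}[\text{group} = B] + \beta_a\,\text{age}
      + \beta_v\,\text{volume} + \varepsilon,$$

with the group term assessed by the partial F test (numerator df 1,
denominator df $n-4$); this F equals the squared t of the group contrast,
an identity asserted on every fit. Covariate-adjusted group means are model
predictions at grand-mean age and brain volume, with standard errors from
the coefficient covariance of the prediction contrast — the usual estimated
marginal means, cross-checked against **emmeans** in the tests. The
reference level is the alphabetically first group; adjusted means are
invariant to that choice and to covariate rescaling, both tested. No
multiple-testing correction is applied across criteria or outcomes (each
combination is reported as its own fit), and family structure among
subjects is not modelled — both documented limitations shared with the
analysis style the package implements.

Degenerate designs are handled explicitly: a constant covariate or single
group level is an error; an outcome with zero residual variance yields
F = 0 when the group adds nothing, and a floored residual sum of squares
(rather than an infinite statistic) in the perfectly separated case.

## The synthetic cohort generator

The generator exists so every downstream stage can be validated without any
neuroimaging data. Per subject it draws:

1. a hidden regime path $s_t$: a Markov chain over $K$ covariance states
   (uniform start; per-timepoint stay probability $p_g$ for the subject's
   group; switches go to a uniformly random different state);
2. latent node noise $\varepsilon_t$, white across nodes, temporally
   smoothed by a unit-variance Gaussian FIR kernel (SD `smoothSd` samples);
3. the observed series $y_t = L_{s_t}^\top \varepsilon_t$ with
   $\Sigma_k = L_k^\top L_k$, so the marginal covariance within a regime is
   exactly $\Sigma_k$ (verified by a Frobenius-norm recovery test at
   $T = 5000$);

plus age and total brain volume from per-group normals, independent of the
series given group — so covariate adjustment can be probed separately from
dynamics.

Two modelling choices deserve explanation, because simpler variants
provably carry no signal:

* **Regimes must differ in co-fluctuation strength.** The default states
  come from a block recipe — state $k$ raises the within-block correlation
  of block $k$ to $r_k$ — with $r = (0.05, 0.60)$. If all states shared one
  $r$, they would be exchangeable, the RSS amplitude distribution would be
  identical in every regime, and the switching rate could not influence any
  RSS statistic. Distinct $r_k$ make high- and low-co-fluctuation regimes,
  so regime switches appear as excursions of the RSS trace.
* **The latent noise must be smooth at the sample scale.** Temporally white
  draws (and equally AR(1) noise, which is rough at lag 1) put a strict
  local minimum at roughly every third or fourth sample regardless of the
  regime path, burying regime structure under sampling noise. Real
  resting-state BOLD is bandpass-filtered and hemodynamically smoothed, so
  the default kernel SD of 2 samples (1.44 s at TR 0.72 s) is both the
  realistic choice and the one that lets regime persistence reach the
  trough statistics. `smoothSd = 0` remains available for covariance and
  calibration tests that want white noise.

Default cohort parameters: TR 0.72 s; 1200 timepoints; two groups of 30
with stay probabilities 0.97 (slow-switching) and 0.93 (fast-switching);
ages 27.9 (SD 2.4) vs 29.5 (SD 3.5) years; brain volumes 1215.13 (SD 44.89)
vs 1063.80 (SD 36.27) ml. The covariate SDs deserve a note: in the
demographic table these defaults echo, the age dispersions are only
plausible as standard errors (converted here via $\mathrm{SD} =
\mathrm{SE}\sqrt{n}$ at the reported group sizes) while the volume
dispersions are only plausible as standard deviations (used as printed) —
an SE reading would imply a 977 ml volume SD, which is anatomically
impossible. The node count defaults to 20 to keep examples fast; the
machinery supports 268-node cohorts, at which scale the end-to-end
validation below is run with 100 nodes as a compromise between realism and
runtime.

What the generator does *not* emulate: hemodynamic response functions,
scanner noise and drift, head motion, spatial autocorrelation beyond the
block structure, and the heavy-tailed segment structure of real regime
dynamics. Passing tests therefore demonstrate that the pipeline measures
what it claims on data whose ground truth is known — not that any particular
empirical group difference is real.

## Validation summary

The test suite and `scripts/acceptance.R` recompute, among others:

* 35,778 edges for 268 nodes; shortcut vs explicit RSS to 1e-10;
* base trough detection against an exhaustive neighbour scan (200 random
  series) and adjacent-peak pruning against exhaustive subset enumeration;
* per-subject monotonicity over $\theta \in \{0, 0.01, 0.02, 0.05\}$:
  trough counts non-increasing, mean durations non-decreasing;
* calibration: on 500 replicate null cohorts (identical dynamics,
  group-shifted covariates; 16 nodes × 300 timepoints × 12 + 12 subjects),
  the rejection rate at $\alpha = 0.05$ stays inside the exact binomial 95%
  band;
* end-to-end recovery: on 20 replicate cohorts (100 nodes × 1200
  timepoints, 30 + 30 subjects, stay 0.97 vs 0.93), the slower-switching
  group shows the longer covariate-adjusted mean trough duration with
  p < 0.05 in at least 80% of replicates.

The problem sizes above are the package's chosen validation conditions;
they are deliberately smaller than a full 268-node, 1024-subject study
while preserving every qualitative property being checked.

## A worked example

```{r example, fig.width = 7, fig.height = 3.5}
spec <- syntheticSpec(groupSizes = c(A = 10, B = 10), nTimepoints = 600)
cohort <- simulateCohort(spec, seed = 42)

z <- zscoreNodes(cohortSubjects(cohort)[[1]]@series)
rss <- computeRSS(z)
ext <- detectExtrema(rss, troughCriterion(0.02))
plotRss(rss, ext)

summaries <- summarizeCohort(cohort,
                             lapply(c(0, 0.02), troughCriterion))
results <- cohortAncova(summaries, cohortTable(cohort))
results[, c("theta", "outcome", "f", "p", "adj_mean_A", "adj_mean_B")]
```

## Known limitations

* The two percent-criterion modes are both reported because the underlying
  rule is ambiguous; results should always state the mode.
* Endpoint convention: partial intervals at the series ends are discarded;
  an analysis that retained them would shift duration means slightly.
* The ANCOVA assumes independent subjects and homoscedastic residuals;
  twin/family structure, if present, is not modelled.
* The generator's Markov regimes are a deliberately minimal stand-in for
  whatever generative process distinguishes real groups; recovery of the
  switching-rate effect here is evidence about the pipeline, not about
  mechanism in any population.
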