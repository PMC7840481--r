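---
title: "Methods: relating dietary nutrient intake to circulating miRNA expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relating dietary nutrient intake to circulating miRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrimir)
```

## The problem

Circulating microRNAs (miRNAs) in plasma respond to physiological
state, and diet is one of the strongest chronic exposures shaping that
state. nutrimir implements an observational analysis design for
cohorts in which (i) plasma miRNA expression has been profiled by
small RNA sequencing and (ii) habitual diet has been recorded with a
food-frequency questionnaire (FFQ): estimate each subject's daily
intake of a panel of dietary natural compounds (NCs — lipids,
micro-elements and vitamins), then screen for monotone associations
between intake and miRNA expression that are reproducible across
dietary groups (omnivore, vegetarian, vegan) and robust to the obvious
demographic confounders.

The pipeline is a funnel:

1. **Intake estimation** — FFQ responses × food-composition table →
   daily intakes, energy-normalized.
2. **Count normalization** — median-of-ratios size factors;
   detectability and analysis-set filters.
3. **Correlation screen** — diet-stratified Spearman correlations
   with a sign-coherence rule.
4. **Model confirmation** — covariate-adjusted linear models with a
   dominance criterion for the nutrient term.
5. **Differential expression** — negative-binomial likelihood-ratio
   tests between high- and low-intake subjects.
6. **Target enrichment** — logistic-regression gene-set analysis of
   the miRNAs' target genes.
7. **Network export** — the bipartite miRNA–NC association graph.

Every stage is exercised end to end on synthetic cohorts with planted,
calibrated effects, so the package's operating characteristics
(calibration under the null, sensitivity to planted signal) are
measured rather than assumed.

## Intake estimation

For subject $s$ and nutrient $k$, the raw daily intake is

$$\mathrm{raw}_k(s) \;=\; \sum_{\text{items } i}
  f_{si}\, g_{si}\, \frac{a_{ik}}{100},$$

where $f_{si}$ is consumption frequency (times/day), $g_{si}$ the
portion (grams) and $a_{ik}$ the nutrient amount per 100 g edible
portion. Daily energy (kcal) is computed identically from the
composition table's energy column.

**Energy normalization.** Absolute intakes scale with how much a
person eats; associations with absolute intake partly reflect total
energy. The default is the *density* method,
$\mathrm{norm}_k = \mathrm{raw}_k / E \times 1000$ (units per
1,000 kcal), the simplest reading of "kcal-normalized". The *residual*
method (per-nutrient regression of raw intake on energy, residuals
recentred at the mean) is available via
`kcal_normalize(method = "residual")`; which of the two a given study
used is often unstated, so both are provided and the choice is an
explicit argument. Subjects with zero recorded energy cannot be
normalized and are excluded from the normalized table with a warning.

The packaged 23-NC vocabulary (`nc_compounds()`) spans seven
lipid-related compounds, six micro-elements and ten vitamin-related
compounds; missing composition values are zeroed with a logged count
(strict mode available), matching common food-table practice.

## Count normalization and filters

Size factors use the median-of-ratios estimator: over miRNAs with
strictly positive counts in all samples, a sample's factor is the
median ratio of its count to the miRNA's geometric mean. miRNAs with
any zero are excluded from the reference set because their log-scale
geometric mean is undefined; when no all-positive miRNA exists a
"poscounts"-style pseudo-reference is available behind an explicit
option. Medians of even-length vectors are the arithmetic midpoint of
the two central order statistics — stated explicitly because the
15-read detectability cutoff sits near typical plasma medians, and
because log-scale median interpolation (the geometric midpoint used by
some implementations) differs in the last decimal places.

Two filters are exposed separately:

* **detectability** — normalized count strictly greater than 15 in a
  sample;
* **analysis set** — median normalized count strictly greater than 15
  within at least one dietary group.

The group-median rule defines the correlation screen's input; the
per-sample rule is reported alongside. Size factors are computed on
all samples jointly by default (per-group computation is possible by
subsetting the matrix first).

## The correlation screen

Spearman's $\rho$ is computed as the Pearson correlation of mid-ranked
values, with the two-sided p-value from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom at all
sample sizes — the behaviour of the widely used `rcorr`-style
implementation. No exact permutation null is used by default; the
approximation's adequacy at the per-group $n$ of interest (40) is
checked empirically in the test suite (Kolmogorov–Smirnov uniformity
of null p-values).

For each (analysis-set miRNA, NC) pair, correlations are computed
separately per dietary group, and the pair is flagged:

* **coherent** when all per-group $\rho$ share one sign — a zero
  $\rho$ in any group breaks coherence, since it is neither positive
  nor negative;
* **significant** when it is coherent, reaches $p < 0.05$ in at least
  `min_sig_groups` groups, and $|\bar\rho| > 0.3$ where $\bar\rho$ is
  the arithmetic mean of the per-group coefficients.

Two screening conventions are genuinely ambiguous in this design and
are therefore configurable with documented defaults:
`min_sig_groups = 2` (the two-group requirement governs the headline
pair counts in the target analysis; a one-group variant exists), and
the 0.3 threshold applied to the *average* $\rho$ rather than to each
group's $\rho$ (per-group variant by `rho_on = "per_group"`). Pairs
with a constant expression or intake vector have undefined $\rho$ and
are dropped and logged in the `dropped_pairs` attribute, so the tested
count is always the full analysis-set × NC grid minus explicit drops.

**Trend classification.** Among significant pairs, $|\rho|$ strictly
increasing along omnivore → vegetarian → vegan is `increasing`,
strictly decreasing is `decreasing`, anything else (any tie) is
`none`. Strictness makes the classification invariant to which group
is used as anchor and keeps ties out of both classes.

No multiple-testing correction is applied at the screen stage — a
deliberate mirror of the screening design this package implements,
documented here as a caveat. The compound filter (coherence + two
groups + average-$\rho$ threshold) is itself strongly conservative:
its measured false-positive rate on null cohorts is below 0.5%
per pair (see the acceptance tests).

## Confirmatory models

Each screened pair is re-examined in a Gaussian-identity linear model
(the default family of R's `glm`) pooled across all subjects:

$$\log_2(\mathrm{norm}+1) \sim \mathrm{age} + \mathrm{sex} +
\mathrm{BMI} + \mathrm{intake}.$$

The log2 transform stabilizes the variance of normalized counts; a
raw-scale option is retained. The overall model is tested against the
intercept-only null by an F-test; the nutrient *dominates* when the
model is significant, the nutrient's t-test p-value is below 0.05, and
it is strictly smaller than each of the age, sex and BMI p-values
(ties are conservatively not dominant). Pooling without a diet-group
term follows the covariate list of the design being implemented; a
diet-adjusted variant amounts to adding the factor to the model and is
left to the user. Constant predictor columns are rejected by name
rather than silently dropped.

## Differential expression

For a chosen nutrient, subjects are split at the median intake —
strictly above the median is "high", ties at the median go to "low"
(deterministic and documented). Each miRNA's raw counts are then
modelled by nested negative-binomial regressions with log link and
log-size-factor offset:

* full: age + sex + BMI + diet group + intake group;
* reduced: the same without the intake group.

The dispersion is estimated by maximum likelihood on the full model
(via `MASS::glm.nb`) and shared by both fits; the statistic
$2(\ell_\mathrm{full} - \ell_\mathrm{reduced})$ is referred to
$\chi^2_1$, and $\log_2\mathrm{FC}$ is the intake-group coefficient
divided by $\ln 2$. This is deliberately a *simplified* NB-LRT — one
MLE dispersion per miRNA, no empirical-Bayes shrinkage, no outlier
replacement — so its behaviour is fully testable by calibration
properties (null rejection rate, fold-change recovery, label-swap
antisymmetry, Poisson agreement at vanishing dispersion) rather than
by parity with any particular published tool. The commonly seen
"Log-Rank Test (LRT)" label for this procedure is a misnomer: the
log-rank test is a survival-analysis statistic; what is computed here
(and by the tools that use the acronym) is a likelihood-ratio test.

A miRNA is *expressed* when its median normalized count exceeds 15 in
at least one intake group, and *significant* when its raw p < 0.05 and
it passes the expressed flag; Benjamini–Hochberg adjustment across
tested miRNAs is reported per nutrient. Non-convergent fits are
flagged untested with the reason, never silently zeroed.

## Target enrichment

DE evidence is propagated to genes through a miRNA→target annotation.
Each miRNA contributes the signed weight

$$w = -\operatorname{sign}(\log_2\mathrm{FC})\,(-\log_{10} p_\mathrm{adj}),$$

with the sign flipped because an up-regulated miRNA represses its
targets; a gene's score is the sum over miRNAs targeting it. This
aggregation formula is this package's own documented definition (the
corresponding step in published enrichment tools is not always
specified precisely); it is deliberately simple, linear and testable.
Zero p-values are capped at the machine minimum with a warning; when
planted effects produce astronomically small p-values the examples
floor $p_\mathrm{adj}$ at $10^{-5}$ so weights stay on a conventional
scale — worth knowing because the retention filter below contains a
scale-dependent coefficient threshold.

Enrichment per gene set is a logistic regression of membership (over
the scored-gene universe) on the gene score; the slope and its Wald
p-value are reported, p-values are BH-adjusted across sets, and a set
is *retained* when adjusted p < 0.05, |slope| > 0.5 and at least two
scored target genes fall in the set. The analysis is run separately on
miRNAs positively and negatively associated with the nutrient
(`enrich_targets(direction =)`). Under perfect separation the fit
falls back to a lightly ridge-penalized logistic model
($\lambda = 10^{-3}$ on the slope) and is flagged `penalized`.

## Network export

Significant pairs form a bipartite graph: miRNA and NC nodes (NCs
carry their class), node degree as a size attribute, and per-edge
average $\rho$ (colour), $|\bar\rho|$ (width), trend, and a
`glm_confirmed` flag separating solid from dashed edges. Source
descriptions of this convention disagree internally about whether
dashed marks the GLM-confirmed or the unconfirmed edges; nutrimir
stores the boolean (`glm_confirmed`) so any renderer can choose, and
its own documentation treats *solid = confirmed*. Output is GraphML
(attribute-rich, Cytoscape-loadable) plus paired node/edge TSVs;
round-tripping preserves all attributes.

## The synthetic cohort generator

`generate_cohort()` emulates the target study design: three equal diet
groups (default 40 subjects each, 120 total), ~60% women, age
truncated-normal (45, 12) on [18, 80], BMI normal around 23 kg/m²
with a +1.5 shift in omnivores (mirroring the higher BMI typically
observed in that group), WHO BMI classes (the printed 25–26 gap is
assigned to overweight for continuity), log-normal nutrient intakes
with energy ~2,100 kcal/day, and miRNA counts drawn NB with variance
$\mu + \alpha\mu^2$, $\alpha = 0.2$ by default — typical plasma small
RNA-seq overdispersion — at library sizes uniform on
[5×10^5^, 1.5×10^6^] with strongly log-normal-skewed relative
abundances.

**Planting mechanism.** A planted miRNA–NC association couples the
miRNA's latent log-expression to the normal score of the nutrient's
intake rank through a Gaussian copula:
$\mathrm{latent} = w z + \sqrt{1-w^2}\,\varepsilon$. Because the
Spearman target is attenuated by NB counting noise, the mixing weight
$w$ is calibrated by bisection against a small seeded Monte Carlo
estimate of the realized rank correlation of depth-normalized counts
(25 inner replicates, 12 bisection steps); the calibrated $w$ and the
realized per-group $\rho$ are recorded in the ground-truth table.
Planted miRNAs are promoted to at least the 75th abundance percentile
so the association survives the detectability filters — a planted
effect on an undetectable miRNA would be vacuous. The latent signal
amplitude (`signal_sd`, default 1.2 on the natural-log scale) bounds
the achievable $|\rho|$ at roughly 0.9 under default dispersion.

**What the generator does not emulate:** real miRNA identities and
their correlation structure (miRNAs are independent given depth),
diet-group differences in intake distributions, FFQ reporting error,
batch effects, and zero-inflation beyond what NB sampling produces at
low means. Passing recovery tests on this generator therefore
demonstrates the pipeline's statistical behaviour under its stated
model, not robustness to every artefact of real plasma data.

`generate_ffq()` produces the questionnaire-level inputs (188 food
items by default, per-item frequencies and portions, a composition
table) so the intake-estimation path can be tested end to end against
the directly generated intake table.

## Numerical choices and degenerate inputs

* Even-length medians: arithmetic midpoint (size factors, median
  split, analysis-set filter).
* Median-split ties go to "low"; all-equal intakes are an error, not a
  silent empty group.
* $\rho = \pm 1$ maps to $p = 0$ (the t statistic diverges).
* Constant vectors: Spearman returns NA and the pair is dropped and
  logged; constant model columns are errors naming the column.
* NB fits: IRLS epsilon $10^{-10}$, 200 iterations; $\theta$ clamped
  to $[10^{-4}, 10^8]$ (the upper clamp is the Poisson limit);
  non-convergence is reported per miRNA, and the LRT statistic is
  clamped at 0 against tiny negative numerical residues.
* Logistic fits: epsilon $10^{-12}$; separation triggers the ridge
  fallback with an overflow-safe log-likelihood.
* All randomness flows from the single seed in `cohort_spec()`; fixed
  seed gives byte-identical outputs.

## Problem sizes used by the shipped checks

The test-suite simulations are sized to characterize behaviour at
study-realistic per-group $n$ while remaining quick to run: null
calibration uses one 200-miRNA × 10-NC cohort at 40 subjects per
group (2,000 screened pairs, 600 confirmatory models, ~420 NB tests);
screen recovery uses 50 replicate cohorts with four planted
$|\rho| = 0.5$ pairs each; fold-change recovery uses 200 replicate
NB draws at $n = 60 + 60$; the enumeration identity uses a full-size
382 × 23 fixture. `scripts/acceptance.R` re-runs the complete
pipeline on a 300-miRNA, 23-NC, 120-subject cohort with six planted
associations and writes the funnel counts and recovery measures as
JSON.

## Known limitations

* The screen's p-values are unadjusted by design; its error control
  comes from the compound filter, quantified only under the
  generator's model.
* The NB-LRT does not moderate dispersions; at very low counts its
  per-miRNA dispersion estimates are noisy and the test can be
  mildly anticonservative.
* The dominance criterion compares p-values, not effect sizes; it is
  a screening heuristic, not a causal claim.
* The enrichment coefficient threshold (|slope| > 0.5) is
  scale-dependent on the gene scores; interpret it only together with
  the score convention above.
* Energy normalization by density can itself induce spurious
  correlation when energy is measured with error; the residual method
  is provided for sensitivity analysis.
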