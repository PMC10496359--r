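---
title: "Methods: detecting selection on trait-trait coevolution"
author: "coevotest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting selection on trait-trait coevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevotest)
```

## The question and the model

Two traits can covary across diverging lineages for a mundane reason —
pleiotropic mutations push them around together — or for an interesting
one: selection favors particular combinations of their values. The
package separates the two by comparing, for every trait pair, the
correlation of mutational effects (`COR_M`, estimated across a panel of
mutant lines) with the correlation realized across lineages (`COR_E`,
estimated on phylogenetically independent contrasts so that shared
ancestry does not masquerade as correlation). Under neutrality the
divergence among lineages is an accumulation of the same mutational
input, so `COR_E` is centered on `COR_M`; a significant difference is
evidence of selection on the pair's coevolution.

The test statistic is the classical comparison of two Fisher-transformed
correlations,

$$Z = \frac{\operatorname{atanh}(COR_E) - \operatorname{atanh}(COR_M)}
{\sqrt{1/(n_E-3) + 1/(n_M-3)}},$$

with `n_E` = number of contrasts (tips − 1) and `n_M` = number of mutant
lines, two-sided normal p-values, and Benjamini–Hochberg adjustment
across the pair scan. Phenotypes are standardized as log-ratios to a
reference before anything else; this makes multiplicative measurement
scales comparable and brings trait distributions close to the normality
the z machinery assumes.

### Classification of significant pairs

Significant pairs are labeled by sign and magnitude: *strengthened*
(same sign and |COR_E| > |COR_M|, or opposite signs with only COR_E
distinguishable from zero), *weakened* (the mirror image), *reversed*
(opposite signs, both nonzero). The per-correlation "nonzero" test is the
Fisher-z test $\operatorname{atanh}(r)\sqrt{n-3}$ against the standard
normal at a nominal 0.05 — consistent with the z machinery of the main
test; the underlying studies do not name a specific test for this clause.
A fourth label, `unclassified`, catches significant pairs matching none
of the three rule sets (e.g. opposite signs with neither correlation
nonzero). Real datasets of the kind the method was developed on contain
none of these — the three categories sum exactly to the significant
total — but synthetic data can produce them, and silently forcing such a
pair into a named category would corrupt category counts.

## Conventions fixed where the literature leaves slack

**Contrasts.** Felsenstein pruning requires a binary rooted tree with
branch lengths. Multifurcations are resolved into zero-length binary
splits (the induced tip covariance is unchanged); zero-length branches
are then floored at `1e-8` of tree height so pruning weights stay finite.
Both adjustments are logged. Unrooted input is rejected.

**Covariance of contrasts.** Contrasts have expectation zero under
Brownian motion, so the evolutionary covariance is the mean cross-product
*through the origin* by default; `center = TRUE` provides the ordinary
sample-moment variant for sensitivity analysis. With 15 contrasts the two
differ by little, and the through-origin form uses the model's own
information.

**Missing phenotypes.** Mutant lines with any missing trait value are
dropped listwise (with a count), not pairwise. This keeps every pairwise
correlation on a single common sample so that one `n_M` enters the
z-test; pairwise-complete estimation would silently give each pair its
own sample size.

**Brownian scaling.** The neutral simulator assigns each branch one
multivariate-normal deviate with covariance `M`. Two scalings of the
increment are provided. The default, `standard`, multiplies the deviate
by $\sqrt{l}$ — canonical Brownian motion, under which the scaled
contrasts are i.i.d. draws from the mutational distribution and the
z-test is calibrated. The alternative `as_printed` multiplies by $l$,
a literal per-branch reading of "amount of evolution $= M_i\,l$" that
appears in the simulation recipes of this literature. The population
correlation of any pair is identical under both (the factor is common to
all traits), but on trees with unequal branch lengths the `as_printed`
increments violate the variance structure the contrast standardization
assumes: measured on a 16-tip pure-birth tree, the raw type-I rate of the
z-test at 0.05 is ≈ 0.11 under `as_printed` versus ≈ 0.04 under
`standard`. A null that is miscalibrated by a factor of two would
overstate selection, so the canonical scaling is the default and the
literal one remains available for comparison.

## The origin–fixation simulator

Two traits evolve as a population mean. Per unit time, a
Poisson(`mut_rate` = 1) number of mutations arises; each effect is a
bivariate normal draw from
$M = \begin{bmatrix} V_M & V_M\,COR_M \\ V_M\,COR_M & V_M \end{bmatrix}$.
Fitness is Gaussian, $f = e^{-D^2/2}$, with $D$ the Euclidean distance to
a point optimum or the orthogonal distance $|y - kx|/\sqrt{1+k^2}$ to a
fitness ridge $y = kx$. Each mutation is evaluated *sequentially*: the
selection coefficient is $s = f(\text{mean}+m)/f(\text{mean}) - 1$, the
fixation probability is Kimura's haploid
$P_f = (1-e^{-2s})/(1-e^{-2N_e s})$, and the effect joins the mean with
probability $\min(1, N_e P_f)$ before the next mutation of the same time
unit is evaluated (an accepted effect shifts the wild-type fitness for
its successors; a batch mode was considered and rejected as a poorer
reading of "each mutation is added"). Under neutrality $N_e P_f = 1$, so
every mutation fixes without touching the fitness machinery.

Defaults: $V_M = 0.01$, $N_e = 10^4$, 50 replicate lineages, 200
repetitions, and **1000 time units** per lineage. The duration is a
package choice — the regime descriptions in this literature say only "at
the end of the simulated evolution" — set so that lineages comfortably
reach steady state on the unit scale of the optima: with ~1 fixation
opportunity per unit and mutational s.d. 0.1 per trait, a lineage
traverses an N(0,1)-scale landscape within a few hundred units.
`simulate_regime(..., check_steady_state = TRUE)` reruns at doubled
duration and warns if the median `COR_E` moves by more than 0.05.

Numerical care in the fixation probability: the $s \to 0$ limit $1/N_e$
is substituted below $|s| < 10^{-12}$, and strongly deleterious mutations
($-2N_e s$ beyond the exponential range) underflow to probability zero
instead of overflowing.

**Random optima are drawn once per run.** In the random-optima regime
each lineage's optimum is a pair of standard normal draws. One optima set
is drawn per run and shared by all 200 repetitions; the repetitions then
measure mutation-and-fixation noise around a fixed landscape. This
matches the published behavior of the regime, where the reported median
evolutionary correlations under random optima (≈ 0.087–0.089 across all
mutational correlations) coincide with the single reported correlation of
the drawn optima (0.088) — something that could not happen if optima were
redrawn per repetition. The drawn set is checked for trait independence
(redrawn while |r| ≥ 0.3 across 50 lineages, with a message) and is
returned so users can see the landscape their verdicts refer to.

**Verdicts.** A run is significant when `COR_M` falls in the left or
right 2.5% tail of the 200-value `COR_E` distribution. Significant runs
are labeled strengthened/weakened by |median COR_E| versus |COR_M|, and
*reversed* only when the distribution's central 95% lies entirely on the
other side of zero — a median whose sign flips within noise around zero
is a weakening, not a reversal.

**Mutational bias.** The bias coefficient $B \ge 1$ multiplies both
components of an effect when the first trait's effect is positive and
divides otherwise ($m_1 = 0$, a probability-zero event, is left
unchanged). `bias_cor_check()` verifies that rescaling leaves the
estimated mutational correlation near its pre-set value, so skewed
mutational input alone cannot mimic a selection signal;
`estimate_bias_coefficient()` estimates $B$ from a mutant panel as
$\sqrt{\max(|\bar p|,|\bar n|)/\min(|\bar p|,|\bar n|)}$ where $\bar p$
and $\bar n$ are the means of the positive and negative effects.

## Integration and modularity

`V_eigen` is the *population* variance (divide by n) of the eigenvalues
of a correlation matrix, so the relative index `V_eigen/(n−1)` spans
exactly [0, 1]; this convention also matches the published relative
values for the datasets the method was developed on. The covariance
ratio CR is implemented in two variants because the formula printed in
this literature sums the two within-module traces inside the inner square
root while the statistic's original definition multiplies them. The two
differ materially: the summed form scales as $\sqrt{c}$ when the whole
covariance matrix is scaled by $c$, while the product form is
scale-invariant. Without the original data neither can be adjudicated, so
`as_printed` is the default, the variant is recorded in the result, and
users comparing across datasets on different scales should prefer
`product_denominator`.

Both statistics are compared to rank-matched subsampling nulls: `k`
mutant lines per subset (chosen so the subset correlation matrix has as
many positive eigenvalues as the evolutionary matrix — for 16 strains,
k = 15), `n_subsets` re-estimates, and an empirical two-tailed p-value
$p = 2\min(q, 1-q)$ with $q$ the fraction of null values below the
observed statistic; an observed value beyond every null value is reported
as the band "< 2/n_null" rather than a sharp zero.

## What the synthetic generators emulate — and what they do not

`gen_mutant_panel` draws i.i.d. multivariate-normal lines around a target
covariance; `gen_tree` produces pure-birth ultrametric trees;
`gen_divergence_data` simulates Brownian tips and, for designated pairs,
re-draws the two traits *in contrast space* at an exact target
correlation (mapped back to tips through the pseudo-inverse of the tree's
contrast transform), so power studies have sharp ground truth aligned
with the estimator's own coordinates. `gen_modular_cov` builds exact
block-correlation matrices for closed-form checks.

These generators deliberately omit several features of real data:
measurement error and environment-of-phenotyping shifts (the
`pc_envelope_check` diagnostic exists precisely because real reference
phenotypes may come from a different growth condition), non-normal and
skewed mutational effect distributions (handled separately through the
bias coefficient), mosaic strains whose phylogenetic position varies
along the genome (such strains must be removed upstream), rate shifts or
singular evolutionary events that independent contrasts do not absorb,
and real tree shapes (a pure-birth tree is more balanced than many
empirical phylogenies). Passing tests on synthetic data therefore
demonstrate the machinery's correctness and calibration under the model's
own assumptions, not robustness to these violations.

## Problem sizes and numerical tolerances

The test suite exercises the machinery at reduced but honest scales: the
regime grid at its full stated scale (50 lineages × 200 repetitions ×
1000 units per cell), calibration on 2000 synthetic trait pairs, power on
200 replicate datasets, nulls on 200–1000 simulated datasets. Matrix
validity checks use 1e-10 symmetry and −1e-8 (relative)
positive-semidefiniteness tolerances; correlations at |r| ≥ 1 (possible
in rank-deficient scans) are clamped to 1 − 1e-15 with a warning before
the z transform; closed-form identities are asserted to 1e-12.

## Known limitations

The selection test assumes a single `COR_M` shared across lineages and
tests only correlation shifts common to all lineages — lineage-specific
selection dilutes toward the null, so the significant fraction is an
underestimate. Power at small tip counts is modest: with 15 contrasts
only large |COR_E − COR_M| differences reach significance, which is why
the simulation grid and power analyses report exactly how large. The
forward simulator is origin–fixation on the mean phenotype of two traits
in a haploid population; it does not model standing variation, diploidy,
or more than two traits.
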