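---
title: "Phylogenetic turnover across successional stages and phylogenetic depths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic turnover across successional stages and phylogenetic depths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosucc)
```

## The question and the statistics

Succession after disturbance assembles communities through some mixture of
stochastic colonization and deterministic filtering. When niches are
phylogenetically conserved, relatedness summarizes trait similarity, and the
*phylogenetic turnover* between plots — whether co-occurring species are more
or less related to each other than to species in other plots — becomes a
readable signature of the assembly process. `phylosucc` implements the
Hardy–Senterre decomposition of that signal for a chronosequence design:
plots of different post-disturbance ages grouped into successional stages,
sampled together with an environmental table and a dated phylogeny of the
regional species pool.

The core quantities are mean pairwise phylogenetic (cophenetic) distances.
For a plot $k$, $\Delta^P_w(k)$ is the mean distance between distinct
species present in $k$ (presence mode), and $\Delta^{*P}_w(k)$ the mean
distance between two individuals of distinct species (abundance mode, i.e.
weighted by relative abundances $f_{ik}$). For a plot pair $(k, l)$,
$\Delta^P_a$ and $\Delta^{*P}_a$ are the corresponding cross-plot means,
always excluding conspecific pairs. The turnover statistics are

$$\Pi_{ST} = 1 - \Delta^P_w / \Delta^P_a, \qquad
  B_{ST} = 1 - \Delta^{*P}_w / \Delta^{*P}_a .$$

Values above zero mean species within plots are more related than species
from different plots (*phylogenetic clustering*, high turnover); values
below zero mean *overdispersion*. Pairs of plots from the same stage measure
spatial (within-stage) turnover; pairs from different stages measure
temporal (between-stage) turnover. With stage sizes 5/4/5/6/7 this gives
351 pairs, 62 within and 289 between, with per-stage within counts
10/6/10/15/21 — combinatorics the test suite pins down exactly.

Two aggregation conventions exist and `grouped_turnover()` reports both: the
mean of pairwise statistics (with a descriptive SE — pairs are not
independent, so inference is delegated to the null model), and the pooled
Hardy–Senterre ratio $1 - \overline{\Delta_w} / \overline{\Delta_a}$ over a
group's plots and pairs. The pairwise form is what the environment
regressions consume; the pooled form is the classical stage-level statistic.
Both coincide exactly with brute-force pair enumeration on small instances
(tested to 1e-12), and $\Pi_{ST} = B_{ST}$ whenever within-plot abundances
are equal.

## Null models

Observed turnover is compared against the *tip-shuffling* null model: a
uniform permutation of species names across the phylogeny of the full
regional pool (not only the species observed in plots). The community
matrix is untouched, so richness per plot, species turnover, occurrence
frequencies and abundances are all preserved; only the phylogenetic
identity of each name changes. Equivalently — and this is how the package
implements it — the rows/columns of the pool cophenetic matrix are
permuted. A community-restricted shuffle is available behind an explicit
flag for sensitivity analysis.

P-values use the add-one rank convention $p = (r + 1)/(R + 1)$ with $r$ the
number of replicates strictly more extreme than the observed value; with
continuous statistics ties have probability zero and the test is exact
whenever observed data and replicates are exchangeable — which is precisely
the case under lottery assembly. The acceptance suite verifies this
operationally: over 500 neutral data sets at the design scale, the
two-sided rejection rate at $\alpha = 0.05$ stays inside the binomial 95%
interval. The standardized effect size is
$\mathrm{SES} = (\mathrm{obs} - \overline{\mathrm{null}})/\mathrm{sd}(\mathrm{null})$,
flagged undefined when the null is degenerate (e.g. a star phylogeny).
The package also reports the figure-style "outside the null 95% interval"
flag (type-7 quantiles).

A companion simulation (`plot_count_sensitivity()`) checks that stage-level
turnover is not an artefact of unequal plot counts: over repeated neutral
simulations the mean Pearson correlation between per-stage turnover and the
number of plots should be close to zero.

## Phylogenetic depth

Clustering produced by deep niche conservatism need not be visible at
shallow phylogenetic scales, and opposing processes at different depths can
cancel in whole-tree statistics. `restricted_turnover()` therefore
recomputes the statistics using only species pairs whose most recent common
ancestor is younger than a divergence-time threshold $T$; on an ultrametric
tree this is simply $d_{ij} < 2T$. The default grid
`threshold_grid(30, 128, 10)` spans 30–128 Myr in eleven steps. The
matching null model is the *partial* shuffle: names are permuted only
within maximal clades younger than $T$, leaving deeper structure fixed —
so each threshold is tested against randomness *at that scale only*.
`depth_profile()` assembles the SES-vs-threshold profile per stage.

Tie handling is explicit: "younger than $T$" means strictly less by
default (`ties = "exclude"`), configurable to inclusive. Consequently the
profile equals the unrestricted test for any $T$ strictly above the root
age, which is how the limit invariant is tested; at $T$ exactly the root
age, root-divergence pairs are excluded under the default.

Clade-level attribution uses the `nodesig()` procedure: for every internal
node of the pool tree and every plot, is the number of descendant taxa in
the plot larger (or smaller) than expected under the same tip shuffle?
Because the shuffle drops a plot's $n$ species onto $n$ uniformly chosen
pool tips, the null count for a clade of $c$ tips in a pool of $N$ is
exactly hypergeometric$(N, c, n)$ — the package offers this closed form as
an analytic mode next to the Monte Carlo default, and the acceptance suite
confirms the randomization distribution matches it (chi-squared GOF). No
multiple-testing correction is applied by default, matching common
practice for these node-level screens; a Benjamini–Hochberg option exists
(`p_adjust = "BH"`) as an extension.

## Environmental covariation

To ask whether turnover tracks the abiotic template, plot-pair turnover is
regressed on between-plot environmental distance. The environmental table
is log-transformed where strictly positive (signed variables such as
northness pass through; which variables were logged is recorded on the
result), z-scored, and summarized by PCA; the smallest set of leading
components reaching 90% of variance defines the Euclidean distance. This
damps blocks of collinear descriptors. Note that an exactly duplicated
variable still upweights its axis by $\sqrt 2$ — PCA removes redundant
*dimensions*, not weight — which is why the tests assert the rank and
decomposition behaviour rather than strict invariance.

Spatial structure is partialled out first: the statistic is regressed (OLS)
on the Euclidean distance between plot coordinates and the residuals carry
forward. Significance comes from permuting residual turnover across pairs
(5000 permutations by default, two-sided on the slope). Pair-level
permutation mirrors randomization-based linear-model testing on
distance-derived responses; because pairs sharing a plot are not
independent the test can be mildly liberal, which is why the late-stage
pattern checks below use conservative majority thresholds. A plot-level
Mantel-style alternative was considered out of scope for the default path.
Stage-size artefacts are addressed by `subsample_association()`: all
$\binom{n}{4}$ four-plot subsets per stage (four being the smallest stage)
are enumerated and the association re-run on each.

## Phylogenetic signal

`phylo_signal()` estimates, per trait: Blomberg's $K$ (observed vs
Brownian-expected MSE ratio under the GLS mean, permutation test on the
variance of independent contrasts), Pagel's $\lambda$ (ML over
$[0, \lambda_{max}]$ with the covariance off-diagonal scaled, LR test
against $\lambda = 0$ — the star-phylogeny null of *no* signal, matching
the question asked of these data), and Abouheif/Moran's $I$ (Moran
autocorrelation under the row-normalized Abouheif proximity, the product of
one over the number of direct descendants along the path's interior nodes;
one-sided permutation test). $K$ agrees with `picante::Kcalc` to numerical
precision and $\lambda$ with `phytools::phylosig`; the proximity matrix is
checked against a closed-form three-tip case. Calibration at 128 tips:
Brownian traits give mean $K$ in $[0.9, 1.1]$ and median
$\hat\lambda \ge 0.9$; white-noise traits give $\hat\lambda \approx 0$;
$\lambda = 0.5$ simulations are recovered within the simulation CI.

## The synthetic chronosequence

The generator is first-class, tested code: every other module's guarantees
are demonstrated on data whose truth is known. Defaults reproduce the study
design this package is shaped around: a 410-species pool on a birth–death
tree rescaled to a 128 Myr root, 143 community species, 27 plots in stages
of 5/4/5/6/7, per-plot richness 25–55, individuals declining from ~400
(young stages) to ~150 (old stages), and lognormal abundances whose
`sdlog` falls from 1.5 to 0.5 across stages so evenness rises through
succession. Plots sit on a one-dimensional latent environmental gradient
(span ±2) observed through ten noisy indicator variables (half reported on
a strictly positive scale so the log-transform path is exercised); x/y
coordinates are independent of the gradient by default so spatial
partialling is a no-op, with a correlated variant to test the
residualization path. A six-latent-factor variant exists so the "about six
components reach 90%" PCA behaviour can be reproduced generically.

Scenarios plant known truths:

* `neutral` — uniform lottery from the community pool; the calibration
  scenario.
* `filtering_conserved` — Gaussian niche kernel
  $\exp(-(\text{niche}_i - e_k)^2 / 2w^2)$ with breadth $w = 0.8$ on a
  conserved niche trait, all stages.
* `deep_filtering_late` — neutral in stages 1–3, filtering in stages 4–5,
  with the niche planted as opposite offsets (±2) on the two daughter
  clades of the internal node nearest 100 Myr. The split is deliberately
  *not* at the root: cross-clade pairs then have MRCA ages near 100 Myr,
  so depth profiles can both retain them (thresholds above the split) and
  null them correctly (clade-restricted shuffles below the split). Tip
  niches wobble around their clade optimum with Brownian sd 0.5, so a
  faint, genuinely heritable shallow signal exists but the dominant
  pattern is deep — which is exactly what the recovery tests assert.
* `overdispersion` — filtering plus a greedy repulsion rule that forbids
  co-occurrence of species closer than 30 Myr.
* `dominance_shift` — fixed core composition with the evenness trend only:
  presence-based turnover is exactly zero while abundance evenness rises
  monotonically.

What the generator does *not* emulate: real spatial autocorrelation of
environments, intraspecific variation, detection error, the skewed clade
sizes of real regional floras, or temporal autocorrelation between stages
beyond shared composition. Passing tests therefore demonstrate that the
estimators and tests behave correctly under their own assumptions, not that
any particular field system satisfies those assumptions.

## Numerical choices and degenerate inputs

* Undefined quantities propagate as flagged `NA`s, never as zeros:
  single-species plots (no within-plot pair), plot pairs whose only shared
  material is one conspecific pair, depth cells with no retained pair,
  degenerate nulls (sd = 0), constant traits, zero-variance regressors.
* Ultrametricity is checked with a relative tolerance of 1e-6 of tree
  depth (configurable; `force = TRUE` accepts non-ultrametric trees with a
  warning).
* Name matching is exact after whitespace trimming and
  underscore/space normalization; mismatches error with the offending
  names listed, because silent mis-joins are worse than failures.
* Seeds: every stochastic function takes a `seed`; one master seed spawns
  recorded per-component streams (`spawn_seeds()`), and fixed seeds make
  entire analyses bit-reproducible, including on-disk fixtures.
* One-dimensional $\lambda$ optimization is bounded by the largest
  $\lambda$ keeping the covariance positive definite, with the boundary
  candidates compared explicitly against the interior optimum.

## Problem sizes used in the automated checks

The calibration and recovery experiments run at the full design scale
(410/143/27): 500 neutral data sets with 199-replicate nulls for the
exactness check; 100 deep-filtering data sets with 199-replicate nulls for
stage-level recovery, 499 permutations per environment regression, and
99-replicate partial nulls per depth threshold; 200 trait simulations per
signal scenario at 128 tips. These sizes keep the whole suite within a few
minutes of CPU time while leaving the binomial assertion intervals narrow
enough to be informative.
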