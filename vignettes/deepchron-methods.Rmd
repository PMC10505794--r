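---
title: "Methods: consensus calibrations, the eukaryogenesis interval, and complexity through time"
author: "deepchron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus calibrations, the eukaryogenesis interval, and complexity through time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepchron)
```

deepchron implements three linked deep-time analyses: consensus node
calibrations from collections of published divergence times, an interval
algebra for dating eukaryogenesis against the Great Oxidation Event (GOE),
and a Brownian-motion reconstruction of biological complexity through time
on a timetree. This vignette is the package's own account of the models,
the tunable parameters, the numerical choices, and what the synthetic-data
module does and does not emulate.

Throughout, branch lengths and node ages on trees are in millions of years
(My); published times, posterior summaries, fossil minima and interval
bounds are in billions of years (Ga). The two scales never mix implicitly:
`my_to_ga()` and `ga_to_my()` are the only converters.

## Consensus calibrations from published node ages

Secondary calibration — calibrating a node with previously published
molecular dates rather than fossils — is useful for ancient divergences
with no usable fossil record, but raw literature collections mix strict
and relaxed clocks, superseded datasets, and repeat reports of the same
underlying tree. `filter_published_times()` screens a collection with four
rules, applied in order:

1. **Year cutoff** (`min_year`, default 2000): estimates published before
   modern relaxed-clock methods and genome-scale datasets are dropped.
2. **Relaxed clock required** (`require_relaxed_clock`, default `TRUE`):
   strict-clock dates are systematically distorted at these depths.
3. **Fossil consistency** (`fossil_minima`): at nodes listed in the
   mapping, estimates strictly younger than the stated minimum are
   dropped. The default carries a single entry, a 0.89 Ga minimum for the
   Metazoa crown and its ancestors, reflecting a putative 890-My-old
   sponge fossil; the mapping is configuration, so users who reject that
   fossil simply pass an empty vector.
4. **Redundancy** (`drop_redundant`): at most one record per
   `(source_id, topology_id, node_label)` triple survives, keeping the most
   recent year (first record on ties). Redundancy is defined this way —
   same study *and* same published tree *and* same node — because the same
   research group re-publishing the same timetree should not be counted as
   independent evidence, while genuinely new analyses from the same group
   should.

The filter is idempotent and preserves input order, both asserted as
properties in the test suite.

`consensus_calibration()` then summarises the surviving ages for one node
as a **uniform density** whose bounds are the two-sided 99% confidence
interval of the mean published age,

$$\text{bounds} = \bar{x} \pm t_{(1+c)/2,\,n-1}\; s/\sqrt{n}, \qquad c = 0.99 .$$

Student-t rather than normal quantiles are used deliberately: per-node
study counts are small (two to a few dozen), where the t correction is
material — at $n = 3$ the 99.5% quantile is 9.92 against the normal 2.58.
A uniform density between those bounds adds no distributional shape or
soft-tail assumptions beyond the spread of the published estimates.

Two numerical guards:

* With $n = 2$ the t quantile is ~63.7 and the interval can exceed any
  physically meaningful age; bounds are clamped to $[0, 4.567]$ Ga (the
  age of the Earth) with a warning. Unclamped intervals are exactly
  symmetric about the sample mean (tested to $10^{-12}$).
* Fewer than two ages is an error, not a degenerate interval: a
  single study has no estimable between-study spread.

Ages are carried in Ga end to end. An alternative would be to convert to
My internally, but every input (published times) and every output
(calibration tables) is conventionally reported in Ga, so a My round trip
would add conversions without numerical benefit; display rounds to two
decimals in Ga.

`emit_calibration_table()` serialises either as a TSV with the
conventional calibration-table layout (node, older bound, younger bound,
number of studies) or as MrBayes-style `calibrate <node> =
uniform(<younger>, <older>);` statements for use by external dating
software; the package emits calibration blocks but never runs a dater.

## The eukaryogenesis interval

Eukaryogenesis — the emergence of the eukaryotic cell from an archaeal
host and a bacterial (mitochondrial) endosymbiont — cannot be tied to a
single node on any timetree, because the closest prokaryotic relatives of
eukaryotes are extinct. The package therefore works with an *interval*:

* **Older boundary.** Both partners' divergences from their closest
  *living* relatives (LBCA-K on the bacterial side, LACA-K on the
  archaeal side) necessarily precede the fusion, under single or serial
  endosymbiosis alike. The *younger* of the two divergences is the
  tightest defensible older limit, so `older_boundary()` selects the node
  with the younger posterior mean.
* **Younger boundary.** Eukaryogenesis must have concluded by the
  eukaryote crown node (LECA); `younger_boundary()` uses LECA's posterior
  summary, optionally tightened by fossil minima.

Two modes share those rules but read different fields:

| mode | older bound | younger bound |
|---|---|---|
| `conservative` | older 95% HPD limit of the selected node | younger 95% HPD limit of LECA |
| `core` | posterior mean of the selected node | **older** 95% HPD limit of LECA |

The conservative mode deliberately avoids false precision by spending the
full credibility intervals; the core mode brackets where most of the
posterior probability sits. Using LECA's *older* HPD limit as the core
younger bound follows the numerical usage of the interval it describes (a
mean-based younger bound would be younger than the most probable close of
eukaryogenesis, not older). By construction the conservative interval
always contains the core interval, and widening any HPD can only widen
the conservative interval — both are property-tested.

**Fossils default to tests, not bounds.** `include_fossil = FALSE` keeps
unambiguous eukaryotic fossils (e.g. a 1.62 Ga minimum) out of the
interval construction, so `fossil_margin()` can use them as an
*independent* check afterwards: the margin `delta` is the signed distance
from the fossil minimum to the younger bound. Folding the fossil into the
bound first would make that check circular.

**Derived quantities are always recomputed.** `interval_width()` and
`percent_shorter()` do exact arithmetic on the supplied bounds; no width
or percentage is ever quoted as a constant, so rounded or inconsistent
numbers in upstream reports are not propagated. Similarly
`goe_gap_fraction()` exposes the rule
$\max(0,\, \text{GOE}_\text{end} - \text{older})/\text{GOE}_\text{end}$
with the GOE supplied as configuration (`goe_interval()`, core default
2.43–2.22 Ga, conservative envelope 3.01–1.77 Ga), so the caller controls
the endpoints entering the comparison.

Interval results are reported in Ga; the package's own tests compare them
at an absolute tolerance of 0.005 Ga, i.e. to the two printed decimals.

## Brownian-motion reconstruction and imputation

The complexity analysis needs ancestral values of continuous traits on a
timetree, with many tips unscored. Both reconstruction and imputation are
done under Brownian motion (BM): a trait accrues independent Gaussian
increments of variance $\sigma^2 t$ along a branch of length $t$, so any
two nodes covary by $\sigma^2$ times their shared root-to-node path
length.

`bm_ancestral_states()` computes, for every internal node, the marginal
maximum-likelihood estimate (with a flat prior on the root state) by a
**two-pass pruning algorithm**: a post-order pass conditions each node on
the data in its subtree (each child contributes a Gaussian message with
variance `child variance + branch length`, combined by precision
weighting), and a pre-order pass folds in the information from the rest
of the tree, yielding the exact marginal at every node in $O(\text{nodes})$
time. The estimates equal the dense generalized-least-squares solution on
the shared-path covariance matrix; the test suite holds the two routes to
$10^{-8}$ agreement over hundreds of randomized small trees, and the
dense route exists *only* as a test oracle — pruning is the production
path, because the target use case is family-level trees with thousands of
tips where an explicit covariance matrix is wasteful.

`impute_missing_tips()` is the same machinery with missing tips entering
the upward pass as zero-information (infinite-variance) messages: the
marginal at a missing tip is then exactly the multivariate-normal
conditional expectation of its value given the observed tips. A useful
exact identity follows from linearity — imputing a tip at its conditional
mean and then reconstructing gives the same internal estimates as
marginalizing the tip analytically — and is asserted in the tests.

$\sigma^2$, when not supplied, is estimated by `estimate_bm_rate()`:
restricted maximum likelihood as the mean of squared standardized
phylogenetically independent contrasts over the observed tips. The
contrasts fall out of the same post-order pass; under the model they are
i.i.d. $N(0, \sigma^2)$, which also gives an exact $\chi^2$ interval used
in the recovery tests.

Numerical and modelling choices:

* **Zero-length branches** are floored at $10^{-9}$ My so the implied
  covariance stays non-singular; a tip joined by zero-length branches to
  an observed tip is imputed (numerically) at that tip's value.
* **Polytomies** are handled natively — messages fold child by child — so
  no arbitrary binary resolution is introduced.
* **Raw-scale reconstruction.** States are reconstructed on the raw trait
  scale and only logged afterwards in the composite; reconstructing
  log-traits instead would change the estimator (Jensen) and is not done.
* **Univariate per metric.** Each metric is imputed and reconstructed
  independently; cross-trait correlations are not exploited. Multivariate
  phylogenetic imputation can borrow strength across correlated metrics
  and would likely tighten imputations here; this is a documented scope
  limit of the package, not an oversight.
* Estimates are positive-weight averages of observed values, so every
  reconstructed or imputed value lies within the observed range — tested,
  and worth knowing: the reconstruction can never exaggerate past states.

## The composite complexity metric and its curves

Three metrics apply across the whole tree of life: number of unique cell
types, number of genes, and genome size (Mb). They live on wildly
different scales, so `composite_complexity()` makes them commensurable
per node $i$ and metric $m$:

$$C_i = \frac{1}{M} \sum_{m=1}^{M} \ln\!\left(\frac{x_{im}}{\bar{x}_m}\right),$$

normalizing each metric by its mean across nodes, taking logs, and
averaging. Choices worth stating:

* **Natural log.** Any other base rescales all composites by one positive
  constant and changes nothing qualitative.
* **Normalizing mean over all nodes** (tips and internals of the
  reconstructed metric), so the composite is a self-contained function of
  one reconstruction. The key invariance — rescaling any single metric by
  a positive constant leaves the composite unchanged — holds for any
  fixed node set and is asserted to $10^{-12}$.
* Non-positive values are a hard error naming the node and metric: logs
  of reconstructed non-positive complexity values indicate an unsuitable
  input, not something to patch silently.

`node_ages()` dates every node as (deepest root-to-tip path) minus (the
node's root-to-node path), so tips of an ultrametric tree sit at age 0
and non-ultrametric trees are handled by the same rule.

`moving_maximum()` builds the through-time envelope: half-open age
windows $[s, s + w)$ of width $w = 500$ My, starts anchored at multiples
of the step (100 My) spanning the data, each non-empty bin reporting its
maximum at the bin midpoint minus a 100 My report offset. The offset is
applied to the *reported age* (it shifts the curve toward the present,
compensating for the midpoint lagging the youngest evidence in a bin) and
is a parameter, so offset-free curves are one argument away. Empty bins
are omitted, not interpolated — an interpolated maximum would claim
evidence where there is none. The implementation is held equal to an
exhaustive bin-enumeration oracle on random point sets.

`complexity_through_time()` composes the pipeline — impute, reconstruct
per metric, composite, ages, curves — deterministically. The mean-panel
points exclude extant tips (age 0) by default because thousands of tips
at time zero visually and numerically swamp the through-time signal; the
full per-node table always retains them. Whether a mean panel should
average per node or per time bin is left to the caller: the per-node
(age, composite) points are returned so either view can be drawn.

## What the synthetic module emulates — and what it does not

All fixtures are generated in code, seeded, and pure functions of their
arguments; every generator restores the caller's RNG state.

* `simulate_yule_tree()` draws pure-birth (Yule) ultrametric timetrees:
  with $k$ lineages the epoch lasts $\mathrm{Exp}(k\lambda)$, and one
  further epoch after the $n$-th lineage precedes the present, giving the
  analytic mean root age $\sum_{k=2}^{n} 1/(k\lambda)$ used as a
  distributional test. Yule rather than birth–death is a deliberate
  simplification: extinction adds realism to branch-length structure but
  nothing to what these fixtures must exercise, and the pure-birth
  analytics keep the generator itself testable.
* `simulate_bm_traits()` evolves traits by exact BM transition sampling
  and returns the *true* states at every node, so recovery can be scored
  against truth. An optional clade shift multiplies all states in one
  clade by a constant — a stylised version of a discrete complexity gain
  in a single lineage (the eukaryote jump), chosen over a BM mean jump
  because it produces a step of known size in the moving-maximum curve.
  Because real complexity metrics are positive, the generator expects the
  root state to dominate the diffusion scale and warns and re-centres if
  any state goes non-positive.
* `mask_tips()` masks a `floor(fraction * n)` uniform subset (exact
  count, so tests can assert it), refusing to leave fewer than two
  observed tips. Missingness is uniform at random — real trait databases
  are missing *non*-randomly (well-studied clades are overrepresented),
  which BM-conditional imputation does not model.
* `simulate_published_times()` scatters i.i.d. normal ages (truncated at
  zero) around a true age with uniform publication years and distinct
  study identifiers — the statistical structure the consensus calibration
  assumes. Real literature estimates are neither independent nor
  identically distributed (shared data, shared calibrations, citation
  lineages); passing coverage tests on this generator shows the interval
  construction is correct under its own assumptions, not that real
  literature samples achieve nominal coverage.

The same caveat applies to the whole suite: synthetic BM traits on Yule
trees validate the estimators under the model they assume. Real
complexity data involve rate heterogeneity, correlated traits,
non-random missingness and tree uncertainty, none of which the fixtures
emulate.

## Problem sizes and statistical tests

The packaged checks run at sizes chosen to make their statistics sharp
while staying quick on one CPU: dual-route (pruning vs dense GLS)
equivalence on 200 randomized trees of up to 6 tips at $10^{-8}$; root
and rate recovery over 1,000 BM replicates on one 50-tip Yule tree (bias
within 3 Monte-Carlo SEs of zero; exact $\chi^2_{49}$ interval coverage
within 3 binomial SEs of 95%); calibration coverage over 2,000 simulated
ten-study tables (99% ± 1%); Yule root-age calibration over 400 trees.
Larger runs reproduce the same results; the suites are ordinary tests,
not benchmarks.

## Known limitations

* Univariate BM only: no Ornstein–Uhlenbeck, no rate shifts, no
  multivariate imputation.
* Calibration densities are uniform only; no soft bounds or shaped
  priors, and no interaction with dating software beyond emitting
  calibration blocks.
* Node estimates are consumed as printed posterior summaries; the
  package performs no Bayesian dating and does not propagate posterior
  correlation between nodes into the interval algebra.
* The GOE enters only as a configurable pair of intervals; no oxygen
  proxy modelling.
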