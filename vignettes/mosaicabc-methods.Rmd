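---
title: "Models and methods behind mosaicabc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mosaicabc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicabc)
```

mosaicabc asks a simple question with awkward data: clinics publish the
proportions of trophectoderm biopsies classified euploid, mosaic and
aneuploid by PGT-A, but a biopsy is five cells out of a ~256-cell
blastocyst. What rates of meiotic and mitotic chromosome mis-segregation,
and what whole-embryo karyotype composition, are consistent with those
published proportions? Because the generative model is an easy-to-simulate
stochastic process with an intractable likelihood, the package answers by
simulation-based inference: approximate Bayesian computation (ABC) with an
adaptive population Monte Carlo sampler.

This vignette documents the model, the algorithmic choices, the defaults
and why they were chosen, and what the package's tests do and do not
establish.

## The embryo model

**Lineage.** A zygote carries a meiotic-origin aneuploidy with probability
$m$ per meiosis; such embryos are entirely aneuploid. Otherwise the zygote
is euploid and grows through $R = 8$ synchronous division rounds to
$2^R = 256$ cells. Aneuploid cells breed true. Under the default
*per-daughter* convention, each daughter of a euploid division
independently becomes aneuploid with probability $p$ per mitosis, so the
euploid count follows the binomial recursion
$E_{r+1} \sim \mathrm{Bin}(2E_r,\, 1-p)$ from $E_0 = 1$. Two closed forms
anchor the tests:

$$\Pr(\text{fully euploid}) = (1-m)(1-p)^{2(2^R-1)}
  \qquad
  \mathbb{E}[\text{aneuploid fraction}] = m + (1-m)\bigl(1-(1-p)^R\bigr),$$

with $2(2^R - 1) = 510$ daughter draws at $R = 8$. An alternative
*per-division* convention (the division errs as a unit and both daughters
become aneuploid, $E_{r+1} = 2\,\mathrm{Bin}(E_r, 1-p)$) is available via
`model_config()`. Both share the per-cell marginal euploid probability
$(1-p)^R$ and differ only in clone-size correlation; we default to
per-daughter because its fully-euploid probability $(1-p)^{510}$ (rather
than $(1-p)^{255}$) is the one whose posterior-predictive magnitude
(~$10^{-4}$ at dispersal 1) matches multi-study clinical expectations of
very rare fully euploid blastocysts.

**Geometry.** The trophectoderm is modelled as a deterministic Fibonacci
lattice of 256 points on the unit sphere — a near-uniform packing whose
nearest-neighbour distances vary by under 25%. Each cell's neighbours are
pre-ordered by chordal distance (ties broken by lowest cell id). The
geometry is a deliberate, explicit stand-in for a real blastocyst surface;
everything spatial in the package reduces to these orderings.

**Dispersal and placement.** Given $k$ aneuploid cells and a dispersal
level $d \in [0,1]$, placement is seed-and-grow:
$s = \max(1, \mathrm{round}(dk))$ seed cells are drawn uniformly without
replacement (rounding half away from zero, clamped to $k$), and clusters
then grow — a cluster is picked uniformly at random and its seed's nearest
unmarked cell is marked — until $k$ cells are aneuploid. $d = 0$ yields a
single spatially contiguous patch; $d = 1$ makes every aneuploid cell its
own seed, i.e. a uniform random subset, so a biopsy's aneuploid count is
exactly hypergeometric given $k$; intermediate $d$ interpolates. The
mechanics at intermediate dispersal are a design choice of this package
(the clinical literature does not pin them down); results quoted at
dispersal 0 or 0.5 should be read with that caveat, and the test suite
checks dispersal-0 behaviour only qualitatively (single connected patch,
strongest meiotic-mitotic posterior correlation).

**Biopsy and classification.** A biopsy is an index cell plus its four
nearest neighbours; the first biopsy anchors at cell 1, a re-biopsy at a
uniformly drawn index cell with overlap permitted (the embryo is
re-biopsied intact — no cells are removed). Two classification rules are
supported for $a$ of 5 aneuploid cells: the clinical 20%/70% copy-number
thresholds (euploid $a/5 < 0.2$, mosaic $0.2 \le a/5 \le 0.7$, aneuploid
$a/5 > 0.7$) and the *any-but-not-all* rule. They disagree only at 4/5,
where the thresholds say aneuploid and any-but-not-all says mosaic. The
package defaults to the 20%/70% thresholds everywhere — at dispersal 1 the
two rules produce nearly identical class proportions (4/5 counts are rare
under scattered low-level mosaicism), so the choice is immaterial for
inference at high dispersal, and the thresholds are the rule clinics
actually apply and the one used for re-biopsy comparisons.

## The ABC engine

`run_abc()` implements adaptive population Monte Carlo ABC with uniform
$(0,1)$ priors on both rates. The summary statistic of a parameter pair is
the triple of biopsy-class proportions over `n_embryos_per_trial = 1000`
simulated embryos; the discrepancy is the Euclidean distance on the raw
proportions (the three summaries share a scale, so no rescaling or MAD
normalisation is applied). The sampler:

1. draws $N = 2000$ pairs from the prior, simulates and scores them, and
   retains the best $N_\alpha = \lceil \alpha N \rceil = 1000$ with unit
   weights; the first tolerance $\varepsilon_1$ is the worst retained
   distance;
2. each iteration resamples parents by weight, perturbs each coordinate
   with a Gaussian kernel whose variance is twice the weighted empirical
   variance of the retained set (perturbations leaving $(0,1)^2$ are
   redrawn — truncation with a kept parent), weights proposals by the
   prior density over the weight-normalised kernel mixture, merges
   proposals with the retained set and keeps the $N_\alpha$ smallest
   distances;
3. stops when the fraction of fresh proposals beating the previous
   tolerance drops to `p_acc_min = 0.05`, or after `max_iterations = 40`.

$N = 2000$ with $\alpha = 0.5$ was chosen so the retained set holds 1,000
particles, the population size the published analyses report per dispersal
level; `p_acc_min = 0.05` is the adaptive method's conventional stopping
value. The cap of 40 iterations exists because a stochastic simulator sets
a noise floor on attainable distances (about $0.02$ with 1000 embryos per
trial), under which the acceptance proportion decays slowly; 40 iterations
let the stopping rule engage in most runs while bounding a full fit to
roughly half a minute on one CPU. No post-hoc regression adjustment is
applied: the importance weighting of the adaptive scheme is the only
correction.

**Lookup-table acceleration.** Conditional on the aneuploid cell count,
the dispersal level and the fixed geometry, the first-biopsy class is a
draw from a fixed three-way distribution. `biopsy_class_lookup()`
tabulates it once per dispersal — 8,000 Monte-Carlo placements per
non-degenerate count, with counts 0 and 256 exact — and ABC samples biopsy
classes from the table instead of placing every embryo. The table agrees
with direct placement simulation within Monte-Carlo error (tested), and at
dispersal 1 with the exact hypergeometric class probabilities. Building
the table consumes the R random stream, so seeded pipelines that build it
inline remain exactly reproducible.

**Summaries.** Posterior means and 95% credible intervals are weighted;
quantiles interpolate the cumulative normalised weight against the ordered
particle values, resolving exact ties to the lower index. `tidy()` returns
the particle table, `glance()` a one-row run summary, `autoplot()` the
particle cloud.

## Posterior-predictive analysis

`simulate_predictive()` draws parameter pairs from the posterior (weighted,
with replacement; 1,000 draws by default) and simulates 1,000 embryos per
draw — a million embryos per dispersal level, each carried through
placement and two biopsies. "Unique embryos" means independent
simulations; no deduplication is attempted. `predictive_tables()` then
tabulates whole-embryo types (an embryo is *mosaic* if any but not all of
its cells are aneuploid), the aneuploid-fraction distribution (exact
257-count tallies plus a 20-bin export), the first-biopsy-class by
embryo-type cross-tabulation, and the re-biopsy table with per-class
concordance.

## Robustness modules

`adjust_target()` models over-diagnosis of mosaicism by moving a fraction
$r$ of the mosaic proportion half to euploid and half to aneuploid —
exact simplex arithmetic, identity at $r = 0$.
`run_misclassification_sweep()` re-runs ABC and the predictive stage over
a rate grid (0 to 1 in steps of 0.1 by default) and the three dispersal
levels. `run_dataset_battery()` applies the full pipeline to each entry of
the published catalog at each dispersal. Both default to a reduced "desk"
preset ($N = 600$, 200 embryos per trial) because they multiply ABC runs;
every output row carries the target and dispersal it came from, and
full-scale settings are one argument away.

## Synthetic targets and what the tests establish

`published_targets()` freezes the four published biopsy-class proportion
sets (Capalbo et al. at its precise 23.2/18.7/58.1 over 6,766 biopsies;
Clarke, Munné and Rodrigo at printed two-decimal precision) — these are
constants, checksummed in the tests. `generate_synthetic_target()`
produces targets with known ground truth by running the full generative
chain, either at a finite biopsy count (multinomial sampling noise at a
realistic study size) or in a noise-free limit approximated with $10^5$
embryos. Parameter-recovery tests default to noise-free targets so that
credible-interval coverage reflects sampler error rather than target
noise.

The synthetic generator emulates exactly what the model assumes: binary
per-cell ploidy, a fixed spherical geometry, synchronous divisions, a
single fixed mitotic rate across divisions, no cell death or selection, no
chromosome identity, no segmental events, and no rescue of aneuploid
lineages. Passing recovery tests therefore demonstrate that the sampler
inverts *this* model — they cannot certify the model against real embryos,
where all of those simplifications are known to be violated to some
degree.

## Numerical choices and degenerate inputs

* Aneuploid counts of 0 or 256 bypass placement; their biopsy classes are
  deterministic.
* Seed counts round half away from zero and clamp to $[1, k]$.
* Neighbour ties (rare on the lattice) break by lowest cell id, making
  biopsies fully deterministic given the index cell.
* Proposals outside the prior support are redrawn for the same parent
  rather than zero-weighted, keeping the population size fixed; weights
  use the untruncated kernel mixture, as in the reference adaptive
  scheme.
* A collapsed retained set (kernel variance underflow) raises an error
  with the offending mixture density rather than propagating non-finite
  weights.
* All randomness flows through R's RNG, including the compiled placement
  kernels, so `set.seed()` (or the `seed` arguments) makes every pipeline
  stage bit-reproducible; serialised outputs round-trip through plain
  text.

Problem sizes used by the test suite and the acceptance script: full ABC
fits use the defaults above ($N = 2000$, 1000 embryos per trial);
predictive samples use $10^3 \times 10^3$ embryos; property tests use
$10^4$–$10^6$ replicates chosen so that three-standard-error bands are
decisive. The whole suite runs in a few minutes on one CPU.

## Known limitations

**Clonal variance drives the mitotic estimate.** The branching lineage
produces heavy-tailed aneuploid-count distributions: an error in the first
cleavages founds a clone of up to half the embryo. The fitted mitotic rate
for a given mosaic-biopsy proportion depends strongly on this variance —
a simulator with independent per-cell aneuploidy (binomial counts, no
clones) fits the same published target with a noticeably lower mitotic
rate than the branching model does at dispersal 1, because clonal variance
inflates the chance that a biopsy misses all aneuploid cells. Published
estimates obtained with different effective count distributions are
therefore not directly comparable to ours at the second decimal; the
package reports what its own, internally consistent model implies, and its
acceptance checks record those values as computed.

**Intermediate dispersal is a stand-in.** The seed-and-grow mechanism
reproduces the stated anchor behaviours (contiguous patch at 0, uniform
subset at 1, moderate clustering between) but is not calibrated to any
imaging data; dispersal-0.5 and dispersal-0 magnitudes inherit that
uncertainty.

**Scope.** No chromosome identity, gain/loss distinction, rescue events,
division-dependent error rates, intra-embryo selection, maternal-age
structure, or inner-cell-mass biopsies. Published PGT-A data also carry
survivorship and cohort ascertainment biases that no re-analysis of the
printed proportions can remove; inferred rates describe the clinically
tested population of blastocysts that survived to biopsy.
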