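---
title: "Two-population demographic model selection from the joint SFS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-population demographic model selection from the joint SFS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demsel)
```

## The inference problem

Given biallelic SNPs from two populations, `demsel` asks which divergence
scenario best explains the joint site-frequency spectrum (jSFS): the matrix
counting SNPs by their minor-allele copy number jointly in both
populations. The candidate scenarios form three families:

* **vicariance** — an ancestral population splits into two descendants of
  unconstrained size, with no gene flow, continuous gene flow (symmetric
  or asymmetric), or ancient gene flow that later ceased;
* **founder events** — the derived ("island") population is established by
  a fraction $s \le 0.5$ of the ancestral ("mainland") population and
  grows exponentially; an *old founder event* adds a second epoch in which
  gene flow resumes after the initial isolation (the peripatric-speciation
  signature: a peripheral isolate of a large central population with
  later secondary contact);
* **secondary contact** — a split with an initial period of isolation
  followed by migration, optionally with per-epoch size changes and a
  final epoch of renewed isolation (three-epoch variants).

All models are expressed in coalescent units: population sizes $\nu$
relative to a reference effective size $N_\mathrm{ref}$, epoch durations
$T$ in units of $2 N_\mathrm{ref}$ generations, migration rates scaled by
$2 N_\mathrm{ref}$, and a composite mutation scale
$\theta = 4 N_\mathrm{ref} \mu L$ that sets absolute SNP counts.
Population 1 is the derived/island entity, population 2 the
ancestral/mainland entity, and $m_{ij}$ is forward-in-time gene flow from
population $i$ into population $j$ — so an estimate with
$m_{12} > m_{21}$ reads literally as "more gene flow from the island into
the mainland than the reverse".

## From VCF to folded spectrum

`read_vcf()` parses GT/DP fields (the locus identifier may live in CHROM
or ID; de-novo RAD catalogues use both dialects). `filter_variants()`
applies the standard export filters: a site is kept when at most half of
its genotypes are missing (`max_missing = 0.5`, retention uses $\le$) and
its mean depth is at least 5. Two conventions here were genuinely open
and are fixed as follows: mean depth is computed over *called* genotypes
only, because missing genotypes carry no depth signal; and "more than
50% missing" excludes strictly, so exactly-half-missing sites survive.
An optional minimum-presence filter (the `-R`-style export rule) is
available but off by default. `thin_one_snp_per_locus()` retains one
uniformly chosen SNP per locus so that sites can be treated as
independent — the assumption the composite likelihood relies on.

`build_jsfs()` absorbs residual missingness by hypergeometric
downprojection: a site observed as $d$ derived copies among $t$ called
haploid alleles contributes weight
$\binom{d}{j}\binom{t-d}{t'-j}/\binom{t}{t'}$ to derived count $j$ at the
target size $t'$, per population, independently per site. Sites with
fewer called alleles than the target contribute nothing. The default
target heuristic (`choose_projection()`) maximizes $t'_1 + t'_2$ subject
to retaining at least 80% of sites, the trade-off the projection exists
to make. Folding merges each cell $(i, j)$ with its complement
$(n_1 - i, n_2 - j)$; cells on the fold line (total count exactly half)
keep the lexicographically smaller index of the pair, self-complement
cells pass through unchanged, and the absorbing cells $(0,0)$ and
$(n_1, n_2)$ are masked out of every likelihood.

## The expectation engine

The expected jSFS under a model is computed by Monte-Carlo simulation of
the structured coalescent rather than by a diffusion solver: genealogies
of the $n_1 + n_2$ sampled lineages are simulated backward through the
piecewise demography, every branch is classified by the number of sampled
descendants it subtends in each population, and cell $(i,j)$ of the
expectation is the mean total length of $(i,j)$-class branches divided by
two — the expected number of segregating sites of that configuration per
unit of $\theta$. Both estimators target the same mathematical
expectation; the Monte-Carlo route is exact in expectation and
self-contained.

Numerical choices:

* Constant-size epochs use a single total-rate exponential draw per event
  (coalescence in either deme, migration in either direction, competing).
* Exponential size trajectories (founder growth) invert the integrated
  coalescent hazard in closed form — no Euler stepping; waiting times that
  overshoot an epoch boundary advance to the boundary and redraw, which is
  exact by memorylessness of the unit-exponential residual.
* Branch classes are constant over a lineage's lifetime, so accrual is
  O(1) per lineage via birth/death timestamps.
* The RNG is a dedicated counter-seeded xoshiro256++ stream, so identical
  seeds give bit-identical spectra independently of R's RNG state.
* A guard caps $n_1 + n_2$ at 60 lineages; raise `max_lineages` expressly
  for larger spectra.
* A 1% parameter perturbation moves no well-populated cell by more than a
  bounded factor (smoke-tested), and Monte-Carlo standard errors are
  returned per cell; they shrink as $1/\sqrt{\text{replicates}}$.

The per-epoch demography (sizes, trajectories, migration matrix) can be
exported as JSON (`demography_json()`), which is also the hook for
cross-validating the engine against an independent coalescent simulator
given the same demography.

## Composite likelihood and optimization

Unmasked cells are treated as independent Poisson counts with means
$\theta \cdot E_{ij}$. The scale profiles out analytically,
$\hat\theta = \sum d_{ij} / \sum E_{ij}$, and the reported
log-likelihood is $\sum d_{ij}\ln\mu_{ij} - \mu_{ij}$ with the
data-constant log-factorial dropped and model cells clamped at
$10^{-12}$. Model score is AIC $= 2k - 2\ln L$ and support is summarized
by Akaike weights $\omega_i \propto e^{-\Delta_i/2}$.

`optimize_model()` runs the four-round randomized restart scheme: by
default 60, 70, 70 and 80 replicates per round, round 1 drawing starts
log-uniformly within bounds and later rounds perturbing the incumbent
best by up to 3-, 2-, 2- and 1-fold per parameter. Each replicate fixes
one engine seed for all of its objective evaluations (common random
numbers), making the per-replicate objective deterministic, and runs a
bounded Nelder-Mead search in log-parameter space (relative tolerance
`1e-4`, at most 200 evaluations). Because a single random start in an
8-dimensional box frequently misses the relevant basin, each replicate
first *screens* 20 candidate starts (drawn by the round's rule) with one
evaluation each and polishes only the best — without this the restart
schedule needed far more replicates for the same reliability. The best
point overall is re-evaluated at a higher replicate count (200,000 by
default) so the reported likelihood is not inflated by selection on
Monte-Carlo noise. A compute guard bounds the event count a single
objective evaluation may simulate (500 events per genealogy on average):
near-panmictic corners — strong migration sustained over long epochs —
cost orders of magnitude more simulation work than any plausible optimum
while fitting essentially as a single population, and are treated as
infeasible rather than allowed to dominate the runtime. Default bounds are $\nu \in [10^{-3}, 100]$,
$T \in [10^{-3}, 10]$, $m \in [10^{-3}, 20]$ (a strictly positive floor
so log-uniform draws are well defined; the floor is biologically
migration-free), $s \in [0.01, 0.5]$.

`run_comparison()` fits a candidate set with independent derived seeds,
ranks by AIC (ties broken by fewer parameters, then name), renormalizes
weights over successful fits (failed fits are recorded, not fatal), and
`run_hierarchical()` applies the three-comparison design: the
species-level pair screened with the founder/vicariance set, the two
within-species pairs with the secondary-contact/isolation/size-change
set.

## The synthetic generator

`simulate_jsfs()` draws each unmasked folded cell independently from a
Poisson distribution around $\theta$ times the engine expectation —
exactly the sampling model the composite likelihood assumes.
`simulate_vcf()` emulates RAD-style data further down the stack: L
unlinked loci with one biallelic SNP each, per-site minor-allele
configurations drawn from the folded expectation, genotypes formed by
random union of gametes, per-genotype missingness (default 0.1), and
negative-binomial depths (mean 20, size 5). The generating truth is
written as a JSON sidecar.

Default study conditions, chosen once: $\theta$ as printed for the pair
under study (211.23 for the species-level comparison), a haploid
projection of 8+8, missingness 0.1. Eight haploids per population is a
deliberately desk-scale projection; it keeps a full four-round founder
fit in the low minutes on one CPU, which is what the test suite and the
acceptance script run. What the generator does *not* emulate: linkage
within loci, sequencing error, allele-dropout or other RAD ascertainment
beyond the fixed-cell mask, and Hardy-Weinberg deviation. Passing
recovery tests therefore demonstrate correctness of the estimator under
its own sampling assumptions, not robustness to real-data artefacts.

## Identifiability limits worth knowing

Two structural facts about this model family shape what parameter
recovery can and cannot show:

* **A scaling ridge.** Rescaling all sizes and times by $c$ and
  migration by $1/c$ leaves the genealogy process — hence the relative
  spectrum — exactly invariant, with $\hat\theta$ absorbing the scale.
  Absolute parameter values are therefore only meaningful up to this
  ridge, and dimensionless quantities (the founding fraction $s$,
  migration *ratios*) are the stable readouts. This is the flip side of
  reporting estimates in genetic units rather than converting them to
  biological quantities.
* **A competing basin for the founder model.** At desk-scale spectra
  (a few hundred to ~1000 SNPs, 8+8 haploids, folded), the two-epoch
  founder likelihood surface contains a second configuration — very small
  founding fraction, near-immediate secondary contact, strong
  near-symmetric migration — whose folded expectation is nearly
  indistinguishable from the generating one. Fits can legitimately land
  there, so the founding fraction is weakly identified at this scale.
  Relatedly, model *selection* resolves the coarse question cleanly —
  gene-flow scenarios beat isolation-only vicariance decisively on such
  spectra — while separating the founder refinement from plain
  divergence-with-gene-flow models may not overcome the AIC penalty of
  its extra parameters.

## Problem sizes in tests

Unit tests run the engine at 3-6 haploids per population with a few
thousand replicates, property tests at 150,000 replicates, and the
acceptance-style experiments use the printed species-pair parameters
with reduced restart schedules — (10, 10, 10, 20) for single-model
recovery, (6, 6, 6, 10) for the four-model comparison — 20,000 engine
replicates during search, and 200,000 for final refits: the package's
chosen desk-scale operating point.
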