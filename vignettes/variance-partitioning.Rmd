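---
title: "Partitioning additive genetic variance into genomic and polygenic components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning additive genetic variance into genomic and polygenic components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvpart)
```

## The problem

Genomic selection in dairy cattle predicts breeding values from dense SNP
panels.  A marker panel, however, only captures the part of the additive
genetic variance that is in linkage disequilibrium with the genotyped loci
(or tracked through familial co-segregation); the remainder is still carried
by pedigree relationships.  Quantifying that split matters for two practical
questions: how much is gained by adding a residual polygenic term to a
genomic evaluation, and how much would be gained by increasing marker
density.

`gvpart` implements the variance-partitioning analysis for this setting:
progeny-tested bulls with deregressed proofs (DRP) as records, a pedigree, and
a genome-wide SNP panel.  A DRP behaves like a progeny-group mean corrected
for non-genetic effects; its precision is summarized by an effective number
of records `w_i`, so its residual variance is modelled as `sigma_e^2 / w_i`.

## The four models

All models have the general mean as the only fixed effect and differ in the
random genetic terms:

* **Model 1** (animal model): `y = 1 mu + Z a + e`, `var(a) = A sigma_a^2`,
  with `A` the pedigree numerator relationship matrix.  Its estimate of
  `sigma_a^2` is the benchmark for total additive variance.
* **Model 2** (genomic model): `var(g) = G sigma_g^2` with `G` the
  marker-based relationship matrix.
* **Model 3** (joint): both terms; `sigma_g^2 / (sigma_g^2 + sigma_a^2)` is
  the *genomic share* — the proportion of additive variance captured by
  markers.
* **Model 4** (chromosome split): `g_c + g_o + a`, where `G_c` is built from
  the markers of one chromosome and `G_o` from all others; run once per
  chromosome to partition the genomic variance along the genome.

In every model `var(e) = D sigma_e^2` with `D = diag(1/w_i)`.  The effective
record counts enter as `1/w_i` so that more progeny information means a
smaller residual: the natural reading of DRP weighting (stating the weights
as "proportional to the effective number of records" would make the residual
grow with information, which cannot be meant).  The variance ratio reported
with each fit, `VR = sum(sigma_genetic^2) / (sum(sigma_genetic^2) + dbar *
sigma_e^2)` with `dbar` the mean diagonal of `D`, is the heritability of a
DRP at the average reliability of the animals, not the heritability of the
underlying trait.

## Relationship matrices

`make_A()` uses the tabular method on the topologically sorted pedigree:
`a_ii = 1 + a(s_i, d_i)/2` and `a_ij = (a(j, s_i) + a(j, d_i))/2`.  Missing
parents are unknown, unrelated, non-inbred founders.  Storage is dense; for
a large national pedigree the recursion is restricted to the ancestors of
the genotyped subset (`make_A(ped, ids = ...)`), which is all the downstream
REML ever needs.  Sparse-inverse machinery (Henderson's rules) is therefore
deliberately not implemented.

`build_G()` uses the centered cross-product construction
`G = (M - P)(M - P)' / (2 sum_j p_j (1 - p_j))`, which puts `G` on the scale
of `A`.  Allele frequencies default to the observed sample frequencies —
there is no deposited base-population reference, and sample frequencies make
every run reproducible from the data alone; an external frequency vector can
be supplied (the simulator records its founder frequencies for exactly this
use).  Missing genotypes are mean-imputed to `2 p_j` before centering.

Marker QC (`qc_markers()`) removes markers with MAF strictly below the
threshold (default 0.01; a marker exactly at the threshold is kept) and then
removes "non-informative" markers that are an exact affine function of an
earlier marker in genome order.  Exactness is intentional: dependence is
detected by canonicalizing each genotype vector up to shift and scale, not
by a correlation cut-off, so duplicated assays, allele-flipped copies
(`2 - m`) and constant vectors are removed while merely correlated markers
are kept.  Only pairwise dependence is screened; affine combinations of
several markers are left alone.

For the chromosome split, each of `G_c` and `G_o` is normalized by its own
heterozygosity sum.  The alternative — one whole-genome denominator for both
— is available via `shared_denominator = TRUE` and changes only the scale of
the per-chromosome variances, not their ranking; with own denominators each
`G_c` has mean diagonal near 1, so `sigma_c^2` is directly comparable across
chromosomes.

## REML

`greml()` maximizes the restricted likelihood
`-1/2 [log|V| + log|X'V^{-1}X| + y'Py]` with
`V = sum_r sigma_r^2 Z_r K_r Z_r' + sigma_e^2 D` by average-information (AI)
updates.  Numerical choices, none of which are data-dependent:

* start at an equal split of `var(y)` over all components;
* an AI step is accepted only if it does not decrease the restricted
  likelihood; otherwise it is halved (up to 12 times) and finally replaced
  by an EM update, which is an ascent step — the accepted trace is
  monotone by construction;
* parameters are floored at `1e-8 * var(y)`; a parameter pinned at the floor
  whose score points further down is dropped from the AI system for that
  iteration (an active-set step), which is what lets fits with boundary
  components converge quickly instead of crawling;
* convergence requires a relative log-likelihood change below `1e-8` *and* a
  maximum parameter change below `1e-6` relative to the larger of the
  parameter and `1e-3 * var(y)` (the floor keeps boundary wiggles from
  stalling the test); the iteration cap is 200;
* standard errors come from the inverse AI matrix at convergence;
* all algebra is dense Cholesky — the intended scale is a few thousand
  records, where dense factorizations are fast and simple.

## Chromosome scan and the length regression

`chromosome_scan()` fits model 4 per chromosome, records `sigma_c^2` with its
SE and the chromosome length (Mb between first and last marker, 1-based
coordinates), and relates `sum_c sigma_c^2` to the model-3 `sigma_g^2` fitted
on the same data.  Cross-chromosome covariances of genomic effects are not
modelled, matching the analysis this reproduces; the shortfall of the sum is
reported, not corrected.  A non-converged chromosome yields a flagged row
rather than a failure.  `regress_variance_on_length()` is the ordinary
least-squares regression whose `R^2` diagnoses whether QTL are spread evenly
(high `R^2`) or concentrated in major genes (low `R^2`).

## How much variance can a panel of N markers explain?

`beta_curve()` implements the split-panel regression: sample `2N` markers,
build `G_m` from one half and `G_t` from the other (each centered at its own
panel frequencies), subtract 1 from both diagonals to remove their diagonal
dominance, and regress the elements of `G_t` on those of `G_m` over all
pairs `j <= k`.  The slope `beta` estimates the proportion of the variance
of the "causal" relationships that the panel reproduces; repeating over
panel sizes traces how that proportion grows with density.  The regression
includes the shifted diagonal by default, exactly as defined;
`include_diagonal = FALSE` is available for sensitivity analysis.  Ten
replicates per `N` with the replicate SD is the default — enough to see the
curve's spread without dominating runtime.  `adjust_G()` applies the
resulting correction `G* = beta (G_m - I) + I`, which undoes the downward
bias of genomic variance estimated with a finite panel (a model-2 fit with
`G*` scales the estimate up by about `1/beta`).

## The simulator

No bull data are distributable, so `sim_config()` / `simulate_population()`
generate populations with the statistical structure the analysis assumes —
they define the study conditions for every validation in the package:

* **Pedigree**: unrelated founders; each later generation is sired by a
  fixed number of males sampled from the previous generation, mated to
  founder females — the sire-heavy shape of dairy pedigrees.  With
  `unknown_dams = TRUE` the recorded dam is blanked while the true dam still
  drives inheritance, so `A` loses maternal links that `G` can still see.
* **Genome**: 29 autosomes of 1 Morgan (100 Mb) by default; marker positions
  uniform; founder allele frequencies uniform on (0.05, 0.5); inheritance by
  gene dropping with Poisson crossovers (Haldane, no interference).
* **Architecture**: `n_qtl` additive QTL with i.i.d. normal effects; a
  fraction (default 10%) sits on *hidden* loci that are dropped through the
  same pedigree but excluded from the panel.  The hidden loci live on extra
  chromosomes that carry no markers — emulating unassayed genome.  This
  placement matters: loci interleaved with the markers are transmitted in
  the very meioses the markers record, so their realized relationships are
  essentially the marker GRM and the genomic term rightly absorbs them; only
  variance from unassayed regions behaves as a residual polygenic component
  that pedigree relationships capture and markers do not.  Each component is
  rescaled so its realized variance among final-generation individuals hits
  its target exactly, so "truth" is known by construction.
* **Phenotypes**: `y = mu + TBV + e`, `e ~ N(0, sigma_e^2 / w)`, with
  effective-record weights uniform on (20, 200) — progeny-tested bulls with
  large, heterogeneous daughter groups.  The weight law is a free choice (no
  reliability distribution is available to copy) and is config-exposed.

What the simulator does *not* emulate: coalescent-realistic LD (founder loci
are drawn independently, so population-level LD arises only from the
pedigree), selection within the breeding program, genotyping error, the X
chromosome, and the national-evaluation deregression machinery that produces
real DRPs.  Passing recovery tests therefore demonstrates that the
estimators are consistent under the model they assume, not that real dairy
data would give the same shares.

## Validation sizes

The test suite validates each stage at sizes a desk machine handles in
minutes, chosen as the smallest instances at which the checks are
informative: exact oracles on hand-sized fixtures; REML against a
closed-form balanced ANOVA and a dense likelihood grid at `n = 20`;
parameter recovery over 20 seeded replicates at `n = 1000` — the population
whose realized component variances the generator pins to their targets is
exactly the phenotyped one (5000 markers for the genomic model, 2000 for the
joint model); the chromosome scan over 10 planted-architecture seeds on a
6-chromosome genome at `n = 450`; and the accuracy curve at panel sizes
250–4000 from an 8800-marker pool.

## Limitations

Single-trait only; variance components and their ratios, not BLUP breeding
values or prediction accuracy; no one-step blended pedigree–genomic matrix
(only the `adjust_G()` rescaling on the genomic side); dense algebra only.
The interface is R functions plus a YAML-driven `run_pipeline()` — a thin
command-line wrapper would add nothing the config file does not already
provide.
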