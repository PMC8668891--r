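---
title: "Three-population demographic inference with coalescent simulation and ABC random forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-population demographic inference with coalescent simulation and ABC random forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abctrio)
```

## The inference problem

`abctrio` asks two questions about a trio of closely related species sampled
at anonymous short loci (RAD-seq style data): (1) is gene flow between the
two sister species P1 and P2 ongoing, or was it confined to the early epoch
after their split (current isolation)? and (2) does either sister species
exchange migrants with the more distant third species P3? The motivating
system is a trio of sympatric *Morpho* butterflies (*M. helenor* = P1,
*M. achilles* = P2, *M. deidamia* = P3), but nothing in the package is
specific to it beyond defaults that match that dataset's shape: 10/13/8
sequenced diploid males (20/26/16 phased allele sequences), 2,740 polymorphic
biallelic loci of 343-908 bp.

Because full-likelihood inference is intractable for this model class, the
package uses approximate Bayesian computation with random forests (ABC-RF):
datasets are simulated under each candidate scenario, reduced to a fixed
summary-statistic vector, and a random-forest classifier/regressor trained
on those simulations is applied to the observed vector.

## The generalist demographic model

Backward in time, an ancestral population splits at `T_split123` generations
into the P3 lineage and the common ancestor of P1/P2, which splits again at
`T_split12 <= T_split123`. Each split is accompanied by a size change drawn
independently of the ancestral size, and each modern lineage additionally
changes size once at an independent time (`T_change_i`), reflecting the
strongly negative Tajima's D typical of recent demographic change. Migration
can connect every pair of contemporaneous populations at scaled rates 4Nm.

Eight scenario categories arise from crossing:

* **inner flow** (P1-P2): `AM` -- ancestral migration, active only on
  `[T_trans12, T_split12]`, so no present-day flow; `SC` -- secondary
  contact, active only on `[0, T_trans12]`, i.e. ongoing today;
* **outer flow** (with P3): `SI` (none), `GF13`, `GF23`, `GF1323`.

To keep the two inner categories from collapsing into each other when
`T_trans12` approaches 0 or `T_split12`, the transition time is drawn as a
Beta-distributed fraction of `T_split12`: Beta(5, 1) under `AM` (transition
near the split, long migration epoch) and Beta(1, 5) under `SC` (recent
contact). Each category is represented by four sub-models that allow or
disallow genomic heterogeneity of effective size and of migration rate,
giving 32 simulated models whose labels are pooled to the 8 categories for
model choice.

### Priors and units

All internal units are diploid individuals and generations. Defaults:

| parameter | prior | units |
|---|---|---|
| all population sizes | U[0, 1e6], resampled below 10 | diploid individuals |
| `T_split123` | U[0, 8e6] | generations |
| `T_split12` | U[0, `T_split123`] | generations |
| `T_change_i` | U[0, origin of lineage i] | generations |
| `T_trans12 / T_split12` | Beta(5,1) (`AM`) / Beta(1,5) (`SC`) | -- |
| 4Nm (each enabled pair) | U[0, 50] | scaled migrants |
| mutation rate | 3e-9 | /bp/generation |

The resampling floor of 10 diploids exists because the coalescent degenerates
as N tends to 0; it removes a prior sliver of width 1e-5 and is the package's
own regularisation, not part of the biological model. Size-change times of
the modern sister lineages are bounded by `T_split12` (and `T_change_P3` by
`T_split123`): a lineage cannot change size before it exists.

### Linked-selection heterogeneity

Under heterogeneous sub-models each locus gets multiplicative factors:
effective sizes are scaled by a Beta(a, b) variable rescaled to mean 1
(so the genome-wide average Ne is preserved), migration rates by a
Beta(a, b) variable on [0, 1] (linked selection can only reduce effective
gene flow). The shape hyperpriors have no canonical values in this model family;
the package draws both shapes uniformly on [0, 20] (resampling
until at least one shape is >= 0.1 to avoid a numerically degenerate Beta),
following the convention of the DILS family of pipelines. Whether ancestral
populations are also rescaled is equally unspecified; the package applies a
locus's Ne factor to every epoch of that locus, which keeps the factor a
property of the genomic region rather than of an epoch.

## The coalescent simulator

The structured coalescent is implemented in C++ with continuous time in
generations. Pairwise coalescence in a population of N diploids occurs at
rate 1/(2N); a scaled rate M = 4Nm between demes a and b moves a lineage
currently in a to b at backward rate M/(4 N_a(t)), with N_a(t) the current
epoch's size of the lineage's own deme. Per-locus Ne heterogeneity
rescales the coalescence denominator only: linked selection changes local
drift, while the fraction of migrant ancestry is modelled separately by the
locus's migration factor. (This also keeps the event rate bounded — scaling
the migration denominator by a near-zero Ne factor would let a single
lineage shuttle between demes at arbitrarily high rates while waiting for an
absolute split boundary.) Epoch boundaries (size
changes, migration transitions, splits) are half-open, the boundary instant
belonging to the older epoch. Between `T_split12` and `T_split123` the
merged P1/P2 ancestor exchanges migrants with P3 at the combined rate
`M13 + M23` whenever either pair is enabled, so that outer gene flow spans
the whole coexistence window of the two ancestral demes. There is no
intralocus recombination: RAD loci are a few hundred bp, short enough for
this to be the standard approximation.

Two mutation modes are provided, both infinite-sites with the ancestral
state fixed by the simulation (root state 0, which makes ABBA-BABA
polarization exact in simulations):

* **theta mode**: mutations are a Poisson process along branches with
  intensity `mu * L_i` per generation, so the expected number of segregating
  sites is driven by theta = 4 N mu L_i through the realised branch lengths.
  Loci with zero mutations are *excluded*, not re-simulated -- mirroring the
  conditioning of the observed data, where the assembler only reports
  polymorphic loci; re-simulation would distort the tree-length distribution.
* **fixed-SNP mode**: exactly `S_obs` mutations are placed, each landing on
  a branch with probability proportional to its length, independently per
  site. This conditions each simulated locus on the observed SNP count
  (1-91 in the motivating dataset) and removes the monomorphic-locus
  asymmetry between simulation and observation.

If a theta-mode draw would produce more mutations than base pairs (possible
only under extreme parameter corners), the count saturates at `L_i` so that
sites can keep distinct integer positions; this is a finite-sites guard, not
a model feature.

## Summary statistics

Each locus is reduced to 33 statistics: per-species nucleotide diversity,
Watterson's theta and Tajima's D; per-pair gross divergence `d_xy`, net
divergence `d_a`, and FST; per-pair counts of shared polymorphisms, fixed
differences and exclusive polymorphisms; and the per-locus ABBA-BABA
numerator, denominator and D with populations ordered (P1, P2, P3). A
dataset is the vector of means and population standard deviations (divide
by the number of loci) of these across loci, plus the dataset-level D (ratio
of summed numerators to summed denominators) -- 67 entries.

Two conventions are deliberately fixed because the source material leaves
them open:

* **FST estimator**: `1 - pi_within / pi_total` with `pi_within` the
  unweighted mean of the two within-species diversities and `pi_total` the
  pooled-sample diversity. A Hudson-style `1 - pi_within / d_xy` variant is
  available via `fst(..., estimator = "hudson")`. The same estimator is
  applied to observed and simulated data, so model choice is insensitive to
  the convention; absolute FST values are not.
* **Missing values**: statistics undefined at a locus (Tajima's D with
  S = 0 in that species, FST for a pair monomorphic in the pooled pair,
  per-locus D with a zero denominator) are excluded from that statistic's
  mean/SD, never imputed. If a statistic is missing at *every* locus the
  aggregate is recorded as 0 so that reference tables stay complete; this
  occurs only for near-degenerate parameter draws.
* **Polarization of observed data**: simulations know the ancestral allele;
  real data without an outgroup do not. `read_loci_fasta()` defaults to
  treating the pooled major allele as ancestral (ties broken
  alphabetically), which is an approximation that attenuates D towards 0
  but leaves frequency-symmetric statistics untouched. The
  `ancestral_base` option gives exact round trips for simulated data.

## Random-forest inference

Model choice trains a 500-tree classification forest (the `ranger` engine)
on the reference-table statistics. The two gene-flow questions are answered
independently on pooled labels -- binary `AM` vs `SC` for question 1,
four-way outer-flow for question 2 -- rather than as one 8-way problem,
because each question pools 16 sub-models' simulations and is easier than
the joint problem; the combined winner is reported as the winning category.
The posterior probability of the winner follows the abcrf construction: a
second regression forest is fitted to the indicator that the classifier's
out-of-bag prediction was correct, and its prediction at the observed vector
estimates P(correct allocation | data). Out-of-bag classification error is
always reported. Forest size (500 trees) and mtry follow the abcrf/ranger
defaults; both are exposed as arguments.

Parameter estimation fits one quantile-regression forest per parameter on
the winning category's rows (its four sub-models pooled -- the same pooling
used for model choice) and reports the point prediction with a central 90%
interval from the tree quantiles. With `normalize = TRUE` sizes are reported
relative to the estimated current P1 size (N_P1 = 1 exactly by construction)
and times in coalescent units of 4 N_P1 generations; the conversion between
natural and relative units uses the mutation rate only through the
simulations themselves.

A posterior predictive check simulates replicate datasets at the point
estimates and reports two-sided tail probabilities of each observed summary
statistic within the replicate distribution.

## The synthetic-data generator

`generate_pseudo_observed()` produces datasets with known ground truth in
the same FASTA/VCF dialects the reader accepts, plus a key-value sidecar
sufficient to regenerate the dataset byte-identically. Locus lengths are
drawn uniformly within the preset bounds by default; the observed mean
length (463.12 bp) is not compatible with a uniform on [343, 908], so a
truncated-geometric option that matches the mean is provided, with uniform
kept as the default for its simplicity. Pseudo-observed SNP counts arise
from theta-mode simulation rather than being imposed, so the fixed-SNP
inference mode can be exercised against data whose counts it must match.

What the generator does *not* emulate: sequencing error, missing data,
paralogous assembly artefacts, reference bias, intralocus recombination and
selection. Passing recovery tests on synthetic data therefore demonstrates
the internal consistency of the pipeline -- that the inference machinery
recovers what the simulator encodes -- not robustness to those real-data
complications.

## Validation scales and numerical choices

The package's own validation (test suite and `scripts/acceptance.R`) runs
the full design at a reduced scale chosen to keep a complete run on a single
CPU in the tens of minutes: 2,000 simulations per scenario category
(sub-models pooled, i.e. 500 per sub-model) with 300 loci per dataset and
the study's sample sizes (20/26/16 sequences), against the full scale of
the motivating analysis (50,000 simulations per model, 2,740 loci). At this scale the binary
question reaches held-out accuracy near 0.9 (chance 0.5), the four-way
question likewise near 0.9 (chance 0.25), and the rank correlation between
true and estimated `log T_split123` under strict isolation exceeds 0.99.
Accuracies improve with table size, so these figures are conservative
relative to a full-scale run; the misclassifications that do occur
concentrate between categories differing only in the partner of the P3 gene
flow, or where the transition time sits near the category boundary.

Other numerical conventions: all randomness flows through R's RNG (the C++
simulator consumes `unif_rand`), so a single integer seed makes an entire
analysis reproducible bit-for-bit, including forest training; per-locus
statistics are computed in C++ from derived-allele counts and are tested to
1e-12 against brute-force R oracles; reference-table rows whose simulated
dataset is entirely monomorphic (possible in theta mode under tiny-theta
draws) are redrawn, with an error if such failures exceed 1% of the
requested simulations.

## Known limitations

* Absolute parameter values are weakly identified when monomorphic loci are
  excluded; relative reporting (N_P1 = 1) is the intended output.
* The model space is the eight categories described above; cyclic
  contact-isolation histories and more than three populations are out of
  scope, and a win for "current isolation" within this set does not exclude
  a better fit by an untested intermediate model.
* The `AM`/`SC` boundary remains intrinsically fuzzy for transition times
  near 0 or `T_split12` despite the Beta priors; misclassifications
  concentrate there.
* Heterogeneity hyperpriors are a convention (see above); inference about
  the *presence* of heterogeneity is deliberately not exposed as a result,
  the sub-models existing only to make category-level inference robust.

## A worked example at miniature scale

```{r, eval = FALSE}
library(abctrio)

specs <- make_locus_specs(locus_preset(n_loci = 300), rng_seed = 1)
tab <- build_reference_table(enumerate_models(), 100, specs,
                             n_seq = c(20, 26, 16), rng_seed = 2)

pod <- generate_pseudo_observed("AM.SI", "NeHet.MHom",
                                locus_preset(n_loci = 300), rng_seed = 3)
obs <- dataset_summary(dataset_stats(pod$dataset))

h <- hierarchical_inference(tab, obs, rng_seed = 4)
h$category          # combined winning category
h$question1         # AM vs SC with posterior and OOB error

est <- estimate_parameters(tab, obs, category = h$category,
                           normalize = TRUE, rng_seed = 5)
est                 # sizes relative to N_P1 = 1, times in 4*N_P1 units
```
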