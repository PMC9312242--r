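---
title: "Microsatellite development and population genetics: models and methods"
author: "ssrpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite development and population genetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrpopgen)
```

ssrpopgen reimplements, as one coherent and tested pipeline, the
computations behind a microsatellite-based survey of wild fish populations:
genome-wide SSR mining, primer-constraint screening, per-locus diversity
statistics, AMOVA differentiation with permutation tests, distance-based
clustering, and a lightweight admixture model. This vignette explains the
models, the parameters that matter, the numerical choices, and what the
synthetic-data validation does and does not demonstrate.

## SSR mining

A perfect microsatellite is a maximal uninterrupted run of a 2–5 bp motif.
`find_ssrs()` compares each base with the base one period downstream and
extracts maximal match runs, so a tract can neither be extended by one
motif-phase base nor shortened without losing a full repeat unit. Only
complete units are counted (`end − start = period × n_repeats`), mirroring
MISA's convention. Reported motifs are primitive: an `(ACAC)` hit is the
period-2 tract `AC`, which also guarantees one report per tract when a run
qualifies under a multiple of its true period.

Motifs are grouped into canonical classes under cyclic rotation and reverse
complementation (`canonical_motif()`); there are exactly four dinucleotide
classes (AC, AG, AT, CG) and at most 33 tetranucleotide classes. Default
repeat-count thresholds are at least 5/4/3/2 units for periods 2/3/4/5.
The criterion phrase "more than five dinucleotide repeats" in marker-
development protocols is ambiguous between strict and inclusive; ssrpopgen
reads it inclusively (≥ 5) and exposes every threshold as a parameter. The
markers this matters for in practice carry 10–20 units, so downstream
statistics are insensitive to the choice. Mononucleotide and hexanucleotide
runs, and compound or interrupted repeats, are deliberately out of scope:
only perfect tracts are reported. `N` (or any non-ACGT base) terminates a
run; soft-masked lowercase is uppercased first. Coordinates are 0-based
half-open internally and 1-based inclusive in TSV exports (stated in the
file header).

## Primer screening

Marker candidates are screened against constraint windows rather than
redesigned: product length 50–500 bp, primer length 18–30 nt, melting
temperature 52–65 °C by default (`screen_constraints()`). All constraints
are evaluated and violations enumerated, so screening is monotone: widening
a window can never turn a pass into a fail. Primer *design* (objective
functions, dimer/hairpin thermodynamics) is not reimplemented.

`melting_temp()` uses the nearest-neighbor model with the SantaLucia
unified parameter set, terminal A/T and G/C initiation corrections, the
symmetry correction for self-complementary oligos, and the entropic salt
correction `0.368 (N−1) ln[Na⁺]`. Published screening protocols rarely
state their Tm conditions, so the defaults — 50 mM monovalent salt, 250 nM
total strand, CT/4 — are declared as this package's choice, not inferred as
anyone else's; both are arguments, and a Wallace 2+4 rule is available for
quick checks. Degenerate bases are rejected rather than expanded.
`in_silico_pcr()` is exact-match only: it validates planted amplicons and
fixture genomes, not mispriming behaviour.

## Genotypes and allele frequencies

`genotype_matrix` stores, per individual, a population label and an
unordered pair of positive integer allele codes per locus — conventionally
fragment sizes in bp, as reported by capillary electrophoresis. Missing
calls are `NA` in both slots, never an ambiguous 0. GenePop files are read
and written with 3-digit allele fields: sizes up to 999 bp are encoded
verbatim, so files round-trip without a recoding table. Statistics use the
per-locus complete-case sample size `n`, the convention of the classic
desktop packages; the missing-data rate of the emulated survey is unstated
in its report, so the generator default (2%) is a typical
capillary-genotyping failure rate.

## Diversity statistics

With allele frequencies `p_i` at one locus and `n` complete cases:
`Na` counts observed alleles; `Ne = 1/Σp_i²` (Kimura–Crow) is the allele
number of an equifrequent locus with the same homozygosity; `Ho` is the
observed heterozygote fraction; `He = (2n/(2n−1))(1 − Σp_i²)` is Nei's
unbiased expected heterozygosity; `PIC = 1 − Σp_i² − Σ_{i<j} 2p_i²p_j²`
(computed via `(Σp²)² − Σp⁴` rather than the double loop). The unbiased
form of He is fixed as the default because the identity
`He = (2n/(2n−1))(1 − 1/Ne)` reproduces, to the printed 3 decimals, the
He column of the bundled reference table from its Ne column at n = 268 —
direct evidence that this is what the original desktop software computed.
The biased form `1 − Σp²` is available by flag. Published tables print 3
decimals with half-up rounding, so `round_half_up()` is used whenever
output mirrors them (R's own `round()` is half-even).

The Hardy–Weinberg test is a Monte-Carlo exact test: conditioning on the
observed allele counts, the allele pool is randomly re-paired `n_mc` times
and the p-value is the fraction of tables no more probable than the
observed one, with the observed table included in numerator and denominator
so p is never 0. An exact test is used rather than chi-square because
microsatellite loci here carry up to 29 alleles and chi-square cells are
hopelessly sparse. Probability comparisons use a 1e-9 log-scale tolerance
so floating-point ties count as ties. How the emulated survey counted
HWE departures per population (its 8/7/8/4 loci) is unstated; the default
here is per-locus α = 0.05 uncorrected, with `p.adjust` methods (e.g.
sequential Bonferroni) as an option.

## Differentiation

`amova()` partitions the allele-mismatch distances among the `2N` gene
copies of the dataset into among- and within-population components, the
convention of the standard AMOVA software for codominant data — visible in
its degrees of freedom (`P−1`, `2N−P`, `2N−1`), which this implementation
reproduces. The squared distance between two copies is the number of loci
at which their alleles differ; loci missing in either copy are skipped
pairwise. Unequal sample sizes enter through
`n′ = (2N − Σ(2N_k)²/2N)/(P−1)`, and `Fst = σ²_a/(σ²_a + σ²_w)`.
An individual-level variant of the distance matrix (optimal allele matching
between genotypes) is exported as `genotype_distance_matrix()` for
exploratory use, but the variance decomposition itself is done at the copy
level: on Balding–Nichols simulations the copy-level estimator recovers the
simulated divergence essentially unbiasedly, while the individual-level
matching distance overstates it.

Permutation p-values permute whole individuals among populations (sizes
preserved; the two copies of an individual move together, so
within-individual structure is untouched) and use the `(b+1)/(m+1)`
correction. Negative among-population components are reported as-is with a
warning — standard AMOVA practice — and only floored at zero for Wright's
classification bands (<0.05 low, 0.05–0.15 moderate, 0.15–0.25 high,
≥0.25 very high, left-inclusive). Stepwise-mutation (Rst) models and
three-level hierarchies are out of scope.

## Distance and clustering

`nei_distance()` implements Nei's (1972) standard distance: the identity
probabilities `J_xy`, `J_x`, `J_y` are averaged across loci first and the
logarithm applied once. Populations sharing no alleles anywhere give an
explicit `Inf` flag rather than an error. `upgma()` is classic
size-weighted UPGMA built on `stats::hclust(method = "average")` and
returned as an `ape` tree; node height is half the merge distance, so the
tree is ultrametric and cophenetic distances reproduce ultrametric inputs
exactly. Ties in merge order follow `hclust`'s deterministic internal
ordering; with real-valued distances ties essentially never arise.
Bootstrap support is not offered because a published distance matrix has no
resampling unit.

## The admixture model

`fit_admixture()` is a deliberately simplified ("structure-lite")
Pritchard-style admixture model: each of the `2NL` allele copies carries a
latent cluster label; a Gibbs sampler alternates assignments given (Q, P),
cluster allele frequencies P given assignments (Dirichlet posterior,
uniform prior `lambda = 1`), and memberships Q given assignments
(Dirichlet with fixed admixture parameter `alpha`). Q and P are posterior
means over sampled sweeps, and `mean_lnP` is the average observed-data
log-likelihood under the sampled (Q, P). Missing copies are marginalized.
The sampler is compiled (Rcpp) and draws from R's RNG stream, so runs are
bit-reproducible under a seed. The correlated-allele-frequencies and
linkage models of the full software are intentionally omitted.

`alpha` is fixed rather than sampled — the simplification that gives the
model its name — and defaults to 0.1. The full samplers infer `alpha` and
converge to roughly 0.02–0.2 on non-admixed wild populations; a flat
`alpha = 1` adds a pseudo-copy to every cluster and measurably drags the
membership of clearly assigned individuals toward uniform at typical locus
counts (on three well-separated simulated populations it caps mean
self-membership near 0.86 even though a supervised classifier with the
true frequencies assigns individuals perfectly). Fixing a small `alpha`
emulates the inferred-alpha behaviour without the extra sampling machinery;
it remains a user argument for admixed scenarios.

Chain lengths default to 2,000 burn-in and 10,000 sampling sweeps — enough,
at tens of loci and a few hundred individuals, for the likelihood trace to
plateau well before sampling begins; production analyses mirroring the
classic 50,000/100,000 settings just pass larger values. `evanno_delta_k()`
computes `ΔK = |L(K+1) − 2L(K) + L(K−1)|/SD(K)` over replicate runs
(undefined and flagged at zero SD, defined only for interior K) and
`run_k_scan()` wires the replicate runs together. Because the original
survey published no likelihood values, its best-K (3 clusters) is a
qualitative, not numeric, reference point.

## Synthetic data: what it emulates, and what it does not

`simulate_genome()` plants perfect SSR tracts and primer-delimited
amplicons into i.i.d. background sequence at a chosen GC content. Guard
bases prevent a planted tract from extending by a motif-phase base, and the
neighbourhood of each feature (two periods on each side) is
rejection-sampled free of accidental SSRs, so truth coordinates are exact;
background farther away may still contain chance repeats, which the truth
table deliberately excludes. Infeasible packings raise an error rather than
silently truncating.

`simulate_genotypes()` draws from the Balding–Nichols island model:
ancestral frequencies Dirichlet-uniform, population frequencies
`Dirichlet(p (1−F)/F)` so `F` is the expected differentiation, individuals
as two independent copies (HWE within populations), calls masked at the
missing rate. Defaults mirror the emulated survey: four populations of
34/77/68/89, 29 loci, 12 ancestral alleles (the survey's mean allele count),
F = 0.074 (its reported global Fst), allele codes on a 4-bp fragment-size
ladder starting between 86 and 150 bp. Balding–Nichols was chosen over a
coalescent simulator because it gives an analytic handle on expected Fst
with no external dependencies.

What passing simulation tests shows: the estimators recover known
parameters under the model's assumptions (unlinked loci, HWE within
populations, no null alleles, no genotyping error, island-model
differentiation). What they do not show: robustness to stepwise-mutation
homoplasy, null alleles, linkage, or inbreeding — real microsatellite
datasets violate all four to varying degrees, and the bundled reference
tables are the only contact with real data in this package.

## Validation scales and reproducibility

The test suite validates the miner against a naive per-position oracle on
one hundred 5 kb planted genomes; AMOVA against an explicit pair-loop
oracle and against simulated truth (F = 0.10 recovered within ±0.04 on one
hundred survey-sized replicates); the permutation test for uniformity under
the null (200 replicates of two 20-individual populations, 199 permutations
each); the HWE test for its type-I error (200 HWE loci); and the admixture
model for cluster recovery and Evanno best-K (five experiments of three
50-individual populations at F = 0.2, K scanned 1–5 with two runs each at
the default chain lengths). These sizes keep the full suite to a few
minutes on one CPU while leaving each check statistically meaningful; all
stochastic tests run under fixed seeds, and `scripts/acceptance.R`
re-derives the headline numbers from scratch under a caller-supplied seed.

## Known limitations

Imperfect/compound repeats, Rst-style mutation models, allelic-richness
rarefaction, null-allele estimation, linkage disequilibrium, hierarchical
(3-level) AMOVA, correlated-frequency admixture and CLUMPP-style multi-run
Q averaging are all out of scope. The GenePop writer requires allele codes
≤ 999. The admixture model's fixed `alpha` is a modelling simplification:
strongly admixed individuals are better served by software that samples it.
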