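---
title: "Models and methods behind lupuspg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lupuspg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lupuspg` re-implements, as one coherent toolkit, the genotype-level
inference stack used to study admixture, inbreeding and genetic load in
structured wolf populations. This vignette explains the models behind
each stage, the parameters that matter, what the built-in simulator does
and does not emulate, and the numerical choices made where the design was
genuinely open.

## The cohort data model

All stages operate on a `cohort`: biallelic SNPs for a fixed diploid
panel, with 0-based half-open coordinates internally (VCF I/O converts
to 1-based POS). Missing genotypes are excluded from every
allele-frequency denominator. Read-depth filters of upstream
variant-calling pipelines have no genotype-level analogue, so
`filter_spec()` exposes site-quality, missingness and minor-allele-count
knobs instead; the simulator can plant missingness so these filters are
exercisable. An optional one-sided exact Hardy-Weinberg test against
heterozygote excess is available as a filter predicate; it is applied
cohort-wide because the population scope of such filters is a
study-design choice, not a property of the statistic.

## The coalescent simulator

`simulate_cohort()` draws structured-coalescent genealogies with
population splits, pulse admixture and piecewise-constant sizes
(compiled to a backward-time event list for the C++ engine) and drops
infinite-sites mutations on the branches. Recombination is approximated
by partitioning each chromosome into 25 kb blocks that recombine freely
between and not within — each block carries a single genealogy. This
block approximation matches the independence structure the downstream
analyses assume (window trees, jackknife blocks, unlinked SFS blocks)
and keeps desk-scale runs in seconds; it does not reproduce the
continuous decay of linkage disequilibrium within blocks, background
selection, or gene conversion. Deleteriousness is annotation-only
(`assign_impact_annotations()` draws categories at fixed proportions):
load analyses on simulated data are accounting checks, not selection
tests, and nothing in a passing test implies the simulator captures
selective dynamics of real genomes.

`default_wolf_model()` encodes the three-lineage study system: Indian
divergence at 100 ky, Tibetan at 80 ky, a southwest-Asian population
splitting from the Holarctic/central stock at 10.3 ky, a 0.11 pulse of
Indian ancestry into southwest Asia at 6 ky (all divided by the 4.4-year
generation time), mutation rate 4.5e-9 per bp per generation, and mean
recombination 1.34 cM/Mb. Two outgroup populations split 2.5 and 3.0 My
ago anchor polarization, emulating the role of distant canids. Effective
sizes (3,000 for the Indian and Tibetan lineages, 5,000 for southwest
Asia, 20,000 for the Holarctic stock and ancestors) are
order-of-magnitude defaults expressing "small southern, large northern"
population structure; they are fields of the model object, not claims.
The default genome is 10 chromosomes of 5 Mb — large enough for stable
block-jackknife and window statistics, small enough that a full
simulate-analyse cycle takes seconds.

## D statistics

Sites are polarized by the P4 outgroup consensus: the majority allele
among non-missing P4 calls is ancestral; sites where P4 is polymorphic,
tied, or uncalled are skipped (deterministic, no random tie-breaks).
The frequency-based ABBA/BABA contributions are accumulated in genomic
blocks (5 Mb default — a common jackknife scale; the block length is a
parameter) and the standard error is a delete-one-block jackknife
weighted by the number of informative sites per block, following the
unequal-block-size formulation. The sign convention is fixed so that an
excess of derived sharing between P2 and P3 gives negative D; tools
differ on this, so the package pins the observable behaviour. Both
population-frequency and single-individual quartets are supported
(single-sample frequencies are then 0, 1/2 or 1).

## Topology weighting

Window trees are neighbor-joining on haplotype p-distances
(pairwise-complete proportion of differing sites). For 100-SNP windows
NJ recovers local topologies reliably and is deterministic; tips are
sorted lexicographically before the NJ call so zero-distance ties cannot
depend on input order, and zero-length internal branches are collapsed
to honest multifurcations. This replaces maximum-likelihood window trees
(e.g. GTR in phyml): the weighting consumes topologies only, and at this
window size the substitution model is immaterial.

Weighting is exact: the full Cartesian product of one tip per group is
enumerated (capped at 1e6 combinations), each choice's induced topology
read directly off the gene tree's bipartitions, and matched to the
catalog of all `(2k−5)!!` leaf-labeled unrooted topologies by canonical
split signature. An unresolved (multifurcating) choice is distributed
equally over all compatible catalog topologies, preserving the sum-to-1
invariant without arbitrary resolution. Terminal windows with fewer than
100 SNPs are dropped and counted.

Stratification by recombination rate uses bp-overlap-weighted window
means against a BED4 map; the boundary values join the medium stratum
(low `[0, 0.2)`, medium `[0.2, 2]`, high `(2, ∞)` cM/Mb), matching the
printed "0.2–2" label of the medium class.

## Runs of homozygosity

The caller is a two-state HMM: state AZ (autozygous) emits
heterozygotes at an error rate (1e-4), state HW emits them at
`2 f (1−f)` with `f = 0.4` fixed — the default of the genotype-based ROH
callers this follows. Genotype-likelihood emissions are simplified to
hard genotypes, and the per-site transition probability is constant
(default 1e-5), optionally scaled by inter-site genetic distance when a
recombination map is supplied. Segments are maximal runs of AZ posterior
above 0.5, extended to the midpoint between flanking sites, and filtered
at 100 kb length and quality 80.

Quality is the mean per-site phred score of the AZ posterior, capped at
99 per site. Two numerical points matter here. First, phred-transforming
the *mean posterior* instead would be dominated by a handful of boundary
sites and could never reach 80 on real segments, so the per-site mean is
used. Second, the posterior's per-site phred ceiling is set by the
transition probability (approximately `−10 log10(τ² · 0.52)`); at
τ = 1e-4 that ceiling is ~83 and even perfect planted tracts average
below the quality-80 filter, which is why the default is τ = 1e-5
(ceiling above the cap; clean tracts score ~95). Both parameters are
exposed in `hmm_params()`.

Inbreeding timing uses `g = 100/(2 r L)` with the genome-wide mean rate
(1.34 cM/Mb by default): the expected age in generations of the
inbreeding loop that produced a ROH of length `L` Mb. The formula
assumes a uniform recombination rate, so outputs are estimates; a 5 Mb
ROH dates to ~7 generations.

## Diversity and inbreeding

Heterozygosity is `n_het / n_callable` per individual. The inbreeding
coefficient is a moment estimator, `F = 1 − observed/expected`
heterozygous sites, with allele frequencies taken from the focal
individual's population *excluding the individual itself* and the
unbiased per-site expectation `2p(1−p)·n/(n−1)` (with `n` the number of
reference alleles): without the correction, small reference panels bias
F upward noticeably. This genotype-level estimator stands in for
likelihood-based identity-by-descent estimators used on low-coverage
data; the two agree in rank, which is what the downstream comparisons
use.

## Genetic load

Polarization keeps exactly the sites where the two pseudo-haploidized
outgroups carry the same allele; that allele is ancestral and the
derived allele is assumed deleterious at annotated sites. Each outgroup
contributes one allele per site drawn uniformly from its pooled
non-missing calls — for a single-genome outgroup this is precisely
"homozygous → that allele, heterozygous → coin flip". Sites whose agreed
allele matched neither cohort allele would be dropped; in the biallelic
data model this case cannot arise but the accounting logs it.

Loads are counted in *alleles* by default (2 per homozygous-derived
site, 1 per heterozygous), which makes
`total = realized + masked` an exact identity; a per-site variant
(`units = "sites"`) is provided because figure axes in the literature are
ambiguous between the two. Normalized rates divide each category's
derived-allele count by the MODIFIER (assumed-neutral) count × 100,000,
and are flagged undefined when an individual carries no neutral derived
alleles. The drift prediction tested on simulations — bottlenecked
populations show more realized and less masked load — is a genotype
redistribution effect and needs no selection to hold.

## SFS construction and model comparison

The folded 3D SFS is built per 2 Mb block: within each block the
requested numbers of individuals per population (3/6/9 diploids by
default) are chosen to minimize within-block missingness (ties by sample
order), and only SNPs complete in that selection are retained, so every
block contributes complete data at fixed sample sizes. Folding merges
each joint cell with its complement; exact half-frequency ties are keyed
by the lexicographically smaller cell index. Retained sites monomorphic
in the subsample feed a separate monomorphic count. A companion spectrum
keeps one uniformly chosen SNP per block for the unlinked-likelihood
recomputation.

Three histories are compared for the origin of the southwest-Asian
population: (A) pure divergence, (B) divergence plus an Indian→SWAsia
pulse (`alpha`, `T_intro < T_sw`), and (C) a hybrid founding event in
which a fraction `h` of the founding ancestry is Indian, implemented as
a pulse immediately preceding the founding split. Expected spectra are
obtained by simulating unlinked loci under the candidate model
(matching the simulation-based strategy of SFS fitters), with a
pseudocount of `1/(10 n_loci)` on empty cells before normalization.
The composite log-likelihood `Σ m log p` over polymorphic cells drives a
seeded coarse log-grid search plus Nelder-Mead refinement (Brent in one
dimension) on the log-parameter scale; every evaluation reuses one
simulation seed (common random numbers), so fits are deterministic given
seed and budget. Because composite likelihoods on linked SNPs are valid
for point estimation but not for model comparison, the likelihood is
recomputed at the optimum on the unlinked spectrum and
`AIC = 2k − 2 lnL_unlinked`; Akaike weights
`exp(−ΔAIC/2)/Σ exp(−ΔAIC/2)` give each model's relative likelihood.
Default free parameters are the SWAsia–Central split time plus, per
model, the pulse parameters; sizes and the deep Indian split are fixed
at desk scale and exposed in `sfs_model_spec()`.

## Pipeline and reproducibility

`run_pipeline()` executes the enabled stages in dependency order,
derives every stage seed from the one global seed, writes plain TSVs
with commented `#key=value` headers, and records versions, seeds,
parameters and input checksums in `manifest.json`. One stage failing is
recorded and does not abort the others. No output contains timestamps,
so identical config + seed reproduce every output byte for byte
(wall-clock information goes to the log only, which is excluded from
that guarantee).

## Problem sizes used by the test suite

The packaged checks run on simulated cohorts sized for a desk: 10 × 5 Mb
genomes for D-statistic calibration (100 null replicates; 20 replicates
at pulse fraction 0.11), ROH recovery (20 replicates, three planted
tracts each) and SFS model data; 1e5 unlinked loci for the neutral-SFS
law; 10 replicates each for model-selection power and split-time
recovery with ~4,000 loci per likelihood evaluation. These sizes were
chosen so the full suite completes on one CPU while leaving the
statistical margins comfortable; all are parameters, not constants.

## Known limitations

* The block-recombination approximation leaves no within-block LD decay;
  analyses that depend on fine-scale LD (e.g. haplotype-based dating)
  are out of scope.
* No selection in the simulator: genetic-load results on simulated data
  validate the accounting, not evolutionary dynamics.
* Genotype-level only — no genotype likelihoods, no BAM/FASTQ handling;
  low-coverage workflows should pre-call genotypes upstream.
* The SFS fitter's search is a coarse grid plus local refinement with a
  fixed budget, adequate for the three desk-scale models; it does not
  replicate the ECM machinery of dedicated SFS fitters, and confidence
  intervals on parameters are not provided.
* When the introgression pulse falls close to the population split — as
  it does in the default wolf history — the introgression (B) and
  hybrid-origin (C) models are nearly likelihood-equivalent on data
  generated under B, and the hybrid model's smaller parameter count can
  carry the AIC comparison. Discriminating B from C therefore needs far
  more unlinked sites than a desk-scale genome provides; B versus the
  pure-divergence model A is well separated at 50 Mb.
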