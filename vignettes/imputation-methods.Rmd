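---
title: "Genotype imputation and genomic prediction in multi-breed sheep: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype imputation and genomic prediction in multi-breed sheep: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ovimp)
```

# Scope

`ovimp` studies a practical question in sheep genomic evaluation: animals are
genotyped cheaply on a low-density (~12k) SNP array, their genotypes are
imputed up to the medium-density (~50k) panel used by the national
evaluation, and GBLUP breeding values are estimated from the imputed data.
How accurate is that imputation in purebred Merinos and in Merino crossbreds,
how does it depend on the size, breed composition and *relatedness* of the
imputation reference set, and how much genomic-prediction accuracy is lost
when imputed rather than observed genotypes enter the relationship matrix?

Because the original resource-flock genotypes are proprietary, the package
pairs every analysis component with a synthetic multi-breed population
generator that reproduces the *structure* those analyses rely on: diverged
breeds, F1 crosses onto Merino ewes, large half-sib families connected
across flocks by shared AI sires, a nested low/medium-density panel pair,
and phenotypes with additive, maternal, breed and fixed effects. All
quantitative claims the package makes are therefore claims about this
synthetic population; the qualitative trends — not the published values from
any particular flock — are what the test suite checks.

# The synthetic population

**Breed divergence.** Per-marker ancestral allele frequencies are uniform on
a configurable range (default 0.05–0.95). Each breed's frequency is drawn
from the Balding–Nichols model, Beta(p(1−F)/F, (1−p)(1−F)/F), which has mean
p and variance F·p(1−p); F is the fixation index Fst (default 0.15, a
deliberate over-separation relative to real sheep breeds so that
across-breed imputation contrast is visible at desk scale). Fst = 0 returns
the ancestral frequency exactly.

**Pedigree structure.** Founders are drawn in Hardy–Weinberg proportions
within breed. Purebred progeny are produced in flocks; each flock's sire
slots are filled partly from a shared artificial-insemination pool (default
fraction 0.5, reflecting strong AI connectedness between research flocks)
and partly from flock-local sires, each leaving a half-sib family of the
configured size. F1 crosses mate non-Merino sires (Border Leicester, Poll
Dorset, White Suffolk) to Merino ewes, so every F1 animal has breed
composition 0.5/0.5 and its informative paternal haplotypes come from the
sire breed.

**Recombination.** Gametes recombine on the genetic map with crossover
counts Poisson(map length in Morgans) and crossover positions uniform on the
cM map — the Haldane model, no interference. True haplotypes are retained
for every animal, which gives the imputation and phasing modules an exact
truth standard.

**What the simulator does not emulate.** Founder haplotypes are drawn with
independent markers, so there is no ancestral linkage disequilibrium: all LD
is familial (one or two meioses deep) plus breed-level frequency divergence.
Imputation in this population therefore works mainly by tracking long
shared family haplotypes — which is also the regime the half-sib resource
population design creates — but absolute accuracies are not comparable to
panels whose LD has accumulated over many generations. There is no selection
history, no Merino strain substructure, no multi-generation crossbreeding,
and map positions are abstract (1 cM/Mb).

**Desk scale.** The default study population uses 2 chromosomes of 100 cM
with 250 markers each (500 total, every 4th marker on the low-density
panel, giving the same nesting ratio as an 11k-in-48k panel pair), 420
purebred Merino progeny, 3 × 140 F1 crossbreds, 162 non-Merino purebreds
and about 24 Merino validation sires. The scenario grid runs at one tenth
of the study's sizes: test sets of 100, purebred and crossbred reference
sets of 100/200/300, 37 "all available" non-Merino purebreds, and a
prediction reference population of 100 with progeny-tested validation
sires. All sizes are configuration, not
constants; the defaults are chosen so the full grid runs in minutes on a
laptop.

# Quality control

`apply_qc()` applies the standard array-QC cascade in a fixed, documented
order: per-genotype confidence (GC) masking (< 0.6 set missing), marker call
rate (< 90% removed), marker heterozygosity outliers (> 3 SD from the mean
over markers surviving the call-rate stage), minor allele frequency
(strictly below 0.01 removed — a marker at exactly 0.01 survives), excluded
(sex) chromosomes, Hardy–Weinberg disequilibrium (chi-square p < 1e-15), and
finally duplicate samples (genotype correlation > 0.98 over
pairwise-complete markers; the later-indexed member of a pair is dropped).
Two points were genuinely open and are fixed here by decision: the
heterozygosity rule is applied at the *marker* level (the rule sits in a SNP
edit list, and sample-level checks are out of scope), and the HWE test is a
1-df chi-square rather than an exact test — at a removal floor of 1e-15 the
distinction is immaterial. The cascade is a single pass on the union set,
with no re-estimation loop; on clean data it is a no-op and re-running it
on its own output removes nothing further.

# The relationship matrices

`compute_grm()` implements VanRaden's first method, G = McMc′ / 2Σp(1−p)
with Mc = M − 2p. Allele frequencies default to those of the individuals in
the matrix being built — a base-population frequency is unavailable, and
for the test-by-candidate block (`compute_cross_grm()`) the pooled
test+candidate frequencies are used, which makes the block exactly the
off-diagonal block of the stacked-matrix GRM. Markers fixed in the sample
contribute nothing to numerator or denominator. Dosages are accepted in
place of integer genotypes, so relationship matrices from imputed data use
the full posterior information.

# Reference selection by relatedness

`select_reference()` builds an imputation reference set targeted at a test
set: relationships between test animals and every candidate are computed on
the shared low-density genotypes; each test animal nominates its k most
related candidates (default k = 20, ties broken by higher relationship then
id); the union is deduplicated; k escalates by 1 while the union is short of
the target size; and if the union overshoots, candidates with the lowest
mean relationship to the test set are removed in one rank-ordered batch.
Batch pruning (rather than iterative re-computation) is a decision: the mean
relationship of a candidate to the test set does not change as other
candidates are removed, so re-ranking would be a no-op. An optional
diversity post-filter that greedily breaks up over-related selected pairs is
provided but off by default — in strongly half-sib-structured data it barely
changes the selection, which is also why it is not part of the core
algorithm.

# The imputation engine

Beagle-style localized haplotype-cluster modelling is out of scope; the
imputer is a Li–Stephens haplotype-copying HMM, the standard and verifiable
population imputation model. A target haplotype is modelled as an imperfect
mosaic of reference haplotypes: between adjacent markers at genetic distance
d Morgans the chain switches to a random reference haplotype with
probability rho = 1 − exp(−4·Ne·d/H) (H = number of conditioning
haplotypes), and each copied allele is miscopied with probability
epsilon.

Numerical and design choices:

* **Diploid imputation is exact.** `impute_individual()` runs the
  forward–backward recursion over *ordered pairs* of reference haplotypes.
  The pair transition factorises per chain, so one marker step costs
  O(H²) rather than O(H⁴), and the posterior genotype dosage at every
  untyped marker is the exact conditional expectation under the model —
  no pre-phasing approximation enters the dosages. (A factorised
  pre-phase-then-two-haploid-chains scheme was considered; the exact pair
  chain is affordable at the panel sizes this package targets and is
  verifiable against independent dense-matrix computation to 1e-8, which
  settled the choice.)
* **Conditioning panel.** For large references the chain conditions on the
  `max_states` haplotypes most similar to the target at its typed markers
  (default 100), the standard state-space cap of large-panel imputation
  tools. Toy instances below the cap see the full panel, so oracle
  comparisons are exact.
* **Phasing.** Reference genotypes are phased by iterative Viterbi
  re-decoding: heterozygote phases start random; for `n_iterations` rounds
  (default 10, matching common practice for population imputation runs)
  each individual is re-phased by diploid Viterbi against the current
  haplotypes of the other individuals (capped at `phase_states` = 40 most
  similar). Where the decoded state pair is uninformative at a heterozygote
  (both states carry the same allele) the current phase is kept rather than
  overwritten, which avoids injecting arbitrary switches. The haplotype
  pair always sums to the observed genotype. At a 200-individual,
  500-marker panel the mean switch-error rate is about 2%.
* **Parameters.** epsilon defaults to 0.003; Ne defaults to 20. The Ne
  default matters: with the desk-scale map (~0.4 cM marker spacing) and a
  panel of a few hundred haplotypes it implies roughly one or two chain
  switches per chromosome, matching the single-meiosis LD of the simulated
  population. These are artifact defaults for this package's model, not
  estimates of any Beagle setting.
* **Degenerate maps.** Markers at identical cM positions get d = 1e-8
  Morgans so the chain stays irreducible. Imputing per chromosome (the
  default) and imputing one chain with rho forced to 1 at chromosome
  boundaries are algebraically identical, and tested to be.
* **Outputs.** Dosages in [0, 2] are primary; best-guess genotypes are
  banker's-rounded dosages; observed markers pass through untouched.

# Accuracy statistics

Imputation accuracy is the Pearson correlation between observed and imputed
genotypes computed over the *withheld* markers only — the low-density
scaffold markers are always discarded from the evaluation, since including
them mechanically inflates the correlation. Per-individual accuracy
correlates one animal's masked genotypes with its dosages; per-SNP accuracy
correlates one masked marker across test animals. Correlations are computed
on dosages by default (best-guess genotypes are available as a switch).
A correlation is undefined when the observed vector is constant (e.g. a
masked marker monomorphic in the test set); undefined cases are flagged and
excluded from summaries, with counts reported. Distribution summaries use
fixed histogram bins of width 0.02.

# Genomic prediction

The mixed model is y = Xb + Zg + Ww + Z1Qq + e with g ~ N(0, G·sigma2_g),
w ~ N(0, I·sigma2_w) (maternal, through the dam), q ~ N(0, I·sigma2_q)
(breed effects through the breed-proportion matrix Q), and e ~ N(0,
I·sigma2_e). Fixed effects are birth type, rearing type and gender as
classes, age and weight as covariates (the class-vs-covariate choice for
age/weight was open; covariates are the parsimonious reading), and
contemporary group = flock × birth year × management group. Factors with a
single observed level collapse into the intercept and aliased columns are
dropped to full rank. The breed term is fitted only when more than one
breed is present — in pure-Merino analyses Q is a constant column and is
dropped.

Variance components are estimated by REML, in-house: a model with only the
genomic and residual components is solved exactly by eigendecomposing ZGZ′,
rotating, and profiling the restricted likelihood over the variance ratio in
one dimension; models with maternal and/or breed components use
average-information REML with EM-REML fallback whenever an AI step leaves
the parameter space or decreases the restricted likelihood (EM steps are
monotone). Convergence is a maximum relative component change below 1e-6
(cap 200 rounds, non-convergence is flagged, never silent); estimates are
clamped at 1e-8 × the phenotypic variance and flagged as boundary.
Henderson's mixed-model equations then give joint solutions; the additive
solutions are the GEBVs. Boundary components drop their random term from
the equations.

GEBV validation follows progeny-test logic: the validation sires carry
simulated progeny-test EBVs whose per-sire accuracy is drawn on 0.70–0.99
with mean 0.88, and GEBV accuracy is the Pearson correlation between GEBVs
and those EBVs over the validation sires, which are never phenotyped in the
prediction reference. Correlations between relationship matrices (observed
vs imputed genotypes) use the vectorised upper triangle including the
diagonal — whether to include the diagonal was open; including it counts
the inbreeding/self-relationship agreement, and the choice is recorded
here.

# The scenario grid

`run_scenario()` executes one cell of the study grid: sample a test set of
the requested composition, mask it to the low-density panel, form the
reference (random from a named pool, or relatedness-selected from all
non-test animals), phase the reference, impute, and score accuracy.
`run_prediction_comparison()` implements the downstream contrast: GBLUP on
the same phenotyped animals with relationship matrices built from observed
medium-density genotypes, imputed dosages of varying quality, or observed
low-density genotypes, with validation sires always carried at their
observed genotypes. Every step draws from substreams of one scenario seed,
so reruns are bit-identical; reports carry the config hash, seed, and every
intermediate summary.

The trends the package reproduces on its synthetic population, each over
five replicate populations (the numbers in parentheses are the desk-scale
sizes used by the test suite): imputation accuracy increases with
within-breed reference size (40/80/140); a purebred Merino target is
imputed better from purebred Merinos than from crossbred Merinos, and far
better than from non-Merino purebreds (reference 100); a
relatedness-selected reference outperforms a random reference of equal size
(120) in mean accuracy with a narrower range; and GEBV accuracy orders
observed-50k ≥ accurately-imputed ≥ observed-12k ≥ poorly-imputed across
genotype sources (120 phenotyped animals, ~19 validation sires). The REML
machinery separately recovers a planted heritability of 0.3 within ±0.05
averaged over 20 replicates of n = 2000.

# Known limitations

* No ancestral LD in the simulator (see above): absolute accuracy levels
  reflect family-haplotype tracking, not population LD.
* The pair-chain imputer is exact but O(M·H²) per individual; very large
  reference panels rely on the `max_states` cap, which makes results depend
  weakly on the similarity pre-selection.
* Phasing is Viterbi-based (best path, not sampled); switch-error behaviour
  below a few percent is adequate for imputation but the phased panel is
  not a posterior sample.
* Single-trait analyses only; no Bayesian whole-genome regression; no
  pedigree-based (family) imputation — population-based imputation
  indirectly exploits the family structure anyway.
* The QC GC-score filter models a generic per-call confidence in [0, 1],
  not any vendor's exact score semantics.
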