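---
title: "Detecting early-life selective mortality from settler/survivor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting early-life selective mortality from settler/survivor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survscan)
```

## The question and the design

Most marine fishes suffer massive mortality in the weeks after larvae settle
from the plankton to the benthic habitat. If that mortality is selective with
respect to phenotype — hatch timing, larval growth, the temperature an
individual experienced as a larva — it leaves two measurable footprints: the
phenotype distribution of older juveniles (*survivors*) differs from that of
recent *settlers*, and allele frequencies at loci associated with those
phenotypes shift between the two age groups. `survscan` implements an analysis
of exactly this two-sample, multi-locality design: per-individual RAD-seq
genotypes plus nine otolith-derived phenotypic/environmental variables (hatch
date, hatch size, moon phase at hatch, pelagic larval duration PLD, pelagic
larval growth rate GRPLD, mean sea-surface temperature during the larval
phase, settlement date, settlement size, moon phase at settlement), for
settlers and survivors sampled at several localities.

The central multiplicity control of the design is *parallelism*: a candidate
locus is only believed when it is flagged independently in **every** locality,
associated with the **same** predictor, with the **same** correlation sign.
Under a neutral model the probability of such a three-way coincidence is tiny,
which the package verifies by simulation.

## The pipeline, stage by stage

### Filter cascade

Genotypes enter as a multi-sample VCF of biallelic SNPs whose IDs
(`tag<k>_snp<j>`) group SNPs into RAD-tag loci. Five filters run in a fixed,
auditable order:

1. individual calls with depth < 5 are masked;
2. SNPs with > 30% missing calls are dropped;
3. SNPs with minor-allele frequency < 0.05 are dropped (a MAF of exactly 0.05
   is retained);
4. all SNPs on tags whose mean depth across non-missing calls exceeds the
   Tukey upper fence (Q3 + 1.5 × IQR) of the per-tag mean-depth distribution
   are dropped — high-depth tags are the signature of collapsed paralogues;
5. SNPs out of Hardy–Weinberg equilibrium (exact mid-p test, α = 0.05) in at
   least two localities are dropped, again targeting paralogues.

The order matters only mildly in practice, but fixing it makes the
`filter_report` attribution reproducible. Two choices deserve comment. The
mean-depth rule is stated in the source material for this kind of protocol
only as "1.5 times the interquartile range"; we read it as the standard Tukey
upper fence and expose `depth_fence = "median"` as the alternative. For the
Hardy–Weinberg stage no test or α is conventional; we use the exact
conditional test with the mid-p correction because the plain exact test is
conservative at RAD-scale sample sizes, and we test each locality with
settlers and survivors pooled (viability selection strong enough to disturb
HWE within a cohort would be of interest, but the stage's purpose is
paralogue removal, for which pooling maximises power). The fence stage is
relative, so idempotence of the cascade is a property we verify by test
rather than assume.

SNPs sharing a tag collapse into multi-allelic *haplotype loci* by
concatenating phased alleles. When phase is absent, an individual with at
most one heterozygous SNP in a tag still has a determined haplotype pair;
with two or more unphased heterozygous sites the pair is ambiguous and is set
to missing (and counted) rather than guessed.

### Population structure

Differentiation between groups uses the Weir–Cockerham (1984) θ estimator,
computed from the a/b/c variance components per locus (per allele for
multi-allelic haplotype loci) with the multi-locus estimate as the ratio of
summed components. Significance comes from permuting individuals between the
two groups, `p = (1 + #{θ* ≥ θ}) / (B + 1)` with B = 999 by default.

Phenotype differences use PERMANOVA in the McArdle–Anderson form: Gower-
centering of the squared distance matrix, sequential (Type I) sums of squares
for `age_group`, `locality` and their interaction, pseudo-F against the
full-model residual, free permutation of individuals. With one response
variable and Euclidean distance the pseudo-F reduces exactly to the classical
ANOVA F — a property the tests exploit as an oracle. Distances other than
Euclidean (`manhattan`, a range-normalised `gower`) exist as options, but
Euclidean is the default: the responses here are single scalar variables, and
dissimilarities for abundance data are undefined for negative values such as
centred dates.

DAPC retains `floor(n/3)` principal components of the centred-scaled allele
table by default (missing alleles mean-imputed, the usual convention for
allele tables) and fits a linear discriminant analysis on the retained
scores.

### Per-locality RDA scans

Before ordination, predictors are screened for collinearity: walking pairs in
canonical life-stage order (hatch → larval → settlement), the later member of
any pair with |r| > 0.8 is dropped. With the default phenotype structure this
removes settlement date, which is nearly determined by hatch date + PLD.
Moon-phase variables enter as ordinal 0–9 numerics (one-hot encoding is a
config option); genotypes are alternate-allele counts, column-centred but
*not* variance-scaled — scaling would up-weight rare alleles, and the allele-
count convention keeps loadings comparable to the allele-frequency scale.
Missing calls are imputed by the within-locality modal genotype (ties to the
lower code; a SNP unseen in a locality falls back to the global mode).

The RDA itself is ordinary least squares of the centred genotype matrix on
the standardized predictors followed by an SVD of the fitted matrix;
eigenvalues are squared singular values over (n − 1). Computationally the SVD
is taken of the p × L matrix `t(Q) %*% Y` (Q an orthonormal basis of the
predictor space), so the scan costs O(npL) and handles thousands of SNPs
comfortably. Settlers and survivors of a locality are pooled in its scan: the
association signal lives in the genotype–phenotype covariance, and pooling
the two age groups maximises the phenotype spread.

Outliers are SNPs whose loading falls outside mean ± 3 SD on any screened
axis (all constrained axes by default; the first k is a config option). For
Gaussian loadings this flags a two-tailed fraction of 2Φ(−3) ≈ 0.0027 per
axis, which the acceptance suite verifies on 10⁵ standard-normal draws. Each
flagged SNP is then assigned to the predictor with the largest |Pearson r|
(ties resolved by canonical order, sign recorded).

### Parallel candidates and their characterisation

`intersect_parallel()` keeps SNPs flagged in *all* localities with identical
predictor and sign, recording why every other candidate fell out (absent /
predictor mismatch / sign mismatch). Allele-frequency change between settlers
and survivors is tested per SNP with the uncorrected Pearson chi-square on
the 2 × 2 allele-count table (two alleles per homozygote, one per
heterozygote, missing individuals ignored — tests reflect observed data
only), with a flag when any expected count is below 5 and an explicit
not-applicable result on zero margins.

For predictor-combination counts, a SNP is "associated" with every predictor
whose |r| reaches at least 90% of its assigned predictor's in all localities
with consistent sign (the runner-up threshold is configurable; some such rule
is needed because argmax assignment alone can never produce multi-predictor
memberships). Each combination's overlap is tested with an exact multi-set
intersection test: the distribution of |A₁ ∩ … ∩ A_k| for independent
uniform subsets of a background of size N, computed by iterated
hypergeometric folding. For k = 2 this is the hypergeometric survival
function; for all k the pmf sums to one (≤ 1e−9 error, asserted) and its mean
has the closed form N·∏(nᵢ/N), both used as test oracles alongside a
10⁶-draw Monte-Carlo check.

### Annotation

Tag sequences BLASTed against a reference genome (tabular outfmt-6 input,
E ≤ 1e−4 inclusive) classify loci as unmapped / unique / multiple after
coordinate deduplication; "unique" means exactly one passing hit — no
bitscore-margin best-hit rule, the stricter reading. Unique hits are placed
against a GFF3 annotation: ≥ 1 bp of exon overlap ⇒ exonic (junction-spanning
hits included), inside a gene otherwise ⇒ intronic, else intergenic; overlap
with several genes goes to the longest overlap, ties to the lexicographically
smallest gene ID. Enrichment between a candidate set and the background is
the Pearson chi-square on the category × set table. `codon_effect()`
substitutes alternate alleles into a coding sequence (jointly for SNPs
sharing a codon, reverse-complementing positions and alleles for minus-strand
genes) and translates with the standard genetic code — the canonical pattern
is a CGT→GTT double substitution at codon positions 1–2, an
arginine-to-valine replacement.

## The synthetic cohort: what it emulates and what it does not

The generator plants every statistical feature the analysis assumes, with
defaults chosen as the study conditions:

* **Structure** — ancestral allele frequencies uniform on (0.1, 0.5); per-
  locality frequencies from the Balding–Nichols beta model. Locality 1 draws
  at F = 0.01 while localities 2 and 3 descend from one shared parent
  frequency (F = 0.01 to the parent, 0.002 within), emulating a two-sided
  oceanographic front: the north–south pair is measurably differentiated, the
  southern pair barely.
* **Cohorts** — 200 settlers and 100 survivors sampled per locality, HWE
  genotypes drawn as two phased gametes. Survivors are drawn from an
  independent virtual pool (5 × the survivor count by default — the wild
  survival fraction is unknown and the multiplier is a free parameter), not
  from the sampled settlers, matching a field design where the two samples
  are different individuals collected months apart.
* **Phenotypes** — a latent 9-variate normal with a fixed correlation matrix
  containing one pair above the collinearity threshold (hatch date vs
  settlement date, r = 0.9, so the screen always has work to do); moon phases
  discretised to ordinal 0–9 by the normal CDF.
* **Selection** — each of the 50 selected SNPs (single-SNP tags) shifts its
  linked predictor by 0.8 SD per alternate allele, *on the centred allele
  count*: a raw-count effect would shift the predictor's mean and, with
  random effect signs, systematically bias overall survival, starving the
  survivor sample; centring keeps every correlation the scan uses while
  leaving acceptance balanced. Survival is Bernoulli with probability
  `plogis(2 × mean(linked predictors))`, giving indirect viability selection
  on genotypes.
* **Noise** — read depth is negative-binomial (mean 29.7, size 5.7, i.e.
  SD ≈ 13.5, overdispersed relative to Poisson as RAD depth always is), and
  5% of calls go missing at random. Neutral tags carry 1–3 SNPs
  (probabilities 0.65/0.25/0.10, matching a realised ≈1.46 SNPs per tag).

What it deliberately does **not** emulate: linkage disequilibrium between
tags, within-tag haplotype structure beyond shared tag membership (SNPs in a
tag are drawn independently, though phase is tracked), demographic history,
genotyping error beyond missingness, or read-level artefacts. Passing the
recovery tests therefore shows the statistics behave as designed under their
own assumptions — not that any particular field dataset satisfies those
assumptions.

At these defaults, 20 replicate simulations recover on average ≥ 60% of
selected SNPs per locality while flagging neutral SNPs at 0.001–0.006 per
axis, and neutral-only runs produce an empty parallel set — the quantitative
content of the acceptance suite, recomputed on every run.

## Numerical and degenerate-input choices

* SVD axes with singular values below 1e−12 of the largest are discarded;
  loading comparisons in tests are up to sign, as eigenvectors are.
* A degenerate loading axis (SD = 0) flags no outliers; a zero-variance SNP
  after imputation is dropped from assignment with a warning.
* Tied imputation modes go to the lower genotype code; assignment |r| ties go
  to the earlier canonical predictor — both deterministic.
* Permutation p-values always include the observed ordering
  (`(1 + count)/(B + 1)`), so p = 0 is unreachable.
* HWE localities with fewer than 5 genotyped individuals at a SNP are skipped
  for that SNP with a warning; monomorphic samples return p = 1.
* PERMANOVA errors on a zero total sum of squares ("degenerate response");
  F_ST errors when no shared polymorphic locus remains.
* Chi-square tests are uncorrected (no Yates continuity), matching the
  conventions of the scale of table this pipeline produces; low expected
  counts are flagged, not hidden.

## Problem sizes used in the validation suite

The test and acceptance suites run entirely on synthetic data generated at
run time: the recovery experiment uses the full default design (3 × 300
individuals, ≈ 7,300 SNPs, 20 seeds), type-I-error checks use 500 replicates
of 30-individual groups at 199 permutations, oracle comparisons use 10–50
random small instances, and the Monte-Carlo check of the intersection test
uses 10⁶ draws. These sizes were chosen so the whole validation runs
comfortably on one CPU while leaving every estimate's Monte-Carlo error well
inside the asserted tolerance.

## Known limitations

* The runner-up rule for multi-predictor membership is a declared convention;
  other reasonable rules (per-correlation significance, commonality analysis)
  would change combination counts, though not the parallel set itself.
* F_ST permutation tests permute freely; no stratified or restricted
  permutation schemes are provided.
* The RDA is unconditioned — there is no partial RDA on structure covariates,
  so locality-confounded signals are controlled only by the per-locality
  design plus the parallelism requirement.
* Imputation by the modal genotype slightly shrinks variance at high-
  missingness SNPs; the filter cascade's 30% missingness cap bounds the
  effect.
* The generator's survivors are unrelated to its settlers (two independent
  draws from the same locality pool), so kinship between the two samples is
  absent by construction.
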