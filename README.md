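# survscan

Genomic scans for early-life **selective mortality** in two-stage cohort
designs: recently settled juveniles ("settlers") versus older juveniles that
survived the post-settlement period ("survivors"), sampled at several
localities. The package is aimed at population geneticists working with
RAD-seq genotypes plus per-individual phenotypic/environmental covariates
(typically otolith-derived: hatch date and size, moon phases, pelagic larval
duration, larval growth rate, sea-surface temperature, settlement date and
size).

## What it computes

Given a multi-sample VCF of tag-grouped biallelic SNPs, a metadata table
(individual, locality, age group) and a phenotype table, `survscan` runs:

* a five-stage **filter cascade** — per-call depth masking (< 5×), SNP
  missingness (> 30%), minor-allele frequency (< 0.05), per-tag mean-depth
  Tukey fence (Q3 + 1.5 × IQR), and exact Hardy–Weinberg disequilibrium
  (mid-p, α = 0.05, ≥ 2 localities) — then collapses within-tag SNPs into
  multi-allelic haplotype loci;
* **population structure**: pairwise Weir–Cockerham θ
  (θ = Σa / Σ(a + b + c) over loci) with permutation p-values, PERMANOVA
  pseudo-F per phenotype (sequential SS on the Gower-centred distance
  matrix; equals classical ANOVA F for univariate Euclidean responses), and
  DAPC retaining ⌊n/3⌋ principal components;
* per-locality **redundancy analysis** (RDA) of the centred genotype matrix
  on the standardized predictors (after dropping the later member of any
  predictor pair with |r| > 0.8), flagging SNPs whose axis loadings fall
  outside mean ± 3 SD (a two-tailed Gaussian fraction of 2Φ(−3) ≈ 0.0027 per
  axis) and assigning each to its strongest predictor with sign;
* the cross-locality **parallel set** — SNPs flagged in *every* locality with
  the same predictor and sign — with settler-versus-survivor allele-frequency
  chi-square tests and exact multi-set intersection tests (iterated
  hypergeometric folding, the k = 2 case being the hypergeometric survival
  function) over predictor combinations;
* locus **annotation** from BLAST tabular hits (E ≤ 1e−4) and a GFF3:
  unmapped/unique/multiple mapping classes, exonic/intronic/intergenic
  regions, biotypes, set-versus-background enrichment chi-squares, and
  strand-aware codon-level amino-acid effects of exonic SNPs;
* a **synthetic-cohort generator** (Balding–Nichols hierarchical structure,
  latent multivariate-normal phenotypes, logistic viability selection on a
  virtual settler pool, negative-binomial depth, per-call missingness) with a
  per-SNP truth table, so the entire pipeline is validated by parameter
  recovery.

## Worked example

Simulate a three-locality cohort with 20 selected loci, filter it, measure
structure, scan each locality and call the parallel set:

```r
library(survscan)

cfg <- simulation_config(n_settlers_per_locality = 60,
                         n_survivors_per_locality = 40,
                         n_neutral_loci = 1000, n_selected_loci = 20,
                         seed = 42)
sim <- simulate_cohort(cfg)
sim$cohort
#> cohort_genotypes: 300 individuals x 1466 SNPs (1020 tags, phased)
#>        settler survivor
#>   loc1      60       40
#>   loc2      60       40
#>   loc3      60       40

filt <- apply_filters(sim$cohort)
filt$report
#> filter_report: 1466 SNPs in, 1445 SNPs out (1007 haplotype loci)
#>   depth_mask   removed 0 SNP(s), masked 1326 call(s)
#>   missingness  removed 0 SNP(s)
#>   maf          removed 0 SNP(s)
#>   tag_depth    removed 7 SNP(s)
#>   hwe          removed 14 SNP(s)

ind <- filt$cohort$individuals
fst_permutation_test(
  filt$cohort$calls[ind$locality == "loc1" & ind$age_group == "settler", ],
  filt$cohort$calls[ind$locality == "loc2" & ind$age_group == "settler", ],
  n_perm = 999, seed = 1)
#> Weir-Cockerham multi-locus theta = 0.01084 (1445 loci)
#> permutation p = 0.001 (999 permutations)

scans <- lapply(unique(ind$locality),
                function(l) rda_scan(filt$cohort, sim$pheno, l))
pset <- intersect_parallel(scans)
pset
#> parallel_set: 3 SNP(s) on 3 locus/loci across 3 localities
#>              -1 1
#>   hatch_date  0 1
#>   pld         2 0
```

The settler F_ST between localities 1 and 2 recovers the planted
differentiation (θ ≈ 0.011 against a Balding–Nichols F of 0.01, permutation
p = 0.001), and all three parallel-set SNPs are planted selected loci
(`sim$truth` confirms: 3/3 true positives). At this reduced size most
selected loci do not reach three-way parallelism; at the default design
(200 + 100 individuals per locality, 5,000 neutral + 50 selected loci) the
per-locality scans recover ≥ 60% of selected SNPs with a neutral flagging
rate of ~0.003 per axis.

The same analysis runs end-to-end from files via a single configuration:

```r
cfg <- run_config(vcf = "cohort.vcf", metadata = "metadata.csv",
                  phenotypes = "phenotypes.csv",
                  blast = "hits.tsv", gff = "annotation.gff3",
                  output_dir = "results")
run_pipeline(cfg)   # writes CSV/JSON per stage plus manifest.json
```

## Vignette

`vignettes/selective-mortality-pipeline.Rmd` documents the statistical model,
every tunable threshold with its default and rationale, what the synthetic
cohort does and does not emulate, and the numerical conventions
(tie-breaking, degenerate inputs, permutation p-value construction).
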