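# shared fixtures and independent oracles, built in code

# build a cohort_genotypes object by hand
make_cohort <- function(calls, depth = NULL, locality, age_group,
                        tags = NULL, phased = FALSE,
                        allele1 = NULL, allele2 = NULL) {
  n <- nrow(calls)
  L <- ncol(calls)
  ids <- rownames(calls) %||% sprintf("ind%02d", seq_len(n))
  snp_ids <- colnames(calls) %||% sprintf("tag%d_snp1", seq_len(L))
  rownames(calls) <- ids
  colnames(calls) <- snp_ids
  if (is.null(depth)) depth <- matrix(20L, n, L, dimnames = dimnames(calls))
  if (is.null(tags)) tags <- sub("_snp[0-9]+$", "", snp_ids)
  snps <- data.frame(snp_id = snp_ids, tag = tags,
                     contig = "ctg1", pos = seq_len(L) * 100L,
                     pos_in_tag = 17L, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  structure(list(
    individuals = data.frame(individual = ids, locality = locality,
                             age_group = age_group, stringsAsFactors = FALSE),
    snps = snps, calls = calls, depth = depth,
    allele1 = allele1, allele2 = allele2, phased = phased),
    class = "cohort_genotypes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independently coded Weir & Cockerham (1984) two-group worked computation,
# written as plain scalar arithmetic on genotype counts (nAA, nAa, naa)
wc_fst_oracle <- function(counts_a, counts_b) {
  n1 <- sum(counts_a); n2 <- sum(counts_b)
  p1 <- (2 * counts_a[3] + counts_a[2]) / (2 * n1)
  p2 <- (2 * counts_b[3] + counts_b[2]) / (2 * n2)
  h1 <- counts_a[2] / n1
  h2 <- counts_b[2] / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  unname(a / (a + b + cc))
}

# expand genotype counts (nAA, nAa, naa) into a one-locus genotype matrix
counts_to_geno <- function(counts) {
  matrix(rep(c(0L, 1L, 2L), counts), ncol = 1)
}

# brute-force redundancy-analysis oracle: explicit hat matrix times the
# centered response, then eigendecomposition of the fitted covariance
rda_oracle <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  X <- scale(X)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  Yfit <- H %*% Yc
  C <- crossprod(Yfit) / (nrow(Y) - 1)
  e <- eigen(C, symmetric = TRUE)
  pos <- e$values > max(e$values[1], 0) * 1e-10
  list(eigenvalues = e$values[pos], loadings = e$vectors[, pos, drop = FALSE])
}

# exact conditional Hardy-Weinberg pmf oracle via log-factorials
hwe_pmf_oracle <- function(n_a, n) {
  n_b <- 2 * n - n_a
  rare <- min(n_a, n_b)
  hets <- seq.int(rare %% 2, rare, by = 2)
  logp <- sapply(hets, function(h) {
    haa <- (n_a - h) / 2
    hbb <- (n_b - h) / 2
    lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  })
  data.frame(het = hets, p = exp(logp))
}

# hand-built six-SNP cohort: each of snp_miss/snp_maf/snp_depth/snp_hwe trips
# exactly one cascade stage; snp_clean1/snp_clean2 survive
filter_fixture <- function() {
  n_loc <- 10L
  loc <- rep(c("locA", "locB", "locC"), each = n_loc)
  age <- rep(rep(c("settler", "survivor"), c(5, 5)), 3)
  n <- length(loc)
  clean_geno <- rep(c(0L, 1L, 2L), c(3, 5, 2)) # near-HWE, MAF 0.45
  hwe_bad <- rep(c(0L, 2L), c(5, 5))           # no heterozygotes at p = 0.5
  calls <- cbind(
    snp_clean1 = rep(clean_geno, 3),
    snp_miss   = rep(clean_geno, 3),
    snp_maf    = c(1L, rep(0L, n - 1)),
    snp_depth  = rep(clean_geno, 3),
    snp_hwe    = c(hwe_bad, hwe_bad, clean_geno),
    snp_clean2 = rep(clean_geno, 3))
  depth <- matrix(20L, n, 6, dimnames = list(NULL, colnames(calls)))
  depth[seq_len(ceiling(0.4 * n)), "snp_miss"] <- 2L # masked -> 40% missing
  depth[, "snp_depth"] <- 200L
  rownames(calls) <- sprintf("ind%02d", seq_len(n))
  make_cohort(calls, depth, loc, age,
              tags = c("tagA", "tagC", "tagD", "tagE", "tagF", "tagB"))
}

# small GFF3 annotation written to a temp file:
#   geneA (protein_coding, +) on ctg1: exons 101-200 and 301-400
#   geneB (lncRNA, -) on ctg1: exon 1001-1100
#   ctg2 has no features
write_test_gff <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    "ctg1\ttest\tgene\t101\t400\t.\t+\t.\tID=geneA;gene_biotype=protein_coding",
    "ctg1\ttest\tmRNA\t101\t400\t.\t+\t.\tID=geneA.t1;Parent=geneA",
    "ctg1\ttest\texon\t101\t200\t.\t+\t.\tID=geneA.e1;Parent=geneA.t1",
    "ctg1\ttest\texon\t301\t400\t.\t+\t.\tID=geneA.e2;Parent=geneA.t1",
    "ctg1\ttest\tgene\t1001\t1100\t.\t-\t.\tID=geneB;gene_biotype=lncRNA",
    "ctg1\ttest\tmRNA\t1001\t1100\t.\t-\t.\tID=geneB.t1;Parent=geneB",
    "ctg1\ttest\texon\t1001\t1100\t.\t-\t.\tID=geneB.e1;Parent=geneB.t1")
  writeLines(lines, path)
  path
}

# write outfmt-6 BLAST rows; each row a list/vector of the 12 fields
write_test_blast <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

blast_row <- function(q, s, sstart, send, evalue = 1e-10, bits = 60,
                      pident = 100, len = 34) {
  c(q, s, pident, len, 0, 0, 1, 34, sstart, send,
    format(evalue, scientific = TRUE), bits)
}
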