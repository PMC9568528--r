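# Weir & Cockerham (1984) variance components.
# n, p, h are (locus-allele rows) x (group columns) matrices of sample sizes
# (genotyped individuals), allele frequencies, and observed heterozygote
# frequencies (proportion of individuals carrying exactly one copy).
wc_components <- function(n, p, h) {
  r <- ncol(n)
  nbar <- rowMeans(n)
  rn <- r * nbar
  nc <- (rn - rowSums(n^2) / rn) / (r - 1)
  pbar <- rowSums(n * p) / rn
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / rn
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2
  usable <- nbar > 1 & apply(n, 1, min) > 0
  list(a = a, b = b, c = c_, usable = usable)
}

# per-group summaries for biallelic genotype matrices (0/1/2/NA, ind x loci)
geno_summary <- function(g) {
  n <- colSums(!is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  h <- colMeans(g == 1L, na.rm = TRUE)
  list(n = n, p = p, h = h)
}

#' Weir-Cockerham F_ST between two groups
#'
#' Computes the Weir and Cockerham (1984) theta estimator of differentiation
#' between two groups of diploid individuals at biallelic loci, from the
#' variance components a (among groups), b (among individuals within groups)
#' and c (within individuals). The multi-locus estimate is the ratio of
#' summed components, `sum(a) / sum(a + b + c)`; loci with a zero or
#' undefined denominator are excluded from both sums.
#'
#' @param genotypes_a,genotypes_b Individuals x loci matrices of
#'   alternate-allele counts (0/1/2), `NA` for missing, with matching locus
#'   columns.
#' @return List of class `fst_result` with `theta` (multi-locus),
#'   `theta_locus` (per locus; `NaN` where undefined), the per-locus
#'   components, and the number of loci used.
#' @export
weir_cockerham_fst <- function(genotypes_a, genotypes_b) {
  stopifnot(is.matrix(genotypes_a), is.matrix(genotypes_b),
            ncol(genotypes_a) == ncol(genotypes_b))
  if (nrow(genotypes_a) < 2L || nrow(genotypes_b) < 2L)
    stop("each group needs at least 2 individuals")
  sa <- geno_summary(genotypes_a)
  sb <- geno_summary(genotypes_b)
  comp <- wc_components(cbind(sa$n, sb$n), cbind(sa$p, sb$p), cbind(sa$h, sb$h))
  denom <- comp$a + comp$b + comp$c
  use <- comp$usable & is.finite(denom) & denom != 0
  if (!any(use))
    stop("no shared polymorphic locus between the two groups")
  theta_locus <- ifelse(use, comp$a / denom, NaN)
  structure(list(theta = sum(comp$a[use]) / sum(denom[use]),
                 theta_locus = theta_locus,
                 components = list(a = comp$a, b = comp$b, c = comp$c),
                 n_loci_used = sum(use)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham multi-locus theta = %.5f (%d loci)\n",
              x$theta, x$n_loci_used))
  if (!is.null(x$p_value))
    cat(sprintf("permutation p = %.4g (%d permutations)\n",
                x$p_value, x$n_permutations))
  invisible(x)
}

#' Permutation test of Weir-Cockerham F_ST
#'
#' Individuals are permuted between the two groups, preserving group sizes;
#' the p-value is `(1 + #(theta_perm >= theta_obs)) / (n_perm + 1)`.
#'
#' @inheritParams weir_cockerham_fst
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return An `fst_result` with `p_value` and `n_permutations` added.
#' @export
fst_permutation_test <- function(genotypes_a, genotypes_b, n_perm = 999,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- weir_cockerham_fst(genotypes_a, genotypes_b)
  pooled <- rbind(genotypes_a, genotypes_b)
  na <- nrow(genotypes_a)
  n <- nrow(pooled)
  count <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    th <- tryCatch(
      weir_cockerham_fst(pooled[idx[seq_len(na)], , drop = FALSE],
                         pooled[idx[-seq_len(na)], , drop = FALSE])$theta,
      error = function(e) -Inf)
    if (th >= obs$theta) count <- count + 1L
  }
  obs$p_value <- (1 + count) / (n_perm + 1)
  obs$n_permutations <- n_perm
  obs
}

#' F_ST on multi-allelic haplotype loci
#'
#' Weir-Cockerham theta generalised to multi-allelic loci: each allele of a
#' haplotype locus contributes one set of variance components (its frequency
#' and the frequency of individuals heterozygous for it), and the
#' multi-locus estimate sums components over all alleles of all loci.
#'
#' @param haplotypes Long data frame as produced by [collapse_haplotypes()]
#'   (columns individual, tag, allele1, allele2).
#' @param groups Named character vector (or factor) of group labels keyed by
#'   individual, with exactly two distinct groups among the individuals
#'   present.
#' @param n_perm If > 0, a permutation p-value is computed.
#' @param seed Optional integer seed for the permutations.
#' @return An `fst_result`.
#' @export
haplotype_fst <- function(haplotypes, groups, n_perm = 0, seed = NULL) {
  stopifnot(all(c("individual", "tag", "allele1", "allele2") %in%
                  names(haplotypes)))
  grp <- groups[haplotypes$individual]
  lv <- unique(stats::na.omit(as.character(grp)))
  if (length(lv) != 2L) stop("exactly two groups required")
  if (!is.null(seed)) set.seed(seed)

  theta_of <- function(grp_vec) {
    rows_n <- rows_p <- rows_h <- list()
    for (d in split(data.frame(a1 = haplotypes$allele1, a2 = haplotypes$allele2,
                               g = as.character(grp_vec),
                               stringsAsFactors = FALSE),
                    haplotypes$tag)) {
      ok <- !is.na(d$a1) & !is.na(d$a2) & !is.na(d$g)
      d <- d[ok, , drop = FALSE]
      alleles <- unique(c(d$a1, d$a2))
      if (length(alleles) < 2L) next
      n <- vapply(lv, function(g) sum(d$g == g), numeric(1))
      if (min(n) < 1) next
      for (u in alleles) {
        cnt <- (d$a1 == u) + (d$a2 == u)
        p <- vapply(lv, function(g) mean(cnt[d$g == g]) / 2, numeric(1))
        h <- vapply(lv, function(g) mean(cnt[d$g == g] == 1L), numeric(1))
        rows_n[[length(rows_n) + 1L]] <- n
        rows_p[[length(rows_p) + 1L]] <- p
        rows_h[[length(rows_h) + 1L]] <- h
      }
    }
    if (!length(rows_n)) stop("no shared polymorphic locus between the two groups")
    comp <- wc_components(do.call(rbind, rows_n), do.call(rbind, rows_p),
                          do.call(rbind, rows_h))
    denom <- comp$a + comp$b + comp$c
    use <- comp$usable & is.finite(denom) & denom != 0
    sum(comp$a[use]) / sum(denom[use])
  }

  theta <- theta_of(grp)
  res <- structure(list(theta = theta, theta_locus = NULL, components = NULL,
                        n_loci_used = NA_integer_), class = "fst_result")
  if (n_perm > 0) {
    inds <- unique(haplotypes$individual)
    glab <- as.character(groups[inds])
    count <- 0L
    for (b in seq_len(n_perm)) {
      perm <- stats::setNames(sample(glab), inds)
      th <- tryCatch(theta_of(perm[haplotypes$individual]),
                     error = function(e) -Inf)
      if (th >= theta) count <- count + 1L
    }
    res$p_value <- (1 + count) / (n_perm + 1)
    res$n_permutations <- n_perm
  }
  res
}
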