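#' Discriminant analysis of principal components (DAPC)
#'
#' Center-scales an individual x allele (or genotype) table, retains a fixed
#' number of principal components - one third of the number of individuals by
#' default - and runs a linear discriminant analysis of the group labels on
#' the retained component scores. Missing cells are replaced by their column
#' mean (i.e. zero after centering), the usual convention for allele tables.
#'
#' @param x Numeric matrix, individuals in rows (e.g. the output of
#'   [haplotype_indicator_matrix()] or a 0/1/2 genotype matrix).
#' @param groups Factor (or coercible) of group labels, one per row.
#' @param n_pcs Number of principal components retained; default
#'   `floor(nrow(x) / 3)`.
#' @return A `dapc_result` with the retained PC count, discriminant axes
#'   (loadings of the PCs), individual scores on the discriminant axes,
#'   posterior group-assignment probabilities (rows sum to 1) and the
#'   assigned group per individual.
#' @export
dapc <- function(x, groups, n_pcs = floor(nrow(x) / 3)) {
  x <- as.matrix(x)
  groups <- factor(groups)
  n <- nrow(x)
  if (length(groups) != n) stop("groups must match rows of x")
  if (nlevels(groups) < 2L) stop("at least two groups required")
  if (n_pcs >= n) stop("n_pcs must be smaller than the number of individuals")
  if (n_pcs < 1L) stop("n_pcs must be at least 1")

  ctr <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  keep <- !is.na(sdv) & sdv > 0
  x <- x[, keep, drop = FALSE]
  xs <- scale(x, center = ctr[keep], scale = sdv[keep])
  xs[is.na(xs)] <- 0 # mean imputation on the scaled table

  pca <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  n_avail <- sum(pca$sdev > 1e-10)
  n_use <- min(n_pcs, n_avail)
  scores <- pca$x[, seq_len(n_use), drop = FALSE]

  fit <- MASS::lda(scores, grouping = groups)
  pred <- stats::predict(fit, scores)
  structure(list(n_pcs = n_use,
                 discriminant_axes = fit$scaling,
                 pc_rotation = pca$rotation[, seq_len(n_use), drop = FALSE],
                 scores = pred$x,
                 posterior = pred$posterior,
                 assignment = pred$class,
                 groups = groups),
            class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("DAPC: %d PCs retained, %d discriminant axes, %d groups\n",
              x$n_pcs, ncol(x$scores), nlevels(x$groups)))
  acc <- mean(x$assignment == x$groups)
  cat(sprintf("reassignment accuracy: %.3f\n", acc))
  invisible(x)
}

#' One-hot allele dosage table from haplotype loci
#'
#' Expands a long haplotype table into an individuals x (tag:allele) matrix
#' of allele dosages (0, 1 or 2 copies), the standard input for DAPC on
#' multi-allelic loci. Individuals missing a tag get `NA` across that tag's
#' allele columns.
#'
#' @param haplotypes Long data frame from [collapse_haplotypes()].
#' @return Numeric matrix with rownames = individuals and colnames =
#'   `tag:allele`.
#' @export
haplotype_indicator_matrix <- function(haplotypes) {
  inds <- unique(haplotypes$individual)
  cols <- list()
  for (d in split(haplotypes, haplotypes$tag)) {
    alleles <- sort(unique(stats::na.omit(c(d$allele1, d$allele2))))
    if (!length(alleles)) next
    m <- matrix(NA_real_, length(inds), length(alleles),
                dimnames = list(inds, paste0(d$tag[1], ":", alleles)))
    ri <- match(d$individual, inds)
    for (j in seq_along(alleles)) {
      dose <- (d$allele1 == alleles[j]) + (d$allele2 == alleles[j])
      m[ri, j] <- dose
    }
    cols[[d$tag[1]]] <- m
  }
  do.call(cbind, cols)
}
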