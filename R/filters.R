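#' Configuration of the post-genotyping filter cascade
#'
#' Thresholds for the five-stage SNP filter cascade: per-call depth masking,
#' per-SNP missingness, minor-allele frequency, per-tag mean-depth outlier
#' removal (Tukey upper fence by default), and Hardy-Weinberg disequilibrium
#' across localities.
#'
#' @param min_depth Calls with depth below this are masked as missing.
#' @param max_missingness SNPs with a missing-call fraction above this are
#'   dropped (computed over all individuals, after depth masking).
#' @param min_maf SNPs with minor-allele frequency below this are dropped;
#'   the boundary is inclusive (MAF equal to `min_maf` is retained).
#' @param depth_iqr_multiplier Multiplier of the interquartile range in the
#'   per-tag mean-depth fence.
#' @param depth_fence Either `"q3"` (Tukey: Q3 + mult*IQR, default) or
#'   `"median"` (median + mult*IQR).
#' @param hwe_alpha Significance level of the per-locality exact
#'   Hardy-Weinberg test (mid-p).
#' @param hwe_min_localities A SNP is dropped when out of Hardy-Weinberg
#'   equilibrium in at least this many localities.
#' @param hwe_min_n Localities with fewer genotyped individuals than this at
#'   a SNP are skipped for that SNP's Hardy-Weinberg stage.
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_depth = 5, max_missingness = 0.30,
                          min_maf = 0.05, depth_iqr_multiplier = 1.5,
                          depth_fence = c("q3", "median"),
                          hwe_alpha = 0.05, hwe_min_localities = 2L,
                          hwe_min_n = 5L) {
  depth_fence <- match.arg(depth_fence)
  stopifnot(min_depth >= 0, depth_iqr_multiplier > 0, hwe_min_localities >= 1)
  stopifnot_scalar_prob(max_missingness, "max_missingness")
  stopifnot_scalar_prob(min_maf, "min_maf")
  stopifnot_scalar_prob(hwe_alpha, "hwe_alpha")
  structure(list(min_depth = min_depth, max_missingness = max_missingness,
                 min_maf = min_maf, depth_iqr_multiplier = depth_iqr_multiplier,
                 depth_fence = depth_fence, hwe_alpha = hwe_alpha,
                 hwe_min_localities = as.integer(hwe_min_localities),
                 hwe_min_n = as.integer(hwe_min_n)),
            class = "filter_config")
}

# subset a cohort_genotypes object by SNP column index
subset_snps <- function(cohort, keep) {
  cohort$snps <- cohort$snps[keep, , drop = FALSE]
  rownames(cohort$snps) <- NULL
  for (f in c("calls", "depth", "allele1", "allele2"))
    if (!is.null(cohort[[f]])) cohort[[f]] <- cohort[[f]][, keep, drop = FALSE]
  cohort
}

#' Apply the post-genotyping filter cascade
#'
#' Stages run in a fixed, auditable order: (1) mask individual calls with
#' depth below `min_depth`; (2) drop SNPs whose missingness (missing calls
#' over all individuals, after masking) exceeds `max_missingness`; (3) drop
#' SNPs with minor-allele frequency below `min_maf` over the non-missing
#' calls of all individuals; (4) drop every SNP on tags whose mean depth
#' across non-missing calls lies above the upper fence of the per-tag
#' mean-depth distribution, removing putative repetitive/paralogous tags;
#' (5) drop SNPs out of Hardy-Weinberg equilibrium (exact mid-p test at
#' `hwe_alpha`) in at least `hwe_min_localities` localities, testing each
#' locality's settlers and survivors pooled.
#'
#' @param cohort A `cohort_genotypes` object with locality labels.
#' @param config A [filter_config()].
#' @return List with the filtered `cohort` and a `filter_report` recording
#'   per-stage removals and final SNP/haplotype-locus counts.
#' @export
apply_filters <- function(cohort, config = filter_config()) {
  stopifnot(inherits(cohort, "cohort_genotypes"))
  stopifnot(inherits(config, "filter_config"))
  n_input <- ncol(cohort$calls)
  stages <- list()

  ## stage 1: depth mask on individual calls
  low <- !is.na(cohort$calls) & cohort$depth < config$min_depth
  cohort$calls[low] <- NA_integer_
  for (f in c("allele1", "allele2"))
    if (!is.null(cohort[[f]])) cohort[[f]][low] <- NA_integer_
  stages$depth_mask <- list(stage = "depth_mask", calls_masked = sum(low),
                            snps_removed = 0L)

  ## stage 2: per-SNP missingness
  missfrac <- colMeans(is.na(cohort$calls))
  drop <- missfrac > config$max_missingness
  stages$missingness <- list(stage = "missingness", snps_removed = sum(drop))
  cohort <- subset_snps(cohort, !drop)

  ## stage 3: minor-allele frequency (boundary inclusive: MAF == min_maf kept)
  p <- colMeans(cohort$calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop <- maf < config$min_maf - 1e-12
  drop[is.na(drop)] <- TRUE # SNPs with zero genotyped calls
  stages$maf <- list(stage = "maf", snps_removed = sum(drop))
  cohort <- subset_snps(cohort, !drop)

  ## stage 4: per-tag mean depth upper fence
  depth_ok <- !is.na(cohort$calls)
  tagf <- factor(cohort$snps$tag, levels = unique(cohort$snps$tag))
  tag_depth <- vapply(split(seq_len(ncol(cohort$calls)), tagf), function(j) {
    d <- cohort$depth[, j, drop = FALSE]
    ok <- depth_ok[, j, drop = FALSE]
    if (!any(ok)) return(NA_real_)
    mean(d[ok])
  }, numeric(1))
  q <- stats::quantile(tag_depth, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[3] - q[1]
  fence <- switch(config$depth_fence,
                  q3 = q[3] + config$depth_iqr_multiplier * iqr,
                  median = q[2] + config$depth_iqr_multiplier * iqr)
  bad_tags <- names(tag_depth)[!is.na(tag_depth) & tag_depth > fence]
  drop <- cohort$snps$tag %in% bad_tags
  stages$tag_depth <- list(stage = "tag_depth", snps_removed = sum(drop),
                           tags_removed = length(bad_tags), fence = fence)
  cohort <- subset_snps(cohort, !drop)

  ## stage 5: Hardy-Weinberg disequilibrium in >= hwe_min_localities localities
  loc <- factor(cohort$individuals$locality)
  loc_rows <- split(seq_len(nrow(cohort$calls)), loc)
  n_skipped <- 0L
  diseq <- matrix(FALSE, ncol(cohort$calls), length(loc_rows))
  for (li in seq_along(loc_rows)) {
    sub <- cohort$calls[loc_rows[[li]], , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      g <- sub[, j]
      g <- g[!is.na(g)]
      if (length(g) < config$hwe_min_n) {
        n_skipped <- n_skipped + 1L
        next
      }
      pval <- hwe_exact_midp(sum(g == 0L), sum(g == 1L), sum(g == 2L))
      diseq[j, li] <- pval < config$hwe_alpha
    }
  }
  if (n_skipped > 0L)
    warning(sprintf(
      "HWE stage: %d SNP x locality combination(s) skipped (< %d genotyped individuals)",
      n_skipped, config$hwe_min_n))
  drop <- rowSums(diseq) >= config$hwe_min_localities
  stages$hwe <- list(stage = "hwe", snps_removed = sum(drop))
  cohort <- subset_snps(cohort, !drop)

  report <- structure(list(
    n_input_snps = n_input,
    stages = stages,
    n_output_snps = ncol(cohort$calls),
    n_output_tags = length(unique(cohort$snps$tag)),
    config = unclass(config)), class = "filter_report")
  list(cohort = cohort, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d SNPs in, %d SNPs out (%d haplotype loci)\n",
              x$n_input_snps, x$n_output_snps, x$n_output_tags))
  for (s in x$stages)
    cat(sprintf("  %-12s removed %d SNP(s)%s\n", s$stage, s$snps_removed,
                if (!is.null(s$calls_masked))
                  sprintf(", masked %d call(s)", s$calls_masked) else ""))
  invisible(x)
}

#' Collapse within-tag SNPs into multi-allelic haplotype loci
#'
#' SNPs sharing a RAD-tag ID become one haplotype locus whose alleles are
#' the per-tag concatenation of phased SNP alleles (in position order). An
#' individual heterozygous at more than one SNP of an unphased multi-SNP tag
#' has ambiguous haplotypes and is set to missing for that tag (the count of
#' such calls is reported); with at most one heterozygous SNP the pair is
#' determined without phase information. Any missing constituent SNP call
#' also yields a missing haplotype.
#'
#' @param cohort A `cohort_genotypes` object.
#' @return List with `haplotypes` (long data frame: individual, tag,
#'   allele1, allele2; missing pairs are `NA`) and `n_unphased_missing`, the
#'   number of individual-by-tag calls set to missing for phase ambiguity.
#' @export
collapse_haplotypes <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_genotypes"))
  phased <- isTRUE(cohort$phased) && !is.null(cohort$allele1)
  inds <- cohort$individuals$individual
  tagf <- factor(cohort$snps$tag, levels = unique(cohort$snps$tag))
  idx_by_tag <- split(seq_len(nrow(cohort$snps)), tagf)
  n_unphased <- 0L
  out <- vector("list", length(idx_by_tag))
  for (t in seq_along(idx_by_tag)) {
    j <- idx_by_tag[[t]]
    j <- j[order(cohort$snps$pos[j])]
    if (phased) {
      h1 <- cohort$allele1[, j, drop = FALSE]
      h2 <- cohort$allele2[, j, drop = FALSE]
    } else {
      g <- cohort$calls[, j, drop = FALSE]
      h1 <- (g >= 1L) * 1L # het -> arbitrary but unambiguous when <= 1 het
      h1[g == 1L] <- 0L
      h2 <- g - h1
      ambiguous <- rowSums(g == 1L, na.rm = TRUE) > 1L & length(j) > 1L
      if (any(ambiguous)) {
        n_unphased <- n_unphased + sum(ambiguous)
        h1[ambiguous, ] <- NA_integer_
        h2[ambiguous, ] <- NA_integer_
      }
    }
    a1 <- apply(h1, 1, paste, collapse = "")
    a2 <- apply(h2, 1, paste, collapse = "")
    any_na <- rowSums(is.na(h1) | is.na(h2)) > 0L
    a1[any_na] <- NA_character_
    a2[any_na] <- NA_character_
    # canonical order within the pair so haplotype pairs are unordered
    swap <- !is.na(a1) & !is.na(a2) & a2 < a1
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
    out[[t]] <- data.frame(individual = inds, tag = levels(tagf)[t],
                           allele1 = a1, allele2 = a2,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  list(haplotypes = do.call(rbind, out), n_unphased_missing = n_unphased)
}

#' Write a filter report as JSON
#'
#' @param report A `filter_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
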