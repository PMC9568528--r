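#' Call the parallel candidate set across localities
#'
#' Keeps the SNPs flagged as outliers in every locality scan with an
#' identical assigned predictor and an identical correlation sign; a
#' candidate differing in any locality is excluded. Exclusions are reported
#' with their reason: `absent` (not flagged everywhere), `predictor
#' mismatch`, or `sign mismatch`.
#'
#' @param scans List (length >= 2) of `rda_scan` objects or of candidate
#'   data frames with columns `snp_id`, `predictor`, `sign` (and optionally
#'   the `r_<predictor>` correlation profile columns).
#' @return A `parallel_set`: data frame `members` (snp_id, tag, predictor,
#'   sign, per-locality r), data frame `dropped` (snp_id, reason), and the
#'   locality labels.
#' @export
intersect_parallel <- function(scans) {
  if (length(scans) < 2L) stop("need at least two locality scans")
  tabs <- lapply(scans, function(s)
    if (inherits(s, "rda_scan")) s$candidates else s)
  locs <- vapply(seq_along(scans), function(i) {
    if (inherits(scans[[i]], "rda_scan")) scans[[i]]$locality
    else names(scans)[i] %||% paste0("scan", i)
  }, character(1))
  all_ids <- sort(unique(unlist(lapply(tabs, `[[`, "snp_id"))))
  member <- character(0)
  dropped <- data.frame(snp_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (id in all_ids) {
    rows <- lapply(tabs, function(t) t[t$snp_id == id, , drop = FALSE])
    present <- vapply(rows, nrow, integer(1)) > 0L
    reason <- NULL
    if (!all(present)) {
      reason <- "absent"
    } else {
      preds <- vapply(rows, function(r) r$predictor[1], character(1))
      signs <- vapply(rows, function(r) r$sign[1], integer(1))
      if (length(unique(preds)) > 1L) reason <- "predictor mismatch"
      else if (length(unique(signs)) > 1L) reason <- "sign mismatch"
    }
    if (is.null(reason)) {
      member <- c(member, id)
    } else {
      dropped <- rbind(dropped, data.frame(snp_id = id, reason = reason,
                                           stringsAsFactors = FALSE))
    }
  }
  members <- data.frame(snp_id = member,
                        tag = sub("_snp[0-9]+$", "", member),
                        stringsAsFactors = FALSE)
  if (nrow(members)) {
    first <- tabs[[1]][match(member, tabs[[1]]$snp_id), , drop = FALSE]
    members$predictor <- first$predictor
    members$sign <- first$sign
    for (i in seq_along(tabs)) {
      members[[paste0("r_", locs[i])]] <-
        tabs[[i]]$r[match(member, tabs[[i]]$snp_id)]
    }
  } else {
    members$predictor <- character(0)
    members$sign <- integer(0)
  }
  structure(list(members = members, dropped = dropped, localities = locs,
                 scans = tabs), class = "parallel_set")
}

#' @export
print.parallel_set <- function(x, ...) {
  cat(sprintf("parallel_set: %d SNP(s) on %d locus/loci across %d localities\n",
              nrow(x$members), length(unique(x$members$tag)),
              length(x$localities)))
  if (nrow(x$members)) print(table(x$members$predictor, x$members$sign))
  invisible(x)
}

#' Exact multi-set intersection test
#'
#' Exact distribution of the intersection cardinality of k independent
#' uniformly random subsets of a background of size N, computed by iterated
#' hypergeometric folding: the overlap of the first two sets is
#' hypergeometric, and conditional on a current overlap of m the overlap
#' with the next set of size n_i is hypergeometric(N, m, n_i). The p-value
#' is the upper tail P(overlap >= x). For k = 2 this reduces to the
#' hypergeometric survival function.
#'
#' @param sizes Integer vector of set sizes (k >= 2), each <= `background`.
#' @param background Background population size N.
#' @param observed Observed intersection cardinality x.
#' @return An `intersection_test`: observed overlap, expected overlap,
#'   p-value, the full probability mass function over 0..min(sizes), and the
#'   inputs.
#' @export
multiset_intersection_test <- function(sizes, background, observed) {
  sizes <- as.integer(sizes)
  background <- as.integer(background)
  observed <- as.integer(observed)
  if (length(sizes) < 2L) stop("need at least two sets")
  if (any(sizes < 0) || any(sizes > background))
    stop("each set size must be in [0, background]")
  if (observed < 0 || observed > min(sizes))
    stop("observed overlap must be in [0, min(sizes)]")

  # pmf over intersection size, folded one set at a time
  pmf <- stats::dhyper(0:min(sizes[1], sizes[2]), sizes[1],
                       background - sizes[1], sizes[2])
  for (i in seq_along(sizes)[-(1:2)]) {
    m_max <- length(pmf) - 1L
    new_max <- min(m_max, sizes[i])
    new <- numeric(new_max + 1L)
    for (m in 0:m_max) {
      if (pmf[m + 1L] == 0) next
      j <- 0:min(m, sizes[i])
      new[j + 1L] <- new[j + 1L] +
        pmf[m + 1L] * stats::dhyper(j, m, background - m, sizes[i])
    }
    pmf <- new
  }
  support <- seq_along(pmf) - 1L
  expected <- sum(support * pmf)
  p <- if (observed == 0) 1 else sum(pmf[support >= observed])
  structure(list(observed = observed, expected = expected,
                 p_value = min(max(p, 0), 1), pmf = pmf, support = support,
                 sizes = sizes, background = background),
            class = "intersection_test")
}

#' @export
print.intersection_test <- function(x, ...) {
  cat(sprintf(
    "multi-set intersection: observed %d, expected %.3f (N = %d, sizes %s), p = %.4g\n",
    x$observed, x$expected, x$background,
    paste(x$sizes, collapse = "/"), x$p_value))
  invisible(x)
}

#' Chi-square test of settler-versus-survivor allele proportions
#'
#' Builds the 2x2 allele-count table (reference/alternate by group) from
#' genotype vectors - two alleles per homozygote, one per heterozygote,
#' missing calls ignored - and computes the Pearson chi-square without
#' continuity correction. When any expected count is below 5 the result
#' carries a low-count flag. A zero margin (e.g. a monomorphic SNP) makes
#' the statistic undefined and is reported as not applicable with a reason.
#'
#' @param genotypes_a,genotypes_b Genotype vectors (0/1/2/NA) for the two
#'   groups (e.g. settlers and survivors), or 2-length allele-count vectors
#'   `c(ref, alt)` when `counts = TRUE`.
#' @param counts Interpret inputs as ready-made allele counts.
#' @return List with `statistic`, `p_value`, `table` (observed counts),
#'   `expected`, `low_expected` flag, and `applicable`/`reason`.
#' @export
allele_freq_change_test <- function(genotypes_a, genotypes_b, counts = FALSE) {
  count_alleles <- function(g) {
    g <- g[!is.na(g)]
    c(ref = sum(2 - g), alt = sum(g))
  }
  tab <- if (counts) {
    rbind(a = genotypes_a, b = genotypes_b)
  } else {
    rbind(a = count_alleles(genotypes_a), b = count_alleles(genotypes_b))
  }
  colnames(tab) <- c("ref", "alt")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_, table = tab,
                expected = NULL, low_expected = NA, applicable = FALSE,
                reason = "zero margin: statistic undefined"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       table = tab, expected = expected,
       low_expected = any(expected < 5), applicable = TRUE, reason = NULL)
}

#' Categorize parallel SNPs by their predictor combinations
#'
#' A parallel SNP is "associated" with its assigned predictor and with every
#' further predictor whose absolute correlation reaches at least
#' `runner_up_frac` of the assigned predictor's in every locality, with a
#' consistent sign across localities. SNPs are then grouped by their exact
#' combination of associated predictors, and each combination's observed
#' intersection is tested with [multiset_intersection_test()] against the
#' per-predictor set sizes on the parallel-set background.
#'
#' @param pset A `parallel_set` whose scans carry `r_<predictor>` columns.
#' @param runner_up_frac Fraction of the assigned |r| a runner-up predictor
#'   must reach (default 0.9).
#' @return List with `membership` (logical SNPs x predictors matrix),
#'   `categories` (data frame: combination label, n_snps, observed overlap
#'   of the full predictor sets, p-value), and `set_sizes`.
#' @export
categorize_by_predictor <- function(pset, runner_up_frac = 0.9) {
  stopifnot(inherits(pset, "parallel_set"))
  members <- pset$members
  if (!nrow(members))
    return(list(membership = matrix(logical(0), 0, 0),
                categories = data.frame(combination = character(0),
                                        n_snps = integer(0),
                                        observed = integer(0),
                                        p_value = numeric(0)),
                set_sizes = integer(0)))
  rcols <- grep("^r_", names(pset$scans[[1]]), value = TRUE)
  preds <- sub("^r_", "", rcols)
  membership <- matrix(FALSE, nrow(members), length(preds),
                       dimnames = list(members$snp_id, preds))
  for (i in seq_len(nrow(members))) {
    id <- members$snp_id[i]
    assigned <- members$predictor[i]
    profs <- lapply(pset$scans, function(t)
      unlist(t[t$snp_id == id, rcols, drop = TRUE]))
    prof <- do.call(rbind, profs) # localities x predictors
    colnames(prof) <- preds
    thr <- abs(prof[, assigned]) * runner_up_frac
    ok <- vapply(seq_along(preds), function(j) {
      all(abs(prof[, j]) >= thr) &&
        (all(prof[, j] > 0) || all(prof[, j] < 0))
    }, logical(1))
    membership[i, ] <- ok
    membership[i, assigned] <- TRUE
  }
  combo <- apply(membership, 1, function(m) paste(preds[m], collapse = "+"))
  set_sizes <- colSums(membership)
  N <- nrow(members)
  cats <- lapply(split(seq_along(combo), combo), function(idx) {
    p_in <- strsplit(combo[idx[1]], "+", fixed = TRUE)[[1]]
    obs <- sum(apply(membership[, p_in, drop = FALSE], 1, all))
    pval <- if (length(p_in) >= 2L)
      multiset_intersection_test(set_sizes[p_in], N, obs)$p_value
    else NA_real_
    data.frame(combination = combo[idx[1]], n_snps = length(idx),
               observed = obs, p_value = pval, stringsAsFactors = FALSE)
  })
  categories <- do.call(rbind, cats)
  rownames(categories) <- NULL
  list(membership = membership, categories = categories,
       set_sizes = set_sizes)
}
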