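#' Screen predictors for collinearity and standardize them
#'
#' Walks predictor pairs in canonical life-stage order (hatch variables,
#' then larval, then settlement; see [predictor_names()]) and, for every
#' pair still present whose absolute Pearson correlation exceeds the
#' threshold, drops the later column. The survivors are standardized to
#' mean 0, SD 1. With the default phenotype structure this removes
#' settlement date, which is collinear with hatch date.
#'
#' @param pheno Data frame containing the predictor columns (extra columns
#'   such as `individual` are ignored).
#' @param threshold Absolute correlation above which the later predictor of
#'   a pair is dropped (default 0.8, strict inequality).
#' @param predictors Predictor columns to consider, in canonical order.
#' @return A `predictor_matrix`: list with the standardized `matrix`, a
#'   `dropped` data frame (predictor, partner, r), and the centering/scaling
#'   parameters.
#' @export
drop_correlated_predictors <- function(pheno, threshold = 0.8,
                                       predictors = predictor_names()) {
  predictors <- predictors[predictors %in% names(pheno)]
  if (length(predictors) < 2L) stop("at least two predictors required")
  X <- as.matrix(pheno[, predictors, drop = FALSE])
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant predictor(s): %s",
                 paste(predictors[sds == 0], collapse = ", ")))
  keep <- rep(TRUE, length(predictors))
  dropped <- data.frame(predictor = character(0), partner = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  cm <- stats::cor(X)
  for (i in seq_along(predictors)) {
    if (!keep[i]) next
    for (j in seq_along(predictors)) {
      if (j <= i || !keep[j]) next
      if (abs(cm[i, j]) > threshold) {
        keep[j] <- FALSE
        dropped <- rbind(dropped, data.frame(
          predictor = predictors[j], partner = predictors[i], r = cm[i, j],
          stringsAsFactors = FALSE))
      }
    }
  }
  Xk <- scale(X[, keep, drop = FALSE])
  structure(list(matrix = Xk[, , drop = FALSE],
                 predictors = predictors[keep],
                 dropped = dropped,
                 center = attr(Xk, "scaled:center"),
                 scale = attr(Xk, "scaled:scale")),
            class = "predictor_matrix")
}

#' Impute missing genotype calls by the within-group mode
#'
#' Replaces each missing call by the most common genotype code (0/1/2) of
#' that SNP in the supplied matrix (normally one locality's individuals);
#' ties go to the lower code. Columns with no observed call fall back to the
#' corresponding entry of `fallback` (e.g. the global modes) and are an
#' error when no fallback is given.
#'
#' @param calls Individuals x SNPs matrix of genotype codes with `NA`s.
#' @param fallback Optional named (by SNP) or positional vector of fallback
#'   codes for entirely missing columns.
#' @return The completed matrix.
#' @export
impute_missing_genotypes <- function(calls, fallback = NULL) {
  stopifnot(is.matrix(calls))
  counts <- cbind(colSums(calls == 0L, na.rm = TRUE),
                  colSums(calls == 1L, na.rm = TRUE),
                  colSums(calls == 2L, na.rm = TRUE))
  modes <- max.col(counts, ties.method = "first") - 1L # ties -> lower code
  empty <- rowSums(counts) == 0L
  if (any(empty)) {
    fb <- rep(NA_integer_, ncol(calls))
    if (!is.null(fallback)) {
      fb <- if (!is.null(colnames(calls)) && !is.null(names(fallback)))
        as.integer(fallback[colnames(calls)]) else as.integer(fallback)
    }
    modes[empty] <- fb[empty]
    if (anyNA(modes[empty]))
      stop(sprintf("SNP '%s' has no observed genotype and no fallback",
                   (colnames(calls) %||% seq_len(ncol(calls)))[empty][
                     is.na(modes[empty])][1]))
  }
  miss <- which(is.na(calls))
  if (length(miss))
    calls[miss] <- modes[((miss - 1L) %/% nrow(calls)) + 1L]
  calls
}

#' Fit a redundancy analysis of genotypes on predictors
#'
#' Column-centers the genotype matrix, projects it onto the column space of
#' the standardized predictors (ordinary least squares), and takes the
#' singular value decomposition of the fitted matrix. Constrained
#' eigenvalues are squared singular values divided by (n - 1); SNP loadings
#' are the unit-norm right singular vectors; site scores are the projections
#' of the fitted values onto the axes. Genotypes are intentionally not
#' variance-scaled (allele-count convention for genotype-environment
#' association scans); set `scale_genotypes = TRUE` to scale.
#'
#' @param genotypes Complete individuals x SNPs matrix of allele counts
#'   (impute first; see [impute_missing_genotypes()]).
#' @param predictors A `predictor_matrix` from
#'   [drop_correlated_predictors()], or a plain numeric matrix (standardized
#'   internally).
#' @param scale_genotypes Scale genotype columns to unit variance.
#' @return An `rda_fit`: eigenvalues, loadings (SNPs x axes), site scores,
#'   total and constrained inertia, and the predictor matrix used.
#' @export
rda_fit <- function(genotypes, predictors, scale_genotypes = FALSE) {
  Y <- as.matrix(genotypes)
  if (anyNA(Y)) stop("genotype matrix must be complete; impute first")
  X <- if (inherits(predictors, "predictor_matrix")) predictors$matrix else
    scale(as.matrix(predictors))
  n <- nrow(Y)
  if (nrow(X) != n) stop("genotypes and predictors must have matching rows")
  if (n <= ncol(X)) stop("need more individuals than predictors")
  Yc <- scale(Y, center = TRUE, scale = scale_genotypes)
  if (scale_genotypes) Yc[is.nan(Yc)] <- 0
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop(sprintf("rank-deficient predictors: rank %d < %d columns; remove collinear predictors",
                 qr_x$rank, ncol(X)))
  Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
  A <- crossprod(Q, Yc)            # p x SNPs; fitted = Q %*% A
  sv <- svd(A)
  pos <- sv$d > max(sv$d[1], 1e-300) * 1e-12
  d <- sv$d[pos]
  axes <- paste0("RDA", seq_along(d))
  loadings <- sv$v[, pos, drop = FALSE]
  dimnames(loadings) <- list(colnames(Y), axes)
  site_scores <- Q %*% sv$u[, pos, drop = FALSE] %*% diag(d, length(d))
  dimnames(site_scores) <- list(rownames(Y), axes)
  eig <- d^2 / (n - 1)
  names(eig) <- axes
  structure(list(eigenvalues = eig,
                 loadings = loadings,
                 site_scores = site_scores,
                 total_inertia = sum(Yc^2) / (n - 1),
                 constrained_inertia = sum(eig),
                 n = n, predictors = X),
            class = "rda_fit")
}

#' Flag outlier SNPs by extreme axis loadings
#'
#' On each of the first `n_axes` constrained axes, flags SNPs whose loading
#' falls outside mean +/- `sd_mult` standard deviations of that axis's
#' loading distribution (for standard-normal loadings and the default
#' multiplier of 3 this tags a two-tailed fraction of about 0.0027). The
#' result is the union over axes. A degenerate axis with zero loading spread
#' flags nothing.
#'
#' @param fit An `rda_fit`.
#' @param n_axes Number of leading axes screened (default: all).
#' @param sd_mult Standard-deviation multiplier (default 3).
#' @return Data frame of flagged SNPs (`snp_id`, `axis`, `loading`); one row
#'   per SNP, attributed to the first axis that flagged it.
#' @export
detect_outliers <- function(fit, n_axes = NULL, sd_mult = 3) {
  stopifnot(inherits(fit, "rda_fit"))
  n_avail <- ncol(fit$loadings)
  n_axes <- min(n_axes %||% n_avail, n_avail)
  flagged <- data.frame(snp_id = character(0), axis = character(0),
                        loading = numeric(0), stringsAsFactors = FALSE)
  seen <- character(0)
  for (k in seq_len(n_axes)) {
    l <- fit$loadings[, k]
    s <- stats::sd(l)
    if (!is.finite(s) || s == 0) next
    m <- mean(l)
    hit <- names(l)[l < m - sd_mult * s | l > m + sd_mult * s]
    hit <- setdiff(hit, seen)
    if (length(hit)) {
      flagged <- rbind(flagged, data.frame(
        snp_id = hit, axis = colnames(fit$loadings)[k],
        loading = l[hit], stringsAsFactors = FALSE))
      seen <- c(seen, hit)
    }
  }
  rownames(flagged) <- NULL
  flagged
}

#' Assign each outlier SNP to its best-correlated predictor
#'
#' Computes the Pearson correlation of each flagged SNP's genotype vector
#' with every retained predictor; the assigned predictor is the one with the
#' largest absolute correlation (ties broken by canonical predictor order)
#' and the sign of that correlation is recorded. SNPs with zero variance
#' after imputation are dropped with a warning.
#'
#' @param genotypes Complete genotype matrix (same rows as the predictors).
#' @param predictors A `predictor_matrix` or standardized matrix.
#' @param snp_ids SNPs to assign (default: all columns).
#' @return Data frame with `snp_id`, `predictor`, `r`, `sign`, plus one
#'   `r_<predictor>` column per retained predictor holding the full
#'   correlation profile.
#' @export
assign_predictor <- function(genotypes, predictors, snp_ids = colnames(genotypes)) {
  X <- if (inherits(predictors, "predictor_matrix")) predictors$matrix else
    scale(as.matrix(predictors))
  G <- as.matrix(genotypes[, snp_ids, drop = FALSE])
  sds <- apply(G, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropped %d zero-variance SNP(s) from assignment",
                    sum(sds == 0)))
    G <- G[, sds > 0, drop = FALSE]
    snp_ids <- colnames(G)
  }
  if (!ncol(G))
    return(data.frame(snp_id = character(0), predictor = character(0),
                      r = numeric(0), sign = integer(0)))
  R <- stats::cor(G, X) # SNPs x predictors
  best <- apply(abs(R), 1, which.max) # first max = canonical order tie-break
  out <- data.frame(snp_id = snp_ids,
                    predictor = colnames(X)[best],
                    r = R[cbind(seq_len(nrow(R)), best)],
                    stringsAsFactors = FALSE)
  out$sign <- ifelse(out$r >= 0, 1L, -1L)
  rcols <- as.data.frame(R)
  names(rcols) <- paste0("r_", colnames(X))
  rownames(out) <- NULL
  cbind(out, rcols, stringsAsFactors = FALSE)
}

#' Per-locality RDA candidate scan
#'
#' Convenience wrapper running the whole per-locality genotype-environment
#' association scan: subset the cohort to one locality (settlers and
#' survivors pooled), impute missing genotypes by the within-locality mode,
#' standardize the screened predictors within the locality, fit the RDA,
#' flag loading outliers and assign each to its strongest predictor.
#'
#' @param cohort A `cohort_genotypes` object.
#' @param pheno Phenotype data frame with an `individual` column.
#' @param locality Locality label to scan.
#' @param predictors Predictor columns to use (canonical order) - normally
#'   the retained set after [drop_correlated_predictors()] on the full table.
#' @param n_axes,sd_mult Outlier-detection controls; see [detect_outliers()].
#' @param scale_genotypes Passed to [rda_fit()].
#' @return An `rda_scan`: the locality, the fit, the outlier table merged
#'   with predictor assignments, and the predictor matrix.
#' @export
rda_scan <- function(cohort, pheno, locality, predictors = NULL,
                     n_axes = NULL, sd_mult = 3, scale_genotypes = FALSE) {
  stopifnot(inherits(cohort, "cohort_genotypes"))
  rows <- which(cohort$individuals$locality == locality)
  if (!length(rows)) stop(sprintf("no individuals in locality '%s'", locality))
  ids <- cohort$individuals$individual[rows]
  ph <- pheno[match(ids, pheno$individual), , drop = FALSE]
  if (anyNA(ph$individual)) stop("phenotype table is missing individuals")
  pm <- drop_correlated_predictors(
    ph, predictors = predictors %||% predictor_names())
  calls <- cohort$calls[rows, , drop = FALSE]
  global_counts <- cbind(colSums(cohort$calls == 0L, na.rm = TRUE),
                         colSums(cohort$calls == 1L, na.rm = TRUE),
                         colSums(cohort$calls == 2L, na.rm = TRUE))
  global_mode <- stats::setNames(max.col(global_counts, ties.method = "first") - 1L,
                                 colnames(cohort$calls))
  calls <- impute_missing_genotypes(calls, fallback = global_mode)
  fit <- rda_fit(calls, pm, scale_genotypes = scale_genotypes)
  out <- detect_outliers(fit, n_axes = n_axes, sd_mult = sd_mult)
  if (nrow(out)) {
    asg <- assign_predictor(calls, pm, snp_ids = out$snp_id)
    out <- merge(out, asg, by = "snp_id", sort = FALSE)
  } else {
    out$predictor <- character(0)
    out$r <- numeric(0)
    out$sign <- integer(0)
  }
  structure(list(locality = locality, fit = fit, candidates = out,
                 predictor_matrix = pm), class = "rda_scan")
}

#' @export
print.rda_scan <- function(x, ...) {
  cat(sprintf("rda_scan [%s]: %d axes, %d candidate SNP(s)\n",
              x$locality, length(x$fit$eigenvalues), nrow(x$candidates)))
  invisible(x)
}
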