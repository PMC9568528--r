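#' Permutational multivariate analysis of variance (pseudo-F)
#'
#' PERMANOVA on a distance matrix in the McArdle-Anderson formulation: the
#' squared distances are Gower-centered into an inner-product matrix G and
#' sequential (Type I) sums of squares are extracted as traces of `H %*% G`
#' for the cumulative hat matrices of the model terms. The pseudo-F of each
#' term uses the residual mean square of the full model; significance is
#' assessed by free permutation of individuals. With a univariate response
#' and Euclidean distance the pseudo-F of a single factor equals the
#' classical one-way ANOVA F statistic.
#'
#' @param formula Model formula, e.g. `y ~ age_group * locality`. The left
#'   side is a numeric vector or matrix (columns = response variables); terms
#'   are entered sequentially in formula order.
#' @param data Data frame holding the factors (and optionally the response).
#' @param n_perm Number of permutations (default 999). `0` skips the test.
#' @param seed Optional integer seed.
#' @param distance `"euclidean"` (default), `"manhattan"`, or `"gower"`
#'   (range-normalised manhattan).
#' @return A `permanova_result`: data frame of terms with df, SS, pseudo-F,
#'   r2 and permutation p, plus residual and total rows. Term r2 values and
#'   the residual r2 sum to 1.
#' @export
permanova <- function(formula, data, n_perm = 999, seed = NULL,
                      distance = c("euclidean", "manhattan", "gower")) {
  distance <- match.arg(distance)
  if (!is.null(seed)) set.seed(seed)
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  y <- as.matrix(y)
  if (anyNA(y)) stop("missing values in the response are not allowed")
  n <- nrow(y)

  D <- switch(distance,
    euclidean = stats::dist(y, method = "euclidean"),
    manhattan = stats::dist(y, method = "manhattan"),
    gower = {
      rng <- apply(y, 2, function(v) diff(range(v)))
      rng[rng == 0] <- 1
      stats::dist(sweep(y, 2, rng, "/"), method = "manhattan") / ncol(y)
    })
  A <- -0.5 * as.matrix(D)^2
  Jc <- diag(n) - matrix(1 / n, n, n)
  G <- Jc %*% A %*% Jc
  ss_total <- sum(diag(G))
  if (ss_total <= .Machine$double.eps * n)
    stop("degenerate response: zero total sum of squares")

  trm <- stats::terms(formula, data = data)
  term_labels <- attr(trm, "term.labels")
  if (!length(term_labels)) stop("formula must contain at least one term")
  hats <- vector("list", length(term_labels))
  ranks <- numeric(length(term_labels))
  for (i in seq_along(term_labels)) {
    f_i <- stats::reformulate(term_labels[seq_len(i)])
    X <- stats::model.matrix(f_i, data = mf)
    qr_x <- qr(X)
    Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
    hats[[i]] <- tcrossprod(Q)
    ranks[i] <- qr_x$rank
  }
  df_terms <- diff(c(1, ranks)) # intercept absorbs 1 df
  rank_full <- ranks[length(ranks)]
  df_res <- n - rank_full
  if (df_res <= 0) stop("no residual degrees of freedom")

  ss_seq <- function(Gm) {
    cum <- vapply(hats, function(H) sum(H * Gm), numeric(1))
    diff(c(0, cum))
  }
  ss_terms <- ss_seq(G)
  ss_res <- ss_total - sum(ss_terms)
  ms_res <- ss_res / df_res
  f_obs <- (ss_terms / df_terms) / ms_res

  p_vals <- rep(NA_real_, length(term_labels))
  if (n_perm > 0) {
    exceed <- numeric(length(term_labels))
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      Gp <- G[idx, idx]
      ssp <- ss_seq(Gp)
      ssr <- ss_total - sum(ssp)
      fp <- (ssp / df_terms) / (ssr / df_res)
      exceed <- exceed + (fp >= f_obs)
    }
    p_vals <- (1 + exceed) / (n_perm + 1)
  }

  tab <- data.frame(
    term = c(term_labels, "Residual", "Total"),
    df = c(df_terms, df_res, n - 1),
    ss = c(ss_terms, ss_res, ss_total),
    pseudo_F = c(f_obs, NA, NA),
    r2 = c(ss_terms, ss_res, ss_total) / ss_total,
    p = c(p_vals, NA, NA),
    row.names = NULL)
  structure(list(table = tab, n = n, distance = distance,
                 n_permutations = n_perm), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s distance, %d permutations, n = %d)\n",
              x$distance, x$n_permutations, x$n))
  print(x$table, digits = 4)
  invisible(x)
}
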