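#' Configuration for the synthetic settler/survivor cohort generator
#'
#' Builds and validates the parameter set of the viability-selection cohort
#' simulator. Defaults describe three localities with hierarchical
#' differentiation (locality 1 versus a pair of southern localities sharing a
#' parent gene pool), 200 settlers and 100 survivors sampled per locality,
#' 5000 neutral RAD-tag loci plus 50 selected single-SNP loci, an allelic
#' effect of 0.8 phenotype standard deviations on the linked predictor, and a
#' logistic viability-selection coefficient of 2.
#'
#' @param n_localities Number of sampled localities.
#' @param n_settlers_per_locality,n_survivors_per_locality Sampled cohort
#'   sizes per locality.
#' @param n_neutral_loci,n_selected_loci Numbers of neutral and selected
#'   RAD-tag loci. Selected loci carry exactly one SNP; neutral loci carry
#'   1-3 SNPs according to `snps_per_tag_probs`.
#' @param snps_per_tag_probs Probabilities of a neutral tag carrying 1, 2 or
#'   3 SNPs.
#' @param fst_baseline Balding-Nichols differentiation parameter F in (0,1)
#'   between locality 1 and the shared southern parent pool.
#' @param fst_within Differentiation of each southern locality from the
#'   shared parent pool (hierarchical model); ignored when
#'   `hierarchical = FALSE`.
#' @param hierarchical If `TRUE` (default for 3 localities) localities 2 and 3
#'   descend from one parent frequency drawn once, emulating a two-sided
#'   oceanographic front; if `FALSE` all localities draw independently at
#'   `fst_baseline`.
#' @param ancestral_maf_range Interval within (0.05, 0.5) for the ancestral
#'   alternate-allele frequency draw.
#' @param effect_size_beta Shift of the linked predictor (in latent SD units)
#'   per copy of the alternate allele at a selected SNP.
#' @param selection_strength Logistic coefficient of the (mean) linked
#'   predictor on survival.
#' @param linked_predictors Predictors that selected SNPs are attached to,
#'   round-robin. Defaults to the six continuous variables retained after the
#'   collinearity screen.
#' @param pheno_corr_matrix 9x9 target correlation matrix of the latent
#'   predictors, in [predictor_names()] order; must be positive semi-definite
#'   and is required to contain at least one pair with |r| > 0.8 (by default
#'   hatch date vs settlement date, r = 0.9).
#' @param mean_depth,depth_dispersion Negative-binomial read-depth model
#'   (mean and size); defaults reproduce a mean depth near 29.7 with SD near
#'   13.5, overdispersed relative to Poisson.
#' @param missing_rate Per-call missingness probability in [0, 1).
#' @param pool_multiplier The virtual settler pool from which survivors are
#'   accepted is `pool_multiplier * n_survivors_per_locality` individuals.
#' @param locality_names Optional locality labels.
#' @param seed Integer random seed; identical configurations and seeds give
#'   byte-identical outputs.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_localities = 3L,
                              n_settlers_per_locality = 200L,
                              n_survivors_per_locality = 100L,
                              n_neutral_loci = 5000L,
                              n_selected_loci = 50L,
                              snps_per_tag_probs = c(0.65, 0.25, 0.10),
                              fst_baseline = 0.01,
                              fst_within = 0.002,
                              hierarchical = (n_localities == 3L),
                              ancestral_maf_range = c(0.1, 0.5),
                              effect_size_beta = 0.8,
                              selection_strength = 2,
                              linked_predictors = c("hatch_date", "hatch_size",
                                                    "pld", "grpld", "sst",
                                                    "settlement_size"),
                              pheno_corr_matrix = default_pheno_corr(),
                              mean_depth = 29.7,
                              depth_dispersion = 5.7,
                              missing_rate = 0.05,
                              pool_multiplier = 5,
                              locality_names = NULL,
                              seed = 1L) {
  counts <- c(n_localities = n_localities,
              n_settlers_per_locality = n_settlers_per_locality,
              n_survivors_per_locality = n_survivors_per_locality,
              n_neutral_loci = n_neutral_loci)
  if (any(counts <= 0)) stop("all cohort/locus counts must be positive")
  if (n_selected_loci < 0) stop("n_selected_loci must be >= 0")
  if (!(fst_baseline > 0 && fst_baseline < 1)) stop("fst_baseline must be in (0,1)")
  if (!(fst_within > 0 && fst_within < 1)) stop("fst_within must be in (0,1)")
  stopifnot_scalar_prob(missing_rate, "missing_rate", open_right = TRUE)
  if (length(ancestral_maf_range) != 2L ||
      ancestral_maf_range[1] < 0.05 - 1e-9 || ancestral_maf_range[2] > 0.5 + 1e-9 ||
      diff(ancestral_maf_range) <= 0)
    stop("ancestral_maf_range must be an increasing interval within [0.05, 0.5]")
  if (length(snps_per_tag_probs) != 3L || any(snps_per_tag_probs < 0) ||
      abs(sum(snps_per_tag_probs) - 1) > 1e-8)
    stop("snps_per_tag_probs must be three probabilities summing to 1")
  pn <- predictor_names()
  if (!all(linked_predictors %in% pn))
    stop("linked_predictors must be a subset of predictor_names()")
  if (!is.matrix(pheno_corr_matrix) || any(dim(pheno_corr_matrix) != 9L))
    stop("pheno_corr_matrix must be 9x9")
  ev <- eigen(pheno_corr_matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("pheno_corr_matrix must be positive semi-definite")
  if (max(abs(pheno_corr_matrix[upper.tri(pheno_corr_matrix)])) <= 0.8)
    stop("pheno_corr_matrix must contain at least one pair with |r| > 0.8")
  if (pool_multiplier * n_survivors_per_locality < n_survivors_per_locality)
    stop("pool_multiplier must be >= 1")
  if (is.null(locality_names))
    locality_names <- paste0("loc", seq_len(n_localities))
  structure(list(
    n_localities = as.integer(n_localities),
    n_settlers_per_locality = as.integer(n_settlers_per_locality),
    n_survivors_per_locality = as.integer(n_survivors_per_locality),
    n_neutral_loci = as.integer(n_neutral_loci),
    n_selected_loci = as.integer(n_selected_loci),
    snps_per_tag_probs = snps_per_tag_probs,
    fst_baseline = fst_baseline, fst_within = fst_within,
    hierarchical = isTRUE(hierarchical),
    ancestral_maf_range = ancestral_maf_range,
    effect_size_beta = effect_size_beta,
    selection_strength = selection_strength,
    linked_predictors = linked_predictors,
    pheno_corr_matrix = pheno_corr_matrix,
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    missing_rate = missing_rate,
    pool_multiplier = pool_multiplier,
    locality_names = locality_names,
    seed = as.integer(seed)), class = "simulation_config")
}

#' Default latent correlation structure of the nine predictors
#'
#' Hatch date and settlement date are strongly collinear (r = 0.9, the pair
#' the downstream collinearity screen is expected to prune); larval growth
#' rate correlates positively with temperature and negatively with larval
#' duration; hatch and settlement sizes correlate moderately. All remaining
#' pairs are uncorrelated.
#'
#' @return 9x9 positive-definite correlation matrix in [predictor_names()]
#'   order.
#' @export
default_pheno_corr <- function() {
  pn <- predictor_names()
  C <- diag(9)
  dimnames(C) <- list(pn, pn)
  set_r <- function(a, b, r) {
    C[a, b] <<- r
    C[b, a] <<- r
  }
  set_r("hatch_date", "settlement_date", 0.9)
  set_r("grpld", "sst", 0.4)
  set_r("pld", "grpld", -0.3)
  set_r("hatch_size", "settlement_size", 0.3)
  C
}

# draw per-locality allele frequencies under the Balding-Nichols model
balding_nichols <- function(p, F) {
  shape1 <- p * (1 - F) / F
  shape2 <- (1 - p) * (1 - F) / F
  q <- stats::rbeta(length(p), shape1, shape2)
  pmin(pmax(q, 1e-6), 1 - 1e-6)
}

# latent multivariate-normal predictors for n individuals
draw_latent_pheno <- function(n, corr) {
  L <- chol(corr + diag(1e-10, nrow(corr)))
  z <- matrix(stats::rnorm(n * nrow(corr)), n, nrow(corr)) %*% L
  colnames(z) <- colnames(corr)
  z
}

#' Simulate a settler/survivor cohort with planted viability selection
#'
#' Generates, per locality: Balding-Nichols allele frequencies (localities 2+
#' optionally sharing a parent frequency, emulating a north/south
#' oceanographic split); Hardy-Weinberg settler genotypes drawn as two phased
#' gametes; latent multivariate-normal phenotypes shifted by
#' `effect_size_beta` per alternate allele at each selected SNP; a virtual
#' settler pool from which survivors are accepted with probability
#' `plogis(selection_strength * mean(linked predictors))`, producing
#' allele-frequency shifts at selected loci; and negative-binomial read
#' depths with random per-call missingness. Moon-phase variables are
#' discretised to the ordinal levels 0-9.
#'
#' @param config A [simulation_config()].
#' @return List with elements `cohort` (a `cohort_genotypes` object: sampled
#'   settlers plus survivors), `pheno` (data frame of the nine predictors per
#'   sampled individual) and `truth` (per-SNP truth table with selected flag,
#'   linked predictor, effect sign and realised settler/survivor allele
#'   frequencies per locality).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cfg <- config
  pn <- predictor_names()

  ## --- locus map ----------------------------------------------------------
  n_tags <- cfg$n_neutral_loci + cfg$n_selected_loci
  snps_per_tag <- c(sample(1:3, cfg$n_neutral_loci, replace = TRUE,
                           prob = cfg$snps_per_tag_probs),
                    rep(1L, cfg$n_selected_loci))
  tag_id <- rep(seq_len(n_tags), snps_per_tag)
  n_snps <- length(tag_id)
  snp_in_tag <- sequence(snps_per_tag)
  selected_tag <- tag_id > cfg$n_neutral_loci
  snp_id <- sprintf("tag%d_snp%d", tag_id, snp_in_tag)
  # 34-bp tags tiled on synthetic contigs, 100 tags per contig
  contig <- sprintf("contig_%d", (tag_id - 1L) %/% 100L + 1L)
  tag_start <- ((tag_id - 1L) %% 100L) * 1000L + 1L
  pos_in_tag <- ifelse(snps_per_tag[tag_id] == 1L, 17L,
                       5L + (snp_in_tag - 1L) * 12L)
  pos <- tag_start + pos_in_tag - 1L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

  ## --- allele frequencies -------------------------------------------------
  p_anc <- stats::runif(n_snps, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
  p_loc <- matrix(NA_real_, n_snps, cfg$n_localities)
  if (cfg$hierarchical && cfg$n_localities >= 3L) {
    p_loc[, 1] <- balding_nichols(p_anc, cfg$fst_baseline)
    p_parent <- balding_nichols(p_anc, cfg$fst_baseline)
    for (k in 2:cfg$n_localities)
      p_loc[, k] <- balding_nichols(p_parent, cfg$fst_within)
  } else {
    for (k in seq_len(cfg$n_localities))
      p_loc[, k] <- balding_nichols(p_anc, cfg$fst_baseline)
  }

  ## --- selected-SNP bookkeeping -------------------------------------------
  sel_idx <- which(selected_tag)
  sel_pred <- character(0)
  sel_sign <- integer(0)
  if (length(sel_idx)) {
    sel_pred <- rep(cfg$linked_predictors, length.out = length(sel_idx))
    sel_sign <- sample(c(-1L, 1L), length(sel_idx), replace = TRUE)
  }
  pred_used <- unique(sel_pred)

  draw_group <- function(n, k) {
    a1 <- matrix(stats::rbinom(n * n_snps, 1L, rep(p_loc[, k], each = n)), n, n_snps)
    a2 <- matrix(stats::rbinom(n * n_snps, 1L, rep(p_loc[, k], each = n)), n, n_snps)
    z <- draw_latent_pheno(n, cfg$pheno_corr_matrix)
    g <- a1 + a2
    # effects act on the centered allele count, so selected loci shift the
    # predictor without shifting its population mean (and hence without
    # biasing overall survival)
    for (j in seq_along(sel_idx))
      z[, sel_pred[j]] <- z[, sel_pred[j]] +
        sel_sign[j] * cfg$effect_size_beta *
          (g[, sel_idx[j]] - 2 * p_loc[sel_idx[j], k])
    list(a1 = a1, a2 = a2, z = z)
  }

  localities <- cfg$locality_names
  blocks <- list()
  truth_freq <- vector("list", cfg$n_localities)
  for (k in seq_len(cfg$n_localities)) {
    settlers <- draw_group(cfg$n_settlers_per_locality, k)
    pool_n <- ceiling(cfg$pool_multiplier * cfg$n_survivors_per_locality)
    pool <- draw_group(pool_n, k)
    # viability selection on the mean of the linked predictors
    lin <- if (length(pred_used)) rowMeans(pool$z[, pred_used, drop = FALSE]) else
      rep(0, pool_n)
    acc <- stats::runif(pool_n) < stats::plogis(cfg$selection_strength * lin)
    if (sum(acc) < cfg$n_survivors_per_locality)
      stop(sprintf(paste0("cannot draw %d survivors in locality '%s': only %d of ",
                          "%d pool settlers were accepted; increase pool_multiplier ",
                          "or reduce selection_strength"),
                   cfg$n_survivors_per_locality, localities[k], sum(acc), pool_n))
    keep <- which(acc)[seq_len(cfg$n_survivors_per_locality)]
    surv <- list(a1 = pool$a1[keep, , drop = FALSE],
                 a2 = pool$a2[keep, , drop = FALSE],
                 z = pool$z[keep, , drop = FALSE])
    blocks[[k]] <- list(settlers = settlers, survivors = surv)
    truth_freq[[k]] <- data.frame(
      settler_freq = colMeans(settlers$a1 + settlers$a2) / 2,
      survivor_freq = colMeans(surv$a1 + surv$a2) / 2)
  }

  ## --- assemble sampled cohort --------------------------------------------
  n_per_loc <- cfg$n_settlers_per_locality + cfg$n_survivors_per_locality
  ind <- do.call(rbind, lapply(seq_len(cfg$n_localities), function(k) {
    data.frame(
      individual = c(sprintf("%s_set_%03d", localities[k],
                             seq_len(cfg$n_settlers_per_locality)),
                     sprintf("%s_sur_%03d", localities[k],
                             seq_len(cfg$n_survivors_per_locality))),
      locality = localities[k],
      age_group = rep(c("settler", "survivor"),
                      c(cfg$n_settlers_per_locality, cfg$n_survivors_per_locality)),
      stringsAsFactors = FALSE)
  }))
  a1 <- do.call(rbind, lapply(blocks, function(b) rbind(b$settlers$a1, b$survivors$a1)))
  a2 <- do.call(rbind, lapply(blocks, function(b) rbind(b$settlers$a2, b$survivors$a2)))
  z <- do.call(rbind, lapply(blocks, function(b) rbind(b$settlers$z, b$survivors$z)))
  n_ind <- nrow(ind)

  ## --- depth and missingness ----------------------------------------------
  depth <- matrix(stats::rnbinom(n_ind * n_snps, mu = cfg$mean_depth,
                                 size = cfg$depth_dispersion), n_ind, n_snps)
  miss <- matrix(stats::runif(n_ind * n_snps) < cfg$missing_rate, n_ind, n_snps)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  calls <- a1 + a2
  dimnames(calls) <- list(ind$individual, snp_id)
  dimnames(depth) <- dimnames(a1) <- dimnames(a2) <- dimnames(calls)

  ## --- phenotype table (moons discretised to ordinal 0-9) ------------------
  pheno <- as.data.frame(z)
  names(pheno) <- pn
  for (m in c("moon_hatch", "moon_settlement")) {
    sdm <- stats::sd(pheno[[m]])
    pheno[[m]] <- pmin(pmax(floor(10 * stats::pnorm(pheno[[m]] / sdm)), 0L), 9L)
    pheno[[m]] <- as.integer(pheno[[m]])
  }
  pheno <- cbind(individual = ind$individual, pheno)
  rownames(pheno) <- NULL

  snps <- data.frame(snp_id = snp_id, tag = paste0("tag", tag_id),
                     contig = contig, pos = pos, pos_in_tag = pos_in_tag,
                     ref = ref, alt = alt, stringsAsFactors = FALSE)

  truth <- data.frame(
    snp_id = snp_id, tag = paste0("tag", tag_id),
    selected = selected_tag,
    predictor = NA_character_, effect_sign = NA_integer_,
    ancestral_freq = p_anc, stringsAsFactors = FALSE)
  if (length(sel_idx)) {
    truth$predictor[sel_idx] <- sel_pred
    truth$effect_sign[sel_idx] <- sel_sign
  }
  for (k in seq_len(cfg$n_localities)) {
    truth[[paste0("freq_", localities[k])]] <- p_loc[, k]
    truth[[paste0("settler_freq_", localities[k])]] <- truth_freq[[k]]$settler_freq
    truth[[paste0("survivor_freq_", localities[k])]] <- truth_freq[[k]]$survivor_freq
  }

  cohort <- structure(list(individuals = ind, snps = snps, calls = calls,
                           depth = depth, allele1 = a1, allele2 = a2,
                           phased = TRUE),
                      class = "cohort_genotypes")
  list(cohort = cohort, pheno = pheno, truth = truth)
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat(sprintf("cohort_genotypes: %d individuals x %d SNPs (%d tags, %s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$snps$tag)),
              if (isTRUE(x$phased)) "phased" else "unphased"))
  tab <- table(x$individuals$locality, x$individuals$age_group)
  print(tab)
  invisible(x)
}

#' Write a cohort as a VCF 4.2 file
#'
#' Emits biallelic SNP records with `GT:DP` sample fields. Genotypes are
#' written phased (`0|1`) when the cohort carries phased gametes and unphased
#' otherwise; missing calls are `./.`. SNP IDs follow the `tag<k>_snp<j>`
#' convention that groups SNPs into RAD-tag loci.
#'
#' @param cohort A `cohort_genotypes` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_genotypes"))
  snps <- cohort$snps
  n_ind <- nrow(cohort$calls)
  sep <- if (isTRUE(cohort$phased)) "|" else "/"
  gt_from <- function(a1, a2) {
    out <- paste0(a1, sep, a2)
    out[is.na(a1) | is.na(a2)] <- "./."
    out
  }
  if (!is.null(cohort$allele1)) {
    gt <- gt_from(cohort$allele1, cohort$allele2)
  } else {
    gmap <- c("0/0", "0/1", "1/1")
    gt <- ifelse(is.na(cohort$calls), "./.", gmap[cohort$calls + 1L])
  }
  dim(gt) <- dim(cohort$calls)
  body <- matrix(paste0(gt, ":", ifelse(is.na(cohort$depth), ".", cohort$depth)),
                 nrow = n_ind)
  contigs <- unique(snps$contig)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=survscan",
    sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$individuals$individual), collapse = "\t"))
  fixed <- paste(snps$contig, snps$pos, snps$snp_id, snps$ref, snps$alt,
                 ".", "PASS", ".", "GT:DP", sep = "\t")
  records <- paste(fixed, apply(body, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, records), path)
  invisible(path)
}

#' Write individual metadata and phenotype tables
#'
#' `write_metadata()` writes the individual/locality/age-group table;
#' `write_phenotypes()` writes the nine named predictor columns keyed by
#' individual. Both are UTF-8 CSV with a header row.
#'
#' @param cohort A `cohort_genotypes` object.
#' @param pheno Phenotype data frame from [simulate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_genotypes"))
  utils::write.csv(cohort$individuals, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
write_phenotypes <- function(pheno, path) {
  stopifnot(all(c("individual", predictor_names()) %in% names(pheno)))
  utils::write.csv(pheno[, c("individual", predictor_names())], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
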