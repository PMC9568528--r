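#' Build and validate an end-to-end run configuration
#'
#' A single configuration object drives the whole pipeline; every threshold
#' of the analysis surfaces as a named, defaulted field, so a standard run
#' is "defaults plus data paths". Configurations can be read from a YAML
#' file. When `simulate` is supplied, input files are generated by the
#' synthetic-cohort module instead of being read from `vcf`/`metadata`/
#' `phenotypes`.
#'
#' @param vcf,metadata,phenotypes Input file paths (ignored when
#'   `simulate` is given).
#' @param blast,gff Optional annotation inputs; the annotation stage runs
#'   only when both are present.
#' @param output_dir Directory for all stage outputs.
#' @param simulate `NULL`, or a [simulation_config()] (or list of its
#'   arguments).
#' @param filter A [filter_config()] or list of its arguments.
#' @param cor_threshold Predictor collinearity threshold (default 0.8).
#' @param sd_mult Loading-outlier SD multiplier (default 3).
#' @param n_axes Axes screened for outliers (`NULL` = all).
#' @param scale_genotypes Variance-scale genotypes in the RDA.
#' @param evalue_cutoff BLAST E-value cutoff (default 1e-4).
#' @param n_perm Permutations for F_ST and PERMANOVA (default 999).
#' @param seed Master seed; stage seeds are derived from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(vcf = NULL, metadata = NULL, phenotypes = NULL,
                       blast = NULL, gff = NULL,
                       output_dir = "survscan_out",
                       simulate = NULL,
                       filter = filter_config(),
                       cor_threshold = 0.8, sd_mult = 3, n_axes = NULL,
                       scale_genotypes = FALSE,
                       evalue_cutoff = 1e-4, n_perm = 999, seed = 1L) {
  if (is.list(filter) && !inherits(filter, "filter_config"))
    filter <- do.call(filter_config, filter)
  if (!is.null(simulate) && !inherits(simulate, "simulation_config"))
    simulate <- do.call(simulation_config, as.list(simulate))
  if (is.null(simulate)) {
    if (is.null(vcf) || is.null(metadata) || is.null(phenotypes))
      stop("vcf, metadata and phenotypes paths are required unless simulating")
    missing <- c(vcf, metadata, phenotypes)[!file.exists(c(vcf, metadata, phenotypes))]
    if (length(missing))
      stop(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")))
  }
  for (p in c(blast, gff))
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("input file not found: %s", p))
  structure(list(vcf = vcf, metadata = metadata, phenotypes = phenotypes,
                 blast = blast, gff = gff, output_dir = output_dir,
                 simulate = simulate, filter = filter,
                 cor_threshold = cor_threshold, sd_mult = sd_mult,
                 n_axes = n_axes, scale_genotypes = scale_genotypes,
                 evalue_cutoff = evalue_cutoff, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments
#'   (`simulate:` and `filter:` may be nested maps of their own arguments).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full selective-mortality pipeline
#'
#' Executes, in order: optional cohort simulation; the variant filter
#' cascade and haplotype collapse; population-structure statistics
#' (pairwise settler and survivor F_ST between localities with permutation
#' p-values, one PERMANOVA per predictor on age group x locality, DAPC on
#' haplotype allele dosages); one RDA candidate scan per locality; the
#' cross-locality parallel set with settler-versus-survivor allele-frequency
#' chi-square tests and predictor-combination intersection tests; and, when
#' BLAST and GFF inputs are configured, locus annotation with mapping-class
#' enrichment. All stage outputs land in `output_dir` and a JSON manifest
#' records per-stage input/output counts and file checksums; rerunning an
#' identical configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest, invisibly (also written to
#'   `output_dir/manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(package_version = as.character(utils::packageVersion("survscan")),
                   config_hash = object_md5(config), stages = list())
  outfile <- function(x) file.path(config$output_dir, x)
  stage_done <- function(name, ...) {
    manifest$stages[[name]] <<- c(list(stage = name, elapsed_s = round(
      as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)), list(...))
  }

  ## stage 1: inputs (simulated or on disk)
  if (!is.null(config$simulate)) {
    say("stage simulate: generating synthetic cohort")
    sim <- simulate_cohort(config$simulate)
    vcf_path <- outfile("cohort.vcf")
    meta_path <- outfile("metadata.csv")
    pheno_path <- outfile("phenotypes.csv")
    write_cohort_vcf(sim$cohort, vcf_path)
    write_metadata(sim$cohort, meta_path)
    write_phenotypes(sim$pheno, pheno_path)
    utils::write.csv(sim$truth, outfile("truth.csv"), row.names = FALSE)
    stage_done("simulate", n_individuals = nrow(sim$cohort$individuals),
               n_snps = ncol(sim$cohort$calls))
  } else {
    vcf_path <- config$vcf
    meta_path <- config$metadata
    pheno_path <- config$phenotypes
    stage_done("simulate", skipped = TRUE)
  }

  ## stage 2: filter cascade + haplotype collapse
  say("stage filter: reading VCF and applying the filter cascade")
  cohort <- read_cohort_vcf(vcf_path, meta_path)
  pheno <- utils::read.csv(pheno_path, stringsAsFactors = FALSE)
  filt <- apply_filters(cohort, config$filter)
  cohort_f <- filt$cohort
  write_filter_report(filt$report, outfile("filter_report.json"))
  haps <- suppressWarnings(collapse_haplotypes(cohort_f))
  utils::write.csv(haps$haplotypes, outfile("haplotypes.csv"), row.names = FALSE)
  stage_done("filter", n_snps_in = filt$report$n_input_snps,
             n_snps_out = filt$report$n_output_snps,
             n_haplotype_loci = filt$report$n_output_tags)

  ## stage 3: population structure
  say("stage structure: F_ST, PERMANOVA, DAPC")
  ind <- cohort_f$individuals
  locs <- unique(ind$locality)
  fst_rows <- list()
  for (ag in c("settler", "survivor")) {
    for (i in seq_along(locs)) for (j in seq_along(locs)) {
      if (j <= i) next
      ga <- cohort_f$calls[ind$locality == locs[i] & ind$age_group == ag, ,
                           drop = FALSE]
      gb <- cohort_f$calls[ind$locality == locs[j] & ind$age_group == ag, ,
                           drop = FALSE]
      res <- fst_permutation_test(ga, gb, n_perm = config$n_perm,
                                  seed = config$seed + 101L * i + j)
      fst_rows[[length(fst_rows) + 1L]] <- data.frame(
        age_group = ag, pop_a = locs[i], pop_b = locs[j],
        theta = res$theta, p = res$p_value, stringsAsFactors = FALSE)
    }
  }
  fst_tab <- do.call(rbind, fst_rows)
  utils::write.csv(fst_tab, outfile("fst_pairwise.csv"), row.names = FALSE)

  ph <- pheno[match(ind$individual, pheno$individual), , drop = FALSE]
  perm_rows <- lapply(predictor_names()[predictor_names() %in% names(ph)],
                      function(v) {
    dat <- data.frame(y = ph[[v]], age_group = ind$age_group,
                      locality = ind$locality)
    res <- permanova(y ~ age_group * locality, dat, n_perm = config$n_perm,
                     seed = config$seed + 7L)
    tt <- res$table[res$table$term != "Total" & res$table$term != "Residual", ]
    cbind(variable = v, tt)
  })
  perm_tab <- do.call(rbind, perm_rows)
  utils::write.csv(perm_tab, outfile("permanova.csv"), row.names = FALSE)

  hap_mat <- haplotype_indicator_matrix(haps$haplotypes)
  hap_mat <- hap_mat[ind$individual, , drop = FALSE]
  dap <- dapc(hap_mat, interaction(ind$locality, ind$age_group, drop = TRUE))
  utils::write.csv(data.frame(individual = ind$individual, dap$scores),
                   outfile("dapc_scores.csv"), row.names = FALSE)
  stage_done("structure", n_fst_pairs = nrow(fst_tab),
             n_permanova = length(perm_rows), dapc_pcs = dap$n_pcs)

  ## stage 4: per-locality RDA scans
  say("stage gea: per-locality RDA scans")
  pm_global <- drop_correlated_predictors(
    pheno[match(ind$individual, pheno$individual), ],
    threshold = config$cor_threshold)
  scans <- lapply(locs, function(l)
    rda_scan(cohort_f, pheno, l, predictors = pm_global$predictors,
             n_axes = config$n_axes, sd_mult = config$sd_mult,
             scale_genotypes = config$scale_genotypes))
  names(scans) <- locs
  for (l in locs)
    utils::write.csv(scans[[l]]$candidates,
                     outfile(sprintf("rda_candidates_%s.csv", l)),
                     row.names = FALSE)
  stage_done("gea", candidates_per_locality = stats::setNames(
    vapply(scans, function(s) nrow(s$candidates), integer(1)), locs))

  ## stage 5: parallel set + allele-frequency change tests
  say("stage parallel: cross-locality candidate intersection")
  pset <- intersect_parallel(scans)
  members <- pset$members
  if (nrow(members)) {
    set_rows <- ind$age_group == "settler"
    members$chisq <- members$chisq_p <- NA_real_
    for (i in seq_len(nrow(members))) {
      g <- cohort_f$calls[, members$snp_id[i]]
      res <- allele_freq_change_test(g[set_rows], g[!set_rows])
      members$chisq[i] <- res$statistic
      members$chisq_p[i] <- res$p_value
    }
  }
  utils::write.csv(members, outfile("parallel_set.csv"), row.names = FALSE)
  cats <- categorize_by_predictor(pset)
  jsonlite::write_json(cats$categories, outfile("intersection_tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_done("parallel", n_parallel_snps = nrow(members),
             n_categories = nrow(cats$categories))

  ## stage 6: annotation (optional)
  if (!is.null(config$blast) && !is.null(config$gff)) {
    say("stage annotate: BLAST/GFF locus classification")
    hits <- parse_blast_tab(config$blast, config$evalue_cutoff)
    all_tags <- unique(cohort_f$snps$tag)
    ann <- classify_mapping(hits, loci = all_tags)
    ann <- locate_in_gff(ann, config$gff)
    utils::write.csv(ann, outfile("annotation.csv"), row.names = FALSE)
    cand_tags <- unique(sub("_snp[0-9]+$", "",
                            unlist(lapply(scans, function(s) s$candidates$snp_id))))
    mk_counts <- function(tags) {
      m <- ann$mapping[ann$locus %in% tags]
      c(mapped = sum(m != "unmapped"), unmapped = sum(m == "unmapped"))
    }
    enr <- enrichment_chisq(mk_counts(cand_tags), mk_counts(all_tags))
    jsonlite::write_json(list(mapping_enrichment = list(
      statistic = enr$statistic, p_value = enr$p_value)),
      outfile("enrichment.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_done("annotate", n_loci = nrow(ann),
               mapping_chisq = enr$statistic)
  } else {
    stage_done("annotate", skipped = TRUE)
  }

  files <- list.files(config$output_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("pipeline complete: %d stages", length(manifest$stages))
  invisible(manifest)
}
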