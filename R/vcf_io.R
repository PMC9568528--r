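#' Read a multi-sample VCF plus metadata into a cohort object
#'
#' Loads biallelic SNP records from a VCF 4.2 file, attaches locality and
#' age-group labels from the metadata table, and decodes genotypes as
#' alternate-allele counts (0/1/2). Half-missing diploid calls (e.g. `./1`)
#' are treated as missing. Non-biallelic records are skipped with a warning.
#' SNP IDs of the form `tag<k>_snp<j>` group SNPs into RAD-tag loci; any
#' other ID is treated as its own single-SNP tag.
#'
#' @param path VCF file path.
#' @param metadata Either a path to a metadata CSV with columns
#'   `individual,locality,age_group`, or an equivalent data frame. Every VCF
#'   sample must appear in it.
#' @return A `cohort_genotypes` object. Phase is preserved when every
#'   genotype in the file uses the `|` separator.
#' @export
read_cohort_vcf <- function(path, metadata) {
  if (!file.exists(path)) stop(sprintf("VCF file '%s' does not exist", path))
  if (is.character(metadata)) {
    if (!file.exists(metadata))
      stop(sprintf("metadata file '%s' does not exist", metadata))
    metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  }
  need <- c("individual", "locality", "age_group")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns individual, locality, age_group")

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(multi)) {
    warning(sprintf("skipped %d non-biallelic-SNP record(s)", sum(multi)))
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  samples <- colnames(vcf@gt)[-1]
  missing_meta <- setdiff(samples, metadata$individual)
  if (length(missing_meta))
    stop(sprintf("sample(s) not in metadata: %s",
                 paste(missing_meta, collapse = ", ")))
  meta <- metadata[match(samples, metadata$individual), need]
  rownames(meta) <- NULL

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  phased <- all(grepl("\\|", gt_raw[!is.na(gt_raw) & gt_raw != "./." &
                                      gt_raw != ".|." & gt_raw != "."]))
  a1 <- substr(gt_raw, 1, 1)
  a2 <- substr(gt_raw, 3, 3)
  to_int <- function(a) {
    out <- suppressWarnings(as.integer(a))
    out[!a %in% c("0", "1")] <- NA_integer_
    out
  }
  a1 <- matrix(to_int(a1), nrow = nrow(gt_raw), dimnames = dimnames(gt_raw))
  a2 <- matrix(to_int(a2), nrow = nrow(gt_raw), dimnames = dimnames(gt_raw))
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_integer_
  a2[half] <- NA_integer_

  id <- fix$ID
  no_id <- is.na(id) | id == "."
  id[no_id] <- sprintf("%s_%s", fix$CHROM[no_id], fix$POS[no_id])
  tag <- ifelse(grepl("^.+_snp[0-9]+$", id), sub("_snp[0-9]+$", "", id), id)
  snps <- data.frame(snp_id = id, tag = tag, contig = fix$CHROM,
                     pos = as.integer(fix$POS),
                     pos_in_tag = NA_integer_, ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)

  tr <- function(m) {
    m <- t(m)
    dimnames(m) <- list(samples, id)
    m
  }
  a1 <- tr(a1); a2 <- tr(a2)
  calls <- a1 + a2
  depth <- tr(dp)
  depth[is.na(depth)] <- 0
  structure(list(individuals = meta, snps = snps, calls = calls, depth = depth,
                 allele1 = a1, allele2 = a2, phased = phased),
            class = "cohort_genotypes")
}
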