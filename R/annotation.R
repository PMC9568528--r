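blast_outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                        "gapopen", "qstart", "qend", "sstart", "send",
                        "evalue", "bitscore")

#' Parse a tabular BLAST hit file
#'
#' Reads a 12-column outfmt-6 style hit table, discards hits with E-value
#' above the cutoff (the boundary is inclusive: E-value equal to the cutoff
#' is retained), and groups the remaining hits by query locus. Subject
#' coordinates reported on the minus strand (sstart > send) are normalised
#' to start <= end with `strand = "-"`.
#'
#' @param path Tabular BLAST file (standard outfmt-6 column order).
#' @param evalue_cutoff Maximum E-value retained (default 1e-4).
#' @return Data frame of passing hits with a `strand` column, sorted by
#'   query; attribute `n_discarded` counts hits over the cutoff.
#' @export
parse_blast_tab <- function(path, evalue_cutoff = 1e-4) {
  if (!file.exists(path)) stop(sprintf("BLAST file '%s' does not exist", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 13)),
      c(blast_outfmt6_cols, "strand"))
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop(sprintf("malformed BLAST row at line %d: %d column(s), expected 12",
                 which(nf < 12L)[1], nf[nf < 12L][1]))
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  hits <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  num <- apply(m[, 3:12, drop = FALSE], 2, as.numeric)
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  if (anyNA(num))
    stop(sprintf("malformed BLAST row at line %d: non-numeric field",
                 which(rowSums(is.na(num)) > 0)[1]))
  colnames(num) <- blast_outfmt6_cols[3:12]
  hits <- cbind(hits, as.data.frame(num))
  keep <- hits$evalue <= evalue_cutoff
  n_discarded <- sum(!keep)
  hits <- hits[keep, , drop = FALSE]
  hits$strand <- ifelse(hits$sstart <= hits$send, "+", "-")
  s1 <- pmin(hits$sstart, hits$send)
  s2 <- pmax(hits$sstart, hits$send)
  hits$sstart <- s1
  hits$send <- s2
  hits <- hits[order(hits$qseqid), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "n_discarded") <- n_discarded
  hits
}

#' Classify loci by BLAST mapping status
#'
#' After deduplicating hits with identical subject coordinates, each query
#' locus is `unique` (exactly one passing hit), `multiple` (hits at two or
#' more distinct reference positions) or `unmapped` (no passing hit).
#'
#' @param hits Passing-hit data frame from [parse_blast_tab()].
#' @param loci Character vector of all query loci (so unmapped loci are
#'   reported); defaults to the loci present in `hits`.
#' @return Data frame `locus`, `mapping` plus, for unique loci, the hit
#'   coordinates (`sseqid`, `sstart`, `send`, `strand`).
#' @export
classify_mapping <- function(hits, loci = unique(hits$qseqid)) {
  dedup <- hits[!duplicated(hits[, c("qseqid", "sseqid", "sstart", "send")]),
                , drop = FALSE]
  counts <- table(factor(dedup$qseqid, levels = loci))
  mapping <- ifelse(counts == 0L, "unmapped",
                    ifelse(counts == 1L, "unique", "multiple"))
  out <- data.frame(locus = loci, mapping = as.character(mapping),
                    sseqid = NA_character_, sstart = NA_real_,
                    send = NA_real_, strand = NA_character_,
                    stringsAsFactors = FALSE)
  uni <- out$locus[out$mapping == "unique"]
  idx <- match(uni, dedup$qseqid)
  out[out$mapping == "unique", c("sseqid", "strand")] <-
    dedup[idx, c("sseqid", "strand")]
  out[out$mapping == "unique", c("sstart", "send")] <-
    dedup[idx, c("sstart", "send")]
  out
}

#' Locate uniquely mapped loci in a GFF3 annotation
#'
#' Classifies each uniquely mapped hit interval as `exonic` (at least 1 bp
#' of overlap with any exon of an overlapping gene), `intronic` (inside a
#' gene but not overlapping any of its exons) or `intergenic`. A hit
#' overlapping several genes is assigned to the gene with the longest
#' overlap, ties going to the lexicographically smallest gene ID. Hits on
#' contigs absent from the annotation are classified intergenic with a
#' warning.
#'
#' @param mapped Data frame from [classify_mapping()] (only `unique` rows
#'   are annotated).
#' @param gff Path to a GFF3 file with gene and exon features, or a
#'   `GRanges` of the same.
#' @return The input with `region`, `gene_id` and `biotype` columns added
#'   for unique rows.
#' @export
locate_in_gff <- function(mapped, gff) {
  gr <- if (methods::is(gff, "GRanges")) gff else
    rtracklayer::import(gff, format = "gff3")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  gene_ids <- genes$ID %||% genes$gene_id
  if (is.null(gene_ids)) gene_ids <- as.character(seq_along(genes))
  bio <- genes$gene_biotype %||% genes$biotype
  if (is.null(bio)) bio <- rep(NA_character_, length(genes))
  # map each exon to its gene by the Parent/gene_id attribute chain, falling
  # back to containment within the gene interval
  exon_gene <- rep(NA_integer_, length(exons))
  if (!is.null(exons$gene_id)) {
    exon_gene <- match(as.character(exons$gene_id), gene_ids)
  }
  if (anyNA(exon_gene) && !is.null(exons$Parent)) {
    par <- as.character(S4Vectors::unstrsplit(exons$Parent, ","))
    # Parent may be an mRNA; resolve transcript -> gene
    tx <- gr[gr$type %in% c("mRNA", "transcript")]
    tx_gene <- match(as.character(tx$Parent %||% tx$gene_id), gene_ids)
    names(tx_gene) <- tx$ID
    cand <- ifelse(par %in% gene_ids, match(par, gene_ids),
                   unname(tx_gene[par]))
    exon_gene[is.na(exon_gene)] <- cand[is.na(exon_gene)]
  }
  if (anyNA(exon_gene)) {
    ov <- GenomicRanges::findOverlaps(exons, genes, type = "within")
    fill <- tapply(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov), min)
    exon_gene[as.integer(names(fill))][is.na(exon_gene[as.integer(names(fill))])] <-
      as.integer(fill)[is.na(exon_gene[as.integer(names(fill))])]
  }

  mapped$region <- NA_character_
  mapped$gene_id <- NA_character_
  mapped$biotype <- NA_character_
  uni <- which(mapped$mapping == "unique")
  if (!length(uni)) return(mapped)
  known <- as.character(GenomicRanges::seqnames(genes))
  off_contig <- !(mapped$sseqid[uni] %in%
                    c(known, as.character(GenomicRanges::seqnames(exons))))
  if (any(off_contig))
    warning(sprintf("%d hit contig(s) absent from the annotation; classified intergenic",
                    sum(off_contig)))
  hit_gr <- GenomicRanges::GRanges(
    mapped$sseqid[uni],
    IRanges::IRanges(mapped$sstart[uni], mapped$send[uni]))
  ovg <- suppressWarnings(GenomicRanges::findOverlaps(hit_gr, genes))
  region <- rep("intergenic", length(uni))
  gene_of <- rep(NA_integer_, length(uni))
  if (length(ovg)) {
    qh <- S4Vectors::queryHits(ovg)
    sh <- S4Vectors::subjectHits(ovg)
    wid <- GenomicRanges::width(GenomicRanges::pintersect(
      hit_gr[qh], genes[sh]))
    for (q in unique(qh)) {
      rows <- which(qh == q)
      best <- rows[order(-wid[rows], gene_ids[sh[rows]])][1]
      gene_of[q] <- sh[best]
    }
    genic <- which(!is.na(gene_of))
    for (q in genic) {
      g <- gene_of[q]
      ex <- exons[!is.na(exon_gene) & exon_gene == g]
      hit_exon <- length(ex) > 0 &&
        length(suppressWarnings(GenomicRanges::findOverlaps(hit_gr[q], ex))) > 0
      region[q] <- if (hit_exon) "exonic" else "intronic"
    }
  }
  mapped$region[uni] <- region
  mapped$gene_id[uni] <- ifelse(is.na(gene_of), NA_character_,
                                gene_ids[gene_of])
  mapped$biotype[uni] <- ifelse(is.na(gene_of), NA_character_, bio[gene_of])
  mapped
}

#' Chi-square enrichment test between a locus set and a background
#'
#' Pearson chi-square of the category x set-membership contingency table,
#' e.g. mapped/unmapped or region/biotype counts in a candidate set versus
#' all loci. Categories with a zero total across both sets are dropped with
#' a warning. The statistic is symmetric in which vector is called the set
#' and which the background.
#'
#' @param set_counts,background_counts Named count vectors over the same
#'   categories.
#' @return List with `statistic`, `df`, `p_value`, the contingency `table`
#'   and `expected` counts.
#' @export
enrichment_chisq <- function(set_counts, background_counts) {
  if (length(set_counts) != length(background_counts))
    stop("count vectors must cover the same categories")
  if (!is.null(names(set_counts)) && !is.null(names(background_counts)) &&
      !identical(names(set_counts), names(background_counts)))
    background_counts <- background_counts[names(set_counts)]
  tab <- rbind(set = set_counts, background = background_counts)
  zero <- colSums(tab) == 0
  if (any(zero)) {
    warning(sprintf("dropped empty category(ies): %s",
                    paste(colnames(tab)[zero] %||% which(zero), collapse = ", ")))
    tab <- tab[, !zero, drop = FALSE]
  }
  if (ncol(tab) < 2L) stop("need at least two non-empty categories")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- ncol(tab) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = tab, expected = expected)
}

#' Amino-acid effect of SNPs within a coding sequence
#'
#' Substitutes alternate alleles into the reference coding sequence and
#' translates the affected codons with the standard genetic code. For genes
#' on the minus strand, SNP positions are given on the genomic (plus)
#' strand of the gene span and alleles as genomic bases; they are converted
#' to the coding strand internally. Multiple SNPs falling in one codon are
#' substituted jointly, so e.g. two SNPs at codon positions 1 and 2 turning
#' CGT into GTT are reported as a single arginine-to-valine replacement.
#'
#' @param cds Character string or `DNAString`: the reference coding
#'   sequence, 5'->3' on the coding strand, length a multiple of 3.
#' @param positions SNP positions. For `strand = "+"`, 1-based positions in
#'   the coding sequence. For `strand = "-"`, 1-based positions in the
#'   genomic span of the CDS (position 1 = genomic start, which is the last
#'   coding base).
#' @param ref,alt Reference and alternate alleles; genomic bases for
#'   `strand = "-"`.
#' @param strand `"+"` or `"-"`.
#' @return Data frame with one row per affected codon: codon number,
#'   reference and alternate codons, codon positions hit (comma-separated,
#'   1-3), reference and alternate amino acids, and a `synonymous` flag.
#' @export
codon_effect <- function(cds, positions, ref, alt, strand = c("+", "-")) {
  strand <- match.arg(strand)
  cds <- toupper(as.character(cds))
  L <- nchar(cds)
  if (L %% 3 != 0) stop("coding sequence length must be a multiple of 3")
  stopifnot(length(positions) == length(ref), length(ref) == length(alt))
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    positions <- L - positions + 1
    ref <- unname(comp[toupper(ref)])
    alt <- unname(comp[toupper(alt)])
  }
  if (any(positions < 1 | positions > L))
    stop("SNP position outside the coding sequence")
  cds_vec <- strsplit(cds, "")[[1]]
  mismatch <- cds_vec[positions] != toupper(ref)
  if (any(mismatch))
    stop(sprintf("reference allele mismatch at CDS position %d (found %s, given %s)",
                 positions[mismatch][1], cds_vec[positions[mismatch][1]],
                 toupper(ref)[mismatch][1]))
  alt_vec <- cds_vec
  alt_vec[positions] <- toupper(alt)
  codon_no <- (positions - 1) %/% 3 + 1
  out <- lapply(sort(unique(codon_no)), function(cn) {
    span <- (cn - 1) * 3 + (1:3)
    ref_codon <- paste(cds_vec[span], collapse = "")
    alt_codon <- paste(alt_vec[span], collapse = "")
    if (grepl("N", ref_codon) || grepl("N", alt_codon))
      return(data.frame(codon = cn, ref_codon = ref_codon,
                        alt_codon = alt_codon, codon_positions = NA_character_,
                        ref_aa = NA_character_, alt_aa = NA_character_,
                        synonymous = NA, stringsAsFactors = FALSE))
    gc <- Biostrings::GENETIC_CODE
    ref_aa <- unname(gc[ref_codon])
    alt_aa <- unname(gc[alt_codon])
    hit <- positions[codon_no == cn] - (cn - 1) * 3
    data.frame(codon = cn, ref_codon = ref_codon, alt_codon = alt_codon,
               codon_positions = paste(sort(hit), collapse = ","),
               ref_aa = ref_aa, alt_aa = alt_aa,
               synonymous = identical(ref_aa, alt_aa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
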