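# --- BLAST parsing ----------------------------------------------------------

test_that("E-value filtering is inclusive at the cutoff", {
  p <- write_test_blast(list(
    blast_row("L1", "ctg1", 120, 153, evalue = 1e-3),
    blast_row("L2", "ctg1", 120, 153, evalue = 1e-4),
    blast_row("L3", "ctg1", 120, 153, evalue = 1e-5)))
  hits <- parse_blast_tab(p)
  expect_setequal(hits$qseqid, c("L2", "L3"))
  expect_equal(attr(hits, "n_discarded"), 1L)
})

test_that("an empty hit file leaves every locus unmapped", {
  p <- tempfile(); writeLines(character(0), p)
  hits <- parse_blast_tab(p)
  expect_equal(nrow(hits), 0L)
  cls <- classify_mapping(hits, loci = c("L1", "L2"))
  expect_equal(cls$mapping, c("unmapped", "unmapped"))
})

test_that("malformed rows error with the line number", {
  p <- tempfile()
  writeLines(c(paste(blast_row("L1", "c", 1, 34), collapse = "\t"),
               "L2\tctg1\tbroken"), p)
  expect_error(parse_blast_tab(p), "line 2")
})

test_that("minus-strand subject coordinates are normalised", {
  p <- write_test_blast(list(blast_row("L1", "ctg1", 200, 167)))
  hits <- parse_blast_tab(p)
  expect_equal(hits$sstart, 167)
  expect_equal(hits$send, 200)
  expect_equal(hits$strand, "-")
})

# --- mapping class ----------------------------------------------------------

test_that("hit multiplicity classifies unique and multiple after dedup", {
  p <- write_test_blast(list(
    blast_row("U", "ctg1", 120, 153),
    blast_row("M", "ctg1", 120, 153), blast_row("M", "ctg2", 500, 533),
    blast_row("D", "ctg1", 700, 733), blast_row("D", "ctg1", 700, 733)))
  hits <- parse_blast_tab(p)
  cls <- classify_mapping(hits, loci = c("U", "M", "D", "None"))
  got <- setNames(cls$mapping, cls$locus)
  expect_equal(got[["U"]], "unique")
  expect_equal(got[["M"]], "multiple")
  expect_equal(got[["D"]], "unique") # identical coordinates deduplicated
  expect_equal(got[["None"]], "unmapped")
})

# --- GFF region classification ----------------------------------------------

test_that("exonic, intronic and intergenic regions are assigned", {
  gff <- write_test_gff()
  p <- write_test_blast(list(
    blast_row("Lex", "ctg1", 120, 153),   # inside geneA exon 1
    blast_row("Lin", "ctg1", 220, 253),   # between geneA's exons
    blast_row("Lig", "ctg1", 600, 633),   # no gene overlap
    blast_row("Ljx", "ctg1", 180, 213),   # spans the exon-intron junction
    blast_row("Lnc", "ctg1", 1020, 1053)))# inside geneB (lncRNA exon)
  cls <- classify_mapping(parse_blast_tab(p),
                          loci = c("Lex", "Lin", "Lig", "Ljx", "Lnc"))
  ann <- locate_in_gff(cls, gff)
  got <- setNames(ann$region, ann$locus)
  expect_equal(got[["Lex"]], "exonic")
  expect_equal(got[["Lin"]], "intronic")
  expect_equal(got[["Lig"]], "intergenic")
  expect_equal(got[["Ljx"]], "exonic") # any-exon-overlap rule
  expect_equal(got[["Lnc"]], "exonic")
  expect_equal(ann$gene_id[ann$locus == "Lex"], "geneA")
  expect_equal(ann$biotype[ann$locus == "Lnc"], "lncRNA")
  # region classes partition the uniquely mapped loci
  expect_equal(sum(ann$region %in% c("exonic", "intronic", "intergenic")),
               sum(ann$mapping == "unique"))
})

test_that("a hit contig absent from the annotation is intergenic with warning", {
  gff <- write_test_gff()
  p <- write_test_blast(list(blast_row("Lx", "ctgZ", 10, 43)))
  cls <- classify_mapping(parse_blast_tab(p), loci = "Lx")
  expect_warning(ann <- locate_in_gff(cls, gff), "absent")
  expect_equal(ann$region, "intergenic")
})

test_that("overlap with two genes picks the longer overlap", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "ctg1\tt\tgene\t100\t150\t.\t+\t.\tID=gShort;gene_biotype=protein_coding",
    "ctg1\tt\texon\t100\t150\t.\t+\t.\tID=e1;Parent=gShort",
    "ctg1\tt\tgene\t120\t400\t.\t+\t.\tID=gLong;gene_biotype=protein_coding",
    "ctg1\tt\texon\t120\t400\t.\t+\t.\tID=e2;Parent=gLong"), gff)
  p <- write_test_blast(list(blast_row("L", "ctg1", 140, 173)))
  ann <- locate_in_gff(classify_mapping(parse_blast_tab(p), loci = "L"), gff)
  expect_equal(ann$gene_id, "gLong") # 34 bp in gLong vs 11 bp in gShort
})

# --- enrichment chi-square --------------------------------------------------

test_that("identical proportions give zero and the 2x2 matches by hand", {
  res0 <- enrichment_chisq(c(mapped = 30, unmapped = 70),
                           c(mapped = 300, unmapped = 700))
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  tab <- rbind(c(10, 90), c(50, 50))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  by_hand <- sum((tab - expected)^2 / expected)
  res <- enrichment_chisq(c(mapped = 10, unmapped = 90),
                          c(mapped = 50, unmapped = 50))
  expect_equal(res$statistic, by_hand, tolerance = 1e-12)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("the statistic is symmetric in set and background", {
  a <- c(x = 12, y = 30, z = 8)
  b <- c(x = 40, y = 25, z = 35)
  expect_equal(enrichment_chisq(a, b)$statistic,
               enrichment_chisq(b, a)$statistic, tolerance = 1e-12)
})

test_that("empty categories are dropped with a warning", {
  a <- c(pc = 10, lnc = 5, pseudo = 0, tRNA = 3)
  b <- c(pc = 40, lnc = 10, pseudo = 0, tRNA = 6)
  expect_warning(res <- enrichment_chisq(a, b), "pseudo")
  expect_equal(res$df, 2L)
  expect_equal(ncol(res$table), 3L)
})

# --- codon effects ----------------------------------------------------------

test_that("joint substitution at codon positions 1 and 2 turns Arg into Val", {
  cds <- "ATGCGTAAA" # Met-Arg-Lys
  res <- codon_effect(cds, positions = c(4, 5), ref = c("C", "G"),
                      alt = c("G", "T"), strand = "+")
  expect_equal(nrow(res), 1L)
  expect_equal(res$ref_codon, "CGT")
  expect_equal(res$alt_codon, "GTT")
  expect_equal(res$ref_aa, "R")
  expect_equal(res$alt_aa, "V")
  expect_false(res$synonymous)
  expect_equal(res$codon_positions, "1,2")
})

test_that("a wobble substitution is synonymous", {
  res <- codon_effect("CGTTTT", positions = 3, ref = "T", alt = "C",
                      strand = "+")
  expect_equal(res$alt_codon, "CGC")
  expect_true(res$synonymous)
  expect_equal(res$ref_aa, "R")
})

test_that("minus-strand effects match the plus-strand oracle on the revcomp", {
  cds <- "ATGCGTAAA"
  # genomic span of a minus-strand gene with this CDS is its reverse complement
  plus <- codon_effect(cds, positions = c(4, 5), ref = c("C", "G"),
                       alt = c("G", "T"), strand = "+")
  L <- nchar(cds)
  # genomic position of CDS position p is L - p + 1; alleles complemented
  minus <- codon_effect(cds, positions = L - c(4, 5) + 1,
                        ref = c("G", "C"), alt = c("C", "A"), strand = "-")
  expect_equal(minus, plus)
})

test_that("joint substitution equals sequential substitution order-free", {
  cds <- "ATGCGTAAA"
  r12 <- codon_effect(cds, c(4, 5), c("C", "G"), c("G", "T"), "+")
  r21 <- codon_effect(cds, c(5, 4), c("G", "C"), c("T", "G"), "+")
  expect_equal(r12, r21)
})

test_that("positions outside the CDS and reference mismatches error", {
  expect_error(codon_effect("ATGAAA", positions = 7, ref = "A", alt = "G",
                            strand = "+"), "outside")
  expect_error(codon_effect("ATGAAA", positions = 1, ref = "C", alt = "G",
                            strand = "+"), "mismatch")
  expect_error(codon_effect("ATGAA", positions = 1, ref = "A", alt = "G",
                            strand = "+"), "multiple of 3")
})

test_that("codons containing N give an undetermined effect", {
  res <- codon_effect("ATGCNT", positions = 4, ref = "C", alt = "G",
                      strand = "+")
  expect_true(is.na(res$synonymous))
  expect_true(is.na(res$ref_aa))
})
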