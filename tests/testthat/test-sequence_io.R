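# Genome parsing, TIR/CDS extraction and gene filters.

make_genbank <- function(contig, features, name = "TESTCTG",
                         topology = "linear") {
  lines <- c(
    sprintf("LOCUS       %s %d bp DNA %s BCT 01-JAN-2000", name,
            nchar(contig), topology),
    "FEATURES             Location/Qualifiers")
  for (f in features) {
    loc <- sprintf("%d..%d", f$start, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines, sprintf("     CDS             %s", loc),
               sprintf("                     /locus_tag=\"%s\"", f$id))
  }
  lines <- c(lines, "ORIGIN",
             paste("       ", gsub("(.{60})", "\\1\n        ", contig)),
             "//")
  path <- tempfile(fileext = ".gb")
  writeLines(lines, path)
  path
}

test_that("GenBank CDS features are read with correct coordinates and strand", {
  set.seed(42)
  contig <- random_dna(200)
  gb <- make_genbank(contig, list(
    list(start = 101, end = 190, strand = "+", id = "gA"),
    list(start = 50, end = 100, strand = "-", id = "gB")))
  g <- load_annotated_genome(gb, "genbank")
  expect_equal(unname(g$contigs), contig)
  expect_equal(nrow(g$annotations), 2L)
  a <- g$annotations[g$annotations$gene_id == "gA", ]
  expect_equal(c(a$start, a$end), c(101, 190))
  expect_equal(a$strand, "+")
  expect_equal(g$annotations$strand[g$annotations$gene_id == "gB"], "-")
})

test_that("FASTA+GFF3 round-trips through Biostrings/rtracklayer", {
  b <- get_bundle(12, 7)
  dir <- tempfile(); write_bundle(b, dir)
  g <- load_annotated_genome(file.path(dir, "genome.fasta"),
                             format = "fasta+gff3",
                             gff_path = file.path(dir, "annotations.gff3"))
  expect_equal(unname(g$contigs), unname(b$genome$contigs))
  expect_setequal(g$annotations$gene_id, b$genome$annotations$gene_id)
  reread <- extract_regions_table(g)
  reread <- reread[match(b$regions$gene_id, reread$gene_id), ]
  expect_equal(reread$cds_seq, b$regions$cds_seq)
  expect_equal(reread$tir_seq, b$regions$tir_seq)
})

test_that("FASTA without a GFF3 companion is a format error", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">c1", "ACGTACGTACGT"), fa)
  expect_error(load_annotated_genome(fa, "fasta+gff3"), "format error")
})

test_that("annotations outside a linear contig are a coordinate error", {
  gb <- make_genbank(strrep("ACGT", 25), list(
    list(start = 50, end = 150, strand = "+", id = "bad")))
  expect_error(load_annotated_genome(gb, "genbank"), "coordinate error")
})

test_that("TIR/CDS extraction follows the -25..+30 convention", {
  set.seed(1)
  contig <- random_dna(200)
  ann <- data.frame(gene_id = "g1", start = 101, end = 190, strand = "+",
                    contig_id = "c", stringsAsFactors = FALSE)
  r <- extract_gene_regions(c(c = contig), ann, "linear")
  expect_equal(r$tir_seq, substr(contig, 76, 130))
  expect_equal(nchar(r$tir_seq), 55L)
  expect_equal(r$cds_seq, substr(contig, 101, 190))
  expect_equal(r$start_codon, substr(contig, 101, 103))
  expect_equal(r$stop_codon, substr(contig, 188, 190))
})

test_that("insufficient upstream on linear topology is an extraction error", {
  set.seed(2)
  contig <- random_dna(200)
  ann <- data.frame(gene_id = "g1", start = 10, end = 90, strand = "+",
                    contig_id = "c", stringsAsFactors = FALSE)
  expect_error(extract_gene_regions(c(c = contig), ann, "linear"),
               class = "s2a_extraction_error")
})

test_that("circular extraction wraps and equals extraction on a rotation", {
  set.seed(3)
  contig <- random_dna(200)
  ann <- data.frame(gene_id = "g1", start = 10, end = 90, strand = "+",
                    contig_id = "c", stringsAsFactors = FALSE)
  r <- extract_gene_regions(c(c = contig), ann, "circular")
  expect_equal(nchar(r$tir_seq), 55L)
  # rotate so the gene is internal: move the last 50 bases to the front
  rot <- paste0(substr(contig, 151, 200), substr(contig, 1, 150))
  ann2 <- ann; ann2$start <- 60; ann2$end <- 140
  r2 <- extract_gene_regions(c(c = rot), ann2, "circular")
  expect_equal(r$tir_seq, r2$tir_seq)
  expect_equal(r$cds_seq, r2$cds_seq)
})

test_that("a gene and its reverse-complement mirror yield identical regions", {
  set.seed(4)
  contig <- random_dna(300)
  ann <- data.frame(gene_id = "g1", start = 101, end = 190, strand = "+",
                    contig_id = "c", stringsAsFactors = FALSE)
  r_fwd <- extract_gene_regions(c(c = contig), ann, "linear")
  mirror <- seq2abundance:::revcomp(contig)
  ann_rev <- data.frame(gene_id = "g1", start = 300 - 190 + 1,
                        end = 300 - 101 + 1, strand = "-", contig_id = "c",
                        stringsAsFactors = FALSE)
  r_rev <- extract_gene_regions(c(c = mirror), ann_rev, "linear")
  expect_equal(r_fwd$tir_seq, r_rev$tir_seq)
  expect_equal(r_fwd$cds_seq, r_rev$cds_seq)
})

test_that("aberrant genes are partitioned with the right reason codes", {
  reg <- data.frame(
    gene_id = c("ok", "fs", "badstart", "istop"),
    tir_seq = strrep("A", 55),
    cds_seq = c("ATGAAATAG", "ATGAAAA", "ATTAAATAG", "ATGTAAAAATAG"),
    stringsAsFactors = FALSE)
  reg$start_codon <- substr(reg$cds_seq, 1, 3)
  reg$stop_codon <- substring(reg$cds_seq, nchar(reg$cds_seq) - 2)
  out <- screen_aberrant_genes(reg)
  expect_equal(out$valid$gene_id, "ok")
  expect_equal(out$aberrant$reason[out$aberrant$gene_id == "fs"],
               "frameshift")
  expect_equal(out$aberrant$reason[out$aberrant$gene_id == "badstart"],
               "nonsense_start_codon")
  expect_equal(out$aberrant$reason[out$aberrant$gene_id == "istop"],
               "internal_stop")
  # idempotent on the valid part; empty input is fine
  again <- screen_aberrant_genes(out$valid)
  expect_equal(again$valid, out$valid)
  expect_equal(nrow(again$aberrant), 0L)
  empty <- screen_aberrant_genes(reg[0, ])
  expect_equal(nrow(empty$valid), 0L)
})

test_that("expression outlier filter removes planted outliers and only those", {
  set.seed(11)
  n <- 500
  mrna <- 10^rnorm(n, 1, 0.5)
  # residuals bounded well inside 3 SD by construction
  res <- pmin(pmax(rnorm(n, 0, 0.2), -0.55), 0.55)
  prot <- 10^(1 + 0.8 * log10(mrna) + res)
  rec <- data.frame(gene_id = sprintf("g%03d", 1:n), mrna_level = mrna,
                    protein_mean = prot, stringsAsFactors = FALSE)
  clean <- flag_expression_outliers(rec)
  expect_equal(nrow(clean$removed), 0L)

  # displace one gene by ~6 residual SDs
  rec2 <- rec
  rec2$protein_mean[77] <- rec2$protein_mean[77] * 10^(6 * sd(res))
  flt <- flag_expression_outliers(rec2)
  expect_equal(flt$removed$gene_id, "g077")

  # perfectly collinear log-abundances: nothing removed
  rec3 <- rec
  rec3$protein_mean <- 10^(2 + 1.3 * log10(rec3$mrna_level))
  expect_equal(nrow(flag_expression_outliers(rec3)$removed), 0L)

  # nonpositive abundance names the offending gene
  rec4 <- rec; rec4$mrna_level[5] <- 0
  expect_error(flag_expression_outliers(rec4), "g005")
})
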