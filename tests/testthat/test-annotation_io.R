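test_that("read_genome normalises case and U, and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgt"), fa)
  expect_identical(read_genome(fa), c(chr1 = "ACGT"))

  writeLines(c(">c", "ACGU"), fa)
  expect_identical(read_genome(fa), c(c = "ACGT"))

  writeLines(c(">c desc words", "ACGT", "NNAC"), fa)
  expect_identical(read_genome(fa), c(c = "ACGTNNAC"))

  writeLines(c(">c", "ACGT", ">c", "GGGG"), fa)
  expect_error(read_genome(fa), "duplicate")

  writeLines(c("ACGT", ">c", "ACGT"), fa)
  expect_error(read_genome(fa), "line 1")

  writeLines(c(">c", "ACGT", "ACXT"), fa)
  expect_error(read_genome(fa), "line 3")

  writeLines(c(">c", "ACGT", ">empty"), fa)
  expect_error(read_genome(fa), "empty sequence")
})

test_that("FASTA writing round-trips through read_genome", {
  seqs <- c(a = rdna(157, 1), b = rdna(70, 2), c = "ACGTN")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, fa, width = 60)
  expect_identical(read_genome(fa), seqs)
})

test_that("read_circrnas parses BED6 and BED12, validates strand and span", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tcircA\t0\t+", bed)
  circs <- read_circrnas(bed)
  expect_length(circs, 1)
  cc <- circs[[1]]
  expect_identical(cc$circ_id, "circA")
  expect_identical(c(cc$start, cc$end), c(100L, 200L))
  expect_identical(unname(cc$exons), cbind(100L, 200L))

  writeLines(paste("chr1", 100, 200, "circB", 0, "-", 100, 200, "0",
                   2, "30,40,", "0,60,", sep = "\t"), bed)
  cb <- read_circrnas(bed)[[1]]
  expect_identical(unname(cb$exons), cbind(c(100L, 160L), c(130L, 200L)))

  writeLines("chr1\t200\t100\tcircC\t0\t+", bed)
  expect_error(read_circrnas(bed), "degenerate")

  writeLines("chr1\t100\t200\tcircD\t0\t.", bed)
  expect_error(read_circrnas(bed), "strand")

  writeLines("chr1\t100\t200\tcircE", bed)
  expect_error(read_circrnas(bed), "BED6")
})

test_that("circ_model rejects inconsistent exon blocks", {
  expect_error(circ_model("c", "chr1", "+", 0, 100,
                          exons = cbind(c(10L, 50L), c(40L, 100L))),
               "start and end at the circle span")
  expect_error(circ_model("c", "chr1", "+", 0, 100,
                          exons = cbind(c(0L, 30L), c(40L, 100L))),
               "overlapping")
})

test_that("BED round-trip reproduces circ models field-for-field", {
  circs <- list(
    circ_model("c1", "chr1", "+", 100, 200),
    circ_model("c2", "chr2", "-", 5, 405,
               exons = cbind(start = c(5L, 205L), end = c(105L, 405L))))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_circrnas(circs, bed)
  back <- read_circrnas(bed)
  expect_equal(back, circs)
})

test_that("coordinate conversions are mutually inverse", {
  start <- c(0L, 100L, 7L)
  end <- c(10L, 200L, 8L)
  g <- circshrna:::bed_to_gtf(start, end)
  b <- circshrna:::gtf_to_bed(g[, "first"], g[, "last"])
  expect_identical(unname(b[, "start"]), start)
  expect_identical(unname(b[, "end"]), end)
  expect_identical(unname(g[, "first"] - 1L), start)  # half-open <-> closed
})

test_that("spliced_sequence honours exon order and strand", {
  g <- c(chr1 = "ATGCCCTAG")
  t_plus <- transcript_model("t1", "g1", "chr1", "+",
                             exons = cbind(c(1L, 7L), c(4L, 9L)))
  expect_identical(spliced_sequence(t_plus, g), "ATGCTAG")

  t_minus <- transcript_model("t2", "g1", "chr1", "-",
                              exons = cbind(1L, 4L))
  expect_identical(spliced_sequence(t_minus, g), bs_revcomp("ATGC"))

  expect_error(transcript_model("t3", "g1", "chr1", "+",
                                exons = matrix(integer(0), ncol = 2)),
               "empty exon")
  t_bad <- transcript_model("t4", "g1", "chrX", "+", exons = cbind(1L, 4L))
  expect_error(spliced_sequence(t_bad, g), "absent from genome")
})

test_that("circular_sequence starts at the back-splice acceptor", {
  # plus strand identity
  tg <- toy_circle_genome("AAAAATTTTT", strand = "+")
  expect_identical(circular_sequence(tg$circ, tg$genome), "AAAAATTTTT")

  # minus strand: oracle reverse complement
  tg2 <- toy_circle_genome("AAAAATTTTT", strand = "-")
  expect_identical(circular_sequence(tg2$circ, tg2$genome),
                   "AAAAATTTTT")  # happens to be its own revcomp
  asym <- "AACCGGTTAACCGGTTAAAA"
  tg3 <- toy_circle_genome(asym, strand = "-")
  expect_identical(circular_sequence(tg3$circ, tg3$genome), asym)

  # two-exon plus-strand circle: hand concatenation on a 20-nt toy
  e1 <- "ACGTACGTAC"
  e2 <- "GGGTTTCCCA"
  genome <- c(chr1 = paste0("TTTTT", e1, "AAAAA", e2, "TTTTT"))
  cc <- circ_model("c2x", "chr1", "+", start = 5, end = 30,
                   exons = cbind(start = c(5L, 20L), end = c(15L, 30L)))
  expect_identical(circular_sequence(cc, genome), paste0(e1, e2))
})

test_that("circular_sequence equals spliced_sequence on equivalent exons", {
  for (strand in c("+", "-")) {
    seqs <- rdna(120, seed = if (strand == "+") 11 else 12)
    genome <- c(chr1 = seqs)
    exons_bed <- cbind(start = c(10L, 60L), end = c(40L, 100L))
    cc <- circ_model("ceq", "chr1", strand, 10, 100, exons = exons_bed)
    g1 <- circshrna:::bed_to_gtf(exons_bed[, "start"], exons_bed[, "end"])
    tt <- transcript_model("teq", "geq", "chr1", strand, exons = g1)
    expect_identical(circular_sequence(cc, genome),
                     spliced_sequence(tt, genome))
  }
})

test_that("GTF round-trip preserves exons and the UTR boundary", {
  g <- c(chr1 = rdna(400, 21))
  tx <- transcript_model("tA", "gA", "chr1", "+",
                         exons = cbind(c(11L, 101L, 201L), c(60L, 160L, 320L)),
                         cds_end = 250L)
  tx_m <- transcript_model("tB", "gB", "chr1", "-",
                           exons = cbind(c(21L, 151L), c(90L, 260L)),
                           cds_end = 60L)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(list(tx, tx_m), gtf)
  back <- read_transcripts(gtf)
  expect_setequal(names(back), c("tA", "tB"))
  expect_equal(back$tA$exons, tx$exons)
  expect_equal(back$tA$cds_end, 250L)
  expect_equal(back$tB$cds_end, 60L)
  expect_identical(utr3_sequence(back$tA, g), utr3_sequence(tx, g))
  expect_identical(utr3_sequence(back$tB, g), utr3_sequence(tx_m, g))
})

test_that("utr3_sequence resolves explicit UTR, cds_end, and no-CDS cases", {
  g <- c(chr1 = "AAACCCGGGTTTAAACCCGGG")
  # explicit three_prime_utr wins
  tx <- transcript_model("t1", "g1", "chr1", "+", exons = cbind(1L, 21L),
                         cds_end = 9L, utr3 = cbind(13L, 21L))
  expect_identical(utr3_sequence(tx, g), "AAACCCGGG")
  # derived from cds_end
  tx2 <- transcript_model("t2", "g1", "chr1", "+", exons = cbind(1L, 21L),
                          cds_end = 9L)
  expect_identical(utr3_sequence(tx2, g), "TTTAAACCCGGG")
  # minus strand: UTR is a suffix in transcript orientation
  tx3 <- transcript_model("t3", "g1", "chr1", "-", exons = cbind(1L, 21L),
                          cds_end = 13L)
  expect_identical(utr3_sequence(tx3, g), bs_revcomp("AAACCCGGGTTT"))
  # no CDS: full sequence, flagged
  tx4 <- transcript_model("t4", "g1", "chr1", "+", exons = cbind(1L, 21L))
  u <- utr3_sequence(tx4, g)
  expect_identical(as.character(u), as.character(g))
  expect_true(attr(u, "no_cds"))
})

test_that("gene_utrs picks the longest UTR per gene and reports no-CDS genes", {
  g <- c(chr1 = rdna(300, 31))
  short <- transcript_model("t1", "gA", "chr1", "+", exons = cbind(1L, 100L),
                            cds_end = 90L)
  long <- transcript_model("t2", "gA", "chr1", "+", exons = cbind(1L, 100L),
                           cds_end = 40L)
  nocds <- transcript_model("t3", "gB", "chr1", "+", exons = cbind(150L, 200L))
  expect_message(u <- gene_utrs(list(short, long, nocds), g), "without annotated CDS")
  expect_identical(u[["gA"]], utr3_sequence(long, g))
  expect_identical(nchar(u[["gB"]]), 51L)
})

test_that("read_de_table validates layout, uniqueness and p ranges", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2fc\tpvalue\tpadj",
               "g1\t0.5\t0.01\t0.04",
               "g2\t-1.2\t0.2\tNA"), tsv)
  tab <- read_de_table(tsv)
  expect_identical(tab$gene_id, c("g1", "g2"))
  expect_true(is.na(tab$padj[2]))

  writeLines(c("gene_id\tlog2fc\tpvalue\tpadj", "g1\t0\t0.1\t0.1",
               "g1\t0\t0.1\t0.1"), tsv)
  expect_error(read_de_table(tsv), "duplicate")

  writeLines(c("gene_id\tlog2fc\tpvalue\tpadj", "g1\t0\t1.7\t0.1"), tsv)
  expect_error(read_de_table(tsv), "pvalue")

  writeLines(c("gene_id\tlfc\tp\tq", "g1\t0\t0.1\t0.1"), tsv)
  expect_error(read_de_table(tsv), "columns")
})
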