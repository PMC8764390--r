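test_that("spliced CDS respects exon order and strand", {
  g <- toy_genome()
  # plus strand: concatenation equals intron removal by string surgery
  expect_equal(spliced_cds(g, "gA"), "ATGAAATGTTAG")
  chr1 <- g$seq[["chr1"]]
  surgery <- paste0(substr(chr1, 11, 16), substr(chr1, 24, 29))
  expect_equal(spliced_cds(g, "gA"), surgery)
  # minus strand: reverse complement of the ascending concatenation
  expect_equal(spliced_cds(g, "gB"), "ATGTAG")
  expect_true(startsWith(spliced_cds(g, "gB"), "ATG"))
  # single exon identity
  expect_equal(spliced_cds(g, "gC"), "ATGAAATAG")
  expect_error(spliced_cds(g, "nope"), "unknown gene")
})

test_that("translation follows the standard code and flags internal stops", {
  expect_equal(as.character(translate_cds("ATGAAATAG")), "MK")
  tr <- translate_cds("ATGTAAAAA")
  expect_equal(as.character(tr), "M*K")
  expect_true(attr(tr, "internal_stop"))
  expect_equal(as.character(translate_cds("")), "")
  expect_equal(as.character(translate_cds("ATGANATAG")), "MX")
  expect_error(translate_cds("ATGXXX"), "non-ACGTN")
})

test_that("FASTA/GFF3 round trip preserves coordinates and sequences", {
  g <- toy_genome()
  fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
  write_genome(g, fa, gff)
  expect_equal(readLines(gff, n = 1L), "##gff-version 3")
  g2 <- load_genome(fa, gff)
  expect_equal(g2$seq, g$seq)
  for (id in g$genes$gene_id) {
    expect_equal(spliced_cds(g2, id), spliced_cds(g, id))
  }
  a <- g$genes[order(g$genes$gene_id), c("gene_id", "chrom", "start", "end", "strand")]
  b <- g2$genes[order(g2$genes$gene_id), c("gene_id", "chrom", "start", "end", "strand")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("loader picks the longest-CDS transcript and rejects broken genes", {
  fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
  writeLines(c(">c1", strrep("ACGT", 30)), fa)
  writeLines(c(
    "##gff-version 3",
    "c1\tx\tgene\t1\t60\t.\t+\t.\tID=G1",
    "c1\tx\tmRNA\t1\t60\t.\t+\t.\tID=G1.t1;Parent=G1",
    "c1\tx\texon\t1\t60\t.\t+\t.\tParent=G1.t1",
    "c1\tx\tCDS\t1\t6\t.\t+\t0\tID=c1a;Parent=G1.t1",
    "c1\tx\tmRNA\t1\t60\t.\t+\t.\tID=G1.t2;Parent=G1",
    "c1\tx\texon\t1\t60\t.\t+\t.\tParent=G1.t2",
    "c1\tx\tCDS\t1\t12\t.\t+\t0\tID=c1b;Parent=G1.t2",
    "c1\tx\tgene\t61\t80\t.\t+\t.\tID=G2",
    "c1\tx\tmRNA\t61\t80\t.\t+\t.\tID=G2.t1;Parent=G2",
    "c1\tx\texon\t61\t80\t.\t+\t.\tParent=G2.t1",
    "c1\tx\tCDS\t61\t64\t.\t+\t0\tID=c2;Parent=G2.t1"
  ), gff)
  expect_warning(g <- load_genome(fa, gff), "not divisible by 3")
  # longest-CDS mRNA retained for G1; G2 (4 bp CDS) excluded
  expect_equal(g$genes$gene_id, "G1")
  expect_equal(nchar(spliced_cds(g, "G1")), 12L)
})

test_that("features on unknown chromosomes are a hard error", {
  fa <- tempfile(fileext = ".fasta"); gff <- tempfile(fileext = ".gff3")
  writeLines(c(">c1", "ACGTACGTACGT"), fa)
  writeLines(c(
    "##gff-version 3",
    "cMISSING\tx\tgene\t1\t9\t.\t+\t.\tID=G1",
    "cMISSING\tx\tmRNA\t1\t9\t.\t+\t.\tID=G1.t1;Parent=G1",
    "cMISSING\tx\texon\t1\t9\t.\t+\t.\tParent=G1.t1",
    "cMISSING\tx\tCDS\t1\t9\t.\t+\t0\tParent=G1.t1"
  ), gff)
  expect_error(load_genome(fa, gff), "cMISSING")
})

test_that("translated spliced CDS length matches exon arithmetic genome-wide", {
  sim <- get_small_sim()
  g <- sim$genome
  for (id in sample(g$genes$gene_id, 25)) {
    cds <- spliced_cds(g, id)
    prot <- translate_cds(cds)
    trailing_stop <- substr(cds, nchar(cds) - 2, nchar(cds)) %in%
      c("TAA", "TAG", "TGA")
    expect_equal(nchar(prot), nchar(cds) / 3 - as.integer(trailing_stop))
  }
})
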