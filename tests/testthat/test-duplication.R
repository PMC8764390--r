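test_that("codon-aware alignment maps residues back to codon pairs", {
  cds <- "ATGAAATGTCCCGGG"
  pr <- codon_align(cds, cds)
  expect_equal(pr$a, pr$b)
  expect_equal(nrow(pr), 5L)
  # a gap column drops exactly one codon pair
  a <- "ATGAAATGTCCCGGGTTT"
  b <- "ATGAAACCCGGGTTT"     # TGT deleted
  pr2 <- codon_align(a, b)
  expect_equal(nrow(pr2), 5L)
  # inconsistent pre-supplied protein alignment is rejected by position
  expect_error(codon_align(a, b, protA = "MKCPGF", protB = "MW-PGF"),
               "column")
})

test_that("NG86 matches the pathway-enumeration oracle", {
  expect_equal(ng86_kaks(data.frame(a = c("ATG", "AAA"),
                                    b = c("ATG", "AAA")))$Ks, 0)
  set.seed(101)
  sense <- retrodup:::SENSE_CODONS
  for (r in 1:10) {
    cds <- paste(sample(sense, 30, replace = TRUE), collapse = "")
    mut <- retrodup:::mutate_cds(cds, runif(1, 0.05, 0.5))
    pr <- codon_align(cds, mut)
    mine <- ng86_kaks(pr)
    orc <- ng86_oracle(pr$a, pr$b)
    expect_equal(mine$Ks, orc$Ks, tolerance = 1e-9)
    expect_equal(mine$Ka, orc$Ka, tolerance = 1e-9)
    expect_equal(mine$S, orc$S, tolerance = 1e-9)
    # symmetry in the two sequences
    rev <- ng86_kaks(data.frame(a = pr$b, b = pr$a))
    expect_equal(rev$Ks, mine$Ks)
  }
  # site bookkeeping: S + N = 3 x codons
  pr <- codon_align("ATGAAATGTCCC", "ATGAAGTGCCCA")
  est <- ng86_kaks(pr)
  expect_equal(est$S + est$N, 3 * nrow(pr))
})

test_that("saturated synonymous divergence is flagged, not corrected", {
  pairs <- data.frame(a = rep("GGT", 20), b = rep("GGC", 20))
  est <- ng86_kaks(pairs)  # every third position differs synonymously
  expect_true(est$saturated)
  expect_true(is.na(est$Ks))
})

test_that("collinear chaining matches exhaustive search and its thresholds", {
  mk <- function(ra, rb) data.frame(
    gene_a = paste0("a", seq_along(ra)), gene_b = paste0("b", seq_along(ra)),
    chrom_a = "c1", rank_a = ra, chrom_b = "c2", rank_b = rb,
    stringsAsFactors = FALSE)
  # 5 perfect diagonal anchors -> one block of 5
  b5 <- collinear_blocks(mk(1:5, 11:15))
  expect_equal(nrow(b5), 5L)
  expect_equal(length(unique(b5$block_id)), 1L)
  # 4 anchors: below match_size
  expect_equal(nrow(collinear_blocks(mk(1:4, 11:14))), 0L)
  # shuffled field with one embedded diagonal of 7
  set.seed(202)
  ra <- c(sample(100:400, 23), seq(10, 22, by = 2))
  rb <- c(sample(500:900, 23), seq(60, 84, by = 4))
  anc <- mk(ra, rb)
  blocks <- collinear_blocks(anc)
  expect_equal(max(table(blocks$block_id)), 7L)
  # chain length agrees with the exhaustive oracle
  expect_equal(max(table(blocks$block_id)),
               exhaustive_best_chain(ra, rb, 25L))
  # antisense diagonals chain too
  ba <- collinear_blocks(mk(1:6, 26:21))
  expect_equal(nrow(ba), 6L)
  expect_equal(unique(ba$orientation), "antisense")
})

test_that("duplicate labels follow the rank rules and precedence", {
  og <- data.frame(orthogroup = c("o1", "o1", "o2", "o2", "o3", "o3", "o4"),
                   gene_id = c("t1", "t2", "p1", "p2", "d1", "d2", "s1"),
                   stringsAsFactors = FALSE)
  gt <- data.frame(
    gene_id = c("t1", "t2", "p1", "p2", "d1", "d2", "s1"),
    chrom = c("c1", "c1", "c1", "c1", "c1", "c2", "c1"),
    rank = c(10L, 11L, 20L, 25L, 30L, 1L, 40L), stringsAsFactors = FALSE)
  lab <- classify_duplicates(og, gt)
  l <- stats::setNames(lab$label, lab$gene_id)
  expect_equal(unname(l[c("t1", "t2")]), c("tandem", "tandem"))     # distance 1
  expect_equal(unname(l[c("p1", "p2")]), c("proximal", "proximal")) # 4 genes between
  expect_equal(unname(l[c("d1", "d2")]), c("dispersed", "dispersed"))
  expect_equal(unname(l["s1"]), "singleton")
  # wgd outranks tandem
  blocks <- data.frame(block_id = "B1", gene_a = "t1", gene_b = "t2",
                       orientation = "sense", stringsAsFactors = FALSE)
  l2 <- classify_duplicates(og, gt, blocks)
  expect_equal(l2$label[l2$gene_id == "t1"], "wgd")
})

test_that("Ks converts to time by T = Ks / 2mu", {
  expect_equal(ks_to_time(0), 0)
  expect_equal(ks_to_time(0.91, 7e-9) / 1e6, 65, tolerance = 1e-9)
  expect_equal(ks_to_time(0.182, 9.1e-9) / 1e6, 10, tolerance = 1e-9)
  expect_true(is.na(ks_to_time(NA_real_)))
})

test_that("Ks modes find planted peaks and ignore flat samples", {
  set.seed(303)
  ks <- c(rnorm(200, 0.3, 0.05), rnorm(200, 0.75, 0.05))
  m <- ks_modes(ks)
  stable <- m[m$stable, ]
  expect_gte(nrow(stable), 2L)
  expect_lt(min(abs(stable$mode - 0.3)), 0.05)
  expect_lt(min(abs(stable$mode - 0.75)), 0.05)
  single <- ks_modes(rnorm(300, 0.5, 0.05))
  expect_equal(sum(single$stable), 1L)
  flat <- ks_modes(runif(500, 0, 3))
  expect_equal(sum(flat$stable), 0L)
  expect_error(ks_modes(runif(10)), "larger")
})
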