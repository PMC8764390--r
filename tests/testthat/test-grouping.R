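test_that("gene categories form the four-way partition", {
  cats <- categorize_genes(all_genes = c("r1", "r2", "l1", "b1"),
                           retro_ids = c("r1", "r2"),
                           ltr_flagged_ids = c("r1", "l1"))
  m <- stats::setNames(cats$category, cats$gene_id)
  expect_equal(unname(m[c("r1", "r2", "l1", "b1")]),
               c("A1", "A2", "A3", "B1"))
  expect_equal(sort(unique(table(cats$gene_id))), 1L)  # partition
  expect_error(categorize_genes(c("a"), retro_ids = "ghost",
                                ltr_flagged_ids = character(0)), "ghost")
})

test_that("SEO group membership overlaps for A and is exclusive for B1", {
  cats <- data.frame(gene_id = c("a1", "a2", "a3", paste0("b", 1:9)),
                     category = c("A1", "A2", "A3", rep("B1", 9)),
                     stringsAsFactors = FALSE)
  og <- data.frame(
    orthogroup = c(rep("og1", 10), rep("og2", 2), rep("og3", 2)),
    gene_id = c("a1", paste0("b", 1:9), "a2", "a3", "b1", "b2"),
    stringsAsFactors = FALSE)
  gr <- group_seos(cats, og, seo_ids = c("og1", "og2", "og3"))
  expect_equal(sort(gr$group[gr$orthogroup == "og1"]), "A1")  # not B1
  expect_equal(sort(gr$group[gr$orthogroup == "og2"]), c("A2", "A3"))
  expect_equal(gr$group[gr$orthogroup == "og3"], "B1")
  expect_equal(nrow(group_seos(cats, og, character(0))), 0L)
})

test_that("tandem fraction and group summaries are plain arithmetic", {
  lab <- data.frame(gene_id = paste0("g", 1:10),
                    label = c(rep("tandem", 4), rep("dispersed", 6)),
                    stringsAsFactors = FALSE)
  expect_equal(td_fraction(paste0("g", 1:10), lab), 0.4)
  expect_equal(td_fraction(paste0("g", 5:10), lab), 0)
  expect_error(td_fraction(character(0), lab), "empty")
  groups <- data.frame(orthogroup = c("s1", "s2"), group = c("A1", "B1"),
                       stringsAsFactors = FALSE)
  stats <- data.frame(orthogroup = c("s1", "s2"),
                      td_fraction = c(0.75, 0.25), stringsAsFactors = FALSE)
  ks <- data.frame(orthogroup = c("s1", "s1", "s2"), ks = c(0.1, 0.2, 0.5),
                   stringsAsFactors = FALSE)
  rep_ <- suppressWarnings(group_summary(groups, stats, ks))
  a1 <- rep_[rep_$group == "A1", ]
  expect_equal(a1$td_fraction_median, 0.75)
  expect_equal(a1$td_fraction_mean, 0.75)   # single-SEO group: median = mean
  expect_equal(a1$td_ks_median, 0.15)
  w <- capture_warnings(group_summary(groups, stats, ks))
  expect_true(all(grepl("empty", w)))  # one warning per omitted empty group
})

test_that("ordering test compares retro-parent and tandem Ks", {
  calls <- data.frame(retro_id = c("r1", "r2", "r3"),
                      parent_id = c("p1", "p2", "p3"),
                      stringsAsFactors = FALSE)
  lab <- data.frame(gene_id = c("r1", "r2", "r3", "c1", "c2", "c3"),
                    label = "tandem", stringsAsFactors = FALSE)
  ks <- data.frame(gene_a = c("p1", "r1", "p2", "r2", "p3", "r3"),
                   gene_b = c("r1", "c1", "r2", "c2", "r3", "c3"),
                   ks = c(0.52, 0.18, 0.4, 0.1, 0.1, 0.3),
                   stringsAsFactors = FALSE)
  og <- data.frame(orthogroup = rep(c("s1", "s2", "s3"), each = 2),
                   gene_id = c("r1", "c1", "r2", "c2", "r3", "c3"),
                   stringsAsFactors = FALSE)
  stats <- data.frame(orthogroup = c("s1", "s2", "s3"),
                      td_fraction = c(1, 1, 1), stringsAsFactors = FALSE)
  gt <- data.frame(gene_id = c("r1", "c1", "r2", "c2", "r3", "c3"),
                   chrom = "c1", rank = c(1L, 2L, 10L, 11L, 20L, 21L),
                   stringsAsFactors = FALSE)
  out <- ordering_test(calls, lab, ks, og, stats, gt)
  v <- stats::setNames(out$verdicts$retro_first, out$verdicts$retro_id)
  expect_true(v[["r1"]])   # 0.52 > 0.18
  expect_true(v[["r2"]])
  expect_false(v[["r3"]])  # tandem younger than... 0.1 < 0.3: tandem came first
  expect_equal(out$fraction, 2 / 3)
  # below the tandem-fraction threshold nothing is tested
  stats$td_fraction <- 0.2
  out2 <- ordering_test(calls, lab, ks, og, stats, gt)
  expect_equal(nrow(out2$verdicts), 0L)
})

test_that("repeat summary reproduces printed percentages from printed lengths", {
  path <- system.file("extdata", "tarvense_repeat_lengths.tsv",
                      package = "retrodup")
  tab <- retrodup:::read_report_tsv(path)
  lens <- stats::setNames(tab$length_mb, tab$class)
  genome_mb <- lens[["Genome_assembly"]]
  total_mb <- lens[["All_repeats"]]
  classes <- lens[!names(lens) %in% "Genome_assembly"]
  rs <- repeat_summary(classes, genome_mb = genome_mb,
                       total_repeats_mb = total_mb)
  expect_equal(rs$pct_genome[rs$class == "LTR_retrotransposon"], 56.94)
  # percent-of-repeats entries inherit the rounding of the printed Mb
  # inputs, so agreement is to one unit in the last printed place
  expect_equal(rs$pct_repeats[rs$class == "LTR_retrotransposon"], 86.46,
               tolerance = 0.011)
  expect_equal(rs$pct_genome[rs$class == "Gypsy"], 51.55)
  expect_equal(rs$pct_repeats[rs$class == "All_repeats"], 100)
  # interval input merges overlaps before summation
  iv <- data.frame(chrom = "c1", start = c(1L, 50L, 200L),
                   end = c(100L, 120L, 250L), class = "LTR",
                   stringsAsFactors = FALSE)
  rs2 <- repeat_summary(iv, genome_length = 1000L)
  expect_equal(rs2$length_mb * 1e6, 120 + 51)
})

test_that("family summary reproduces printed per-clade means and totals", {
  path <- system.file("extdata", "tarvense_ltr_family_counts.tsv",
                      package = "retrodup")
  counts <- retrodup:::read_report_tsv(path)
  fs <- family_summary(counts)
  expect_equal(fs$mean_copies_per_family[fs$clade == "athila"], 166.80)
  gy <- fs[fs$superfamily == "Gypsy" & fs$clade == "TOTAL", ]
  expect_equal(gy$n_families, 98); expect_equal(gy$n_copies, 4110)
  expect_equal(gy$mean_copies_per_family, 41.94)
  co <- fs[fs$superfamily == "Copia" & fs$clade == "TOTAL", ]
  expect_equal(co$mean_copies_per_family, 37.42)
  # conservation: totals equal the sum of their clades
  expect_equal(gy$n_copies,
               sum(fs$n_copies[fs$superfamily == "Gypsy" & fs$clade != "TOTAL"]))
  # degenerate family of one copy
  one <- family_summary(data.frame(element_id = "e", family = "f",
                                   clade = "x", superfamily = "S",
                                   stringsAsFactors = FALSE))
  expect_equal(one$mean_copies_per_family, c(1, 1))
})
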