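test_that("intact-LTR detector recovers planted elements with tight boundaries", {
  sim <- get_small_sim()
  g <- sim$genome
  el <- detect_intact_ltrs(g)
  .fixture_cache$small_elements <- el
  tr <- sim$ltr_table
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    any(el$chrom == tr$chrom[i] & abs(el$start - tr$start[i]) <= 5L &
          abs(el$end - tr$end[i]) <= 5L)
  }, logical(1))
  expect_true(all(hit))
  expect_true(all(startsWith(el$motif, "TG") | el$motif == "TGCA"))
  # zero-divergence element reports K = 0
  set.seed(41)
  res <- plant_ltr_element(g, ltr_len = 300, internal_len = 2500, d = 0,
                           element_id = "z")
  el0 <- detect_intact_ltrs(res$genome)
  z <- res$genome$elements[res$genome$elements$element_id == "z", ]
  row <- el0[el0$chrom == z$chrom & el0$start == z$start, ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$K, 0)
})

test_that("elements below the identity floor are rejected", {
  sim <- get_small_sim()
  set.seed(77)
  # d = 0.17 gives ~84% LTR identity, below the 90% rule
  res <- plant_ltr_element(sim$genome, ltr_len = 300, internal_len = 2500,
                           d = 0.17, element_id = "low")
  z <- res$genome$elements[res$genome$elements$element_id == "low", ]
  el <- detect_intact_ltrs(res$genome)
  expect_false(any(el$chrom == z$chrom & abs(el$start - z$start) <= 10L))
})

test_that("insertion ages follow T = K / 2mu", {
  el <- data.frame(element_id = c("a", "b", "c"),
                   K = c(0, 0.00364, 0.0140), stringsAsFactors = FALSE)
  a1 <- ltr_age(el, mu = 9.1e-9)
  expect_equal(a1$T_years[1], 0)
  expect_equal(a1$T_mya[2], 0.2, tolerance = 1e-6)
  a2 <- ltr_age(el, mu = 7e-9)
  expect_equal(a2$T_mya[3], 1.0, tolerance = 1e-6)
  # linearity in K, inverse linearity in mu, over a grid
  for (K in c(0.01, 0.1, 0.3)) for (mu in c(1e-9, 7e-9, 9.1e-9)) {
    expect_equal(ltr_age(data.frame(element_id = "x", K = K), mu)$T_years,
                 K / (2 * mu))
  }
  # saturated divergence yields no age
  sat <- ltr_age(data.frame(element_id = "s", K = NA_real_), 9.1e-9)
  expect_true(sat$saturated && is.na(sat$T_years))
})

test_that("gene flagging distinguishes containment from flanking pairs", {
  sim <- get_small_sim()
  g <- sim$genome
  el <- .fixture_cache$small_elements %||% detect_intact_ltrs(g)
  flags <- flag_ltr_genes(g, el, scan_windows = FALSE)
  tr <- sim$truth
  cargo <- tr$child_id[tr$event_type %in% c("ltr_retro", "ltr_contained")]
  expect_setequal(flags$gene_id, cargo)
  expect_true(all(flags$evidence == "contained"))
  # strictness: a gene overlapping the element boundary is not contained
  fake_el <- el[1, ]
  g1 <- g$genes[1, ]
  fake_el$chrom <- g1$chrom
  fake_el$start <- g1$start + 1L; fake_el$end <- g1$end + 100L
  f <- flag_ltr_genes(g, fake_el[, c("chrom", "start", "end", "ltr5_end",
                                     "ltr3_start")],
                      scan_windows = FALSE)
  expect_false(g1$gene_id %in% f$gene_id)
  # degraded annotation: with no element list, the windowed scan still finds
  # the bracketing pair for a cargo gene
  lr <- tr$child_id[tr$event_type == "ltr_retro"][1]
  f2 <- flag_ltr_genes(
    list(seq = g$seq,
         genes = g$genes[g$genes$gene_id == lr, , drop = FALSE]) |>
      structure(class = "annotated_genome"),
    elements = NULL, scan_windows = TRUE)
  expect_true(lr %in% f2$gene_id)
  expect_equal(f2$evidence[f2$gene_id == lr], "flank_pair")
})

test_that("RT families form by single linkage with positional names", {
  sim <- get_small_sim()
  g <- sim$genome
  el <- .fixture_cache$small_elements %||% detect_intact_ltrs(g)
  el <- annotate_rt_domains(g, el)
  expect_true(all(!is.na(el$rt_start)))
  fam <- cluster_rt_families(g, el)
  # same-exemplar elements cluster; different exemplars never do
  truth_ex <- g$elements$exemplar[match(fam$element_id, g$elements$element_id)]
  for (f in unique(fam$family)) {
    expect_equal(length(unique(truth_ex[fam$family == f])), 1L)
  }
  expect_true(all(grepl("^chr\\d+_\\d+_\\d+_FAM\\d+$", fam$family)))
  # single-linkage on a controlled identity chain: A-B 85%, B-C 85%,
  # A-C ~72% -> one family
  set.seed(55)
  b <- random_dna_str(600)
  d85 <- -0.75 * log(1 - 4 * 0.15 / 3)  # JC69 rate giving p = 0.15
  a <- mutate_sequence(b, d85)
  cc <- mutate_sequence(b, d85)
  chr <- paste0(strrep("T", 100), a, strrep("T", 100), b, strrep("T", 100),
                cc, strrep("T", 100))
  gg <- annotated_genome(
    c(cX = chr),
    data.frame(gene_id = "dummy", chrom = "cX", start = 1L, end = 3L,
               strand = "+", stringsAsFactors = FALSE),
    data.frame(gene_id = "dummy", start = 1L, end = 3L))
  els <- data.frame(
    element_id = c("A", "B", "C"), chrom = "cX",
    start = c(101L, 801L, 1501L), end = c(700L, 1400L, 2100L),
    rt_start = c(101L, 801L, 1501L), rt_end = c(700L, 1400L, 2100L),
    clade = "x", superfamily = "y", stringsAsFactors = FALSE)
  fam2 <- cluster_rt_families(gg, els)
  expect_equal(length(unique(fam2$family)), 1L)
  # a lone element is its own family
  fam3 <- cluster_rt_families(gg, els[1, ])
  expect_equal(nrow(fam3), 1L)
})
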