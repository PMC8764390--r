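test_that("mutate_sequence hits the JC69-inverted substitution rate", {
  s <- random_dna_str(10000)
  expect_identical(mutate_sequence(s, 0, seed = 1), s)
  expect_identical(mutate_sequence(s, 0.1, seed = 42),
                   mutate_sequence(s, 0.1, seed = 42))
  d <- 0.02
  p <- 0.75 * (1 - exp(-4 * d / 3))
  mm <- sum(strsplit(s, "")[[1]] != strsplit(mutate_sequence(s, d, seed = 3), "")[[1]])
  bound <- 4 * sqrt(10000 * p * (1 - p))
  expect_lt(abs(mm - 10000 * p), bound)
  expect_error(mutate_sequence(s, 0.8), "0.75")
})

test_that("simulation is deterministic and conserves configured event counts", {
  cfg <- small_sim_config()
  sim <- get_small_sim()
  sim2 <- simulate_genome(cfg)
  expect_identical(sim$genome$seq, sim2$genome$seq)
  expect_identical(sim$truth, sim2$truth)
  tt <- table(sim$truth$event_type)
  expect_equal(unname(tt["clean_retro"]), cfg$n_clean_retro)
  expect_equal(unname(tt["intron_retention"]), cfg$n_intron_retention)
  expect_equal(unname(tt["exon_skipping"]), cfg$n_exon_skipping)
  expect_equal(unname(tt["intron_gain"]), cfg$n_intron_gain)
  expect_equal(unname(tt["ltr_retro"]), cfg$n_ltr_retro)
  expect_equal(unname(tt["ltr_contained"]), cfg$n_ltr_contained)
  expect_equal(unname(tt["proximal"]), cfg$n_proximal)
  expect_equal(unname(tt["ltr_element"]),
               cfg$n_free_ltr + cfg$n_ltr_retro + cfg$n_ltr_contained)
  # tandem children: (size-1) per array; dna_dup includes the B1 diluters
  expect_equal(unname(tt["tandem"]),
               cfg$tandem_arrays$retro$n * (cfg$tandem_arrays$retro$size - 1L) +
                 cfg$tandem_arrays$base$n * (cfg$tandem_arrays$base$size - 1L))
  expect_equal(unname(tt["dna_dup"]),
               cfg$n_dna_dup + cfg$tandem_arrays$base$n * cfg$b1_dispersed_per_array)
  # every truth child resolves in the annotation (elements in the LTR table)
  gene_rows <- sim$truth$event_type != "ltr_element"
  expect_true(all(sim$truth$child_id[gene_rows] %in% sim$genome$genes$gene_id))
  expect_true(all(sim$truth$child_id[!gene_rows] %in% sim$ltr_table$element_id))
})

test_that("planted retrocopies have the advertised structure", {
  sim <- get_small_sim()
  g0 <- sim$genome
  set.seed(123)
  ec <- retrodup:::exon_counts(g0)
  par4 <- names(ec)[ec >= 4L & grepl("^g", names(ec))][1]
  # clean copy at Ks 0: single-exon CDS equals the parent's spliced CDS
  res <- plant_retrocopy(g0, par4, "clean", ks = 0, gene_id = "t_clean")
  expect_equal(spliced_cds(res$genome, "t_clean"), spliced_cds(g0, par4))
  expect_equal(sum(res$genome$exons$gene_id == "t_clean"), 1L)
  # exon skipping: CDS equals spliced CDS minus exactly one internal exon
  res <- plant_retrocopy(g0, par4, "exon_skipping", ks = 0, gene_id = "t_skip")
  skipped <- as.integer(sub(".*=", "", res$truth$note))
  ex <- g0$exons[g0$exons$gene_id == par4, ]
  ex <- ex[order(ex$start), ]
  gpar <- g0$genes[g0$genes$gene_id == par4, ]
  seqs <- vapply(seq_len(nrow(ex)), function(i)
    substr(g0$seq[[gpar$chrom]], ex$start[i], ex$end[i]), character(1))
  if (gpar$strand == "-") seqs <- rev(vapply(seqs, retrodup:::revcomp, character(1)))
  expect_equal(spliced_cds(res$genome, "t_skip"),
               paste(seqs[-skipped], collapse = ""))
  # intron retention: one parent intron appears verbatim in the copy's locus
  res <- plant_retrocopy(g0, par4, "intron_retention", ks = 0, gene_id = "t_ir")
  ri <- as.integer(sub(".*=", "", res$truth$note))
  ints <- vapply(seq_len(nrow(ex) - 1L), function(i)
    substr(g0$seq[[gpar$chrom]], ex$end[i] + 1L, ex$start[i + 1L] - 1L),
    character(1))
  if (gpar$strand == "-") ints <- rev(vapply(ints, retrodup:::revcomp, character(1)))
  locus <- retrodup:::gene_locus_seq(res$genome, "t_ir")
  expect_true(grepl(ints[ri], locus, fixed = TRUE))
  # the retained intron is annotated as an intron of the new model
  expect_equal(sum(res$genome$exons$gene_id == "t_ir"), 2L)
})

test_that("planted LTR elements have twin TGCA repeats, TSD and cargo inside", {
  sim <- get_small_sim()
  g0 <- sim$genome
  set.seed(5)
  res <- plant_ltr_element(g0, ltr_len = 300, internal_len = 2500, d = 0,
                           element_id = "t_el")
  el <- res$genome$elements[res$genome$elements$element_id == "t_el", ]
  s <- res$genome$seq[[el$chrom]]
  ltr5 <- substr(s, el$ltr5_start, el$ltr5_end)
  ltr3 <- substr(s, el$ltr3_start, el$ltr3_end)
  expect_identical(ltr5, ltr3)  # d = 0
  expect_true(startsWith(ltr5, "TG") && endsWith(ltr5, "CA"))
  expect_identical(substr(s, el$start - 5, el$start - 1),
                   substr(s, el$end + 1, el$end + 5))  # exact TSD
  # cargo gene strictly inside the element
  set.seed(6)
  ec <- retrodup:::exon_counts(g0)
  src <- names(ec)[ec == 1L][1]
  res2 <- plant_ltr_element(g0, ltr_len = 300, internal_len = 2500, d = 0.01,
                            cargo = "gene", cargo_source = src,
                            gene_id = "t_cargo", element_id = "t_el2")
  tr <- res2$truth
  grow <- tr[tr$event_type == "ltr_contained", ]
  erow <- tr[tr$event_type == "ltr_element", ]
  expect_gt(grow$start, erow$start)
  expect_lt(grow$end, erow$end)
})

test_that("impossible configurations fail before any file is written", {
  cfg <- small_sim_config()
  cfg$n_base_genes <- 6L
  out <- file.path(tempdir(), "impossible_sim")
  expect_error(simulate_genome(cfg, outdir = out), "host")
  expect_false(dir.exists(out) && length(list.files(out)) > 0)
})

test_that("written outputs reload into an identical genome", {
  sim <- get_small_sim()
  dir <- tempfile()
  simw <- simulate_genome(small_sim_config(), outdir = dir)
  expect_true(all(file.exists(simw$paths)))
  g2 <- load_genome(simw$paths["fasta"], simw$paths["gff3"])
  expect_equal(g2$seq, sim$genome$seq)
  expect_equal(nrow(g2$genes), nrow(sim$genome$genes))
  some <- sample(g2$genes$gene_id, 10)
  for (id in some) expect_equal(spliced_cds(g2, id), spliced_cds(sim$genome, id))
})
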