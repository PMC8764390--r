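test_that("local alignment scores match the scheme and are symmetric", {
  s <- strrep("ACGT", 5)
  al <- local_align(s, s, "nucleotide")
  expect_equal(al$score, 40)         # 20 matches x +2
  expect_equal(al$identity_pct, 100)
  set.seed(9)
  for (i in 1:5) {
    a <- random_protein(12); b <- random_protein(15)
    expect_equal(local_align(a, b, "protein")$score,
                 local_align(b, a, "protein")$score)
  }
  expect_error(local_align("", "ACGT", "nucleotide"), "empty")
})

test_that("alignment scores equal an independent Gotoh oracle", {
  set.seed(31)
  for (i in 1:30) {
    a <- random_protein(sample(3:10, 1)); b <- random_protein(sample(3:10, 1))
    expect_equal(local_align(a, b, "protein")$score,
                 gotoh_local(a, b, blosum62_oracle(), 11, 1))
  }
  nm <- nuc_matrix_oracle()
  for (i in 1:30) {
    a <- random_dna_str(sample(4:12, 1)); b <- random_dna_str(sample(4:12, 1))
    expect_equal(local_align(a, b, "nucleotide")$score,
                 gotoh_local(a, b, nm, 5, 2))
  }
})

test_that("all-vs-all applies the e-value, length and c-score screens", {
  set.seed(17)
  core <- random_protein(400)
  prots <- c(A = core, B = core,
             C = paste0(substr(core, 1, 102), random_protein(60)))
  h <- all_vs_all(prots)
  keyed <- paste(h$query, h$subject)
  # identical 400-aa pair: mutual hits, c-score 1
  expect_true(all(c("A B", "B A") %in% keyed))
  expect_equal(h$c_score[h$query == "A" & h$subject == "B"], 1)
  # C shares only ~102 aa with A: passes the length screen but fails the
  # c-score screen against A's perfect best hit
  expect_false(any(h$query == "A" & h$subject == "C"))
  # short-alignment hits (<= 100 aa) are gone entirely
  expect_true(all(h$aligned_length >= 101))
  # filters are monotone: tightening never adds hits
  h2 <- all_vs_all(prots, evalue_max = 1e-20, min_len = 150, min_cscore = 0.5)
  expect_lte(nrow(h2), nrow(h))
  expect_true(all(paste(h2$query, h2$subject) %in% keyed))
})

test_that("alignment-length screen is strict (longer than min_len)", {
  set.seed(18)
  p100 <- random_protein(100); p101 <- random_protein(101)
  h100 <- all_vs_all(c(x = p100, y = p100))
  h101 <- all_vs_all(c(x = p101, y = p101))
  expect_equal(nrow(h100), 0L)   # aligned length exactly 100 -> removed
  expect_equal(nrow(h101), 2L)   # both directions retained
})

test_that("reciprocal best hits agree with brute force and break ties stably", {
  set.seed(23)
  base <- random_protein(200)
  prots <- c(A = base,
             B = paste0(substr(base, 1, 180), random_protein(20)),
             C = paste0(substr(base, 1, 140), random_protein(60)))
  h <- all_vs_all(prots)
  r <- reciprocal_best_hits(h)
  # brute force from the hit table
  best_of <- function(q) {
    sub <- h[h$query == q, ]
    sub <- sub[order(-sub$bit_score, sub$e_value, sub$subject), ]
    sub$subject[1]
  }
  expected <- NULL
  for (q in unique(h$query)) {
    s <- best_of(q)
    if (best_of(s) == q) expected <- rbind(expected, sort(c(q, s)))
  }
  expected <- unique(as.data.frame(expected, stringsAsFactors = FALSE))
  got <- data.frame(r$gene_a, r$gene_b, stringsAsFactors = FALSE)
  expect_equal(unname(as.matrix(got)), unname(as.matrix(expected)))
  # exact ties: identical trio pairs deterministically by lexicographic rule
  trio <- c(P = base, Q = base, R = base)
  rt <- reciprocal_best_hits(all_vs_all(trio))
  expect_equal(nrow(rt), 1L)
  expect_equal(c(rt$gene_a, rt$gene_b), c("P", "Q"))
  expect_equal(nrow(reciprocal_best_hits(retrodup:::empty_hits())), 0L)
})

test_that("orthogroups are connected components covering the gene set", {
  hits <- data.frame(
    query = c("A", "B", "D"), subject = c("B", "C", "E"),
    bit_score = c(100, 90, 80), e_value = c(1e-50, 1e-40, 1e-30),
    stringsAsFactors = FALSE)
  og <- cluster_orthogroups(hits, genes = c("A", "B", "C", "D", "E", "F"))
  grp <- split(og$gene_id, og$orthogroup)
  sizes <- sort(lengths(grp), decreasing = TRUE)
  expect_equal(unname(sizes), c(3L, 2L, 1L))
  expect_true(og$singleton[og$gene_id == "F"])
  # partition: every gene exactly once
  expect_equal(sort(og$gene_id), c("A", "B", "C", "D", "E", "F"))
  og2 <- cluster_orthogroups(retrodup:::empty_hits(), genes = letters[1:4])
  expect_equal(sum(og2$singleton), 4L)
})

test_that("TE-like filter removes RT-only genes and keeps the rest", {
  dom <- data.frame(gene_id = c("a", "b", "b", "c"),
                    domain = c("RT", "RT", "PKinase", "transposase"),
                    stringsAsFactors = FALSE)
  kept <- filter_te_like(c("a", "b", "c", "d"), dom)
  expect_equal(kept, c("b", "d"))  # a: only RT; c: only transposase; d: none
})
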