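# Shared fixtures: a hand-built toy genome with known structure, a small
# simulated genome, and (for the acceptance suite) one full default-condition
# pipeline run, all cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

# two chromosomes, three genes:
#   gA (+, 2 exons): CDS "ATGAAA" + "TGTTAG", intron "GGGGGGG"
#   gB (-, 2 exons): forward segments "CTA" (1st) and "CAT" (2nd);
#       spliced minus-strand CDS = revcomp("CTACAT") = "ATGTAG"
#   gC (+, 1 exon): "ATGAAATAG"
toy_genome <- function() {
  chr1 <- paste0("ACGTACGTAC",          # 1-10 spacer
                 "ATGAAA", "GGGGGGG", "TGTTAG",  # gA: 11-16, 17-23, 24-29
                 "TTTTTTTTTT",                   # 30-39
                 "CTA", "AAAA", "CAT",           # gB: 40-42, 43-46, 47-49
                 "GGGGGGGGGG")
  chr2 <- paste0("TTTTT", "ATGAAATAG", "CCCCC")  # gC: 6-14
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(11L, 40L, 6L), end = c(29L, 49L, 14L),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB", "gC"),
    start = c(11L, 24L, 40L, 47L, 6L),
    end = c(16L, 29L, 42L, 49L, 14L), stringsAsFactors = FALSE)
  annotated_genome(c(chr1 = chr1, chr2 = chr2), genes, exons)
}

small_sim_config <- function(seed = 7L) {
  sim_config(seed = seed, n_chromosomes = 3L, n_base_genes = 45L,
             intergenic_len = c(1500L, 3000L),
             n_clean_retro = 3L, n_intron_retention = 2L,
             n_exon_skipping = 2L, n_intron_gain = 2L,
             n_ltr_retro = 1L, n_ltr_contained = 2L, n_dna_dup = 3L,
             tandem_arrays = list(retro = list(n = 1L, size = 3L, ks = 0.05),
                                  base = list(n = 1L, size = 3L, ks = 0.3)),
             n_proximal = 2L, n_free_ltr = 3L,
             free_ltr_divergence = c(0.01, 0.03, 0.05))
}

get_small_sim <- function() {
  if (is.null(.fixture_cache$small_sim)) {
    .fixture_cache$small_sim <- simulate_genome(small_sim_config())
  }
  .fixture_cache$small_sim
}

# one full pipeline run under the default study conditions (shared by the
# planted-truth and group-effect acceptance checks)
get_default_run <- function() {
  if (is.null(.fixture_cache$default_run)) {
    .fixture_cache$default_run <- run_pipeline(sim_config(seed = 1L),
                                               seed = 1L, verbose = FALSE)
  }
  .fixture_cache$default_run
}

random_protein <- function(len) {
  paste(sample(rownames(blosum62_oracle())[1:20], len, replace = TRUE),
        collapse = "")
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
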