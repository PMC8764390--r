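# Synthetic-genome generator. Plants every event class the pipeline must
# detect -- retrocopies (clean / intron-retention / exon-skipping /
# intron-gain), intact LTR elements with twin terminal repeats of tunable
# divergence (TGCA termini, exact target-site duplication), cargo genes
# inside elements, tandem/proximal arrays with target Ks, and DNA-level
# (intron-preserving) duplicates as negative controls -- and emits
# FASTA + GFF3 + LTR/domain tables + a machine-readable truth table.

DOMAIN_POOL <- c("PKinase", "LRR_8", "Myb_DNA-bind", "ABC_tran", "zf-C2H2",
                 "F-box", "UDPGT", "Cyt_P450")

#' Configuration for the synthetic genome
#'
#' Defaults describe the study conditions the package is benchmarked under: a
#' ~2 Mb, ~190-gene multi-chromosome genome in which retro-seeded orthogroups
#' carry younger, larger tandem arrays than plain ones, retro events predate
#' the arrays planted on them, and LTR divergences stay in the young,
#' confidently detectable regime (d <= 0.08, terminal repeats >= 90%
#' identical). All Ks / divergence values are on the JC69-corrected scale, so
#' planted targets match what the estimators report in expectation.
#'
#' @param seed integer RNG seed; a fixed seed makes every output byte-identical.
#' @param n_chromosomes,n_base_genes genome skeleton size.
#' @param exons_per_gene integer range of exon counts for multi-exon genes.
#' @param single_exon_frac fraction of base genes with a single exon.
#' @param exon_len,intron_len,intergenic_len length ranges (bp); exon lengths
#'   are rounded to codon multiples.
#' @param n_clean_retro,n_intron_retention,n_exon_skipping,n_intron_gain
#'   retrocopy counts per splice-origin class.
#' @param retro_ks target Ks between a retrocopy and its parent.
#' @param n_ltr_retro retrocopies planted as cargo inside an LTR element.
#' @param n_ltr_contained single-exon non-retro cargo genes inside elements.
#' @param cargo_extra_domain_frac fraction of contained cargo genes given a
#'   second, non-RT domain (these survive the TE-like filter).
#' @param n_dna_dup DNA-level (intron-preserving) dispersed duplicates.
#' @param dna_dup_ks target Ks for DNA-level duplicates.
#' @param tandem_arrays list with elements `retro` and `base`, each
#'   `list(n=, size=, ks=)`: arrays seeded on retrocopies (younger, default
#'   Ks 0.05) and on plain base genes (older, default Ks 0.3). Array copies
#'   are serial, so every adjacent pair has the target Ks.
#' @param b1_dispersed_per_array DNA-level dispersed copies added to each
#'   base-seeded array's orthogroup (dilutes its tandem fraction).
#' @param n_proximal proximal duplicates (2-19 intervening genes).
#' @param proximal_ks target Ks for proximal duplicates.
#' @param n_free_ltr,free_ltr_divergence free intact LTR elements and their
#'   per-element LTR divergences (JC69 scale).
#' @param cargo_ltr_divergence divergence range for cargo-bearing elements.
#' @param ltr_len,internal_len,tsd_len element geometry (bp).
#' @param mu substitution rate, per site per year.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 5L,
                       n_base_genes = 140L,
                       exons_per_gene = c(2L, 6L),
                       single_exon_frac = 0.15,
                       exon_len = c(165L, 300L),
                       intron_len = c(70L, 180L),
                       intergenic_len = c(4000L, 10000L),
                       n_clean_retro = 8L,
                       n_intron_retention = 4L,
                       n_exon_skipping = 4L,
                       n_intron_gain = 4L,
                       retro_ks = 0.15,
                       n_ltr_retro = 3L,
                       n_ltr_contained = 4L,
                       cargo_extra_domain_frac = 0.5,
                       n_dna_dup = 6L,
                       dna_dup_ks = 0.3,
                       tandem_arrays = list(
                         retro = list(n = 3L, size = 3L, ks = 0.05),
                         base = list(n = 3L, size = 3L, ks = 0.3)
                       ),
                       b1_dispersed_per_array = 2L,
                       n_proximal = 5L,
                       proximal_ks = 0.3,
                       n_free_ltr = 8L,
                       free_ltr_divergence = c(0.005, 0.01, 0.015, 0.02,
                                               0.03, 0.04, 0.05, 0.06),
                       cargo_ltr_divergence = c(0.005, 0.03),
                       ltr_len = 350L,
                       internal_len = c(2500L, 4500L),
                       tsd_len = 5L,
                       mu = 9.1e-9) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_chromosomes, cfg$n_base_genes, cfg$n_clean_retro,
              cfg$n_intron_retention, cfg$n_exon_skipping, cfg$n_intron_gain,
              cfg$n_ltr_retro, cfg$n_ltr_contained, cfg$n_dna_dup,
              cfg$n_proximal, cfg$n_free_ltr)
  if (any(counts < 0L)) stop("all counts must be >= 0")
  dvals <- c(cfg$free_ltr_divergence, cfg$cargo_ltr_divergence)
  if (any(dvals < 0 | dvals >= 0.75)) stop("LTR divergence must be in [0, 0.75)")
  if (length(cfg$free_ltr_divergence) < cfg$n_free_ltr) {
    cfg$free_ltr_divergence <- rep_len(cfg$free_ltr_divergence, cfg$n_free_ltr)
  }
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Mutate a sequence to a target divergence
#'
#' Each site is independently substituted with probability
#' p = 3/4 (1 - exp(-4d/3)) -- the p-distance whose JC69 correction equals
#' `d` -- with the replacement uniform over the three alternative bases.
#' Length is preserved. With a fixed `seed` the output is deterministic;
#' with `seed = NULL` the surrounding RNG stream is used.
#'
#' @param seq DNA string.
#' @param d target JC69-corrected divergence, `0 <= d < 0.75`.
#' @param seed optional integer seed (restores the caller's RNG state).
#' @return mutated DNA string.
#' @export
mutate_sequence <- function(seq, d, seed = NULL) {
  if (d < 0 || d >= 0.75) stop("divergence d must be in [0, 0.75)")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  if (d == 0 || !nzchar(seq)) return(seq)
  p <- jc69_inverse(d)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(chars)) < p & chars %in% DNA_BASES)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# Mutate a CDS at target (JC69) rate ks, reverting any codon that becomes a
# stop so the copy stays translatable end to end. The reversion removes a
# tiny fraction of third-position changes; planted-Ks recovery tests bound
# the residual bias.
mutate_cds <- function(cds, ks) {
  if (ks <= 0) return(cds)
  mut <- mutate_sequence(cds, ks)
  cods <- split_codons(mut)
  orig <- split_codons(cds)
  n <- length(cods)
  bad <- which(cods[-n] %in% STOP_CODONS)
  if (length(bad)) cods[bad] <- orig[bad]
  paste(cods, collapse = "")
}

# Random CDS: ATG + sense codons + TAA, total length L (codon multiple).
random_cds <- function(L) {
  stopifnot(L %% 3L == 0L, L >= 9L)
  k <- L / 3L
  paste(c("ATG", sample(SENSE_CODONS, k - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

# ---------------------------------------------------------------------------
# genome editing primitives

# Insert `seq` so that it occupies positions (pos+1)..(pos+len). Every
# annotation starting beyond pos shifts right; inserting inside an existing
# gene or element is an error.
insert_sequence <- function(genome, chrom, pos, seq) {
  len <- nchar(seq)
  s <- genome$seq[[chrom]]
  if (pos < 0L || pos > nchar(s)) stop("insertion position out of range")
  on_chr <- genome$genes$chrom == chrom
  if (any(on_chr & genome$genes$start <= pos & genome$genes$end > pos)) {
    stop("insertion position falls inside a gene")
  }
  if (!is.null(genome$elements) && nrow(genome$elements)) {
    e_on <- genome$elements$chrom == chrom
    if (any(e_on & genome$elements$start <= pos & genome$elements$end > pos)) {
      stop("insertion position falls inside an LTR element")
    }
  }
  genome$seq[[chrom]] <- paste0(substr(s, 1L, pos), seq,
                                substr(s, pos + 1L, nchar(s)))
  shift <- function(df, cols = c("start", "end")) {
    if (is.null(df) || !nrow(df)) return(df)
    sel <- if ("chrom" %in% names(df)) df$chrom == chrom else
      df$gene_id %in% genome$genes$gene_id[on_chr]
    for (cl in intersect(cols, names(df))) {
      mv <- sel & df[[cl]] > pos
      df[[cl]][mv] <- df[[cl]][mv] + len
    }
    df
  }
  genome$genes <- shift(genome$genes)
  genome$exons$chrom <- genome$genes$chrom[match(genome$exons$gene_id,
                                                 genome$genes$gene_id)]
  genome$cds$chrom <- genome$genes$chrom[match(genome$cds$gene_id,
                                               genome$genes$gene_id)]
  genome$exons <- shift(genome$exons)
  genome$cds <- shift(genome$cds)
  genome$exons$chrom <- NULL
  genome$cds$chrom <- NULL
  if (!is.null(genome$elements)) {
    genome$elements <- shift(genome$elements,
                             c("start", "end", "ltr5_start", "ltr5_end",
                               "ltr3_start", "ltr3_end", "rt_start", "rt_end"))
  }
  genome
}

rerank <- function(genome) {
  g <- genome$genes
  for (ch in unique(g$chrom)) {
    i <- which(g$chrom == ch)
    g$rank[i][order(g$start[i], g$gene_id[i])] <- seq_along(i)
  }
  genome$genes <- g
  genome
}

# Register a new gene whose sequence was just inserted at (pos+1)..(pos+L).
# exon_off / cds_off are 1-based offsets into the inserted sequence.
register_gene <- function(genome, gene_id, chrom, pos, L, exon_off, cds_off,
                          strand) {
  genome$genes <- rbind(genome$genes, data.frame(
    gene_id = gene_id, chrom = chrom, start = pos + 1L, end = pos + L,
    strand = strand, rank = NA_integer_, stringsAsFactors = FALSE))
  genome$exons <- rbind(genome$exons, data.frame(
    gene_id = gene_id, start = pos + exon_off$start, end = pos + exon_off$end,
    stringsAsFactors = FALSE))
  genome$cds <- rbind(genome$cds, data.frame(
    gene_id = gene_id, start = pos + cds_off$start, end = pos + cds_off$end,
    stringsAsFactors = FALSE))
  rerank(genome)
}

# rank distance a gene inserted at `pos` on `chrom` would have from
# `gene_id` (Inf when on different chromosomes)
prospective_rank_distance <- function(genome, chrom, pos, gene_id) {
  g <- gene_record(genome, gene_id)
  if (g$chrom != chrom) return(Inf)
  on_chr <- genome$genes[genome$genes$chrom == chrom, ]
  c_rank <- sum(on_chr$start < pos) + 1L
  if (pos < g$start) g$rank + 1L - c_rank else c_rank - g$rank
}

# a random insertion site at rank distance > 2 from `away_from` (a planted
# retrocopy adjacent to its parent would be indistinguishable from a tandem
# duplicate and is excluded by the caller, so the generator avoids it)
random_site_away_from <- function(genome, away_from, tries = 50L) {
  for (i in seq_len(tries)) {
    site <- random_insertion_site(genome)
    if (prospective_rank_distance(genome, site$chrom, site$pos,
                                  away_from) > 2L) {
      return(site)
    }
  }
  stop("could not place a copy away from ", away_from)
}

# A random position not within `margin` of any gene or element on the chosen
# chromosome. Errors when no intergenic slot exists.
random_insertion_site <- function(genome, chrom = NULL, margin = 150L,
                                  exclude_chrom = NULL) {
  chroms <- setdiff(names(genome$seq), exclude_chrom)
  if (!is.null(chrom)) chroms <- chrom
  chroms <- sample(chroms)
  for (ch in chroms) {
    n <- nchar(genome$seq[[ch]])
    occ_s <- integer(0); occ_e <- integer(0)
    gi <- genome$genes$chrom == ch
    occ_s <- c(occ_s, genome$genes$start[gi]); occ_e <- c(occ_e, genome$genes$end[gi])
    if (!is.null(genome$elements) && nrow(genome$elements)) {
      ei <- genome$elements$chrom == ch
      occ_s <- c(occ_s, genome$elements$start[ei])
      occ_e <- c(occ_e, genome$elements$end[ei])
    }
    ok <- rep(TRUE, n)
    if (length(occ_s)) {
      for (j in seq_along(occ_s)) {
        lo <- max(1L, occ_s[j] - margin); hi <- min(n, occ_e[j] + margin)
        ok[lo:hi] <- FALSE
      }
    }
    ok[1:min(margin, n)] <- FALSE
    ok[max(1L, n - margin):n] <- FALSE
    cand <- which(ok)
    if (length(cand)) {
      return(list(chrom = ch, pos = sample_one(cand)))
    }
  }
  stop("no intergenic slot long enough for insertion")
}

# ---------------------------------------------------------------------------
# event planting

# Build the retro-derived sequence + annotation offsets for one variant.
# Returns list(seq, exon_off, cds_off, note).
build_retro_unit <- function(genome, parent_id, variant, ks,
                             intron_len = c(70L, 180L)) {
  pex <- genome$exons[genome$exons$gene_id == parent_id, , drop = FALSE]
  pex <- pex[order(pex$start), ]
  nex <- nrow(pex)
  g <- gene_record(genome, parent_id)
  # exon sequences in transcription order
  exon_seqs <- vapply(seq_len(nex), function(i)
    genome_substr(genome, g$chrom, pex$start[i], pex$end[i]), character(1))
  intron_seqs <- if (nex > 1L) vapply(seq_len(nex - 1L), function(i)
    genome_substr(genome, g$chrom, pex$end[i] + 1L, pex$start[i + 1L] - 1L),
    character(1)) else character(0)
  if (g$strand == "-") {
    exon_seqs <- rev(vapply(exon_seqs, revcomp, character(1)))
    intron_seqs <- rev(vapply(intron_seqs, revcomp, character(1)))
  }
  note <- ""
  if (variant == "clean") {
    if (nex < 2L) stop("clean retrocopy needs a parent with >= 2 exons")
    cds <- mutate_cds(paste(exon_seqs, collapse = ""), ks)
    segs <- data.frame(start = 1L, end = nchar(cds))
    seqs <- cds
  } else if (variant == "intron_retention") {
    if (nex < 3L) stop("intron retention planting needs >= 3 parent exons")
    ri <- sample_one(seq_len(nex - 1L))  # which intron is retained
    note <- paste0("retained_intron=", ri)
    cds <- mutate_cds(paste(exon_seqs, collapse = ""), ks)
    # split the mutated CDS back at exon boundaries, re-insert intron ri
    bnd <- cumsum(nchar(exon_seqs))
    left <- substr(cds, 1L, bnd[ri])
    right <- substr(cds, bnd[ri] + 1L, nchar(cds))
    intr <- intron_seqs[ri]
    seqs <- paste0(left, intr, right)
    segs <- data.frame(
      start = c(1L, nchar(left) + nchar(intr) + 1L),
      end = c(nchar(left), nchar(seqs)))
  } else if (variant == "exon_skipping") {
    if (nex < 3L) stop("exon skipping needs a parent with >= 3 exons")
    sk <- sample_one(2:(nex - 1L))
    note <- paste0("skipped_exon=", sk)
    keep <- exon_seqs[-sk]
    cds <- paste(keep, collapse = "")
    if (nchar(cds) %% 3L != 0L) {
      # trim the tail to a codon multiple so the model stays loadable
      cds <- substr(cds, 1L, nchar(cds) - nchar(cds) %% 3L)
    }
    cds <- mutate_cds(cds, ks)
    segs <- data.frame(start = 1L, end = nchar(cds))
    seqs <- cds
  } else if (variant == "intron_gain") {
    if (nex < 3L) stop("intron gain planting needs >= 3 parent exons")
    cds <- mutate_cds(paste(exon_seqs, collapse = ""), ks)
    L <- nchar(cds)
    # novel intron at a random interior position well away from parent
    # junctions (so the gained intron is unambiguous)
    bnd <- cumsum(nchar(exon_seqs))
    cand <- setdiff(seq(60L, L - 60L), unlist(lapply(bnd, function(b)
      max(1L, b - 25L):min(L, b + 25L))))
    at <- sample_one(cand)
    ilen <- sample(seq(intron_len[1], intron_len[2]), 1L)
    intr <- random_dna(ilen)
    note <- paste0("gained_intron_at=", at)
    seqs <- paste0(substr(cds, 1L, at), intr, substr(cds, at + 1L, L))
    segs <- data.frame(start = c(1L, at + ilen + 1L),
                       end = c(at, nchar(seqs)))
  } else stop("unknown retrocopy variant: ", variant)
  list(seq = seqs, exon_off = segs, cds_off = segs, note = note)
}

#' Plant a retrocopy of a parent gene
#'
#' Copies the parent's spliced transcript into a random intergenic position
#' (clean variant), optionally re-inserting one parent intron
#' (intron retention, annotated as an intron of the new model), dropping one
#' internal exon (exon skipping), or inserting a novel short intron
#' (intron gain). The copy is mutated towards the target Ks and annotated as
#' a gene.
#'
#' @param genome an [annotated_genome()].
#' @param parent_id parent gene (needs >= 2 exons; >= 3 for the alternative
#'   splice variants).
#' @param variant `"clean"`, `"intron_retention"`, `"exon_skipping"` or
#'   `"intron_gain"`.
#' @param ks target Ks between copy and parent.
#' @param gene_id id for the planted gene.
#' @param seed optional seed for a self-contained draw.
#' @return list with elements `genome` (edited) and `truth` (one truth row).
#' @export
plant_retrocopy <- function(genome, parent_id, variant, ks = 0.15,
                            gene_id = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  variant <- match.arg(variant, c("clean", "intron_retention",
                                  "exon_skipping", "intron_gain"))
  unit <- build_retro_unit(genome, parent_id, variant, ks)
  site <- random_site_away_from(genome, parent_id)
  strand <- sample(c("+", "-"), 1L)
  L <- nchar(unit$seq)
  ins <- unit$seq
  exon_off <- unit$exon_off; cds_off <- unit$cds_off
  if (strand == "-") {
    ins <- revcomp(ins)
    flip <- function(d) {
      s <- L - d$end + 1L; e <- L - d$start + 1L; o <- order(s)
      data.frame(start = s[o], end = e[o])
    }
    exon_off <- flip(exon_off)
    cds_off <- flip(cds_off)
  }
  if (is.null(gene_id)) gene_id <- paste0("retro_", parent_id)
  genome <- insert_sequence(genome, site$chrom, site$pos, ins)
  genome <- register_gene(genome, gene_id, site$chrom, site$pos, L,
                          exon_off, cds_off, strand)
  ev <- switch(variant, clean = "clean_retro", variant)
  truth <- data.frame(event_type = ev, child_id = gene_id,
                      parent_id = parent_id, planted_value = ks,
                      chrom = site$chrom, start = site$pos + 1L,
                      end = site$pos + L, note = unit$note,
                      stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}

# Full-locus (intron-preserving) duplicate of `source_id`. placement:
#  "dispersed"  random site on another chromosome
#  "adjacent"   immediately after `after` (gene or element span) -> tandem
#  "after_k"    after the gene k ranks downstream of the source -> proximal
plant_duplicate <- function(genome, source_id, ks, placement = "dispersed",
                            gene_id = NULL, k_intervening = NULL,
                            spacer = 60L) {
  g <- gene_record(genome, source_id)
  loc <- genome_substr(genome, g$chrom, g$start, g$end)
  ex <- genome$exons[genome$exons$gene_id == source_id, , drop = FALSE]
  ex <- ex[order(ex$start), ]
  cd <- genome$cds[genome$cds$gene_id == source_id, , drop = FALSE]
  cd <- cd[order(cd$start), ]
  exon_off <- data.frame(start = ex$start - g$start + 1L, end = ex$end - g$start + 1L)
  cds_off <- data.frame(start = cd$start - g$start + 1L, end = cd$end - g$start + 1L)
  # mutate the whole locus at the Ks rate, then rebuild the CDS portion with
  # stop-avoiding codon mutation so the copy stays translatable
  L <- nchar(loc)
  mut <- strsplit(mutate_sequence(loc, ks), "", fixed = TRUE)[[1]]
  spl_fwd <- paste(vapply(seq_len(nrow(cds_off)), function(i)
    substr(loc, cds_off$start[i], cds_off$end[i]), character(1)), collapse = "")
  cds_src <- if (g$strand == "-") revcomp(spl_fwd) else spl_fwd
  cds_mut <- mutate_cds(cds_src, ks)
  if (g$strand == "-") cds_mut <- revcomp(cds_mut)
  at <- 1L
  for (i in seq_len(nrow(cds_off))) {
    w <- cds_off$end[i] - cds_off$start[i] + 1L
    mut[cds_off$start[i]:cds_off$end[i]] <-
      strsplit(substr(cds_mut, at, at + w - 1L), "", fixed = TRUE)[[1]]
    at <- at + w
  }
  dup <- paste(mut, collapse = "")

  if (placement == "dispersed") {
    site <- random_insertion_site(genome, exclude_chrom = g$chrom)
  } else if (placement == "adjacent") {
    end_anchor <- g$end
    if (!is.null(genome$elements) && nrow(genome$elements)) {
      cover <- genome$elements$chrom == g$chrom &
        genome$elements$start <= g$start & genome$elements$end >= g$end
      if (any(cover)) end_anchor <- max(genome$elements$end[cover])
    }
    site <- list(chrom = g$chrom, pos = end_anchor + spacer)
  } else if (placement == "after_k") {
    gg <- genome$genes
    same <- gg[gg$chrom == g$chrom, ]
    tgt_rank <- g$rank + k_intervening
    if (!any(same$rank == tgt_rank)) stop("not enough downstream genes")
    anchor <- same[same$rank == tgt_rank, ]
    site <- list(chrom = g$chrom, pos = anchor$end + spacer)
  } else stop("unknown placement")
  if (is.null(gene_id)) gene_id <- paste0("dup_", source_id)
  genome <- insert_sequence(genome, site$chrom, site$pos, dup)
  genome <- register_gene(genome, gene_id, site$chrom, site$pos, L,
                          exon_off, cds_off, g$strand)
  ev <- switch(placement, dispersed = "dna_dup", adjacent = "tandem",
               after_k = "proximal")
  truth <- data.frame(event_type = ev, child_id = gene_id,
                      parent_id = source_id, planted_value = ks,
                      chrom = site$chrom, start = site$pos + 1L,
                      end = site$pos + L, note = "", stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}

#' Plant an intact LTR retrotransposon
#'
#' Builds 5'LTR + internal region + 3'LTR where the 3'LTR is
#' `mutate_sequence(5'LTR, d)`. Both repeats begin `TG` and end `CA`; an
#' exact target-site duplication flanks the element; the internal region
#' carries a reverse-transcriptase cassette drawn from the bundled synthetic
#' exemplar set. Optionally a cargo gene is placed strictly inside the
#' element: a plain single-exon copy of `cargo_source` (`cargo = "gene"`) or
#' a clean retrocopy of it (`cargo = "retro"`).
#'
#' @param genome an [annotated_genome()].
#' @param ltr_len LTR length (>= 100).
#' @param internal_len internal-region length (>= 500), cargo excluded.
#' @param d LTR divergence on the JC69 scale.
#' @param cargo `"none"`, `"gene"` or `"retro"`.
#' @param cargo_source source gene id when cargo is planted.
#' @param cargo_ks target Ks between cargo and its source.
#' @param element_id,gene_id identifiers.
#' @param tsd_len exact target-site duplication length (4-6).
#' @param exemplar RT exemplar id (default: random from the bundled set).
#' @return list(genome, truth, element_id).
#' @export
plant_ltr_element <- function(genome, ltr_len = 350L, internal_len = 3000L,
                              d = 0.02, cargo = c("none", "gene", "retro"),
                              cargo_source = NULL, cargo_ks = 0.15,
                              element_id = NULL, gene_id = NULL,
                              tsd_len = 5L, exemplar = NULL) {
  cargo <- match.arg(cargo)
  if (ltr_len < 100L) stop("ltr_len must be >= 100")
  if (internal_len < 500L) stop("internal_len must be >= 500")
  ex_set <- rt_exemplars()
  if (is.null(exemplar)) exemplar <- sample(names(ex_set$seq), 1L)
  rt_seq <- mutate_sequence(ex_set$seq[[exemplar]], d)

  ltr5 <- paste0("TG", random_dna(ltr_len - 4L), "CA")
  ltr3 <- mutate_sequence(ltr5, d)
  # pin the terminal dinucleotides: insertion termini are structural
  ltr3 <- paste0("TG", substr(ltr3, 3L, ltr_len - 2L), "CA")

  cargo_unit <- NULL
  if (cargo != "none") {
    if (is.null(cargo_source)) stop("cargo planting needs a source gene")
    if (cargo == "gene") {
      src_cds <- spliced_cds(genome, cargo_source)
      cds <- mutate_cds(src_cds, cargo_ks)
      cargo_unit <- list(seq = cds,
                         off = data.frame(start = 1L, end = nchar(cds)))
    } else {
      unit <- build_retro_unit(genome, cargo_source, "clean", cargo_ks)
      cargo_unit <- list(seq = unit$seq, off = unit$exon_off)
    }
  }
  rt_at <- sample(seq(50L, internal_len - nchar(rt_seq) - 50L), 1L)
  internal <- paste0(random_dna(rt_at - 1L), rt_seq,
                     random_dna(internal_len - rt_at + 1L - nchar(rt_seq)))
  cargo_at <- NA_integer_
  if (!is.null(cargo_unit)) {
    # keep the cargo clear of the RT cassette
    lo <- rt_at + nchar(rt_seq) + 30L
    hi <- nchar(internal) - nchar(cargo_unit$seq) - 30L
    if (hi <= lo) {  # not enough room after the cassette; put it before
      lo <- 30L; hi <- rt_at - nchar(cargo_unit$seq) - 30L
    }
    if (hi <= lo) stop("internal region too short for cargo gene")
    cargo_at <- sample_one(seq(lo, hi))
    internal <- paste0(substr(internal, 1L, cargo_at - 1L), cargo_unit$seq,
                       substr(internal, cargo_at, nchar(internal)))
  }
  tsd <- random_dna(tsd_len)
  elem_seq <- paste0(ltr5, internal, ltr3)
  ins <- paste0(tsd, elem_seq, tsd)

  site <- if (cargo == "retro") random_site_away_from(genome, cargo_source)
    else random_insertion_site(genome)
  genome <- insert_sequence(genome, site$chrom, site$pos, ins)
  e_start <- site$pos + tsd_len + 1L
  e_end <- e_start + nchar(elem_seq) - 1L
  if (is.null(element_id)) {
    element_id <- paste0("LTRE_", site$chrom, "_", e_start)
  }
  row <- data.frame(
    element_id = element_id, chrom = site$chrom, start = e_start, end = e_end,
    ltr5_start = e_start, ltr5_end = e_start + ltr_len - 1L,
    ltr3_start = e_end - ltr_len + 1L, ltr3_end = e_end,
    motif = "TGCA",
    rt_start = e_start + ltr_len + rt_at - 1L +
      if (!is.na(cargo_at) && cargo_at <= rt_at) nchar(cargo_unit$seq) else 0L,
    rt_end = NA_integer_, d = d, exemplar = exemplar,
    stringsAsFactors = FALSE)
  row$rt_end <- row$rt_start + nchar(rt_seq) - 1L
  if (is.null(genome$elements)) genome$elements <- row[0, ]
  genome$elements <- rbind(genome$elements, row)

  truths <- data.frame(event_type = "ltr_element", child_id = element_id,
                       parent_id = "", planted_value = d,
                       chrom = site$chrom, start = e_start, end = e_end,
                       note = exemplar, stringsAsFactors = FALSE)
  if (!is.null(cargo_unit)) {
    gstart <- e_start + ltr_len + cargo_at - 1L
    L <- nchar(cargo_unit$seq)
    if (is.null(gene_id)) gene_id <- paste0("cargo_", cargo_source)
    genome <- register_gene(
      genome, gene_id, site$chrom, gstart - 1L, L,
      cargo_unit$off, cargo_unit$off, "+")
    truths <- rbind(truths, data.frame(
      event_type = if (cargo == "retro") "ltr_retro" else "ltr_contained",
      child_id = gene_id, parent_id = cargo_source, planted_value = cargo_ks,
      chrom = site$chrom, start = gstart, end = gstart + L - 1L,
      note = element_id, stringsAsFactors = FALSE))
  }
  list(genome = genome, truth = truths, element_id = element_id)
}

# ---------------------------------------------------------------------------

.rt_env <- new.env(parent = emptyenv())

#' Bundled synthetic RT-domain exemplars
#'
#' A small set of synthetic reverse-transcriptase cassette sequences (one per
#' retroelement clade label) used to seed the internal regions of planted
#' elements and as the query set for RT-domain annotation. The sequences are
#' synthetic stand-ins generated with a fixed seed, not database domains.
#'
#' @return list with `seq` (named character vector) and `meta` (data.frame
#'   with `id`, `clade`, `superfamily`).
#' @export
rt_exemplars <- function() {
  if (is.null(.rt_env$ex)) {
    path <- system.file("extdata", "rt_exemplars_synthetic.fasta",
                        package = "retrodup")
    ss <- Biostrings::readDNAStringSet(path)
    hdr <- names(ss)
    id <- sub("\\s.*$", "", hdr)
    clade <- sub("\\s.*$", "", sub(".*clade=", "", hdr))
    supf <- sub("\\s.*$", "", sub(".*superfamily=", "", hdr))
    seqs <- stats::setNames(as.character(ss), id)
    .rt_env$ex <- list(seq = seqs,
                       meta = data.frame(id = id, clade = clade,
                                         superfamily = supf,
                                         stringsAsFactors = FALSE))
  }
  .rt_env$ex
}

# base genome skeleton: alternating intergenic spacer + gene
build_base_genome <- function(cfg) {
  n <- cfg$n_base_genes
  chrom_of <- sort(rep_len(seq_len(cfg$n_chromosomes), n))
  seqs <- stats::setNames(vector("list", cfg$n_chromosomes),
                          paste0("chr", seq_len(cfg$n_chromosomes)))
  genes <- exons <- NULL
  domains <- character(n)
  gid_all <- sprintf("g%03d", seq_len(n))
  for (ci in seq_len(cfg$n_chromosomes)) {
    pieces <- character(0)
    at <- 0L
    for (gi in which(chrom_of == ci)) {
      spacer <- sample(seq(cfg$intergenic_len[1], cfg$intergenic_len[2]), 1L)
      pieces <- c(pieces, random_dna(spacer))
      at <- at + spacer
      k <- if (stats::runif(1) < cfg$single_exon_frac) 1L else
        sample(seq(max(2L, cfg$exons_per_gene[1]), cfg$exons_per_gene[2]), 1L)
      elens <- sample(seq(cfg$exon_len[1], cfg$exon_len[2]), k, replace = TRUE)
      elens <- elens - elens %% 3L
      if (k == 1L) elens <- elens + 300L  # single-exon genes stay comfortably >100 aa
      ilens <- if (k > 1L) sample(seq(cfg$intron_len[1], cfg$intron_len[2]),
                                  k - 1L, replace = TRUE) else integer(0)
      cds <- random_cds(sum(elens))
      # interleave exons and introns (forward sense)
      exs <- character(k); b <- 0L
      for (j in seq_len(k)) { exs[j] <- substr(cds, b + 1L, b + elens[j]); b <- b + elens[j] }
      body <- exs[1]
      if (k > 1L) for (j in 2:k) body <- paste0(body, random_dna(ilens[j - 1L]), exs[j])
      L <- nchar(body)
      off_s <- cumsum(c(1L, if (k > 1L) elens[-k] + ilens else integer(0)))
      off_e <- off_s + elens - 1L
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") {
        body <- revcomp(body)
        tmp_s <- L - off_e + 1L; tmp_e <- L - off_s + 1L
        o <- order(tmp_s); off_s <- tmp_s[o]; off_e <- tmp_e[o]
      }
      gid <- gid_all[gi]
      genes <- rbind(genes, data.frame(
        gene_id = gid, chrom = names(seqs)[ci], start = at + 1L, end = at + L,
        strand = strand, stringsAsFactors = FALSE))
      exons <- rbind(exons, data.frame(gene_id = gid, start = at + off_s,
                                       end = at + off_e, stringsAsFactors = FALSE))
      domains[gi] <- sample(DOMAIN_POOL, 1L)
      pieces <- c(pieces, body)
      at <- at + L
    }
    tail_sp <- sample(seq(cfg$intergenic_len[1], cfg$intergenic_len[2]), 1L)
    pieces <- c(pieces, random_dna(tail_sp))
    seqs[[ci]] <- paste(pieces, collapse = "")
  }
  genome <- annotated_genome(unlist(seqs), genes, exons)
  genome$elements <- NULL
  list(genome = genome,
       domains = data.frame(gene_id = gid_all, domain = domains,
                            stringsAsFactors = FALSE))
}

#' Simulate a synthetic genome with planted duplication events
#'
#' Builds the base genome, plants every configured event class and returns
#' the annotated genome together with the LTR table, domain table, truth
#' table and default species tree. With `outdir` set, writes
#' `genome.fasta`, `genes.gff3`, `ltr_table.tsv`, `domains.tsv`, `truth.tsv`
#' and `tree.nwk`.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory (created if missing).
#' @return list with `genome`, `ltr_table`, `domains`, `truth`, `tree`
#'   (newick string), and `paths` when files were written.
#' @export
simulate_genome <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  base <- build_base_genome(config)
  genome <- base$genome
  domains <- base$domains
  truth <- NULL

  ecount <- exon_counts(genome)
  multi2 <- names(ecount)[ecount >= 2L]
  multi3 <- names(ecount)[ecount >= 3L]
  # exon-skipping copies keep a spannable junction only when the parent has a
  # junction away from the skipped exon, hence >= 4 exons
  multi4 <- names(ecount)[ecount >= 4L]
  single <- names(ecount)[ecount == 1L]

  n_retro <- config$n_clean_retro + config$n_intron_retention +
    config$n_exon_skipping + config$n_intron_gain
  need3 <- config$n_intron_retention + config$n_exon_skipping +
    config$n_intron_gain
  n_src <- config$n_dna_dup + config$n_proximal +
    config$tandem_arrays$base$n * (1L + (config$b1_dispersed_per_array > 0L))
  if (length(multi4) < config$n_exon_skipping ||
      length(multi3) < need3 + config$n_ltr_retro ||
      length(multi2) < n_retro + config$n_ltr_retro ||
      length(single) < config$n_ltr_contained ||
      length(ecount) < n_retro + config$n_ltr_retro + config$n_ltr_contained +
        config$n_dna_dup + config$n_proximal + config$tandem_arrays$base$n) {
    stop("configuration plants more events than the base genome can host")
  }

  # disjoint source/parent pools, chosen up front
  par_es <- sample(multi4, config$n_exon_skipping)
  pool3 <- sample(setdiff(multi3, par_es))
  par_ir <- pool3[seq_len(config$n_intron_retention)]; pool3 <- setdiff(pool3, par_ir)
  par_ig <- pool3[seq_len(config$n_intron_gain)]; pool3 <- setdiff(pool3, par_ig)
  par_lr <- pool3[seq_len(config$n_ltr_retro)]; pool3 <- setdiff(pool3, par_lr)
  pool2 <- sample(setdiff(multi2, c(par_ir, par_es, par_ig, par_lr)))
  par_cl <- pool2[seq_len(config$n_clean_retro)]
  used <- c(par_ir, par_es, par_ig, par_lr, par_cl)
  src_ct <- sample(setdiff(single, used), config$n_ltr_contained)
  used <- c(used, src_ct)
  rest <- sample(setdiff(genome$genes$gene_id, used))
  src_dna <- rest[seq_len(config$n_dna_dup)]; rest <- setdiff(rest, src_dna)
  src_prox <- rest[seq_len(config$n_proximal)]; rest <- setdiff(rest, src_prox)
  seeds_b1 <- rest[seq_len(config$tandem_arrays$base$n)]

  add <- function(res) {
    genome <<- res$genome
    truth <<- rbind(truth, res$truth)
  }

  # DNA-level dispersed duplicates (negative controls for the retro caller)
  for (s in src_dna) {
    add(plant_duplicate(genome, s, config$dna_dup_ks, "dispersed",
                        gene_id = paste0("dnadup_", s)))
    domains <- rbind(domains, data.frame(
      gene_id = paste0("dnadup_", s),
      domain = domains$domain[domains$gene_id == s], stringsAsFactors = FALSE))
  }
  # retrocopies
  plant_r <- function(parents, variant) {
    for (s in parents) {
      gid <- paste0("retro_", s)
      add(plant_retrocopy(genome, s, variant, ks = config$retro_ks,
                          gene_id = gid))
      domains <<- rbind(domains, data.frame(
        gene_id = gid, domain = domains$domain[domains$gene_id == s],
        stringsAsFactors = FALSE))
    }
  }
  plant_r(par_cl, "clean")
  plant_r(par_ir, "intron_retention")
  plant_r(par_es, "exon_skipping")
  plant_r(par_ig, "intron_gain")

  # LTR elements: free, retro-cargo, contained-cargo
  ilen_rng <- config$internal_len
  draw_ilen <- function() sample(seq(ilen_rng[1], ilen_rng[2]), 1L)
  for (i in seq_len(config$n_free_ltr)) {
    add_el <- plant_ltr_element(genome, ltr_len = config$ltr_len,
                                internal_len = draw_ilen(),
                                d = config$free_ltr_divergence[i],
                                cargo = "none", tsd_len = config$tsd_len,
                                element_id = sprintf("LTR_free%02d", i))
    add(add_el)
  }
  draw_cd <- function() stats::runif(1, config$cargo_ltr_divergence[1],
                                     config$cargo_ltr_divergence[2])
  for (i in seq_along(par_lr)) {
    gid <- paste0("lretro_", par_lr[i])
    add(plant_ltr_element(genome, ltr_len = config$ltr_len,
                          internal_len = draw_ilen(), d = draw_cd(),
                          cargo = "retro", cargo_source = par_lr[i],
                          cargo_ks = config$retro_ks, gene_id = gid,
                          tsd_len = config$tsd_len,
                          element_id = sprintf("LTR_ret%02d", i)))
    domains <- rbind(domains, data.frame(
      gene_id = gid, domain = domains$domain[domains$gene_id == par_lr[i]],
      stringsAsFactors = FALSE))
  }
  for (i in seq_along(src_ct)) {
    gid <- paste0("lgene_", src_ct[i])
    add(plant_ltr_element(genome, ltr_len = config$ltr_len,
                          internal_len = draw_ilen(), d = draw_cd(),
                          cargo = "gene", cargo_source = src_ct[i],
                          cargo_ks = config$dna_dup_ks, gene_id = gid,
                          tsd_len = config$tsd_len,
                          element_id = sprintf("LTR_cnt%02d", i)))
    dom <- "RT"
    if (stats::runif(1) < config$cargo_extra_domain_frac) {
      dom <- c(dom, sample(DOMAIN_POOL, 1L))
    }
    domains <- rbind(domains, data.frame(gene_id = gid, domain = dom,
                                         stringsAsFactors = FALSE))
  }

  # tandem arrays: serial copies so every adjacency hits the target Ks
  plant_array <- function(seed_gene, size, ks, tag, retro_seeded) {
    prev <- seed_gene
    for (j in seq_len(size - 1L)) {
      gid <- sprintf("%s_%s_c%d", tag, seed_gene, j)
      res <- plant_duplicate(genome, prev, ks, "adjacent", gene_id = gid)
      res$truth$parent_id <- prev
      res$truth$note <- if (retro_seeded) "retro_seeded" else "base_seeded"
      add(res)
      src_dom <- domains$domain[domains$gene_id ==
        (if (grepl("^lretro_|^retro_", prev)) prev else prev)][1]
      domains <<- rbind(domains, data.frame(gene_id = gid, domain = src_dom,
                                            stringsAsFactors = FALSE))
      prev <- gid
    }
  }
  ta <- config$tandem_arrays
  retro_seeds <- c(paste0("lretro_", par_lr), paste0("retro_", par_cl))
  retro_seeds <- retro_seeds[retro_seeds %in% genome$genes$gene_id]
  if (ta$retro$n > length(retro_seeds)) stop("not enough retrocopies to seed arrays")
  rs <- retro_seeds[seq_len(ta$retro$n)]  # prefer LTR-carried retro first
  for (s in rs) plant_array(s, ta$retro$size, ta$retro$ks, "tdr", TRUE)
  for (s in seeds_b1) plant_array(s, ta$base$size, ta$base$ks, "tdb", FALSE)
  # dispersed DNA-level copies diluting the base-seeded (B1) orthogroups
  for (s in seeds_b1) {
    for (j in seq_len(config$b1_dispersed_per_array)) {
      gid <- sprintf("disp_%s_%d", s, j)
      add(plant_duplicate(genome, s, config$dna_dup_ks, "dispersed",
                          gene_id = gid))
      domains <- rbind(domains, data.frame(
        gene_id = gid, domain = domains$domain[domains$gene_id == s],
        stringsAsFactors = FALSE))
    }
  }

  # proximal duplicates, planted last so no later insertion can widen the
  # pair beyond the 19-intervening-gene bound; k stays <= 16 and the anchor
  # must have free downstream space outside any element
  anchor_ok <- function(chrom, tgt_rank) {
    on_chr <- genome$genes[genome$genes$chrom == chrom, ]
    a <- on_chr[on_chr$rank == tgt_rank, ]
    if (!nrow(a)) return(FALSE)
    pos <- a$end + 60L
    nxt <- on_chr[on_chr$rank == tgt_rank + 1L, ]
    if (nrow(nxt) && nxt$start - a$end < 500L) return(FALSE)
    if (!is.null(genome$elements) && nrow(genome$elements)) {
      covered <- genome$elements$chrom == chrom &
        genome$elements$start <= pos & genome$elements$end >= pos
      if (any(covered)) return(FALSE)
    }
    TRUE
  }
  for (s in src_prox) {
    g <- gene_record(genome, s)
    on_chr <- genome$genes[genome$genes$chrom == g$chrom, ]
    room <- max(on_chr$rank) - g$rank
    kcand <- c(if (room >= 2L) seq(2L, min(16L, room)),
               if (g$rank >= 4L) -seq(3L, min(17L, g$rank - 1L)))
    kcand <- kcand[sample.int(length(kcand))]
    k <- NA_integer_
    for (kk in kcand) {
      if (anchor_ok(g$chrom, g$rank + kk)) { k <- kk; break }
    }
    if (is.na(k)) {
      warning("no room for a proximal copy of ", s, "; skipped")
      next
    }
    res <- plant_duplicate(genome, s, config$proximal_ks, "after_k",
                           gene_id = paste0("prox_", s), k_intervening = k)
    add(res)
    domains <- rbind(domains, data.frame(
      gene_id = paste0("prox_", s),
      domain = domains$domain[domains$gene_id == s], stringsAsFactors = FALSE))
  }

  genome <- rerank(genome)
  ltr_table <- genome$elements[, c("element_id", "chrom", "start", "end",
                                   "ltr5_start", "ltr5_end", "ltr3_start",
                                   "ltr3_end", "motif", "rt_start", "rt_end")]
  tree <- "(((focal:5,sisterA:5):5,sisterB:10):5,sisterC:15);"
  out <- list(genome = genome, ltr_table = ltr_table, domains = domains,
              truth = truth, tree = tree, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)
    write_genome(genome, p("genome.fasta"), p("genes.gff3"))
    write_report_tsv(ltr_table, p("ltr_table.tsv"))
    write_report_tsv(domains, p("domains.tsv"))
    write_report_tsv(truth, p("truth.tsv"))
    writeLines(tree, p("tree.nwk"))
    out$paths <- c(fasta = p("genome.fasta"), gff3 = p("genes.gff3"),
                   ltr = p("ltr_table.tsv"), domains = p("domains.tsv"),
                   truth = p("truth.tsv"), tree = p("tree.nwk"))
  }
  out
}
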