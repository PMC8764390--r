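# Retrogene calling: candidate pairing on unequal exon counts, DNA-level
# duplicate exclusion, exon-junction evidence against the parent's spliced
# transcript, tandem-with-parent exclusion, parent assignment, and
# splice-origin classification.

#' Candidate retrogene pairs
#'
#' Protein-similar gene pairs (post-filter hits) whose members have unequal
#' exon counts; equal-exon pairs carry no intron-loss signal and are dropped.
#'
#' @param genome an [annotated_genome()].
#' @param hits filtered hit table from [all_vs_all()] (TE-like genes already
#'   removed upstream).
#' @return data.frame with columns `gene_a`, `gene_b` (canonical order) and
#'   `bit_score` (the better of the two directions).
#' @export
candidate_pairs <- function(genome, hits) {
  if (!nrow(hits)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      bit_score = numeric(0), stringsAsFactors = FALSE))
  }
  ec <- exon_counts(genome)
  a <- pmin(hits$query, hits$subject)
  b <- pmax(hits$query, hits$subject)
  df <- data.frame(gene_a = a, gene_b = b, bit_score = hits$bit_score,
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b, -df$bit_score), ]
  df <- df[!duplicated(paste(df$gene_a, df$gene_b)), ]
  keep <- ec[df$gene_a] != ec[df$gene_b]
  df <- df[!is.na(keep) & keep, ]
  rownames(df) <- NULL
  df
}

#' Exon-junction evidence for a retrogene candidate
#'
#' Aligns the few-exon gene's genomic locus to the multi-exon gene's spliced
#' transcript (nucleotide local alignment) and counts parent exon-exon
#' junctions covered by a single contiguous aligned segment. Segments are
#' maximal alignment runs whose internal gap runs are all `<= shift` bases,
#' so a junction is "spanned" when at least two parental exons connect
#' within one retro-side exon, with up to `shift` bases of boundary slop
#' tolerated. A DNA-level duplicate, whose introns interrupt the alignment
#' with long transcript-side gaps, spans no junction.
#'
#' @param genome an [annotated_genome()].
#' @param multi_exon_id,few_exon_id the two genes; the multi-exon member must
#'   have >= 2 exons. Order is re-derived internally, so passing them swapped
#'   gives the same count.
#' @param shift tolerated boundary shift (bp).
#' @return integer count of spanned junctions (0 when the alignment fails).
#' @export
junction_evidence <- function(genome, multi_exon_id, few_exon_id, shift = 19L) {
  ec <- exon_counts(genome)
  if (ec[multi_exon_id] < ec[few_exon_id]) {
    tmp <- multi_exon_id; multi_exon_id <- few_exon_id; few_exon_id <- tmp
  }
  if (ec[multi_exon_id] < 2L) return(0L)
  transcript <- spliced_cds(genome, multi_exon_id, what = "exon")
  retro_locus <- gene_locus_seq(genome, few_exon_id)
  # junction positions in transcript coordinates (after exon i, 1-based)
  ex <- genome$exons[genome$exons$gene_id == multi_exon_id, , drop = FALSE]
  ex <- ex[order(ex$start), ]
  lens <- ex$end - ex$start + 1L
  g <- gene_record(genome, multi_exon_id)
  if (g$strand == "-") lens <- rev(lens)
  junctions <- cumsum(lens)[-length(lens)]
  count_side <- function(locus) {
    aln <- local_align(locus, transcript, mode = "nucleotide")
    if (aln$score <= 0) return(rep(FALSE, length(junctions)))
    segs <- aligned_segments(aln, max_gap = shift)
    spanned <- logical(length(junctions))
    for (i in seq_len(nrow(segs))) {
      spanned <- spanned |
        (segs$sstart[i] <= junctions & segs$send[i] >= junctions + 1L)
    }
    spanned
  }
  # the locus was stored forward-strand; try both orientations of the retro
  sp <- count_side(retro_locus) | count_side(revcomp(retro_locus))
  sum(sp)
}

#' Is a candidate pair a DNA-level duplicate?
#'
#' True iff nucleotide alignment of the two genomic loci (introns included)
#' yields a single contiguous hit -- an aligned segment with no gap run
#' longer than `max_gap` on either side -- covering at least `min_cov` of
#' the shorter locus at `min_identity` percent within the segment.
#' Conserved introns keep the alignment in one piece, so DNA-based
#' duplicates satisfy the rule at any divergence the pipeline considers,
#' while a retrocopy's missing introns fragment the alignment into per-exon
#' segments none of which reaches the coverage bar. Such intron-conserving
#' pairs are discarded upstream of retrogene calling.
#'
#' @param genome an [annotated_genome()].
#' @param gene_a,gene_b the candidate pair.
#' @param min_cov minimum fraction of the shorter locus one segment covers.
#' @param min_identity minimum percent identity within that segment.
#' @param max_gap largest gap run (bp) tolerated inside one segment.
#' @return logical.
#' @export
is_dna_level_duplicate <- function(genome, gene_a, gene_b, min_cov = 0.8,
                                   min_identity = 70, max_gap = 19L) {
  la <- gene_locus_seq(genome, gene_a)
  lb <- gene_locus_seq(genome, gene_b)
  a_shorter <- nchar(la) <= nchar(lb)
  shorter <- min(nchar(la), nchar(lb))
  test <- function(x, y) {
    aln <- local_align(x, y, mode = "nucleotide")
    segs <- aligned_segments(aln, max_gap = max_gap)
    if (!nrow(segs)) return(FALSE)
    span <- if (a_shorter) segs$pend - segs$pstart + 1L else
      segs$send - segs$sstart + 1L
    ident <- 100 * segs$matches / pmax(span, 1L)
    any(span / shorter >= min_cov & ident >= min_identity)
  }
  test(la, lb) || test(la, revcomp(lb))
}

# does any >= min_len stretch of a parent intron survive (>= min_identity)
# in the retro locus?
intron_retained <- function(genome, parent_id, retro_id, min_len = 40L,
                            min_identity = 80) {
  ex <- genome$exons[genome$exons$gene_id == parent_id, , drop = FALSE]
  ex <- ex[order(ex$start), ]
  if (nrow(ex) < 2L) return(FALSE)
  g <- gene_record(genome, parent_id)
  retro_locus <- gene_locus_seq(genome, retro_id)
  for (i in seq_len(nrow(ex) - 1L)) {
    intr <- genome_substr(genome, g$chrom, ex$end[i] + 1L, ex$start[i + 1L] - 1L)
    if (nchar(intr) < min_len) next
    for (q in c(intr, revcomp(intr))) {
      aln <- local_align(q, retro_locus, mode = "nucleotide")
      if (aln$aligned_length >= min_len && aln$identity_pct >= min_identity) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# is an internal parent exon (>= min_len) absent from the retro's spliced
# sequence while both flanking exons are present?
exon_skipped <- function(genome, parent_id, retro_id, min_len = 30L) {
  ex <- genome$exons[genome$exons$gene_id == parent_id, , drop = FALSE]
  ex <- ex[order(ex$start), ]
  nex <- nrow(ex)
  if (nex < 3L) return(FALSE)
  g <- gene_record(genome, parent_id)
  exon_seqs <- vapply(seq_len(nex), function(i)
    genome_substr(genome, g$chrom, ex$start[i], ex$end[i]), character(1))
  if (g$strand == "-") exon_seqs <- rev(vapply(exon_seqs, revcomp, character(1)))
  retro_spliced <- spliced_cds(genome, retro_id, what = "exon")
  present <- function(es, target) {
    best <- 0
    for (q in c(target, revcomp(target))) {
      aln <- local_align(es, q, mode = "nucleotide")
      cov <- (aln$pattern_span[2] - aln$pattern_span[1] + 1L) / nchar(es)
      if (aln$identity_pct >= 60 && cov > best) best <- cov
    }
    best
  }
  for (i in 2:(nex - 1L)) {
    if (nchar(exon_seqs[i]) < min_len) next
    if (present(exon_seqs[i], retro_spliced) < 0.5 &&
        present(exon_seqs[i - 1L], retro_spliced) >= 0.5 &&
        present(exon_seqs[i + 1L], retro_spliced) >= 0.5) {
      return(TRUE)
    }
  }
  FALSE
}

#' Call retrogenes
#'
#' For each surviving candidate pair: the member with more exons is the
#' parent; pairs that are DNA-level duplicates, tandem with their parent
#' (same chromosome, gene-rank distance <= 2), or without junction evidence
#' are discarded; each retrogene keeps its best-supported parent (highest
#' bit score, ties by lower Ks). The splice-origin class is `clean_retro`
#' for single-exon copies, `intron_retention` when a parent intron survives
#' in the copy, `exon_skipping` when an internal parent exon is missing
#' while its flanks are present, and `intron_gain` for a copy with introns
#' at positions where the parent has none.
#'
#' @param genome an [annotated_genome()].
#' @param candidates from [candidate_pairs()].
#' @param shift junction boundary-shift tolerance (bp).
#' @param ks_fun optional function(geneA, geneB) -> Ks used only for parent
#'   tie-breaks.
#' @return data.frame with one row per retrogene: `retro_id`, `parent_id`,
#'   `junctions_spanned`, `intron_delta`, `splice_class`, `parent_exons`,
#'   `retro_exons`.
#' @export
call_retrogenes <- function(genome, candidates, shift = 19L, ks_fun = NULL) {
  out <- NULL
  if (!nrow(candidates)) return(empty_retrocalls())
  ec <- exon_counts(genome)
  for (i in seq_len(nrow(candidates))) {
    a <- candidates$gene_a[i]; b <- candidates$gene_b[i]
    parent <- if (ec[a] >= ec[b]) a else b
    retro <- if (parent == a) b else a
    ga <- gene_record(genome, parent); gb <- gene_record(genome, retro)
    # tandem with its own parent -> discarded
    if (ga$chrom == gb$chrom && abs(ga$rank - gb$rank) <= 2L) next
    if (is_dna_level_duplicate(genome, parent, retro)) next
    js <- junction_evidence(genome, parent, retro, shift = shift)
    if (js < 1L) next
    out <- rbind(out, data.frame(
      retro_id = retro, parent_id = parent, junctions_spanned = js,
      bit_score = candidates$bit_score[i],
      parent_exons = as.integer(ec[parent]), retro_exons = as.integer(ec[retro]),
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) return(empty_retrocalls())
  # one call per retrogene: best parent by bit score, tie by lower Ks
  if (!is.null(ks_fun)) {
    out$ks <- mapply(ks_fun, out$retro_id, out$parent_id)
  } else out$ks <- NA_real_
  out <- out[order(out$retro_id, -out$bit_score, out$ks, out$parent_id), ]
  out <- out[!duplicated(out$retro_id), ]
  out$splice_class <- vapply(seq_len(nrow(out)), function(i) {
    classify_splice_origin(genome, out$parent_id[i], out$retro_id[i])
  }, character(1))
  out$intron_delta <- out$parent_exons - out$retro_exons
  rownames(out) <- NULL
  out[, c("retro_id", "parent_id", "junctions_spanned", "intron_delta",
          "splice_class", "parent_exons", "retro_exons")]
}

empty_retrocalls <- function() {
  data.frame(retro_id = character(0), parent_id = character(0),
             junctions_spanned = integer(0), intron_delta = integer(0),
             splice_class = character(0), parent_exons = integer(0),
             retro_exons = integer(0), stringsAsFactors = FALSE)
}

# priority: retention evidence, then skipping, then the single-exon clean
# rule, then gained introns as the residual multi-exon class
classify_splice_origin <- function(genome, parent_id, retro_id) {
  if (intron_retained(genome, parent_id, retro_id)) return("intron_retention")
  if (exon_skipped(genome, parent_id, retro_id)) return("exon_skipping")
  ec <- exon_counts(genome)
  if (ec[retro_id] == 1L) return("clean_retro")
  "intron_gain"
}
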