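# Ka/Ks estimation (Nei-Gojobori 1986 with equal-weight pathway averaging),
# codon-aware alignment, collinear-block chaining, duplicate-type
# classification (tandem / proximal / dispersed / WGD) and Ks-scale dating.

# fraction of one-step changes at each codon position that are synonymous;
# changes to stop codons count as nonsynonymous
codon_site_fractions <- function(codon) {
  aa <- GENETIC_CODE_STD[[codon]]
  vapply(1:3, function(k) {
    alt <- setdiff(DNA_BASES, substr(codon, k, k))
    syn <- 0L
    for (b in alt) {
      mut <- codon
      substr(mut, k, k) <- b
      if (GENETIC_CODE_STD[[mut]] == aa) syn <- syn + 1L
    }
    syn / 3
  }, numeric(1))
}

.ng_env <- new.env(parent = emptyenv())

site_fraction_table <- function() {
  if (is.null(.ng_env$tab)) {
    tab <- t(vapply(SENSE_CODONS, codon_site_fractions, numeric(3)))
    .ng_env$tab <- tab
  }
  .ng_env$tab
}

# all orderings of substitution positions between two codons; each pathway is
# scored as (synonymous steps, nonsynonymous steps); pathways through stop
# codons are dropped (all pathways kept if every one is blocked)
codon_pair_differences <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(pos) else if (nd == 2L) {
    list(pos, rev(pos))
  } else {
    list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
         pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  }
  score_path <- function(order_pos) {
    cur <- ca
    sd <- 0; ndn <- 0
    for (p in order_pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (GENETIC_CODE_STD[[nxt]] == "*") return(NULL)
      if (GENETIC_CODE_STD[[nxt]] == GENETIC_CODE_STD[[cur]]) sd <- sd + 1
      else ndn <- ndn + 1
      cur <- nxt
    }
    c(sd, ndn)
  }
  res <- lapply(perms, score_path)
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) {
    # every pathway passes a stop; fall back to scoring through them
    res <- lapply(perms, function(order_pos) {
      cur <- ca; sd <- 0; ndn <- 0
      for (p in order_pos) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        aa1 <- GENETIC_CODE_STD[[cur]]; aa2 <- GENETIC_CODE_STD[[nxt]]
        if (aa1 == aa2) sd <- sd + 1 else ndn <- ndn + 1
        cur <- nxt
      }
      c(sd, ndn)
    })
    ok <- rep(TRUE, length(res))
  }
  mat <- do.call(rbind, res[ok])
  c(sd = mean(mat[, 1]), nd = mean(mat[, 2]))
}

#' Nei-Gojobori (1986) Ka/Ks for aligned codon pairs
#'
#' Synonymous and nonsynonymous site counts are averaged over both sequences
#' (each codon position contributes its fraction of synonymous one-step
#' changes); multi-substitution codons are averaged over all minimal
#' mutational pathways with equal weights, skipping pathways through stop
#' codons; the proportions pS = Sd/S and pN = Nd/N receive the Jukes-Cantor
#' correction d = -(3/4) ln(1 - 4p/3). pS >= 3/4 marks Ks saturated.
#'
#' @param pairs data.frame (or 2-column matrix) of aligned codons, columns
#'   `a` and `b`; codons containing N or gaps are skipped.
#' @return list with `Ka`, `Ks`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `saturated` (logical), `method = "NG86"`.
#' @export
ng86_kaks <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("a", "b")
  if (!nrow(pairs)) stop("need at least one codon pair")
  ok <- pairs$a %in% SENSE_CODONS & pairs$b %in% SENSE_CODONS
  pairs <- pairs[ok, , drop = FALSE]
  if (!nrow(pairs)) stop("no scorable codon pairs (stops / ambiguity only)")
  tab <- site_fraction_table()
  sA <- rowSums(tab[pairs$a, , drop = FALSE])
  sB <- rowSums(tab[pairs$b, , drop = FALSE])
  S <- sum((sA + sB) / 2)
  N <- 3 * nrow(pairs) - S
  diffs <- mapply(codon_pair_differences, pairs$a, pairs$b)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  if (S <= 0) warning("zero synonymous sites; Ks undefined")
  list(Ka = jc69(pN), Ks = jc69(pS), S = S, N = N, Sd = Sd, Nd = Nd,
       pS = pS, pN = pN,
       saturated = is.na(jc69(pS)) && !is.na(pS), method = "NG86")
}

#' Codon-aware alignment of two coding sequences
#'
#' Globally aligns the two translations (BLOSUM62, affine gaps) and maps each
#' aligned residue pair back to its codon pair; gap columns are dropped.
#'
#' @param cdsA,cdsB coding sequences (length divisible by 3).
#' @param protA,protB optional pre-aligned (gapped) protein strings; when
#'   given they must be the translations of the CDSs.
#' @return data.frame with columns `a`, `b` of paired codons.
#' @export
codon_align <- function(cdsA, cdsB, protA = NULL, protB = NULL) {
  ta <- as.character(translate_cds(cdsA))
  tb <- as.character(translate_cds(cdsB))
  if (is.null(protA) || is.null(protB)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(ta), Biostrings::AAString(tb),
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      type = "global")
    protA <- as.character(Biostrings::alignedPattern(al))
    protB <- as.character(Biostrings::alignedSubject(al))
  }
  ca <- split_codons(cdsA); cb <- split_codons(cdsB)
  pa <- strsplit(protA, "", fixed = TRUE)[[1]]
  pb <- strsplit(protB, "", fixed = TRUE)[[1]]
  ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
  keep <- pa != "-" & pb != "-"
  # verify the alignment really is over the translations
  chk_a <- pa[keep]; chk_b <- pb[keep]
  aa_a <- GENETIC_CODE_STD[ca[ia[keep]]]; aa_a[is.na(aa_a)] <- "X"
  aa_b <- GENETIC_CODE_STD[cb[ib[keep]]]; aa_b[is.na(aa_b)] <- "X"
  bad <- which(chk_a != aa_a | chk_b != aa_b)
  if (length(bad)) {
    stop("protein alignment does not match CDS translation at aligned column ",
         bad[1])
  }
  data.frame(a = ca[ia[keep]], b = cb[ib[keep]], stringsAsFactors = FALSE)
}

#' Ks/Ka between two genes of a genome
#'
#' Convenience wrapper: spliced CDSs, codon-aware alignment, NG86.
#'
#' @param genome an [annotated_genome()].
#' @param gene_a,gene_b gene ids.
#' @return as [ng86_kaks()].
#' @export
gene_pair_ks <- function(genome, gene_a, gene_b) {
  ng86_kaks(codon_align(spliced_cds(genome, gene_a),
                        spliced_cds(genome, gene_b)))
}

#' Chain anchors into collinear blocks
#'
#' Dynamic-programming chaining of homologous gene pairs (anchors) per
#' chromosome pair, in both orientations: chains with at least `match_size`
#' anchors and inter-anchor rank gaps of at most `max_gap` on both axes are
#' reported as collinear blocks (the duplication signal used for WGD
#' labelling). Chains are extracted greedily by decreasing length.
#'
#' @param anchors data.frame with columns `gene_a`, `gene_b`, `chrom_a`,
#'   `rank_a`, `chrom_b`, `rank_b`.
#' @param match_size,max_gap chaining parameters.
#' @return data.frame `block_id`, `gene_a`, `gene_b`, `orientation`.
#' @export
collinear_blocks <- function(anchors, match_size = 5L, max_gap = 25L) {
  empty <- data.frame(block_id = character(0), gene_a = character(0),
                      gene_b = character(0), orientation = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(anchors) || !nrow(anchors)) return(empty)
  out <- NULL; bid <- 0L
  key <- paste(anchors$chrom_a, anchors$chrom_b)
  best_chain <- function(sub, orient) {
    n <- nrow(sub)
    len <- rep(1L, n); prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        da <- sub$rank_a[i] - sub$rank_a[j]
        db <- if (orient == "sense") sub$rank_b[i] - sub$rank_b[j] else
          sub$rank_b[j] - sub$rank_b[i]
        if (da >= 1L && db >= 1L && da <= max_gap + 1L &&
            db <= max_gap + 1L && len[j] + 1L > len[i]) {
          len[i] <- len[j] + 1L; prev[i] <- j
        }
      }
    }
    top <- which.max(len)
    chain <- integer(0); at <- top
    while (!is.na(at)) { chain <- c(at, chain); at <- prev[at] }
    list(len = len[top], chain = chain)
  }
  for (kk in unique(key)) {
    sub <- anchors[key == kk, , drop = FALSE]
    # extract the globally longest chain first (either orientation), then
    # repeat on what remains
    repeat {
      if (nrow(sub) < match_size) break
      sub <- sub[order(sub$rank_a, sub$rank_b), , drop = FALSE]
      cs <- best_chain(sub, "sense")
      ca <- best_chain(sub, "antisense")
      pick <- if (cs$len >= ca$len) cs else ca
      orient <- if (cs$len >= ca$len) "sense" else "antisense"
      if (pick$len < match_size) break
      bid <- bid + 1L
      out <- rbind(out, data.frame(
        block_id = sprintf("BLK%03d", bid),
        gene_a = sub$gene_a[pick$chain], gene_b = sub$gene_b[pick$chain],
        orientation = orient, stringsAsFactors = FALSE))
      sub <- sub[-pick$chain, , drop = FALSE]
    }
  }
  if (is.null(out)) empty else out
}

#' Classify duplicated genes
#'
#' For each orthogroup-internal gene pair on one chromosome: rank distance
#' 1-2 makes both genes tandem (adjacent or separated by one gene), 3-20
#' proximal (separated by 2-19 genes); pairs inside a collinear block are
#' WGD; remaining genes of multi-member orthogroups are dispersed; genes in
#' singleton orthogroups are singletons. Per-gene labels follow the
#' precedence wgd > tandem > proximal > dispersed.
#'
#' @param orthogroups data.frame `orthogroup`, `gene_id` from
#'   [cluster_orthogroups()].
#' @param gene_table data.frame `gene_id`, `chrom`, `rank` (e.g.
#'   `genome$genes`).
#' @param blocks output of [collinear_blocks()] (may be empty/NULL).
#' @return data.frame `gene_id`, `label`.
#' @export
classify_duplicates <- function(orthogroups, gene_table, blocks = NULL) {
  lvl <- c(singleton = 0L, dispersed = 1L, proximal = 2L, tandem = 3L, wgd = 4L)
  lab <- stats::setNames(rep("singleton", nrow(gene_table)), gene_table$gene_id)
  chrom <- stats::setNames(gene_table$chrom, gene_table$gene_id)
  rank <- stats::setNames(gene_table$rank, gene_table$gene_id)
  blk_key <- if (!is.null(blocks) && nrow(blocks)) {
    paste(pmin(blocks$gene_a, blocks$gene_b), pmax(blocks$gene_a, blocks$gene_b))
  } else character(0)
  raise <- function(g, to) {
    if (lvl[[to]] > lvl[[lab[[g]]]]) lab[g] <<- to
  }
  for (og in split(orthogroups$gene_id, orthogroups$orthogroup)) {
    if (length(og) < 2L) next
    for (g in og) raise(g, "dispersed")
    cmb <- utils::combn(sort(og), 2L)
    for (c1 in seq_len(ncol(cmb))) {
      a <- cmb[1L, c1]; b <- cmb[2L, c1]
      if (!is.na(chrom[a]) && !is.na(chrom[b]) && chrom[a] == chrom[b]) {
        d <- abs(rank[a] - rank[b])
        if (d >= 1L && d <= 2L) { raise(a, "tandem"); raise(b, "tandem") }
        else if (d >= 3L && d <= 20L) { raise(a, "proximal"); raise(b, "proximal") }
      }
      if (paste(a, b) %in% blk_key) { raise(a, "wgd"); raise(b, "wgd") }
    }
  }
  data.frame(gene_id = names(lab), label = unname(lab),
             stringsAsFactors = FALSE)
}

#' Convert a Ks value to divergence time
#'
#' T = Ks / (2 mu) years; saturated (NA) Ks gives no estimate.
#'
#' @param ks Ks value(s), on the JC69-corrected scale.
#' @param mu substitution rate per site per year.
#' @return time(s) in years.
#' @export
ks_to_time <- function(ks, mu = 9.1e-9) {
  stopifnot(mu > 0)
  ifelse(is.na(ks) | ks < 0, NA_real_, ks / (2 * mu))
}

#' Modes of a Ks distribution
#'
#' Gaussian kernel density over [0, 3]; local maxima are candidate WGD
#' peaks, ranked by height. A mode counts as `stable` when its prominence
#' ratio (peak height over the higher of its two flanking density minima)
#' exceeds what featureless data produce: the threshold is the `conf`
#' quantile of the maximum prominence ratio over `null_draws` uniform
#' resamples of the same size, so the ripples of a flat Ks distribution are
#' not flagged. A small absolute height floor screens out numerically empty
#' tail wiggles. The default bandwidth is data-driven (Silverman's rule).
#'
#' @param ks numeric vector of finite Ks values (>= 30 required).
#' @param bandwidth kernel bandwidth; NULL for Silverman's rule-of-thumb.
#' @param null_draws,conf null-calibration resamples and quantile.
#' @param min_height_frac floor on peak height, as a fraction of the
#'   density maximum.
#' @return data.frame `mode`, `height`, `ratio`, `stable`, ordered by height.
#' @export
ks_modes <- function(ks, bandwidth = NULL, null_draws = 50L, conf = 0.95,
                     min_height_frac = 0.05) {
  ks <- ks[is.finite(ks)]
  if (length(ks) < 30L) {
    stop("need at least 30 finite Ks values; provide a larger input")
  }
  peak_table <- function(v, bw) {
    d <- stats::density(v, bw = bw, from = 0, to = 3, n = 1024L)
    y <- d$y
    ddy <- diff(sign(diff(y)))
    peaks <- which(ddy == -2L) + 1L
    valleys <- c(1L, which(ddy == 2L) + 1L, length(y))
    if (!length(peaks)) {
      return(data.frame(mode = numeric(0), height = numeric(0),
                        ratio = numeric(0)))
    }
    ratio <- vapply(peaks, function(p) {
      lo <- max(valleys[valleys < p]); hi <- min(valleys[valleys > p])
      y[p] / max(max(y[lo], y[hi]), .Machine$double.xmin)
    }, numeric(1))
    data.frame(mode = d$x[peaks], height = y[peaks], ratio = ratio)
  }
  obs <- peak_table(ks, bandwidth %||% stats::bw.nrd0(ks))
  if (!nrow(obs)) return(cbind(obs, stable = logical(0)))
  # null calibration on featureless samples of the same size (fixed internal
  # seed; the caller's RNG stream is untouched)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(20260901L)
  null_max <- replicate(null_draws, {
    u <- stats::runif(length(ks), 0, 3)
    pt <- peak_table(u, stats::bw.nrd0(u))
    keep <- pt$height >= min_height_frac * max(pt$height, 0)
    if (any(keep)) max(pt$ratio[keep]) else 1
  })
  thr <- stats::quantile(null_max, conf, names = FALSE)
  obs$stable <- obs$ratio > thr & obs$height >= min_height_frac * max(obs$height)
  obs[order(-obs$height), ]
}
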