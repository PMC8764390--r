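# Intact LTR retrotransposon detection (simplified structural scan),
# LTR-flanked gene flagging, insertion-age dating from terminal-repeat
# divergence, and RT-domain family clustering.

# running mean over window w (centered-ish, truncated at the ends)
running_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - w)
  hi <- pmin(n, seq_len(n) + w)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# seed-pair clusters: duplicated k-mers whose two occurrences are a distance
# apart compatible with an intact element. Candidates with identical offset
# are merged into one extension job.
seed_clusters <- function(seq, k, min_delta, max_delta, max_occ = 6L) {
  n <- nchar(seq)
  if (n < k + min_delta) return(NULL)
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  dup <- duplicated(kmers) | duplicated(kmers, fromLast = TRUE)
  idx <- which(dup)
  if (!length(idx)) return(NULL)
  grp <- split(idx, kmers[idx])
  grp <- grp[lengths(grp) <= max_occ]
  p1 <- integer(0); p2 <- integer(0)
  for (g in grp) {
    cmb <- utils::combn(g, 2L)
    d <- cmb[2L, ] - cmb[1L, ]
    ok <- d >= min_delta & d <= max_delta
    p1 <- c(p1, cmb[1L, ok]); p2 <- c(p2, cmb[2L, ok])
  }
  if (!length(p1)) return(NULL)
  delta <- p2 - p1
  df <- data.frame(p1 = p1, delta = delta)
  df <- df[order(df$delta, df$p1), ]
  # one job per (delta, position window); the median seed sits safely inside
  # the repeat, away from its edges
  job <- cumsum(c(TRUE, diff(df$delta) != 0L | diff(df$p1) > 2000L))
  stats::aggregate(df["p1"], list(job = job, delta = df$delta),
                   function(v) as.integer(stats::median(v)))
}

#' Detect intact LTR retrotransposons
#'
#' Simplified structural scan: exact k-mer seed matching finds direct-repeat
#' candidates; extension along the repeat diagonal (substitution-only, no
#' indel model) delimits the repeat; boundaries are refined so the 5' copy
#' starts `TG`, the 3' copy ends `CA`, and a 4-6 bp exact target-site
#' duplication flanks the element. Overlapping candidates keep the
#' higher-identity, then longer, then leftmost element. The LTR divergence K
#' is the JC69-corrected p-distance over ungapped columns of a global
#' alignment of the two repeats.
#'
#' @param genome an [annotated_genome()] (or a named character vector of
#'   chromosome sequences).
#' @param min_ltr,max_ltr LTR length bounds (bp).
#' @param min_elem,max_elem element length bounds (bp).
#' @param min_identity minimum percent identity between the two LTRs.
#' @param tsd allowed target-site-duplication lengths.
#' @param k seed k-mer length.
#' @return data.frame with one row per element: `element_id`, `chrom`,
#'   `start`, `end`, `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end`,
#'   `motif`, `tsd_len`, `identity_pct`, `K`.
#' @export
detect_intact_ltrs <- function(genome, min_ltr = 100L, max_ltr = 3500L,
                               min_elem = 1000L, max_elem = 15000L,
                               min_identity = 90, tsd = c(4L, 6L), k = 20L) {
  seqs <- if (inherits(genome, "annotated_genome")) genome$seq else genome
  min_delta <- max(min_ltr, min_elem - max_ltr)
  max_delta <- max_elem - min_ltr
  out <- NULL
  for (ch in names(seqs)) {
    s <- seqs[[ch]]
    n <- nchar(s)
    jobs <- seed_clusters(s, k, min_delta, max_delta)
    if (is.null(jobs) || !nrow(jobs)) next
    x <- strsplit(s, "", fixed = TRUE)[[1]]
    for (ji in seq_len(nrow(jobs))) {
      delta <- jobs$delta[ji]; seed <- jobs$p1[ji]
      lo <- max(1L, seed - max_ltr)
      hi <- min(n - delta, seed + max_ltr)
      if (hi <= lo) next
      rng <- lo:hi
      m <- x[rng] == x[rng + delta]
      sm <- running_mean(as.numeric(m), 15L)
      inside <- sm >= 0.72
      r <- rle(inside)
      ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1L) + 1L)
      si <- seed - lo + 1L
      runi <- which(r$values & starts <= si & ends >= si)
      if (!length(runi)) next
      a0 <- rng[starts[runi]]; b0 <- rng[ends[runi]]
      # refine ends: 5' copy must start TG, 3' copy must end CA, exact TSD
      acand <- (max(2L + max(tsd), a0 - 15L)):(min(a0 + 15L, b0))
      acand <- acand[x[acand] == "T" & x[acand + 1L] == "G"]
      bcand <- (max(b0 - 15L, a0)):(min(b0 + 15L, n - delta - max(tsd)))
      bcand <- bcand[x[bcand + delta] == "A" & x[bcand + delta - 1L] == "C"]
      best <- NULL
      for (a in acand) for (b in bcand) {
        lam <- b - a + 1L
        if (lam < min_ltr || lam > max_ltr) next
        elen <- b + delta - a + 1L
        if (elen < min_elem || elen > max_elem) next
        ident <- 100 * mean(x[a:b] == x[(a:b) + delta])
        if (ident < min_identity) next
        tlen <- 0L
        for (t in rev(seq(tsd[1], tsd[2]))) {
          if (a - t < 1L || b + delta + t > n) next
          if (all(x[(a - t):(a - 1L)] == x[(b + delta + 1L):(b + delta + t)])) {
            tlen <- t; break
          }
        }
        if (tlen == 0L) next
        cand <- list(a = a, b = b, ident = ident, lam = lam, tsd = tlen)
        if (is.null(best) || cand$ident > best$ident ||
            (cand$ident == best$ident && cand$lam > best$lam) ||
            (cand$ident == best$ident && cand$lam == best$lam && cand$a < best$a)) {
          best <- cand
        }
      }
      if (is.null(best)) next
      ltr5 <- paste(x[best$a:best$b], collapse = "")
      ltr3 <- paste(x[(best$a:best$b) + delta], collapse = "")
      gi <- global_nuc_identity(ltr5, ltr3)
      out <- rbind(out, data.frame(
        chrom = ch, start = best$a, end = best$b + delta,
        ltr5_start = best$a, ltr5_end = best$b,
        ltr3_start = best$a + delta, ltr3_end = best$b + delta,
        motif = "TGCA", tsd_len = best$tsd,
        identity_pct = best$ident,
        K = jc69(gi$p), stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    return(data.frame(element_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      ltr5_start = integer(0), ltr5_end = integer(0),
                      ltr3_start = integer(0), ltr3_end = integer(0),
                      motif = character(0), tsd_len = integer(0),
                      identity_pct = numeric(0), K = numeric(0),
                      stringsAsFactors = FALSE))
  }
  # overlap resolution: higher identity, then longer, then leftmost
  out <- out[order(out$chrom, -out$identity_pct, -(out$end - out$start),
                   out$start), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(out)) > i & out$chrom == out$chrom[i] &
                 out$start <= out$end[i] & out$end >= out$start[i])
    keep[j] <- FALSE
  }
  out <- out[keep, ]
  out <- out[order(out$chrom, out$start), ]
  out$element_id <- sprintf("%s_%d_%d", out$chrom, out$start, out$end)
  rownames(out) <- NULL
  out[, c("element_id", "chrom", "start", "end", "ltr5_start", "ltr5_end",
          "ltr3_start", "ltr3_end", "motif", "tsd_len", "identity_pct", "K")]
}

#' Annotate RT domains inside detected elements
#'
#' Aligns each bundled RT exemplar against every element's internal region
#' (nucleotide local alignment) and records the best hit of at least
#' `min_len` aligned bases and `min_identity` percent identity.
#'
#' @param genome an [annotated_genome()].
#' @param elements output of [detect_intact_ltrs()].
#' @param min_len,min_identity hit thresholds.
#' @return `elements` with added columns `rt_start`, `rt_end`, `rt_exemplar`,
#'   `clade`, `superfamily` (NA where no cassette was found).
#' @export
annotate_rt_domains <- function(genome, elements, min_len = 200L,
                                min_identity = 60) {
  ex <- rt_exemplars()
  elements$rt_start <- NA_integer_; elements$rt_end <- NA_integer_
  elements$rt_exemplar <- NA_character_
  elements$clade <- NA_character_; elements$superfamily <- NA_character_
  for (i in seq_len(nrow(elements))) {
    internal <- genome_substr(genome, elements$chrom[i],
                              elements$ltr5_end[i] + 1L,
                              elements$ltr3_start[i] - 1L)
    best <- NULL
    for (id in names(ex$seq)) {
      aln <- local_align(ex$seq[[id]], internal, mode = "nucleotide")
      if (aln$aligned_length >= min_len && aln$identity_pct >= min_identity &&
          (is.null(best) || aln$score > best$score)) {
        best <- aln; best$id <- id
      }
    }
    if (!is.null(best)) {
      elements$rt_start[i] <- elements$ltr5_end[i] + best$subject_span[1]
      elements$rt_end[i] <- elements$ltr5_end[i] + best$subject_span[2]
      elements$rt_exemplar[i] <- best$id
      mi <- match(best$id, ex$meta$id)
      elements$clade[i] <- ex$meta$clade[mi]
      elements$superfamily[i] <- ex$meta$superfamily[mi]
    }
  }
  elements
}

#' LTR insertion age from terminal-repeat divergence
#'
#' T = K / (2 mu), with K the JC69-corrected divergence between the two
#' terminal repeats and mu the substitution rate per site per year. Elements
#' with saturated divergence (p >= 3/4, K undefined) are flagged and get no
#' age.
#'
#' @param elements data.frame with columns `element_id` and `K`.
#' @param mu substitution rate per site per year (default 9.1e-9; use 7e-9
#'   for Arabidopsis-like inputs).
#' @return data.frame `element_id`, `K`, `mu`, `T_years`, `T_mya`,
#'   `saturated`.
#' @export
ltr_age <- function(elements, mu = 9.1e-9) {
  stopifnot(mu > 0)
  K <- elements$K
  sat <- is.na(K)
  T_years <- ifelse(sat, NA_real_, K / (2 * mu))
  data.frame(element_id = elements$element_id, K = K, mu = mu,
             T_years = T_years, T_mya = T_years / 1e6, saturated = sat,
             stringsAsFactors = FALSE)
}

#' Flag genes associated with LTR retrotransposons
#'
#' A gene is flagged `contained` when its locus is fully inside an LTR-RT
#' interval (detected elements and/or a repeat annotation), and `flank_pair`
#' when an intact-element scan restricted to the gene +/- `flank` window
#' yields an element whose two terminal repeats bracket the gene. Containment
#' takes precedence.
#'
#' @param genome an [annotated_genome()].
#' @param elements detected elements (may be NULL).
#' @param repeat_annotation optional data.frame `chrom`, `start`, `end` of
#'   LTR-RT repeat intervals (RepeatMasker-style evidence).
#' @param flank scan window half-width (bp).
#' @param scan_windows run the windowed detector for the flank evidence; when
#'   FALSE only the provided `elements` are used for bracketing.
#' @return data.frame `gene_id`, `evidence` (`contained` or `flank_pair`).
#' @export
flag_ltr_genes <- function(genome, elements = NULL, repeat_annotation = NULL,
                           flank = 8000L, scan_windows = TRUE) {
  g <- genome$genes
  res <- NULL
  spans <- NULL
  if (!is.null(elements) && nrow(elements)) {
    spans <- elements[, c("chrom", "start", "end")]
  }
  if (!is.null(repeat_annotation) && nrow(repeat_annotation)) {
    spans <- rbind(spans, repeat_annotation[, c("chrom", "start", "end")])
  }
  for (i in seq_len(nrow(g))) {
    ev <- NA_character_
    if (!is.null(spans)) {
      hit <- spans$chrom == g$chrom[i] & spans$start <= g$start[i] &
        spans$end >= g$end[i]
      if (any(hit)) ev <- "contained"
    }
    if (is.na(ev)) {
      bracket <- function(el, off) {
        any(el$ltr5_end + off < g$start[i] & el$ltr3_start + off > g$end[i] &
              el$chrom == g$chrom[i])
      }
      if (!is.null(elements) && nrow(elements) && bracket(elements, 0L)) {
        ev <- "flank_pair"
      } else if (scan_windows) {
        lo <- max(1L, g$start[i] - flank)
        hi <- min(nchar(genome$seq[[g$chrom[i]]]), g$end[i] + flank)
        win <- stats::setNames(substr(genome$seq[[g$chrom[i]]], lo, hi),
                               g$chrom[i])
        el <- detect_intact_ltrs(win)
        if (nrow(el) && bracket(el, lo - 1L)) ev <- "flank_pair"
      }
    }
    if (!is.na(ev)) {
      res <- rbind(res, data.frame(gene_id = g$gene_id[i], evidence = ev,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(res)) {
    res <- data.frame(gene_id = character(0), evidence = character(0),
                      stringsAsFactors = FALSE)
  }
  res
}

#' Cluster RT domains into LTR-RT families
#'
#' Pairwise global nucleotide identity between RT-domain sequences, computed
#' over alignments covering at least `min_cov` of the shorter sequence and
#' `min_len` bases; single-linkage clusters at `min_identity` percent are
#' families. Each family is named `{chrom}_{start}_{end}_FAM{k}` after its
#' leftmost member. Elements lacking an RT domain are excluded and counted
#' in the `n_without_rt` attribute.
#'
#' @param genome an [annotated_genome()].
#' @param elements elements annotated by [annotate_rt_domains()].
#' @param min_identity,min_len,min_cov clustering thresholds.
#' @return data.frame `element_id`, `family`, `clade`, `superfamily`,
#'   with attribute `n_without_rt`.
#' @export
cluster_rt_families <- function(genome, elements, min_identity = 80,
                                min_len = 200L, min_cov = 0.8) {
  has_rt <- !is.na(elements$rt_start)
  excl <- sum(!has_rt)
  el <- elements[has_rt, , drop = FALSE]
  n <- nrow(el)
  if (!n) {
    out <- data.frame(element_id = character(0), family = character(0),
                      clade = character(0), superfamily = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_without_rt") <- excl
    return(out)
  }
  seqs <- vapply(seq_len(n), function(i)
    genome_substr(genome, el$chrom[i], el$rt_start[i], el$rt_end[i]),
    character(1))
  uf <- uf_new(el$element_id)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      shorter <- min(nchar(seqs[i]), nchar(seqs[j]))
      gi <- global_nuc_identity(seqs[i], seqs[j])
      if (gi$ungapped_columns >= max(min_len, min_cov * shorter) &&
          gi$identity_pct >= min_identity) {
        uf_union(uf, el$element_id[i], el$element_id[j])
      }
    }
  }
  root <- vapply(el$element_id, function(x) uf_find(uf, x), character(1))
  fam_of <- split(seq_len(n), root)
  # leftmost member (lowest chrom id, then lowest start) names the family
  fam_names <- character(length(fam_of))
  ord <- order(vapply(fam_of, function(ix)
    min(paste0(el$chrom[ix], sprintf("_%09d", el$start[ix])))[1], character(1)))
  fam_of <- fam_of[ord]
  out <- NULL
  for (kk in seq_along(fam_of)) {
    ix <- fam_of[[kk]]
    lead <- ix[order(el$chrom[ix], el$start[ix])][1]
    nm <- sprintf("%s_%d_%d_FAM%d", el$chrom[lead], el$start[lead],
                  el$end[lead], kk)
    out <- rbind(out, data.frame(
      element_id = el$element_id[ix], family = nm,
      clade = el$clade[ix], superfamily = el$superfamily[ix],
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  attr(out, "n_without_rt") <- excl
  out
}
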