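# All-vs-all protein comparison with the standard paralog-detection filters
# (e-value, alignment length, c-score), reciprocal best hits, orthogroup
# clustering, and the TE-like gene filter.

# shared-kmer prefilter: candidate pairs must share at least one exact k-mer.
# Unrelated random proteins essentially never do; pairs down to ~40% identity
# almost always do, and anything weaker cannot pass the downstream filters.
kmer_candidate_pairs <- function(proteins, k = 5L) {
  n <- length(proteins)
  ids <- names(proteins)
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    s <- proteins[[i]]
    if (nchar(s) < k) next
    km <- unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
    for (x in km) assign(x, c(idx[[x]], i), envir = idx)
  }
  pairs <- new.env(parent = emptyenv())
  for (x in ls(idx)) {
    v <- idx[[x]]
    if (length(v) < 2L || length(v) > 50L) next
    for (a in seq_len(length(v) - 1L)) {
      for (b in (a + 1L):length(v)) {
        key <- paste0(v[a], "_", v[b])
        assign(key, TRUE, envir = pairs)
      }
    }
  }
  keys <- ls(pairs)
  if (!length(keys)) return(matrix(integer(0), ncol = 2L))
  m <- do.call(rbind, strsplit(keys, "_", fixed = TRUE))
  matrix(as.integer(m), ncol = 2L)
}

#' All-vs-all protein comparison
#'
#' Smith-Waterman alignment of every candidate protein pair, reported in the
#' standard 12-column tabular-hit layout and filtered by the three paralog
#' screens: e-value at most `evalue_max`, alignment length strictly greater
#' than `min_len` residues, and c-score (a hit's bit score divided by its
#' query's best non-self bit score) at least `min_cscore`. Self-hits are
#' excluded; both orientations of each pair are reported.
#'
#' @param proteins named character vector of protein sequences (>= 2).
#' @param evalue_max,min_len,min_cscore filter thresholds. `min_len` is read
#'   strictly ("longer than"), so a hit is kept only when its alignment
#'   length is `>= min_len + 1`.
#' @param prefilter share-a-kmer prescreen before aligning (recommended).
#' @return data.frame with columns `query`, `subject`, `identity_pct`,
#'   `aligned_length`, `mismatches`, `gap_opens`, `qstart`, `qend`, `sstart`,
#'   `send`, `e_value`, `bit_score`, `c_score`.
#' @export
all_vs_all <- function(proteins, evalue_max = 1e-7, min_len = 100L,
                       min_cscore = 0.3, prefilter = TRUE) {
  if (length(proteins) < 2L) stop("need at least 2 proteins")
  ids <- names(proteins)
  cand <- if (prefilter) kmer_candidate_pairs(proteins) else
    t(utils::combn(length(proteins), 2L))
  if (!nrow(cand)) {
    return(empty_hits())
  }
  rows <- vector("list", nrow(cand))
  # batch by subject for vectorized alignment
  bys <- split(seq_len(nrow(cand)), cand[, 2L])
  out <- list()
  for (j_chr in names(bys)) {
    j <- as.integer(j_chr)
    ii <- cand[bys[[j_chr]], 1L]
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(proteins[ii]),
      Biostrings::AAString(proteins[[j]]),
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      type = "local")
    raw <- Biostrings::score(al)
    alen <- Biostrings::nchar(al)
    nm <- Biostrings::nmatch(al)
    nmm <- Biostrings::nmismatch(al)
    ni <- Biostrings::nindel(al)
    gaps <- Biostrings::insertion(ni)[, "Length"] +
      Biostrings::deletion(ni)[, "Length"]
    bs <- bit_score(raw, "protein")
    ev <- nchar(proteins[ii]) * nchar(proteins[[j]]) * 2^(-bs)
    out[[j_chr]] <- data.frame(
      query = ids[ii], subject = ids[j],
      identity_pct = ifelse(alen > 0, 100 * nm / alen, 0),
      aligned_length = alen,
      mismatches = nmm, gap_opens = gaps,
      qstart = Biostrings::start(Biostrings::pattern(al)),
      qend = Biostrings::end(Biostrings::pattern(al)),
      sstart = Biostrings::start(Biostrings::subject(al)),
      send = Biostrings::end(Biostrings::subject(al)),
      e_value = ev, bit_score = bs, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  # symmetrize: SW scoring is symmetric, so mirror each record
  mirror <- hits
  mirror$query <- hits$subject; mirror$subject <- hits$query
  mirror$qstart <- hits$sstart; mirror$qend <- hits$send
  mirror$sstart <- hits$qstart; mirror$send <- hits$qend
  hits <- rbind(hits, mirror)
  hits <- hits[hits$query != hits$subject, ]
  hits <- hits[hits$e_value <= evalue_max & hits$aligned_length >= min_len + 1L, ]
  if (!nrow(hits)) return(empty_hits())
  best <- tapply(hits$bit_score, hits$query, max)
  hits$c_score <- hits$bit_score / as.numeric(best[hits$query])
  hits <- hits[hits$c_score >= min_cscore, ]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(query = character(0), subject = character(0),
             identity_pct = numeric(0), aligned_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             qstart = integer(0), qend = integer(0), sstart = integer(0),
             send = integer(0), e_value = numeric(0), bit_score = numeric(0),
             c_score = numeric(0), stringsAsFactors = FALSE)
}

#' Reciprocal best hits
#'
#' A pair (a, b) is retained iff b is a's best subject and a is b's best
#' subject. Ties are broken by higher bit score, then lower e-value, then
#' lexicographic subject id, making the result deterministic.
#'
#' @param hits filtered hit table from [all_vs_all()].
#' @return data.frame with canonically ordered columns `gene_a < gene_b` and
#'   the supporting `bit_score`.
#' @export
reciprocal_best_hits <- function(hits) {
  if (!nrow(hits)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      bit_score = numeric(0), stringsAsFactors = FALSE))
  }
  h <- hits[order(hits$query, -hits$bit_score, hits$e_value, hits$subject), ]
  best <- h[!duplicated(h$query), c("query", "subject", "bit_score")]
  bmap <- stats::setNames(best$subject, best$query)
  mutual <- best[!is.na(bmap[best$subject]) & bmap[best$subject] == best$query, ]
  if (!nrow(mutual)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      bit_score = numeric(0), stringsAsFactors = FALSE))
  }
  a <- pmin(mutual$query, mutual$subject)
  b <- pmax(mutual$query, mutual$subject)
  out <- data.frame(gene_a = a, gene_b = b, bit_score = mutual$bit_score,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$gene_a, out$gene_b)), ]
  out <- out[order(out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  out
}

# union-find
uf_new <- function(ids) {
  e <- new.env(parent = emptyenv())
  e$parent <- stats::setNames(ids, ids)
  e
}
uf_find <- function(uf, x) {
  while (uf$parent[[x]] != x) {
    uf$parent[[x]] <- uf$parent[[uf$parent[[x]]]]
    x <- uf$parent[[x]]
  }
  x
}
uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a); rb <- uf_find(uf, b)
  if (ra != rb) uf$parent[[max(ra, rb)]] <- min(ra, rb)
  invisible(uf)
}

#' Cluster genes into orthogroups
#'
#' Connected components of the undirected graph whose edges are homologous
#' gene pairs. By default every filtered hit contributes an edge (the
#' behaviour of similarity-graph orthogroup inference); `edges = "rbh"`
#' restricts edges to reciprocal best hits. Genes listed in `genes` but
#' absent from the graph are carried as singleton groups.
#'
#' @param hits filtered hit table from [all_vs_all()].
#' @param genes optional character vector of all gene ids to partition.
#' @param edges `"hits"` (default) or `"rbh"`.
#' @return data.frame with columns `orthogroup`, `gene_id`, `singleton`.
#' @export
cluster_orthogroups <- function(hits, genes = NULL, edges = c("hits", "rbh")) {
  edges <- match.arg(edges)
  ep <- if (edges == "rbh") {
    r <- reciprocal_best_hits(hits); data.frame(a = r$gene_a, b = r$gene_b)
  } else if (nrow(hits)) {
    data.frame(a = pmin(hits$query, hits$subject),
               b = pmax(hits$query, hits$subject))
  } else data.frame(a = character(0), b = character(0))
  ids <- sort(unique(c(ep$a, ep$b, genes)))
  if (!length(ids)) {
    return(data.frame(orthogroup = character(0), gene_id = character(0),
                      singleton = logical(0), stringsAsFactors = FALSE))
  }
  uf <- uf_new(ids)
  for (i in seq_len(nrow(ep))) uf_union(uf, ep$a[i], ep$b[i])
  root <- vapply(ids, function(x) uf_find(uf, x), character(1))
  comp <- split(ids, root)
  # deterministic numbering: by decreasing size, then by first member id
  ord <- order(-lengths(comp), vapply(comp, min, character(1)))
  comp <- comp[ord]
  out <- do.call(rbind, lapply(seq_along(comp), function(k) {
    data.frame(orthogroup = sprintf("OG%04d", k), gene_id = comp[[k]],
               singleton = length(comp[[k]]) == 1L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Remove TE-like genes (reverse-transcriptase-only domain content)
#'
#' A gene is removed iff its domain list is non-empty and every domain is in
#' the RT/transposase set; genes with no domain annotation, or with at least
#' one non-TE domain, are kept.
#'
#' @param genes character vector of gene ids.
#' @param domain_table data.frame with columns `gene_id`, `domain` (several
#'   rows per gene allowed).
#' @param te_domains domain names treated as TE evidence.
#' @return character vector of kept gene ids.
#' @export
filter_te_like <- function(genes, domain_table,
                           te_domains = c("RT", "RVT", "transposase")) {
  doms <- split(domain_table$domain, domain_table$gene_id)
  keep <- vapply(genes, function(g) {
    d <- doms[[g]]
    is.null(d) || length(d) == 0L || !all(d %in% te_domains)
  }, logical(1))
  genes[keep]
}
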