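# Pairwise alignment plumbing. Smith-Waterman / Needleman-Wunsch with affine
# gaps are delegated to Biostrings::pairwiseAlignment; this file fixes the
# scoring schemes and the bit-score / e-value statistics used everywhere else.

# BLAST-style scoring constants. Raw scores are converted to bit scores with
# fixed Karlin-Altschul parameters; at desk scale the search space differs
# from a database search, so e-values are approximate by design and the
# c-score / length filters carry the discrimination.
ka_params <- list(
  protein = c(lambda = 0.267, K = 0.041),     # BLOSUM62, gap 11/1
  nucleotide = c(lambda = 0.625, K = 0.41)    # match +2 / mismatch -3, gap 5/2
)

.align_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.align_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .align_env$BLOSUM62 <- e$BLOSUM62
  }
  .align_env$BLOSUM62
}

nuc_matrix <- function() {
  if (is.null(.align_env$NUC)) {
    b <- c("A", "C", "G", "T", "N")
    m <- matrix(-3L, 5L, 5L, dimnames = list(b, b))
    diag(m) <- 2L
    m["N", ] <- -3L; m[, "N"] <- -3L  # N mismatches everything, itself included
    .align_env$NUC <- m
  }
  .align_env$NUC
}

bit_score <- function(raw, mode) {
  p <- ka_params[[mode]]
  (p[["lambda"]] * raw - log(p[["K"]])) / log(2)
}

#' Local pairwise alignment with BLAST-like statistics
#'
#' Smith-Waterman local alignment with affine gaps. Protein mode scores with
#' BLOSUM62, gap open 11 / extend 1; nucleotide mode scores match +2,
#' mismatch -3, gap open 5 / extend 2 (a gap of length L costs open + L *
#' extend). Raw scores are converted to bit scores S' = (lambda*S - ln K)/ln 2
#' with the fixed parameters in `ka_params`, and e-values as E = m*n*2^(-S')
#' with m, n the two sequence lengths.
#'
#' @param a,b sequences (character scalars), non-empty.
#' @param mode `"protein"` or `"nucleotide"`.
#' @return list with `score` (raw), `bit_score`, `e_value`, `identity_pct`
#'   (percent identical over alignment columns, gap columns included),
#'   `aligned_length` (alignment columns), `pattern_span`/`subject_span`
#'   (start/end of the aligned region in each input), and the two gapped
#'   alignment strings `pattern_aligned`, `subject_aligned`.
#' @export
local_align <- function(a, b, mode = c("protein", "nucleotide")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  al <- if (mode == "protein") {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      type = "local")
  } else {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = nuc_matrix(), gapOpening = 5, gapExtension = 2,
      type = "local")
  }
  raw <- Biostrings::score(al)
  bs <- bit_score(raw, mode)
  pa <- as.character(Biostrings::alignedPattern(al))
  sa <- as.character(Biostrings::alignedSubject(al))
  cols <- nchar(pa)
  pc <- strsplit(pa, "", fixed = TRUE)[[1]]
  sc <- strsplit(sa, "", fixed = TRUE)[[1]]
  ident <- if (cols > 0L) 100 * sum(pc == sc & pc != "-") / cols else 0
  list(
    score = raw, bit_score = bs,
    e_value = nchar(a) * nchar(b) * 2^(-bs),
    identity_pct = ident, aligned_length = cols,
    pattern_span = c(Biostrings::start(Biostrings::pattern(al)),
                     Biostrings::end(Biostrings::pattern(al))),
    subject_span = c(Biostrings::start(Biostrings::subject(al)),
                     Biostrings::end(Biostrings::subject(al))),
    pattern_aligned = pa, subject_aligned = sa
  )
}

# Global (Needleman-Wunsch) nucleotide alignment; returns the p-distance over
# ungapped columns plus column bookkeeping. Used for LTR divergence and RT
# family identity.
global_nuc_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = nuc_matrix(), gapOpening = 5, gapExtension = 2,
    type = "global")
  pc <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ungapped <- pc != "-" & sc != "-"
  n <- sum(ungapped)
  mism <- sum(pc[ungapped] != sc[ungapped])
  list(p = if (n > 0L) mism / n else NA_real_,
       identity_pct = if (n > 0L) 100 * (1 - mism / n) else NA_real_,
       ungapped_columns = n, columns = length(pc))
}

# Decompose a local alignment into segments that are contiguous up to gap
# runs of length <= max_gap in either row. Returns per-segment spans in
# pattern and subject coordinates. Segments are the unit over which exon
# junction coverage is assessed.
aligned_segments <- function(aln, max_gap = 0L) {
  pc <- strsplit(aln$pattern_aligned, "", fixed = TRUE)[[1]]
  sc <- strsplit(aln$subject_aligned, "", fixed = TRUE)[[1]]
  ncol <- length(pc)
  empty_seg <- data.frame(pstart = integer(0), pend = integer(0),
                          sstart = integer(0), send = integer(0),
                          matches = integer(0))
  if (ncol == 0L) return(empty_seg)
  gap <- pc == "-" | sc == "-"
  # positions in original coordinates per column (NA at that row's gaps)
  ppos <- cumsum(pc != "-") + aln$pattern_span[1] - 1L
  spos <- cumsum(sc != "-") + aln$subject_span[1] - 1L
  ppos[pc == "-"] <- NA_integer_
  spos[sc == "-"] <- NA_integer_
  # break before any gap run longer than max_gap
  r <- rle(gap)
  brk <- logical(ncol)
  idx <- cumsum(r$lengths)
  starts <- c(1L, utils::head(idx, -1L) + 1L)
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] > max_gap) brk[starts[k]] <- TRUE
  }
  seg_id <- cumsum(brk)
  keep <- !gap
  if (!any(keep)) return(empty_seg)
  sp <- split(which(keep), seg_id[keep])
  out <- do.call(rbind, lapply(sp, function(ix) {
    data.frame(pstart = min(ppos[ix], na.rm = TRUE),
               pend = max(ppos[ix], na.rm = TRUE),
               sstart = min(spos[ix], na.rm = TRUE),
               send = max(spos[ix], na.rm = TRUE),
               matches = sum(pc[ix] == sc[ix]))
  }))
  rownames(out) <- NULL
  out
}
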