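# Independent oracles used to cross-check the implementation. These are
# deliberately written from first principles (plain triple-matrix DP,
# explicit permutation enumeration, exhaustive chain search) and share no
# code with the package internals they check.

# affine-gap Smith-Waterman, plain Gotoh recurrences; a gap of length L
# costs open + L * ext (the convention of the package's scoring schemes)
gotoh_local <- function(a, b, smat, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    s <- smat[A[i - 1], B[j - 1]]
    M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                   Iy[i - 1, j - 1] + s)
    best <- max(best, M[i, j], Ix[i, j], Iy[i, j])
  }
  best
}

blosum62_oracle <- local({
  e <- new.env()
  function() {
    if (is.null(e$m)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      e$m <- e$BLOSUM62
    }
    e$m
  }
})

nuc_matrix_oracle <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-3L, 5, 5, dimnames = list(b, b))
  diag(m) <- 2L
  m["N", ] <- -3L; m[, "N"] <- -3L
  m
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Nei-Gojobori from first principles: per-position synonymous site
# fractions, explicit enumeration of substitution orderings with
# stop-codon-avoiding pathway filtering, Jukes-Cantor correction. Uses the
# genetic code shipped with Biostrings, not the package's table.
ng86_oracle <- function(ca, cb) {
  GC <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  sites <- function(cod) {
    f <- 0
    for (k in 1:3) {
      for (b in setdiff(bases, substr(cod, k, k))) {
        m <- cod; substr(m, k, k) <- b
        if (GC[[m]] == GC[[cod]]) f <- f + 1 / 3
      }
    }
    f
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    S <- S + (sites(ca[i]) + sites(cb[i])) / 2
    pos <- which(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
    if (!length(pos)) next
    walk <- function(p, allow_stop) {
      cur <- ca[i]; sd <- 0; nd <- 0
      for (k in p) {
        nxt <- cur; substr(nxt, k, k) <- substr(cb[i], k, k)
        if (!allow_stop && GC[[nxt]] == "*") return(NULL)
        if (GC[[nxt]] == GC[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    paths <- all_permutations(pos)
    good <- Filter(Negate(is.null), lapply(paths, walk, allow_stop = FALSE))
    if (!length(good)) good <- lapply(paths, walk, allow_stop = TRUE)
    gm <- do.call(rbind, good)
    Sd <- Sd + mean(gm[, 1]); Nd <- Nd + mean(gm[, 2])
  }
  N <- 3 * length(ca) - S
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(Ks = jc(Sd / S), Ka = jc(Nd / N), S = S, N = N, Sd = Sd, Nd = Nd)
}

# exhaustive best-chain search over anchors (one chromosome pair), both
# orientations, returning the maximum chain length satisfying the gap bound
exhaustive_best_chain <- function(rank_a, rank_b, max_gap) {
  n <- length(rank_a)
  best <- 0L
  for (orient in c(1, -1)) {
    rb <- orient * rank_b
    grow <- function(last, remaining, len) {
      best <<- max(best, len)
      for (i in remaining) {
        da <- rank_a[i] - rank_a[last]
        db <- rb[i] - rb[last]
        if (da >= 1 && db >= 1 && da <= max_gap + 1 && db <= max_gap + 1) {
          grow(i, setdiff(remaining, i), len + 1L)
        }
      }
    }
    for (s in seq_len(n)) grow(s, setdiff(seq_len(n), s), 1L)
  }
  best
}
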