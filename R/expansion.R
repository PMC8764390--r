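# Gene-family expansion testing under a linear birth-death model with equal
# birth and death rates (one global lambda), a uniform root-size prior and
# Monte-Carlo p-values: a lightweight stand-in for full gene-family-evolution
# machinery, adequate for flagging significantly expanded orthogroups (SEOs).

#' Birth-death transition probability
#'
#' Equal birth/death single-parameter model: with a = lambda*t/(1+lambda*t),
#' P(i -> j) = sum_{k=0}^{min(i,j)} C(i,k) C(i+j-k-1, i-1) a^(i+j-2k)
#' (1-2a)^k; P(0 -> 0) = 1 and P(0 -> j>0) = 0 (extinction is absorbing).
#'
#' @param i,j ancestral and descendant family sizes (i >= 0, j >= 0).
#' @param t branch length (time units of the tree).
#' @param lambda birth (= death) rate per lineage per time unit.
#' @return transition probability.
#' @export
bd_transition_prob <- function(i, j, t, lambda) {
  stopifnot(i >= 0, j >= 0, t > 0, lambda > 0)
  a <- lambda * t / (1 + lambda * t)
  if (a >= 0.5) stop("lambda*t too large: alpha >= 1/2 is out of range")
  if (i == 0) return(as.numeric(j == 0))
  k <- 0:min(i, j)
  sum(choose(i, k) * choose(i + j - k - 1, i - 1) *
        a^(i + j - 2 * k) * (1 - 2 * a)^k)
}

# (smax+1) x (smax+1) transition matrix over sizes 0..smax; rows renormalized
# so that truncated mass is folded back (needed for simulation and to keep
# pruning proper under truncation)
bd_matrix <- function(t, lambda, smax, renorm = TRUE) {
  P <- matrix(0, smax + 1L, smax + 1L)
  P[1L, 1L] <- 1
  for (i in 1:smax) {
    P[i + 1L, ] <- vapply(0:smax, function(j) bd_transition_prob(i, j, t, lambda),
                          numeric(1))
  }
  if (renorm) P <- P / rowSums(P)
  P
}

# internal representation of the tree for pruning: postorder edge list
tree_plan <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (any(tree$edge.length <= 0)) stop("degenerate tree: zero-length branch")
  tr <- stats::reorder(tree, "postorder")
  list(edge = tr$edge, len = tr$edge.length, ntip = length(tr$tip.label),
       tips = tr$tip.label, root = length(tr$tip.label) + 1L,
       nnode = max(tr$edge))
}

# inside (pruning) messages for every node; counts: families x species matrix
# returns list(messages = list of (smax+1) x nfam matrices, lik = per-family
# marginal likelihood under the uniform root prior over 1..root_max)
bd_inside <- function(counts, plan, lambda, smax, root_max,
                      Pcache = NULL) {
  nf <- nrow(counts)
  msgs <- vector("list", plan$nnode)
  for (ti in seq_len(plan$ntip)) {
    m <- matrix(0, smax + 1L, nf)
    cnt <- pmin(counts[, plan$tips[ti]], smax)
    m[cbind(cnt + 1L, seq_len(nf))] <- 1
    msgs[[ti]] <- m
  }
  if (is.null(Pcache)) Pcache <- bd_matrix_cache(plan, lambda, smax)
  for (e in seq_len(nrow(plan$edge))) {
    par <- plan$edge[e, 1L]; child <- plan$edge[e, 2L]
    up <- Pcache[[e]] %*% msgs[[child]]
    msgs[[par]] <- if (is.null(msgs[[par]])) up else msgs[[par]] * up
  }
  prior <- rep(0, smax + 1L)
  prior[2:(root_max + 1L)] <- 1 / root_max
  lik <- as.numeric(crossprod(msgs[[plan$root]], prior))
  list(messages = msgs, lik = lik, Pcache = Pcache)
}

bd_matrix_cache <- function(plan, lambda, smax) {
  lens <- plan$len
  ulen <- unique(lens)
  Ps <- lapply(ulen, function(t) bd_matrix(t, lambda, smax))
  Ps[match(lens, ulen)]
}

#' Estimate the global birth-death rate
#'
#' Maximizes the product over families of the pruning-computed likelihood of
#' the tip counts, with a uniform root-size prior over 1..max(observed).
#' One-dimensional bounded search; deterministic.
#'
#' @param counts families x species matrix (or data.frame) of non-negative
#'   integer sizes; column names must match the tree's tip labels.
#' @param tree an `ape::phylo` ultrametric tree with branch lengths.
#' @param lower,upper search bounds; the upper default keeps
#'   lambda * max(branch) < 1 (the model's admissible range).
#' @return the estimate (numeric scalar) with attribute `logLik`.
#' @export
estimate_lambda <- function(counts, tree, lower = 1e-5, upper = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 20L) stop("need at least 20 families")
  plan <- tree_plan(tree)
  if (is.null(upper)) upper <- 0.95 / max(plan$len)
  smax <- max(counts) + 10L
  root_max <- max(counts)
  obj <- function(lam) {
    lik <- bd_inside(counts, plan, lam, smax, root_max)$lik
    -sum(log(pmax(lik, 1e-300)))
  }
  opt <- stats::optimize(obj, c(lower, upper), tol = 1e-6)
  structure(opt$minimum, logLik = -opt$objective)
}

#' Simulate families under the birth-death model
#'
#' Root sizes are drawn uniformly from 1..root_max and evolved down the tree
#' with the model's transition probabilities.
#'
#' @param tree `ape::phylo`.
#' @param lambda rate.
#' @param nsim number of families.
#' @param root_max upper end of the uniform root prior.
#' @param smax state-space cap.
#' @return nsim x ntip matrix of tip counts (columns named by tip label).
#' @export
simulate_bd_families <- function(tree, lambda, nsim, root_max, smax = NULL) {
  plan <- tree_plan(tree)
  if (is.null(smax)) smax <- root_max + 10L
  Pc <- bd_matrix_cache(plan, lambda, smax)
  state <- matrix(NA_integer_, plan$nnode, nsim)
  state[plan$root, ] <- sample.int(root_max, nsim, replace = TRUE)
  # walk edges root-ward first: reverse postorder is a preorder
  for (e in rev(seq_len(nrow(plan$edge)))) {
    par <- plan$edge[e, 1L]; child <- plan$edge[e, 2L]
    P <- Pc[[e]]
    ps <- state[par, ]
    for (s in unique(ps)) {
      ix <- which(ps == s)
      state[child, ix] <- sample.int(smax + 1L, length(ix), replace = TRUE,
                                     prob = P[s + 1L, ]) - 1L
    }
  }
  out <- t(state[seq_len(plan$ntip), , drop = FALSE])
  colnames(out) <- plan$tips
  out
}

# posterior-mean family size at every node given one family's tip counts
# (inside-outside over the truncated state space)
bd_node_expectations <- function(counts_row, plan, lambda, smax, root_max,
                                 Pcache) {
  cm <- matrix(counts_row, nrow = 1L,
               dimnames = list(NULL, names(counts_row)))
  ins <- bd_inside(cm, plan, lambda, smax, root_max, Pcache)
  msgs <- lapply(ins$messages, function(m) m[, 1L])
  prior <- rep(0, smax + 1L)
  prior[2:(root_max + 1L)] <- 1 / root_max
  outside <- vector("list", plan$nnode)
  outside[[plan$root]] <- prior
  kids <- split(seq_len(nrow(plan$edge)), plan$edge[, 1L])
  for (e in rev(seq_len(nrow(plan$edge)))) {
    par <- plan$edge[e, 1L]; child <- plan$edge[e, 2L]
    sibs <- setdiff(kids[[as.character(par)]], e)
    acc <- outside[[par]]
    for (se in sibs) {
      acc <- acc * as.numeric(Pcache[[se]] %*% msgs[[plan$edge[se, 2L]]])
    }
    outside[[child]] <- as.numeric(crossprod(Pcache[[e]], acc))
  }
  vapply(seq_len(plan$nnode), function(v) {
    w <- msgs[[v]] * outside[[v]]
    if (sum(w) <= 0) return(NA_real_)
    sum((0:smax) * w) / sum(w)
  }, numeric(1))
}

#' Flag significantly expanded orthogroups
#'
#' For each family the Monte-Carlo p-value is the fraction of `nsim`
#' simulated families (same root prior and lambda) whose marginal likelihood
#' is at most the observed family's. A family is flagged expanded when
#' p < alpha and the focal species' count strictly exceeds the posterior
#' expected size of every ancestral node on its root-to-tip path.
#'
#' @param counts families x species matrix; rownames are orthogroup ids.
#' @param tree `ape::phylo`; tip labels must match the columns.
#' @param focal focal species (column / tip label).
#' @param lambda rate; estimated with [estimate_lambda()] when NULL.
#' @param alpha significance threshold (no multiplicity correction, matching
#'   raw P < 0.05 practice for this test).
#' @param nsim Monte-Carlo sample size.
#' @param seed integer seed (deterministic output).
#' @return data.frame `orthogroup`, `p_value`, `expanded`, `focal_count`.
#' @export
flag_seos <- function(counts, tree, focal, lambda = NULL, alpha = 0.05,
                      nsim = 1000L, seed = 1L) {
  counts <- as.matrix(counts)
  rn <- rownames(counts) %||% rep(NA_character_, nrow(counts))
  anon <- is.na(rn) | rn == ""
  rn[anon] <- sprintf("OG%04d", which(anon))
  rownames(counts) <- rn
  plan <- tree_plan(tree)
  stopifnot(focal %in% plan$tips, all(plan$tips %in% colnames(counts)))
  counts <- counts[, plan$tips, drop = FALSE]
  if (is.null(lambda)) lambda <- as.numeric(estimate_lambda(counts, tree))
  set.seed(seed)
  smax <- max(counts) + 10L
  root_max <- max(counts)
  ins <- bd_inside(counts, plan, lambda, smax, root_max)
  sims <- simulate_bd_families(tree, lambda, nsim, root_max, smax)
  sim_lik <- bd_inside(sims, plan, lambda, smax, root_max, ins$Pcache)$lik
  p <- vapply(ins$lik, function(L) mean(sim_lik <= L), numeric(1))
  expanded <- rep(FALSE, nrow(counts))
  cand <- which(p < alpha)
  if (length(cand)) {
    # ancestors on the focal root-to-tip path
    ftip <- match(focal, plan$tips)
    path <- integer(0); node <- ftip
    repeat {
      e <- which(plan$edge[, 2L] == node)
      if (!length(e)) break
      node <- plan$edge[e, 1L]
      path <- c(path, node)
    }
    for (i in cand) {
      expect <- bd_node_expectations(counts[i, ], plan, lambda, smax,
                                     root_max, ins$Pcache)
      expanded[i] <- all(counts[i, focal] > expect[path])
    }
  }
  data.frame(orthogroup = rownames(counts), p_value = p, expanded = expanded,
             focal_count = counts[, focal], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Read a family-size matrix
#'
#' TSV with a `#`-prefixed header line: first column orthogroup id, remaining
#' columns per-species counts.
#'
#' @param path file path.
#' @return integer matrix with orthogroup rownames.
#' @export
read_family_matrix <- function(path) {
  df <- read_report_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}
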