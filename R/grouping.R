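# The synthesis layer: A1/A2/A3/B1 gene categories, per-SEO tandem-duplicate
# fractions and Ks stratified by group, the >40%-TD selection with the
# retro-before-tandem ordering test, and the repeat-content / family summary
# tables.

#' Categorize genes by retro and LTR evidence
#'
#' A1 = retrogene and LTR-flagged; A2 = retrogene only; A3 = LTR-flagged
#' only; B1 = neither. Every gene gets exactly one category.
#'
#' @param all_genes character vector of gene ids (TE-like genes already
#'   removed upstream).
#' @param retro_ids retrogene ids (e.g. `retro_id` of [call_retrogenes()]).
#' @param ltr_flagged_ids ids flagged by [flag_ltr_genes()].
#' @return data.frame `gene_id`, `category`.
#' @export
categorize_genes <- function(all_genes, retro_ids, ltr_flagged_ids) {
  missing <- setdiff(retro_ids, all_genes)
  if (length(missing)) {
    stop("retrogene id(s) absent from the gene set: ",
         paste(missing, collapse = ", "))
  }
  is_r <- all_genes %in% retro_ids
  is_l <- all_genes %in% ltr_flagged_ids
  cat <- ifelse(is_r & is_l, "A1",
                ifelse(is_r, "A2", ifelse(is_l, "A3", "B1")))
  data.frame(gene_id = all_genes, category = cat, stringsAsFactors = FALSE)
}

#' Assign SEOs to Groups A1/A2/A3/B1
#'
#' An SEO belongs to Group A1 (A2, A3) iff it contains at least one gene of
#' that category; it belongs to Group B1 iff it contains only B1 genes.
#' Groups overlap; non-SEO orthogroups are excluded.
#'
#' @param categories from [categorize_genes()].
#' @param orthogroups from [cluster_orthogroups()].
#' @param seo_ids orthogroup ids flagged as expanded.
#' @return data.frame `orthogroup`, `group` (long; one row per membership).
#' @export
group_seos <- function(categories, orthogroups, seo_ids) {
  cat_of <- stats::setNames(categories$category, categories$gene_id)
  out <- NULL
  for (og in intersect(seo_ids, unique(orthogroups$orthogroup))) {
    members <- orthogroups$gene_id[orthogroups$orthogroup == og]
    cats <- cat_of[members]
    cats <- cats[!is.na(cats)]
    if (!length(cats)) next
    gs <- intersect(c("A1", "A2", "A3"), cats)
    if (!length(gs) && all(cats == "B1")) gs <- "B1"
    if (length(gs)) {
      out <- rbind(out, data.frame(orthogroup = og, group = gs,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(orthogroup = character(0), group = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Tandem-duplicate fraction of an orthogroup
#'
#' @param members gene ids of one orthogroup (non-empty).
#' @param dup_labels from [classify_duplicates()].
#' @return fraction of members labelled tandem.
#' @export
td_fraction <- function(members, dup_labels) {
  if (!length(members)) stop("empty orthogroup")
  lab <- stats::setNames(dup_labels$label, dup_labels$gene_id)
  mean(lab[members] == "tandem", na.rm = TRUE)
}

# same-orthogroup tandem-labelled adjacencies (rank distance <= 2) of one
# orthogroup; returns a two-column matrix of gene pairs
td_pairs <- function(members, dup_labels, gene_table) {
  lab <- stats::setNames(dup_labels$label, dup_labels$gene_id)
  tds <- members[!is.na(lab[members]) & lab[members] == "tandem"]
  if (length(tds) < 2L) return(NULL)
  gt <- gene_table[match(tds, gene_table$gene_id), ]
  out <- NULL
  cmb <- utils::combn(seq_along(tds), 2L)
  for (cc in seq_len(ncol(cmb))) {
    i <- cmb[1L, cc]; j <- cmb[2L, cc]
    if (gt$chrom[i] == gt$chrom[j] && abs(gt$rank[i] - gt$rank[j]) <= 2L) {
      out <- rbind(out, c(tds[i], tds[j]))
    }
  }
  out
}

#' Per-group summary of SEO tandem fractions and Ks
#'
#' Descriptive medians and means (no significance test): per group, the
#' median/mean of the member SEOs' tandem-duplicate fractions and of the
#' pooled Ks values of their tandem pairs.
#'
#' @param groups from [group_seos()].
#' @param seo_stats data.frame `orthogroup`, `td_fraction`.
#' @param td_ks data.frame `orthogroup`, `ks` (one row per tandem pair).
#' @return data.frame per group: `group`, `n_seos`, `td_fraction_median`,
#'   `td_fraction_mean`, `td_ks_median`, `td_ks_mean`.
#' @export
group_summary <- function(groups, seo_stats, td_ks) {
  out <- NULL
  for (g in c("A1", "A2", "A3", "B1")) {
    ogs <- groups$orthogroup[groups$group == g]
    if (!length(ogs)) {
      warning("group ", g, " is empty; omitted from the summary")
      next
    }
    fr <- seo_stats$td_fraction[seo_stats$orthogroup %in% ogs]
    ks <- td_ks$ks[td_ks$orthogroup %in% ogs]
    ks <- ks[is.finite(ks)]
    out <- rbind(out, data.frame(
      group = g, n_seos = length(ogs),
      td_fraction_median = stats::median(fr),
      td_fraction_mean = mean(fr),
      td_ks_median = if (length(ks)) stats::median(ks) else NA_real_,
      td_ks_mean = if (length(ks)) mean(ks) else NA_real_,
      stringsAsFactors = FALSE))
  }
  out
}

#' Retro-before-tandem ordering test
#'
#' Restricted to SEOs whose tandem fraction exceeds `td_threshold`: for each
#' called retrogene that is itself tandem-labelled, the verdict is
#' `retro_first` iff Ks(retrogene, parent) > Ks(retrogene, nearest tandem
#' partner) -- i.e. the retroduplication predates the tandem duplication.
#'
#' @param retro_calls from [call_retrogenes()].
#' @param dup_labels from [classify_duplicates()].
#' @param ks_table data.frame `gene_a`, `gene_b`, `ks` (canonical order not
#'   required).
#' @param orthogroups from [cluster_orthogroups()].
#' @param seo_stats data.frame `orthogroup`, `td_fraction` for SEOs.
#' @param gene_table data.frame `gene_id`, `chrom`, `rank`.
#' @param td_threshold minimum tandem fraction (strict).
#' @return list with `verdicts` (data.frame `retro_id`, `parent_id`,
#'   `partner_id`, `ks_parent`, `ks_tandem`, `retro_first`), `fraction`
#'   (share of retro_first verdicts) and `n_skipped` (genes without usable
#'   Ks).
#' @export
ordering_test <- function(retro_calls, dup_labels, ks_table, orthogroups,
                          seo_stats, gene_table, td_threshold = 0.4) {
  kkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  kmap <- stats::setNames(ks_table$ks, kkey(ks_table$gene_a, ks_table$gene_b))
  lab <- stats::setNames(dup_labels$label, dup_labels$gene_id)
  og_of <- stats::setNames(orthogroups$orthogroup, orthogroups$gene_id)
  sel_ogs <- seo_stats$orthogroup[seo_stats$td_fraction > td_threshold]
  verdicts <- NULL; skipped <- 0L
  for (i in seq_len(nrow(retro_calls))) {
    r <- retro_calls$retro_id[i]
    if (is.na(og_of[r]) || !(og_of[r] %in% sel_ogs)) next
    if (is.na(lab[r]) || lab[r] != "tandem") next
    sibs <- orthogroups$gene_id[orthogroups$orthogroup == og_of[r]]
    sibs <- setdiff(sibs[!is.na(lab[sibs]) & lab[sibs] == "tandem"], r)
    gt <- gene_table[match(c(r, sibs), gene_table$gene_id), ]
    same <- which(gt$chrom[-1L] == gt$chrom[1L])
    if (!length(same)) next
    dist <- abs(gt$rank[-1L][same] - gt$rank[1L])
    partner <- sibs[same][which.min(dist)]
    ksp <- kmap[kkey(r, retro_calls$parent_id[i])]
    kst <- kmap[kkey(r, partner)]
    if (is.na(ksp) || is.na(kst)) { skipped <- skipped + 1L; next }
    verdicts <- rbind(verdicts, data.frame(
      retro_id = r, parent_id = retro_calls$parent_id[i],
      partner_id = partner, ks_parent = unname(ksp), ks_tandem = unname(kst),
      retro_first = unname(ksp > kst), stringsAsFactors = FALSE))
  }
  if (is.null(verdicts)) {
    verdicts <- data.frame(retro_id = character(0), parent_id = character(0),
                           partner_id = character(0), ks_parent = numeric(0),
                           ks_tandem = numeric(0), retro_first = logical(0),
                           stringsAsFactors = FALSE)
  }
  list(verdicts = verdicts,
       fraction = if (nrow(verdicts)) mean(verdicts$retro_first) else NA_real_,
       n_skipped = skipped)
}

#' Repeat-content summary table
#'
#' Per repeat class: masked length (Mb), percent of the genome and percent of
#' all repeats, reported to 2 decimals with half-up rounding. Input is
#' either a table of labelled intervals (overlaps are merged per class
#' before summation) together with the genome length in bp, or precomputed
#' per-class lengths in Mb with the genome and total-repeat sizes in Mb.
#'
#' @param x data.frame `chrom`, `start`, `end`, `class` of repeat intervals,
#'   or a named numeric vector of per-class lengths in Mb.
#' @param genome_length genome size in bp (interval input).
#' @param genome_mb,total_repeats_mb sizes in Mb (precomputed input);
#'   `total_repeats_mb` defaults to the sum of the classes.
#' @return data.frame `class`, `length_mb`, `pct_genome`, `pct_repeats`.
#' @export
repeat_summary <- function(x, genome_length = NULL, genome_mb = NULL,
                           total_repeats_mb = NULL) {
  if (is.data.frame(x)) {
    stopifnot(!is.null(genome_length))
    lens <- vapply(split(x, x$class), function(df) {
      tot <- 0L
      for (ch in unique(df$chrom)) {
        d <- df[df$chrom == ch, , drop = FALSE]
        d <- d[order(d$start), ]
        # merge overlapping intervals before summation
        s <- d$start[1]; e <- d$end[1]
        for (i in seq_len(nrow(d))[-1]) {
          if (d$start[i] <= e + 1L) e <- max(e, d$end[i])
          else { tot <- tot + (e - s + 1L); s <- d$start[i]; e <- d$end[i] }
        }
        tot <- tot + (e - s + 1L)
      }
      tot
    }, numeric(1))
    length_mb <- lens / 1e6
    genome_mb <- genome_length / 1e6
    if (is.null(total_repeats_mb)) total_repeats_mb <- sum(length_mb)
  } else {
    length_mb <- x
    stopifnot(!is.null(genome_mb))
    if (is.null(total_repeats_mb)) total_repeats_mb <- sum(length_mb)
  }
  data.frame(
    class = names(length_mb),
    length_mb = unname(length_mb),
    pct_genome = round_half_up(100 * unname(length_mb) / genome_mb),
    pct_repeats = round_half_up(100 * unname(length_mb) / total_repeats_mb),
    stringsAsFactors = FALSE)
}

#' LTR family summary per clade
#'
#' Per clade: family count, total RT-domain copies and mean copies per family
#' (2 decimals), plus a TOTAL row per superfamily. Input is either the long
#' family table from [cluster_rt_families()] or a pre-counted table with
#' columns `superfamily`, `clade`, `n_families`, `n_rt_copies`.
#'
#' @param fam either format described above.
#' @return data.frame `superfamily`, `clade`, `n_families`, `n_copies`,
#'   `mean_copies_per_family`.
#' @export
family_summary <- function(fam) {
  if (all(c("n_families", "n_rt_copies") %in% names(fam))) {
    counts <- data.frame(superfamily = fam$superfamily, clade = fam$clade,
                         n_families = fam$n_families,
                         n_copies = fam$n_rt_copies, stringsAsFactors = FALSE)
  } else {
    sp <- split(fam, paste(fam$superfamily, fam$clade))
    counts <- do.call(rbind, lapply(sp, function(df) {
      data.frame(superfamily = df$superfamily[1], clade = df$clade[1],
                 n_families = length(unique(df$family)),
                 n_copies = nrow(df), stringsAsFactors = FALSE)
    }))
  }
  out <- NULL
  for (sf in unique(counts$superfamily)) {
    sub <- counts[counts$superfamily == sf, , drop = FALSE]
    sub <- sub[order(sub$clade), ]
    tot <- data.frame(superfamily = sf, clade = "TOTAL",
                      n_families = sum(sub$n_families),
                      n_copies = sum(sub$n_copies), stringsAsFactors = FALSE)
    out <- rbind(out, sub, tot)
  }
  out$mean_copies_per_family <- round_half_up(out$n_copies / out$n_families)
  rownames(out) <- NULL
  out
}
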