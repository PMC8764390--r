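# Genome + annotation container and on-disk I/O.
#
# Coordinate contract: all coordinates in this package are 1-based inclusive
# on the forward strand (the native GFF3 and R convention). Strand is applied
# only when sequence is spliced out, never in stored coordinates.

#' Construct an annotated genome
#'
#' Low-level constructor used by [load_genome()] and the synthetic-genome
#' generator. Validates the container invariants: every gene lies on a known
#' chromosome and inside it, exons are sorted, non-overlapping and inside the
#' gene locus, and per-chromosome gene ranks are the 1..n ordinals of genes
#' sorted by start coordinate.
#'
#' @param sequences named character vector, chromosome id -> DNA string.
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (one row per gene).
#' @param exons data.frame with columns `gene_id`, `start`, `end`.
#' @param cds data.frame with columns `gene_id`, `start`, `end`; defaults to
#'   `exons` (CDS-only gene models).
#' @return an object of class `annotated_genome`: a list with elements `seq`,
#'   `genes` (with a `rank` column added), `exons`, `cds`.
#' @export
annotated_genome <- function(sequences, genes, exons, cds = exons) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  cds <- as.data.frame(cds, stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  miss <- setdiff(genes$chrom, names(sequences))
  if (length(miss)) {
    stop("gene(s) reference chromosome(s) absent from the sequence set: ",
         paste(miss, collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  clen <- nchar(sequences)[genes$chrom]
  if (any(genes$start < 1L | genes$end > clen | genes$start > genes$end)) {
    stop("gene locus outside chromosome bounds")
  }
  # exon checks, per gene
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
  for (tab in list(exons, cds)) {
    if (!all(tab$gene_id %in% genes$gene_id)) stop("exon/CDS row for unknown gene")
  }
  gspl <- split(exons, exons$gene_id)
  for (gid in genes$gene_id) {
    ex <- gspl[[gid]]
    if (is.null(ex) || nrow(ex) < 1L) stop("gene without exons: ", gid)
    g <- genes[genes$gene_id == gid, ]
    if (any(ex$start < g$start | ex$end > g$end)) stop("exon outside locus: ", gid)
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
      stop("overlapping exons in gene: ", gid)
    }
  }
  genes$rank <- NA_integer_
  for (ch in unique(genes$chrom)) {
    i <- which(genes$chrom == ch)
    genes$rank[i][order(genes$start[i], genes$gene_id[i])] <- seq_along(i)
  }
  structure(list(seq = sequences, genes = genes, exons = exons, cds = cds),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("annotated_genome:", length(x$seq), "chromosome(s),",
      sum(nchar(x$seq)), "bp,", nrow(x$genes), "gene(s)\n")
  invisible(x)
}

#' Load a genome from FASTA and GFF3
#'
#' Reads chromosome sequences and gene models (gene/mRNA/exon/CDS features
#' linked by `Parent` attributes). For genes with several mRNAs the mRNA with
#' the longest total CDS is retained as the gene's representative model.
#' Genes whose spliced CDS length is not divisible by 3 are excluded with a
#' warning. A feature referencing a chromosome absent from the FASTA is a
#' hard error.
#'
#' @param fasta_path path to a (possibly wrapped) multi-record FASTA file.
#' @param gff3_path path to a GFF3 file.
#' @return an [annotated_genome()].
#' @export
load_genome <- function(fasta_path, gff3_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  sequences <- toupper(as.character(seqs))
  names(sequences) <- sub("\\s.*$", "", names(sequences))

  gff <- rtracklayer::import(gff3_path, format = "gff3")
  md <- S4Vectors::mcols(gff)
  feat_chrom <- as.character(GenomicRanges::seqnames(gff))
  miss <- !feat_chrom %in% names(sequences)
  if (any(miss)) {
    i <- which(miss)[1L]
    stop("feature '", md$ID[i] %||% md$type[i], "' references chromosome '",
         feat_chrom[i], "' absent from the FASTA")
  }
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  parent <- vapply(md$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                   character(1))

  is_gene <- type == "gene"
  is_mrna <- type == "mRNA"
  gene_tab <- data.frame(
    gene_id = ids[is_gene],
    chrom = feat_chrom[is_gene],
    start = GenomicRanges::start(gff)[is_gene],
    end = GenomicRanges::end(gff)[is_gene],
    strand = as.character(GenomicRanges::strand(gff))[is_gene],
    stringsAsFactors = FALSE
  )
  mrna_tab <- data.frame(
    mrna_id = ids[is_mrna], gene_id = parent[is_mrna], stringsAsFactors = FALSE
  )
  sub <- type %in% c("exon", "CDS")
  feat_tab <- data.frame(
    type = type[sub], mrna_id = parent[sub],
    start = GenomicRanges::start(gff)[sub], end = GenomicRanges::end(gff)[sub],
    stringsAsFactors = FALSE
  )
  # representative mRNA per gene: longest total CDS, ties by mRNA id
  cds_len <- tapply(
    ifelse(feat_tab$type == "CDS", feat_tab$end - feat_tab$start + 1L, 0L),
    feat_tab$mrna_id, sum
  )
  mrna_tab$cds_len <- as.integer(cds_len[mrna_tab$mrna_id])
  mrna_tab <- mrna_tab[order(mrna_tab$gene_id, -mrna_tab$cds_len, mrna_tab$mrna_id), ]
  rep_mrna <- mrna_tab[!duplicated(mrna_tab$gene_id), ]

  keep <- feat_tab$mrna_id %in% rep_mrna$mrna_id
  feat_tab <- feat_tab[keep, ]
  gene_of <- stats::setNames(rep_mrna$gene_id, rep_mrna$mrna_id)
  feat_tab$gene_id <- unname(gene_of[feat_tab$mrna_id])

  exon_tab <- feat_tab[feat_tab$type == "exon", c("gene_id", "start", "end")]
  cds_tab <- feat_tab[feat_tab$type == "CDS", c("gene_id", "start", "end")]
  # genes whose CDS length is not a codon multiple are excluded, not fatal
  tot <- tapply(cds_tab$end - cds_tab$start + 1L, cds_tab$gene_id, sum)
  bad <- names(tot)[as.integer(tot) %% 3L != 0L]
  if (length(bad)) {
    warning("excluding gene(s) with CDS length not divisible by 3: ",
            paste(bad, collapse = ", "))
    gene_tab <- gene_tab[!gene_tab$gene_id %in% bad, ]
    exon_tab <- exon_tab[!exon_tab$gene_id %in% bad, ]
    cds_tab <- cds_tab[!cds_tab$gene_id %in% bad, ]
  }
  gene_tab <- gene_tab[gene_tab$gene_id %in% exon_tab$gene_id, ]
  annotated_genome(sequences, gene_tab, exon_tab, cds_tab)
}

#' Write a genome to FASTA and GFF3
#'
#' Inverse of [load_genome()]: emits one `gene` + one `mRNA` feature per gene
#' model plus its `exon` and `CDS` rows. Coordinates round-trip exactly.
#'
#' @param genome an [annotated_genome()].
#' @param fasta_path,gff3_path output paths.
#' @return invisibly, the two paths.
#' @export
write_genome <- function(genome, fasta_path, gff3_path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, fasta_path, width = 80L)
  con <- file(gff3_path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- genome$genes[order(genome$genes$chrom, genome$genes$start), ]
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    ex <- genome$exons[genome$exons$gene_id == gid, , drop = FALSE]
    cd <- genome$cds[genome$cds$gene_id == gid, , drop = FALSE]
    mid <- paste0(gid, ".t1")
    lines <- c(
      lines,
      sprintf("%s\tretrodup\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom[i], g$start[i], g$end[i], g$strand[i], gid),
      sprintf("%s\tretrodup\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom[i], g$start[i], g$end[i], g$strand[i], mid, gid),
      sprintf("%s\tretrodup\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              g$chrom[i], ex$start, ex$end, g$strand[i], mid),
      sprintf("%s\tretrodup\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
              g$chrom[i], cd$start, cd$end, g$strand[i], mid, mid)
    )
  }
  writeLines(lines, con)
  invisible(c(fasta_path, gff3_path))
}

# forward-strand genomic substring
genome_substr <- function(genome, chrom, start, end) {
  substr(genome$seq[[chrom]], start, end)
}

gene_record <- function(genome, gene_id) {
  i <- match(gene_id, genome$genes$gene_id)
  if (is.na(i)) stop("unknown gene id: ", gene_id)
  genome$genes[i, ]
}

#' Spliced coding sequence of a gene
#'
#' Concatenates the gene's CDS segments in transcription order: ascending
#' genomic order for `+` genes, reverse complement of the ascending
#' concatenation for `-` genes. Result length is divisible by 3.
#'
#' @param genome an [annotated_genome()].
#' @param gene_id gene identifier.
#' @param what `"cds"` (default) or `"exon"` to splice the full exon chain.
#' @return DNA string.
#' @export
spliced_cds <- function(genome, gene_id, what = c("cds", "exon")) {
  what <- match.arg(what)
  g <- gene_record(genome, gene_id)
  tab <- if (what == "cds") genome$cds else genome$exons
  seg <- tab[tab$gene_id == gene_id, , drop = FALSE]
  seg <- seg[order(seg$start), ]
  s <- paste(vapply(seq_len(nrow(seg)), function(i) {
    genome_substr(genome, g$chrom, seg$start[i], seg$end[i])
  }, character(1)), collapse = "")
  if (g$strand == "-") s <- revcomp(s)
  s
}

# genomic span of a gene locus (forward strand, introns included)
gene_locus_seq <- function(genome, gene_id) {
  g <- gene_record(genome, gene_id)
  s <- genome_substr(genome, g$chrom, g$start, g$end)
  if (g$strand == "-") s <- revcomp(s)
  s
}

# number of exons per gene, as a named integer vector
exon_counts <- function(genome) {
  n <- table(genome$exons$gene_id)
  out <- stats::setNames(as.integer(n), names(n))
  out[genome$genes$gene_id]
}

# write a TSV with '#'-prefixed header
write_report_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df)) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_report_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", skip = 1L, header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          col.names = cols, comment.char = "")
  df
}
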