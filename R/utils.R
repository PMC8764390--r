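# Shared sequence utilities. The standard genetic code is written out here so
# that translation and the NG86 machinery do not silently depend on the same
# lookup the test oracles use.

GENETIC_CODE_STD <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

SENSE_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
STOP_CODONS  <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD == "*"]
DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement; `N` maps to `N`.
#'
#' @param x a single DNA string (A/C/G/T/N).
#' @return the reverse complement as a character scalar.
#' @keywords internal
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- !chars %in% names(comp)
  if (any(bad)) stop("non-ACGTN symbol in sequence: ", chars[which(bad)[1]])
  paste(rev(unname(comp[chars])), collapse = "")
}

# Split a CDS string into codons; errors if length is not a multiple of 3.
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length ", n, " not divisible by 3")
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a coding sequence
#'
#' Standard genetic code. A trailing stop codon is dropped; internal stops are
#' kept as `*` and the result is flagged (attribute `internal_stop`) rather
#' than rejected, so degraded transposon-derived coding copies survive into
#' downstream filtering. Codons containing `N` translate to `X`.
#'
#' @param cds a single DNA string with length divisible by 3.
#' @return protein string with attribute `internal_stop` (logical).
#' @examples
#' translate_cds("ATGAAATAG")  # "MK"
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (nchar(cds) == 0L) {
    return(structure("", internal_stop = FALSE))
  }
  chars <- strsplit(cds, "", fixed = TRUE)[[1]]
  bad <- !chars %in% c(DNA_BASES, "N")
  if (any(bad)) stop("non-ACGTN symbol in CDS: '", chars[which(bad)[1]], "'")
  codons <- split_codons(cds)
  aa <- GENETIC_CODE_STD[codons]
  aa[is.na(aa)] <- "X"  # any codon containing N
  if (length(aa) > 1L && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  prot <- paste(aa, collapse = "")
  structure(prot, internal_stop = grepl("*", prot, fixed = TRUE))
}

# round-half-up to `digits` decimals (reports use 2-decimal half-up rounding,
# matching how the summary tables were printed)
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Jukes-Cantor correction of a p-distance; NA where saturated (p >= 3/4).
jc69 <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

# inverse: p-distance that JC69-corrects to d
jc69_inverse <- function(d) 0.75 * (1 - exp(-4 * d / 3))

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the scalar-expansion surprise
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)
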