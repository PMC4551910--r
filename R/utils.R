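# Shared sequence utilities.

# IUPAC nucleotide code -> set of concrete bases it matches.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# sorted base set (collapsed) -> IUPAC code
IUPAC_FROM_SET <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

STRAINS <- c("WT", "dRI", "none")

PROMOTER_TYPES <- c(
  "sigma54_activator_dependent", "sigma54_bypass",
  "sigma70_constitutive", "sigma70_repressed_by_sigma54"
)

seq_to_chars <- function(sequence) {
  x <- toupper(as.character(sequence))
  strsplit(x, "", fixed = TRUE)[[1]]
}

chars_to_seq <- function(chars) paste(chars, collapse = "")

revcomp_chars <- function(chars) rev(unname(DNA_COMPLEMENT[chars]))

#' Reverse-complement a DNA string
#'
#' @param x a single DNA string over `A`, `C`, `G`, `T`, `N` (IUPAC codes are
#'   also accepted through [Biostrings::reverseComplement()]).
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

check_dna_alphabet <- function(chars, allow_n = TRUE) {
  ok <- c("A", "C", "G", "T", if (allow_n) "N")
  bad <- setdiff(unique(chars), ok)
  if (length(bad) > 0) {
    stop("sequence contains characters outside {A,C,G,T",
         if (allow_n) ",N", "}: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# 5' end of a gene in plus-strand coordinates
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}
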