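#' @keywords internal
"_PACKAGE"

#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement pairwiseAlignment alignedPattern
#'   alignedSubject PDict matchPDict startIndex translate AAString
#' @importFrom IRanges IRanges reduce start end width
#' @importFrom stats rexp runif setNames aggregate hclust cutree as.dist
#'   sd median lm coef
#' @importFrom utils read.table write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

## transition partner of each base (A<->G, C<->T)
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  chars_seq(sample(DNA_BASES, n, replace = TRUE))
}

#' Read sequences from a FASTA file as a named character vector
#' @param path path to a FASTA file
#' @return named character vector of uppercase DNA sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write a named character vector of sequences to FASTA
#' @param seqs named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

## codon -> amino acid lookup (standard code; ambiguity translates to X)
CODON_TABLE <- local({
  tb <- as.character(Biostrings::GENETIC_CODE)
  names(tb) <- names(Biostrings::GENETIC_CODE)
  tb
})

## translate an in-frame nucleotide string; trailing partial codon dropped
translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  codons <- substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(CODON_TABLE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## amino acid -> preferred codon table (used by the simulator to build ORFs)
AA_CODONS <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"), E = c("GAA", "GAG"), G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  L = c("CTT", "CTC", "CTA", "CTG", "TTA", "TTG"), K = c("AAA", "AAG"),
  M = "ATG", F = c("TTT", "TTC"), P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), W = "TGG", Y = c("TAT", "TAC"),
  V = c("GTT", "GTC", "GTA", "GTG"), `*` = c("TAA", "TAG", "TGA")
)

## digest helper for run manifests
file_digest <- function(path) unname(tools::md5sum(path))
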