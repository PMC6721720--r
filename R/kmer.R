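# 3-mer composition encoders for nucleotide and amino-acid sequences.
# Both map to a 64-dimensional (4 x 4 x 4) normalized frequency vector.

# Side-chain polarity classes of the 20 standard amino acids (one-letter).
AA_CLASS <- c(
  A = 1L, V = 1L, L = 1L, I = 1L, M = 1L, F = 1L, W = 1L, P = 1L,
  G = 2L, S = 2L, T = 2L, C = 2L, N = 2L, Q = 2L, Y = 2L,
  R = 3L, K = 3L, H = 3L,
  D = 4L, E = 4L)

RNA_CODE <- c(A = 1L, C = 2L, G = 3L, U = 4L)

kmer3_names <- function(alphabet) {
  g <- expand.grid(c = alphabet, b = alphabet, a = alphabet,
                   stringsAsFactors = FALSE)
  paste0(g$a, g$b, g$c)
}

# Count length-3 sliding windows over an integer code sequence (1..4, NA for
# symbols outside the alphabet); windows containing NA are skipped.
kmer3_freq <- function(codes) {
  n <- length(codes)
  if (n < 3) return(numeric(64))
  a <- codes[1:(n - 2)]; b <- codes[2:(n - 1)]; c_ <- codes[3:n]
  idx <- (a - 1L) * 16L + (b - 1L) * 4L + c_
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) return(numeric(64))
  tabulate(idx, nbins = 64) / length(idx)
}

#' Encode an RNA (or DNA) sequence as 3-mer frequencies
#'
#' Counts all length-3 sliding windows over the alphabet \{A, C, G, U\}
#' (T is read as U) and normalizes by the number of valid windows, giving a
#' 64-dimensional composition vector.  Windows containing any other symbol
#' (e.g. N) are skipped; sequences with no valid window yield the all-zero
#' vector.
#'
#' @param sequence A single nucleotide string; case-insensitive.
#' @return A named numeric vector of length 64 summing to 1 (or all zero).
#' @examples
#' encode_rna_3mer("ACGUACGU")[c("ACG", "CGU", "GUA", "UAC")]
#' @export
encode_rna_3mer <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  chars[chars == "T"] <- "U"
  setNames(kmer3_freq(unname(RNA_CODE[chars])), kmer3_names(names(RNA_CODE)))
}

#' Encode a protein sequence as polarity-class 3-mer frequencies
#'
#' The 20 standard amino acids are grouped into four side-chain polarity
#' classes (nonpolar A/V/L/I/M/F/W/P; polar uncharged G/S/T/C/N/Q/Y; basic
#' R/K/H; acidic D/E); the class sequence is then encoded exactly like
#' [encode_rna_3mer()], yielding 64 normalized 3-mer frequencies.  Windows
#' containing nonstandard residues are skipped.
#'
#' @param sequence A single amino-acid string (one-letter codes).
#' @return A named numeric vector of length 64 summing to 1 (or all zero).
#' @export
encode_protein_3mer <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  setNames(kmer3_freq(unname(AA_CLASS[chars])),
           kmer3_names(paste0("c", 1:4)))
}

#' Read sequences from a FASTA file keyed by node name
#'
#' Headers are trimmed and case-folded so they match network node names the
#' same way edge-list identifiers do.
#'
#' @param path FASTA file path.
#' @return A named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  setNames(as.character(seqs), normalize_name(names(seqs)))
}

#' Write named sequences to a FASTA file
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}
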