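#' Encode k-mers as 2-bit integer codes
#'
#' Maps nucleotide words over \{A,C,G,T\} to their base-4 integer code
#' (A=0, C=1, G=2, T=3, two bits per base). U is folded to T and lower
#' case is accepted, so RNA-style and DNA-style inputs unify. For a word
#' of length k the code lies in \[0, 4^k); codes are returned as doubles
#' so that k up to 26 stays exact within double precision.
#'
#' @param kmers character vector of equal-length nucleotide words.
#' @return numeric vector of codes, one per word.
#' @examples
#' kmer_encode(c("AAA", "ACG", "TTT"))
#' @seealso [kmer_decode()]
#' @export
kmer_encode <- function(kmers) {
  if (length(kmers) == 0L) return(numeric(0))
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("all k-mers must have the same length")
  if (k < 1L || k > 26L) stop("word length must be between 1 and 26")
  up <- chartr("acgtuU", "ACGTTT", kmers)
  code <- numeric(length(kmers))
  for (i in seq_len(k)) {
    b <- match(substr(up, i, i), c("A", "C", "G", "T")) - 1
    if (anyNA(b)) stop("k-mer contains a symbol outside {A,C,G,T,U}")
    code <- code * 4 + b
  }
  code
}

#' Decode 2-bit integer codes back to k-mer strings
#'
#' Inverse of [kmer_encode()]: decoding then re-encoding is the identity on
#' \{A,C,G,T\}^k.
#'
#' @param codes numeric vector of codes in \[0, 4^k).
#' @param k word length.
#' @return character vector of k-mers (DNA alphabet).
#' @export
kmer_decode <- function(codes, k) {
  if (k < 1L || k > 26L) stop("word length must be between 1 and 26")
  if (any(codes < 0 | codes >= 4^k)) stop("code out of range for k = ", k)
  if (any(codes != trunc(codes))) stop("codes must be integers")
  out <- matrix("", nrow = k, ncol = length(codes))
  bases <- c("A", "C", "G", "T")
  x <- codes
  for (i in k:1) {
    out[i, ] <- bases[x %% 4 + 1]
    x <- x %/% 4
  }
  apply(out, 2, paste, collapse = "")
}

#' Reverse complement of a DNA sequence
#'
#' @param x character vector of DNA sequences (U accepted, folded to T).
#' @return character vector of reverse complements, DNA alphabet, 5'->3'.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    s <- chartr("uU", "tT", s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}
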