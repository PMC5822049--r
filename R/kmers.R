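#' @importFrom stats optim rnorm runif setNames sd var quantile p.adjust
#'   pnorm rmultinom cor
#' @importFrom utils head read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")
## dinucleotides in AA, AC, ..., TT order; code of (b1, b2) is (b1-1)*4 + b2
DNA_DINUCS <- paste0(rep(DNA_BASES, each = 4), DNA_BASES)

## Integer encoding used throughout: A=1, C=2, G=3, T=4; a k-mer maps to the
## 1-based index of its lexicographic rank, so kmer_index("AA..A") == 1.

#' Enumerate all k-mers in lexicographic order
#'
#' @param k Window length.
#' @return Character vector of length \code{4^k}.
#' @export
all_kmers <- function(k) {
  m <- kmer_base_matrix(k)
  kmers_from_base_matrix(m)
}

## 4^k x k integer matrix of base codes, rows in lexicographic k-mer order.
kmer_base_matrix <- function(k) {
  stopifnot(k >= 1)
  n <- 4L^k
  m <- matrix(0L, n, k)
  for (i in seq_len(k)) {
    m[, i] <- rep(rep(1:4, each = 4L^(k - i)), times = 4L^(i - 1))
  }
  m
}

kmers_from_base_matrix <- function(m) {
  chars <- matrix(DNA_BASES[m], nrow(m), ncol(m))
  do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
}

## Lexicographic index of each row of an integer base matrix.
kmer_index_from_base <- function(m) {
  k <- ncol(m)
  idx <- rep(1, nrow(m))
  for (i in seq_len(k)) idx <- idx + (m[, i] - 1) * 4^(k - i)
  as.integer(idx)
}

## Integer base matrix (n x k) from a character vector of equal-length k-mers.
base_matrix_from_kmers <- function(x) {
  k <- unique(nchar(x))
  stopifnot(length(k) == 1)
  s <- strsplit(x, "", fixed = TRUE)
  flat <- match(unlist(s), DNA_BASES)
  if (anyNA(flat)) stop("non-ACGT character in sequence")
  matrix(flat, nrow = length(x), ncol = k, byrow = TRUE)
}

#' Reverse complement of DNA strings
#'
#' Thin wrapper around \code{Biostrings::reverseComplement} returning plain
#' character vectors.
#'
#' @param x Character vector of DNA sequences (ACGT only).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Permutation p such that p[s] is the index of revcomp(kmer s);
## pure index arithmetic (no string handling) so it is cheap in loops.
rc_permutation <- function(k) {
  m <- kmer_base_matrix(k)
  rc <- 5L - m[, rev(seq_len(k)), drop = FALSE]
  kmer_index_from_base(rc)
}

## Reverse-complement equivalence classes of k-mer indices: a list of integer
## vectors, each {s} (palindrome) or {s, revcomp(s)}, ordered by smallest
## member.
rc_classes <- function(k) {
  p <- rc_permutation(k)
  n <- 4L^k
  reps <- pmin(seq_len(n), p)
  split(seq_len(n), reps)
}
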