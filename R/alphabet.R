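#' Sequence alphabet helpers
#'
#' Transcript assemblies are stored in the DNA alphabet (A/C/G/T/N); folding
#' and mature-miRNA comparisons operate in RNA space. These helpers convert
#' between the two and compute reverse complements on plain character
#' strings, which keeps the tight generator/scanner loops free of XString
#' overhead. FASTA-level I/O goes through Biostrings.
#'
#' @param x a character vector of sequences.
#' @return a character vector of the same length.
#' @examples
#' as_rna("ATGC")
#' revcomp_dna("ATGC")
#' @name alphabet
NULL

#' @rdname alphabet
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname alphabet
#' @export
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' @rdname alphabet
#' @export
revcomp_dna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "",
                       fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname alphabet
#' @export
revcomp_rna <- function(x) as_rna(revcomp_dna(as_dna(x)))

check_alphabet <- function(x, allowed, what = "sequence") {
  bad <- grepl(sprintf("[^%s]", allowed), toupper(x))
  if (any(bad)) {
    stop(sprintf("%s contains characters outside [%s]", what, allowed),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' GC content of a sequence
#'
#' Percentage of G and C bases over the full sequence length (ambiguous
#' bases count in the denominator). This is the denominator of the MFEI
#' statistic.
#'
#' @param seq a single non-empty sequence (DNA or RNA).
#' @return a percentage on \code{[0, 100]}.
#' @examples
#' gc_percent("GCGC")  # 100
#' gc_percent("GCAU")  # 50
#' @export
gc_percent <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  s <- toupper(seq)
  n_gc <- nchar(s) - nchar(gsub("[GC]", "", s))
  100 * n_gc / nchar(s)
}

## random sequence with exact base composition at the target GC: a
## shuffled multiset rather than i.i.d. draws, so realized GC matches
## the request up to integer rounding on every transcript
random_seq <- function(n, gc = 0.5) {
  n_g <- round(n * gc / 2)
  n_c <- round(n * gc) - n_g
  n_a <- (n - n_g - n_c + 1) %/% 2
  n_t <- n - n_g - n_c - n_a
  pool <- c(rep("G", n_g), rep("C", n_c), rep("A", n_a), rep("T", n_t))
  paste(sample(pool), collapse = "")
}

## round-half-up to `digits` decimals (report convention; R's round() is
## round-half-even)
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}
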