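#' @useDynLib estmine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings over `A,C,G,T,N`.
#' @return Character vector of the reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequences
#'
#' Uniform i.i.d. bases; used by the simulator and by tests.
#'
#' @param n Number of sequences.
#' @param len Length of each sequence (recycled).
#' @return Character vector of DNA strings.
#' @export
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(DNA_BASES, l, replace = TRUE), collapse = "")
  }, character(1))
}

# split a DNA string into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# substitute base at positions `pos` (1-based) with a uniformly drawn
# different base; returns the edited character vector
mutate_bases <- function(chars, pos) {
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  chars
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
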