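#' @useDynLib endophylo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All package randomness funnels through here
# so that pipelines are reproducible from a single integer.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stage offset, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that keeps
#' plain character vectors (the package currency) in and out.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length, names preserved.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Generate uniform-random DNA
#'
#' Background and ancestor sequences are drawn iid over A/C/G/T (GC 50%).
#'
#' @param len sequence length in bp (vectorised).
#' @return character vector of sequences.
#' @export
random_dna <- function(len) {
  vapply(len, function(l) {
    paste(sample(DNA_BASES, l, replace = TRUE), collapse = "")
  }, character(1))
}

str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_str <- function(ch) paste(ch, collapse = "")

# Decode a Phred+33 quality string to integer scores.
phred_decode <- function(qual) utf8ToInt(qual) - 33L

phred_encode <- function(q) intToUtf8(q + 33L)

# Fraction of identical characters between two equal-length strings.
str_identity <- function(a, b) {
  ca <- utf8ToInt(a); cb <- utf8ToInt(b)
  stopifnot(length(ca) == length(cb))
  mean(ca == cb)
}

#' Percent identity of two sequences
#'
#' Global affine-gap alignment identity: matches over alignment length, so
#' gapped columns count against identity.
#'
#' @param a,b DNA sequences (character scalars).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return percent identity in [0, 100].
#' @export
align_identity <- function(a, b, gap_opening = 12, gap_extension = 0.5) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", gapOpening = gap_opening, gapExtension = gap_extension
  )
  100 * Biostrings::nmatch(al) / Biostrings::nchar(al)
}

# All k-mers of a single sequence (character vector, possibly with < k tail
# removed). Used by the recruitment index and the assembler.
seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(x, starts, starts + k - 1L)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}", what), call. = FALSE)
  }
  invisible(x)
}
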