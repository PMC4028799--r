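## Structural comparison of recovered gene copies to the reference and
## functionality prediction by translation.

# Global affine-gap alignment of copy vs reference returning the gapped
# strings; shared by deletion detection and CDS projection.
copy_ref_alignment <- function(copy, reference) {
  # explicit scoring: a high gap-opening cost keeps a long deletion as one
  # gap instead of splitting it around chance micro-matches
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(copy), Biostrings::DNAString(reference),
    type = "global", substitutionMatrix = sub,
    gapOpening = 40, gapExtension = 0.5)
  list(al = al,
       pa = str_chars(as.character(Biostrings::alignedPattern(al))),
       sa = str_chars(as.character(Biostrings::alignedSubject(al))))
}

#' Detect structural deletions in a gene copy
#'
#' Aligns the copy globally against the reference gene and reports maximal
#' runs of reference positions absent from the copy, in 1-based inclusive
#' reference coordinates.
#'
#' @param copy recovered copy sequence.
#' @param reference reference gene sequence.
#' @param min_del_len minimum deletion length reported, bp.
#' @return data.frame: `start`, `end`, `length`.
#' @export
detect_structural_deletions <- function(copy, reference, min_del_len = 10L) {
  aln <- copy_ref_alignment(copy, reference)
  ident <- Biostrings::nmatch(aln$al) / nchar(reference)
  if (ident < 0.5) {
    stop("not homologous: alignment identity below 50%", call. = FALSE)
  }
  pa <- aln$pa; sa <- aln$sa
  # left-normalise score-neutral gap placements so equivalent deletions are
  # always reported at their leftmost coordinates
  r <- rle(pa == "-")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (g in which(r$values)) {
    c1 <- starts[g]; c2 <- ends[g]
    while (c1 > 1L && pa[c1 - 1L] != "-" && sa[c1 - 1L] != "-" && sa[c2] != "-" &&
           pa[c1 - 1L] == sa[c2]) {
      pa[c2] <- pa[c1 - 1L]
      pa[c1 - 1L] <- "-"
      c1 <- c1 - 1L; c2 <- c2 - 1L
    }
  }
  ref_col <- sa != "-"
  refpos <- cumsum(ref_col)
  is_del <- ref_col & pa == "-"
  if (!any(is_del)) {
    return(data.frame(start = integer(0), end = integer(0), length = integer(0)))
  }
  rr <- rle(is_del)
  ends_col <- cumsum(rr$lengths)
  starts_col <- ends_col - rr$lengths + 1L
  sel <- which(rr$values)
  out <- data.frame(start = refpos[starts_col[sel]], end = refpos[ends_col[sel]])
  out$length <- out$end - out$start + 1L
  out[out$length >= min_del_len, , drop = FALSE]
}

normalize_cds_model <- function(cds) {
  if (is.numeric(cds) && length(cds) == 2L) {
    return(data.frame(start = cds[[1]], end = cds[[2]]))
  }
  if (is.list(cds) && !is.null(cds$exons)) return(as.data.frame(cds$exons))
  if (is.data.frame(cds)) return(cds)
  stop("invalid CDS model", call. = FALSE)
}

#' Predict the functionality of a gene copy by translation
#'
#' The copy's coding sequence is inferred by projecting the reference exon
#' intervals through a global pairwise alignment, then translated with the
#' standard genetic code. The copy is called functional only when every
#' indel within the coding region preserves frame, the translation has no
#' internal stop codon, and the protein covers at least `min_cov` of the
#' reference protein length. Non-functional calls carry the failure reason
#' (frameshift, premature stop, or truncated).
#'
#' @param copy recovered copy sequence.
#' @param reference reference gene sequence.
#' @param cds reference CDS model: `c(start, end)` for a single-exon gene or
#'   a data.frame of exon `start`/`end` intervals (reference coordinates,
#'   1-based inclusive, in translation order).
#' @param min_cov minimum protein-length coverage for a functional call.
#' @return a `function_call` list: `verdict` ("functional"/"non-functional"),
#'   `reason` ("intact", "frameshift", "premature stop", "truncated"),
#'   `protein` (the translation), `coverage`.
#' @export
classify_copy_functionality <- function(copy, reference, cds, min_cov = 0.95) {
  exons <- normalize_cds_model(cds)
  aln <- copy_ref_alignment(copy, reference)
  ident <- Biostrings::nmatch(aln$al) / nchar(reference)
  if (ident < 0.5) {
    stop("not homologous: alignment identity below 50%", call. = FALSE)
  }
  ref_col <- aln$sa != "-"
  refpos <- ifelse(ref_col, cumsum(ref_col), NA_integer_)
  frameshift <- FALSE
  cds_chars <- character(0)
  covered <- 0L
  total_ref <- 0L
  prev_exon_offset <- 0L
  for (e in seq_len(nrow(exons))) {
    s <- exons$start[e]; en <- exons$end[e]
    total_ref <- total_ref + (en - s + 1L)
    cols_in <- which(!is.na(refpos) & refpos >= s & refpos <= en)
    if (!length(cols_in)) next
    span <- min(cols_in):max(cols_in)
    pa_span <- aln$pa[span]
    sa_span <- aln$sa[span]
    # indel runs within the exon: any run not a multiple of 3 shifts frame
    indel <- pa_span == "-" | sa_span == "-"
    if (any(indel)) {
      r <- rle(indel)
      if (any(r$lengths[r$values] %% 3L != 0L)) frameshift <- TRUE
    }
    covered <- covered + sum(sa_span != "-" & pa_span != "-")
    cds_chars <- c(cds_chars, pa_span[pa_span != "-"])
    # frame must also be preserved across the exon junction
    net <- sum(sa_span == "-") - sum(pa_span == "-")
    prev_exon_offset <- prev_exon_offset + net
    if (prev_exon_offset %% 3L != 0L) frameshift <- TRUE
  }
  coverage <- covered / total_ref
  cds_seq <- chars_str(cds_chars)
  prot <- ""
  premature <- FALSE
  if (nchar(cds_seq) >= 3L) {
    trim <- 3L * (nchar(cds_seq) %/% 3L)
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(cds_seq, 1L, trim)),
      if.fuzzy.codon = "X"))
    stops <- gregexpr("*", prot, fixed = TRUE)[[1]]
    stops <- stops[stops > 0]
    premature <- any(stops < nchar(prot))
  }
  reason <- if (frameshift) "frameshift"
  else if (premature) "premature stop"
  else if (coverage < min_cov) "truncated"
  else "intact"
  structure(list(
    verdict = if (reason == "intact") "functional" else "non-functional",
    reason = reason, protein = prot, coverage = coverage),
    class = "function_call")
}

#' @export
print.function_call <- function(x, ...) {
  cat(sprintf("<function_call> %s (%s), CDS coverage %.1f%%\n",
              x$verdict, x$reason, 100 * x$coverage))
  invisible(x)
}
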