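#' Parse FASTA
#'
#' Reads FASTA from a file path or from literal text. Sequences are
#' uppercased and validated against the DNA alphabet {A,C,G,T,N}; malformed
#' records raise an error naming the offending line so that broken inputs are
#' caught at the boundary rather than downstream.
#'
#' @param x path to a FASTA file, or a character scalar/vector of FASTA text.
#' @return named character vector of sequences; per-record descriptions (text
#'   after the first whitespace in the header) are kept in the
#'   `"description"` attribute.
#' @export
parse_fasta <- function(x) {
  lines <- if (length(x) == 1L && !grepl("[>\n]", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\r$", "", lines)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("FASTA input is empty", call. = FALSE)
  if (!startsWith(lines[nonempty[1]], ">")) {
    stop(sprintf("FASTA format error at line %d: expected '>'", nonempty[1]),
         call. = FALSE)
  }
  hdr <- startsWith(lines, ">")
  rec <- cumsum(hdr)
  ids <- character(0); desc <- character(0); seqs <- character(0)
  for (r in seq_len(max(rec))) {
    sel <- which(rec == r)
    header <- sub("^>", "", lines[sel[1]])
    id <- sub("\\s.*$", "", header)
    dsc <- ifelse(grepl("\\s", header), sub("^\\S+\\s+", "", header), "")
    if (!nzchar(id)) {
      stop(sprintf("FASTA format error at line %d: empty record id", sel[1]),
           call. = FALSE)
    }
    body <- lines[sel[-1]]
    body <- body[nzchar(trimws(body))]
    sq <- toupper(paste(body, collapse = ""))
    if (!nzchar(sq)) {
      stop(sprintf("FASTA format error at line %d: record '%s' has empty sequence",
                   sel[1], id), call. = FALSE)
    }
    bad <- regexpr("[^ACGTN]", sq)
    if (bad > 0) {
      off <- cumsum(nchar(body))
      ln <- sel[1] + which(off >= bad)[1]
      stop(sprintf("FASTA format error at line %d: illegal character '%s' in '%s'",
                   ln, substr(sq, bad, bad), id), call. = FALSE)
    }
    ids <- c(ids, id); desc <- c(desc, dsc); seqs <- c(seqs, sq)
  }
  names(seqs) <- ids
  attr(seqs, "description") <- desc
  seqs
}

#' Write FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

new_read_pairs <- function(id, seq1, qual1, seq2, qual2) {
  stopifnot(length(id) == length(seq1), length(seq1) == length(seq2),
            length(qual1) == length(seq1), length(qual2) == length(seq2))
  if (any(nchar(qual1) != nchar(seq1)) || any(nchar(qual2) != nchar(seq2))) {
    stop("quality/sequence length mismatch", call. = FALSE)
  }
  structure(list(id = id, seq1 = seq1, qual1 = qual1,
                 seq2 = seq2, qual2 = qual2),
            class = "read_pairs")
}

#' @export
length.read_pairs <- function(x) length(x$id)

#' @export
`[.read_pairs` <- function(x, i) {
  new_read_pairs(x$id[i], x$seq1[i], x$qual1[i], x$seq2[i], x$qual2[i])
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("<read_pairs> %d pairs\n", length(x)))
  invisible(x)
}

#' Decoded Phred scores of a read-pair set
#'
#' @param pairs a `read_pairs` object.
#' @param mate 1 or 2.
#' @return list of integer vectors (one per read).
#' @export
phred_scores <- function(pairs, mate = 1L) {
  qs <- if (mate == 1L) pairs$qual1 else pairs$qual2
  lapply(qs, phred_decode)
}

parse_fastq_one <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("FASTQ format error in '%s': truncated record (line count %d not a multiple of 4)",
                 path, length(lines)), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  at <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(at, "@") | !startsWith(pl, "+"))
  if (length(bad)) {
    stop(sprintf("FASTQ format error in '%s' at line %d", path, (bad[1] - 1L) * 4L + 1L),
         call. = FALSE)
  }
  if (any(nchar(sq) != nchar(ql))) {
    i <- which(nchar(sq) != nchar(ql))[1]
    stop(sprintf("FASTQ format error in '%s' at line %d: quality/sequence length mismatch",
                 path, (i - 1L) * 4L + 4L), call. = FALSE)
  }
  q <- unlist(lapply(ql, function(s) range(utf8ToInt(s))))
  if (length(q) && (min(q) < 33L || max(q) > 93L + 33L)) {
    stop(sprintf("FASTQ format error in '%s': quality characters outside Phred+33 range", path),
         call. = FALSE)
  }
  list(id = sub("\\s.*$", "", sub("^@", "", at)), seq = sq, qual = ql)
}

#' Parse synchronized paired FASTQ files
#'
#' The two files must list mates in the same order (position i of each file
#' forms pair i). Qualities are Phred+33 on disk and are decodable with
#' [phred_scores()].
#'
#' @param path_r1,path_r2 FASTQ paths for mate 1 and mate 2.
#' @return a `read_pairs` object.
#' @export
parse_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- parse_fastq_one(path_r1)
  r2 <- parse_fastq_one(path_r2)
  if (length(r1$id) != length(r2$id)) {
    stop(sprintf("unpaired files: %d records in '%s' but %d in '%s'",
                 length(r1$id), path_r1, length(r2$id), path_r2), call. = FALSE)
  }
  new_read_pairs(r1$id, r1$seq, r1$qual, r2$seq, r2$qual)
}

#' Write a read-pair set as two FASTQ files
#'
#' @param pairs a `read_pairs` object.
#' @param path_r1,path_r2 output FASTQ paths.
#' @export
write_fastq_pairs <- function(pairs, path_r1, path_r2) {
  wr <- function(ids, sq, ql, path, mate) {
    writeLines(as.vector(rbind(paste0("@", ids, "/", mate), sq, "+", ql)), path)
  }
  wr(pairs$id, pairs$seq1, pairs$qual1, path_r1, 1L)
  wr(pairs$id, pairs$seq2, pairs$qual2, path_r2, 2L)
  invisible(c(path_r1, path_r2))
}

#' Read and write Newick trees
#'
#' Wrappers around [ape::read.tree()] / [ape::write.tree()] that validate
#' leaf-label uniqueness and keep internal node labels (bootstrap supports)
#' intact.
#'
#' @param x a Newick string or file path (for `read_newick`); an `ape::phylo`
#'   tree (for `write_newick`).
#' @param path optional output path; when `NULL` the Newick string is
#'   returned.
#' @return `read_newick`: an `ape::phylo` object. `write_newick`: the Newick
#'   string (invisibly, when written to a file).
#' @export
read_newick <- function(x) {
  tr <- if (length(x) == 1L && !grepl("[();]", x) && file.exists(x)) {
    ape::read.tree(file = x)
  } else {
    ape::read.tree(text = x)
  }
  if (is.null(tr)) stop("Newick parse error", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop("Newick parse error: duplicate leaf labels", call. = FALSE)
  }
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "phylo"))
  s <- ape::write.tree(x, digits = 12)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
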