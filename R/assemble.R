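## Minimal de Bruijn assembler.
##
## Contigs are maximal non-branching paths of the k-mer graph after
## low-frequency k-mer pruning; isolated cycles (the circular mitochondrial
## genome at high depth) are walked as circular contigs. Strands are kept
## separate during graph construction and reverse-complement duplicate
## contigs are collapsed afterwards.

# k-mer multiplicity table of a read set.
count_kmers <- function(reads, k) {
  reads <- reads[nchar(reads) >= k]
  if (!length(reads)) return(data.table(kmer = character(0), n = integer(0)))
  maxlen <- max(nchar(reads))
  parts <- vector("list", maxlen - k + 1L)
  for (off in seq_len(maxlen - k + 1L)) {
    sub <- substr(reads, off, off + k - 1L)
    parts[[off]] <- sub[nchar(sub) == k]
  }
  dt <- data.table(kmer = unlist(parts, use.names = FALSE))
  dt[, .(n = .N), by = kmer]
}

# Pruning threshold: max(2, depth mode / 20), the depth mode taken over
# multiplicities >= 2 so that singleton error k-mers do not define it.
prune_threshold <- function(counts) {
  tb <- counts[n >= 2L, .N, by = n]
  if (!nrow(tb)) return(2L)
  setorder(tb, -N, n)
  max(2L, as.integer(round(tb$n[1L] / 20)))
}

#' Assemble contigs from reads with a de Bruijn graph
#'
#' @param reads character vector of reads, or a `read_pairs` object (both
#'   mates are used).
#' @param k odd k-mer size, smaller than the read length.
#' @param min_contig_len contigs shorter than this are dropped.
#' @param prune k-mer multiplicity pruning threshold; derived from the depth
#'   mode when `NULL`.
#' @return data.frame of contigs: `id`, `seq`, `length`, `depth` (mean
#'   combined-strand k-mer multiplicity), `circular`.
#' @export
assemble_contigs <- function(reads, k, min_contig_len = 200L, prune = NULL) {
  if (inherits(reads, "read_pairs")) reads <- c(reads$seq1, reads$seq2)
  stopifnot(k %% 2L == 1L)
  counts <- count_kmers(reads, k)
  if (!nrow(counts)) {
    warning("no k-mers of length ", k, " in the read set")
    return(empty_contigs())
  }
  thr <- prune %||% prune_threshold(counts)
  counts <- counts[n >= thr]
  if (!nrow(counts)) {
    warning("no k-mers survive pruning at threshold ", thr)
    return(empty_contigs())
  }
  K <- counts$kmer
  cnt <- counts$n
  N <- length(K)
  suf <- substr(K, 2L, k)
  pre <- substr(K, 1L, k - 1L)
  succ <- matrix(NA_integer_, N, 4L)
  pred <- matrix(NA_integer_, N, 4L)
  for (b in seq_along(DNA_BASES)) {
    succ[, b] <- match(paste0(suf, DNA_BASES[b]), K)
    pred[, b] <- match(paste0(DNA_BASES[b], pre), K)
  }
  out_deg <- rowSums(!is.na(succ))
  in_deg <- rowSums(!is.na(pred))
  succ1 <- succ[, 1L]
  pred1 <- pred[, 1L]
  for (b in 2:4) {
    na <- is.na(succ1); succ1[na] <- succ[na, b]
    na <- is.na(pred1); pred1[na] <- pred[na, b]
  }
  # a unitig starts where the walk cannot be extended backwards unambiguously
  start <- in_deg != 1L | (out_deg[ifelse(is.na(pred1), 1L, pred1)] != 1L & in_deg == 1L)
  visited <- logical(N)
  paths <- list()
  circ <- logical(0)
  for (s in which(start)) {
    if (visited[s]) next
    path <- s
    visited[s] <- TRUE
    cur <- s
    while (out_deg[cur] == 1L) {
      nxt <- succ1[cur]
      if (is.na(nxt) || visited[nxt] || in_deg[nxt] != 1L || start[nxt]) break
      path <- c(path, nxt)
      visited[nxt] <- TRUE
      cur <- nxt
    }
    # a walk that returns to its own start spells a circle even when a
    # spurious branch made the start node look like a unitig boundary
    closes <- length(path) > 2L && any(succ[cur, ] == path[1L], na.rm = TRUE)
    paths[[length(paths) + 1L]] <- path
    circ <- c(circ, closes)
  }
  # remaining unvisited nodes lie on simple cycles
  for (s in which(!visited)) {
    if (visited[s]) next
    path <- s
    visited[s] <- TRUE
    cur <- s
    repeat {
      nxt <- succ1[cur]
      if (is.na(nxt) || nxt == path[1L]) break
      if (visited[nxt]) break
      path <- c(path, nxt)
      visited[nxt] <- TRUE
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- path
    circ <- c(circ, TRUE)
  }
  if (!length(paths)) return(empty_contigs())
  rc_idx <- match(revcomp(K), K)
  seqs <- vapply(paths, function(p) {
    if (length(p) == 1L) return(K[p])
    paste0(K[p[1L]], paste(substr(K[p[-1L]], k, k), collapse = ""))
  }, character(1))
  depth <- vapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    rc <- rc_idx[p]
    mean(cnt[p] + ifelse(is.na(rc), 0L, cnt[ifelse(is.na(rc), 1L, rc)]))
  }, numeric(1))
  # a circular walk of n k-mers spells n + k - 1 characters whose ends share
  # k - 1 characters; trim to the n-character rotation of the circle
  seqs[circ] <- substr(seqs[circ], 1L, nchar(seqs[circ]) - (k - 1L))
  # collapse strand duplicates: a contig contained in an already-kept
  # contig (or its reverse complement; circular contigs are doubled so
  # containment is rotation-free) carries no extra sequence
  lens <- nchar(seqs)
  ord <- order(-lens)
  keep <- rep(TRUE, length(seqs))
  haystacks <- character(0)
  for (i in ord) {
    s <- seqs[i]
    rs <- revcomp(s)
    dup <- length(haystacks) > 0L &&
      any(vapply(haystacks, function(h) {
        grepl(s, h, fixed = TRUE) || grepl(rs, h, fixed = TRUE)
      }, logical(1)))
    if (dup) {
      keep[i] <- FALSE
    } else {
      haystacks <- c(haystacks, if (circ[i]) paste0(s, s) else s)
    }
  }
  keep <- keep & lens >= min_contig_len
  if (!any(keep)) return(empty_contigs())
  o <- order(-lens[keep])
  data.frame(
    id = sprintf("contig_%03d", seq_len(sum(keep))),
    seq = seqs[keep][o],
    length = lens[keep][o],
    depth = depth[keep][o],
    circular = circ[keep][o],
    stringsAsFactors = FALSE
  )
}

empty_contigs <- function() {
  data.frame(id = character(0), seq = character(0), length = integer(0),
             depth = numeric(0), circular = logical(0), stringsAsFactors = FALSE)
}
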