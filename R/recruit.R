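## Reference-guided read recruitment and padding.
##
## A similarity search in the BLAST mould, built from exact k-mer seeding
## (seed length 13) plus ungapped diagonal extension, with significance
## assessed through the Karlin-Altschul formula E = K m n exp(-lambda S)
## using fixed nucleotide parameters for +1/-2 scoring. Reads recruited to a
## marker gene are oriented to reference sense and padded to reference
## coordinates so they stack into reference-frame columns.

KA_LAMBDA <- 1.28
KA_K <- 0.46
SEED_LEN <- 13L

# First-occurrence k-mer index of the reference.
ref_kmer_index <- function(ref, k = SEED_LEN) {
  kms <- seq_kmers(ref, k)
  first <- !duplicated(kms)
  list(kmers = kms[first], pos = which(first), k = k, ref_len = nchar(ref))
}

# Best seed diagonal per read: for every read offset, look its k-mer up in
# the reference index; the modal diagonal (ref position of read base 1) with
# the most seed support wins, ties to the smallest diagonal.
seed_diagonals <- function(reads, index) {
  k <- index$k
  maxlen <- max(nchar(reads), 0L)
  if (maxlen < k || length(reads) == 0L) {
    return(data.table(read = integer(0), diag = integer(0), support = integer(0)))
  }
  hits <- vector("list", maxlen - k + 1L)
  for (off in seq_len(maxlen - k + 1L)) {
    sub <- substr(reads, off, off + k - 1L)
    m <- match(sub, index$kmers)
    sel <- which(!is.na(m) & nchar(sub) == k)
    if (length(sel)) {
      hits[[off]] <- data.table(read = sel, diag = index$pos[m[sel]] - off + 1L)
    }
  }
  dt <- rbindlist(hits)
  if (!nrow(dt)) {
    return(data.table(read = integer(0), diag = integer(0), support = integer(0)))
  }
  dt <- dt[, .N, by = .(read, diag)]
  setorder(dt, read, -N, diag)
  dt <- dt[, .SD[1L], by = read]
  setnames(dt, "N", "support")
  dt
}

# Maximal-scoring ungapped segment (match +1 / mismatch -2) of a read placed
# at a given diagonal. Returns the segment bounds in read coordinates, its
# score and its match count.
diagonal_segment <- function(read_int, ref_int, diag) {
  rl <- length(read_int)
  refL <- length(ref_int)
  p_lo <- max(1L, 2L - diag)
  p_hi <- min(rl, refL - diag + 1L)
  if (p_lo > p_hi) return(list(score = -Inf))
  mm <- read_int[p_lo:p_hi] == ref_int[(diag + p_lo - 1L):(diag + p_hi - 1L)]
  s <- ifelse(mm, 1, -2)
  cs <- cumsum(s)
  prefix <- c(0, cs[-length(cs)])
  best_end <- cs - cummin(prefix)
  p2r <- which.max(best_end)
  score <- best_end[p2r]
  pref_sub <- c(0, cs)[1:p2r]
  p1r <- which.min(pref_sub)[1]
  p1 <- p_lo + p1r - 1L
  p2 <- p_lo + p2r - 1L
  list(score = score, p1 = p1, p2 = p2,
       matches = sum(mm[p1r:p2r]), len = p2 - p1 + 1L)
}

ka_evalue <- function(score, m, n) {
  if (!is.finite(score)) return(Inf)
  KA_K * m * n * exp(-KA_LAMBDA * score)
}

# Score one orientation of a set of reads against the reference; returns a
# data.table(read, diag, score, evalue, p1, p2).
score_orientation <- function(reads, index, ref_int) {
  sd <- seed_diagonals(reads, index)
  if (!nrow(sd)) {
    return(data.table(read = integer(0), diag = integer(0), score = numeric(0),
                      evalue = numeric(0), p1 = integer(0), p2 = integer(0)))
  }
  res <- lapply(seq_len(nrow(sd)), function(i) {
    r <- sd$read[i]
    seg <- diagonal_segment(utf8ToInt(reads[r]), ref_int, sd$diag[i])
    data.table(read = r, diag = sd$diag[i], score = seg$score,
               evalue = ka_evalue(seg$score, nchar(reads[r]), index$ref_len),
               p1 = seg$p1 %||% NA_integer_, p2 = seg$p2 %||% NA_integer_)
  })
  rbindlist(res)
}

#' Recruit read pairs matching a reference gene
#'
#' A pair is recruited when either mate has a seeded ungapped hit with
#' E-value at or below the threshold; both mates of a recruited pair are
#' returned. Mates hitting in antisense orientation -- and, by the FR mate
#' geometry, the partner of any hitting mate -- are reverse-complemented so
#' every returned read is in reference sense.
#'
#' @param pairs a `read_pairs` object (typically quality-trimmed).
#' @param reference reference gene sequence (character scalar).
#' @param evalue_threshold recruitment E-value cut-off.
#' @param k seed length.
#' @return a `recruited_reads` data.table: one row per mate of each
#'   recruited pair with columns `id`, `mate`, `seq`, `qual` (both oriented
#'   to reference sense), `flipped`, `has_hit`, `diag`, `score`, `evalue`.
#' @export
recruit_read_pairs <- function(pairs, reference, evalue_threshold = 0.1,
                               k = SEED_LEN) {
  if (nchar(reference) < k) {
    stop("recruit_read_pairs: reference shorter than seed length", call. = FALSE)
  }
  index <- ref_kmer_index(reference, k)
  ref_int <- utf8ToInt(reference)
  n <- length(pairs)
  if (n == 0L) return(empty_recruited())

  orient_best <- function(fwd, rev) {
    sf <- score_orientation(fwd, index, ref_int)
    sr <- score_orientation(rev, index, ref_int)
    best <- data.table(read = seq_along(fwd), score = -Inf, evalue = Inf,
                       diag = NA_integer_, p1 = NA_integer_, p2 = NA_integer_,
                       flipped = FALSE)
    if (nrow(sf)) {
      best[sf$read, `:=`(score = sf$score, evalue = sf$evalue, diag = sf$diag,
                         p1 = sf$p1, p2 = sf$p2, flipped = FALSE)]
    }
    if (nrow(sr)) {
      upd <- sr[sr$score > best$score[sr$read]]
      if (nrow(upd)) {
        best[upd$read, `:=`(score = upd$score, evalue = upd$evalue,
                            diag = upd$diag, p1 = upd$p1, p2 = upd$p2,
                            flipped = TRUE)]
      }
    }
    best
  }
  rc1 <- revcomp(pairs$seq1)
  rc2 <- revcomp(pairs$seq2)
  b1 <- orient_best(pairs$seq1, rc1)
  b2 <- orient_best(pairs$seq2, rc2)
  hit1 <- b1$evalue <= evalue_threshold
  hit2 <- b2$evalue <= evalue_threshold
  recruited <- which(hit1 | hit2)
  if (!length(recruited)) return(empty_recruited())

  rows <- lapply(recruited, function(i) {
    f1 <- if (hit1[i]) b1$flipped[i] else !b2$flipped[i]
    f2 <- if (hit2[i]) b2$flipped[i] else !b1$flipped[i]
    s1 <- if (f1) rc1[i] else pairs$seq1[i]
    s2 <- if (f2) rc2[i] else pairs$seq2[i]
    q1 <- if (f1) paste(rev(str_chars(pairs$qual1[i])), collapse = "") else pairs$qual1[i]
    q2 <- if (f2) paste(rev(str_chars(pairs$qual2[i])), collapse = "") else pairs$qual2[i]
    data.table(
      id = pairs$id[i], mate = 1:2, seq = c(s1, s2), qual = c(q1, q2),
      flipped = c(f1, f2), has_hit = c(hit1[i], hit2[i]),
      diag = c(if (hit1[i]) b1$diag[i] else NA_integer_,
               if (hit2[i]) b2$diag[i] else NA_integer_),
      score = c(if (hit1[i]) b1$score[i] else NA_real_,
                if (hit2[i]) b2$score[i] else NA_real_),
      evalue = c(if (hit1[i]) b1$evalue[i] else NA_real_,
                 if (hit2[i]) b2$evalue[i] else NA_real_))
  })
  out <- rbindlist(rows)
  setattr(out, "reference", reference)
  setattr(out, "seed_len", k)
  setattr(out, "class", c("recruited_reads", class(out)))
  out[]
}

empty_recruited <- function() {
  out <- data.table(id = character(0), mate = integer(0), seq = character(0),
                    qual = character(0), flipped = logical(0),
                    has_hit = logical(0), diag = integer(0),
                    score = numeric(0), evalue = numeric(0))
  setattr(out, "class", c("recruited_reads", class(out)))
  out
}

# Left-normalise internal gap runs of a reference-frame placement: when the
# placed base just left of a gap matches the reference base under the gap's
# right end, the two representations score equally and the leftmost is
# canonical (keeps junction columns consistent across reads).
normalize_placed_gaps <- function(placed, start, ref_int) {
  if (!grepl("-", placed, fixed = TRUE)) return(placed)
  ch <- str_chars(placed)
  r <- rle(ch == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (g in which(r$values)) {
    c1 <- starts[g]; c2 <- ends[g]
    while (c1 > 1L && ch[c1 - 1L] != "-" &&
           utf8ToInt(ch[c1 - 1L]) == ref_int[start + c2 - 1L]) {
      ch[c2] <- ch[c1 - 1L]
      ch[c1 - 1L] <- "-"
      c1 <- c1 - 1L; c2 <- c2 - 1L
    }
  }
  chars_str(ch)
}

# Reference-frame placement string from a Biostrings local alignment:
# deletions relative to the reference become '-', read insertions are
# dropped, so the placed string advances one reference column per character.
ref_frame_placement <- function(read, window, window_offset) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(window),
    type = "local", gapOpening = 8, gapExtension = 2)
  pa <- str_chars(as.character(Biostrings::alignedPattern(al)))
  sa <- str_chars(as.character(Biostrings::alignedSubject(al)))
  keep <- sa != "-"
  placed <- chars_str(pa[keep])
  start <- window_offset + Biostrings::start(Biostrings::subject(al)) - 1L
  list(start = start, placed = placed, score = Biostrings::score(al))
}

#' Pad recruited reads to reference coordinates
#'
#' Places each oriented read at the start coordinate of its best hit.
#' Placement is the maximal-scoring ungapped diagonal segment; reads with a
#' large unexplained remainder are either split across a reference gap
#' (deletion-spanning reads, emitted with an internal '-' run) or re-aligned
#' with an affine-gap local aligner against a reference window (small
#' indels). Reads with no scorable placement are routed to the unplaced bin,
#' not an error. Mates are placed independently and remain linked by their
#' shared pair id.
#'
#' @param rec a `recruited_reads` table from [recruit_read_pairs()].
#' @param reference the same reference gene sequence.
#' @param min_segment minimum placed-segment length, bp.
#' @return a `padded_stack` data.table with columns `id`, `mate`, `start`
#'   (1-based reference coordinate of the first placed base) and `placed`
#'   (sequence over A/C/G/T/N/'-' advancing one reference column per
#'   character). Unplaced reads are kept in the `"unplaced"` attribute.
#' @export
pad_to_reference <- function(rec, reference, min_segment = 25L) {
  index <- ref_kmer_index(reference, attr(rec, "seed_len") %||% SEED_LEN)
  ref_int <- utf8ToInt(reference)
  refL <- length(ref_int)
  placed_rows <- vector("list", nrow(rec))
  unplaced <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    read <- rec$seq[i]
    diag <- rec$diag[i]
    if (is.na(diag)) {
      sd <- seed_diagonals(read, index)
      if (!nrow(sd)) { unplaced[i] <- TRUE; next }
      diag <- sd$diag[1]
    }
    seg <- diagonal_segment(utf8ToInt(read), ref_int, diag)
    if (!is.finite(seg$score) || seg$len < min_segment) { unplaced[i] <- TRUE; next }
    placed <- substr(read, seg$p1, seg$p2)
    start <- diag + seg$p1 - 1L
    rl <- nchar(read)
    right_rem <- rl - seg$p2
    left_rem <- seg$p1 - 1L
    split_done <- FALSE
    if (max(right_rem, left_rem) >= 20L) {
      rem_is_right <- right_rem >= left_rem
      rem <- if (rem_is_right) substr(read, seg$p2 + 1L, rl) else substr(read, 1L, seg$p1 - 1L)
      sd2 <- seed_diagonals(rem, index)
      if (nrow(sd2)) {
        off0 <- if (rem_is_right) seg$p2 else 0L
        seg2 <- diagonal_segment(utf8ToInt(rem), ref_int, sd2$diag[1])
        if (is.finite(seg2$score) && seg2$len >= 15L) {
          s2 <- sd2$diag[1] + seg2$p1 - 1L
          e1 <- start + nchar(placed) - 1L
          read_gap <- if (rem_is_right) seg2$p1 - 1L else left_rem - seg2$p2
          if (rem_is_right && s2 > e1 && read_gap <= 8L) {
            gap_len <- s2 - e1 - 1L
            placed <- paste0(placed, strrep("-", gap_len),
                             substr(rem, seg2$p1, seg2$p2))
            split_done <- TRUE
          } else if (!rem_is_right) {
            e2 <- s2 + seg2$len - 1L
            if (e2 < start && read_gap <= 8L) {
              gap_len <- start - e2 - 1L
              placed <- paste0(substr(rem, seg2$p1, seg2$p2),
                               strrep("-", gap_len), placed)
              start <- s2
              split_done <- TRUE
            }
          }
        }
      }
      if (!split_done && seg$matches / seg$len < 0.95) {
        # small indels: gapped re-alignment against a local window
        w0 <- max(1L, diag - 60L)
        w1 <- min(refL, diag + rl + 60L)
        fit <- ref_frame_placement(read, substr(reference, w0, w1), w0)
        if (nchar(fit$placed) >= min_segment) {
          placed <- fit$placed
          start <- fit$start
        }
      }
    }
    placed <- normalize_placed_gaps(placed, start, ref_int)
    placed_rows[[i]] <- data.table(id = rec$id[i], mate = rec$mate[i],
                                   start = start, placed = placed)
  }
  out <- rbindlist(placed_rows[!unplaced & !vapply(placed_rows, is.null, logical(1))])
  if (nrow(out) == 0L) {
    out <- data.table(id = character(0), mate = integer(0),
                      start = integer(0), placed = character(0))
  }
  setattr(out, "unplaced", rec[unplaced, c("id", "mate", "seq")])
  setattr(out, "ref_len", refL)
  setattr(out, "class", c("padded_stack", class(out)))
  out[]
}
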