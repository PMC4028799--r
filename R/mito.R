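## Mitochondrial genome recovery.
##
## Contigs of mitochondrial origin are recognised by similarity to a
## reference mt genome combined with a read-depth coverage cut-off that
## exploits the organelle's high copy number; they are then ordered and
## merged against the reference, assembly gaps are confirmed by junction-
## spanning reads, and the protein-gene complement is annotated and
## concatenated in reference gene order.

# Anchor-chain mapping of a contig onto a reference: exact 21-mer anchors
# grouped into near-diagonal segments, on the better-supported strand.
map_to_reference <- function(contig, ref, k = 21L, max_diag_jump = 30L) {
  refk <- seq_kmers(ref, k)
  first <- !duplicated(refk)
  refk_u <- refk[first]
  refpos <- which(first)
  chain <- function(seqo) {
    kms <- seq_kmers(seqo, k)
    m <- match(kms, refk_u)
    hit <- which(!is.na(m))
    if (!length(hit)) return(NULL)
    cpos <- hit
    rpos <- refpos[m[hit]]
    o <- order(cpos)
    cpos <- cpos[o]; rpos <- rpos[o]
    diag <- rpos - cpos
    brk <- c(TRUE, abs(diff(diag)) > max_diag_jump | diff(rpos) <= 0L)
    grp <- cumsum(brk)
    segs <- data.table(cpos, rpos, grp)[, .(
      ref_start = min(rpos), ref_end = max(rpos) + k - 1L,
      contig_start = min(cpos), contig_end = max(cpos) + k - 1L,
      anchors = .N), by = grp][, grp := NULL]
    segs[order(ref_start)]
  }
  fwd <- chain(contig)
  rev <- chain(revcomp(contig))
  n_f <- if (is.null(fwd)) 0L else sum(fwd$anchors)
  n_r <- if (is.null(rev)) 0L else sum(rev$anchors)
  if (n_f == 0L && n_r == 0L) {
    return(list(strand = NA_character_, segments = NULL, anchored = 0L))
  }
  if (n_f >= n_r) {
    list(strand = "+", segments = fwd[fwd$anchors >= 2L | fwd$ref_end - fwd$ref_start >= 40L],
         anchored = n_f)
  } else {
    list(strand = "-", segments = rev[rev$anchors >= 2L | rev$ref_end - rev$ref_start >= 40L],
         anchored = n_r)
  }
}

#' Classify contigs of mitochondrial origin
#'
#' Candidate contigs must hit the reference mt genome at the configured
#' E-value (exact-match anchor chains scored with the Karlin-Altschul
#' formula). The coverage cut-off is then located at the valley separating
#' the high-depth (mitochondrial) mode from the low-depth (nuclear) mode of
#' the log-depth distribution, and the mt set is the candidates at or above
#' the cut-off. With a unimodal depth distribution the classification falls
#' back to similarity only, with a warning.
#'
#' @param contigs contig data.frame from [assemble_contigs()].
#' @param ref_mt reference mitochondrial genome sequence.
#' @param mt_evalue similarity threshold.
#' @param coverage_cutoff fixed cut-off (k-mer depth units); located from
#'   the depth distribution when `NULL`.
#' @return list with `mt_contigs` (subset of `contigs`), `coverage_cutoff`
#'   (k-mer depth units; `NA` in the similarity-only fallback), `method`,
#'   and `candidates` (similarity hits before the depth filter).
#' @export
classify_mt_contigs <- function(contigs, ref_mt, mt_evalue = 0.001,
                                coverage_cutoff = NULL) {
  if (nrow(contigs) == 0L) {
    stop("classify_mt_contigs: no contigs", call. = FALSE)
  }
  maps <- lapply(contigs$seq, map_to_reference, ref = ref_mt)
  span <- vapply(maps, function(mp) {
    if (is.null(mp$segments) || nrow(mp$segments) == 0L) return(0L)
    sum(mp$segments$ref_end - mp$segments$ref_start + 1L)
  }, integer(1))
  ev <- vapply(seq_len(nrow(contigs)), function(i) {
    if (span[i] == 0L) return(Inf)
    ka_evalue(span[i], contigs$length[i], nchar(ref_mt))
  }, numeric(1))
  cand <- ev <= mt_evalue
  cutoff <- coverage_cutoff %||% depth_valley(contigs$depth)
  if (is.na(cutoff)) {
    warning("unimodal contig depth distribution; similarity-only mt classification")
    sel <- cand
    method <- "similarity-only"
  } else {
    sel <- cand & contigs$depth >= cutoff
    method <- "similarity+coverage"
  }
  list(mt_contigs = contigs[sel, , drop = FALSE],
       coverage_cutoff = cutoff, method = method,
       candidates = contigs[cand, , drop = FALSE])
}

# Valley of a (log-)depth distribution: the minimum of the smoothed density
# between the two dominant modes, or the midpoint of the largest log-gap for
# small contig sets. NA when the distribution looks unimodal.
depth_valley <- function(depths, min_separation = log10(5)) {
  d <- log10(depths[depths > 0])
  if (length(d) < 2L) return(NA_real_)
  if (length(unique(round(d, 6))) < 2L) return(NA_real_)
  if (length(d) >= 10L) {
    dens <- stats::density(d, bw = "nrd0")
    y <- dens$y; x <- dens$x
    is_max <- which(diff(sign(diff(y))) == -2) + 1L
    if (length(is_max) >= 2L) {
      top2 <- is_max[order(-y[is_max])][1:2]
      lo <- min(x[top2]); hi <- max(x[top2])
      if (hi - lo >= min_separation) {
        inner <- which(x > lo & x < hi)
        valley <- inner[which.min(y[inner])]
        return(10^x[valley])
      }
    }
    return(NA_real_)
  }
  ds <- sort(d)
  gaps <- diff(ds)
  i <- which.max(gaps)
  if (gaps[i] < min_separation) return(NA_real_)
  10^((ds[i] + ds[i + 1L]) / 2)
}

#' Order and merge mitochondrial contigs against the reference
#'
#' Contigs are oriented to reference sense and placed by their anchor-chain
#' coordinates; neighbouring contigs whose placements overlap are merged
#' when the overlap is exact over at least 20 bp, and non-overlapping
#' neighbours are joined with a recorded gap at the intervening reference
#' interval. A single circular contig is rotated so the draft starts at
#' reference position 1. Conflicting placements (inconsistent sequence over
#' the same interval) are resolved towards the higher-depth contig and
#' logged in the `conflicts` field.
#'
#' @param mt_contigs mt-classified contig data.frame.
#' @param ref reference mitochondrial genome sequence.
#' @param min_gap smallest reference interval reported as a gap; shorter
#'   uncovered stretches (anchor dropouts over diverged sequence, small
#'   lineage indels) are ignored.
#' @return an `mt_draft` list: `sequence`, `segments` (per-contig reference
#'   extents), `gaps` (1-based inclusive reference intervals), `conflicts`.
#' @export
order_and_merge_contigs <- function(mt_contigs, ref, min_gap = 30L) {
  stopifnot(nrow(mt_contigs) >= 1L)
  conflicts <- character(0)
  oriented <- mt_contigs
  placements <- list()
  for (i in seq_len(nrow(mt_contigs))) {
    mp <- map_to_reference(mt_contigs$seq[i], ref)
    if (is.na(mp$strand)) {
      stop(sprintf("order_and_merge_contigs: contig %s has no reference hit",
                   mt_contigs$id[i]), call. = FALSE)
    }
    s <- mt_contigs$seq[i]
    if (mp$strand == "-") {
      s <- revcomp(s)
      mp <- map_to_reference(s, ref)
    }
    oriented$seq[i] <- s
    placements[[i]] <- mp
  }
  if (nrow(oriented) == 1L && isTRUE(oriented$circular[1L])) {
    s <- oriented$seq[1L]
    mp <- placements[[1L]]
    seg1 <- mp$segments[which.min(mp$segments$ref_start), ]
    rot <- seg1$contig_start - (seg1$ref_start - 1L)
    if (rot < 1L) rot <- rot + nchar(s)
    s <- paste0(substr(s, rot, nchar(s)), substr(s, 1L, rot - 1L))
    mp <- map_to_reference(s, ref)
    segs <- mp$segments
    covered <- interval_union(segs$ref_start, segs$ref_end)
    gaps <- interval_complement(covered, nchar(ref))
    gaps <- gaps[gaps$end - gaps$start + 1L >= min_gap, , drop = FALSE]
    return(structure(list(
      sequence = s,
      segments = data.frame(contig = oriented$id[1L],
                            ref_start = min(segs$ref_start),
                            ref_end = max(segs$ref_end)),
      gaps = gaps, conflicts = conflicts, circular = TRUE),
      class = "mt_draft"))
  }
  ext <- t(vapply(placements, function(mp) {
    c(min(mp$segments$ref_start), max(mp$segments$ref_end))
  }, numeric(2)))
  o <- order(ext[, 1L])
  oriented <- oriented[o, , drop = FALSE]
  ext <- ext[o, , drop = FALSE]
  draft <- oriented$seq[1L]
  cur_end <- ext[1L, 2L]
  segments <- data.frame(contig = oriented$id[1L], ref_start = ext[1L, 1L],
                         ref_end = ext[1L, 2L], stringsAsFactors = FALSE)
  gaps <- list()
  cur_depth <- oriented$depth[1L]
  for (i in seq_len(nrow(oriented))[-1L]) {
    s2 <- oriented$seq[i]
    rs <- ext[i, 1L]; re <- ext[i, 2L]
    if (re <= cur_end) {  # contained; nothing new
      if (oriented$depth[i] > cur_depth) {
        conflicts <- c(conflicts, sprintf("contig %s contained in higher draft", oriented$id[i]))
      }
      next
    }
    if (rs <= cur_end) {
      ov <- cur_end - rs + 1L
      tail_d <- substr(draft, nchar(draft) - ov + 1L, nchar(draft))
      head_c <- substr(s2, 1L, ov)
      if (ov >= 20L && identical(tail_d, head_c)) {
        draft <- paste0(draft, substr(s2, ov + 1L, nchar(s2)))
      } else {
        conflicts <- c(conflicts, sprintf(
          "inconsistent overlap (%d bp) between draft and contig %s; kept higher depth",
          ov, oriented$id[i]))
        if (oriented$depth[i] > cur_depth) {
          draft <- paste0(substr(draft, 1L, nchar(draft) - ov), s2)
        } else {
          draft <- paste0(draft, substr(s2, ov + 1L, nchar(s2)))
        }
      }
    } else {
      if (rs - cur_end - 1L >= min_gap) {
        gaps[[length(gaps) + 1L]] <- c(cur_end + 1L, rs - 1L)
      }
      draft <- paste0(draft, s2)
    }
    segments <- rbind(segments, data.frame(contig = oriented$id[i],
                                           ref_start = rs, ref_end = re))
    cur_end <- re
    cur_depth <- oriented$depth[i]
  }
  gaps <- if (length(gaps)) {
    data.frame(start = vapply(gaps, `[`, numeric(1), 1L),
               end = vapply(gaps, `[`, numeric(1), 2L))
  } else data.frame(start = numeric(0), end = numeric(0))
  for (msg in conflicts) warning(msg, call. = FALSE)
  structure(list(sequence = draft, segments = segments, gaps = gaps,
                 conflicts = conflicts, circular = FALSE),
            class = "mt_draft")
}

interval_union <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  us <- starts[1L]; ue <- ends[1L]
  out <- list()
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= ue + 1L) ue <- max(ue, ends[i])
    else { out[[length(out) + 1L]] <- c(us, ue); us <- starts[i]; ue <- ends[i] }
  }
  out[[length(out) + 1L]] <- c(us, ue)
  do.call(rbind, out)
}

interval_complement <- function(covered, len) {
  gaps <- list()
  prev_end <- 0L
  for (i in seq_len(nrow(covered))) {
    if (covered[i, 1L] > prev_end + 1L) {
      gaps[[length(gaps) + 1L]] <- c(prev_end + 1L, covered[i, 1L] - 1L)
    }
    prev_end <- max(prev_end, covered[i, 2L])
  }
  if (prev_end < len) gaps[[length(gaps) + 1L]] <- c(prev_end + 1L, len)
  if (!length(gaps)) return(data.frame(start = numeric(0), end = numeric(0)))
  m <- do.call(rbind, gaps)
  data.frame(start = m[, 1L], end = m[, 2L])
}

#' Confirm assembly gaps with junction-spanning reads
#'
#' For each recorded gap the two draft flanks abut at a junction; a gap is
#' "confirmed" (a genuine deletion relative to the reference rather than an
#' assembly break) when enough reads span the junction concordantly: at
#' least 15 bp on each side, few mismatches, and no more than
#' `max_gap_openings` alignment gaps (the spanning test here is ungapped).
#'
#' @param pairs a `read_pairs` object (or character vector of reads).
#' @param draft an `mt_draft`.
#' @param reference the reference mt genome (coordinates of the gap report).
#' @param max_gap_openings permitted alignment gap openings.
#' @param min_support spanning reads required for confirmation.
#' @param max_mismatch mismatches tolerated in a spanning read.
#' @return data.frame: `start`, `end`, `support`, `confirmed`.
#' @export
verify_gaps <- function(pairs, draft, reference, max_gap_openings = 5L,
                        min_support = 3L, max_mismatch = 3L) {
  gaps <- draft$gaps
  if (nrow(gaps) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      support = integer(0), confirmed = logical(0)))
  }
  reads <- if (inherits(pairs, "read_pairs")) c(pairs$seq1, pairs$seq2) else pairs
  rl <- max(nchar(reads))
  support <- integer(nrow(gaps))
  for (g in seq_len(nrow(gaps))) {
    # draft coordinate of the junction: reference positions covered before
    # the gap, minus earlier gap intervals (the draft butts flanks together)
    earlier <- gaps$end < gaps$start[g]
    j <- (gaps$start[g] - 1L) - draft$segments$ref_start[1L] + 1L -
      sum((gaps$end - gaps$start + 1L)[earlier])
    w0 <- max(1L, j - rl + 16L)
    w1 <- min(nchar(draft$sequence), j + rl - 15L)
    win <- substr(draft$sequence, w0, w1)
    jloc <- j - w0 + 1L
    idx <- ref_kmer_index(win, 13L)
    win_int <- utf8ToInt(win)
    count_span <- function(rds) {
      sd <- seed_diagonals(rds, idx)
      if (!nrow(sd)) return(0L)
      n <- 0L
      for (i in seq_len(nrow(sd))) {
        r <- rds[sd$read[i]]
        seg <- diagonal_segment(utf8ToInt(r), win_int, sd$diag[i])
        if (!is.finite(seg$score)) next
        a <- sd$diag[i] + seg$p1 - 1L
        b <- sd$diag[i] + seg$p2 - 1L
        mism <- seg$len - seg$matches
        if (a <= jloc - 14L && b >= jloc + 15L && mism <= max_mismatch) n <- n + 1L
      }
      n
    }
    support[g] <- count_span(reads) + count_span(revcomp(reads))
  }
  data.frame(start = gaps$start, end = gaps$end, support = support,
             confirmed = support >= min_support)
}

#' Group gap reports across isolates
#'
#' Gap positions observed in independent isolates of the same taxon support
#' each other; identical (start, end) signatures are grouped.
#'
#' @param reports named list of [verify_gaps()] data.frames (names are
#'   isolate ids).
#' @param taxa optional named character vector mapping isolate id to taxon.
#' @return data.frame: `start`, `end`, `n_isolates`, `isolates`, `taxa`.
#' @export
group_gap_reports <- function(reports, taxa = NULL) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    if (nrow(r) == 0L) return(NULL)
    cbind(isolate = nm, r)
  })
  all <- do.call(rbind, rows)
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_isolates = integer(0), isolates = character(0),
                      taxa = character(0)))
  }
  dt <- as.data.table(all)
  out <- dt[, .(n_isolates = .N, isolates = paste(sort(isolate), collapse = ","),
                taxa = if (is.null(taxa)) "" else
                  paste(sort(unique(taxa[isolate])), collapse = ",")),
            by = .(start, end)]
  as.data.frame(out[order(start)])
}

#' Annotate mitochondrial protein genes
#'
#' Finds, for each reference gene, the best local alignment interval on the
#' mt sequence (either strand) and reports it when the identity over the
#' gene reaches the threshold. Genes are reported in reference order;
#' missing genes are listed in the `"missing"` attribute.
#'
#' @param mt_seq assembled mitochondrial sequence.
#' @param ref_genes named character vector of reference protein genes, in
#'   reference order.
#' @param min_identity minimum identity (0-1).
#' @return data.frame: `gene`, `start`, `end`, `strand`, `identity`
#'   (percent), in reference gene order.
#' @export
annotate_protein_genes <- function(mt_seq, ref_genes, min_identity = 0.7) {
  L <- nchar(mt_seq)
  rc <- revcomp(mt_seq)
  rows <- list(); missing <- character(0)
  for (g in names(ref_genes)) {
    gene <- ref_genes[[g]]
    alf <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(gene), Biostrings::DNAString(mt_seq),
      type = "local", gapOpening = 10, gapExtension = 1)
    alr <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(gene), Biostrings::DNAString(rc),
      type = "local", gapOpening = 10, gapExtension = 1)
    use_rev <- Biostrings::score(alr) > Biostrings::score(alf)
    al <- if (use_rev) alr else alf
    ident <- Biostrings::nmatch(al) / nchar(gene)
    if (ident < min_identity) { missing <- c(missing, g); next }
    s <- Biostrings::start(Biostrings::subject(al))
    e <- Biostrings::end(Biostrings::subject(al))
    if (use_rev) { tmp <- s; s <- L - e + 1L; e <- L - tmp + 1L }
    rows[[g]] <- data.frame(gene = g, start = s, end = e,
                            strand = if (use_rev) "-" else "+",
                            identity = 100 * ident, stringsAsFactors = FALSE)
  }
  ann <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(gene = character(0), start = integer(0), end = integer(0),
               strand = character(0), identity = numeric(0))
  attr(ann, "ref_order") <- names(ref_genes)
  attr(ann, "missing") <- missing
  ann
}

#' Concatenate the annotated protein-gene complement
#'
#' Gene subsequences are extracted strand-resolved and joined in reference
#' gene order regardless of the input row order.
#'
#' @param annotations data.frame from [annotate_protein_genes()].
#' @param mt_seq the annotated mt sequence.
#' @param ref_order reference gene order; defaults to the annotation's
#'   `"ref_order"` attribute.
#' @return single concatenated coding sequence (character scalar).
#' @export
concatenate_complement <- function(annotations, mt_seq, ref_order = NULL) {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    stop("no complement: empty annotation set", call. = FALSE)
  }
  ref_order <- ref_order %||% attr(annotations, "ref_order") %||% annotations$gene
  ann <- annotations[order(match(annotations$gene, ref_order)), , drop = FALSE]
  pieces <- substring(mt_seq, ann$start, ann$end)
  flip <- ann$strand == "-"
  pieces[flip] <- revcomp(pieces[flip])
  paste(pieces, collapse = "")
}

#' Mitochondrial genome summary statistics
#'
#' Total length, percent protein-gene content (summed annotated gene length
#' over total length) and percent identity of the concatenated complement to
#' the reference complement.
#'
#' @param mt_seq assembled mt sequence (or an `mt_draft`).
#' @param annotations annotation data.frame.
#' @param ref_complement reference concatenated complement (character), or
#'   `NULL` to skip the identity column.
#' @return one-row data.frame: `total_length`, `pct_protein_content`,
#'   `pct_identity`.
#' @export
genome_stats <- function(mt_seq, annotations, ref_complement = NULL) {
  if (inherits(mt_seq, "mt_draft")) mt_seq <- mt_seq$sequence
  total <- nchar(mt_seq)
  content <- if (nrow(annotations)) {
    100 * sum(annotations$end - annotations$start + 1) / total
  } else 0
  ident <- NA_real_
  if (!is.null(ref_complement) && nrow(annotations)) {
    cc <- concatenate_complement(annotations, mt_seq)
    ident <- align_identity(cc, ref_complement)
  }
  data.frame(total_length = total, pct_protein_content = content,
             pct_identity = ident)
}
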