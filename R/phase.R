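## Variant-column calling and variant-linkage phasing of a padded stack.
##
## Automates the manual step of separating a reference-frame read stack into
## its homeologous gene copies: columns where at least two alleles are well
## supported are called variant, read pairs (fragments) are clustered by the
## alleles they carry at linked variant columns, and each cluster yields a
## majority consensus with copy-specific deletions preserved as gap runs.

# Long-format (position, character) table of a padded stack, one row per
# placed base; internal '-' (deletion evidence) is retained, leading and
# trailing pads do not exist in this representation.
stack_long <- function(stack) {
  chs <- strsplit(stack$placed, "", fixed = TRUE)
  lens <- lengths(chs)
  data.table(
    id = rep(stack$id, lens),
    pos = sequence(lens) + rep(stack$start, lens) - 1L,
    ch = unlist(chs, use.names = FALSE)
  )
}

ALLELES <- c("A", "C", "G", "T", "-")

# Per-column allele counts of a padded stack.
stack_column_counts <- function(stack) {
  long <- stack_long(stack)
  long <- long[ch %in% ALLELES]
  cnt <- dcast(long[, .N, by = .(pos, ch)], pos ~ ch, value.var = "N", fill = 0L)
  for (a in ALLELES) if (!a %in% names(cnt)) cnt[, (a) := 0L]
  setnames(cnt, "-", "gap")
  cnt[, depth := A + C + G + T + gap]
  setorder(cnt, pos)
  cnt[]
}

#' Call variant columns in a padded stack
#'
#' A reference column is variant when at least two alleles each reach the
#' depth and allele-fraction thresholds. Pad characters are absent from the
#' stack representation and so never enter the counts; internal '-'
#' characters (deletion evidence from gapped placements) count as an allele.
#'
#' @param stack a `padded_stack` from [pad_to_reference()].
#' @param min_depth minimum per-allele read support.
#' @param min_allele_fraction minimum per-allele fraction of column depth.
#' @return data.table of variant columns: `pos`, allele counts
#'   (`A`,`C`,`G`,`T`,`gap`), `depth` and the list-column `alleles`.
#' @export
call_variant_columns <- function(stack, min_depth = 4L, min_allele_fraction = 0.2) {
  cnt <- stack_column_counts(stack)
  if (!nrow(cnt)) {
    return(data.table(pos = integer(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), gap = integer(0),
                      depth = integer(0), alleles = list()))
  }
  amat <- as.matrix(cnt[, .(A, C, G, T, gap)])
  ok <- amat >= min_depth & amat / cnt$depth >= min_allele_fraction
  nall <- rowSums(ok)
  out <- cnt[nall >= 2L]
  okm <- ok[nall >= 2L, , drop = FALSE]
  out[, alleles := lapply(seq_len(.N), function(i) ALLELES[okm[i, ]])]
  out[]
}

# Fragment allele profiles at the variant columns: one row per (fragment,
# column) with the observed allele; mate-conflicting observations dropped.
fragment_profiles <- function(stack, variant_pos) {
  long <- stack_long(stack)
  long <- long[pos %in% variant_pos & ch %in% ALLELES]
  if (!nrow(long)) return(long[, .(id, pos, ch)])
  prof <- long[, .(ch = if (uniqueN(ch) == 1L) ch[1L] else NA_character_),
               by = .(id, pos)]
  prof[!is.na(ch)]
}

#' Phase a padded stack into homeologous gene copies
#'
#' Clusters read pairs by shared alleles at linked variant columns: two
#' columns are linked when fragments span both, and a fragment joins the
#' cluster whose consensus allele profile it agrees with. Clusters surviving
#' the support filter define the copy number k (capped at `k_max`); each
#' yields a per-column majority consensus with copy-specific deletions
#' preserved as gap runs. A stack with no variant columns yields k = 1 and
#' the plain majority consensus. Fragments spanning no variant column, or
#' with ambiguous cluster affinity, are counted as unassigned (they affect
#' consensus depth only).
#'
#' @param stack a `padded_stack`.
#' @param variants variant columns from [call_variant_columns()]; computed
#'   when `NULL`.
#' @param k_max maximum copy number reported.
#' @param min_link minimum fragments spanning two columns for linkage during
#'   cluster merging.
#' @param min_agree minimum allele agreement for cluster membership.
#' @param min_cluster_size,min_cluster_frac support filter on clusters.
#' @param marker marker name carried into the result.
#' @return a `gene_copy_set` list: `marker`, `k`, `consensus` (degapped,
#'   named `<marker>.copy1..k` by decreasing support), `consensus_aligned`
#'   (reference-frame, '-' marking copy deletions), `assignment`
#'   (fragment-to-copy table), `unassigned_fraction`, `variant_pos`, and
#'   `flags` (e.g. "unphased region" when linkage was contradictory).
#' @export
phase_gene_copies <- function(stack, variants = NULL, k_max = 3L,
                              min_link = 2L, min_agree = 0.8,
                              min_cluster_size = 4L, min_cluster_frac = 0.08,
                              marker = "gene") {
  stopifnot(inherits(stack, "padded_stack"))
  ref_len <- attr(stack, "ref_len")
  if (is.null(variants)) variants <- call_variant_columns(stack)
  frag_ids <- unique(stack$id)
  n_frag <- length(frag_ids)
  flags <- character(0)

  counts_all <- stack_column_counts(stack)
  majority_of <- function(cnt) {
    m <- as.matrix(cnt[, .(A, C, G, T, gap)])
    # prefer a base over a gap on ties
    pick <- apply(m, 1L, function(r) ALLELES[order(-r, c(1, 2, 3, 4, 5))][1L])
    data.table(pos = cnt$pos, ch = pick)
  }
  build_consensus <- function(member_long, cluster_variant_cov) {
    cons <- rep("N", ref_len)
    if (nrow(member_long)) {
      cnt <- stack_column_counts_from_long(member_long)
      mj <- majority_of(cnt)
      cons[mj$pos] <- mj$ch
      covered <- mj$pos
    } else covered <- integer(0)
    # columns the cluster does not cover: non-variant columns inherit the
    # overall stack majority; uncovered variant columns stay 'N'
    all_mj <- majority_of(counts_all)
    fallback <- setdiff(all_mj$pos, covered)
    fallback <- setdiff(fallback, variants$pos)
    cons[fallback] <- all_mj$ch[match(fallback, all_mj$pos)]
    chars_str(cons)
  }

  if (nrow(variants) == 0L) {
    aligned <- build_consensus(stack_long(stack), integer(0))
    cons <- gsub("-", "", aligned, fixed = TRUE)
    return(structure(list(
      marker = marker, k = 1L,
      consensus = stats::setNames(cons, paste0(marker, ".copy1")),
      consensus_aligned = stats::setNames(aligned, paste0(marker, ".copy1")),
      assignment = data.table(id = frag_ids, copy = 1L),
      unassigned_fraction = 0,
      variant_pos = integer(0), flags = flags), class = "gene_copy_set"))
  }

  prof <- fragment_profiles(stack, variants$pos)
  vpos <- sort(unique(variants$pos))
  vix <- stats::setNames(seq_along(vpos), vpos)
  prof[, col := vix[as.character(pos)]]
  cov <- prof[, .N, by = id]
  order_ids <- cov[order(-N)]$id

  # cluster state: per-cluster allele count matrix over variant columns
  clusters <- list()
  assign_map <- stats::setNames(rep(NA_integer_, n_frag), frag_ids)
  frag_split <- split(prof[, .(col, ch)], prof$id)

  cluster_cons <- function(cl) {
    cons <- rep(NA_character_, length(vpos))
    cov_cols <- which(colSums(cl) > 0L)
    if (length(cov_cols)) {
      cons[cov_cols] <- ALLELES[apply(cl[, cov_cols, drop = FALSE], 2L, which.max)]
    }
    cons
  }
  add_to <- function(cl, cols, chs) {
    ii <- cbind(match(chs, ALLELES), cols)
    cl[ii] <- cl[ii] + 1L
    cl
  }
  score_against <- function(cons, cols, chs) {
    known <- !is.na(cons[cols])
    agree <- sum(chs[known] == cons[cols][known])
    disagree <- sum(known) - agree
    c(agree = agree, disagree = disagree)
  }

  for (fid in order_ids) {
    fp <- frag_split[[fid]]
    if (is.null(fp) || nrow(fp) == 0L) next
    best <- 0L; best_score <- -Inf
    for (ci in seq_along(clusters)) {
      sc <- score_against(attr(clusters[[ci]], "cons"), fp$col, fp$ch)
      tot <- sc[["agree"]] + sc[["disagree"]]
      if (tot >= 1L && sc[["agree"]] / tot >= min_agree) {
        s <- sc[["agree"]] - 2 * sc[["disagree"]]
        if (s > best_score) { best_score <- s; best <- ci }
      }
    }
    if (best > 0L) {
      cl <- add_to(clusters[[best]], fp$col, fp$ch)
      attr(cl, "cons") <- cluster_cons(cl)
      attr(cl, "size") <- attr(clusters[[best]], "size") + 1L
      clusters[[best]] <- cl
      assign_map[fid] <- best
    } else if (nrow(fp) >= 2L) {
      cl <- add_to(matrix(0L, length(ALLELES), length(vpos)), fp$col, fp$ch)
      attr(cl, "cons") <- cluster_cons(cl)
      attr(cl, "size") <- 1L
      clusters[[length(clusters) + 1L]] <- cl
      assign_map[fid] <- length(clusters)
    }
  }

  # merge clusters whose consensus profiles agree over linked columns
  repeat {
    merged <- FALSE
    if (length(clusters) >= 2L) {
      for (a in seq_along(clusters)) {
        for (b in seq_along(clusters)) {
          if (b <= a) next
          ca <- attr(clusters[[a]], "cons"); cb <- attr(clusters[[b]], "cons")
          shared <- which(!is.na(ca) & !is.na(cb))
          if (length(shared) >= min_link) {
            agr <- mean(ca[shared] == cb[shared])
            if (agr >= 0.9) {
              cl <- clusters[[a]] + clusters[[b]]
              attr(cl, "cons") <- cluster_cons(cl)
              attr(cl, "size") <- attr(clusters[[a]], "size") + attr(clusters[[b]], "size")
              clusters[[a]] <- cl
              assign_map[which(assign_map == b)] <- a
              shift <- which(assign_map > b)
              assign_map[shift] <- assign_map[shift] - 1L
              clusters[[b]] <- NULL
              merged <- TRUE
              break
            }
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }

  sizes <- vapply(clusters, function(cl) attr(cl, "size"), integer(1))
  n_assigned <- sum(sizes)
  keep <- which(sizes >= max(min_cluster_size, ceiling(min_cluster_frac * n_assigned)))
  if (!length(keep)) {
    keep <- which.max(sizes)
    flags <- c(flags, "weak clustering")
  }
  keep <- keep[order(-sizes[keep])]
  if (length(keep) > k_max) {
    flags <- c(flags, "excess clusters capped at k_max")
    keep <- keep[seq_len(k_max)]
  }
  k <- length(keep)

  # final pass: reassign every fragment to the kept clusters
  final_cons <- lapply(clusters[keep], function(cl) attr(cl, "cons"))
  final <- stats::setNames(rep(NA_integer_, n_frag), frag_ids)
  for (fid in frag_ids) {
    fp <- frag_split[[fid]]
    if (is.null(fp) || nrow(fp) == 0L) next
    best <- NA_integer_; best_score <- -Inf
    for (ci in seq_len(k)) {
      sc <- score_against(final_cons[[ci]], fp$col, fp$ch)
      tot <- sc[["agree"]] + sc[["disagree"]]
      if (tot >= 1L && sc[["agree"]] / tot >= min_agree) {
        s <- sc[["agree"]] - 2 * sc[["disagree"]]
        if (s > best_score) { best_score <- s; best <- ci }
      }
    }
    final[fid] <- best
  }
  long <- stack_long(stack)
  copy_names <- paste0(marker, ".copy", seq_len(k))
  cons_aligned <- character(k)
  for (ci in seq_len(k)) {
    members <- names(final)[!is.na(final) & final == ci]
    cons_aligned[ci] <- build_consensus(long[id %in% members], integer(0))
  }
  consensus <- gsub("-", "", cons_aligned, fixed = TRUE)
  names(cons_aligned) <- names(consensus) <- copy_names
  unassigned <- mean(is.na(final))
  structure(list(
    marker = marker, k = k,
    consensus = consensus, consensus_aligned = cons_aligned,
    assignment = data.table(id = names(final), copy = unname(final)),
    unassigned_fraction = unassigned,
    variant_pos = vpos, flags = flags), class = "gene_copy_set")
}

# Column counts from an already-exploded long table.
stack_column_counts_from_long <- function(long) {
  long <- long[ch %in% ALLELES]
  cnt <- dcast(long[, .N, by = .(pos, ch)], pos ~ ch, value.var = "N", fill = 0L)
  for (a in ALLELES) if (!a %in% names(cnt)) cnt[, (a) := 0L]
  setnames(cnt, "-", "gap")
  cnt[, depth := A + C + G + T + gap]
  setorder(cnt, pos)
  cnt[]
}

#' @export
print.gene_copy_set <- function(x, ...) {
  cat(sprintf("<gene_copy_set> %s: k = %d, %d variant columns, %.1f%% unassigned\n",
              x$marker, x$k, length(x$variant_pos), 100 * x$unassigned_fraction))
  invisible(x)
}
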