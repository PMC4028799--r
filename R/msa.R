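## Progressive multiple sequence alignment.
##
## Guide tree from neighbour-joining on k-mer distances; profiles merged
## bottom-up by global affine-gap profile-profile alignment (compiled DP).

msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

msa_from_matrix <- function(m) {
  out <- apply(m, 1L, paste, collapse = "")
  names(out) <- rownames(m)
  out
}

# 4 x L count profile of an alignment block ('-' and 'N' carry no weight).
block_profile <- function(m) {
  L <- ncol(m)
  prof <- matrix(0, 4L, L)
  for (b in seq_along(DNA_BASES)) {
    prof[b, ] <- colSums(m == DNA_BASES[b])
  }
  prof
}

# Fractional shared k-mer distance between sequences (guide-tree metric).
kmer_distance <- function(seqs, k = 6L) {
  n <- length(seqs)
  counts <- lapply(seqs, function(s) {
    km <- seq_kmers(s, k)
    as.list(table(km))
  })
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ci <- counts[[i]]; cj <- counts[[j]]
      shared <- sum(vapply(intersect(names(ci), names(cj)), function(km) {
        min(ci[[km]], cj[[km]])
      }, numeric(1)))
      tot <- sum(unlist(ci)) + sum(unlist(cj))
      D[i, j] <- D[j, i] <- 1 - 2 * shared / tot
    }
  }
  D
}

merge_blocks <- function(mA, mB, match = 2, mismatch = -1,
                         gap_open = 10, gap_ext = 0.5) {
  path <- align_profiles_cpp(block_profile(mA), block_profile(mB),
                             match, mismatch, gap_open, gap_ext)
  ncols <- length(path$a)
  out <- matrix("-", nrow(mA) + nrow(mB), ncols)
  sel <- path$a > 0L
  out[seq_len(nrow(mA)), sel] <- mA[, path$a[sel], drop = FALSE]
  sel <- path$b > 0L
  out[nrow(mA) + seq_len(nrow(mB)), sel] <- mB[, path$b[sel], drop = FALSE]
  rownames(out) <- c(rownames(mA), rownames(mB))
  out
}

#' Progressive multiple sequence alignment
#'
#' @param seqs named character vector of DNA sequences (>= 1).
#' @param match,mismatch,gap_open,gap_ext alignment scoring parameters.
#' @return an `msa`: named character vector of equal-length rows over
#'   A/C/G/T/N/'-', in the input order.
#' @export
progressive_align <- function(seqs, match = 2, mismatch = -1,
                              gap_open = 10, gap_ext = 0.5) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  n <- length(seqs)
  if (n == 1L) return(structure(seqs, class = "msa"))
  blocks <- lapply(seq_len(n), function(i) {
    m <- matrix(str_chars(seqs[[i]]), 1L)
    rownames(m) <- names(seqs)[i]
    m
  })
  names(blocks) <- names(seqs)
  if (n == 2L) {
    m <- merge_blocks(blocks[[1]], blocks[[2]], match, mismatch, gap_open, gap_ext)
  } else {
    guide <- nj_tree(kmer_distance(seqs))
    guide <- stats::reorder(ape::root(guide, outgroup = names(seqs)[1],
                                      resolve.root = TRUE), "postorder")
    ntip <- length(guide$tip.label)
    node_block <- vector("list", ntip + guide$Nnode)
    for (i in seq_len(ntip)) node_block[[i]] <- blocks[[guide$tip.label[i]]]
    for (e in seq_len(nrow(guide$edge))) {
      par <- guide$edge[e, 1L]; ch <- guide$edge[e, 2L]
      if (is.null(node_block[[par]])) {
        node_block[[par]] <- node_block[[ch]]
      } else {
        node_block[[par]] <- merge_blocks(node_block[[par]], node_block[[ch]],
                                          match, mismatch, gap_open, gap_ext)
      }
    }
    m <- node_block[[ntip + 1L]]
  }
  m <- m[names(seqs), , drop = FALSE]
  structure(msa_from_matrix(m), class = "msa")
}

#' Remove alignment columns containing gaps or missing data
#'
#' Complete-deletion treatment: every column containing '-' or 'N' in any
#' row is eliminated; row order is preserved.
#'
#' @param msa an `msa` (named character vector of equal-length rows).
#' @return the stripped `msa`.
#' @export
strip_ambiguous_columns <- function(msa) {
  m <- msa_matrix(msa)
  keep <- apply(matrix(m %in% DNA_BASES, nrow(m)), 2L, all)
  if (!any(keep)) stop("no informative columns", call. = FALSE)
  structure(msa_from_matrix(m[, keep, drop = FALSE]), class = "msa")
}

#' Uncorrected p-distance matrix of an alignment
#'
#' d(i, j) is the mismatch fraction over the compared columns of a stripped
#' alignment.
#'
#' @param msa a stripped `msa`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(msa) {
  m <- msa_matrix(msa)
  if (ncol(m) == 0L) stop("zero-length alignment", call. = FALSE)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- mean(m[i, ] != m[j, ])
    }
  }
  D
}
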