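#' Quality-control parameters
#'
#' Sliding-window 3' quality trimming with a minimum surviving length and a
#' whole-pair drop policy (downstream recruitment assumes intact pairs).
#'
#' @param window_len sliding-window length, bases (>= 1).
#' @param min_mean_q minimum mean window quality, Phred (0-60).
#' @param min_read_len reads trimmed below this length are discarded.
#' @param drop_pair_if_either_fails drop the whole pair when one mate fails.
#' @return a `qc_params` list.
#' @export
qc_params <- function(window_len = 4L, min_mean_q = 20, min_read_len = 50L,
                      drop_pair_if_either_fails = TRUE) {
  stopifnot(window_len >= 1L, min_mean_q >= 0, min_mean_q <= 60,
            min_read_len >= 1L)
  structure(list(window_len = as.integer(window_len), min_mean_q = min_mean_q,
                 min_read_len = as.integer(min_read_len),
                 drop_pair_if_either_fails = isTRUE(drop_pair_if_either_fails)),
            class = "qc_params")
}

# Keep-length of each read: scan windows from the 5' end; at the first
# window whose mean quality drops below the threshold, cut at the first
# individually failing base inside that window (so a still-good prefix of
# the window survives). Trimming is therefore always a prefix operation.
qc_keep_length <- function(quals, params) {
  w <- params$window_len
  thr <- params$min_mean_q
  vapply(quals, function(q) {
    n <- length(q)
    if (n < w) return(if (n && mean(q) < thr) 0L else n)
    cs <- cumsum(c(0L, q))
    wmean <- (cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]) / w
    i <- match(TRUE, wmean < thr)
    if (is.na(i)) return(n)
    j <- match(TRUE, q[i:(i + w - 1L)] < thr)
    if (is.na(j)) i + w - 2L else i + j - 2L
  }, integer(1))
}

#' Trim and filter read pairs on quality
#'
#' Applies sliding-window 3' trimming to both mates, discards reads shorter
#' than `min_read_len`, and applies the pair policy. Returns the surviving
#' pairs together with before/after statistics.
#'
#' @param pairs a `read_pairs` object.
#' @param params a [qc_params()] object.
#' @return list with `pairs` (surviving, trimmed `read_pairs`) and `stats`
#'   (pairs in/out, mean quality before/after).
#' @export
trim_and_filter <- function(pairs, params = qc_params()) {
  n <- length(pairs)
  if (n == 0L) {
    return(list(pairs = pairs,
                stats = list(pairs_in = 0L, pairs_out = 0L,
                             mean_q_in = NA_real_, mean_q_out = NA_real_)))
  }
  decode_all <- function(qs) {
    # fast path: uniform read length decodes in one pass
    if (length(unique(nchar(qs))) == 1L) {
      w <- nchar(qs[1L])
      m <- matrix(utf8ToInt(paste(qs, collapse = "")) - 33L, nrow = w)
      lapply(seq_len(ncol(m)), function(j) m[, j])
    } else {
      lapply(qs, phred_decode)
    }
  }
  q1 <- decode_all(pairs$qual1)
  q2 <- decode_all(pairs$qual2)
  mean_q_in <- mean(unlist(c(q1, q2)))
  keep_lengths <- function(qs, decoded) {
    # identical quality strings (e.g. simulator output) share one result
    if (length(unique(qs)) == 1L) {
      rep(qc_keep_length(decoded[1L], params), length(qs))
    } else {
      qc_keep_length(decoded, params)
    }
  }
  k1 <- keep_lengths(pairs$qual1, q1)
  k2 <- keep_lengths(pairs$qual2, q2)
  s1 <- substr(pairs$seq1, 1L, k1); ql1 <- substr(pairs$qual1, 1L, k1)
  s2 <- substr(pairs$seq2, 1L, k2); ql2 <- substr(pairs$qual2, 1L, k2)
  ok1 <- k1 >= params$min_read_len
  ok2 <- k2 >= params$min_read_len
  keep <- if (params$drop_pair_if_either_fails) ok1 & ok2 else ok1 | ok2
  out <- new_read_pairs(pairs$id[keep], s1[keep], ql1[keep], s2[keep], ql2[keep])
  mean_q_out <- if (any(keep)) {
    mean(unlist(lapply(c(out$qual1, out$qual2), phred_decode)))
  } else NA_real_
  list(pairs = out,
       stats = list(pairs_in = n, pairs_out = sum(keep),
                    mean_q_in = mean_q_in, mean_q_out = mean_q_out))
}
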