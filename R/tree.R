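## Tree inference: neighbour-joining, Fitch parsimony, bootstrap consensus.

fmt_len <- function(x) sprintf("%.12g", max(x, 0))

#' Neighbour-joining tree
#'
#' Standard NJ agglomeration on the Q criterion. Negative branch lengths
#' are clamped to zero; ties in Q are broken towards the smallest
#' label-pair index, making the result deterministic.
#'
#' @param d symmetric distance matrix with labelled rows (n >= 3).
#' @return an unrooted `ape::phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d) %||% colnames(d)
  if (is.null(labels)) stop("nj_tree: distance matrix must be labelled", call. = FALSE)
  n <- nrow(d)
  if (n < 3L) stop("nj_tree: need at least 3 taxa", call. = FALSE)
  nodes <- labels
  D <- unname(d)
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (Q[i, j] < bestq - 1e-12) { bestq <- Q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    newnode <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt_len(li),
                       nodes[j], fmt_len(lj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- matrix(0, m - 1L, m - 1L)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
    D2[m - 1L, seq_along(keep)] <- D2[seq_along(keep), m - 1L] <- dk[keep]
    D <- D2
    nodes <- c(nodes[keep], newnode)
  }
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt_len(l1),
                 nodes[2], fmt_len(l2), nodes[3], fmt_len(l3))
  ape::read.tree(text = txt)
}

# --- Fitch parsimony ---------------------------------------------------

FITCH_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

fitch_encode <- function(msa) {
  m <- msa_matrix(msa)
  enc <- matrix(15L, nrow(m), ncol(m), dimnames = list(rownames(m), NULL))
  for (b in names(FITCH_BITS)) enc[m == b] <- FITCH_BITS[[b]]
  enc
}

#' Fitch parsimony score of a tree
#'
#' Linear-time two-pass Fitch count of the minimum number of state changes
#' summed over alignment columns.
#'
#' @param msa a stripped `msa`.
#' @param tree an `ape::phylo` whose tip labels match the alignment rows.
#' @return integer parsimony score.
#' @export
fitch_score <- function(msa, tree) {
  enc <- fitch_encode(msa)
  if (!setequal(rownames(enc), tree$tip.label)) {
    stop("fitch_score: leaf/label mismatch between tree and alignment", call. = FALSE)
  }
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  L <- ncol(enc)
  st <- matrix(0L, nnode, L)
  st[seq_len(ntip), ] <- enc[tr$tip.label, , drop = FALSE]
  seen <- logical(nnode)
  seen[seq_len(ntip)] <- TRUE
  changes <- integer(L)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    if (!seen[par]) {
      st[par, ] <- st[ch, ]
      seen[par] <- TRUE
    } else {
      a <- bitwAnd(st[par, ], st[ch, ])
      zero <- a == 0L
      changes <- changes + zero
      st[par, ] <- ifelse(zero, bitwOr(st[par, ], st[ch, ]), a)
    }
  }
  sum(changes)
}

# Enumerate all unrooted binary topologies over the given labels as
# undirected edge matrices (tips 1..n, internal nodes n+1..2n-2).
enumerate_topologies <- function(n) {
  stopifnot(n >= 3L)
  base <- cbind(c(n + 1L, n + 1L, n + 1L), 1:3)
  trees <- list(base)
  if (n == 3L) return(trees)
  for (t in 4:n) {
    newint <- n + t - 2L
    out <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr))) {
        u <- tr[e, 1L]; v <- tr[e, 2L]
        nt <- rbind(tr[-e, , drop = FALSE],
                    c(u, newint), c(newint, v), c(newint, t))
        out[[length(out) + 1L]] <- nt
      }
    }
    trees <- out
  }
  trees
}

# Fitch score of an undirected edge matrix (tips 1..n encoded in `enc` row
# order), rooted arbitrarily at the first internal node.
fitch_edges <- function(edges, enc) {
  n <- nrow(enc)
  nnode <- max(edges)
  adj <- vector("list", nnode)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1L]; v <- edges[e, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  L <- ncol(enc)
  changes <- 0L
  states <- matrix(0L, nnode, L)
  # iterative postorder from root n+1
  root <- n + 1L
  stack <- list(c(root, 0L))
  order <- integer(0)
  parent <- integer(nnode)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[1L]; par <- top[2L]
    parent[node] <- par
    order <- c(order, node)
    for (nb in adj[[node]]) if (nb != par) stack[[length(stack) + 1L]] <- c(nb, node)
  }
  colchanges <- integer(L)
  seen <- logical(nnode)
  for (node in rev(order)) {
    if (node <= n) {
      states[node, ] <- enc[node, ]
    } else {
      first <- TRUE
      for (nb in adj[[node]]) {
        if (nb == parent[node]) next
        if (first) { states[node, ] <- states[nb, ]; first <- FALSE }
        else {
          a <- bitwAnd(states[node, ], states[nb, ])
          zero <- a == 0L
          colchanges <- colchanges + zero
          states[node, ] <- ifelse(zero, bitwOr(states[node, ], states[nb, ]), a)
        }
      }
    }
  }
  sum(colchanges)
}

# Convert an undirected edge matrix plus labels to an ape::phylo via Newick.
edges_to_phylo <- function(edges, labels) {
  n <- length(labels)
  nnode <- max(edges)
  adj <- vector("list", nnode)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1L]; v <- edges[e, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  sub <- function(node, par) {
    kids <- setdiff(adj[[node]], par)
    if (!length(kids)) return(labels[node])
    paste0("(", paste(vapply(kids, sub, character(1), par = node),
                      collapse = ","), ")")
  }
  ape::read.tree(text = paste0(sub(n + 1L, 0L), ";"))
}

# All NNI neighbours of an undirected edge-matrix tree.
nni_neighbours <- function(edges, n) {
  internal <- edges[, 1L] > n & edges[, 2L] > n
  out <- list()
  adj_of <- function(node) {
    c(edges[edges[, 1L] == node, 2L], edges[edges[, 2L] == node, 1L])
  }
  for (e in which(internal)) {
    u <- edges[e, 1L]; v <- edges[e, 2L]
    au <- setdiff(adj_of(u), v)
    av <- setdiff(adj_of(v), u)
    for (b in av[1:2]) {
      # swap au[1] <-> b
      nt <- edges
      swap_one <- function(m, from, to, other) {
        hit <- which((m[, 1L] == from & m[, 2L] == to) |
                       (m[, 1L] == to & m[, 2L] == from))[1]
        m[hit, ] <- c(other, to)
        m
      }
      nt <- swap_one(nt, u, au[1L], v)
      nt <- swap_one(nt, v, b, u)
      out[[length(out) + 1L]] <- nt
    }
  }
  out
}

phylo_to_edges <- function(tree) {
  tr <- ape::unroot(tree)
  n <- length(tr$tip.label)
  edges <- tr$edge
  # ape numbers tips 1..n and internals n+1..; already the convention used
  list(edges = edges, labels = tr$tip.label)
}

#' Fitch parsimony scoring and tree search
#'
#' With a tree supplied, scores it. Without one, searches: exhaustively over
#' all unrooted topologies for n <= 8 taxa, otherwise by NNI hill-climbing
#' from the neighbour-joining tree with seed-controlled random restarts.
#'
#' @param msa a stripped `msa`.
#' @param tree optional `ape::phylo` to score.
#' @param nni_restarts random restarts for the NNI search.
#' @param seed integer seed for the restarts.
#' @return list with `score` and `tree` (the scored or best tree).
#' @export
fitch_parsimony <- function(msa, tree = NULL, nni_restarts = 5L, seed = 1L) {
  if (!is.null(tree)) {
    return(list(score = fitch_score(msa, tree), tree = tree))
  }
  labels <- names(msa)
  n <- length(labels)
  enc <- fitch_encode(msa)[labels, , drop = FALSE]
  if (n <= 8L) {
    tops <- enumerate_topologies(n)
    scores <- vapply(tops, fitch_edges, integer(1), enc = enc)
    best <- which.min(scores)
    return(list(score = scores[best], tree = edges_to_phylo(tops[[best]], labels)))
  }
  start <- phylo_to_edges(nj_tree(p_distance_matrix(msa)))
  enc <- enc[start$labels, , drop = FALSE]
  climb <- function(edges) {
    cur <- edges
    cur_s <- fitch_edges(cur, enc)
    repeat {
      nbs <- nni_neighbours(cur, n)
      ss <- vapply(nbs, fitch_edges, integer(1), enc = enc)
      if (min(ss) < cur_s) {
        cur <- nbs[[which.min(ss)]]
        cur_s <- min(ss)
      } else break
    }
    list(edges = cur, score = cur_s)
  }
  best <- climb(start$edges)
  with_seed(derive_seed(seed, 31L), {
    for (r in seq_len(nni_restarts)) {
      pert <- start$edges
      for (p in seq_len(2L)) {
        nbs <- nni_neighbours(pert, n)
        pert <- nbs[[sample.int(length(nbs), 1L)]]
      }
      res <- climb(pert)
      if (res$score < best$score) best <- res
    }
  })
  list(score = best$score, tree = edges_to_phylo(best$edges, start$labels))
}

# --- bootstrap consensus ----------------------------------------------

#' Majority-rule bootstrap consensus tree
#'
#' Alignment columns are resampled with replacement `reps` times; each
#' replicate is analysed with the chosen method (neighbour-joining on
#' p-distances, or Fitch parsimony search), and the majority-rule (> 50%)
#' consensus is returned with internal-edge supports as percentages of
#' replicates containing the corresponding leaf bipartition. Deterministic
#' for a given seed.
#'
#' @param msa a stripped `msa`.
#' @param method `"nj"` or `"parsimony"`.
#' @param reps bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return rooted-at-first-tip `ape::phylo` consensus with `node.label`
#'   percent supports.
#' @export
bootstrap_consensus <- function(msa, method = c("nj", "parsimony"),
                                reps = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (reps < 1L) stop("bootstrap_consensus: reps must be >= 1", call. = FALSE)
  labels <- names(msa)
  n <- length(labels)
  m <- msa_matrix(msa)
  L <- ncol(m)
  og <- labels[1L]
  trees <- vector("list", reps)
  with_seed(derive_seed(seed, 97L), {
    if (method == "nj") {
      pairs <- utils::combn(n, 2L)
      P <- matrix(0, ncol(pairs), L)
      for (pr in seq_len(ncol(pairs))) {
        P[pr, ] <- m[pairs[1L, pr], ] != m[pairs[2L, pr], ]
      }
      W <- stats::rmultinom(reps, L, rep(1 / L, L))
      Drep <- (P %*% W) / L
      for (rp in seq_len(reps)) {
        D <- matrix(0, n, n, dimnames = list(labels, labels))
        D[t(pairs)] <- Drep[, rp]
        D <- D + t(D)
        trees[[rp]] <- ape::root(nj_tree(D), outgroup = og, resolve.root = TRUE)
      }
    } else {
      for (rp in seq_len(reps)) {
        cols <- sample.int(L, L, replace = TRUE)
        bs <- structure(msa_from_matrix(m[, cols, drop = FALSE]), class = "msa")
        fit <- fitch_parsimony(bs, seed = derive_seed(seed, 1000L + rp))
        trees[[rp]] <- ape::root(fit$tree, outgroup = og, resolve.root = TRUE)
      }
    }
  })
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5, rooted = TRUE)
  pp <- ape::prop.part(trees)
  supports <- ape::prop.clades(cons, part = pp, rooted = TRUE)
  supports[is.na(supports)] <- 0L
  cons$node.label <- as.character(round(100 * supports / reps))
  # the full-data tree with per-edge bootstrap proportions (which, unlike
  # the consensus, can fall below 50)
  full <- if (method == "nj") nj_tree(p_distance_matrix(msa)) else
    fitch_parsimony(msa, seed = derive_seed(seed, 2L))$tree
  full <- ape::root(full, outgroup = og, resolve.root = TRUE)
  fsup <- ape::prop.clades(full, part = pp, rooted = TRUE)
  fsup[is.na(fsup)] <- 0L
  full$node.label <- as.character(round(100 * fsup / reps))
  attr(cons, "full_tree") <- full
  attr(cons, "method") <- method
  attr(cons, "reps") <- reps
  cons
}

# Descendant tip sets of every internal node of a rooted tree.
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- stats::reorder(tree, "postorder")
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    sets[[par]] <- union(sets[[par]], sets[[ch]])
  }
  sets
}

#' Bootstrap support of a clade
#'
#' Looks up the internal-node support of the clade containing exactly the
#' given tips in a consensus tree from [bootstrap_consensus()].
#'
#' @param tree consensus tree with `node.label` supports.
#' @param tips character vector of tip labels.
#' @return numeric support (percent), or `NA` when the clade is absent.
#' @export
clade_support <- function(tree, tips) {
  sets <- node_tip_sets(tree)
  ntip <- length(tree$tip.label)
  for (nd in (ntip + 1L):length(sets)) {
    if (setequal(sets[[nd]], tips)) {
      return(as.numeric(tree$node.label[nd - ntip]))
    }
  }
  NA_real_
}

#' Concatenate marker copies per sub-genome
#'
#' Joins each sub-genome's marker copies in the stated marker order into a
#' supermatrix row. A sub-genome missing a marker is padded with 'N' of the
#' reference length and flagged.
#'
#' @param copies named list: marker -> named character vector of copy
#'   sequences keyed by sub-genome (donor) label.
#' @param order marker concatenation order.
#' @param ref_lengths named reference lengths used for 'N' padding.
#' @return list with `sequences` (named by sub-genome) and `flags`
#'   (data.frame of padded sub-genome/marker combinations).
#' @export
concatenate_markers <- function(copies, order = c("tub2", "tefA", "perA"),
                                ref_lengths = NULL) {
  if (!length(order)) stop("concatenate_markers: empty marker order", call. = FALSE)
  stopifnot(all(order %in% names(copies)))
  subgenomes <- unique(unlist(lapply(copies[order], names)))
  flags <- list()
  seqs <- stats::setNames(character(length(subgenomes)), subgenomes)
  for (sg in subgenomes) {
    parts <- character(0)
    for (mk in order) {
      s <- unname(copies[[mk]][sg])
      if (is.null(s) || is.na(s)) {
        padlen <- ref_lengths[[mk]] %||%
          max(nchar(copies[[mk]]), 0L)
        s <- strrep("N", padlen)
        flags[[length(flags) + 1L]] <- data.frame(subgenome = sg, marker = mk)
      }
      parts <- c(parts, s)
    }
    seqs[sg] <- paste(parts, collapse = "")
  }
  list(sequences = seqs,
       flags = if (length(flags)) do.call(rbind, flags) else
         data.frame(subgenome = character(0), marker = character(0)))
}
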