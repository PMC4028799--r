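test_that("three taxa solve the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["a"]], 1)  # (d_ab + d_ac - d_bc) / 2
  expect_equal(lens[["b"]], 2)
  expect_equal(lens[["c"]], 3)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ is exactly consistent on additive distances", {
  set.seed(41)
  for (i in 1:10) {
    t0 <- ape::rtree(6, rooted = FALSE)
    t0$edge.length <- stats::runif(nrow(t0$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(t0)
    out <- nj_tree(D)
    expect_equal(as.integer(ape::dist.topo(t0, out)), 0L)
    Dhat <- ape::cophenetic.phylo(out)
    expect_lt(max(abs(Dhat[rownames(D), colnames(D)] - D)), 1e-9)
  }
})

test_that("permuting the input label order gives an isomorphic tree", {
  set.seed(42)
  t0 <- ape::rtree(7, rooted = FALSE)
  t0$edge.length <- stats::runif(nrow(t0$edge), 0.05, 1)
  D <- ape::cophenetic.phylo(t0)
  perm <- sample(rownames(D))
  out1 <- nj_tree(D)
  out2 <- nj_tree(D[perm, perm])
  expect_equal(as.integer(ape::dist.topo(out1, out2)), 0L)
})

test_that("negative NJ branch lengths are clamped to zero", {
  D <- matrix(c(0, 0.1, 0.1, 0.4,
                0.1, 0, 0.05, 0.45,
                0.1, 0.05, 0, 0.45,
                0.4, 0.45, 0.45, 0), 4,
              dimnames = rep(list(letters[1:4]), 2))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("Fitch scores match direct expectations and the oracle", {
  msa0 <- structure(c(a = "AAA", b = "AAA", c = "AAA", d = "AAA"), class = "msa")
  tr4 <- read_newick("((a,b),(c,d));")
  expect_equal(fitch_score(msa0, tr4), 0L)

  # one column with four distinct states costs 3 on every topology
  msa1 <- structure(c(a = "A", b = "C", c = "G", d = "T"), class = "msa")
  expect_equal(fitch_score(msa1, tr4), 3L)
  expect_equal(fitch_score(msa1, read_newick("((a,c),(b,d));")), 3L)

  expect_error(fitch_score(msa1, read_newick("((a,b),(c,x));")),
               "leaf/label mismatch")

  skip_if_not_installed("phangorn")
  set.seed(43)
  for (i in 1:5) {
    m <- matrix(sample(c("A", "C", "G", "T"), 6 * 30, replace = TRUE), 6,
                dimnames = list(paste0("t", 1:6), NULL))
    msa <- structure(apply(m, 1, paste, collapse = ""), class = "msa")
    tr <- ape::unroot(ape::rtree(6))
    tr$tip.label <- sample(paste0("t", 1:6))
    pd <- phangorn::phyDat(m, type = "DNA")
    expect_equal(fitch_score(msa, tr),
                 as.integer(phangorn::fitch(tr, pd)))
  }
})

test_that("exhaustive parsimony search equals the brute-force optimum", {
  skip_if_not_installed("phangorn")
  set.seed(44)
  m <- matrix(sample(c("A", "C", "G", "T"), 6 * 30, replace = TRUE), 6,
              dimnames = list(paste0("t", 1:6), NULL))
  msa <- structure(apply(m, 1, paste, collapse = ""), class = "msa")
  fit <- fitch_parsimony(msa)
  pd <- phangorn::phyDat(m, type = "DNA")
  oracle <- min(vapply(phangorn::allTrees(6, tip.label = paste0("t", 1:6)),
                       function(t) as.integer(phangorn::fitch(t, pd)),
                       integer(1)))
  expect_equal(fit$score, oracle)
  expect_equal(fitch_score(msa, fit$tree), fit$score)
})

test_that("topology enumeration counts (2n-5)!! trees", {
  expect_length(endophylo:::enumerate_topologies(4L), 3L)
  expect_length(endophylo:::enumerate_topologies(5L), 15L)
  expect_length(endophylo:::enumerate_topologies(6L), 105L)
})

test_that("bootstrap gives full support to a clean split and is seed-stable", {
  block <- function(ch, n) strrep(ch, n)
  # two clades: identical within, very different between
  msa <- structure(c(a = paste0(block("A", 50), block("C", 50)),
                     b = paste0(block("A", 50), block("C", 50)),
                     c = paste0(block("G", 50), block("C", 50)),
                     d = paste0(block("G", 50), block("C", 50))),
                   class = "msa")
  # add private signal so distances are informative
  m <- endophylo:::msa_matrix(msa)
  set.seed(45)
  noise <- matrix(sample(c("A", "C", "G", "T"), 4 * 30, replace = TRUE), 4)
  m <- cbind(m, noise)
  rownames(m) <- names(msa)
  msa <- structure(apply(m, 1, paste, collapse = ""), class = "msa")
  ct <- bootstrap_consensus(msa, "nj", reps = 200, seed = 6L)
  expect_equal(clade_support(ct, c("c", "d")), 100)

  ct2 <- bootstrap_consensus(msa, "nj", reps = 200, seed = 6L)
  expect_identical(ct$node.label, ct2$node.label)
  expect_error(bootstrap_consensus(msa, "nj", reps = 0), "reps")
})

test_that("iid random columns earn only weak internal support", {
  set.seed(46)
  mean_sup <- vapply(1:10, function(s) {
    m <- matrix(sample(c("A", "C", "G", "T"), 6 * 60, replace = TRUE), 6,
                dimnames = list(paste0("t", 1:6), NULL))
    msa <- structure(apply(m, 1, paste, collapse = ""), class = "msa")
    ct <- bootstrap_consensus(msa, "nj", reps = 100, seed = s)
    full <- attr(ct, "full_tree")
    # exclude the clades forced by rooting (all tips; all but the outgroup)
    sets <- endophylo:::node_tip_sets(full)
    ntip <- length(full$tip.label)
    internal <- (ntip + 1L):length(sets)
    real <- internal[lengths(sets[internal]) < ntip - 1L]
    mean(as.numeric(full$node.label[real - ntip]))
  }, numeric(1))
  expect_lt(mean(mean_sup), 70)
})

test_that("parsimony bootstrap runs and supports the planted split", {
  set.seed(47)
  m <- matrix("A", 5, 40, dimnames = list(paste0("t", 1:5), NULL))
  m[4:5, 1:20] <- "T"
  for (j in seq(2, 40, by = 4)) m[sample(5, 1), j] <- "G"
  msa <- structure(apply(m, 1, paste, collapse = ""), class = "msa")
  ct <- bootstrap_consensus(msa, "parsimony", reps = 30, seed = 2L)
  expect_equal(clade_support(ct, c("t4", "t5")), 100)
})

test_that("marker concatenation follows the stated order and pads losses", {
  copies <- list(
    tefA = c(sg1 = strrep("C", 40), sg2 = strrep("G", 40)),
    tub2 = c(sg1 = strrep("A", 30), sg2 = strrep("T", 30)),
    perA = c(sg1 = strrep("T", 50))  # sg2 lost
  )
  out <- concatenate_markers(copies, order = c("tub2", "tefA", "perA"),
                             ref_lengths = c(tub2 = 30, tefA = 40, perA = 50))
  expect_equal(nchar(out$sequences[["sg1"]]), 120L)
  expect_identical(out$sequences[["sg1"]],
                   paste0(strrep("A", 30), strrep("C", 40), strrep("T", 50)))
  expect_identical(out$sequences[["sg2"]],
                   paste0(strrep("T", 30), strrep("G", 40), strrep("N", 50)))
  expect_equal(out$flags$subgenome, "sg2")
  expect_equal(out$flags$marker, "perA")
  expect_error(concatenate_markers(copies, order = character(0)), "empty")
})
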