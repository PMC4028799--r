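test_that("zero divergence and zero indel rate reproduce the ancestor", {
  anc <- tiny_ancestor()
  model <- lineage_model(anc, lineages = c("L1", "L2"), divergence = 0,
                         indel_rate = 0)
  lin <- evolve_lineages(model, seed = 3L)
  expect_identical(lin$L1$markers, anc$markers)
  expect_identical(lin$L1$background, anc$background)
  expect_identical(lin$L1$mt_genome, anc$mt_genome)
})

test_that("observed divergence follows the binomial expectation", {
  anc <- tiny_ancestor()  # background is 12 kb of unconstrained sequence
  p <- 0.1
  model <- lineage_model(anc, lineages = "L1", divergence = p, indel_rate = 0)
  lin <- evolve_lineages(model, seed = 11L)
  L <- nchar(anc$background)
  obs <- 1 - str_identity(anc$background, lin$L1$background)
  tol <- 3 * sqrt(p * (1 - p) / L)
  expect_lt(abs(obs - p), tol)

  # two independent lineages: pairwise divergence concentrates near the
  # no-back-mutation composition 1 - (1 - p1)(1 - p2)
  model2 <- lineage_model(anc, lineages = c("A", "B"), divergence = 0.05,
                          indel_rate = 0)
  lin2 <- evolve_lineages(model2, seed = 12L)
  obs2 <- 1 - str_identity(lin2$A$background, lin2$B$background)
  exp2 <- 1 - (1 - 0.05) * (1 - 0.05)
  # allow a small back-mutation correction: coincident substitutions at the
  # same site occasionally restore agreement
  expect_lt(abs(obs2 - exp2), 3 * sqrt(exp2 * (1 - exp2) / L) + 0.004)
})

test_that("lineage evolution is deterministic in the seed", {
  anc <- tiny_ancestor()
  model <- lineage_model(anc)
  a <- evolve_lineages(model, seed = 42L)
  b <- evolve_lineages(model, seed = 42L)
  expect_identical(a$E_typhina$markers, b$E_typhina$markers)
  expect_identical(a$FGC1$mt_genome, b$FGC1$mt_genome)
})

test_that("divergence outside [0, 0.75) is rejected", {
  expect_error(lineage_model(tiny_ancestor(), divergence = 0.8), "0.75")
  expect_error(lineage_model(tiny_ancestor(), divergence = -0.1), "0.75")
})

test_that("heteroploid composition records complete truth", {
  lin <- tiny_lineages()
  hyb <- compose_heteroploid(lin, donors = c("E_festucae", "E_typhina", "FGC1"),
                             seed = 5L)
  expect_equal(hyb$truth$k, 3L)
  counts <- table(hyb$truth$copies$marker)
  expect_equal(unname(counts[c("perA", "tub2", "tefA")]), rep(3L, 3),
               ignore_attr = TRUE)
  # every embedded copy is recoverable from the stated chromosome position
  for (i in seq_len(nrow(hyb$truth$copies))) {
    cp <- hyb$truth$copies[i, ]
    emb <- substr(hyb$chromosomes[[cp$chrom]], cp$start,
                  cp$start + nchar(cp$seq) - 1L)
    expect_identical(if (cp$strand == "+") emb else revcomp(emb), cp$seq)
  }
})

test_that("copy loss and planted deletions are honoured", {
  lin <- tiny_lineages()
  hyb <- compose_heteroploid(
    lin, donors = c("E_typhina", "E_bromicola"),
    losses = data.frame(marker = "tub2", donor = "E_bromicola"),
    deletions = data.frame(marker = "perA", donor = "E_typhina",
                           start = 201L, end = 300L),
    seed = 6L)
  counts <- table(hyb$truth$copies$marker)
  expect_equal(unname(counts["tub2"]), 1L, ignore_attr = TRUE)
  expect_equal(unname(counts["perA"]), 2L, ignore_attr = TRUE)
  del_copy <- hyb$truth$copies[hyb$truth$copies$marker == "perA" &
                                 hyb$truth$copies$donor == "E_typhina", ]
  full <- lin$E_typhina$markers[["perA"]]
  expect_equal(nchar(del_copy$seq), nchar(full) - 100L)
  expect_identical(del_copy$seq,
                   paste0(substr(full, 1, 200), substr(full, 301, nchar(full))))
  expect_equal(hyb$truth$deletions$start, 201L)

  expect_error(compose_heteroploid(
    lin, donors = "E_typhina",
    deletions = data.frame(marker = "perA", donor = "E_typhina",
                           start = 100L, end = 5000L), seed = 1L),
    "outside gene")
  expect_error(compose_heteroploid(lin, donors = "E_typhina", r = 0.5),
    "r must be >= 1")
  expect_error(compose_heteroploid(lin, donors = "no_such_lineage"),
    "subset")
})

test_that("noiseless reads are exact substrings in FR orientation", {
  lin <- tiny_lineages()
  hyb <- compose_heteroploid(lin, donors = "E_festucae", seed = 2L)
  cfg <- pipeline_config(rng_seed = 1L)
  sim <- simulate_paired_reads(hyb, coverage = 3, config = cfg, seed = 9L,
                               include_mt = FALSE, error_rate = 0)
  chrom <- hyb$chromosomes[["E_festucae"]]
  for (i in seq_len(min(50L, length(sim$pairs)))) {
    tr <- sim$truth[i, ]
    frag <- substr(chrom, tr$start, tr$start + tr$frag_len - 1L)
    if (tr$strand == "-") frag <- revcomp(frag)
    expect_identical(sim$pairs$seq1[i], substr(frag, 1, cfg$read_len))
    expect_identical(sim$pairs$seq2[i],
                     revcomp(substr(frag, tr$frag_len - cfg$read_len + 1L,
                                    tr$frag_len)))
  }
})

test_that("pair counts follow the coverage identity and the mt ratio", {
  lin <- tiny_lineages()
  hyb <- compose_heteroploid(lin, donors = "E_festucae", r = 100, seed = 2L)
  cfg <- pipeline_config(rng_seed = 1L)
  sim <- simulate_paired_reads(hyb, coverage = 10, config = cfg, seed = 4L)
  Ln <- nchar(hyb$chromosomes[["E_festucae"]])
  Lm <- nchar(hyb$mt_genome)
  n_nuc <- sum(sim$truth$source != "mt")
  n_mt <- sum(sim$truth$source == "mt")
  expect_lt(abs(n_nuc - Ln * 10 / 200), 5 * sqrt(Ln * 10 / 200) + 1)
  ratio <- (n_mt / Lm) / (n_nuc / Ln)
  expect_gt(ratio, 80)
  expect_lt(ratio, 120)

  # circularity: some fragments span the origin yet match the doubled genome
  wrap <- sim$truth[sim$truth$source == "mt" &
                      sim$truth$start + sim$truth$frag_len - 1L > Lm, ]
  expect_gt(nrow(wrap), 0L)
  sim0 <- simulate_paired_reads(hyb, coverage = 10, config = cfg, seed = 4L,
                                error_rate = 0)
  doubled <- paste0(hyb$mt_genome, hyb$mt_genome)
  wrap_ids <- match(wrap$id, sim0$truth$id)
  for (i in wrap_ids[seq_len(min(10L, length(wrap_ids)))]) {
    r1 <- sim0$pairs$seq1[i]
    expect_true(grepl(r1, doubled, fixed = TRUE) ||
                  grepl(revcomp(r1), doubled, fixed = TRUE))
  }

  expect_error(simulate_paired_reads(hyb, coverage = 0, config = cfg),
               "positive")
})

test_that("the study presets reproduce the analysed taxon structures", {
  st <- default_study()
  expect_equal(length(st$N_coenophialum$donors), 3L)
  expect_equal(st$N_uncinatum$losses$marker, "tub2")
  expect_equal(st$FaTG2$deletions$start, c(1251L, 4590L))
  expect_equal(st$FaTG2$deletions$end, c(1878L, 4918L))
  # UNS: both perA copies carry a lesion (deletions on one, stop on the other)
  expect_equal(nrow(st$UNS$lesions), 1L)
  expect_equal(nrow(st$UNS$deletions), 2L)
})
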