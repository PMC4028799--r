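mock_contigs <- function(seqs, depths, circular = FALSE) {
  data.frame(id = sprintf("contig_%03d", seq_along(seqs)), seq = seqs,
             length = nchar(seqs), depth = depths,
             circular = rep_len(circular, length(seqs)),
             stringsAsFactors = FALSE)
}

test_that("the coverage cut-off separates two planted depth modes", {
  ref <- fixture("mtref6k", endophylo:::with_seed(666L, random_dna(6000)))
  set.seed(14)
  mt_seqs <- substring(ref, c(1, 1500, 3000, 4500), c(1600, 3100, 4600, 6000))
  nuc_seqs <- random_dna(rep(400L, 12))
  contigs <- mock_contigs(c(mt_seqs, nuc_seqs),
                          c(stats::rlnorm(4, log(3000), 0.1),
                            stats::rlnorm(12, log(30), 0.2)))
  cls <- classify_mt_contigs(contigs, ref, 0.001)
  expect_gt(cls$coverage_cutoff, max(contigs$depth[-(1:4)]))
  expect_lt(cls$coverage_cutoff, min(contigs$depth[1:4]))
  expect_setequal(cls$mt_contigs$id, contigs$id[1:4])
})

test_that("contigs without reference similarity are never classified mt", {
  ref <- fixture("mtref6k", endophylo:::with_seed(666L, random_dna(6000)))
  contigs <- mock_contigs(random_dna(rep(500L, 5)), rep(2000, 5))
  expect_warning(cls <- classify_mt_contigs(contigs, ref, 0.001), "unimodal")
  expect_equal(nrow(cls$mt_contigs), 0L)
})

test_that("raising the coverage cut-off is a monotone filter", {
  ref <- fixture("mtref6k", endophylo:::with_seed(666L, random_dna(6000)))
  seqs <- substring(ref, seq(1, 5001, by = 500), seq(600, 5600, by = 500))
  contigs <- mock_contigs(seqs, seq(100, 2200, length.out = length(seqs)))
  sel_sets <- lapply(c(100, 500, 1000, 2000), function(cut) {
    cls <- classify_mt_contigs(contigs, ref, 0.001, coverage_cutoff = cut)
    cls$mt_contigs$id
  })
  for (i in seq_along(sel_sets)[-1]) {
    expect_true(all(sel_sets[[i]] %in% sel_sets[[i - 1]]))
  }
})

test_that("overlapping contigs merge exactly and in reference order", {
  ref <- fixture("mtref6k", endophylo:::with_seed(666L, random_dna(6000)))
  A <- substr(ref, 1, 3000)
  B <- substr(ref, 2951, 6000)
  draft <- order_and_merge_contigs(mock_contigs(c(A, B), c(900, 900)), ref)
  expect_equal(nchar(draft$sequence), 6000L)
  expect_identical(draft$sequence, ref)
  expect_equal(nrow(draft$gaps), 0L)

  # shuffled order and strand still follow the reference
  draft2 <- order_and_merge_contigs(mock_contigs(c(revcomp(B), A), c(900, 900)), ref)
  expect_identical(draft2$sequence, ref)
})

test_that("non-overlapping neighbours record the intervening gap", {
  ref <- fixture("mtref6k", endophylo:::with_seed(666L, random_dna(6000)))
  A <- substr(ref, 1, 3000)
  B <- substr(ref, 3501, 6000)
  draft <- order_and_merge_contigs(mock_contigs(c(A, B), c(900, 900)), ref)
  expect_equal(draft$gaps$start, 3001)
  expect_equal(draft$gaps$end, 3500)
})

test_that("gap confirmation distinguishes deletions from assembly breaks", {
  ref <- fixture("mtref6k", endophylo:::with_seed(666L, random_dna(6000)))
  # sample genome truly lacks ref 3001-3500: junction-spanning reads exist
  sample_genome <- paste0(substr(ref, 1, 3000), substr(ref, 3501, 6000))
  reads <- substring(sample_genome,
                     seq(1, nchar(sample_genome) - 99, by = 5),
                     seq(100, nchar(sample_genome), by = 5))
  draft <- order_and_merge_contigs(
    mock_contigs(c(substr(ref, 1, 3000), substr(ref, 3501, 6000)), c(900, 900)), ref)
  rep1 <- verify_gaps(reads, draft, ref)
  expect_true(rep1$confirmed[1])
  expect_gt(rep1$support[1], 10)

  # an assembly break: reads come from the full reference, no junction reads
  reads2 <- substring(ref, seq(1, 5901, by = 5), seq(100, 6000, by = 5))
  reads2 <- reads2[!(seq_along(reads2) %in% 580:720)]  # coverage hole
  rep2 <- verify_gaps(reads2, draft, ref)
  expect_false(rep2$confirmed[1])

  # identical draft: no gaps, empty report
  full <- order_and_merge_contigs(mock_contigs(ref, 900, circular = FALSE), ref)
  expect_equal(nrow(verify_gaps(reads2, full, ref)), 0L)
})

test_that("shared gap signatures group across isolates", {
  r <- data.frame(start = 3001, end = 3500, support = 20, confirmed = TRUE)
  g <- group_gap_reports(list(iso1 = r, iso2 = r),
                         taxa = c(iso1 = "T1", iso2 = "T1"))
  expect_equal(nrow(g), 1L)
  expect_equal(g$n_isolates, 2L)
  expect_equal(g$taxa, "T1")
})

test_that("protein genes annotate at the right place, strand and identity", {
  anc <- tiny_ancestor()
  genes <- mt_reference_genes(anc)
  ann <- annotate_protein_genes(anc$mt_genome, genes)
  expect_equal(nrow(ann), 13L)
  expect_equal(ann$gene, anc$mt_genes$gene)       # reference order
  expect_equal(ann$start, anc$mt_genes$start)
  expect_equal(ann$end, anc$mt_genes$end)
  expect_true(all(ann$identity == 100))

  # reverse-complemented genome: coordinates flip, strand is '-'
  rc <- revcomp(anc$mt_genome)
  ann_rc <- annotate_protein_genes(rc, genes["cox1"])
  expect_equal(ann_rc$strand, "-")
  expect_identical(revcomp(substr(rc, ann_rc$start, ann_rc$end)),
                   unname(genes[["cox1"]]))

  # a gene diverged by ~10% is found at ~90% identity
  lin <- evolve_lineages(lineage_model(anc, lineages = "X", divergence = 0.1,
                                       indel_rate = 0), seed = 4L)
  ann_div <- annotate_protein_genes(lin$X$mt_genome, genes["nad5"])
  expect_lt(abs(ann_div$identity - 90), 3.5)
})

test_that("the complement concatenates strand-resolved in reference order", {
  anc <- tiny_ancestor()
  genes <- mt_reference_genes(anc)
  ann <- annotate_protein_genes(anc$mt_genome, genes)
  cc <- concatenate_complement(ann, anc$mt_genome)
  expect_identical(cc, paste(genes, collapse = ""))
  expect_equal(nchar(cc), sum(ann$end - ann$start + 1))

  # shuffled annotation rows still concatenate in reference order
  shuf <- ann[sample(nrow(ann)), ]
  attr(shuf, "ref_order") <- attr(ann, "ref_order")
  expect_identical(concatenate_complement(shuf, anc$mt_genome), cc)

  expect_error(concatenate_complement(ann[0, ], anc$mt_genome), "no complement")

  one <- concatenate_complement(ann[ann$gene == "cob", ], anc$mt_genome)
  expect_identical(one, unname(genes[["cob"]]))
})

test_that("genome statistics follow their definitions and survive rotation", {
  gene <- random_dna(1000)
  ann1 <- data.frame(gene = "g1", start = 1L, end = 1000L, strand = "+",
                     identity = 100)
  expect_equal(genome_stats(gene, ann1)$pct_protein_content, 100)

  genome <- random_dna(3000)
  ann2 <- data.frame(gene = c("g1", "g2"), start = c(101L, 1001L),
                     end = c(400L, 1600L), strand = "+", identity = 100)
  st <- genome_stats(genome, ann2)
  expect_equal(st$pct_protein_content, 30)
  expect_equal(st$total_length, 3000L)

  # content is invariant to rotation of a circular genome (rotation point
  # in an intergenic spacer so no gene is split across the origin)
  anc <- tiny_ancestor()
  genes <- mt_reference_genes(anc)
  cut <- anc$mt_genes$start[3] - 5L
  rot <- paste0(substr(anc$mt_genome, cut, nchar(anc$mt_genome)),
                substr(anc$mt_genome, 1, cut - 1L))
  c0 <- genome_stats(anc$mt_genome,
                     annotate_protein_genes(anc$mt_genome, genes))$pct_protein_content
  c1 <- genome_stats(rot, annotate_protein_genes(rot, genes))$pct_protein_content
  expect_equal(c0, c1, tolerance = 1e-6)
})
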