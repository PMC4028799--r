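test_that("an unmodified copy has no deletions and is functional", {
  anc <- tiny_ancestor()
  ref <- anc$markers[["perA"]]
  lin <- tiny_lineages()
  copy <- lin$FGC1$markers[["perA"]]
  expect_equal(nrow(detect_structural_deletions(copy, ref)), 0L)
  fc <- classify_copy_functionality(copy, ref, anc$marker_cds[["perA"]])
  expect_equal(fc$verdict, "functional")
  expect_equal(fc$reason, "intact")
})

test_that("planted deletions are recovered at their coordinates", {
  anc <- tiny_ancestor()
  ref <- anc$markers[["perA"]]  # 900 bp
  copy <- paste0(substr(ref, 1, 399), substr(ref, 600, 900))
  d <- detect_structural_deletions(copy, ref)
  expect_equal(nrow(d), 1L)
  expect_lte(abs(d$start - 400L), 2L)
  expect_lte(abs(d$end - 599L), 2L)
  expect_equal(d$length, 200L)

  # a 10 bp deletion sits exactly on the reporting floor; 9 bp does not
  c10 <- paste0(substr(ref, 1, 99), substr(ref, 110, 900))
  d10 <- detect_structural_deletions(c10, ref)
  expect_equal(d10$length, 10L)
  expect_lte(abs(d10$start - 100L), 2L)
  c9 <- paste0(substr(ref, 1, 99), substr(ref, 109, 900))
  expect_equal(nrow(detect_structural_deletions(c9, ref)), 0L)
})

test_that("non-homologous input is rejected", {
  anc <- tiny_ancestor()
  expect_error(detect_structural_deletions(random_dna(900), anc$markers[["perA"]]),
               "not homologous")
  expect_error(classify_copy_functionality(random_dna(900), anc$markers[["perA"]],
                                           anc$marker_cds[["perA"]]),
               "not homologous")
})

test_that("a point nonsense mutation is called premature stop", {
  anc <- tiny_ancestor()
  ref <- anc$markers[["perA"]]
  cds <- anc$marker_cds[["perA"]]
  copy <- ref
  pos <- cds[["start"]] + 3L * 49L          # codon 50
  substr(copy, pos, pos + 2L) <- "TAA"
  # direct translation oracle: the mutated CDS really carries an internal stop
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(
    substr(copy, cds[["start"]], cds[["end"]]))))
  expect_equal(substr(prot, 50, 50), "*")
  fc <- classify_copy_functionality(copy, ref, cds)
  expect_equal(fc$verdict, "non-functional")
  expect_equal(fc$reason, "premature stop")
})

test_that("frame-shifting deletions inside the CDS are non-functional", {
  anc <- tiny_ancestor()
  ref <- anc$markers[["perA"]]
  cds <- anc$marker_cds[["perA"]]
  for (len in c(100L, 329L)) {             # both lengths != 0 mod 3
    copy <- paste0(substr(ref, 1, 299), substr(ref, 300 + len, 900))
    d <- detect_structural_deletions(copy, ref)
    expect_true(any(d$length %% 3L != 0L))
    fc <- classify_copy_functionality(copy, ref, cds)
    expect_equal(fc$verdict, "non-functional")
    expect_equal(fc$reason, "frameshift")
  }
  # an in-frame deletion keeps the frame but fails the coverage floor
  copy3 <- paste0(substr(ref, 1, 299), substr(ref, 600, 900))  # 300 bp, 0 mod 3
  fc3 <- classify_copy_functionality(copy3, ref, cds)
  expect_equal(fc3$verdict, "non-functional")
  expect_equal(fc3$reason, "truncated")
})

test_that("multi-exon models project through the alignment", {
  set.seed(21)
  exon1 <- endophylo:::random_orf(300L)
  exon2_body <- substr(endophylo:::random_orf(303L), 4, 300)  # continues frame
  intron <- random_dna(150)
  gene <- paste0(random_dna(50), substr(exon1, 1, 297), intron, exon2_body,
                 "TAA", random_dna(50))
  exons <- data.frame(start = c(51L, 51L + 297L + 150L),
                      end = c(50L + 297L, 50L + 297L + 150L + 297L + 3L))
  fc <- classify_copy_functionality(gene, gene, exons)
  expect_equal(fc$verdict, "functional")
  # a 1 bp deletion inside exon 1 shifts the frame
  broken <- paste0(substr(gene, 1, 99), substr(gene, 101, nchar(gene)))
  fc2 <- classify_copy_functionality(broken, gene, exons)
  expect_equal(fc2$verdict, "non-functional")
  expect_equal(fc2$reason, "frameshift")
  # deleting the intron (not the exons) leaves the protein intact
  no_intron <- paste0(substr(gene, 1, 50 + 297), substr(gene, 51 + 297 + 150,
                                                        nchar(gene)))
  fc3 <- classify_copy_functionality(no_intron, gene, exons)
  expect_equal(fc3$verdict, "functional")
})
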