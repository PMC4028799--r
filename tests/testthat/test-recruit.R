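ref3k <- function() fixture("ref3k", endophylo:::with_seed(1234L, random_dna(3000)))

one_pair <- function(s1, s2) {
  endophylo:::new_read_pairs("p1", s1, strrep("I", nchar(s1)),
                             s2, strrep("I", nchar(s2)))
}

test_that("exact substrings and their reverse complements are recruited in sense", {
  ref <- ref3k()
  sense <- substr(ref, 501, 600)
  anti <- revcomp(substr(ref, 1501, 1600))
  p <- one_pair(sense, anti)  # mate 2 antisense, as in FR geometry
  rec <- recruit_read_pairs(p, ref, 0.1)
  expect_equal(nrow(rec), 2L)
  expect_false(rec$flipped[rec$mate == 1L])
  expect_true(rec$flipped[rec$mate == 2L])
  # both returned reads are reference-sense
  expect_identical(rec$seq[rec$mate == 1L], sense)
  expect_identical(rec$seq[rec$mate == 2L], substr(ref, 1501, 1600))
  expect_lt(max(rec$evalue), 1e-10)
})

test_that("a pair is recruited when either mate hits, and both mates return", {
  ref <- ref3k()
  hit <- substr(ref, 1001, 1100)
  junk <- random_dna(100)
  rec <- recruit_read_pairs(one_pair(hit, revcomp(junk)), ref, 0.1)
  expect_equal(nrow(rec), 2L)
  expect_true(rec$has_hit[rec$mate == 1L])
  expect_false(rec$has_hit[rec$mate == 2L])
  # the non-hitting mate is oriented by the FR geometry
  expect_true(rec$flipped[rec$mate == 2L])
})

test_that("random reads are almost never recruited at E <= 0.1", {
  ref <- ref3k()
  set.seed(33)
  n <- 2000L
  reads <- random_dna(rep(100L, n))
  p <- endophylo:::new_read_pairs(sprintf("r%04d", 1:n), reads,
                                  rep(strrep("I", 100), n),
                                  random_dna(rep(100L, n)),
                                  rep(strrep("I", 100), n))
  rec <- recruit_read_pairs(p, ref, 0.1)
  false_rate <- sum(rec$has_hit) / (2 * n)  # per-read false recruitment
  expect_lte(false_rate, 0.01)
})

test_that("recruitment is monotone in the E-value threshold", {
  lin <- tiny_lineages()
  ref <- tiny_ancestor()$markers[["tefA"]]
  pairs <- tiled_pairs(c(cp = lin$E_festucae$markers[["tefA"]]), step = 40L)
  strict <- recruit_read_pairs(pairs, ref, 1e-6)
  loose <- recruit_read_pairs(pairs, ref, 0.1)
  expect_true(all(unique(strict$id) %in% unique(loose$id)))
  expect_gte(length(unique(loose$id)), length(unique(strict$id)))
})

test_that("a reference shorter than the seed is rejected", {
  p <- one_pair(random_dna(100), random_dna(100))
  expect_error(recruit_read_pairs(p, "ACGTACGT", 0.1), "shorter than seed")
})

test_that("padding places reads at their reference offset deterministically", {
  ref <- ref3k()
  read <- substr(ref, 101, 200)
  p <- endophylo:::new_read_pairs(c("a", "b"), rep(read, 2),
                                  rep(strrep("I", 100), 2),
                                  revcomp(rep(substr(ref, 401, 500), 2)),
                                  rep(strrep("I", 100), 2))
  rec <- recruit_read_pairs(p, ref, 0.1)
  stack <- pad_to_reference(rec, ref)
  m1 <- stack[stack$mate == 1L]
  expect_equal(unique(m1$start), 101L)   # 100 leading pad columns
  expect_identical(unique(m1$placed), read)
  # identical reads give identical placements
  expect_equal(nrow(unique(m1[, .(start, placed)])), 1L)
})

test_that("reads spanning a copy-specific deletion open a gap in the stack", {
  ref <- ref3k()
  # copy lacking reference positions 1001-1250
  copy <- paste0(substr(ref, 1, 1000), substr(ref, 1251, 3000))
  junction_read <- substr(copy, 951, 1050)  # 50 bp each side of the junction
  p <- one_pair(junction_read, revcomp(substr(copy, 1201, 1300)))
  rec <- recruit_read_pairs(p, ref, 0.1)
  stack <- pad_to_reference(rec, ref)
  placed <- stack[stack$mate == 1L]
  expect_equal(placed$start, 951L)
  gap <- gregexpr("-+", placed$placed)[[1]]
  # the junction may slide a few columns when flank bases coincide with the
  # deleted sequence (score-equivalent placements, left-normalised)
  expect_lte(abs(as.integer(gap) - 51L), 4L)
  expect_equal(attr(gap, "match.length"), 250L)    # the full deleted interval
})

test_that("reads with no scorable placement go to the unplaced bin", {
  ref <- ref3k()
  hit <- substr(ref, 201, 300)
  junk <- random_dna(100)  # mate-rescued but unplaceable
  rec <- recruit_read_pairs(one_pair(hit, revcomp(junk)), ref, 0.1)
  stack <- pad_to_reference(rec, ref)
  expect_equal(nrow(stack), 1L)
  expect_equal(nrow(attr(stack, "unplaced")), 1L)
})

test_that("small indels are resolved by gapped window realignment", {
  ref <- ref3k()
  # read carrying a 2 bp deletion relative to the reference
  read <- paste0(substr(ref, 501, 550), substr(ref, 553, 602))
  p <- one_pair(read, revcomp(substr(ref, 801, 900)))
  rec <- recruit_read_pairs(p, ref, 0.1)
  stack <- pad_to_reference(rec, ref)
  placed <- stack[stack$mate == 1L]
  expect_equal(placed$start, 501L)
  expect_equal(nchar(placed$placed), 102L)  # spans 102 reference columns
  expect_equal(sum(strsplit(placed$placed, "")[[1]] == "-"), 2L)
})
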