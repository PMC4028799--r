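# Shared fixtures, built lazily in code and cached for the session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# Small ancestor/lineage set for unit tests (markers shrunk, mt minimal).
tiny_ancestor <- function() {
  fixture("tiny_anc", synth_ancestor(
    seed = 101L, marker_lengths = c(tub2 = 600L, tefA = 700L, perA = 900L),
    background_len = 12000L, mt_len = 7000L))
}

tiny_lineages <- function() {
  fixture("tiny_lin", evolve_lineages(lineage_model(tiny_ancestor()), seed = 7L))
}

# Full-size ancestor matching the study conditions (perA long enough to
# carry the canonical deletions).
study_ancestor <- function() {
  fixture("study_anc", synth_ancestor(seed = derive_seed(1L, 1L)))
}

study_lineages <- function() {
  fixture("study_lin",
          evolve_lineages(lineage_model(study_ancestor()), seed = derive_seed(1L, 2L)))
}

derive_seed <- endophylo:::derive_seed
str_identity <- endophylo:::str_identity

# Tiled error-free reads over a sequence (uniform quality Q40).
tiled_pairs <- function(seqs, read_len = 100L, step = 10L, insert = 200L) {
  ids <- character(0); s1 <- character(0); s2 <- character(0)
  for (nm in names(seqs)) {
    x <- seqs[[nm]]
    L <- nchar(x)
    starts <- seq(1L, max(1L, L - insert + 1L), by = step)
    frag <- substring(x, starts, pmin(starts + insert - 1L, L))
    keep <- nchar(frag) >= read_len
    frag <- frag[keep]
    ids <- c(ids, sprintf("%s:%04d", nm, seq_along(frag)))
    s1 <- c(s1, substring(frag, 1L, read_len))
    s2 <- c(s2, revcomp(substring(frag, nchar(frag) - read_len + 1L, nchar(frag))))
  }
  q <- strrep("I", read_len)
  endophylo:::new_read_pairs(ids, s1, rep(q, length(s1)), s2, rep(q, length(s2)))
}
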