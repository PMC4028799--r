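## Synthetic heteroploid endophyte genomes with full ground truth.
##
## The simulator emulates the biological structure the pipeline is built for:
## 2-3 diverged progenitor sub-genomes per hybrid, one copy of each nuclear
## marker gene (tub2, tefA, perA) per sub-genome with optional copy loss and
## planted multi-hundred-bp deletions, and a single high-copy circular
## mitochondrial genome carrying an ordered protein-gene complement.

# Random open reading frame: ATG + non-stop codons + TAA. `len` must be a
# multiple of 3 and >= 9.
random_orf <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  ncod <- len %/% 3L - 2L
  codons <- apply(matrix(sample(DNA_BASES, 3L * ncod, replace = TRUE), nrow = 3L),
                  2L, paste, collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  while (any(codons %in% stops)) {
    i <- which(codons %in% stops)
    codons[i] <- apply(matrix(sample(DNA_BASES, 3L * length(i), replace = TRUE),
                              nrow = 3L), 2L, paste, collapse = "")
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# Scaled-down fungal mitochondrial protein-gene complement: 13 genes in a
# fixed canonical order, used both as the simulated truth and as the
# reference gene set for annotation.
MT_GENE_LENGTHS <- c(
  cox1 = 639L, cox2 = 450L, cox3 = 480L, cob = 561L, atp6 = 420L,
  atp8 = 150L, nad1 = 501L, nad2 = 699L, nad3 = 249L, nad4 = 639L,
  nad4L = 261L, nad5 = 801L, nad6 = 300L
)

#' Synthesize an ancestral endophyte genome model
#'
#' Builds the common ancestor from which progenitor lineages are evolved:
#' three nuclear marker genes with intact single-exon coding sequences, an
#' intergenic background pool, and a circular mitochondrial genome carrying a
#' 13-gene protein-coding complement in a fixed order. Marker and genome
#' sizes default to desk-scale values; coding regions are real open reading
#' frames so that translation-based functionality calls are meaningful.
#'
#' @param seed integer seed.
#' @param marker_lengths named lengths (bp) of the `tub2`, `tefA` and `perA`
#'   marker genes. `perA` must be long enough to host planted deletions.
#' @param background_len length of the intergenic background pool per
#'   lineage, bp.
#' @param mt_len total mitochondrial genome length, bp.
#' @return an `ancestor_genome` list: `markers`, `marker_cds` (1-based
#'   inclusive CDS intervals), `background`, `mt_genome`, `mt_genes`
#'   (annotation data frame in reference order).
#' @export
synth_ancestor <- function(seed = 1L,
                           marker_lengths = c(tub2 = 1700L, tefA = 1900L, perA = 5600L),
                           background_len = 12000L,
                           mt_len = 12000L) {
  stopifnot(all(c("tub2", "tefA", "perA") %in% names(marker_lengths)),
            mt_len > sum(MT_GENE_LENGTHS) + 14L * 20L)
  with_seed(seed, {
    markers <- character(0); cds <- list()
    for (m in names(marker_lengths)) {
      L <- as.integer(marker_lengths[[m]])
      stopifnot(L >= 400L)
      cds_len <- 3L * ((L - 200L) %/% 3L)
      gene <- paste0(random_dna(100L), random_orf(cds_len),
                     random_dna(L - 100L - cds_len))
      markers[m] <- gene
      cds[[m]] <- c(start = 101L, end = 100L + cds_len)
    }
    spacer_total <- mt_len - sum(MT_GENE_LENGTHS)
    sp <- as.vector(stats::rmultinom(1L, spacer_total - 14L * 20L, rep(1 / 14, 14))) + 20L
    pieces <- character(0); ann <- list(); pos <- 0L
    for (i in seq_along(MT_GENE_LENGTHS)) {
      pieces <- c(pieces, random_dna(sp[i]))
      pos <- pos + sp[i]
      g <- random_orf(MT_GENE_LENGTHS[[i]])
      ann[[i]] <- data.frame(gene = names(MT_GENE_LENGTHS)[i],
                             start = pos + 1L,
                             end = pos + MT_GENE_LENGTHS[[i]],
                             strand = "+", stringsAsFactors = FALSE)
      pieces <- c(pieces, g)
      pos <- pos + MT_GENE_LENGTHS[[i]]
    }
    pieces <- c(pieces, random_dna(sp[14]))
    structure(list(
      markers = markers,
      marker_cds = cds,
      background = random_dna(background_len),
      mt_genome = paste(pieces, collapse = ""),
      mt_genes = do.call(rbind, ann)
    ), class = "ancestor_genome")
  })
}

#' Mitochondrial reference gene set of an ancestor model
#'
#' Extracts the ordered protein-gene sequences from an `ancestor_genome`,
#' for use as the annotation reference (the role a curated outgroup gene set
#' plays on real data).
#'
#' @param ancestor an `ancestor_genome`.
#' @return named character vector of gene sequences in reference order.
#' @export
mt_reference_genes <- function(ancestor) {
  ann <- ancestor$mt_genes
  out <- substring(ancestor$mt_genome, ann$start, ann$end)
  names(out) <- ann$gene
  out
}

#' Progenitor lineage model
#'
#' Describes how sexual progenitor lineages diverge from the common
#' ancestor: iid substitutions at `divergence` expected substitutions/site
#' (Jukes-Cantor style, uniform over the three alternative bases) and indels
#' at `indel_rate` per site with geometric lengths (mean `indel_mean_len`).
#' Coding regions evolve under purifying selection: substitutions creating
#' in-frame stop codons are rejected and indels are excluded, so marker and
#' mitochondrial ORFs stay intact unless a lesion is planted explicitly.
#'
#' @param ancestor an `ancestor_genome` from [synth_ancestor()].
#' @param lineages character vector of lineage labels.
#' @param divergence expected substitutions/site; scalar or per-lineage
#'   vector, each in [0, 0.75).
#' @param indel_rate indel events per site (>= 0).
#' @param indel_mean_len mean indel length, bp.
#' @return a `lineage_model` list.
#' @export
lineage_model <- function(ancestor,
                          lineages = c("E_festucae", "E_typhina", "FGC1", "E_bromicola"),
                          divergence = 0.05,
                          indel_rate = 2e-4,
                          indel_mean_len = 3) {
  stopifnot(inherits(ancestor, "ancestor_genome"), length(lineages) >= 1L)
  p <- rep_len(divergence, length(lineages))
  if (any(p < 0 | p >= 0.75)) {
    stop("lineage_model: divergence must lie in [0, 0.75)", call. = FALSE)
  }
  if (indel_rate < 0) stop("lineage_model: indel_rate must be >= 0", call. = FALSE)
  structure(list(ancestor = ancestor, lineages = lineages,
                 divergence = stats::setNames(p, lineages),
                 indel_rate = indel_rate, indel_mean_len = indel_mean_len),
            class = "lineage_model")
}

# Evolve one sequence: substitutions everywhere, indels outside `protect`
# intervals, stop-codon creation inside protected ORFs reverted (purifying
# selection). `protect` is a data.frame(start, end) of ORF intervals in
# frame with their start coordinate.
evolve_seq <- function(seq, p, indel_rate, indel_mean_len, protect = NULL) {
  ch <- str_chars(seq)
  anc <- ch
  L <- length(ch)
  idx <- which(stats::runif(L) < p)
  n_sub <- length(idx)
  if (n_sub) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- sample.int(3L, n_sub, replace = TRUE)
    ch[idx] <- vapply(seq_len(n_sub),
                      function(i) alt[[ch[idx[i]]]][pick[i]] %||% "N", character(1))
  }
  if (!is.null(protect) && nrow(protect)) {
    for (j in seq_len(nrow(protect))) {
      s <- protect$start[j]; e <- protect$end[j]
      starts <- seq(s, e - 2L, by = 3L)
      cod <- paste0(ch[starts], ch[starts + 1L], ch[starts + 2L])
      anc_cod <- paste0(anc[starts], anc[starts + 1L], anc[starts + 2L])
      bad <- which(cod %in% c("TAA", "TAG", "TGA") & cod != anc_cod)
      bad <- union(bad, 1L)  # keep the start codon
      for (b in bad) {
        ii <- starts[b] + 0:2
        ch[ii] <- anc[ii]
      }
    }
  }
  n_sub <- sum(ch != anc)
  indels <- data.frame(pos = integer(0), type = character(0), len = integer(0))
  if (indel_rate > 0) {
    n_ind <- stats::rbinom(1L, L, indel_rate)
    if (n_ind > 0) {
      pos <- sort(sample.int(L, n_ind))
      len <- 1L + stats::rgeom(n_ind, 1 / indel_mean_len)
      type <- sample(c("ins", "del"), n_ind, replace = TRUE)
      keep <- rep(TRUE, n_ind)
      if (!is.null(protect) && nrow(protect)) {
        for (j in seq_len(nrow(protect))) {
          hit <- pos + ifelse(type == "del", len - 1L, 0L) >= protect$start[j] &
            pos <= protect$end[j]
          keep <- keep & !hit
        }
      }
      pos <- pos[keep]; len <- len[keep]; type <- type[keep]
      for (i in rev(seq_along(pos))) {
        if (type[i] == "del") {
          e <- min(pos[i] + len[i] - 1L, length(ch))
          ch <- ch[-(pos[i]:e)]
        } else {
          ins <- sample(DNA_BASES, len[i], replace = TRUE)
          ch <- append(ch, ins, after = pos[i])
        }
      }
      indels <- data.frame(pos = pos, type = type, len = len)
    }
  }
  list(seq = chars_str(ch), n_sub = n_sub, indels = indels)
}

#' Evolve progenitor lineages from the ancestor
#'
#' Derives each lineage's marker genes, background and mitochondrial genome
#' from the ancestor by the substitution/indel process of the model. All
#' events are recorded so downstream stages can be scored against truth.
#'
#' @param model a [lineage_model()].
#' @param seed integer seed; the same seed reproduces the same lineages.
#' @return a `lineage_set`: named list of lineages, each with `markers`,
#'   `background`, `mt_genome` and an `events` record; the model is kept in
#'   the `"model"` attribute.
#' @export
evolve_lineages <- function(model, seed = 1L) {
  stopifnot(inherits(model, "lineage_model"))
  anc <- model$ancestor
  out <- list()
  for (i in seq_along(model$lineages)) {
    ln <- model$lineages[i]
    p <- model$divergence[[ln]]
    with_seed(derive_seed(seed, i), {
      markers <- character(0)
      ev <- list()
      for (m in names(anc$markers)) {
        # purifying selection across promoter+CDS keeps marker coordinates
        # stable; indels accumulate in intergenic background instead
        prot <- data.frame(start = anc$marker_cds[[m]][["start"]],
                           end = anc$marker_cds[[m]][["end"]])
        res <- evolve_seq(anc$markers[[m]], p, 0, model$indel_mean_len, prot)
        markers[m] <- res$seq
        ev[[m]] <- res[c("n_sub", "indels")]
      }
      bg <- evolve_seq(anc$background, p, model$indel_rate, model$indel_mean_len)
      mt <- evolve_seq(anc$mt_genome, p, model$indel_rate, model$indel_mean_len,
                       protect = anc$mt_genes[, c("start", "end")])
      out[[ln]] <- list(name = ln, markers = markers, background = bg$seq,
                        mt_genome = mt$seq,
                        events = list(markers = ev, background = bg[-1], mt = mt[-1]))
    })
  }
  structure(out, class = "lineage_set", model = model)
}

#' Compose a heteroploid hybrid genome
#'
#' Builds a hybrid carrying one copy of each marker per donor sub-genome
#' (minus planted losses), each embedded in >= 2 kb of donor background on a
#' randomly chosen strand, together with the mitochondrial genome of the
#' designated donor. Planted deletions, premature-stop lesions, copy losses
#' and the mitochondrial copy-number ratio are all recorded verbatim in the
#' returned truth.
#'
#' @param lineages a `lineage_set` from [evolve_lineages()].
#' @param donors character vector (1-3) of donor lineage names.
#' @param losses optional `data.frame(marker, donor)` of lost copies.
#' @param deletions optional `data.frame(marker, donor, start, end)` of
#'   excised intervals (1-based inclusive, marker coordinates).
#' @param lesions optional `data.frame(marker, donor, codon)` premature-stop
#'   lesions (codon index within the marker CDS set to TAA).
#' @param mt_donor lineage donating the mitochondrial genome.
#' @param mt_deletion optional `c(start, end)` interval removed from the
#'   hybrid mitochondrial genome (donor-genome coordinates).
#' @param r mitochondrial / nuclear depth ratio (>= 1).
#' @param seed integer seed (strand choices, flank sampling).
#' @param flank_len background flank length per side, bp (>= 2000).
#' @return a `hybrid_genome`: `chromosomes` (one per donor), `mt_genome`,
#'   and `truth` (sub-genome count k, per-copy sequences and donors, planted
#'   deletions/losses/lesions, mt donor and copy ratio).
#' @export
compose_heteroploid <- function(lineages, donors, losses = NULL,
                                deletions = NULL, lesions = NULL,
                                mt_donor = donors[[1]], mt_deletion = NULL,
                                r = 100, seed = 1L, flank_len = 2200L) {
  stopifnot(inherits(lineages, "lineage_set"))
  if (!all(donors %in% names(lineages))) {
    stop("compose_heteroploid: donors must be a subset of the lineage set", call. = FALSE)
  }
  if (!(length(donors) %in% 1:3)) {
    stop("compose_heteroploid: 1-3 donor sub-genomes supported", call. = FALSE)
  }
  if (r < 1) stop("compose_heteroploid: mt copy ratio r must be >= 1", call. = FALSE)
  model <- attr(lineages, "model")
  anc <- model$ancestor
  marker_names <- names(anc$markers)
  lost <- function(m, d) {
    !is.null(losses) && nrow(losses) &&
      any(losses$marker == m & losses$donor == d)
  }
  copies <- list(); chroms <- character(0)
  with_seed(derive_seed(seed, 101L), {
    for (d in donors) {
      lin <- lineages[[d]]
      blocks <- character(0)
      bg <- lin$background
      bg_pos <- 1L
      take_bg <- function() {
        len <- flank_len + sample.int(400L, 1L)
        if (bg_pos + len - 1L > nchar(bg)) bg_pos <<- 1L
        s <- substr(bg, bg_pos, bg_pos + len - 1L)
        bg_pos <<- bg_pos + len
        s
      }
      pos <- 0L
      for (m in marker_names) {
        b <- take_bg(); blocks <- c(blocks, b); pos <- pos + nchar(b)
        if (lost(m, d)) next
        cp <- lin$markers[[m]]
        if (!is.null(lesions) && nrow(lesions)) {
          sel <- lesions$marker == m & lesions$donor == d
          for (j in which(sel)) {
            cs <- anc$marker_cds[[m]][["start"]] + 3L * (lesions$codon[j] - 1L)
            if (cs + 2L > nchar(cp)) {
              stop("compose_heteroploid: lesion codon outside CDS", call. = FALSE)
            }
            substr(cp, cs, cs + 2L) <- "TAA"
          }
        }
        if (!is.null(deletions) && nrow(deletions)) {
          sel <- which(deletions$marker == m & deletions$donor == d)
          ints <- deletions[sel, , drop = FALSE]
          if (nrow(ints)) {
            if (any(ints$start < 1L | ints$end > nchar(lin$markers[[m]]) |
                    ints$start > ints$end)) {
              stop("compose_heteroploid: deletion interval outside gene", call. = FALSE)
            }
            for (j in order(ints$start, decreasing = TRUE)) {
              cp <- paste0(substr(cp, 1L, ints$start[j] - 1L),
                           substr(cp, ints$end[j] + 1L, nchar(cp)))
            }
          }
        }
        strand <- sample(c("+", "-"), 1L)
        emb <- if (strand == "+") cp else revcomp(cp)
        blocks <- c(blocks, emb)
        copies[[length(copies) + 1L]] <- data.frame(
          marker = m, donor = d, strand = strand, chrom = d,
          start = pos + 1L, seq = cp, stringsAsFactors = FALSE)
        pos <- pos + nchar(emb)
      }
      blocks <- c(blocks, take_bg())
      chroms[d] <- paste(blocks, collapse = "")
    }
  })
  mt <- lineages[[mt_donor]]$mt_genome
  if (!is.null(mt_deletion)) {
    stopifnot(length(mt_deletion) == 2L, mt_deletion[1] >= 1L,
              mt_deletion[2] <= nchar(mt), mt_deletion[1] <= mt_deletion[2])
    mt <- paste0(substr(mt, 1L, mt_deletion[1] - 1L),
                 substr(mt, mt_deletion[2] + 1L, nchar(mt)))
  }
  structure(list(
    chromosomes = chroms,
    mt_genome = mt,
    truth = list(
      k = length(donors), donors = donors,
      copies = do.call(rbind, copies),
      losses = losses, deletions = deletions, lesions = lesions,
      mt_donor = mt_donor, mt_deletion = mt_deletion, r = r)
  ), class = "hybrid_genome")
}

# Shared quality profile: constant Q40 with a quality drop over the last 10
# cycles (39 down to 30); per-base error probability follows the quality.
quality_profile <- function(read_len) {
  if (read_len <= 10L) return(rep(35L, read_len))
  c(rep(40L, read_len - 10L), 39:30)
}

# Draw paired-end fragments from one source sequence and sequence both ends.
sim_source_reads <- function(source, src_name, coverage, circular, config) {
  L <- nchar(source)
  rl <- config$read_len
  n <- max(1L, round(L * coverage / (2 * rl)))
  flen <- pmin(pmax(round(stats::rnorm(n, config$insert_size_bp, config$insert_sd_bp)),
                    config$fragment_min_bp), config$fragment_max_bp)
  flen <- pmin(flen, L)
  if (circular) {
    start <- sample.int(L, n, replace = TRUE)
    endp <- start + flen - 1L
    wrap <- endp > L
    frag <- character(n)
    frag[!wrap] <- substring(source, start[!wrap], endp[!wrap])
    if (any(wrap)) {
      frag[wrap] <- paste0(substring(source, start[wrap], L),
                           substring(source, 1L, endp[wrap] - L))
    }
  } else {
    start <- vapply(flen, function(fl) sample.int(L - fl + 1L, 1L), integer(1))
    frag <- substring(source, start, start + flen - 1L)
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  frag[strand == "-"] <- revcomp(frag[strand == "-"])
  m1 <- substring(frag, 1L, rl)
  m2 <- revcomp(substring(frag, flen - rl + 1L, flen))
  list(id = sprintf("%s:%06d", src_name, seq_len(n)),
       seq1 = m1, seq2 = m2,
       truth = data.frame(id = sprintf("%s:%06d", src_name, seq_len(n)),
                          source = src_name, start = start, frag_len = flen,
                          strand = strand, stringsAsFactors = FALSE))
}

# Inject substitution errors at the rate implied by the quality profile.
apply_seq_errors <- function(reads, qprof) {
  perr <- 10^(-qprof / 10)
  n <- length(reads)
  for (cyc in seq_along(perr)) {
    nerr <- stats::rbinom(1L, n, perr[cyc])
    if (nerr == 0L) next
    rows <- sample.int(n, nerr)
    rows <- rows[nchar(reads[rows]) >= cyc]
    for (i in rows) {
      cur <- substr(reads[i], cyc, cyc)
      substr(reads[i], cyc, cyc) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }
  reads
}

#' Simulate paired-end sequencing of a hybrid genome
#'
#' Draws fragments uniformly from each nuclear chromosome at
#' `coverage_nuclear` and from the circular mitochondrial genome at
#' `r * coverage_nuclear` (fragments may span the origin). Fragment lengths
#' are Normal(insert_size, sd) truncated to the configured bounds; mate 2 is
#' the reverse complement of the fragment end (FR orientation). Per-base
#' substitution errors follow the quality profile (Q40 with a 10-cycle
#' 3'-tail drop).
#'
#' @param hybrid a `hybrid_genome` (or any named list of `chromosomes` plus
#'   optional `mt_genome`).
#' @param coverage_nuclear haploid per-sub-genome fold coverage (> 0).
#' @param config a [pipeline_config()].
#' @param seed integer seed.
#' @param r mitochondrial/nuclear depth ratio; defaults to the hybrid truth.
#' @param include_mt set `FALSE` to sequence the nuclear genome only (for
#'   experiments that do not touch the organelle).
#' @param error_rate optional constant per-base substitution rate overriding
#'   the quality-derived model (0 gives noiseless reads).
#' @return list with `pairs` (a `read_pairs`) and `truth` (per-fragment
#'   source, start, length and strand placements).
#' @export
simulate_paired_reads <- function(hybrid, coverage_nuclear, config = pipeline_config(),
                                  seed = 1L, r = NULL, include_mt = TRUE,
                                  error_rate = NULL) {
  if (!is_scalar_number(coverage_nuclear) || coverage_nuclear <= 0) {
    stop("simulate_paired_reads: coverage must be positive", call. = FALSE)
  }
  r <- r %||% (hybrid$truth$r %||% 100)
  qprof <- quality_profile(config$read_len)
  qstr <- phred_encode(qprof)
  eprof <- if (is.null(error_rate)) qprof else rep(-10 * log10(max(error_rate, 1e-12)),
                                                   config$read_len)
  parts <- list()
  with_seed(derive_seed(seed, 7L), {
    for (nm in names(hybrid$chromosomes)) {
      parts[[nm]] <- sim_source_reads(hybrid$chromosomes[[nm]], nm,
                                      coverage_nuclear, FALSE, config)
    }
    if (include_mt && !is.null(hybrid$mt_genome)) {
      parts[["mt"]] <- sim_source_reads(hybrid$mt_genome, "mt",
                                        r * coverage_nuclear, TRUE, config)
    }
    seq1 <- apply_seq_errors(unlist(lapply(parts, `[[`, "seq1"), use.names = FALSE), eprof)
    seq2 <- apply_seq_errors(unlist(lapply(parts, `[[`, "seq2"), use.names = FALSE), eprof)
  })
  id <- unlist(lapply(parts, `[[`, "id"), use.names = FALSE)
  pairs <- new_read_pairs(id, seq1, rep(qstr, length(id)), seq2, rep(qstr, length(id)))
  list(pairs = pairs, truth = do.call(rbind, c(lapply(parts, `[[`, "truth"),
                                               make.row.names = FALSE)))
}

#' Study presets mirroring the analysed endophyte taxa
#'
#' Hybrid compositions reproducing the copy-number, lesion and
#' mitochondrial-donor structure of the six analysed taxa: a tri-parental
#' hybrid with three copies of every marker, bi-parental hybrids with two,
#' a taxon with a planted tub2 copy loss, and the shared perA deletions
#' (1251-1878 and 4590-4918) and premature-stop lesions that drive the
#' functionality patterns.
#'
#' @return named list of composition specs consumable by
#'   [compose_heteroploid()].
#' @export
default_study <- function() {
  perA_dels <- function(donor) data.frame(
    marker = "perA", donor = donor,
    start = c(1251L, 4590L), end = c(1878L, 4918L), stringsAsFactors = FALSE)
  list(
    N_coenophialum = list(
      donors = c("E_festucae", "E_typhina", "FGC1"),
      lesions = data.frame(marker = "perA", donor = "FGC1", codon = 300L),
      mt_donor = "E_festucae"),
    FaTG2 = list(
      donors = c("E_festucae", "FGC1"),
      deletions = perA_dels("FGC1"),
      mt_donor = "E_festucae"),
    FaTG3 = list(
      donors = c("E_typhina", "FGC1"),
      deletions = perA_dels("FGC1"),
      mt_donor = "E_festucae"),
    UNS = list(
      donors = c("E_festucae", "FGC1"),
      deletions = perA_dels("FGC1"),
      lesions = data.frame(marker = "perA", donor = "E_festucae", codon = 450L),
      mt_donor = "FGC1"),
    N_uncinatum = list(
      donors = c("E_typhina", "E_bromicola"),
      losses = data.frame(marker = "tub2", donor = "E_bromicola"),
      lesions = data.frame(marker = "perA", donor = "E_bromicola", codon = 200L),
      mt_donor = "E_typhina")
  )
}

#' Compose one preset hybrid from a lineage set
#'
#' Convenience wrapper applying a [default_study()] composition spec.
#'
#' @param lineages a `lineage_set`.
#' @param spec one element of [default_study()].
#' @param seed integer seed.
#' @param r mitochondrial/nuclear depth ratio.
#' @return a `hybrid_genome` (see [compose_heteroploid()]).
#' @export
compose_preset <- function(lineages, spec, seed = 1L, r = 100) {
  compose_heteroploid(lineages, donors = spec$donors,
                      losses = spec$losses, deletions = spec$deletions,
                      lesions = spec$lesions,
                      mt_donor = spec$mt_donor %||% spec$donors[[1]],
                      mt_deletion = spec$mt_deletion, r = r, seed = seed)
}
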