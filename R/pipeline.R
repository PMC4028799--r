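## End-to-end pipeline orchestration and report writing.

n50 <- function(lens) {
  if (!length(lens)) return(0L)
  lens <- sort(lens, decreasing = TRUE)
  lens[which(cumsum(lens) >= sum(lens) / 2)[1L]]
}

#' Assemble and classify the mitochondrial genome from reads
#'
#' Two-pass, mirroring the coverage-cut-off protocol: a first assembly at
#' each odd k-mer size in the configured range locates the depth valley
#' separating mitochondrial from nuclear contigs; the best k (maximum
#' mt-contig N50, subject to total classified length within 20% of the
#' reference length) is then re-assembled with that cut-off applied as the
#' k-mer pruning threshold, which removes both nuclear k-mers and the
#' sequencing-error k-mers that fragment a very deep organelle graph.
#'
#' @param pairs a `read_pairs` object (quality-trimmed).
#' @param ref_mt reference mitochondrial genome sequence.
#' @param config a [pipeline_config()].
#' @return list: `k` (chosen k-mer size), `contigs` (final assembly),
#'   `classification` (from [classify_mt_contigs()]), `scan` (per-k summary
#'   table of the first pass).
#' @export
assemble_mt <- function(pairs, ref_mt, config = pipeline_config()) {
  ks <- seq(config$kmer_min, config$kmer_max, by = 2L)
  ref_len <- nchar(ref_mt)
  scan <- list()
  results <- list()
  for (k in ks) {
    contigs <- suppressWarnings(
      assemble_contigs(pairs, k, config$min_contig_len))
    if (!nrow(contigs)) next
    cls <- suppressWarnings(
      classify_mt_contigs(contigs, ref_mt, config$mt_evalue))
    mtc <- cls$mt_contigs
    if (!nrow(mtc)) next
    tot <- sum(mtc$length)
    scan[[as.character(k)]] <- data.frame(
      k = k, n_contigs = nrow(mtc), total_length = tot,
      n50 = n50(mtc$length), within_20pct = abs(tot - ref_len) / ref_len <= 0.2)
    results[[as.character(k)]] <- list(k = k, contigs = contigs, classification = cls)
  }
  if (!length(scan)) {
    stop("assemble_mt: no mitochondrial contigs recovered at any k", call. = FALSE)
  }
  scan <- do.call(rbind, c(scan, make.row.names = FALSE))
  pool <- if (any(scan$within_20pct)) scan[scan$within_20pct, ] else scan
  kbest <- pool$k[which.max(pool$n50)]
  out <- results[[as.character(kbest)]]
  cutoff <- out$classification$coverage_cutoff
  if (!is.na(cutoff)) {
    # second pass: the located cut-off becomes the pruning threshold
    # (contig depths are combined-strand, k-mer counts are per strand)
    contigs2 <- suppressWarnings(
      assemble_contigs(pairs, kbest, config$min_contig_len,
                       prune = max(2L, ceiling(cutoff / 2))))
    if (nrow(contigs2)) {
      cls2 <- suppressWarnings(
        classify_mt_contigs(contigs2, ref_mt, config$mt_evalue,
                            coverage_cutoff = cutoff))
      if (nrow(cls2$mt_contigs)) {
        out <- list(k = kbest, contigs = contigs2, classification = cls2)
      }
    }
  }
  out$scan <- scan
  out
}

#' Assign recovered copies to donor lineages
#'
#' Each recovered copy is assigned the reference lineage it is closest to in
#' p-distance on the per-gene alignment (the tree-placement criterion: on a
#' clean phylogeny the nearest reference is the copy's sister lineage).
#'
#' @param dist p-distance matrix over copies and references.
#' @param copy_names,ref_names row label subsets.
#' @return named character vector: copy -> reference lineage.
#' @export
assign_copy_origins <- function(dist, copy_names, ref_names) {
  vapply(copy_names, function(cp) {
    ref_names[which.min(dist[cp, ref_names])]
  }, character(1))
}

process_marker <- function(qc_pairs, marker, reference, cds, config) {
  rec <- recruit_read_pairs(qc_pairs, reference, config$recruit_evalue)
  if (nrow(rec) == 0L) {
    stop(sprintf("stage copy_recovery [%s]: zero recruited reads", marker),
         call. = FALSE)
  }
  stack <- pad_to_reference(rec, reference)
  cset <- phase_gene_copies(stack, marker = marker)
  copies <- list()
  for (ci in seq_len(cset$k)) {
    cons <- cset$consensus[[ci]]
    dels <- detect_structural_deletions(cons, reference)
    func <- classify_copy_functionality(cons, reference, cds)
    copies[[ci]] <- list(consensus = cons, deletions = dels, func = func)
  }
  list(recruited = nrow(rec), copyset = cset, copies = copies)
}

#' Run the full pipeline
#'
#' Orchestrates simulation (or reading of real inputs), quality control,
#' per-marker copy recovery, structural/functional copy characterisation,
#' mitochondrial genome assembly and annotation, and phylogenetic analysis,
#' writing a report directory of FASTA, Newick and TSV outputs. All
#' randomness derives from `config$rng_seed`; two runs with the same seed
#' and inputs produce identical reports.
#'
#' @param config a [pipeline_config()].
#' @param input `"synthetic"` (bundled simulator) or a named list with
#'   elements `r1`, `r2` (FASTQ paths), `markers` (FASTA of reference
#'   genes), `mt` (reference mt genome FASTA) and `mt_genes` (FASTA of
#'   reference mt protein genes in order).
#' @param outdir report directory (created).
#' @param study for synthetic input, the hybrid compositions to simulate
#'   (see [default_study()]).
#' @param coverage nuclear fold coverage per sub-genome for simulation.
#' @param mt_ratio mitochondrial/nuclear depth ratio for simulation.
#' @param ancestor_args overrides passed to [synth_ancestor()] (genome
#'   sizes).
#' @param qc [qc_params()] for trimming.
#' @param do_mito,do_phylo stage switches.
#' @return invisibly, a list with all per-taxon results and report paths.
#' @export
run_pipeline <- function(config = pipeline_config(), input = "synthetic",
                         outdir = file.path(tempdir(), "endophylo_report"),
                         study = default_study(), coverage = 50,
                         mt_ratio = 20, ancestor_args = list(),
                         qc = qc_params(), do_mito = TRUE, do_phylo = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "copies"), showWarnings = FALSE)
  dir.create(file.path(outdir, "mt"), showWarnings = FALSE)
  dir.create(file.path(outdir, "trees"), showWarnings = FALSE)
  log <- file.path(outdir, "pipeline.log")
  cat(sprintf("endophylo pipeline, seed %d\n", config$rng_seed), file = log)
  logmsg <- function(...) cat(sprintf(...), "\n", file = log, append = TRUE)

  synthetic <- identical(input, "synthetic")
  if (synthetic) {
    anc <- do.call(synth_ancestor,
                   c(list(seed = derive_seed(config$rng_seed, 1L)), ancestor_args))
    model <- lineage_model(anc)
    lineages <- evolve_lineages(model, seed = derive_seed(config$rng_seed, 2L))
    markers <- anc$markers
    marker_cds <- anc$marker_cds
    ref_mt <- anc$mt_genome
    ref_genes <- mt_reference_genes(anc)
    samples <- names(study)
  } else {
    if (!all(c("r1", "r2", "markers") %in% names(input))) {
      stop("stage input: need r1, r2 and markers for real input", call. = FALSE)
    }
    markers <- parse_fasta(input$markers)
    marker_cds <- lapply(markers, function(s) c(start = 1L, end = 3L * (nchar(s) %/% 3L)))
    ref_mt <- if (!is.null(input$mt)) parse_fasta(input$mt)[[1]] else NULL
    ref_genes <- if (!is.null(input$mt_genes)) parse_fasta(input$mt_genes) else NULL
    samples <- "sample"
  }

  results <- list()
  for (si in seq_along(samples)) {
    taxon <- samples[si]
    logmsg("processing %s", taxon)
    if (synthetic) {
      hybrid <- compose_preset(lineages, study[[taxon]],
                               seed = derive_seed(config$rng_seed, 10L + si),
                               r = mt_ratio)
      sim <- simulate_paired_reads(hybrid, coverage, config,
                                   seed = derive_seed(config$rng_seed, 50L + si))
      pairs <- sim$pairs
    } else {
      hybrid <- NULL
      pairs <- parse_fastq_pairs(input$r1, input$r2)
    }
    qc_res <- trim_and_filter(pairs, qc)
    logmsg("  QC: %d of %d pairs survive", qc_res$stats$pairs_out, qc_res$stats$pairs_in)
    mk_res <- list()
    for (m in names(markers)) {
      mk_res[[m]] <- process_marker(qc_res$pairs, m, markers[[m]],
                                    marker_cds[[m]], config)
      cons <- mk_res[[m]]$copyset$consensus
      names(cons) <- paste0(taxon, ".", names(cons))
      write_fasta(cons, file.path(outdir, "copies", sprintf("%s_%s.fasta", taxon, m)))
      logmsg("  %s: k = %d", m, mk_res[[m]]$copyset$k)
    }
    mt_res <- NULL
    if (do_mito && !is.null(ref_mt)) {
      asm <- assemble_mt(qc_res$pairs, ref_mt, config)
      draft <- order_and_merge_contigs(asm$classification$mt_contigs, ref_mt)
      gaps <- verify_gaps(qc_res$pairs, draft, ref_mt, config$max_gap_openings)
      ann <- annotate_protein_genes(draft$sequence, ref_genes)
      stats <- genome_stats(draft$sequence, ann,
                            ref_complement = paste(ref_genes, collapse = ""))
      write_fasta(stats::setNames(draft$sequence, paste0(taxon, "_mt")),
                  file.path(outdir, "mt", sprintf("%s_mt.fasta", taxon)))
      utils::write.table(ann, file.path(outdir, "mt", sprintf("%s_mt_genes.tsv", taxon)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      mt_res <- list(assembly = asm, draft = draft, gaps = gaps,
                     annotations = ann, stats = stats)
      logmsg("  mt: %d contigs, %d bp, k = %d", nrow(asm$classification$mt_contigs),
             stats$total_length, asm$k)
    }
    results[[taxon]] <- list(hybrid = hybrid, qc = qc_res$stats,
                             markers = mk_res, mt = mt_res)
  }

  # report tables
  counts <- do.call(rbind, lapply(names(results), function(tx) {
    data.frame(taxon = tx, t(vapply(names(markers), function(m) {
      results[[tx]]$markers[[m]]$copyset$k
    }, integer(1))))
  }))
  utils::write.table(counts, file.path(outdir, "copy_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  func_rows <- list(); del_rows <- list()
  for (tx in names(results)) {
    for (m in names(markers)) {
      cps <- results[[tx]]$markers[[m]]$copies
      for (ci in seq_along(cps)) {
        fc <- cps[[ci]]$func
        func_rows[[length(func_rows) + 1L]] <- data.frame(
          taxon = tx, marker = m, copy = ci, verdict = fc$verdict,
          reason = fc$reason)
        dl <- cps[[ci]]$deletions
        if (nrow(dl)) {
          del_rows[[length(del_rows) + 1L]] <- cbind(
            data.frame(taxon = tx, marker = m, copy = ci), dl)
        }
      }
    }
  }
  functionality <- do.call(rbind, func_rows)
  utils::write.table(functionality, file.path(outdir, "functionality.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  deldf <- if (length(del_rows)) do.call(rbind, del_rows) else
    data.frame(taxon = character(0), marker = character(0), copy = integer(0),
               start = integer(0), end = integer(0), length = integer(0))
  utils::write.table(deldf, file.path(outdir, "deletions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (do_mito) {
    mt_rows <- lapply(names(results), function(tx) {
      mr <- results[[tx]]$mt
      if (is.null(mr)) return(NULL)
      data.frame(taxon = tx,
                 n_contigs = nrow(mr$assembly$classification$mt_contigs),
                 coverage = round(mean(mr$assembly$classification$mt_contigs$depth)),
                 mr$stats)
    })
    mt_tab <- do.call(rbind, mt_rows)
    if (!is.null(mt_tab)) {
      utils::write.table(mt_tab, file.path(outdir, "mt_stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  phylo <- NULL
  if (do_phylo && synthetic) {
    phylo <- pipeline_phylogenetics(results, lineages, anc, config, outdir)
  }
  out <- list(outdir = outdir, results = results, copy_counts = counts,
              functionality = functionality, deletions = deldf, phylo = phylo)
  if (synthetic) {
    out$ancestor <- anc
    out$lineages <- lineages
  }
  invisible(out)
}

# Per-gene and concatenated phylogenies of recovered copies plus reference
# lineage sequences, with donor-origin assignment from the per-gene trees.
pipeline_phylogenetics <- function(results, lineages, anc, config, outdir) {
  marker_names <- names(anc$markers)
  gene_trees <- list(); origins <- list(); msas <- list()
  for (m in marker_names) {
    seqs <- stats::setNames(
      vapply(names(lineages), function(ln) lineages[[ln]]$markers[[m]], character(1)),
      names(lineages))
    seqs <- c(stats::setNames(anc$markers[m], "ancestor"), seqs)
    for (tx in names(results)) {
      cons <- results[[tx]]$markers[[m]]$copyset$consensus
      names(cons) <- paste0(tx, ".", names(cons))
      seqs <- c(seqs, cons)
    }
    msa <- strip_ambiguous_columns(progressive_align(seqs))
    msas[[m]] <- msa
    cons_tree <- bootstrap_consensus(msa, "nj", reps = config$bootstrap_reps,
                                     seed = derive_seed(config$rng_seed, 200L + match(m, marker_names)))
    gene_trees[[m]] <- cons_tree
    write_newick(cons_tree, file.path(outdir, "trees", sprintf("%s_nj_consensus.nwk", m)))
    D <- p_distance_matrix(msa)
    copy_names <- setdiff(names(seqs), c("ancestor", names(lineages)))
    origins[[m]] <- assign_copy_origins(D, copy_names, names(lineages))
  }
  # concatenated supermatrix over (taxon, origin) sub-genomes
  copies_by_marker <- lapply(marker_names, function(m) {
    o <- origins[[m]]
    sg <- stats::setNames(character(0), character(0))
    for (cp in names(o)) {
      tx <- sub("\\..*$", "", cp)
      cons <- results[[tx]]$markers[[m]]$copyset$consensus
      key <- paste0(tx, "|", o[[cp]])
      sg[key] <- cons[[sub("^[^.]*\\.", "", cp)]]
    }
    sg
  })
  names(copies_by_marker) <- marker_names
  ref_lengths <- vapply(anc$markers, nchar, integer(1))
  concat <- concatenate_markers(copies_by_marker, order = c("tub2", "tefA", "perA"),
                                ref_lengths = ref_lengths)
  ref_concat <- vapply(names(lineages), function(ln) {
    paste(vapply(c("tub2", "tefA", "perA"), function(m) lineages[[ln]]$markers[[m]],
                 character(1)), collapse = "")
  }, character(1))
  anc_concat <- paste(anc$markers[c("tub2", "tefA", "perA")], collapse = "")
  allseq <- c(stats::setNames(anc_concat, "ancestor"), ref_concat, concat$sequences)
  concat_tree <- NULL
  if (length(allseq) >= 3L) {
    cmsa <- strip_ambiguous_columns(progressive_align(allseq))
    concat_tree <- bootstrap_consensus(cmsa, "nj", reps = config$bootstrap_reps,
                                       seed = derive_seed(config$rng_seed, 300L))
    write_newick(concat_tree, file.path(outdir, "trees", "concatenated_nj_consensus.nwk"))
  }
  # mitochondrial complement tree
  mt_tree <- NULL
  ref_genes <- mt_reference_genes(anc)
  mt_cc <- list()
  for (tx in names(results)) {
    mr <- results[[tx]]$mt
    if (is.null(mr) || nrow(mr$annotations) == 0L) next
    mt_cc[[tx]] <- concatenate_complement(mr$annotations, mr$draft$sequence)
  }
  if (length(mt_cc) >= 1L) {
    lin_cc <- vapply(names(lineages), function(ln) {
      ann <- annotate_protein_genes(lineages[[ln]]$mt_genome, ref_genes)
      concatenate_complement(ann, lineages[[ln]]$mt_genome)
    }, character(1))
    seqs <- c(stats::setNames(paste(ref_genes, collapse = ""), "ancestor"),
              lin_cc, unlist(mt_cc))
    if (length(seqs) >= 3L) {
      mmsa <- strip_ambiguous_columns(progressive_align(seqs))
      mt_tree <- bootstrap_consensus(mmsa, "nj", reps = config$bootstrap_reps,
                                     seed = derive_seed(config$rng_seed, 301L))
      write_newick(mt_tree, file.path(outdir, "trees", "mt_complement_nj_consensus.nwk"))
    }
  }
  list(gene_trees = gene_trees, origins = origins, msas = msas,
       concatenated = list(sequences = concat, tree = concat_tree),
       mt_tree = mt_tree)
}
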