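#' Pipeline configuration
#'
#' Collects every fixed parameter of the copy-recovery / mitochondrial
#' assembly / phylogenetics pipeline in one validated object. Defaults follow
#' the analysis protocol the package implements: read pairs are recruited to a
#' marker gene at a BLAST-style E-value of 0.1, mitochondrial similarity uses
#' E = 0.001 with at most five gap openings during gap confirmation, de Bruijn
#' assembly scans odd k-mer sizes 39-51 with a 200 bp minimum contig length,
#' libraries carry ~400 bp inserts from 100-900 bp fragments, and bootstrap
#' analyses use 1000 replicates.
#'
#' @param recruit_evalue E-value threshold for recruiting read pairs to a
#'   nuclear marker gene.
#' @param mt_evalue E-value threshold for contig-to-reference mitochondrial
#'   similarity.
#' @param kmer_min,kmer_max odd k-mer bounds scanned by the assembler.
#' @param min_contig_len minimum contig length retained, bp.
#' @param bootstrap_reps bootstrap replicates for tree support.
#' @param max_gap_openings maximum gap openings allowed when reads confirm an
#'   assembly gap.
#' @param insert_size_bp mean paired-end insert size, bp.
#' @param insert_sd_bp standard deviation of the insert-size distribution.
#' @param fragment_min_bp,fragment_max_bp sheared-fragment size bounds, bp.
#' @param read_len sequenced read length, bp.
#' @param rng_seed integer seed from which all pipeline randomness derives.
#' @return an object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config(rng_seed = 42)
#' cfg$recruit_evalue
#' @export
pipeline_config <- function(recruit_evalue = 0.1,
                            mt_evalue = 0.001,
                            kmer_min = 39L,
                            kmer_max = 51L,
                            min_contig_len = 200L,
                            bootstrap_reps = 1000L,
                            max_gap_openings = 5L,
                            insert_size_bp = 400L,
                            insert_sd_bp = 80L,
                            fragment_min_bp = 100L,
                            fragment_max_bp = 900L,
                            read_len = 100L,
                            rng_seed = 1L) {
  cfg <- list(
    recruit_evalue = recruit_evalue, mt_evalue = mt_evalue,
    kmer_min = as.integer(kmer_min), kmer_max = as.integer(kmer_max),
    min_contig_len = as.integer(min_contig_len),
    bootstrap_reps = as.integer(bootstrap_reps),
    max_gap_openings = as.integer(max_gap_openings),
    insert_size_bp = as.integer(insert_size_bp),
    insert_sd_bp = as.integer(insert_sd_bp),
    fragment_min_bp = as.integer(fragment_min_bp),
    fragment_max_bp = as.integer(fragment_max_bp),
    read_len = as.integer(read_len),
    rng_seed = as.integer(rng_seed)
  )
  for (f in c("recruit_evalue", "mt_evalue", "kmer_min", "kmer_max",
              "min_contig_len", "bootstrap_reps", "insert_size_bp",
              "insert_sd_bp", "fragment_min_bp", "fragment_max_bp",
              "read_len")) {
    if (!is_scalar_number(cfg[[f]]) || cfg[[f]] <= 0) {
      stop(sprintf("pipeline_config: '%s' must be a positive number", f),
           call. = FALSE)
    }
  }
  if (cfg$max_gap_openings < 0) {
    stop("pipeline_config: 'max_gap_openings' must be non-negative", call. = FALSE)
  }
  if (cfg$kmer_min > cfg$kmer_max) {
    stop("pipeline_config: kmer_min must not exceed kmer_max", call. = FALSE)
  }
  if (cfg$kmer_min %% 2L == 0L || cfg$kmer_max %% 2L == 0L) {
    stop("pipeline_config: k-mer bounds must both be odd", call. = FALSE)
  }
  if (!(cfg$fragment_min_bp <= cfg$insert_size_bp &&
        cfg$insert_size_bp <= cfg$fragment_max_bp)) {
    stop("pipeline_config: need fragment_min_bp <= insert_size_bp <= fragment_max_bp",
         call. = FALSE)
  }
  if (cfg$read_len > cfg$fragment_min_bp) {
    stop("pipeline_config: read_len must not exceed fragment_min_bp", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
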