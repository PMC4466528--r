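#' Pipeline configuration
#'
#' Collects every numeric threshold the pipeline uses. The defaults are the
#' published operating point of the refined targeted-assembly approach:
#' translated recruitment at e-value <= 1e-2 under bacterial genetic code 11,
#' overlap assembly at minimum overlap length 40 nt and minimum overlap
#' identity 90%, a >= 1 kb contig length filter, a 16S screen at
#' e-value <= 1e-5 / match length >= 65 nt / identity >= 80%, and amplicon
#' validation at >= 95% identity. All cutoffs are applied inclusively.
#'
#' @param recruit_evalue_max maximum e-value for translated recruitment and
#'   family assignment (inclusive).
#' @param genetic_code NCBI genetic code table id; only table 11 (bacterial)
#'   is supported.
#' @param min_overlap_len minimum overlap length in nt for assembly,
#'   extension and merging.
#' @param min_overlap_identity minimum overlap identity (fraction of matching
#'   alignment columns; indel columns count as mismatches).
#' @param min_contig_len minimum contig length (nt) retained by
#'   [filter_by_length()].
#' @param rrna_evalue_max,rrna_min_len,rrna_min_identity thresholds of the
#'   16S rRNA metagenomic read screen.
#' @param validation_min_identity minimum amplicon identity for an in-silico
#'   PCR product to validate its contig.
#' @param max_extension_iters maximum contig end-extension iterations.
#' @param min_orf_nt minimum ORF length in nt reported by [call_orfs()].
#' @param seed_k k-mer size used to seed nucleotide overlap detection.
#' @param rng_seed integer seed driving every stochastic choice (primer
#'   contig sampling, simulation when run through the pipeline).
#' @return a named list with class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_overlap_len
pipeline_config <- function(recruit_evalue_max = 1e-2,
                            genetic_code = 11L,
                            min_overlap_len = 40L,
                            min_overlap_identity = 0.90,
                            min_contig_len = 1000L,
                            rrna_evalue_max = 1e-5,
                            rrna_min_len = 65L,
                            rrna_min_identity = 0.80,
                            validation_min_identity = 0.95,
                            max_extension_iters = 20L,
                            min_orf_nt = 300L,
                            seed_k = 16L,
                            rng_seed = 1L) {
  cfg <- list(
    recruit_evalue_max = as.numeric(recruit_evalue_max),
    genetic_code = as.integer(genetic_code),
    min_overlap_len = as.integer(min_overlap_len),
    min_overlap_identity = as.numeric(min_overlap_identity),
    min_contig_len = as.integer(min_contig_len),
    rrna_evalue_max = as.numeric(rrna_evalue_max),
    rrna_min_len = as.integer(rrna_min_len),
    rrna_min_identity = as.numeric(rrna_min_identity),
    validation_min_identity = as.numeric(validation_min_identity),
    max_extension_iters = as.integer(max_extension_iters),
    min_orf_nt = as.integer(min_orf_nt),
    seed_k = as.integer(seed_k),
    rng_seed = as.integer(rng_seed)
  )
  fracs <- c("min_overlap_identity", "rrna_min_identity",
             "validation_min_identity")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      abort(paste0(f, " must lie in [0, 1]"))
  lens <- c("min_overlap_len", "min_contig_len", "rrna_min_len",
            "max_extension_iters", "min_orf_nt", "seed_k")
  for (f in lens)
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      abort(paste0(f, " must be a positive integer"))
  if (cfg$recruit_evalue_max <= 0)
    abort("recruit_evalue_max must be > 0")
  if (cfg$genetic_code != 11L)
    abort("only genetic code table 11 (bacterial) is supported")
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key=value pipeline configuration file
#'
#' The file holds `key = value` lines, optionally under `[defaults]`
#' (pipeline thresholds, keys of [pipeline_config()]) and `[simulate]`
#' (simulator settings, scalar keys of [sim_config()]) sections; lines
#' starting with `#` are comments. Unknown keys are a hard error, so a
#' typo can never silently fall back to a default.
#'
#' @param path configuration file path.
#' @param seed optional seed overriding `rng_seed` in both sections.
#' @return list with `cfg` (a [pipeline_config()]) and `sim` (a
#'   [sim_config()], or `NULL` if no `[simulate]` section is present).
#' @export
read_config <- function(path, seed = NULL) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  section <- "defaults"
  vals <- list(defaults = list(), simulate = list())
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      if (!section %in% names(vals))
        abort(paste0("unknown config section: [", section, "]"))
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort(paste0("cannot parse config line: ", ln))
    key <- trimws(kv[1])
    val <- type.convert(trimws(kv[2]), as.is = TRUE)
    vals[[section]][[key]] <- val
  }
  known_cfg <- names(formals(pipeline_config))
  known_sim <- setdiff(names(formals(sim_config)),
                       c("samples", "abundance"))
  bad <- setdiff(names(vals$defaults), known_cfg)
  if (length(bad) > 0)
    abort(paste0("unknown config key: ", bad[1]))
  bad <- setdiff(names(vals$simulate),
                 c(known_sim, "sample_names", "reads_per_sample"))
  if (length(bad) > 0)
    abort(paste0("unknown config key: ", bad[1]))
  if (!is.null(seed)) vals$defaults$rng_seed <- as.integer(seed)
  cfg <- do.call(pipeline_config, vals$defaults)
  sim <- NULL
  if (length(vals$simulate) > 0) {
    sv <- vals$simulate
    if (!is.null(sv$sample_names)) {
      nm <- strsplit(as.character(sv$sample_names), ",")[[1]]
      nr <- as.integer(strsplit(as.character(sv$reads_per_sample),
                                ",")[[1]])
      sv$samples <- as.list(setNames(nr, trimws(nm)))
      sv$sample_names <- NULL
      sv$reads_per_sample <- NULL
    }
    if (!is.null(seed)) sv$rng_seed <- as.integer(seed)
    sim <- do.call(sim_config, sv)
  }
  list(cfg = cfg, sim = sim)
}

#' Simulated community configuration
#'
#' Parameters of the 454-style two-sample community simulator. Defaults
#' emulate a GS FLX-like run: read lengths ~ Normal(400, 100) truncated to
#' a 50 nt minimum, ~0.3% substitution errors and homopolymer-biased
#' single-nucleotide indels at 1% per homopolymer run of length >= 3. Two
#' samples named "Z7" and "Z8" carry independent lognormal genome abundance
#' profiles, mirroring a two-digester design.
#'
#' @param n_genomes number of source genomes.
#' @param genome_len genome length in nt (all genomes equal length).
#' @param genes_per_genome panel genes embedded per genome.
#' @param samples named list: sample name -> number of reads. Defaults to
#'   two samples Z7 and Z8.
#' @param abundance optional list of per-sample abundance vectors (each of
#'   length `n_genomes`, summing to 1). When `NULL`, independent lognormal
#'   (meanlog 0, sdlog 1) profiles are drawn per sample under the seed.
#' @param read_len_mean,read_len_sd,read_len_min read length distribution
#'   (truncated normal), nt.
#' @param gene_divergence per-residue probability that an embedded gene's
#'   protein differs from its panel reference. Community genes are diverged
#'   homologs of the reference panel, not identical copies; this also keeps
#'   independently recoded genes from sharing high-identity nucleotide
#'   stretches. Set to 0 for exact panel copies.
#' @param subst_rate per-base substitution error rate.
#' @param homopolymer_indel_rate per-run probability of a +/-1 nt indel in
#'   homopolymer runs of length >= 3 (the dominant 454 error mode).
#' @param qual constant Phred quality assigned to simulated bases.
#' @param rng_seed integer seed; the whole module is deterministic given it.
#' @return a named list with class `"sim_config"`.
#' @export
sim_config <- function(n_genomes = 10L,
                       genome_len = 40000L,
                       genes_per_genome = 2L,
                       samples = list(Z7 = 20000L, Z8 = 20000L),
                       abundance = NULL,
                       gene_divergence = 0.25,
                       read_len_mean = 400,
                       read_len_sd = 100,
                       read_len_min = 50L,
                       subst_rate = 0.003,
                       homopolymer_indel_rate = 0.01,
                       qual = 30L,
                       rng_seed = 1L) {
  cfg <- list(
    n_genomes = as.integer(n_genomes),
    genome_len = as.integer(genome_len),
    genes_per_genome = as.integer(genes_per_genome),
    samples = lapply(samples, as.integer),
    abundance = abundance,
    gene_divergence = as.numeric(gene_divergence),
    read_len_mean = as.numeric(read_len_mean),
    read_len_sd = as.numeric(read_len_sd),
    read_len_min = as.integer(read_len_min),
    subst_rate = as.numeric(subst_rate),
    homopolymer_indel_rate = as.numeric(homopolymer_indel_rate),
    qual = as.integer(qual),
    rng_seed = as.integer(rng_seed)
  )
  if (cfg$subst_rate < 0 || cfg$subst_rate > 1 ||
      cfg$homopolymer_indel_rate < 0 || cfg$homopolymer_indel_rate > 1)
    abort("error rates must lie in [0, 1]")
  if (cfg$gene_divergence < 0 || cfg$gene_divergence >= 1)
    abort("gene_divergence must lie in [0, 1)")
  if (cfg$read_len_min < 1L) abort("read_len_min must be >= 1")
  if (length(cfg$samples) < 1L || any(unlist(cfg$samples) < 1L))
    abort("each sample needs >= 1 read")
  if (is.null(names(cfg$samples)) || any(names(cfg$samples) == ""))
    abort("samples must be a named list")
  if (!is.null(abundance)) {
    if (length(abundance) != length(cfg$samples))
      abort("abundance must hold one vector per sample")
    for (v in abundance) {
      if (length(v) != cfg$n_genomes)
        abort("each abundance vector must have n_genomes entries")
      if (abs(sum(v) - 1) > 1e-8)
        abort("abundance vectors must sum to 1")
    }
  }
  structure(cfg, class = "sim_config")
}
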