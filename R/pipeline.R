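# Pipeline orchestration: simulate -> recruit -> assemble -> extend ->
# filter -> annotate -> depth -> validate, with per-stage artifacts, a
# manifest (parameters, seed, checksums) and deterministic reruns. Stages
# not selected read their inputs from artifacts of a previous run in the
# same output directory, so the pipeline can be resumed at stage
# granularity.

.stage_order <- c("simulate", "recruit", "assemble", "extend", "filter",
                  "annotate", "depth", "validate")

.write_tsv_with_header <- function(x, path, header_lines = character(0)) {
  writeLines(paste0("# ", header_lines), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

.read_tsv_c <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Run the targeted gene-recovery pipeline
#'
#' Executes the selected stages in fixed order, writing per-stage artifacts
#' plus a `manifest.json` (inputs, parameter values, seed, md5 checksums)
#' into `outdir`. Rerunning with an identical configuration reproduces
#' identical artifacts. A selected stage whose inputs are neither supplied
#' nor present as artifacts of a previous run is a hard error before any
#' work is done.
#'
#' @param outdir artifact directory (created if missing).
#' @param cfg a [pipeline_config()].
#' @param sim a [sim_config()] to simulate inputs, or `NULL` when `reads`
#'   and `panel` are given.
#' @param reads read tibble or FASTA/FASTQ path (used when not simulating).
#' @param panel panel tibble or FASTA path (headers with `family=`).
#' @param global_contigs optional whole-metagenome contig tibble or FASTA
#'   path used by the extension stage.
#' @param ref16s optional 16S reference tibble or FASTA path; when given,
#'   the annotate stage also screens the reads for 16S fragments.
#' @param stages character vector of stages to run, a subset of
#'   simulate, recruit, assemble, extend, filter, annotate, depth,
#'   validate; `"all"` selects everything (simulate only when `sim` is
#'   given).
#' @param validate_n number of contigs sampled for primer validation.
#' @return an object of class `"gh_pipeline"`: a list with `contigs`,
#'   `gh_contigs`, `annotations`, `depth`, `validation`, `hits`,
#'   `extension_report`, `manifest`, `outdir` and the configurations.
#' @export
run_pipeline <- function(outdir, cfg = pipeline_config(), sim = NULL,
                         reads = NULL, panel = NULL, global_contigs = NULL,
                         ref16s = NULL, stages = "all", validate_n = 50L) {
  if (identical(stages, "all"))
    stages <- if (is.null(sim)) setdiff(.stage_order, "simulate")
              else .stage_order
  unknown <- setdiff(stages, .stage_order)
  if (length(unknown) > 0)
    abort(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  stages <- .stage_order[.stage_order %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)

  load_seq <- function(x, what, type = "dna") {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) return(x)
    if (!file.exists(x)) abort(paste0(what, " file not found: ", x))
    if (what == "panel") return(read_panel(x))
    if (grepl("\\.f(ast)?q$", x)) return(read_fastq(x))
    read_fasta(x, type = type)
  }
  reads_in <- load_seq(reads, "reads")
  panel_in <- load_seq(panel, "panel")
  global_in <- load_seq(global_contigs, "global contigs")
  if (!is.null(global_in) && !"contig_id" %in% names(global_in))
    global_in <- rename(global_in, contig_id = "id")
  ref16s_in <- load_seq(ref16s, "16S reference")

  # pre-flight input checks, before any work
  if ("simulate" %in% stages && is.null(sim))
    abort("stage 'simulate' selected but no sim_config given")
  if ("recruit" %in% stages && !"simulate" %in% stages &&
      is.null(reads_in) && !file.exists(p("reads.fastq")))
    abort("stage 'recruit' needs reads (argument or simulated artifact)")
  if (any(c("recruit", "annotate") %in% stages) && is.null(panel_in) &&
      !"simulate" %in% stages && !file.exists(p("panel.fasta")))
    abort("recruitment/annotation need a reference panel")

  truth <- NULL; genomes <- NULL
  if ("simulate" %in% stages) {
    simres <- simulate_metagenome(sim, panel = panel_in)
    reads_in <- simres$reads
    panel_in <- simres$panel
    genomes <- simres$genomes
    truth <- simres
    write_fasta(rename(simres$genomes, contig_id = "genome_id"),
                p("genomes.fasta"))
    write_fastq(simres$reads, p("reads.fastq"))
    write_fasta(simres$panel, p("panel.fasta"))
    readr::write_tsv(simres$genes, p("truth_genes.tsv"))
    readr::write_tsv(simres$truth, p("truth_reads.tsv"))
    readr::write_tsv(simres$abundance, p("truth_abundance.tsv"))
  }
  if (is.null(reads_in) && file.exists(p("reads.fastq")))
    reads_in <- read_fastq(p("reads.fastq"))
  if (is.null(panel_in) && file.exists(p("panel.fasta")))
    panel_in <- read_panel(p("panel.fasta"))

  hits <- NULL; recruited <- NULL
  if ("recruit" %in% stages) {
    if (is.null(reads_in)) abort("no reads available for recruitment")
    rec <- recruit_reads(reads_in, panel_in, cfg)
    recruited <- rec$reads
    hits <- rec$hits
    write_fasta(recruited, p("recruited_reads.fasta"))
    readr::write_tsv(hits, p("hits.tsv"))
  } else if (file.exists(p("recruited_reads.fasta"))) {
    recruited <- read_fasta(p("recruited_reads.fasta"))
    recruited$sample <- sub("_r[0-9]+$", "", recruited$id)
    if (file.exists(p("hits.tsv"))) hits <- .read_tsv_c(p("hits.tsv"))
  }

  contigs <- NULL
  if ("assemble" %in% stages) {
    if (is.null(recruited)) abort("no recruited reads to assemble")
    ov <- find_overlaps(recruited, cfg)
    contigs <- greedy_assemble(recruited, ov, cfg)
    contigs <- polish_contigs(contigs, recruited, cfg)
    write_fasta(contigs, p("contigs.fasta"))
    readr::write_tsv(contig_layout(contigs), p("layout.tsv"))
  } else if (file.exists(p("contigs.fasta"))) {
    contigs <- read_fasta(p("contigs.fasta"))
    contigs <- tibble(contig_id = contigs$id, seq = contigs$seq,
                      length = str_length(contigs$seq),
                      n_reads = NA_integer_,
                      placements = lapply(seq_len(nrow(contigs)), function(i)
                        tibble(read_id = character(),
                               orientation = character(),
                               start = integer(), identity = double(),
                               sample = character())))
  }

  ext_report <- NULL
  if ("extend" %in% stages) {
    if (is.null(contigs)) abort("no contigs to extend")
    if (is.null(reads_in)) abort("no read pool for extension")
    ext <- extend_contigs(contigs, reads_in, cfg = cfg)
    contigs <- ext$contigs
    ext_report <- ext$report
    if (!is.null(global_in))
      contigs <- merge_with_global_contigs(contigs, global_in, cfg)
    contigs <- polish_contigs(contigs, reads_in, cfg, rounds = 2L)
    write_fasta(contigs, p("extended_contigs.fasta"))
    .write_tsv_with_header(
      ext_report, p("extension_report.tsv"),
      c(paste0("extension thresholds reuse the assembly overlap cutoffs: ",
               "min_overlap_len=", cfg$min_overlap_len,
               " min_overlap_identity=", cfg$min_overlap_identity)))
  }

  if ("filter" %in% stages) {
    if (is.null(contigs)) abort("no contigs to filter")
    contigs <- filter_by_length(contigs, cfg)
    write_fasta(contigs, p("contigs_filtered.fasta"))
  }

  annotations <- NULL; gh_contigs <- contigs; rrna <- NULL
  if ("annotate" %in% stages) {
    if (is.null(contigs)) abort("no contigs to annotate")
    annotations <- annotate_contigs(contigs, panel_in, cfg)
    gh_contigs <- select_gh_contigs(contigs, annotations)
    readr::write_tsv(annotations, p("annotations.tsv"))
    ass <- annotations[annotations$family != "unassigned", , drop = FALSE]
    write_gff3(ass, contigs, p("annotations.gff3"))
    write_fasta(gh_contigs, p("gh_contigs.fasta"))
    if (!is.null(ref16s_in)) {
      rrna <- screen_rrna(reads_in, ref16s_in, cfg)
      if (nrow(rrna$reads) > 0)
        write_fasta(rrna$reads, p("rrna_reads.fasta"))
      readr::write_tsv(rrna$hits, p("rrna_hits.tsv"))
    }
  }

  depth <- NULL
  if ("depth" %in% stages) {
    if (is.null(contigs)) abort("no contigs for depth profiling")
    if (is.null(reads_in)) abort("no reads for depth profiling")
    depth <- depth_profile(contigs, reads_in)
    .write_tsv_with_header(
      depth, p("depth.tsv"),
      c("depth = summed aligned bases of best-hit-assigned reads / contig length",
        "per-sample rows partition assigned reads; 'pooled' rows aggregate them"))
  }

  validation <- NULL; primers <- NULL
  if ("validate" %in% stages) {
    targets <- if (!is.null(gh_contigs) && nrow(gh_contigs) > 0) gh_contigs
               else contigs
    if (is.null(targets)) abort("no contigs to validate")
    templates <- if (!is.null(genomes)) genomes$seq
                 else if (file.exists(p("genomes.fasta")))
                   read_fasta(p("genomes.fasta"))$seq
                 else reads_in$seq
    val <- validate_contigs(targets, templates, n = validate_n, cfg = cfg)
    primers <- val$primers
    validation <- val$report
    readr::write_tsv(primers, p("primers.tsv"))
    readr::write_tsv(validation, p("validation.tsv"))
  }

  params <- unclass(cfg)
  manifest <- list(
    stages = stages,
    parameters = params,
    sim = if (!is.null(sim)) unclass(sim)[setdiff(names(sim), "abundance")],
    seed = cfg$rng_seed,
    files = as.list(tools::md5sum(list.files(outdir, full.names = TRUE,
                                             pattern = "\\.(fasta|fastq|tsv|gff3)$")))
  )
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  structure(list(
    contigs = contigs, gh_contigs = gh_contigs, annotations = annotations,
    depth = depth, validation = validation, primers = primers, hits = hits,
    recruited = recruited, extension_report = ext_report, rrna = rrna,
    truth = truth, manifest = manifest, outdir = outdir,
    cfg = cfg, sim = sim
  ), class = "gh_pipeline")
}

#' @export
print.gh_pipeline <- function(x, ...) {
  g <- glance(x)
  cat("<gh_pipeline>  stages:", paste(x$manifest$stages, collapse = " > "),
      "\n")
  cat(sprintf("  contigs: %s (GH-containing: %s)   annotations: %s   validated: %s\n",
              g$n_contigs, g$n_gh_contigs, g$n_assigned_orfs,
              g$n_validated))
  invisible(x)
}

#' Tidy the annotations of a pipeline run
#'
#' @param x a `gh_pipeline` object.
#' @param ... unused.
#' @return the annotation tibble (one row per ORF).
#' @export
tidy.gh_pipeline <- function(x, ...) {
  x$annotations %||%
    tibble(contig_id = character(), orf_id = character(),
           family = character())
}

#' One-row summary of a pipeline run
#'
#' @param x a `gh_pipeline` object.
#' @param ... unused.
#' @return one-row tibble with headline counts.
#' @export
glance.gh_pipeline <- function(x, ...) {
  ann <- x$annotations
  tibble(
    n_recruited = if (!is.null(x$recruited)) nrow(x$recruited) else NA_integer_,
    n_contigs = if (!is.null(x$contigs)) nrow(x$contigs) else 0L,
    n_gh_contigs = if (!is.null(x$gh_contigs)) nrow(x$gh_contigs) else 0L,
    n_orfs = if (!is.null(ann)) nrow(ann) else 0L,
    n_assigned_orfs = if (!is.null(ann))
      sum(ann$family != "unassigned") else 0L,
    n_validated = if (!is.null(x$validation))
      sum(x$validation$verdict == "validated") else NA_integer_
  )
}

#' Plot a pipeline result
#'
#' `type = "families"` shows assigned ORF counts per GH family,
#' `type = "depth"` shows per-sample contig depth, and `type = "lengths"`
#' the contig length distribution against the length cutoff.
#'
#' @param object a `gh_pipeline` object.
#' @param type which panel to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gh_pipeline <- function(object,
                                 type = c("families", "depth", "lengths"),
                                 ...) {
  type <- match.arg(type)
  if (type == "families") {
    ann <- tidy(object)
    ann <- ann[ann$family != "unassigned", , drop = FALSE]
    ggplot2::ggplot(ann, ggplot2::aes(x = .data$family)) +
      ggplot2::geom_bar(fill = "steelblue") +
      ggplot2::labs(x = "GH family", y = "assigned ORFs",
                    title = "GH catalytic modules on recovered contigs")
  } else if (type == "depth") {
    d <- object$depth
    d <- d[d$sample != "pooled", , drop = FALSE]
    ggplot2::ggplot(d, ggplot2::aes(x = .data$contig_id, y = .data$depth,
                                    fill = .data$sample)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "mean per-base depth",
                    title = "Per-sample contig depth")
  } else {
    ggplot2::ggplot(object$contigs,
                    ggplot2::aes(x = .data$length)) +
      ggplot2::geom_histogram(bins = 30, fill = "grey40") +
      ggplot2::geom_vline(xintercept = object$cfg$min_contig_len,
                          linetype = 2, colour = "red") +
      ggplot2::labs(x = "contig length (nt)", y = "contigs",
                    title = "Contig lengths and the retention cutoff")
  }
}
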