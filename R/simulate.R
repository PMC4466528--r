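# Ground-truthed 454-style community simulation. Genomes are random
# 50%-GC background with panel genes embedded at recorded coordinates
# (codon-randomised reverse translation under code 11, uniform synonymous
# choice); reads follow a truncated-normal length distribution with iid
# substitution errors and homopolymer-biased single-base indels, the
# dominant pyrosequencing error mode. Everything is deterministic under the
# configured seed, and the truth ledger is sufficient to score recruitment,
# assembly, annotation and depth without re-deriving anything.

# inverse codon table for code 11: aa -> codons
.codon_choices <- function() {
  code <- .genetic_code_11()
  split(names(code), unname(code))
}

#' Generate a synthetic reference protein panel
#'
#' Random protein sequences labelled with GH family names. These are
#' synthetic stand-ins for a CAZy-derived panel: they exercise the
#' homology machinery (their reverse-translated genes are embedded in
#' simulated genomes) but carry no real GH sequence signal.
#'
#' @param families family labels, one protein per entry by default.
#' @param per_family proteins per family.
#' @param aa_len protein length in residues (genes are 3*(aa_len+1) nt
#'   including the stop).
#' @param rng_seed seed.
#' @return panel tibble: `id`, `family`, `seq`.
#' @export
synthetic_panel <- function(families = c("GH1", "GH3", "GH5", "GH9",
                                         "GH10", "GH11"),
                            per_family = 1L, aa_len = 480L, rng_seed = 1L) {
  aas <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
  withr::with_seed(rng_seed, {
    rows <- list()
    for (fam in families) {
      for (k in seq_len(per_family)) {
        body <- paste(sample(aas, aa_len - 1L, replace = TRUE),
                      collapse = "")
        rows[[length(rows) + 1L]] <- tibble(
          id = sprintf("%s_ref%d", fam, k),
          family = fam,
          seq = paste0("M", body))
      }
    }
    bind_rows(rows)
  })
}

#' Reverse-translate a protein under code 11
#'
#' Synonymous codons are chosen uniformly at random (under the current RNG
#' state); a uniformly chosen stop codon is appended, so the gene is
#' 3*(nchar(protein)+1) nt and translates back to exactly the protein.
#'
#' @param protein amino-acid string (no stops, no X).
#' @return nucleotide gene string.
#' @export
reverse_translate <- function(protein) {
  choices <- .codon_choices()
  aa <- strsplit(protein, "")[[1]]
  cods <- vapply(aa, function(a) {
    opt <- choices[[a]]
    opt <- setdiff(opt, .stop_codons)
    if (length(opt) == 0) abort(paste0("no codon for residue ", a))
    opt[sample.int(length(opt), 1L)]
  }, "", USE.NAMES = FALSE)
  stop_c <- .stop_codons[sample.int(3L, 1L)]
  paste0(paste(cods, collapse = ""), stop_c)
}

.mutate_protein <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < divergence)
  for (p in hit)
    v[p] <- sample(setdiff(aas, v[p]), 1L)
  paste(v, collapse = "")
}

#' Simulate a gene-bearing genome community
#'
#' Genomes are uniform-random sequence (GC 50%) carrying
#' `cfg$genes_per_genome` genes each, embedded non-overlapping on either
#' strand with equal probability at recorded coordinates. Each gene is a
#' diverged homolog of a panel protein (per-residue divergence
#' `cfg$gene_divergence`), reverse-translated under code 11 with uniform
#' synonymous codon choice; the realized protein is recorded in the truth
#' ledger. Gene proteins are drawn without replacement across the whole
#' community while the panel lasts, then with replacement.
#'
#' @param cfg a [sim_config()].
#' @param panel panel tibble; defaults to [synthetic_panel()] under the
#'   same seed.
#' @return list with `genomes` (tibble: `genome_id`, `seq`, `length`),
#'   `genes` (truth tibble: `genome_id`, `gene_id`, `protein_id`, `family`,
#'   `lo`, `hi`, `strand`, `protein` -- the realized diverged protein) and
#'   `panel`.
#' @export
simulate_community <- function(cfg = sim_config(), panel = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  panel <- panel %||% synthetic_panel(rng_seed = cfg$rng_seed)
  withr::with_seed(cfg$rng_seed, {
    genomes <- list(); genes <- list()
    n_genes_total <- cfg$n_genomes * cfg$genes_per_genome
    pool <- rep(seq_len(nrow(panel)),
                length.out = max(n_genes_total, nrow(panel)))
    picks_all <- matrix(sample(pool, n_genes_total),
                        nrow = cfg$n_genomes)
    for (g in seq_len(cfg$n_genomes)) {
      gid <- sprintf("genome%02d", g)
      bg <- paste(sample(c("A", "C", "G", "T"), cfg$genome_len,
                         replace = TRUE), collapse = "")
      picks <- picks_all[g, ]
      occ <- matrix(numeric(0), ncol = 2)
      for (k in seq_along(picks)) {
        gene_prot <- .mutate_protein(panel$seq[picks[k]],
                                     cfg$gene_divergence)
        gene_nt <- reverse_translate(gene_prot)
        Lg <- str_length(gene_nt)
        if (Lg > cfg$genome_len)
          abort("gene longer than genome")
        ok_place <- FALSE
        for (try in 1:1000) {
          lo <- sample.int(cfg$genome_len - Lg + 1L, 1L) - 1L
          hi <- lo + Lg
          if (nrow(occ) == 0 ||
              all(hi <= occ[, 1] | lo >= occ[, 2])) { ok_place <- TRUE; break }
        }
        if (!ok_place) abort("could not place gene without overlap")
        occ <- rbind(occ, c(lo, hi))
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") gene_nt else revcomp(gene_nt)
        stringr::str_sub(bg, lo + 1L, hi) <- ins
        genes[[length(genes) + 1L]] <- tibble(
          genome_id = gid,
          gene_id = sprintf("%s_gene%d", gid, k),
          protein_id = panel$id[picks[k]],
          family = panel$family[picks[k]],
          lo = lo, hi = hi, strand = strand,
          protein = gene_prot)
      }
      genomes[[g]] <- tibble(genome_id = gid, seq = bg,
                             length = str_length(bg))
    }
    list(genomes = bind_rows(genomes), genes = bind_rows(genes),
         panel = panel)
  })
}

.apply_454_errors <- function(seq, subst_rate, hp_rate) {
  v <- strsplit(seq, "")[[1]]
  n_ins <- 0L; n_del <- 0L
  if (hp_rate > 0) {
    r <- rle(v)
    runs <- which(r$lengths >= 3L)
    if (length(runs) > 0) {
      hit <- runs[runif(length(runs)) < hp_rate]
      if (length(hit) > 0) {
        ends <- cumsum(r$lengths)
        # process from the right so positions stay valid
        for (h in rev(hit)) {
          pos <- ends[h]
          if (runif(1) < 0.5) {
            v <- append(v, r$values[h], after = pos)
            n_ins <- n_ins + 1L
          } else {
            v <- v[-pos]
            n_del <- n_del + 1L
          }
        }
      }
    }
  }
  n_sub <- 0L
  if (subst_rate > 0) {
    flip <- which(runif(length(v)) < subst_rate)
    if (length(flip) > 0) {
      bases <- c("A", "C", "G", "T")
      for (p in flip)
        v[p] <- sample(setdiff(bases, v[p]), 1L)
      n_sub <- length(flip)
    }
  }
  list(seq = paste(v, collapse = ""), n_subst = n_sub,
       n_ins = n_ins, n_del = n_del)
}

#' Simulate 454-style reads from a community
#'
#' Read start positions are uniform within genomes chosen proportionally to
#' per-sample abundance; lengths follow Normal(mean, sd) truncated to
#' `[read_len_min, genome_len]`; strands are uniform; substitution errors
#' are iid and homopolymer runs >= 3 receive single-base indels at the
#' configured per-run rate. Per-sample read counts are exactly as
#' configured and every read's origin and error counts are recorded in the
#' truth ledger.
#'
#' @param community output of [simulate_community()].
#' @param cfg the same [sim_config()].
#' @return list with `reads` (read tibble: `id`, `seq`, `qual`, `sample`)
#'   and `truth` (tibble: `read_id`, `sample`, `genome_id`, `lo`, `hi`,
#'   `strand`, `n_subst`, `n_ins`, `n_del`) and `abundance` (tibble:
#'   `sample`, `genome_id`, `abundance`).
#' @export
simulate_reads <- function(community, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  genomes <- community$genomes
  if (nrow(genomes) != cfg$n_genomes)
    abort("community does not match cfg$n_genomes")
  withr::with_seed(cfg$rng_seed + 1L, {
    ab_rows <- list(); read_rows <- list(); truth_rows <- list()
    for (si in seq_along(cfg$samples)) {
      sname <- names(cfg$samples)[si]
      nreads <- cfg$samples[[si]]
      ab <- if (!is.null(cfg$abundance)) cfg$abundance[[si]] else {
        a <- stats::rlnorm(cfg$n_genomes, 0, 1)
        a / sum(a)
      }
      if (length(ab) != cfg$n_genomes)
        abort("abundance vector length must equal n_genomes")
      ab_rows[[si]] <- tibble(sample = sname,
                              genome_id = genomes$genome_id,
                              abundance = ab)
      gidx <- sample.int(cfg$n_genomes, nreads, replace = TRUE, prob = ab)
      glen <- genomes$length[gidx]
      lo_u <- pnorm((cfg$read_len_min - cfg$read_len_mean) / cfg$read_len_sd)
      hi_u <- pnorm((glen - cfg$read_len_mean) / cfg$read_len_sd)
      u <- runif(nreads, lo_u, hi_u)
      rlen <- pmin(pmax(as.integer(round(
        qnorm(u) * cfg$read_len_sd + cfg$read_len_mean)),
        cfg$read_len_min), glen)
      start <- vapply(seq_len(nreads), function(i)
        sample.int(glen[i] - rlen[i] + 1L, 1L) - 1L, 0L)
      strand <- sample(c("+", "-"), nreads, replace = TRUE)
      seqs <- substring(genomes$seq[gidx], start + 1L, start + rlen)
      seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
      ns <- integer(nreads); ni <- integer(nreads); nd <- integer(nreads)
      if (cfg$subst_rate > 0 || cfg$homopolymer_indel_rate > 0) {
        for (i in seq_len(nreads)) {
          e <- .apply_454_errors(seqs[i], cfg$subst_rate,
                                 cfg$homopolymer_indel_rate)
          seqs[i] <- e$seq; ns[i] <- e$n_subst
          ni[i] <- e$n_ins; nd[i] <- e$n_del
        }
      }
      ids <- sprintf("%s_r%06d", sname, seq_len(nreads))
      qual <- vapply(str_length(seqs),
                     function(L) .int_to_qual(rep(cfg$qual, L)), "")
      read_rows[[si]] <- tibble(id = ids, seq = seqs, qual = qual,
                                sample = sname)
      truth_rows[[si]] <- tibble(
        read_id = ids, sample = sname,
        genome_id = genomes$genome_id[gidx],
        lo = start, hi = start + rlen, strand = strand,
        n_subst = ns, n_ins = ni, n_del = nd)
    }
    list(reads = bind_rows(read_rows), truth = bind_rows(truth_rows),
         abundance = bind_rows(ab_rows))
  })
}

#' Simulate a full two-sample metagenome with ground truth
#'
#' Convenience wrapper: [synthetic_panel()] + [simulate_community()] +
#' [simulate_reads()] under one seed.
#'
#' @param cfg a [sim_config()].
#' @param panel optional panel tibble.
#' @return list: `panel`, `genomes`, `genes`, `reads`, `truth`,
#'   `abundance`.
#' @export
simulate_metagenome <- function(cfg = sim_config(), panel = NULL) {
  comm <- simulate_community(cfg, panel)
  rd <- simulate_reads(comm, cfg)
  list(panel = comm$panel, genomes = comm$genomes, genes = comm$genes,
       reads = rd$reads, truth = rd$truth, abundance = rd$abundance)
}
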