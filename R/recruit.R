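# Homology-guided read recruitment: six-frame translated local alignment of
# every read against a reference GH protein panel, with Karlin-Altschul
# e-values and an inclusive cutoff. This re-implements the translated-search
# (BLASTX-style) step as exhaustive Smith-Waterman over all six frames;
# alignments never cross a stop codon (the scoring matrix makes any
# stop-crossing alignment strictly worse than staying within a stop-free
# segment for read-scale lengths).

.frame_labels <- c("+1", "+2", "+3", "-1", "-2", "-3")
.frame_ints <- c(1L, 2L, 3L, -1L, -2L, -3L)

#' Align one read against one reference protein in all six frames
#'
#' Returns the best local alignment per frame with raw score > 0, with
#' Karlin-Altschul bit scores and e-values. By default the search space is
#' the single pair (`m` = protein residues, `n` = the read's total
#' translated residues); recruitment over a whole dataset uses dataset-wide
#' totals instead.
#'
#' @param read_seq nucleotide sequence (character scalar).
#' @param protein_seq amino-acid sequence (character scalar).
#' @param m,n search-space factors; defaults to the single-pair sizes.
#' @return tibble with one row per frame with positive score: `frame`
#'   (integer in +1..+3, -1..-3), `score`, `bitscore`, `evalue`,
#'   `read_lo`, `read_hi` (0-based half-open on the forward strand),
#'   `prot_lo`, `prot_hi`, `matches`, `columns`.
#' @export
align_translated <- function(read_seq, protein_seq, m = NULL, n = NULL) {
  stopifnot(length(read_seq) == 1, length(protein_seq) == 1)
  sf <- six_frame_table(read_seq)
  n <- n %||% sum(str_length(sf$peptide))
  m <- m %||% str_length(protein_seq)
  rows <- list()
  for (k in seq_len(6L)) {
    pep <- sf$peptide[k]
    if (str_length(pep) == 0) next
    al <- sw_align(pep, protein_seq, type = "protein")
    if (al$score <= 0) next
    ka <- karlin_altschul(al$score, m = m, n = n, type = "protein")
    sp <- .aa_span_to_read_span(.frame_labels[k], al$a_lo, al$a_hi,
                                str_length(read_seq))
    rows[[length(rows) + 1L]] <- tibble(
      frame = .frame_ints[k], score = al$score,
      bitscore = ka$bitscore, evalue = ka$evalue,
      read_lo = sp$lo, read_hi = sp$hi,
      prot_lo = al$b_lo, prot_hi = al$b_hi,
      matches = al$matches, columns = al$columns)
  }
  if (length(rows) == 0)
    return(tibble(frame = integer(), score = integer(), bitscore = double(),
                  evalue = double(), read_lo = integer(), read_hi = integer(),
                  prot_lo = integer(), prot_hi = integer(),
                  matches = integer(), columns = integer()))
  bind_rows(rows)
}

#' Recruit metagenomic reads homologous to a reference protein panel
#'
#' Every read is translated in all six frames and aligned against every
#' panel protein by exhaustive local dynamic programming (BLOSUM62, gap
#' 11/1). A read is recruited iff at least one alignment reaches
#' e-value <= `cfg$recruit_evalue_max` (inclusive), with the search space
#' m * n = (total panel residues) * (total translated read residues over the
#' dataset). Each recruited read keeps its best hit per panel protein
#' (ties between frames resolved in frame order +1,+2,+3,-1,-2,-3).
#'
#' @param reads read tibble (`id`, `seq`, optional `qual`, `sample`).
#' @param panel panel tibble (`id`, `family`, `seq`), see [read_panel()].
#' @param cfg a [pipeline_config()].
#' @return a list with `reads` (the recruited subset, input order) and
#'   `hits` (tibble: `read_id`, `frame`, `protein_id`, `family`, `score`,
#'   `bitscore`, `evalue`, `read_lo`, `read_hi`, `prot_lo`, `prot_hi`,
#'   `identity`).
#' @export
recruit_reads <- function(reads, panel, cfg = pipeline_config()) {
  .assert_reads(reads)
  stopifnot(is.data.frame(panel), all(c("id", "family", "seq") %in% names(panel)))
  if (nrow(panel) == 0) abort("panel must be non-empty")
  empty_hits <- tibble(
    read_id = character(), frame = integer(), protein_id = character(),
    family = character(), score = integer(), bitscore = double(),
    evalue = double(), read_lo = integer(), read_hi = integer(),
    prot_lo = integer(), prot_hi = integer(), identity = double())
  if (nrow(reads) == 0)
    return(list(reads = reads, hits = empty_hits))

  sf <- six_frame_table(reads$seq, genetic_code = cfg$genetic_code)
  nreads <- nrow(reads)
  n_space <- sum(str_length(sf$peptide))
  m_space <- sum(str_length(panel$seq))
  smin <- .score_at_evalue(cfg$recruit_evalue_max, m_space, n_space)
  smin_int <- as.integer(ceiling(smin - 1e-9))

  hits <- list()
  for (p in seq_len(nrow(panel))) {
    sc <- .sw_scores(sf$peptide, panel$seq[p], type = "protein")
    scm <- matrix(sc, nrow = nreads, ncol = 6L)
    best_f <- max.col(scm, ties.method = "first")
    best_s <- scm[cbind(seq_len(nreads), best_f)]
    keep <- which(best_s >= smin_int & best_s > 0L)
    if (length(keep) == 0) next
    hits[[length(hits) + 1L]] <- tibble(
      ridx = keep, pidx = p, fidx = best_f[keep],
      score = best_s[keep])
  }
  if (length(hits) == 0)
    return(list(reads = reads[0, ], hits = empty_hits))
  h <- bind_rows(hits)

  # traceback pass for spans and identities
  pep_of <- function(ridx, fidx) sf$peptide[(fidx - 1L) * nreads + ridx]
  det <- pmap(list(h$ridx, h$pidx, h$fidx), function(r, p, f) {
    al <- sw_align(pep_of(r, f), panel$seq[p], type = "protein")
    sp <- .aa_span_to_read_span(.frame_labels[f], al$a_lo, al$a_hi,
                                str_length(reads$seq[r]))
    c(read_lo = sp$lo, read_hi = sp$hi, prot_lo = al$b_lo,
      prot_hi = al$b_hi, matches = al$matches, columns = al$columns)
  })
  det <- do.call(rbind, det)
  ka <- karlin_altschul(h$score, m = m_space, n = n_space, type = "protein")
  out <- tibble(
    read_id = reads$id[h$ridx],
    frame = .frame_ints[h$fidx],
    protein_id = panel$id[h$pidx],
    family = panel$family[h$pidx],
    score = h$score,
    bitscore = ka$bitscore,
    evalue = ka$evalue,
    read_lo = as.integer(det[, "read_lo"]),
    read_hi = as.integer(det[, "read_hi"]),
    prot_lo = as.integer(det[, "prot_lo"]),
    prot_hi = as.integer(det[, "prot_hi"]),
    identity = ifelse(det[, "columns"] > 0,
                      det[, "matches"] / det[, "columns"], 0)
  )
  out <- arrange(out, match(.data$read_id, reads$id), .data$evalue,
                 .data$protein_id)
  recruited <- reads[reads$id %in% out$read_id, , drop = FALSE]
  list(reads = recruited, hits = out)
}
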