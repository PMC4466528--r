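# Contig annotation: a simple longest-ORF caller (stop-to-stop segments on
# both strands, start at ATG/GTG/TTG, bacterial code 11) plus translated
# best-hit GH family assignment against the reference panel. Downstream
# logic only needs GH catalytic-module detection, and family assignment is
# homology-based, so a full gene finder is not required. Partial ORFs at
# contig edges are reported and eligible for family assignment (recovered
# genes are frequently partial).

.start_codons <- c("ATG", "GTG", "TTG")
.stop_codons <- c("TAA", "TAG", "TGA")

.codons_of <- function(s, offset) {
  L <- str_length(s)
  n <- (L - offset) %/% 3L
  if (n <= 0) return(character(0))
  starts <- offset + 1L + 3L * (seq_len(n) - 1L)
  substring(s, starts, starts + 2L)
}

# ORFs on one strand's forward-reading sequence; coordinates in that
# strand's frame (0-based half-open), caller maps to contig coordinates.
.orfs_one_strand <- function(s, min_orf_nt) {
  out <- list()
  for (f in 0:2) {
    cod <- .codons_of(s, f)
    n <- length(cod)
    if (n == 0) next
    is_stop <- cod %in% .stop_codons
    stop_idx <- which(is_stop)
    seg_start <- c(1L, stop_idx + 1L)
    seg_stop <- c(stop_idx, NA_integer_)   # codon index of the stop, NA = edge
    for (k in seq_along(seg_start)) {
      a <- seg_start[k]
      z <- seg_stop[k]
      last <- if (is.na(z)) n else z       # last codon incl. stop
      if (a > last) next
      body_end <- if (is.na(z)) n else z - 1L
      if (body_end < a) next
      edge5 <- a == 1L
      first_start <- {
        hits <- which(cod[a:body_end] %in% .start_codons)
        if (length(hits) > 0) a + hits[1] - 1L else NA_integer_
      }
      orf_from <- if (edge5) a else first_start
      if (is.na(orf_from)) next
      partial5 <- edge5 && !(cod[orf_from] %in% .start_codons)
      partial3 <- is.na(z)
      len_nt <- (last - orf_from + 1L) * 3L
      if (len_nt < min_orf_nt) next
      lo <- f + 3L * (orf_from - 1L)
      hi <- f + 3L * last
      prot_cod <- cod[orf_from:body_end]
      out[[length(out) + 1L]] <- list(
        lo = lo, hi = hi, frame = f + 1L,
        partial5 = partial5, partial3 = partial3,
        prot = paste(prot_cod, collapse = ""))
    }
  }
  out
}

#' Call open reading frames on contigs
#'
#' Reports, per stop-to-stop frame segment on both strands, the longest
#' reading frame starting at ATG/GTG/TTG and ending at a stop codon (the
#' stop is included in the span) with length >= `min_orf_nt`. Segments
#' truncated by a contig edge yield partial ORFs, flagged in `partial`.
#'
#' @param contigs contig tibble (`contig_id`, `seq`).
#' @param min_orf_nt minimum ORF length in nt (default 300, i.e. 100
#'   codons; GH catalytic modules exceed this).
#' @param genetic_code NCBI table id; only 11 is supported.
#' @return tibble: `contig_id`, `orf_id`, `lo`, `hi` (0-based half-open on
#'   the forward strand), `strand`, `frame`, `partial`
#'   (`none`/`5p`/`3p`/`both`), `protein`.
#' @export
call_orfs <- function(contigs, min_orf_nt = 300L, genetic_code = 11L) {
  .assert_contigs(contigs)
  if (genetic_code != 11L)
    abort("only genetic code table 11 (bacterial) is supported")
  code <- .genetic_code_11()
  rows <- list()
  for (ci in seq_len(nrow(contigs))) {
    s <- contigs$seq[ci]
    L <- str_length(s)
    for (strand in c("+", "-")) {
      ss <- if (strand == "+") s else revcomp(s)
      orfs <- .orfs_one_strand(ss, min_orf_nt)
      for (o in orfs) {
        if (strand == "+") {
          lo <- o$lo; hi <- o$hi
        } else {
          lo <- L - o$hi; hi <- L - o$lo
        }
        prot <- .translate_frame(
          Biostrings::DNAStringSet(o$prot), 0L, code)
        partial <- if (o$partial5 && o$partial3) "both"
                   else if (o$partial5) "5p"
                   else if (o$partial3) "3p" else "none"
        rows[[length(rows) + 1L]] <- tibble(
          contig_id = contigs$contig_id[ci],
          lo = lo, hi = hi, strand = strand, frame = o$frame,
          partial = partial, protein = prot)
      }
    }
  }
  if (length(rows) == 0)
    return(tibble(contig_id = character(), orf_id = character(),
                  lo = integer(), hi = integer(), strand = character(),
                  frame = integer(), partial = character(),
                  protein = character()))
  out <- bind_rows(rows) |>
    arrange(.data$contig_id, .data$lo, .data$strand)
  out$orf_id <- sprintf("%s_orf%03d", out$contig_id,
                        stats::ave(seq_len(nrow(out)), out$contig_id,
                                   FUN = seq_along))
  select(out, "contig_id", "orf_id", "lo", "hi", "strand", "frame",
         "partial", "protein")
}

#' Assign GH families to ORFs by translated best hit
#'
#' Each ORF protein is aligned against every panel protein (BLOSUM62,
#' gap 11/1). The best hit by bit score with e-value <=
#' `cfg$recruit_evalue_max` sets the family; ties are broken by lower
#' e-value, then higher identity, then lexicographic protein id. ORFs with
#' no passing hit are `"unassigned"`. The search space per ORF is
#' (total panel residues) x (ORF residues).
#'
#' @param orfs ORF tibble from [call_orfs()].
#' @param panel panel tibble (`id`, `family`, `seq`).
#' @param cfg a [pipeline_config()].
#' @return the ORF tibble with `family`, `best_protein_id`, `score`,
#'   `bitscore`, `evalue`, `identity` columns appended.
#' @export
assign_family <- function(orfs, panel, cfg = pipeline_config()) {
  stopifnot(is.data.frame(orfs))
  if (nrow(panel) == 0) abort("panel must be non-empty")
  n_orf <- nrow(orfs)
  res <- tibble(
    family = rep("unassigned", n_orf),
    best_protein_id = NA_character_,
    score = NA_integer_, bitscore = NA_real_,
    evalue = NA_real_, identity = NA_real_)
  if (n_orf == 0) return(bind_cols(orfs, res))
  m_space <- sum(str_length(panel$seq))
  scm <- matrix(0L, n_orf, nrow(panel))
  for (p in seq_len(nrow(panel)))
    scm[, p] <- .sw_scores(orfs$protein, panel$seq[p], type = "protein")
  for (i in seq_len(n_orf)) {
    s_best <- max(scm[i, ])
    if (s_best <= 0) next
    ka <- karlin_altschul(s_best, m = m_space,
                          n = str_length(orfs$protein[i]),
                          type = "protein")
    if (ka$evalue > cfg$recruit_evalue_max) next
    tied <- which(scm[i, ] == s_best)
    ids <- vapply(tied, function(p) {
      al <- sw_align(orfs$protein[i], panel$seq[p], type = "protein")
      al$identity
    }, 0)
    pick <- tied[order(-ids, panel$id[tied])][1]
    res$family[i] <- panel$family[pick]
    res$best_protein_id[i] <- panel$id[pick]
    res$score[i] <- s_best
    res$bitscore[i] <- ka$bitscore
    res$evalue[i] <- ka$evalue
    res$identity[i] <- ids[order(-ids, panel$id[tied])][1]
  }
  bind_cols(orfs, res)
}

#' Call and annotate ORFs on contigs in one step
#'
#' @param contigs contig tibble.
#' @param panel panel tibble.
#' @param cfg a [pipeline_config()].
#' @return annotation tibble ([call_orfs()] + [assign_family()] columns).
#' @export
annotate_contigs <- function(contigs, panel, cfg = pipeline_config()) {
  orfs <- call_orfs(contigs, min_orf_nt = cfg$min_orf_nt,
                    genetic_code = cfg$genetic_code)
  assign_family(orfs, panel, cfg)
}

#' Keep contigs carrying at least one assigned GH ORF
#'
#' @param contigs contig tibble.
#' @param annotations annotation tibble from [annotate_contigs()] computed
#'   on these contigs.
#' @return the GH-containing subset of `contigs`.
#' @export
select_gh_contigs <- function(contigs, annotations) {
  .assert_contigs(contigs)
  keep_ids <- unique(annotations$contig_id[annotations$family != "unassigned"])
  contigs[contigs$contig_id %in% keep_ids, , drop = FALSE]
}

#' Screen reads against a 16S rRNA reference set
#'
#' A read is retained iff it has a nucleotide local alignment to any
#' reference with e-value <= `cfg$rrna_evalue_max` AND aligned length >=
#' `cfg$rrna_min_len` AND identity >= `cfg$rrna_min_identity` (all
#' inclusive). The search space is (total reference nt) x (total read nt).
#'
#' @param reads read tibble.
#' @param ref16s reference tibble (`id`, `seq`), e.g. from [read_fasta()].
#' @param cfg a [pipeline_config()].
#' @return list with `reads` (retained subset) and `hits` (tibble:
#'   `read_id`, `ref_id`, `score`, `bitscore`, `evalue`, `length`,
#'   `identity`, `read_lo`, `read_hi`).
#' @export
screen_rrna <- function(reads, ref16s, cfg = pipeline_config()) {
  .assert_reads(reads)
  stopifnot(is.data.frame(ref16s), nrow(ref16s) > 0)
  m_space <- sum(str_length(ref16s$seq))
  n_space <- sum(str_length(reads$seq))
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    for (r in seq_len(nrow(ref16s))) {
      best <- NULL
      for (s in c(FALSE, TRUE)) {
        q <- if (s) revcomp(reads$seq[i]) else reads$seq[i]
        al <- sw_align(q, ref16s$seq[r], type = "dna")
        if (is.null(best) || al$score > best$al$score)
          best <- list(al = al, rc = s)
      }
      al <- best$al
      if (al$score <= 0) next
      ka <- karlin_altschul(al$score, m = m_space, n = n_space,
                            type = "dna")
      if (ka$evalue <= cfg$rrna_evalue_max &&
          al$columns >= cfg$rrna_min_len &&
          al$identity >= cfg$rrna_min_identity) {
        L <- str_length(reads$seq[i])
        lo <- if (best$rc) L - al$a_hi else al$a_lo
        hi <- if (best$rc) L - al$a_lo else al$a_hi
        rows[[length(rows) + 1L]] <- tibble(
          read_id = reads$id[i], ref_id = ref16s$id[r],
          score = al$score, bitscore = ka$bitscore, evalue = ka$evalue,
          length = al$columns, identity = al$identity,
          read_lo = lo, read_hi = hi)
      }
    }
  }
  hits <- if (length(rows) > 0) bind_rows(rows) else
    tibble(read_id = character(), ref_id = character(), score = integer(),
           bitscore = double(), evalue = double(), length = integer(),
           identity = double(), read_lo = integer(), read_hi = integer())
  list(reads = reads[reads$id %in% hits$read_id, , drop = FALSE],
       hits = hits)
}
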