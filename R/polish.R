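# Consensus polishing: one or more rounds of gapped realignment of reads
# against each contig, followed by a per-column majority vote over aligned
# bases, deletions and single-base insertions. This absorbs the coordinate
# drift that ungapped layout voting cannot (homopolymer indel errors shift
# a read's downstream votes by one) and lifts single-read-coverage
# extension tails to the pool consensus. On error-free input the votes are
# unanimous and polishing is the identity.

.polish_one <- function(seq, pool_seqs, cand, cfg) {
  if (is.null(cand) || nrow(cand) == 0) return(seq)
  v <- cpp_polish_votes(seq, pool_seqs, cand$ib, cand$rc, cand$diag)
  L <- str_length(seq)
  bm <- matrix(v$base_votes, nrow = 5L)          # A,C,G,T,N x position
  im <- matrix(v$ins_base, nrow = 5L)            # insertions before pos
  acgt <- colSums(bm[1:4, , drop = FALSE])
  cov <- acgt + bm[5L, ] + v$del_votes
  pick <- max.col(t(bm[1:4, , drop = FALSE]), ties.method = "first")
  bases <- c("A", "C", "G", "T")[pick]
  orig <- strsplit(seq, "")[[1]]
  bases[acgt == 0L] <- orig[acgt == 0L]          # uncovered: keep as-is
  drop_pos <- v$del_votes > (cov - v$del_votes)  # strict majority deletes
  bases[drop_pos] <- ""
  # insertions: strict majority of the local coverage must support one
  junc_cov <- cov[pmin(pmax(seq_len(L + 1L) - 1L, 1L), L)]
  ins_keep <- v$ins_votes > junc_cov / 2
  ins_chars <- rep("", L + 1L)
  if (any(ins_keep)) {
    ipick <- max.col(t(im[1:4, , drop = FALSE]), ties.method = "first")
    ins_chars[ins_keep] <- c("A", "C", "G", "T")[ipick[ins_keep]]
  }
  paste0(paste0(ins_chars[seq_len(L)], bases, collapse = ""),
         ins_chars[L + 1L])
}

#' Polish contig consensus by gapped realignment
#'
#' Realigns pool reads to each contig (banded, seeded) and rebuilds the
#' consensus by per-column majority over aligned bases, deletions and
#' single-base insertions. Columns without read support are left unchanged.
#' Deterministic; on error-free input it returns the contigs unchanged.
#'
#' @param contigs contig tibble.
#' @param reads read tibble used as the polishing pool.
#' @param cfg a [pipeline_config()] (reuses the overlap identity/length
#'   cutoffs to admit reads into the vote).
#' @param rounds number of polish rounds (coordinates re-seed each round).
#' @return the contig tibble with polished sequences, updated lengths and
#'   refreshed placement identities.
#' @export
polish_contigs <- function(contigs, reads, cfg = pipeline_config(),
                           rounds = 1L) {
  .assert_contigs(contigs)
  .assert_reads(reads)
  if (nrow(contigs) == 0 || nrow(reads) == 0) return(contigs)
  out <- contigs
  for (r in seq_len(rounds)) {
    cand <- cpp_seed_pairs(out$seq, reads$seq, k = cfg$seed_k,
                           same_set = FALSE)
    if (nrow(cand) == 0) break
    ver <- cpp_verify_overlaps(out$seq, reads$seq, cand$ia, cand$ib,
                               cand$rc, cand$diag)
    identity <- ifelse(ver$columns > 0, ver$matches / ver$columns, 0)
    keep <- identity >= cfg$min_overlap_identity &
      ver$columns >= cfg$min_overlap_len
    cand <- cand[keep, , drop = FALSE]
    changed <- FALSE
    for (ci in seq_len(nrow(out))) {
      s <- .polish_one(out$seq[ci], reads$seq,
                       cand[cand$ia == ci, , drop = FALSE], cfg)
      if (!identical(s, out$seq[ci])) changed <- TRUE
      out$seq[ci] <- s
    }
    if (!changed) break
  }
  for (ci in seq_len(nrow(out))) {
    s <- out$seq[ci]
    out$length[ci] <- str_length(s)
    if ("placements" %in% names(out) && !is.null(out$placements[[ci]])) {
      plc <- out$placements[[ci]]
      if (nrow(plc) > 0 && all(plc$read_id %in% reads$id)) {
        oseq <- reads$seq[match(plc$read_id, reads$id)]
        oseq <- ifelse(plc$orientation == "-", revcomp(oseq), oseq)
        plc$identity <- vapply(seq_len(nrow(plc)), function(i)
          .placement_identity(s, oseq[i], min(plc$start[i],
                                              max(0L, str_length(s) - 1L))), 0)
        out$placements[[ci]] <- plc
      }
    }
  }
  out
}
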