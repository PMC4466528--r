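# Greedy overlap-layout-consensus assembly of recruited reads.
#
# Overlap candidates come from shared k-mer seeds (modal diagonal per pair
# and orientation); each candidate is verified by a banded end-to-end
# alignment of the implied overlap region with unit mismatch/indel costs and
# band max(10, 10% of the overlap length). Identity is matches over
# alignment columns (indel columns count as mismatches). Contigs are built
# by merging overlaps greedily -- longest first, then highest identity, then
# lexicographically smallest (read_a, read_b) -- with a union-find layout;
# the consensus is a per-column weighted majority vote.

#' Find pairwise read overlaps
#'
#' Returns all dovetail/containment overlaps between reads, in both
#' orientations, with alignment length >= `cfg$min_overlap_len` and identity
#' >= `cfg$min_overlap_identity` (both inclusive).
#'
#' @param reads read tibble (>= 2 rows).
#' @param cfg a [pipeline_config()].
#' @return tibble: `read_a`, `read_b`, `orientation` (`"F"` or `"RC"`,
#'   applying to `read_b`), `offset` (start of oriented b on a, nt),
#'   `length` (alignment columns), `identity`, plus internal indices
#'   `ia`, `ib`.
#' @export
find_overlaps <- function(reads, cfg = pipeline_config()) {
  .assert_reads(reads)
  empty <- tibble(read_a = character(), read_b = character(),
                  orientation = character(), offset = integer(),
                  length = integer(), identity = double(),
                  ia = integer(), ib = integer())
  if (nrow(reads) < 2) return(empty)
  seqs <- reads$seq
  cand <- cpp_seed_pairs(seqs, seqs, k = cfg$seed_k, same_set = TRUE)
  if (nrow(cand) == 0) return(empty)
  ver <- cpp_verify_overlaps(seqs, seqs, cand$ia, cand$ib, cand$rc,
                             cand$diag)
  identity <- ifelse(ver$columns > 0, ver$matches / ver$columns, 0)
  keep <- ver$columns >= cfg$min_overlap_len &
    identity >= cfg$min_overlap_identity
  if (!any(keep)) return(empty)
  tibble(
    read_a = reads$id[cand$ia[keep]],
    read_b = reads$id[cand$ib[keep]],
    orientation = ifelse(cand$rc[keep], "RC", "F"),
    offset = cand$diag[keep],
    length = ver$columns[keep],
    identity = identity[keep],
    ia = cand$ia[keep],
    ib = cand$ib[keep]
  )
}

#' Column-wise consensus base
#'
#' Majority base of one alignment column. Ties are broken by higher summed
#' quality, then by the fixed base order A < C < G < T. `N` votes never win
#' unless they are the only votes.
#'
#' @param bases character vector of single-base votes (`A,C,G,T,N`).
#' @param quals optional integer vector of per-vote qualities.
#' @return a single base.
#' @export
#' @examples
#' consensus_base(c("A", "A", "G"))          # "A"
#' consensus_base(c("A", "C"))               # "A" (tie -> base order)
consensus_base <- function(bases, quals = NULL) {
  stopifnot(length(bases) >= 1)
  code <- .base_codes[utf8ToInt(paste(bases, collapse = ""))]
  if (any(code == 0L)) abort("votes must be A, C, G, T or N")
  counts <- tabulate(code, nbins = 5L)
  if (all(counts[1:4] == 0L)) return("N")
  qs <- numeric(5L)
  if (!is.null(quals)) {
    stopifnot(length(quals) == length(bases))
    qs <- vapply(1:5, function(b) sum(quals[code == b]), 0)
  }
  rank <- counts[1:4] * 1e7 + qs[1:4]
  c("A", "C", "G", "T")[which.max(rank)]
}

# Build a consensus string from oriented placements.
# placements: tibble with seq (oriented), offset (0-based), qual (Phred+33
# string or NA). Returns list(seq, length).
.consensus_from_placements <- function(oriented_seq, offset, qual) {
  lens <- str_length(oriented_seq)
  total_len <- max(offset + lens)
  nbase <- sum(lens)
  cols <- integer(nbase)
  codes <- integer(nbase)
  wts <- numeric(nbase)
  pos <- 0L
  for (i in seq_along(oriented_seq)) {
    v <- .encode_bases(oriented_seq[i])
    L <- lens[i]
    idx <- pos + seq_len(L)
    cols[idx] <- offset[i] + seq_len(L) - 1L
    codes[idx] <- v
    if (!is.na(qual[i])) wts[idx] <- .qual_to_int(qual[i])
    pos <- pos + L
  }
  # counts and quality sums per (column, base)
  key <- cols * 5L + codes            # codes in 1..5
  counts <- tabulate(key, nbins = (total_len - 1L) * 5L + 5L)
  qsums <- numeric(length(counts))
  agg <- rowsum(wts, key)
  qsums[as.integer(rownames(agg))] <- agg[, 1]
  cmat <- matrix(counts, nrow = 5L)   # rows = A,C,G,T,N; cols = positions
  qmat <- matrix(qsums, nrow = 5L)
  rank <- cmat[1:4, , drop = FALSE] * 1e7 + qmat[1:4, , drop = FALSE]
  best <- max.col(t(rank), ties.method = "first")
  only_n <- colSums(cmat[1:4, , drop = FALSE]) == 0L
  bases <- c("A", "C", "G", "T")[best]
  bases[only_n & cmat[5L, ] > 0L] <- "N"
  # uncovered columns cannot occur inside a contig built from overlapping
  # reads, but guard anyway
  bases[only_n & cmat[5L, ] == 0L] <- "N"
  paste(bases, collapse = "")
}

# ungapped identity of an oriented read against the consensus at its offset
.placement_identity <- function(consensus, oriented_seq, offset) {
  L <- str_length(oriented_seq)
  ref <- str_sub(consensus, offset + 1L, offset + L)
  a <- utf8ToInt(ref)
  b <- utf8ToInt(oriented_seq)
  n <- min(length(a), length(b))
  if (n == 0) return(0)
  sum(a[seq_len(n)] == b[seq_len(n)]) / n
}

#' Greedy overlap-layout-consensus assembly
#'
#' Merges reads along overlaps in deterministic priority order (longest
#' overlap, then highest identity, then lexicographically smallest read id
#' pair) until no admissible overlap remains. Every read is placed in
#' exactly one contig (singletons included); overlaps that would force a
#' read into two contigs are skipped and counted. The consensus is a
#' per-column majority vote weighted by quality on ties; no `N` is emitted
#' unless a column is covered only by `N` votes.
#'
#' @param reads read tibble.
#' @param overlaps overlap tibble from [find_overlaps()] on the same reads.
#' @param cfg a [pipeline_config()].
#' @return contig tibble: `contig_id`, `seq`, `length`, `n_reads`,
#'   `placements` (list column of tibbles `read_id`, `orientation`,
#'   `start`, `identity`, `sample`).
#' @export
greedy_assemble <- function(reads, overlaps, cfg = pipeline_config()) {
  .assert_reads(reads)
  n <- nrow(reads)
  if (n == 0)
    return(tibble(contig_id = character(), seq = character(),
                  length = integer(), n_reads = integer(),
                  placements = list()))
  lens <- str_length(reads$seq)
  comp <- seq_len(n)            # component id per read
  members <- as.list(seq_len(n))
  strand <- rep(1L, n)
  off <- rep(0L, n)

  if (nrow(overlaps) > 0 && !all(c("ia", "ib") %in% names(overlaps))) {
    overlaps$ia <- match(overlaps$read_a, reads$id)
    overlaps$ib <- match(overlaps$read_b, reads$id)
  }
  if (nrow(overlaps) > 0) {
    ord <- order(-overlaps$length, -overlaps$identity,
                 overlaps$read_a, overlaps$read_b)
    ov <- overlaps[ord, , drop = FALSE]
    skipped <- 0L
    for (t in seq_len(nrow(ov))) {
      a <- ov$ia[t]; b <- ov$ib[t]
      ca <- comp[a]; cb <- comp[b]
      if (ca == cb) { skipped <- skipped + 1L; next }
      rc <- ov$orientation[t] == "RC"
      d <- ov$offset[t]
      La <- lens[a]; Lb <- lens[b]
      # placement of b in a's component frame
      s_b_new <- strand[a] * (if (rc) -1L else 1L)
      off_b_new <- if (strand[a] > 0) off[a] + d else off[a] + La - d - Lb
      mb <- members[[cb]]
      if (s_b_new == strand[b]) {
        delta <- off_b_new - off[b]
        off[mb] <- off[mb] + delta
      } else {
        beta <- off_b_new + off[b] + Lb
        off[mb] <- beta - off[mb] - lens[mb]
        strand[mb] <- -strand[mb]
      }
      # weighted union: merge smaller member list into larger
      ma <- members[[ca]]
      if (length(ma) >= length(mb)) {
        comp[mb] <- ca
        members[[ca]] <- c(ma, mb)
        members[[cb]] <- integer(0)
      } else {
        comp[ma] <- cb
        members[[cb]] <- c(mb, ma)
        members[[ca]] <- integer(0)
      }
    }
  }

  comps <- unique(comp)
  qual <- if ("qual" %in% names(reads)) reads$qual else rep(NA_character_, n)
  samp <- if ("sample" %in% names(reads)) reads$sample else rep(NA_character_, n)
  build <- lapply(comps, function(cc) {
    m <- members[[cc]]
    m <- m[order(off[m], reads$id[m])]
    o <- off[m] - min(off[m])
    oseq <- ifelse(strand[m] > 0, reads$seq[m], revcomp(reads$seq[m]))
    cons <- .consensus_from_placements(oseq, o, qual[m])
    pid <- vapply(seq_along(m), function(i)
      .placement_identity(cons, oseq[i], o[i]), 0)
    list(seq = cons,
         placements = tibble(
           read_id = reads$id[m],
           orientation = ifelse(strand[m] > 0, "+", "-"),
           start = o,
           identity = pid,
           sample = samp[m]))
  })
  seqs <- map_chr(build, "seq")
  first_read <- map_chr(build, function(b) b$placements$read_id[1])
  ordc <- order(-str_length(seqs), first_read)
  tibble(
    contig_id = sprintf("tig%05d", seq_along(ordc)),
    seq = seqs[ordc],
    length = str_length(seqs[ordc]),
    n_reads = map_int(build, function(b) nrow(b$placements))[ordc],
    placements = lapply(build[ordc], function(b) b$placements)
  )
}

#' Flatten contig placements into a layout table
#'
#' @param contigs contig tibble from [greedy_assemble()].
#' @return tibble: `contig_id`, `read_id`, `orientation`, `start`,
#'   `identity`, `sample`.
#' @export
contig_layout <- function(contigs) {
  .assert_contigs(contigs)
  if (nrow(contigs) == 0)
    return(tibble(contig_id = character(), read_id = character(),
                  orientation = character(), start = integer(),
                  identity = double(), sample = character()))
  out <- contigs |>
    select("contig_id", "placements") |>
    tidyr::unnest("placements")
  out
}
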