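# Iterative contig end extension -- the "refined" part of the targeted
# assembly. Contig ends are compared against the full read pool (and,
# optionally, whole-metagenome contigs) by seeded, banded high-identity
# overlap alignment; when every candidate protrusion agrees (pairwise
# identity >= the assembly overlap identity over the shared region) the end
# grows by their consensus, otherwise the end is flagged ambiguous and left
# alone (fail-safe fork rule). The assembly thresholds (min overlap length /
# identity) are reused as the extension cutoffs; that interpretation is
# recorded in the report header written by the pipeline.

# Filter verified seed candidates of one end window down to admissible
# 3'-dovetail extensions; `cand`/`ver` rows already subset to this window.
.end_candidates <- function(cand, ver, W, pool_seqs, cfg) {
  if (is.null(cand) || nrow(cand) == 0) return(NULL)
  lens <- str_length(pool_seqs)[cand$ib]
  identity <- ifelse(ver$columns > 0, ver$matches / ver$columns, 0)
  keep <- which(ver$columns >= cfg$min_overlap_len &
                  identity >= cfg$min_overlap_identity &
                  cand$diag + lens > W)
  if (length(keep) == 0) return(NULL)
  oseq <- ifelse(cand$rc[keep],
                 revcomp(pool_seqs[cand$ib[keep]]),
                 pool_seqs[cand$ib[keep]])
  tibble(
    ib = cand$ib[keep],
    rc = cand$rc[keep],
    diag = cand$diag[keep],
    b_hi = ver$b_hi[keep],
    identity = identity[keep],
    protrusion = str_sub(oseq, ver$b_hi[keep] + 1L)
  )
}

# aligned identity of two protrusions over their shared region (banded,
# absorbing the occasional homopolymer indel)
.protrusion_identity <- function(a, b) {
  v <- cpp_verify_overlaps(a, b, 1L, 1L, FALSE, 0L)
  if (v$columns == 0) return(1)
  v$matches / v$columns
}

# Fork detection: candidate extensions must agree pairwise over shared
# regions. Pairs whose shared region is shorter than the minimum overlap
# length carry too little signal to witness a fork (one sequencing error in
# a 15 nt tail would otherwise fake a conflict) and are skipped. For large
# candidate sets the check anchors on the longest protrusion (any genuine
# fork conflicts with it).
.pairwise_agree <- function(protrusions, min_identity, min_len,
                            max_full = 25L) {
  k <- length(protrusions)
  if (k < 2) return(TRUE)
  ord <- order(-str_length(protrusions))
  pr <- protrusions[ord]
  lens <- str_length(pr)
  check <- function(i, j) {
    if (min(lens[i], lens[j]) < min_len) return(TRUE)
    .protrusion_identity(pr[i], pr[j]) >= min_identity
  }
  if (k <= max_full) {
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        if (!check(i, j)) return(FALSE)
      }
    }
  } else {
    for (j in seq.int(2L, k)) {
      if (!check(1L, j)) return(FALSE)
    }
  }
  TRUE
}

#' Iteratively extend contig ends against a sequence pool
#'
#' Each end of each contig is repeatedly compared against the pool; when
#' candidate extensions agree they contribute a consensus extension and
#' their reads join the contig's placements, and when they conflict the end
#' is flagged `"ambiguous"` and never extended further. Stops at fixpoint or
#' after `cfg$max_extension_iters` iterations. Contig length never
#' decreases. Reads may extend more than one contig; such reads are flagged
#' in the `reads_used` table.
#'
#' @param contigs contig tibble from [greedy_assemble()].
#' @param pool read tibble used for extension (typically the full read set).
#' @param pool_contigs optional whole-metagenome contig tibble whose
#'   sequences join the pool.
#' @param cfg a [pipeline_config()].
#' @return list with `contigs` (extended), `report` (tibble: `contig_id`,
#'   `end` (`"5p"`/`"3p"`), `iterations`, `nt_added`, `status` in
#'   fixpoint/ambiguous/max_iters) and `reads_used` (tibble: `contig_id`,
#'   `read_id`, `multiply_used`).
#' @export
extend_contigs <- function(contigs, pool, pool_contigs = NULL,
                           cfg = pipeline_config()) {
  .assert_contigs(contigs)
  pool_seqs <- character(0)
  pool_ids <- character(0)
  if (!is.null(pool) && nrow(pool) > 0) {
    .assert_reads(pool)
    pool_seqs <- pool$seq
    pool_ids <- pool$id
  }
  if (!is.null(pool_contigs) && nrow(pool_contigs) > 0) {
    .assert_contigs(pool_contigs)
    pool_seqs <- c(pool_seqs, pool_contigs$seq)
    pool_ids <- c(pool_ids, pool_contigs$contig_id)
  }
  nc <- nrow(contigs)
  state <- contigs
  rep_rows <- list()
  used_rows <- list()
  if (nc == 0 || length(pool_seqs) == 0) {
    report <- tibble(
      contig_id = rep(contigs$contig_id, each = 2L),
      end = rep(c("5p", "3p"), times = nc),
      iterations = rep(1L, 2L * nc),
      nt_added = rep(0L, 2L * nc),
      status = rep("fixpoint", 2L * nc))
    return(list(contigs = state, report = report,
                reads_used = tibble(contig_id = character(),
                                    read_id = character(),
                                    multiply_used = logical())))
  }
  window_max <- 600L

  # per-end bookkeeping; all still-active ends share one pool seed scan
  # per round
  ends <- tidyr::expand_grid(ci = seq_len(nc), side = c("3p", "5p"))
  ends$active <- TRUE
  ends$iterations <- 0L
  ends$nt_added <- 0L
  ends$status <- "max_iters"
  plcs <- state$placements

  for (round in seq_len(cfg$max_extension_iters)) {
    act <- which(ends$active)
    if (length(act) == 0) break
    L0 <- str_length(state$seq)
    W0 <- pmin(L0, window_max)
    windows <- vapply(act, function(k) {
      ci <- ends$ci[k]
      if (ends$side[k] == "3p")
        str_sub(state$seq[ci], L0[ci] - W0[ci] + 1L, L0[ci])
      else revcomp(str_sub(state$seq[ci], 1L, W0[ci]))
    }, "")
    cand <- cpp_seed_pairs(windows, pool_seqs, k = cfg$seed_k,
                           same_set = FALSE)
    ver <- if (nrow(cand) > 0)
      cpp_verify_overlaps(windows, pool_seqs, cand$ia, cand$ib, cand$rc,
                          cand$diag)
    else NULL
    ends$iterations[act] <- ends$iterations[act] + 1L
    for (w in seq_along(act)) {
      k <- act[w]
      ci <- ends$ci[k]
      side <- ends$side[k]
      rows <- if (!is.null(ver)) which(cand$ia == w) else integer(0)
      cands <- .end_candidates(cand[rows, , drop = FALSE],
                               ver[rows, , drop = FALSE],
                               W0[ci], pool_seqs, cfg)
      if (!is.null(cands))
        cands <- cands[str_length(cands$protrusion) > 0L, , drop = FALSE]
      if (is.null(cands) || nrow(cands) == 0) {
        ends$active[k] <- FALSE
        ends$status[k] <- "fixpoint"
        next
      }
      if (!.pairwise_agree(cands$protrusion, cfg$min_overlap_identity,
                           cfg$min_overlap_len)) {
        ends$active[k] <- FALSE
        ends$status[k] <- "ambiguous"
        next
      }
      ext <- .consensus_from_placements(
        cands$protrusion, rep(0L, nrow(cands)),
        rep(NA_character_, nrow(cands)))
      LE <- str_length(ext)
      Lbo <- str_length(pool_seqs[cands$ib])
      plc <- plcs[[ci]]
      if (side == "3p") {
        # oriented pool seq starts at (L - W) + diag on the grown contig;
        # valid even if the other end already extended this round, since
        # the 3' window coordinates only shift with 5' prepends (below)
        pre_grow <- str_length(state$seq[ci]) - L0[ci]  # 5' growth so far
        new_start <- (L0[ci] - W0[ci]) + cands$diag + pre_grow
        new_orient <- ifelse(cands$rc, "-", "+")
        state$seq[ci] <- paste0(state$seq[ci], ext)
      } else {
        # window frame is the reverse complement of the round-start prefix
        new_start <- (W0[ci] + LE) - (cands$diag + Lbo)
        new_orient <- ifelse(cands$rc, "+", "-")
        plc$start <- plc$start + LE
        state$seq[ci] <- paste0(revcomp(ext), state$seq[ci])
      }
      newp <- tibble(
        read_id = pool_ids[cands$ib],
        orientation = new_orient,
        start = as.integer(new_start),
        identity = cands$identity,
        sample = NA_character_)
      newp <- newp[!(newp$read_id %in% plc$read_id), , drop = FALSE]
      plcs[[ci]] <- bind_rows(plc, newp)
      ends$nt_added[k] <- ends$nt_added[k] + LE
    }
  }

  for (ci in seq_len(nc)) {
    state$length[ci] <- str_length(state$seq[ci])
    state$n_reads[ci] <- nrow(plcs[[ci]])
    state$placements[[ci]] <- plcs[[ci]]
    used_rows[[ci]] <- tibble(contig_id = state$contig_id[ci],
                              read_id = plcs[[ci]]$read_id)
  }
  rep_rows <- list(tibble(
    contig_id = state$contig_id[ends$ci],
    end = ends$side,
    iterations = ends$iterations,
    nt_added = ends$nt_added,
    status = ends$status))
  used <- bind_rows(used_rows)
  used <- used |>
    group_by(.data$read_id) |>
    mutate(multiply_used = dplyr::n() > 1L) |>
    ungroup() |>
    select("contig_id", "read_id", "multiply_used")
  list(contigs = state,
       report = bind_rows(rep_rows),
       reads_used = used)
}

#' Extend a single contig
#'
#' Convenience wrapper around [extend_contigs()] for one contig.
#'
#' @param contig a one-row contig tibble.
#' @param pool read tibble used for extension.
#' @param pool_contigs optional contig tibble joining the pool.
#' @param cfg a [pipeline_config()].
#' @return list with `contig` (one-row tibble) and `report`.
#' @export
extend_contig <- function(contig, pool, pool_contigs = NULL,
                          cfg = pipeline_config()) {
  stopifnot(nrow(contig) == 1)
  r <- extend_contigs(contig, pool, pool_contigs, cfg)
  list(contig = r$contigs, report = r$report)
}

#' Merge targeted contigs with whole-metagenome contigs
#'
#' A targeted contig contained in (or dovetailing with) a global contig at
#' >= `cfg$min_overlap_identity` over >= `cfg$min_overlap_len` columns is
#' replaced by the merged consensus: containment adopts the global sequence,
#' a dovetail appends the global protrusion. Read placements and the
#' targeted contig id are kept (`merged_with` records the lineage). When a
#' targeted contig matches several incompatible global contigs, the
#' highest-identity merge wins and the rest are dropped.
#'
#' @param targeted targeted contig tibble.
#' @param global_contigs whole-metagenome contig tibble (`contig_id`, `seq`).
#' @param cfg a [pipeline_config()].
#' @return the targeted contig tibble with updated sequences and a
#'   `merged_with` column (`NA` where no merge occurred).
#' @export
merge_with_global_contigs <- function(targeted, global_contigs,
                                      cfg = pipeline_config()) {
  .assert_contigs(targeted)
  .assert_contigs(global_contigs)
  out <- targeted
  out$merged_with <- NA_character_
  if (nrow(targeted) == 0 || nrow(global_contigs) == 0) return(out)
  cand <- cpp_seed_pairs(targeted$seq, global_contigs$seq, k = cfg$seed_k,
                         same_set = FALSE)
  if (nrow(cand) == 0) return(out)
  ver <- cpp_verify_overlaps(targeted$seq, global_contigs$seq,
                             cand$ia, cand$ib, cand$rc, cand$diag)
  identity <- ifelse(ver$columns > 0, ver$matches / ver$columns, 0)
  keep <- which(ver$columns >= cfg$min_overlap_len &
                  identity >= cfg$min_overlap_identity)
  if (length(keep) == 0) return(out)
  cand <- cand[keep, , drop = FALSE]
  identity <- identity[keep]
  ord <- order(cand$ia, -identity)
  cand <- cand[ord, , drop = FALSE]
  identity <- identity[ord]
  done <- logical(nrow(targeted))
  for (t in seq_len(nrow(cand))) {
    ci <- cand$ia[t]
    if (done[ci]) next
    done[ci] <- TRUE
    g <- global_contigs$seq[cand$ib[t]]
    g_or <- if (cand$rc[t]) revcomp(g) else g
    d <- cand$diag[t]
    Lt <- str_length(out$seq[ci])
    Lg <- str_length(g_or)
    plc <- out$placements[[ci]]
    if (d <= 0 && d + Lg >= Lt) {
      # containment: adopt the global sequence, shift placements
      out$seq[ci] <- g_or
      plc$start <- plc$start - d
    } else if (d + Lg > Lt) {
      # global protrudes past the 3' end
      out$seq[ci] <- paste0(out$seq[ci], str_sub(g_or, Lt - d + 1L))
    } else if (d < 0) {
      # global protrudes past the 5' end
      pre <- str_sub(g_or, 1L, -d)
      out$seq[ci] <- paste0(pre, out$seq[ci])
      plc$start <- plc$start + str_length(pre)
    } else {
      # global strictly inside the targeted contig: nothing to add
      out$merged_with[ci] <- global_contigs$contig_id[cand$ib[t]]
      next
    }
    out$placements[[ci]] <- plc
    out$length[ci] <- str_length(out$seq[ci])
    out$merged_with[ci] <- global_contigs$contig_id[cand$ib[t]]
  }
  out
}

#' Keep contigs at or above the minimum length
#'
#' The published operating point keeps contigs >= 1 kb (inclusive).
#'
#' @param contigs contig tibble.
#' @param cfg a [pipeline_config()].
#' @return the filtered contig tibble.
#' @export
filter_by_length <- function(contigs, cfg = pipeline_config()) {
  .assert_contigs(contigs)
  if (nrow(contigs) == 0) return(contigs)
  contigs[str_length(contigs$seq) >= cfg$min_contig_len, , drop = FALSE]
}
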