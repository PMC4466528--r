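# Contig-specific primer design and in-silico PCR, emulating the wet-lab
# validation of assembled contigs: primer pairs are designed from randomly
# selected GH-containing contigs, amplified in silico against a template set
# (source genomes or the read pool), and the amplicon is compared with the
# predicted contig interval. Melting temperatures use the Wallace rule
# Tm = 2(A+T) + 4(G+C), valid for <= 25-mers, keeping the check
# deterministic and closed-form. Specificity requires the primer's 3'
# 15-mer to occur exactly once (its own site) across the whole contig set,
# both strands.

#' Wallace-rule melting temperature
#'
#' `Tm = 2(A+T) + 4(G+C)` in degrees C, the standard closed-form rule for
#' oligos of up to 25 nt.
#'
#' @param primers character vector of primer sequences.
#' @return numeric vector of melting temperatures.
#' @export
#' @examples
#' wallace_tm("AAAATTTTGGGGCCCC")  # 48
wallace_tm <- function(primers) {
  gc <- vapply(strsplit(primers, ""), function(b) sum(b %in% c("G", "C")), 0L)
  2 * (str_length(primers) - gc) + 4 * gc
}

# occurrence counts of every 15-mer over a contig set, both strands
.kmer15_table <- function(seqs) {
  grab <- function(s) {
    L <- str_length(s)
    if (L < 15L) return(character(0))
    substring(s, 1:(L - 14L), 15:L)
  }
  all_k <- c(unlist(lapply(seqs, grab)), unlist(lapply(revcomp(seqs), grab)))
  table(all_k)
}

# candidate primers on one strand of a contig: start (0-based), len, tm
.primer_candidates <- function(seq, len_range, gc_range, tm_range) {
  L <- str_length(seq)
  out <- list()
  fails <- c(gc_fail = 0L, tm_fail = 0L)
  for (pl in seq.int(len_range[1], len_range[2])) {
    if (L < pl) next
    starts <- 1:(L - pl + 1L)
    prim <- substring(seq, starts, starts + pl - 1L)
    gc <- vapply(strsplit(prim, ""), function(b) sum(b %in% c("G", "C")), 0L)
    gcf <- gc / pl
    tm <- 2 * (pl - gc) + 4 * gc
    ok_gc <- gcf >= gc_range[1] & gcf <= gc_range[2]
    ok_tm <- tm >= tm_range[1] & tm <= tm_range[2]
    fails["gc_fail"] <- fails["gc_fail"] + sum(!ok_gc)
    fails["tm_fail"] <- fails["tm_fail"] + sum(ok_gc & !ok_tm)
    k <- which(ok_gc & ok_tm)
    if (length(k) > 0)
      out[[length(out) + 1L]] <- tibble(start = starts[k] - 1L, len = pl,
                                        primer = prim[k], tm = tm[k])
  }
  list(cand = if (length(out) > 0) bind_rows(out) else
    tibble(start = integer(), len = integer(), primer = character(),
           tm = double()),
    fails = fails)
}

#' Design contig-specific primer pairs
#'
#' Primer constraints: length 18-25 nt, GC 40-60%, Wallace-rule Tm 55-65
#' deg C with |Tm_fwd - Tm_rev| <= 5, product length 100-1500 nt, and no
#' perfect match of the primer's 3' 15-mer anywhere else in the contig set
#' (either strand).
#'
#' @param contig a one-row contig tibble (>= 400 nt).
#' @param all_contigs the full contig set used for the specificity check
#'   (must include `contig`).
#' @param n_pairs maximum number of pairs to return.
#' @param len_range,gc_range,tm_range,product_range constraint knobs.
#' @return tibble: `contig_id`, `fwd`, `rev`, `fwd_pos`, `rev_pos` (0-based
#'   starts of the two binding sites on the contig), `product_len`,
#'   `tm_fwd`, `tm_rev`. Empty (with a `reasons` attribute of failure
#'   counts) when no admissible pair exists.
#' @export
design_primers <- function(contig, all_contigs, n_pairs = 1L,
                           len_range = c(18L, 25L), gc_range = c(0.40, 0.60),
                           tm_range = c(55, 65), product_range = c(100L, 1500L)) {
  stopifnot(nrow(contig) == 1)
  .assert_contigs(all_contigs)
  s <- contig$seq
  L <- str_length(s)
  if (L < 400L) abort("primer design needs a contig >= 400 nt")
  empty <- tibble(contig_id = character(), fwd = character(),
                  rev = character(), fwd_pos = integer(),
                  rev_pos = integer(), product_len = integer(),
                  tm_fwd = double(), tm_rev = double())
  k15 <- .kmer15_table(all_contigs$seq)
  cc <- .primer_candidates(s, len_range, gc_range, tm_range)
  cand <- cc$cand
  reasons <- c(cc$fails, specificity_fail = 0L, pairing_fail = 0L)
  if (nrow(cand) == 0) {
    attr(empty, "reasons") <- reasons
    return(empty)
  }
  # specificity on the 3' 15-mer: forward primers end at start+len,
  # reverse primers (revcomp of a site window) have their 3' 15-mer equal
  # to the revcomp of the window's first 15 bases -- both must be unique
  # across the set (count 1 = own site; rc windows are counted separately,
  # so a self-reverse-palindromic site would show count 2 and be rejected).
  tail15 <- str_sub(cand$primer, -15L)
  uniq_f <- as.integer(k15[tail15]) == 1L
  uniq_f[is.na(uniq_f)] <- FALSE
  head15rc <- revcomp(str_sub(cand$primer, 1L, 15L))
  uniq_r <- as.integer(k15[head15rc]) == 1L
  uniq_r[is.na(uniq_r)] <- FALSE
  reasons["specificity_fail"] <- sum(!uniq_f)
  fwd_c <- cand[uniq_f, , drop = FALSE]
  rev_c <- cand[uniq_r, , drop = FALSE]   # site windows; primer = revcomp
  if (nrow(fwd_c) == 0 || nrow(rev_c) == 0) {
    attr(empty, "reasons") <- reasons
    return(empty)
  }
  fwd_c <- arrange(fwd_c, .data$start, .data$len)
  rev_c <- arrange(rev_c, desc(.data$start + .data$len), .data$len)
  pairs <- list()
  used_f <- integer(0)
  for (i in seq_len(nrow(fwd_c))) {
    if (length(pairs) >= n_pairs) break
    prod <- (rev_c$start + rev_c$len) - fwd_c$start[i]
    ok <- prod >= product_range[1] & prod <= product_range[2] &
      abs(rev_c$tm - fwd_c$tm[i]) <= 5 &
      rev_c$start >= fwd_c$start[i] + fwd_c$len[i]
    j <- which(ok)
    if (length(j) == 0) next
    j <- j[1]   # largest product first given ordering
    pairs[[length(pairs) + 1L]] <- tibble(
      contig_id = contig$contig_id,
      fwd = fwd_c$primer[i],
      rev = revcomp(rev_c$primer[j]),
      fwd_pos = fwd_c$start[i],
      rev_pos = rev_c$start[j],
      product_len = as.integer(prod[j]),
      tm_fwd = fwd_c$tm[i],
      tm_rev = rev_c$tm[j])
  }
  if (length(pairs) == 0) {
    reasons["pairing_fail"] <- 1L
    attr(empty, "reasons") <- reasons
    return(empty)
  }
  bind_rows(pairs)
}

# global identity of two near-identical sequences: matches over alignment
# columns of a global alignment favouring matches
.global_identity <- function(a, b) {
  if (str_length(a) == 0 || str_length(b) == 0) return(0)
  sm <- matrix(-1L, 5, 5,
               dimnames = list(c("A","C","G","T","N"), c("A","C","G","T","N")))
  diag(sm) <- 1L
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 1)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

#' In-silico PCR of one primer pair against a template set
#'
#' Amplicons are template intervals between perfectly matched primer sites
#' in convergent orientation within 1500 nt (both template strands are
#' searched). The verdict is `"validated"` iff exactly one amplicon arises
#' across all templates and it aligns to the pair's predicted contig
#' interval with identity >= `validation_min_identity`.
#'
#' @param pair one-row tibble from [design_primers()].
#' @param templates character vector of template sequences (or a tibble
#'   with a `seq` column).
#' @param contig the contig the pair was designed on (for the predicted
#'   interval); one-row tibble.
#' @param validation_min_identity inclusive identity cutoff.
#' @param max_product maximum amplicon length considered.
#' @return list with `amplicons` (tibble: `template`, `start`, `strand`,
#'   `product_len`, `seq`), `verdict` (`"validated"`/`"not_validated"`),
#'   and `identity` (of the single amplicon, else `NA`).
#' @export
insilico_pcr <- function(pair, templates, contig,
                         validation_min_identity = 0.95,
                         max_product = 1500L) {
  stopifnot(nrow(pair) == 1, nrow(contig) == 1)
  if (is.data.frame(templates)) templates <- templates$seq
  fwd <- pair$fwd
  rev <- pair$rev
  rc_rev <- revcomp(rev)
  rc_fwd <- revcomp(fwd)
  amps <- list()
  find_all <- function(hay, needle) {
    hits <- gregexpr(needle, hay, fixed = TRUE)[[1]]
    if (hits[1] == -1) integer(0) else as.integer(hits)
  }
  for (ti in seq_along(templates)) {
    tp <- templates[ti]
    # top strand: fwd ... rc(rev)
    p1 <- find_all(tp, fwd)
    p2 <- find_all(tp, rc_rev)
    for (a in p1) for (b in p2) {
      plen <- (b + str_length(rev) - 1L) - a + 1L
      if (b >= a + str_length(fwd) && plen <= max_product)
        amps[[length(amps) + 1L]] <- tibble(
          template = ti, start = a - 1L, strand = "+",
          product_len = plen, seq = str_sub(tp, a, a + plen - 1L))
    }
    # bottom strand: rev ... rc(fwd) on the top-strand sequence
    q1 <- find_all(tp, rev)
    q2 <- find_all(tp, rc_fwd)
    for (a in q1) for (b in q2) {
      plen <- (b + str_length(fwd) - 1L) - a + 1L
      if (b >= a + str_length(rev) && plen <= max_product)
        amps[[length(amps) + 1L]] <- tibble(
          template = ti, start = a - 1L, strand = "-",
          product_len = plen,
          seq = revcomp(str_sub(tp, a, a + plen - 1L)))
    }
  }
  amplicons <- if (length(amps) > 0) bind_rows(amps) else
    tibble(template = integer(), start = integer(), strand = character(),
           product_len = integer(), seq = character())
  identity <- NA_real_
  verdict <- "not_validated"
  if (nrow(amplicons) == 1) {
    predicted <- str_sub(contig$seq, pair$fwd_pos + 1L,
                         pair$rev_pos + str_length(rev))
    identity <- .global_identity(amplicons$seq[1], predicted)
    if (identity >= validation_min_identity) verdict <- "validated"
  }
  list(amplicons = amplicons, verdict = verdict, identity = identity)
}

#' Design and validate primers for a set of contigs
#'
#' Emulates the contig-accuracy check: up to `n` contigs (>= 400 nt) are
#' drawn at random under `cfg$rng_seed`, one primer pair is designed per
#' contig, and each pair is amplified in silico against `templates`.
#'
#' @param contigs contig tibble (typically the GH-containing set).
#' @param templates character vector (or tibble with `seq`) of template
#'   sequences, e.g. source genomes or the read pool.
#' @param n number of contigs to sample.
#' @param cfg a [pipeline_config()]; supplies the sampling seed and the
#'   validation identity cutoff.
#' @return list with `primers` (tibble of designed pairs) and `report`
#'   (tibble: `contig_id`, `verdict` in validated/not_validated/no_primers,
#'   `amplicon_identity`, `product_len`).
#' @export
validate_contigs <- function(contigs, templates, n = 50L,
                             cfg = pipeline_config()) {
  .assert_contigs(contigs)
  eligible <- contigs[str_length(contigs$seq) >= 400L, , drop = FALSE]
  if (nrow(eligible) == 0)
    return(list(primers = tibble(), report = tibble(
      contig_id = character(), verdict = character(),
      amplicon_identity = double(), product_len = integer())))
  picked <- withr::with_seed(cfg$rng_seed, {
    idx <- sample.int(nrow(eligible), min(n, nrow(eligible)))
    sort(idx)
  })
  primers <- list()
  rep_rows <- list()
  for (i in picked) {
    ctg <- eligible[i, , drop = FALSE]
    pr <- design_primers(ctg, contigs)
    if (nrow(pr) == 0) {
      rep_rows[[length(rep_rows) + 1L]] <- tibble(
        contig_id = ctg$contig_id, verdict = "no_primers",
        amplicon_identity = NA_real_, product_len = NA_integer_)
      next
    }
    res <- insilico_pcr(pr[1, ], templates, ctg,
                        validation_min_identity = cfg$validation_min_identity)
    primers[[length(primers) + 1L]] <- pr[1, ]
    rep_rows[[length(rep_rows) + 1L]] <- tibble(
      contig_id = ctg$contig_id, verdict = res$verdict,
      amplicon_identity = res$identity,
      product_len = pr$product_len[1])
  }
  list(primers = if (length(primers) > 0) bind_rows(primers) else tibble(),
       report = bind_rows(rep_rows))
}
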