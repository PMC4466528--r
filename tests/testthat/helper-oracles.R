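# Independent oracles and fixture builders. The oracles deliberately avoid
# the package's own code paths: translation uses a hand-built codon table,
# protein local alignment goes through Biostrings::pairwiseAlignment, and
# overlap detection scans every offset by brute force.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
rand_prot <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                      n, replace = TRUE), collapse = "")

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# codon -> amino acid, bacterial/standard translation table, indexed by the
# classic TCAG ordering
.oracle_codon_table <- local({
  b <- c("T", "C", "A", "G")
  # third base varies fastest, first base slowest (TTT, TTC, TTA, TTG, TCT, ...)
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L),
                   rep(b, 16L))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa, codons)
})

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0) return("")
  cods <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- .oracle_codon_table[cods]
  aa[is.na(aa)] <- "X"   # codons containing N
  paste(aa, collapse = "")
}

oracle_six_frames <- function(seq) {
  rc <- oracle_revcomp(seq)
  out <- c(
    "+1" = oracle_translate(seq),
    "+2" = oracle_translate(substring(seq, 2)),
    "+3" = oracle_translate(substring(seq, 3)),
    "-1" = oracle_translate(rc),
    "-2" = oracle_translate(substring(rc, 2)),
    "-3" = oracle_translate(substring(rc, 3))
  )
  out
}

# best Smith-Waterman score of a peptide vs a protein, BLOSUM62 gap 11/1,
# never crossing a stop: maximum over stop-free segments, via Biostrings
oracle_sw_protein <- function(pep, prot) {
  segs <- strsplit(pep, "*", fixed = TRUE)[[1]]
  segs <- segs[nchar(segs) > 0]
  if (length(segs) == 0) return(0)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  max(vapply(segs, function(s)
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(s), Biostrings::AAString(prot), type = "local",
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE), 0))
}

# Karlin-Altschul significance, written out independently
oracle_evalue_protein <- function(score, m, n) {
  bits <- (0.267 * score - log(0.041)) / log(2)
  m * n * 2^(-bits)
}

# exhaustive six-frame recruitment oracle: returns recruited read ids
oracle_recruit <- function(reads, panel, evalue_max = 1e-2) {
  frames <- lapply(reads$seq, oracle_six_frames)
  n_space <- sum(vapply(frames, function(f) sum(nchar(f)), 0))
  m_space <- sum(nchar(panel$seq))
  hit <- vapply(seq_len(nrow(reads)), function(i) {
    for (p in seq_len(nrow(panel))) {
      for (f in frames[[i]]) {
        if (nchar(f) == 0) next
        s <- oracle_sw_protein(f, panel$seq[p])
        if (s > 0 && oracle_evalue_protein(s, m_space, n_space) <= evalue_max)
          return(TRUE)
      }
    }
    FALSE
  }, TRUE)
  reads$id[hit]
}

# brute-force overlap scan: all offsets, both orientations, ungapped
# identity (intended for error-free fixtures); best offset per pair and
# orientation by (overlap length, identity)
oracle_overlaps <- function(reads, min_len = 40L, min_id = 0.90) {
  n <- nrow(reads)
  rows <- list()
  ham <- function(a, b) {
    va <- utf8ToInt(a); vb <- utf8ToInt(b)
    sum(va == vb)
  }
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      for (orient in c("F", "RC")) {
        a <- reads$seq[i]
        b <- if (orient == "F") reads$seq[j] else oracle_revcomp(reads$seq[j])
        La <- nchar(a); Lb <- nchar(b)
        best <- NULL
        for (d in seq.int(-Lb + 1L, La - 1L)) {
          a_lo <- max(0L, d); a_hi <- min(La, d + Lb)
          len <- a_hi - a_lo
          if (len < min_len) next
          sa <- substring(a, a_lo + 1L, a_hi)
          sb <- substring(b, a_lo - d + 1L, a_hi - d)
          idn <- ham(sa, sb) / len
          if (idn < min_id) next
          if (is.null(best) || len > best$len ||
              (len == best$len && idn > best$id))
            best <- list(len = len, id = idn, d = d)
        }
        if (!is.null(best))
          rows[[length(rows) + 1L]] <- data.frame(
            read_a = reads$id[i], read_b = reads$id[j],
            orientation = orient, length = best$len, identity = best$id,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(read_a = character(), read_b = character(),
                      orientation = character(), length = integer(),
                      identity = double(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# brute-force ORF enumeration: every (start codon or 5' edge) to (stop or
# 3' edge) reading frame on both strands, then per-stop maxima
oracle_orfs <- function(seq, min_nt = 300L) {
  rows <- list()
  L <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    for (f in 0:2) {
      ncod <- (L - f) %/% 3L
      if (ncod == 0) next
      starts <- f + 3L * (seq_len(ncod) - 1L) + 1L
      cods <- substring(s, starts, starts + 2L)
      stops <- which(cods %in% c("TAA", "TAG", "TGA"))
      bounds <- c(0L, stops)
      for (k in seq_along(bounds)) {
        lo_c <- bounds[k] + 1L
        hi_c <- if (k < length(bounds)) bounds[k + 1L] else ncod
        if (hi_c < lo_c) next
        has_stop <- k < length(bounds)
        cand_starts <- lo_c - 1L +
          which(cods[lo_c:min(hi_c, ncod)] %in% c("ATG", "GTG", "TTG"))
        if (lo_c == 1L) cand_starts <- union(lo_c, cand_starts)
        if (length(cand_starts) == 0) next
        best_start <- min(cand_starts)
        last_c <- hi_c
        len_nt <- (last_c - best_start + 1L) * 3L
        if (len_nt < min_nt) next
        lo <- f + 3L * (best_start - 1L)
        hi <- f + 3L * last_c
        if (strand == "-") { tmp <- lo; lo <- L - hi; hi <- L - tmp }
        rows[[length(rows) + 1L]] <- data.frame(
          lo = lo, hi = hi, strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(lo = integer(), hi = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# error-free reads tiling a template at a fixed step
tiling_reads <- function(template, read_len = 100L, step = 56L,
                         prefix = "t") {
  L <- nchar(template)
  starts <- seq.int(1L, L - read_len + 1L, by = step)
  if (max(starts) + read_len - 1L < L)
    starts <- c(starts, L - read_len + 1L)
  tibble::tibble(
    id = sprintf("%s%03d", prefix, seq_along(starts)),
    seq = substring(template, starts, starts + read_len - 1L),
    qual = NA_character_,
    sample = "Z7")
}
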