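# Local alignment scoring and Karlin-Altschul significance.
#
# Protein searches use BLOSUM62 with affine gap costs 11 (existence) + 1 per
# residue, the classic translated-search operating point. Nucleotide local
# alignments (the 16S screen) use match +1 / mismatch -2 with gap costs
# 5 + 2 per base. E-values follow Karlin-Altschul statistics,
#   bitscore = (lambda * S - ln K) / ln 2,   E = m * n * 2^(-bitscore),
# with published (lambda, K) for each scoring system and search space m * n
# taken as (total subject residues) * (total query residues), without
# edge-length correction. Cutoffs are applied inclusively everywhere.

# Karlin-Altschul parameters: gapped BLOSUM62 11/1 and nucleotide +1/-2.
.ka_params <- list(
  protein = list(lambda = 0.267, K = 0.041),
  dna = list(lambda = 1.28, K = 0.46)
)

.align_env <- new.env(parent = emptyenv())

# BLOSUM62 with the stop column dropped to a prohibitive penalty: local
# alignments therefore never cross a stop codon, which is exactly the
# maximum over stop-free translated segments for read-scale sequences.
.protein_scoring <- function() {
  if (is.null(.align_env$blosum)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    storage.mode(m) <- "integer"
    m["*", ] <- -10000L
    m[, "*"] <- -10000L
    m["*", "*"] <- -10000L
    .align_env$blosum <- m
    .align_env$alpha_aa <- paste(colnames(m), collapse = "")
  }
  list(mat = .align_env$blosum, alphabet = .align_env$alpha_aa,
       gap_open = 11L, gap_ext = 1L)
}

.dna_scoring <- function() {
  if (is.null(.align_env$dnamat)) {
    b <- c("A", "C", "G", "T", "N")
    m <- matrix(-2L, 5, 5, dimnames = list(b, b))
    diag(m) <- 1L
    m["N", ] <- -2L
    m[, "N"] <- -2L
    .align_env$dnamat <- m
  }
  list(mat = .align_env$dnamat, alphabet = "ACGTN",
       gap_open = 5L, gap_ext = 2L)
}

#' Bit score and e-value from a raw local alignment score
#'
#' @param score raw alignment score(s).
#' @param m,n effective search space factors: total subject residues times
#'   total query residues.
#' @param type `"protein"` (BLOSUM62 11/1) or `"dna"` (+1/-2).
#' @return tibble with `score`, `bitscore`, `evalue`.
#' @export
#' @examples
#' karlin_altschul(100, m = 500, n = 130)
karlin_altschul <- function(score, m, n, type = c("protein", "dna")) {
  type <- match.arg(type)
  p <- .ka_params[[type]]
  bits <- (p$lambda * score - log(p$K)) / log(2)
  tibble(score = score, bitscore = bits,
         evalue = as.numeric(m) * as.numeric(n) * 2^(-bits))
}

# raw score needed to reach e-value `emax` at search space m*n
.score_at_evalue <- function(emax, m, n, type = "protein") {
  p <- .ka_params[[type]]
  bits <- log2(as.numeric(m) * as.numeric(n) / emax)
  (bits * log(2) + log(p$K)) / p$lambda
}

#' Best local alignment of two sequences
#'
#' Full (exhaustive) Smith-Waterman with affine gaps; returns the single
#' best-scoring local alignment with 0-based half-open spans.
#'
#' @param a,b sequences (character scalars).
#' @param type `"protein"` or `"dna"`.
#' @return a one-row tibble: `score`, `a_lo`, `a_hi`, `b_lo`, `b_hi`,
#'   `matches`, `columns`, `identity`.
#' @export
sw_align <- function(a, b, type = c("protein", "dna")) {
  type <- match.arg(type)
  sc <- if (type == "protein") .protein_scoring() else .dna_scoring()
  r <- cpp_sw_align(a, b, sc$mat, sc$alphabet, sc$gap_open, sc$gap_ext)
  tibble(score = r$score, a_lo = r$a_lo, a_hi = r$a_hi,
         b_lo = r$b_lo, b_hi = r$b_hi, matches = r$matches,
         columns = r$columns,
         identity = ifelse(r$columns > 0, r$matches / r$columns, 0))
}

#' Identity of a sequence against a (longer) template
#'
#' Locates `query` on `template` by shared k-mer seeding (both strands) and
#' computes matches over alignment columns of a banded end-to-end alignment
#' of the implied region -- the same identity definition used for overlaps.
#' Intended for comparing an assembled contig with its source genome.
#'
#' @param query sequence (character scalar), e.g. a contig.
#' @param template sequence (character scalar), e.g. the source genome.
#' @param seed_k seed k-mer size.
#' @return identity in `[0, 1]`; 0 when no seed match locates the query.
#' @export
sequence_identity <- function(query, template, seed_k = 16L) {
  stopifnot(length(query) == 1, length(template) == 1)
  cand <- cpp_seed_pairs(template, query, k = seed_k, same_set = FALSE)
  if (nrow(cand) == 0) return(0)
  cand <- cand[which.max(cand$votes), , drop = FALSE]
  ver <- cpp_verify_overlaps(template, query, cand$ia, cand$ib, cand$rc,
                             cand$diag)
  if (ver$columns == 0) return(0)
  ver$matches / ver$columns
}

# vectorised score-only pass: many queries against one subject
.sw_scores <- function(queries, subject, type = "protein") {
  sc <- if (type == "protein") .protein_scoring() else .dna_scoring()
  cpp_sw_score(queries, subject, sc$mat, sc$alphabet, sc$gap_open, sc$gap_ext)
}
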