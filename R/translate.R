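# Six-frame translation under the bacterial genetic code (NCBI table 11).
# Translation itself is delegated to Biostrings; this module fixes the frame
# conventions: frames -1/-2/-3 are computed on the reverse complement,
# trailing partial codons are dropped, stops are rendered '*', and codons
# containing N translate to 'X'.

.genetic_code_11 <- function() {
  Biostrings::getGeneticCode("11")
}

.translate_frame <- function(dna_set, offset, code) {
  w <- Biostrings::width(dna_set)
  keep_w <- pmax(0L, w - offset)
  keep_w <- keep_w - keep_w %% 3L
  sub <- Biostrings::subseq(dna_set, start = offset + 1L,
                            width = keep_w)
  aa <- Biostrings::translate(sub, genetic.code = code,
                              if.fuzzy.codon = "solve",
                              no.init.codon = TRUE)
  as.character(aa)
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames `+1,+2,+3` read the forward strand at offsets 0,1,2; frames
#' `-1,-2,-3` read the reverse complement the same way. Trailing partial
#' codons are dropped, stop codons are rendered `*`, and any codon
#' containing `N` that is not resolvable translates to `X`. Sequences
#' shorter than 3 nt in a frame give an empty string for that frame.
#'
#' @param seq a single nucleotide string.
#' @param genetic_code NCBI table id; only 11 is supported.
#' @return named character vector with elements `+1,+2,+3,-1,-2,-3`.
#' @export
#' @examples
#' translate_six_frames("ATGAAA")[["+1"]]  # "MK"
translate_six_frames <- function(seq, genetic_code = 11L) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (genetic_code != 11L)
    abort("only genetic code table 11 (bacterial) is supported")
  tab <- six_frame_table(seq)
  setNames(tab$peptide, tab$frame)
}

#' Six-frame translations of many sequences
#'
#' Vectorised companion of [translate_six_frames()] used by recruitment:
#' one row per (sequence, frame).
#'
#' @param seqs character vector of nucleotide sequences.
#' @param genetic_code NCBI table id; only 11 is supported.
#' @return tibble with `idx` (index into `seqs`), `frame` (one of
#'   `+1,+2,+3,-1,-2,-3`) and `peptide`.
#' @export
six_frame_table <- function(seqs, genetic_code = 11L) {
  if (genetic_code != 11L)
    abort("only genetic code table 11 (bacterial) is supported")
  code <- .genetic_code_11()
  fwd <- Biostrings::DNAStringSet(seqs)
  rev <- Biostrings::reverseComplement(fwd)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  peps <- c(
    lapply(0:2, function(o) .translate_frame(fwd, o, code)),
    lapply(0:2, function(o) .translate_frame(rev, o, code))
  )
  tibble(
    idx = rep(seq_along(seqs), times = 6L),
    frame = rep(frames, each = length(seqs)),
    peptide = unlist(peps, use.names = FALSE)
  )
}

# frame label -> strand (+1/-1) and 0-based frame offset
.frame_parts <- function(frame) {
  list(strand = ifelse(startsWith(frame, "-"), -1L, 1L),
       offset = as.integer(substr(frame, 2L, 2L)) - 1L)
}

# Convert an amino-acid span (0-based half-open, in frame coordinates) to
# the nucleotide span on the read's FORWARD strand.
.aa_span_to_read_span <- function(frame, aa_lo, aa_hi, read_len) {
  fp <- .frame_parts(frame)
  nt_lo <- fp$offset + 3L * aa_lo
  nt_hi <- fp$offset + 3L * aa_hi
  if (fp$strand > 0) {
    list(lo = nt_lo, hi = nt_hi)
  } else {
    list(lo = read_len - nt_hi, hi = read_len - nt_lo)
  }
}
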