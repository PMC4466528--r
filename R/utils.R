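#' Reverse complement of nucleotide sequences
#'
#' Vectorised reverse complement over plain character sequences. Uppercase
#' IUPAC codes are supported; `N` maps to `N`.
#'
#' @param seqs character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "TTTCAT"))
revcomp <- function(seqs) {
  stopifnot(is.character(seqs))
  cpp_revcomp(seqs)
}

# map A,C,G,T,N -> 1..5; anything else errors upstream
.base_codes <- local({
  v <- integer(256)
  v[utf8ToInt("A")] <- 1L
  v[utf8ToInt("C")] <- 2L
  v[utf8ToInt("G")] <- 3L
  v[utf8ToInt("T")] <- 4L
  v[utf8ToInt("N")] <- 5L
  v
})

.encode_bases <- function(seq) {
  .base_codes[utf8ToInt(seq)]
}

.qual_to_int <- function(qual) {
  if (is.na(qual)) return(NULL)
  utf8ToInt(qual) - 33L
}

.int_to_qual <- function(q) {
  intToUtf8(q + 33L)
}

.assert_reads <- function(reads) {
  stopifnot(is.data.frame(reads))
  need <- c("id", "seq")
  miss <- setdiff(need, names(reads))
  if (length(miss) > 0)
    abort(paste0("reads table lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(reads$id))
    abort(paste0("duplicate read id: ", reads$id[duplicated(reads$id)][1]))
  invisible(reads)
}

.assert_contigs <- function(contigs) {
  stopifnot(is.data.frame(contigs))
  need <- c("contig_id", "seq")
  miss <- setdiff(need, names(contigs))
  if (length(miss) > 0)
    abort(paste0("contig table lacks column(s): ", paste(miss, collapse = ", ")))
  invisible(contigs)
}
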