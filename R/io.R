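# On-disk formats: FASTA / FASTQ (Phred+33) / GFF3 / TSV. Parsing is done by
# Biostrings and rtracklayer; the wrappers here add the strict validation the
# pipeline relies on (unique ids, restricted alphabets, quality range) and
# convert between internal 0-based half-open coordinates and 1-based
# inclusive GFF3.

.find_bad_char_line <- function(path, bad_char) {
  lines <- readLines(path, warn = FALSE)
  hit <- which(!startsWith(lines, ">") &
                 str_detect(toupper(lines), stringr::fixed(toupper(bad_char))))
  if (length(hit) > 0) hit[1] else NA_integer_
}

.validate_alphabet <- function(seqs, ids, allowed, path) {
  pat <- paste0("[^", allowed, "]")
  bad <- stringr::str_extract(seqs, pat)
  i <- which(!is.na(bad))
  if (length(i) > 0) {
    ln <- .find_bad_char_line(path, bad[i[1]])
    abort(sprintf(
      "record '%s' contains character '%s' outside the allowed alphabet (line %s of %s)",
      ids[i[1]], bad[i[1]], ifelse(is.na(ln), "?", ln), path))
  }
  invisible(TRUE)
}

.first_token <- function(x) sub("\\s.*$", "", x)

#' Read a FASTA file into a tibble
#'
#' Records are returned in file order with sequences uppercased. For
#' `type = "protein"`, a single trailing `*` (stop) is stripped. Duplicate
#' ids, empty files and characters outside the allowed alphabet
#' (`A,C,G,T,N` for DNA; the 20 standard residues plus `X` for protein) are
#' hard errors.
#'
#' @param path path to a plain (uncompressed) FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @param sample optional sample label attached to every record (DNA only).
#' @return a tibble: `id`, `seq` (+ `qual`, `sample` for DNA).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "acgt"), fa)
#' read_fasta(fa)
read_fasta <- function(path, type = c("dna", "protein"),
                       sample = NA_character_) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- .first_token(names(x))
  if (any(ids == "")) abort(paste0("record with empty id in ", path))
  if (anyDuplicated(ids))
    abort(paste0("duplicate record id: ", ids[duplicated(ids)][1]))
  seqs <- str_to_upper(as.character(x))
  if (type == "protein") {
    seqs <- sub("\\*$", "", seqs)
    if (any(str_length(seqs) == 0)) abort("zero-length protein record")
    .validate_alphabet(seqs, ids, "ACDEFGHIKLMNPQRSTVWYX", path)
    tibble(id = ids, seq = unname(seqs))
  } else {
    if (any(str_length(seqs) == 0)) abort("zero-length sequence record")
    .validate_alphabet(seqs, ids, "ACGTN", path)
    tibble(id = ids, seq = unname(seqs), qual = NA_character_,
           sample = sample)
  }
}

#' Read a reference protein panel with family labels
#'
#' Headers must carry the family as a `family=` attribute
#' (e.g. `>ref1 family=GH5`); as a fallback, a bare second header token is
#' used. Records without a family label are a hard error.
#'
#' @param path FASTA path.
#' @return a tibble: `id`, `family`, `seq`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) abort(paste0("empty FASTA file: ", path))
  hdr <- names(x)
  ids <- .first_token(hdr)
  fam <- stringr::str_match(hdr, "family=([^\\s]+)")[, 2]
  fallback <- stringr::str_match(hdr, "^\\S+\\s+(\\S+)\\s*$")[, 2]
  fam <- ifelse(is.na(fam), fallback, fam)
  if (any(is.na(fam) | fam == ""))
    abort(paste0("panel record without family label: ",
                 ids[is.na(fam) | fam == ""][1]))
  prot <- read_fasta(path, type = "protein")
  tibble(id = prot$id, family = unname(fam), seq = prot$seq)
}

#' Read a FASTQ file (Sanger/Phred+33) into a read tibble
#'
#' Only the Sanger/Phred+33 quality encoding is accepted; per-base scores
#' must lie in 0-60, so any other dialect is rejected.
#'
#' @param path plain FASTQ path.
#' @param sample sample label attached to every read.
#' @return a tibble: `id`, `seq`, `qual` (Phred+33 string), `sample`.
#' @export
read_fastq <- function(path, sample = NA_character_) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  if (length(x) == 0) abort(paste0("empty FASTQ file: ", path))
  ids <- .first_token(names(x))
  if (anyDuplicated(ids))
    abort(paste0("duplicate record id: ", ids[duplicated(ids)][1]))
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  qr <- range(utf8ToInt(paste(quals, collapse = "")) - 33L)
  if (qr[1] < 0 || qr[2] > 60)
    abort("quality scores outside 0-60: not Sanger/Phred+33 within the 454 range")
  seqs <- str_to_upper(as.character(x))
  .validate_alphabet(seqs, ids, "ACGTN", path)
  tibble(id = ids, seq = unname(seqs), qual = unname(quals), sample = sample)
}

#' Write sequences to FASTA
#'
#' Accepts read tibbles (`id`), contig tibbles (`contig_id`) and panel
#' tibbles (`id` + `family`; the family is emitted as a `family=` header
#' attribute).
#'
#' @param x a tibble with a `seq` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.data.frame(x), "seq" %in% names(x))
  ids <- if ("contig_id" %in% names(x)) x$contig_id else x$id
  if ("family" %in% names(x))
    ids <- paste0(ids, " family=", x$family)
  ss <- Biostrings::BStringSet(setNames(x$seq, ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write reads to FASTQ (Phred+33)
#'
#' Reads without qualities are written at a constant Phred 30.
#'
#' @param reads a read tibble (`id`, `seq`, optional `qual`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  .assert_reads(reads)
  qual <- if ("qual" %in% names(reads)) reads$qual else NA_character_
  fill <- vapply(str_length(reads$seq), function(n) .int_to_qual(rep(30L, n)), "")
  qual <- ifelse(is.na(qual), fill, qual)
  if (any(str_length(qual) != str_length(reads$seq)))
    abort("quality and sequence lengths differ")
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Write gene annotations to GFF3
#'
#' Internal 0-based half-open spans are emitted as 1-based inclusive GFF3
#' coordinates. The assigned family is written into the attributes column.
#'
#' @param annotations tibble with `contig_id`, `lo`, `hi` (0-based half-open),
#'   `strand` (`+`/`-`) and `family`; optional `orf_id`, `evalue`,
#'   `identity`, `partial` columns become attributes.
#' @param contigs contig tibble used to validate coordinates.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotations, contigs, path) {
  .assert_contigs(contigs)
  lens <- setNames(str_length(contigs$seq), contigs$contig_id)
  if (nrow(annotations) > 0) {
    clen <- lens[annotations$contig_id]
    bad <- which(is.na(clen) | annotations$lo < 0 |
                   annotations$hi > clen | annotations$lo >= annotations$hi)
    if (length(bad) > 0)
      abort(sprintf("annotation %d has coordinates outside its contig",
                    bad[1]))
    gr <- GenomicRanges::GRanges(
      seqnames = annotations$contig_id,
      ranges = IRanges::IRanges(start = annotations$lo + 1L,
                                end = annotations$hi),
      strand = annotations$strand)
    gr$source <- "ghrecover"
    gr$type <- "CDS"
    gr$phase <- 0L
    gr$ID <- annotations$orf_id %||%
      sprintf("orf%04d", seq_len(nrow(annotations)))
    gr$family <- annotations$family
    for (extra in c("evalue", "identity", "partial"))
      if (extra %in% names(annotations))
        S4Vectors::mcols(gr)[[extra]] <- as.character(annotations[[extra]])
  } else {
    gr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation file back into a tibble
#'
#' The inverse of [write_gff3()]: 1-based inclusive GFF3 coordinates come
#' back as 0-based half-open `lo`/`hi`.
#'
#' @param path GFF3 path.
#' @return tibble with `contig_id`, `lo`, `hi`, `strand`, `family` and any
#'   extra attribute columns present.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0)
    return(tibble(contig_id = character(), lo = integer(), hi = integer(),
                  strand = character(), family = character()))
  out <- tibble(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    lo = GenomicRanges::start(gr) - 1L,
    hi = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  for (extra in c("ID", "family", "evalue", "identity", "partial"))
    if (extra %in% names(S4Vectors::mcols(gr)))
      out[[tolower(sub("^ID$", "orf_id", extra))]] <-
        as.character(S4Vectors::mcols(gr)[[extra]])
  out
}
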