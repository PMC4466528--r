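random_codons <- function(n) {
  sense <- setdiff(names(ghrecover:::.genetic_code_11()),
                   c("TAA", "TAG", "TGA"))
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

test_that("a constructed gene yields one ORF whose span includes the stop codon", {
  set.seed(91)
  gene <- paste0("ATG", random_codons(120), "TAA")   # 122 codons = 366 nt
  # stop-codon flanks pin the stop-to-stop segment to the gene itself
  contig <- tibble::tibble(
    contig_id = "c1",
    seq = paste0(strrep("TAA", 17), gene, strrep("TAA", 17)))
  orfs <- call_orfs(contig, min_orf_nt = 300L)
  plus <- orfs[orfs$strand == "+" & orfs$lo == 51L, ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$hi - plus$lo, 366L)
  expect_equal(plus$partial, "none")
  expect_equal(substr(contig$seq, plus$lo + 1, plus$lo + 3), "ATG")

  # same gene on the reverse strand: same protein, strand '-'
  contig_rc <- tibble::tibble(contig_id = "c1", seq = revcomp(contig$seq))
  orfs_rc <- call_orfs(contig_rc, min_orf_nt = 300L)
  minus <- orfs_rc[orfs_rc$strand == "-" & orfs_rc$protein == plus$protein, ]
  expect_equal(nrow(minus), 1)
  expect_equal(minus$hi - minus$lo, 366L)
})

test_that("overlapping starts sharing one stop report only the longest ORF", {
  set.seed(92)
  # ATG ... ATG ... TAA : two starts, one stop
  inner <- random_codons(40)
  gene <- paste0("ATG", random_codons(30), "ATG", inner, "TAA")
  flank <- strrep("TAA", 10)
  contig <- tibble::tibble(
    contig_id = "c1",
    seq = paste0(flank, gene, flank))
  orfs <- call_orfs(contig, min_orf_nt = 100L)
  hit <- orfs[orfs$strand == "+" & orfs$hi == 30L + nchar(gene), ]
  # one ORF for this stop, anchored at the most upstream start
  expect_equal(nrow(hit), 1)
  expect_equal(hit$lo, 30L)
  expect_equal(hit$hi - hit$lo, nchar(gene))
})

test_that("ORF calls agree with brute-force enumeration on random contigs", {
  set.seed(93)
  for (i in 1:6) {
    contig <- tibble::tibble(contig_id = "c1", seq = rand_dna(2000))
    orfs <- call_orfs(contig, min_orf_nt = 150L)
    want <- oracle_orfs(contig$seq, 150L)
    key <- function(d) sort(paste(d$lo, d$hi, d$strand))
    expect_equal(key(orfs), key(want), info = paste("iter", i))
  }
})

test_that("every reported ORF translates without internal stops", {
  set.seed(94)
  contig <- tibble::tibble(contig_id = "c1", seq = rand_dna(5000))
  orfs <- call_orfs(contig, min_orf_nt = 150L)
  expect_gt(nrow(orfs), 0)
  expect_false(any(grepl("\\*", orfs$protein)))
  expect_true(all((orfs$hi - orfs$lo) %% 3L == 0L))
})

test_that("family assignment takes the best passing hit and is order-invariant", {
  set.seed(95)
  panel <- synthetic_panel(families = c("GH5", "GH9", "GH3"), aa_len = 150,
                           rng_seed = 6)
  orfs <- tibble::tibble(
    contig_id = "c1", orf_id = c("o1", "o2"),
    lo = c(0L, 500L), hi = c(453L, 953L), strand = "+", frame = 1L,
    partial = "none",
    protein = c(panel$seq[1], rand_prot(150)))
  cfg <- pipeline_config()
  ann <- assign_family(orfs, panel, cfg)
  expect_equal(ann$family, c("GH5", "unassigned"))
  expect_equal(ann$identity[1], 1)
  ann2 <- assign_family(orfs, panel[sample.int(3), ], cfg)
  expect_equal(ann2$family, ann$family)
  expect_equal(ann2$best_protein_id, ann$best_protein_id)
})

test_that("exact ties between panel proteins resolve to the lexicographic id", {
  prot <- rand_prot(150)
  panel <- tibble::tibble(
    id = c("GH3_refB", "GH3_refA"), family = "GH3", seq = prot)
  orfs <- tibble::tibble(
    contig_id = "c1", orf_id = "o1", lo = 0L, hi = 453L, strand = "+",
    frame = 1L, partial = "none", protein = prot)
  ann <- assign_family(orfs, panel, pipeline_config())
  expect_equal(ann$family, "GH3")
  expect_equal(ann$best_protein_id, "GH3_refA")
})

test_that("GH-containing contigs are exactly those with an assigned ORF", {
  set.seed(96)
  panel <- synthetic_panel(families = "GH5", aa_len = 150, rng_seed = 6)
  gene <- withr::with_seed(1, reverse_translate(panel$seq[1]))
  contigs <- tibble::tibble(
    contig_id = c("with", "without"),
    seq = c(paste0(rand_dna(300), gene, rand_dna(300)), rand_dna(1100)))
  ann <- annotate_contigs(contigs, panel, pipeline_config())
  kept <- select_gh_contigs(contigs, ann)
  expect_equal(kept$contig_id, "with")
})

test_that("the 16S screen applies all three thresholds inclusively", {
  set.seed(97)
  ref <- tibble::tibble(id = "16s_1", seq = rand_dna(1500))
  seg <- function(len) substr(ref$seq, 501, 500 + len)
  mm_read <- function(len, n_mm, spacing) {
    v <- strsplit(seg(len), "")[[1]]
    rot <- c(A = "C", C = "G", G = "T", T = "A")
    # interior mismatches with >= 3 matches on each flank so the full
    # alignment is the unique local optimum
    pos <- seq(4, by = spacing, length.out = n_mm)
    v[pos] <- rot[v[pos]]
    paste(v, collapse = "")
  }
  reads <- tibble::tibble(
    id = c("len65", "len64", "id80", "id79"),
    seq = c(seg(65), seg(64),
            mm_read(100, 20, 4),    # 80/100 identity
            mm_read(100, 21, 4)),   # 79/100 identity
    qual = NA_character_, sample = "Z7")
  res <- screen_rrna(reads, ref, pipeline_config())
  expect_true("len65" %in% res$reads$id)
  expect_false("len64" %in% res$reads$id)
  expect_true("id80" %in% res$reads$id)
  expect_false("id79" %in% res$reads$id)
  h <- res$hits[res$hits$read_id == "id80", ]
  expect_equal(h$identity, 0.80)

  # e-value boundary: the cutoff is inclusive
  one <- reads[1, ]
  e <- screen_rrna(one, ref, pipeline_config())$hits$evalue[1]
  at <- pipeline_config(rrna_evalue_max = e)
  below <- pipeline_config(rrna_evalue_max = e * (1 - 1e-9))
  expect_equal(nrow(screen_rrna(one, ref, at)$reads), 1)
  expect_equal(nrow(screen_rrna(one, ref, below)$reads), 0)
})
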