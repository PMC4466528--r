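# Recruitment fixtures: a tiny panel plus reads that either embed a
# reverse-translated panel segment (true positives) or are random
# background (true negatives).

make_panel <- function(n = 3, aa_len = 120, seed = 5) {
  synthetic_panel(families = paste0("GH", c(5, 9, 10))[seq_len(n)],
                  aa_len = aa_len, rng_seed = seed)
}

gene_read <- function(panel_row, aa_from, aa_n, flank = 30, seed = 1) {
  withr::with_seed(seed, {
    seg <- substr(panel_row$seq, aa_from, aa_from + aa_n - 1L)
    gene <- reverse_translate(seg)
    gene <- substr(gene, 1, 3 * aa_n)  # drop the appended stop
    paste0(rand_dna(flank), gene, rand_dna(flank))
  })
}

test_that("a read embedding an exact panel segment is recruited with its family", {
  panel <- make_panel()
  reads <- tibble::tibble(
    id = c("hit", "bg"),
    seq = c(gene_read(panel[1, ], 10, 25), rand_dna(400)),
    qual = NA_character_, sample = "Z7")
  res <- recruit_reads(reads, panel, pipeline_config())
  expect_true("hit" %in% res$reads$id)
  expect_false("bg" %in% res$reads$id)
  expect_equal(unique(res$hits$family[res$hits$read_id == "hit"]), "GH5")
})

test_that("recruitment equals the exhaustive six-frame dynamic-programming oracle", {
  set.seed(31)
  panel <- make_panel()
  reads <- tibble::tibble(
    id = sprintf("r%03d", 1:40),
    seq = c(
      vapply(1:10, function(i)
        gene_read(panel[sample.int(3, 1), ], sample(1:60, 1),
                  sample(15:40, 1), seed = i), ""),
      vapply(1:30, function(i) rand_dna(sample(100:400, 1)), "")),
    qual = NA_character_, sample = "Z7")
  cfg <- pipeline_config()
  mine <- sort(recruit_reads(reads, panel, cfg)$reads$id)
  want <- sort(oracle_recruit(reads, panel, cfg$recruit_evalue_max))
  expect_equal(mine, want)
})

test_that("the e-value cutoff is inclusive at the boundary", {
  panel <- make_panel(1)
  reads <- tibble::tibble(
    id = "r1", seq = gene_read(panel[1, ], 5, 20),
    qual = NA_character_, sample = "Z7")
  hits <- recruit_reads(reads, panel, pipeline_config())$hits
  e <- min(hits$evalue)
  at <- pipeline_config(recruit_evalue_max = e)
  below <- pipeline_config(recruit_evalue_max = e * (1 - 1e-9))
  expect_equal(recruit_reads(reads, panel, at)$reads$id, "r1")
  expect_equal(nrow(recruit_reads(reads, panel, below)$reads), 0L)
})

test_that("recruitment is monotone in the e-value cutoff", {
  set.seed(41)
  panel <- make_panel()
  reads <- tibble::tibble(
    id = sprintf("r%02d", 1:20),
    seq = c(vapply(1:6, function(i)
      gene_read(panel[sample.int(3, 1), ], sample(1:80, 1),
                sample(8:30, 1), seed = 100 + i), ""),
      vapply(1:14, function(i) rand_dna(300), "")),
    qual = NA_character_, sample = "Z7")
  cuts <- c(1e-6, 1e-4, 1e-2, 1)
  sets <- lapply(cuts, function(e)
    recruit_reads(reads, panel, pipeline_config(recruit_evalue_max = e))$reads$id)
  for (k in seq_len(length(cuts) - 1))
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
})

test_that("reverse-complementing every read leaves the recruited set unchanged", {
  set.seed(51)
  panel <- make_panel()
  reads <- tibble::tibble(
    id = sprintf("r%02d", 1:12),
    seq = c(vapply(1:4, function(i)
      gene_read(panel[sample.int(3, 1), ], sample(1:80, 1), 22,
                seed = 200 + i), ""),
      vapply(1:8, function(i) rand_dna(350), "")),
    qual = NA_character_, sample = "Z7")
  cfg <- pipeline_config()
  fwd <- recruit_reads(reads, panel, cfg)$reads$id
  flipped <- reads
  flipped$seq <- revcomp(flipped$seq)
  rev <- recruit_reads(flipped, panel, cfg)$reads$id
  expect_equal(sort(fwd), sort(rev))
})

test_that("align_translated reports frames, spans and strand-symmetric hits", {
  panel <- make_panel(1)
  read <- gene_read(panel[1, ], 10, 30, flank = 21)
  h <- align_translated(read, panel$seq[1])
  expect_gt(nrow(h), 0)
  best <- h[which.max(h$score), ]
  # ungapped exact hit: nucleotide span is three times the aligned residues
  expect_equal(best$matches / best$columns, 1)
  expect_equal(best$read_hi - best$read_lo, 3L * best$columns)
  # the reverse complement hits with the mirrored frame and same score
  h2 <- align_translated(revcomp(read), panel$seq[1])
  expect_equal(max(h2$score), best$score)
  expect_equal(sort(unique(sign(h2$frame[h2$score == max(h2$score)]))),
               -sort(unique(sign(best$frame))))
  # spans map back to the forward strand: same nucleotide interval length
  b2 <- h2[which.max(h2$score), ]
  expect_equal(b2$read_hi - b2$read_lo, best$read_hi - best$read_lo)
})

test_that("empty inputs are handled gracefully", {
  panel <- make_panel(1)
  empty <- tibble::tibble(id = character(), seq = character(),
                          qual = character(), sample = character())
  res <- recruit_reads(empty, panel, pipeline_config())
  expect_equal(nrow(res$reads), 0)
  expect_equal(nrow(res$hits), 0)
  expect_error(recruit_reads(empty, panel[0, ], pipeline_config()),
               "non-empty")
})
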