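make_contig <- function(seq, id = "c1") {
  tibble::tibble(
    contig_id = id, seq = seq, length = nchar(seq), n_reads = 0L,
    placements = list(tibble::tibble(
      read_id = character(), orientation = character(), start = integer(),
      identity = double(), sample = character())))
}

test_that("agreeing protruding reads extend a contig end by exactly their flank", {
  set.seed(81)
  template <- rand_dna(900)
  contig <- make_contig(substr(template, 1, 600))
  # five error-free reads covering 520..720: protrude 120 nt past the end
  pool <- tibble::tibble(
    id = sprintf("p%d", 1:5),
    seq = vapply(1:5, function(i) substr(template, 481 + 8 * i, 720), ""),
    qual = NA_character_, sample = "Z7")
  res <- extend_contigs(contig, pool, cfg = pipeline_config())
  expect_equal(res$contigs$seq[1], substr(template, 1, 720))
  r3 <- res$report[res$report$end == "3p", ]
  expect_equal(r3$nt_added, 120L)
  expect_equal(r3$status, "fixpoint")
  # the 5' end had no candidates
  r5 <- res$report[res$report$end == "5p", ]
  expect_equal(r5$nt_added, 0L)
  expect_equal(r5$iterations, 1L)
  expect_equal(r5$status, "fixpoint")
  # incorporated reads joined the placements
  expect_true(all(pool$id %in% res$contigs$placements[[1]]$read_id))
})

test_that("both ends extend and the 5' extension is reverse-aware", {
  set.seed(82)
  template <- rand_dna(1000)
  contig <- make_contig(substr(template, 301, 700))
  pool <- tibble::tibble(
    id = c("l1", "l2", "r1", "r2"),
    seq = c(substr(template, 201, 400), revcomp(substr(template, 211, 410)),
            substr(template, 601, 800), revcomp(substr(template, 611, 810))),
    qual = NA_character_, sample = "Z7")
  res <- extend_contigs(contig, pool, cfg = pipeline_config())
  # the union of agreeing protrusions reaches 201 on the left (l1) and 810
  # on the right (r2)
  expect_equal(res$contigs$seq[1], substr(template, 201, 810))
})

test_that("a contig with no overlapping pool reads is unchanged at fixpoint", {
  set.seed(83)
  contig <- make_contig(rand_dna(500))
  pool <- tibble::tibble(id = "x", seq = rand_dna(300),
                         qual = NA_character_, sample = "Z7")
  res <- extend_contigs(contig, pool, cfg = pipeline_config())
  expect_equal(res$contigs$seq, contig$seq)
  expect_true(all(res$report$status == "fixpoint"))
  expect_true(all(res$report$iterations == 1L))
})

test_that("irreconcilable candidate extensions flag the end ambiguous without extending", {
  set.seed(84)
  template <- rand_dna(600)
  contig <- make_contig(template)
  over <- substr(template, 521, 600)   # 80 nt anchored on the 3' end
  pool <- tibble::tibble(
    id = c("f1", "f2"),
    seq = c(paste0(over, rand_dna(100)), paste0(over, rand_dna(100))),
    qual = NA_character_, sample = "Z7")
  res <- extend_contigs(contig, pool, cfg = pipeline_config())
  r3 <- res$report[res$report$end == "3p", ]
  expect_equal(r3$status, "ambiguous")
  expect_equal(r3$nt_added, 0L)
  expect_equal(res$contigs$seq, template)
})

test_that("extension never shrinks contigs and terminates within the budget", {
  set.seed(85)
  template <- rand_dna(3000)
  contig <- make_contig(substr(template, 1401, 1700))
  pool <- tiling_reads(template, 150, 40, prefix = "p")
  cfg <- pipeline_config(max_extension_iters = 4L)
  res <- extend_contigs(contig, pool, cfg = cfg)
  expect_gte(res$contigs$length[1], contig$length[1])
  expect_true(all(res$report$iterations <= 4L))
  expect_true(all(res$report$status %in%
                    c("fixpoint", "ambiguous", "max_iters")))
})

test_that("10x error-free local coverage recovers the full unambiguous flank", {
  set.seed(86)
  template <- rand_dna(1200)
  contig <- make_contig(substr(template, 401, 800))
  pool <- tiling_reads(template, 200, 20, prefix = "p")  # 10x coverage
  res <- extend_contigs(contig, pool, cfg = pipeline_config())
  expect_equal(res$contigs$seq[1], template)
})

test_that("a targeted contig contained in a global contig adopts its sequence", {
  set.seed(87)
  global <- rand_dna(5000)
  targeted <- make_contig(substr(global, 2001, 3200), id = "t1")
  globals <- tibble::tibble(contig_id = "g1", seq = global)
  out <- merge_with_global_contigs(targeted, globals, pipeline_config())
  expect_equal(out$seq[1], global)
  expect_equal(out$merged_with[1], "g1")

  # no match: unchanged
  none <- tibble::tibble(contig_id = "g2", seq = rand_dna(4000))
  out2 <- merge_with_global_contigs(targeted, none, pipeline_config())
  expect_equal(out2$seq[1], targeted$seq[1])
  expect_true(is.na(out2$merged_with[1]))
})

test_that("dovetail merges respect the overlap thresholds at the junction", {
  set.seed(88)
  targeted <- make_contig(rand_dna(1000), id = "t1")
  junction <- substr(targeted$seq[1], 956, 1000)  # 45 nt
  mk_global <- function(n_mm) {
    v <- strsplit(junction, "")[[1]]
    if (n_mm > 0) {
      rot <- c(A = "C", C = "G", G = "T", T = "A")
      pos <- seq(20, by = 3, length.out = n_mm)
      v[pos] <- rot[v[pos]]
    }
    tibble::tibble(contig_id = "g1",
                   seq = paste0(paste(v, collapse = ""), rand_dna(800)))
  }
  ok <- merge_with_global_contigs(targeted, mk_global(2),
                                  pipeline_config())   # 43/45 ~ 95%
  expect_equal(ok$length[1], 1800L)
  expect_equal(ok$merged_with[1], "g1")
  no <- merge_with_global_contigs(targeted, mk_global(6),
                                  pipeline_config())   # 39/45 ~ 87%
  expect_equal(no$length[1], 1000L)
})

test_that("the contig length filter is inclusive at the 1 kb boundary", {
  cfg <- pipeline_config()
  contigs <- dplyr::bind_rows(
    make_contig(rand_dna(1000), "a"),
    make_contig(rand_dna(999), "b"),
    make_contig(rand_dna(2500), "c"))
  kept <- filter_by_length(contigs, cfg)
  expect_equal(kept$contig_id, c("a", "c"))
  expect_equal(nrow(filter_by_length(contigs[0, ], cfg)), 0)
})
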