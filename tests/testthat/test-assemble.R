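test_that("exact suffix-prefix overlaps are found with correct length and identity", {
  set.seed(61)
  x <- rand_dna(100)
  y <- paste0(substr(x, 51, 100), rand_dna(50))   # 50 nt exact overlap
  reads <- tibble::tibble(id = c("a", "b"), seq = c(x, y),
                          qual = NA_character_, sample = "Z7")
  ov <- find_overlaps(reads, pipeline_config())
  expect_equal(nrow(ov), 1)
  expect_equal(ov$length, 50L)
  expect_equal(ov$identity, 1)
  expect_equal(ov$orientation, "F")
})

test_that("overlap thresholds are inclusive: 40 nt passes, 39 nt fails", {
  set.seed(62)
  x <- rand_dna(120)
  mk <- function(ovl) {
    y <- paste0(substr(x, 121 - ovl, 120), rand_dna(80))
    tibble::tibble(id = c("a", "b"), seq = c(x, y),
                   qual = NA_character_, sample = "Z7")
  }
  expect_equal(nrow(find_overlaps(mk(40), pipeline_config())), 1)
  expect_equal(nrow(find_overlaps(mk(39), pipeline_config())), 0)
})

test_that("overlap identity 90% passes and 88% fails", {
  set.seed(63)
  x <- rand_dna(150)
  make_mm <- function(n_mm) {
    ov <- substr(x, 101, 150)
    v <- strsplit(ov, "")[[1]]
    # clustered at the overlap 5' side so a clean >= 16-mer seed remains
    pos <- seq(3, by = 3, length.out = n_mm)
    rot <- c(A = "C", C = "G", G = "T", T = "A")
    v[pos] <- rot[v[pos]]
    y <- paste0(paste(v, collapse = ""), rand_dna(100))
    tibble::tibble(id = c("a", "b"), seq = c(x, y),
                   qual = NA_character_, sample = "Z7")
  }
  ov5 <- find_overlaps(make_mm(5), pipeline_config())   # 45/50 = 0.90
  expect_equal(nrow(ov5), 1)
  expect_gte(ov5$identity, 0.90)
  ov6 <- find_overlaps(make_mm(6), pipeline_config())   # 44/50 = 0.88
  expect_equal(nrow(ov6), 0)
})

test_that("reverse-complement overlaps are detected", {
  set.seed(64)
  x <- rand_dna(100)
  y <- revcomp(paste0(substr(x, 41, 100), rand_dna(40)))
  reads <- tibble::tibble(id = c("a", "b"), seq = c(x, y),
                          qual = NA_character_, sample = "Z7")
  ov <- find_overlaps(reads, pipeline_config())
  expect_equal(nrow(ov), 1)
  expect_equal(ov$orientation, "RC")
  expect_equal(ov$length, 60L)
})

test_that("find_overlaps equals the brute-force all-offset oracle on small inputs", {
  cfg <- pipeline_config()
  for (seed in c(71, 72, 73)) {
    set.seed(seed)
    template <- rand_dna(600)
    reads <- tiling_reads(template, read_len = 100, step = sample(40:60, 1))
    reads <- reads[seq_len(min(nrow(reads), 15)), ]
    # reverse-complement a few reads to exercise orientations
    flip <- seq(2, nrow(reads), by = 3)
    reads$seq[flip] <- revcomp(reads$seq[flip])
    mine <- find_overlaps(reads, cfg)
    want <- oracle_overlaps(reads, cfg$min_overlap_len,
                            cfg$min_overlap_identity)
    key <- function(d) sort(paste(d$read_a, d$read_b, d$orientation,
                                  d$length, round(d$identity, 6)))
    expect_equal(key(mine), key(want), info = paste("seed", seed))
  }
})

test_that("error-free tiling reads reassemble the template exactly", {
  set.seed(65)
  template <- rand_dna(1500)
  reads <- tiling_reads(template, read_len = 100, step = 56)
  cfg <- pipeline_config()
  ov <- find_overlaps(reads, cfg)
  ctg <- greedy_assemble(reads, ov, cfg)
  expect_equal(nrow(ctg), 1)
  expect_true(ctg$seq[1] == template || ctg$seq[1] == revcomp(template))
  expect_equal(ctg$n_reads, nrow(reads))
})

test_that("singletons and unrelated read groups stay separate", {
  set.seed(66)
  one <- tibble::tibble(id = "solo", seq = rand_dna(200),
                        qual = NA_character_, sample = "Z7")
  ctg1 <- greedy_assemble(one, find_overlaps(one, pipeline_config()),
                          pipeline_config())
  expect_equal(nrow(ctg1), 1)
  expect_equal(ctg1$seq, one$seq)

  t1 <- rand_dna(500); t2 <- rand_dna(500)
  reads <- rbind(tiling_reads(t1, 100, 60, prefix = "a"),
                 tiling_reads(t2, 100, 60, prefix = "b"))
  cfg <- pipeline_config()
  ctg <- greedy_assemble(reads, find_overlaps(reads, cfg), cfg)
  expect_equal(nrow(ctg), 2)
})

test_that("every input read is placed in exactly one contig", {
  set.seed(67)
  t1 <- rand_dna(800)
  reads <- rbind(tiling_reads(t1, 120, 70, prefix = "a"),
                 tibble::tibble(id = "orphan", seq = rand_dna(150),
                                qual = NA_character_, sample = "Z8"))
  cfg <- pipeline_config()
  ctg <- greedy_assemble(reads, find_overlaps(reads, cfg), cfg)
  placed <- sort(unlist(lapply(ctg$placements, function(p) p$read_id)))
  expect_equal(placed, sort(reads$id))
})

test_that("assembly is deterministic", {
  set.seed(68)
  template <- rand_dna(1200)
  reads <- tiling_reads(template, 110, 60)
  cfg <- pipeline_config()
  a <- greedy_assemble(reads, find_overlaps(reads, cfg), cfg)
  b <- greedy_assemble(reads, find_overlaps(reads, cfg), cfg)
  expect_identical(a$seq, b$seq)
  expect_identical(a$placements, b$placements)
})

test_that("consensus_base follows majority, quality and base-order rules", {
  expect_equal(consensus_base(c("A", "A", "A", "G")), "A")
  expect_equal(consensus_base(c("A", "A", "G", "G"),
                              quals = c(20, 20, 30, 30)), "G")
  expect_equal(consensus_base(c("A", "C")), "A")
  expect_equal(consensus_base(c("N", "N", "A")), "A")
  expect_equal(consensus_base(c("N", "N")), "N")
})

test_that("consensus at 8x error-free coverage equals the template", {
  set.seed(69)
  template <- rand_dna(1000)
  reads <- tiling_reads(template, 200, 24)  # ~8x coverage
  cfg <- pipeline_config()
  ctg <- greedy_assemble(reads, find_overlaps(reads, cfg), cfg)
  expect_equal(nrow(ctg), 1)
  expect_true(ctg$seq[1] == template || ctg$seq[1] == revcomp(template))
})
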