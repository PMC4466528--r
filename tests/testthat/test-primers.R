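test_that("Wallace rule Tm and constraint screening reject bad oligos", {
  expect_equal(wallace_tm("AAAATTTTGGGGCCCC"), 48)   # 2*8 + 4*8
  expect_equal(wallace_tm("GCGCGCGCGCGCGCGCGC"), 72)
  # a contig whose only admissible oligos would be too cold never yields
  # primers with Tm < 55
  set.seed(121)
  contig <- tibble::tibble(contig_id = "c1", seq = rand_dna(600))
  pr <- design_primers(contig, contig, n_pairs = 3)
  if (nrow(pr) > 0) {
    expect_true(all(pr$tm_fwd >= 55 & pr$tm_fwd <= 65))
    expect_true(all(pr$tm_rev >= 55 & pr$tm_rev <= 65))
  }
})

test_that("designed pairs satisfy every constraint field by field", {
  set.seed(122)
  contigs <- tibble::tibble(
    contig_id = sprintf("c%d", 1:4),
    seq = vapply(1:4, function(i) rand_dna(1200), ""))
  for (i in 1:4) {
    pr <- design_primers(contigs[i, ], contigs, n_pairs = 2)
    if (nrow(pr) == 0) next
    expect_true(all(nchar(pr$fwd) %in% 18:25))
    expect_true(all(nchar(pr$rev) %in% 18:25))
    gc <- function(s) vapply(strsplit(s, ""), function(b)
      mean(b %in% c("G", "C")), 0)
    expect_true(all(gc(pr$fwd) >= 0.40 & gc(pr$fwd) <= 0.60))
    expect_true(all(gc(pr$rev) >= 0.40 & gc(pr$rev) <= 0.60))
    expect_true(all(abs(pr$tm_fwd - pr$tm_rev) <= 5))
    expect_true(all(pr$product_len >= 100 & pr$product_len <= 1500))
    # primer sequences occur on the contig as designed
    expect_true(all(substring(contigs$seq[i], pr$fwd_pos + 1,
                              pr$fwd_pos + nchar(pr$fwd)) == pr$fwd))
    expect_true(all(revcomp(substring(contigs$seq[i], pr$rev_pos + 1,
                                      pr$rev_pos + nchar(pr$rev))) == pr$rev))
  }
})

test_that("primers whose 3' 15-mer recurs elsewhere are rejected as non-specific", {
  set.seed(123)
  base <- rand_dna(800)
  # duplicate a window of c1 inside c2: any primer ending there is non-specific
  dup <- substr(base, 101, 400)
  contigs <- tibble::tibble(
    contig_id = c("c1", "c2"),
    seq = c(base, paste0(rand_dna(300), dup, rand_dna(300))))
  pr <- design_primers(contigs[1, ], contigs, n_pairs = 5)
  if (nrow(pr) > 0) {
    # no accepted forward primer may end inside the duplicated window
    ends <- pr$fwd_pos + nchar(pr$fwd)
    expect_true(all(ends <= 115 | pr$fwd_pos >= 385))
  }
  k15 <- ghrecover:::.kmer15_table(contigs$seq)
  inside <- substr(base, 201, 215)
  expect_gte(as.integer(k15[inside]), 2L)
})

test_that("in-silico PCR amplifies the predicted product from a faithful template", {
  set.seed(124)
  contig <- tibble::tibble(contig_id = "c1", seq = rand_dna(1200))
  pr <- design_primers(contig, contig, n_pairs = 1)
  expect_equal(nrow(pr), 1)
  template <- paste0(rand_dna(500), contig$seq, rand_dna(500))
  res <- insilico_pcr(pr, template, contig)
  expect_equal(nrow(res$amplicons), 1)
  expect_equal(res$amplicons$product_len, pr$product_len)
  expect_equal(res$identity, 1)
  expect_equal(res$verdict, "validated")

  # a template lacking the primer sites yields nothing
  res2 <- insilico_pcr(pr, rand_dna(2000), contig)
  expect_equal(nrow(res2$amplicons), 0)
  expect_equal(res2$verdict, "not_validated")

  # the reverse-complemented template amplifies identically
  res3 <- insilico_pcr(pr, revcomp(template), contig)
  expect_equal(nrow(res3$amplicons), 1)
  expect_equal(res3$verdict, "validated")
})

test_that("amplicon identity is checked inclusively at the 95% cutoff", {
  set.seed(125)
  contig <- tibble::tibble(contig_id = "c1", seq = rand_dna(1200))
  pr <- design_primers(contig, contig, n_pairs = 1)
  expect_equal(nrow(pr), 1)
  inner_lo <- pr$fwd_pos + nchar(pr$fwd) + 5L
  inner_hi <- pr$rev_pos - 5L
  n_inner <- inner_hi - inner_lo
  mutate_template <- function(n_mm) {
    v <- strsplit(contig$seq, "")[[1]]
    rot <- c(A = "C", C = "G", G = "T", T = "A")
    pos <- inner_lo + round(seq(1, n_inner, length.out = n_mm))
    v[pos] <- rot[v[pos]]
    paste(v, collapse = "")
  }
  n95 <- floor(pr$product_len * 0.05)        # identity exactly >= 0.95
  res95 <- insilico_pcr(pr, mutate_template(n95), contig)
  expect_equal(res95$verdict, "validated")
  expect_gte(res95$identity, 0.95)
  n94 <- ceiling(pr$product_len * 0.06)
  res94 <- insilico_pcr(pr, mutate_template(n94), contig)
  expect_equal(res94$verdict, "not_validated")
  expect_lt(res94$identity, 0.95)
})

test_that("contig validation reports one verdict per sampled contig", {
  set.seed(126)
  genomes <- vapply(1:3, function(i) rand_dna(4000), "")
  contigs <- tibble::tibble(
    contig_id = sprintf("c%d", 1:3),
    seq = substring(genomes, 1001, 2500))
  val <- validate_contigs(contigs, genomes, n = 3,
                          cfg = pipeline_config(rng_seed = 3))
  expect_equal(sort(val$report$contig_id), sort(contigs$contig_id))
  ok <- val$report[val$report$verdict != "no_primers", ]
  expect_true(all(ok$verdict == "validated"))
})
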