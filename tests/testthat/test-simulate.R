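test_that("the truth ledger records every gene placement and translates back", {
  sc <- sim_config(n_genomes = 2L, genome_len = 6000L, genes_per_genome = 3L,
                   samples = list(Z7 = 10L), gene_divergence = 0,
                   rng_seed = 17)
  panel <- synthetic_panel(aa_len = 120, rng_seed = 17)
  comm <- simulate_community(sc, panel)
  expect_equal(nrow(comm$genes), 6L)
  expect_true(all(comm$genes$hi <= 6000L & comm$genes$lo >= 0L))
  for (i in seq_len(nrow(comm$genes))) {
    g <- comm$genes[i, ]
    gseq <- substr(comm$genomes$seq[comm$genomes$genome_id == g$genome_id],
                   g$lo + 1, g$hi)
    if (g$strand == "-") gseq <- revcomp(gseq)
    prot <- sub("\\*$", "", translate_six_frames(gseq)[["+1"]])
    # zero divergence: the embedded gene is an exact panel copy
    expect_equal(prot, panel$seq[panel$id == g$protein_id])
    expect_equal(prot, g$protein)
  }
})

test_that("diverged genes still translate to the recorded realized protein", {
  sc <- sim_config(n_genomes = 2L, genome_len = 6000L, genes_per_genome = 2L,
                   samples = list(Z7 = 10L), gene_divergence = 0.25,
                   rng_seed = 19)
  panel <- synthetic_panel(aa_len = 120, rng_seed = 19)
  comm <- simulate_community(sc, panel)
  for (i in seq_len(nrow(comm$genes))) {
    g <- comm$genes[i, ]
    gseq <- substr(comm$genomes$seq[comm$genomes$genome_id == g$genome_id],
                   g$lo + 1, g$hi)
    if (g$strand == "-") gseq <- revcomp(gseq)
    prot <- sub("\\*$", "", translate_six_frames(gseq)[["+1"]])
    expect_equal(prot, g$protein)
    ref <- panel$seq[panel$id == g$protein_id]
    idn <- mean(strsplit(prot, "")[[1]] == strsplit(ref, "")[[1]])
    expect_gt(idn, 0.55)
    expect_lt(idn, 0.95)
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  sc <- sim_config(n_genomes = 2L, genome_len = 5000L,
                   samples = list(Z7 = 50L, Z8 = 50L), rng_seed = 23)
  a <- simulate_metagenome(sc)
  b <- simulate_metagenome(sc)
  expect_identical(a$genomes$seq, b$genomes$seq)
  expect_identical(a$reads$seq, b$reads$seq)
  expect_identical(a$truth, b$truth)
  c <- simulate_metagenome(sim_config(n_genomes = 2L, genome_len = 5000L,
                                      samples = list(Z7 = 50L, Z8 = 50L),
                                      rng_seed = 24))
  expect_false(identical(a$reads$seq, c$reads$seq))
})

test_that("zero-error reads are exact genome substrings with matching truth", {
  sc <- sim_config(n_genomes = 2L, genome_len = 5000L, genes_per_genome = 1L,
                   samples = list(Z7 = 80L), subst_rate = 0,
                   homopolymer_indel_rate = 0, rng_seed = 29)
  sim <- simulate_metagenome(sc)
  for (i in seq_len(nrow(sim$reads))) {
    tr <- sim$truth[i, ]
    g <- sim$genomes$seq[sim$genomes$genome_id == tr$genome_id]
    frag <- substr(g, tr$lo + 1, tr$hi)
    if (tr$strand == "-") frag <- revcomp(frag)
    expect_identical(sim$reads$seq[i], frag)
  }
  expect_true(all(sim$truth$n_subst == 0 & sim$truth$n_ins == 0 &
                    sim$truth$n_del == 0))
})

test_that("per-genome read counts follow the abundance vector", {
  sc <- sim_config(n_genomes = 4L, genome_len = 8000L, genes_per_genome = 1L,
                   samples = list(Z7 = 10000L),
                   abundance = list(c(0.1, 0.2, 0.3, 0.4)),
                   subst_rate = 0, homopolymer_indel_rate = 0,
                   rng_seed = 31)
  sim <- simulate_metagenome(sc)
  counts <- table(factor(sim$truth$genome_id,
                         levels = sim$genomes$genome_id))
  for (k in 1:4) {
    p <- c(0.1, 0.2, 0.3, 0.4)[k]
    expect_lt(abs(counts[[k]] - 10000 * p), 3 * sqrt(10000 * p * (1 - p)))
  }
})

test_that("total emitted nucleotides match the truncated-normal expectation", {
  sc <- sim_config(n_genomes = 2L, genome_len = 20000L,
                   genes_per_genome = 1L,
                   samples = list(Z7 = 5000L), subst_rate = 0,
                   homopolymer_indel_rate = 0, rng_seed = 37)
  sim <- simulate_metagenome(sc)
  total <- sum(nchar(sim$reads$seq))
  expect_lt(abs(total - 5000 * 400) / (5000 * 400), 0.05)
})

test_that("error rates surface in the truth ledger at the configured scale", {
  sc <- sim_config(n_genomes = 1L, genome_len = 20000L,
                   genes_per_genome = 1L, samples = list(Z7 = 400L),
                   subst_rate = 0.01, homopolymer_indel_rate = 0.02,
                   rng_seed = 41)
  sim <- simulate_metagenome(sc)
  total_nt <- sum(nchar(sim$reads$seq))
  sub_rate <- sum(sim$truth$n_subst) / total_nt
  expect_gt(sub_rate, 0.005); expect_lt(sub_rate, 0.02)
  expect_gt(sum(sim$truth$n_ins + sim$truth$n_del), 0)
})

test_that("invalid simulator configurations fail fast", {
  expect_error(sim_config(subst_rate = 1.5), "rates")
  expect_error(sim_config(samples = list(Z7 = 0L)), "sample")
  expect_error(sim_config(n_genomes = 2, abundance = list(c(1))), "one vector")
  expect_error(
    simulate_community(
      sim_config(n_genomes = 1L, genome_len = 300L, genes_per_genome = 1L,
                 samples = list(Z7 = 5L)),
      synthetic_panel(families = "GH5", aa_len = 200)),
    "longer than genome")
})
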