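# ghrecover

Targeted recovery of glycoside hydrolase (GH) family genes from
metagenomic short reads.

## What it is for

Whole-metagenome assembly of complex communities (biogas digesters, rumen,
soil) usually fails at low coverage, but the lignocellulase genes of the
dominant degraders are individually well covered. `ghrecover` implements a
homology-guided, gene-centric assembly pipeline for single-end 454-style
reads (50–800 nt):

1. **Recruit** reads homologous to a reference GH protein panel by
   six-frame translated Smith–Waterman (BLOSUM62, gap 11/1) with
   Karlin–Altschul e-values, bit score
   `S' = (λS − ln K)/ln 2`, `E = m·n·2^(−S')` (λ = 0.267, K = 0.041),
   inclusive cutoff `E ≤ 1e-2`, bacterial genetic code (table 11).
2. **Assemble** recruited reads with a greedy overlap–layout–consensus
   assembler: overlaps of ≥ 40 nt at ≥ 90 % identity (indel columns count
   as mismatches), deterministic greedy priority, majority-vote consensus,
   then gapped consensus polishing.
3. **Extend** contig ends iteratively against the full read pool (and,
   optionally, whole-metagenome contigs), growing each end by the
   consensus of agreeing candidates and flagging conflicting ends
   `ambiguous` (fail-safe fork rule).
4. **Filter** to contigs ≥ 1 kb, **annotate** ORFs (longest frame per
   stop-to-stop segment, starts ATG/GTG/TTG, ≥ 300 nt, partials flagged)
   and assign GH families by translated best hit; optionally **screen**
   reads against a 16S reference set (`E ≤ 1e-5`, length ≥ 65 nt,
   identity ≥ 80 %).
5. **Weight** contigs by per-sample read depth (best-hit mapping; depth =
   aligned bases / contig length).
6. **Validate** contigs by contig-specific primer design (18–25 nt,
   GC 40–60 %, Wallace-rule Tm 55–65 °C, unique 3' 15-mer, product
   100–1500 nt) with in-silico PCR; a contig validates when its single
   amplicon matches the prediction at ≥ 95 % identity.

A ground-truthed two-sample 454-style community simulator (lognormal
abundances, truncated-normal read lengths, substitution errors and
homopolymer-biased indels) makes the whole pipeline testable offline.

All user-facing functions take a tibble first and return tibbles, so
stages chain with the pipe; `run_pipeline()` orchestrates everything with
per-stage artifacts and a checksummed manifest, and the result supports
`tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(ghrecover)

res <- run_pipeline(outdir = "demo",
                    cfg = pipeline_config(rng_seed = 47),
                    sim = sim_config(n_genomes = 2, genome_len = 6000,
                                     genes_per_genome = 1,
                                     samples = list(Z7 = 700, Z8 = 700),
                                     read_len_mean = 300, read_len_sd = 50,
                                     subst_rate = 0.002,
                                     homopolymer_indel_rate = 0.005,
                                     rng_seed = 47),
                    panel = synthetic_panel(families = c("GH5", "GH9"),
                                            aa_len = 350, rng_seed = 47),
                    validate_n = 5)
glance(res)
#> # A tibble: 1 × 6
#>   n_recruited n_contigs n_gh_contigs n_orfs n_assigned_orfs n_validated
#>         <int>     <int>        <int>  <int>           <int>       <int>
#> 1         293         2            2      8               2           2
```

Two simulated genomes each carry one GH gene; 293 of 1,400 reads are
recruited, they assemble into 2 contigs ≥ 1 kb, each receives a
family-correct catalytic-module annotation, and both contigs are confirmed
by in-silico PCR against the source genomes (`n_validated = 2`).
`tidy(res)` lists the per-ORF annotations; `demo/` holds the FASTA / GFF3
/ TSV artifacts and `manifest.json` with the exact thresholds and seed
used.

The methods vignette (`vignettes/targeted-gh-recovery.Rmd`) describes the
models, parameter defaults, numerical choices and limitations.

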