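---
title: "Targeted recovery of glycoside hydrolase genes from metagenomic short reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted recovery of glycoside hydrolase genes from metagenomic short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghrecover)
```

## The problem

Low-coverage metagenomes of complex communities -- anaerobic digesters,
rumen, soil -- rarely assemble the genomes of individual members, yet the
genes of interest (here, glycoside hydrolase (GH) catalytic modules driving
lignocellulose degradation) are often well covered because they come from
the dominant degraders. A *targeted*, gene-centric strategy therefore works
where whole-metagenome assembly fails: recruit exactly the reads that look
like known GH proteins, assemble only those, then grow the resulting
contigs outwards to capture neighbouring sequence. ghrecover implements
that strategy end-to-end for single-end short reads with 454-like length
and error characteristics, together with a ground-truthed community
simulator so that every stage can be validated without any external data.

## Pipeline and models

### Read recruitment

Every read is translated in all six reading frames under the bacterial
genetic code (NCBI table 11) and aligned against each panel protein by
exhaustive local dynamic programming (Smith-Waterman) with BLOSUM62 and
affine gap costs 11 (existence) + 1 per residue -- the classical
translated-search operating point. Alignments never cross a stop codon:
the scoring matrix assigns stops a prohibitive penalty, which for
read-scale sequences is exactly equivalent to taking the maximum over
stop-free translated segments.

Significance uses Karlin-Altschul statistics,

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad
  E = m\,n\,2^{-S'},$$

with the published gapped-BLOSUM62 parameters $\lambda = 0.267$,
$K = 0.041$, and search space $m n$ = (total panel residues) x (total
translated residues of the read set), without edge-length correction. A
read is recruited iff any alignment reaches $E \le 10^{-2}$; the cutoff is
inclusive, and is applied per alignment (any passing HSP recruits the
read). The same scoring backs ORF family assignment; the nucleotide 16S
screen uses match +1 / mismatch -2 with gap costs 5 + 2g and the
corresponding $\lambda = 1.28$, $K = 0.46$. Because the e-value is
calibrated against the whole dataset, recruiting a given read depends
(weakly, through $n$) on the size of the read set it is searched with --
the same property a database search has.

### Overlap assembly

Recruited reads are assembled by a greedy overlap-layout-consensus (OLC)
assembler. Overlap candidates come from shared 16-mers (the modal diagonal
per read pair and orientation); each candidate is verified by a banded
end-to-end alignment of the implied overlap region with unit
mismatch/indel costs and band $\max(10, 0.1\,\ell)$ for overlap length
$\ell$, so that the occasional pyrosequencing homopolymer indel is
absorbable within the 90% identity allowance. An overlap is admissible
when it spans at least 40 alignment columns at >= 90% identity (matches
over columns; indel columns count as mismatches) -- both cutoffs
inclusive. Merging is greedy in a deterministic priority order (longest
overlap, then highest identity, then lexicographically smallest read-id
pair); overlaps that would place a read in two contigs are skipped. The
consensus is a per-column majority vote, ties broken by summed base
quality and then the fixed order A < C < G < T; `N` never wins unless it
is the only vote.

### Consensus polishing

Ungapped column voting cannot absorb coordinate drift: a read carrying a
homopolymer indel shifts all its downstream votes by one. After assembly
(and again after extension) each contig is therefore polished: reads are
realigned to the contig with the banded aligner, and the consensus is
rebuilt by majority over aligned bases, deletions and single-base
insertions, exactly as short-read consensus polishers do. On error-free
input the votes are unanimous and polishing is the identity, which the
test suite asserts.

### Iterative end extension

The "refined" part of the approach: each contig end is compared against
the *full* read pool (and, optionally, whole-metagenome contigs) using the
same seeded, banded overlap alignment and the same 40 nt / 90% cutoffs --
the extension thresholds are deliberately reused from assembly and the
report header says so. If every candidate protrusion agrees pairwise
(aligned identity >= 90% over the shared region) the end grows by their
consensus; if candidates conflict, the end is flagged `ambiguous` and
never extended -- the tool fails safe and surfaces the fork rather than
guessing. Pairs whose shared protrusion is shorter than the minimum
overlap length are not counted as fork evidence: one sequencing error in a
15 nt tail would otherwise fake a conflict. Iteration stops at a fixpoint
or after `max_extension_iters` (default 20) rounds; contig length never
decreases. Reads may extend more than one contig and are flagged when they
do.

### Annotation, depth, validation

Only contigs >= 1 kb (inclusive) are retained. ORFs are called per
stop-to-stop frame segment on both strands -- the longest frame starting
at ATG/GTG/TTG and ending at a stop (included in the span), minimum 300 nt
(100 codons; GH catalytic modules exceed this), with contig-edge-truncated
ORFs reported as partial and still eligible for family assignment, since
recovered genes are frequently partial. A deliberately simple longest-ORF
caller replaces a trained gene finder: downstream logic only needs GH
catalytic-module detection, and family assignment is homology-based
anyway. The best panel hit by bit score with $E \le 10^{-2}$ sets the
family (ties: lower e-value, higher identity, lexicographic protein id),
making the assignment invariant to panel order.

Contig depth is defined as summed aligned bases of best-hit-assigned reads
divided by contig length -- mean per-base coverage. Each read maps to at
most one contig (best alignment with identity >= 0.90 covering >= 90% of
the read; ties to the lexicographically smallest contig id), which keeps
per-sample counts additive. Whether such depth should be pooled or
per-sample is genuinely ambiguous, so both are emitted, and the output
header states the definition since depth values are comparable only
within this tool.

Assembly accuracy is checked the way a wet lab would: contig-specific
primer pairs (length 18-25 nt, GC 40-60%, Wallace-rule
$T_m = 2(A{+}T) + 4(G{+}C)$ between 55 and 65 degrees C, pair difference <= 5,
product 100-1500 nt) whose 3' 15-mer occurs nowhere else in the contig set
on either strand, followed by in-silico PCR against the source templates.
A pair validates its contig iff exactly one amplicon arises and it matches
the predicted interval at >= 95% identity (inclusive). The Wallace rule is
used instead of nearest-neighbour thermodynamics deliberately: it is
closed-form, deterministic and entirely adequate for a specificity-driven
accuracy check.

## The simulator and what it does (not) show

`simulate_metagenome()` builds a two-sample community the pipeline can be
scored against: `n_genomes` uniform-random genomes (GC 50%) each carrying
`genes_per_genome` genes at recorded coordinates on either strand; reads
with truncated-normal lengths (default mean 400 nt, sd 100 nt, minimum
50 nt), uniform start positions within genomes drawn proportionally to
per-sample abundance (default: independent lognormal profiles per sample,
echoing a two-digester design with samples named Z7 and Z8); iid
substitution errors (default 0.3%) and, as the dominant 454 error mode,
single-base indels in homopolymer runs >= 3 at 1% per run. Every read's
origin, strand and error counts go into a truth ledger sufficient to score
recruitment, assembly, annotation and depth without re-deriving anything.

Embedded genes are *diverged homologs* of the reference panel: each gene's
protein is mutated at `gene_divergence` (default 0.25) per residue before
codon-randomized reverse translation (uniform synonymous choice, code 11),
and the realized protein is recorded. Two reasons. Scientifically,
metagenomic GH genes are never amino-acid-identical to database
references; recruitment must work across family-level divergence.
Technically, embedding aa-identical copies of the same reference in
several genomes creates pairs of genes whose independent recodings still
share occasional >= 90%/40 nt nucleotide windows (runs of low-degeneracy
codons), which a greedy OLC assembler -- any greedy OLC assembler --
merges into cross-genome chimeras. That failure mode is an artifact of
synthetic aa-identical duplicates rather than a property of real
communities, where paralog/strain ambiguity is resolved by manual
inspection and is out of scope here. Setting `gene_divergence = 0`
restores exact panel copies, and the reverse-translation inverse property
is tested in that regime.

What passing tests on this simulator do **not** show: performance on real
454 data with quality-dependent error rates, chimeric reads, strain
mixtures, conserved multi-domain architectures shared between unrelated
contigs, or rRNA-like repeats. The simulator's genomes are random
background, so off-target recruitment and primer non-specificity are both
easier than in real genomes.

## Numerical choices and degenerate inputs

* All cutoffs stated anywhere in the configuration are applied
  **inclusively** (e-values, overlap length/identity, contig length, 16S
  thresholds, amplicon identity), and the boundary behaviour is pinned by
  tests on constructed fixtures.
* All internal coordinates are 0-based half-open; GFF3 output is 1-based
  inclusive; converting back and forth is the identity.
* Ties anywhere resolve deterministically (frame order, base order
  A < C < G < T, lexicographic ids), so byte-identical reruns are a tested
  property.
* Banded alignments use band $\max(10, 0.1\,\ell)$ capped at 2000 columns;
  at the simulator's error rates the accumulated indel drift over even a
  20 kb contig stays far inside the cap.
* Empty inputs (no reads, no overlaps, no admissible primer pair, empty
  annotation set) return empty-but-well-formed results, never errors;
  violated preconditions (duplicate ids, non-IUPAC characters,
  out-of-range coordinates, genes longer than genomes) are hard errors
  raised before any work.
* Reads shorter than 3 nt in a frame translate to an empty string for that
  frame; a read all of whose frames are empty can never be recruited.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script simulations use the study conditions
the pipeline is specified against: an end-to-end community of 10 genomes
(40 kb each) x 2 genes (~1.5 kb), two samples of 20,000 reads; a depth
panel of 20 genomes spanning a 10-fold abundance range with 50,000 reads;
and an error-free 4-genome community for primer validation. Oracle
comparisons (exhaustive Smith-Waterman via an independent implementation,
all-offset overlap scans, brute-force ORF enumeration) run at small n
where exhaustive computation is exact.

## Known limitations

* Greedy OLC cannot separate haplotypes or near-identical paralogs; the
  fork rule stops extension rather than branching, mirroring how
  ambiguous joins must be resolved by inspection.
* The e-value calibration uses fixed published Karlin-Altschul constants
  without composition-based or edge-length corrections; e-values are
  therefore comparable within a run, not to BLAST output digit-for-digit.
* Frameshift-aware (protein-vs-DNA) alignment is not implemented; 454
  homopolymer frameshifts are handled downstream by the consensus and
  polishing, not during the search.
* The depth model counts each read once; contigs sharing long identical
  regions would split reads by the lexicographic tie rule rather than
  fractionally.

## A worked run

```{r, eval = FALSE}
library(ghrecover)

sim <- simulate_metagenome(sim_config(rng_seed = 1))
cfg <- pipeline_config(rng_seed = 1)

res <- run_pipeline(outdir = "run1", cfg = cfg,
                    sim = sim_config(rng_seed = 1))
glance(res)
tidy(res) |> dplyr::filter(family != "unassigned")
autoplot(res, type = "families")
```
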