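---
title: "Models and methods behind the ervpop pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the ervpop pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervpop)
```

# Scope

`ervpop` reconstructs the computational path from short-read cohort data to
a population-level account of a recently active endogenous retrovirus (ERV)
lineage: where its insertions sit, who carries them, when they formed, and
what their proviral sequences say about how the lineage spread. The package
is organized as seven cooperating modules — file formats, synthetic data,
insertion discovery, in-silico genotyping, LTR molecular-clock dating,
genic-depletion testing, and provirus annotation — each usable on its own.

This vignette explains the models, the parameters that matter, and the
design choices made where reasonable alternatives existed.

# The biological model

A retroviral integration leaves a provirus — `5'LTR-gag-pol-env-3'LTR` —
flanked by a short target site duplication (TSD) of host sequence, here
fixed at 5 bp, the value typical of this lineage. Two post-insertion fates
matter for the pipeline:

* **Allele forms.** Recombination between a provirus's two LTRs excises the
  internal genes and leaves a **solo LTR** (canonically 457 bp). A locus
  can therefore segregate three ways: unoccupied, solo LTR, or full
  provirus, always with the same TSD footprint.
* **The LTR clock.** The two LTRs are identical at integration and then
  drift apart neutrally, so their divergence dates the insertion.

# Module-by-module notes

## Synthetic data (`make_reference`, `make_truth_insertions`, `implant_insertions`, `simulate_cohort`, `simulate_reads`)

The generator's defaults encode the study conditions the pipeline is
designed for: 5-bp TSDs duplicated around every element, solo-LTR and
provirus allele forms, per-population insertion frequencies sampled under
Hardy-Weinberg into diploid genotypes, paired-end reads with Normal
fragment lengths (mean 400, sd 50), 100-bp reads, and a per-base
substitution error rate of 0.1% — ordinary short-insert Illumina-like
values. `coverage` is per-haplotype depth: each haplotype of a pair
receives `coverage * length / (2 * read_len)` pairs.

LTR divergence is simulated substitution-only: the change count over a pair
of age `a` is drawn `D ~ Poisson(a * rate * L)` and scattered uniformly
over the two copies. This is deliberately the exact inverse of the dating
formula (below); an indel process is not simulated, because the clock
counts changes rather than modelling indel evolution — the gap rule is
exercised with hand-built alignments instead.

What the generator does **not** emulate: repetitive host genomes (the
background is i.i.d. sequence at GC 0.41, so mapping ambiguity is limited
to the implanted elements themselves), CpG hypermutability, quality-score
structure beyond a flat proxy, PCR duplicates, and structural variation
other than the ERV alleles. Passing tests on this background therefore
demonstrate the machinery's correctness, not its performance on a real,
repeat-rich genome.

## Discovery

Non-reference insertions are found in three stages, mirroring standard
mobile-element-insertion callers:

1. **Anchored pairs.** Read pairs with exactly one mate mapped to the
   reference and the other matching the LTR or internal consensus (>= 90%
   identity over >= 30 bp; the matching thresholds are configuration
   values, not published constants) are collected and clustered by anchor
   position with single linkage at 200 bp. Clusters need >= 2 supporting
   pairs; clusters within +/- 500 bp of an annotated ERV are dropped as
   re-detections of known elements.
2. **Junction assembly.** Reads in the candidate window are assembled by a
   greedy overlap-layout-consensus assembler (minimum overlap 25 bp at 95%
   identity, reverse complements considered, per-column majority
   consensus). Junction-bearing reads are prioritized over plain genomic
   reads in the assembly budget. Contigs must carry >= 30 bp of LTR-derived
   *and* >= 30 bp of flanking sequence to count as junctions.
3. **Breakpoint + TSD.** Junction contigs are re-mapped to the reference.
   The breakpoint is reported as the leftmost TSD start on the forward
   strand regardless of insertion orientation; when both junctions are
   present the 5-mer duplicated between the two genomic abutments is the
   TSD, and an abutment mismatch is flagged rather than silently accepted.

Two behaviors deserve comment. First, because the two LTRs of a provirus
are nearly identical, assembly at a provirus locus collapses the 5' and 3'
junctions through the shared LTR into a single solo-LTR-like contig. This
is expected — short reads genuinely cannot distinguish a solo LTR from a
provirus at a given locus — so the discovery output calls `form =
"provirus"` only when junction flanks or anchor mates match internal
proviral sequence, and otherwise reports the (always-defensible) solo-LTR
interpretation. Second, the bundled seed-and-extend mapper (exact 20-mer
seeds, ungapped extension, a map-quality proxy from the best/second-best
score ratio) exists to make the pipeline self-contained and deterministic;
alignments from any external mapper can be substituted as a SAM subset.

Unfixed **reference** insertions are detected the opposite way: pairs with
both mates at mapping quality >= 20 whose span exceeds
`median + 7 * MAD` of the proper-pair insert distribution support a
deletion; merged supports are kept only where they intersect an annotated
ERV and imply a size in the solo-LTR (400-500 bp) or provirus (7-9 kb)
range. `MAD` is the normal-consistent median absolute deviation
(`stats::mad`), the standard MAD-score convention.

## Genotyping

For each locus both alleles are rebuilt from +/- 600 bp of reference flank
with the TSD handled explicitly (one copy on the unoccupied allele, two on
the occupied one); unresolved element interiors are filled from the
consensus and flagged. Candidate pairs are remapped to both alleles and a
pair supports the allele with the higher summed alignment score, subject to
two guards: a supporting pair must overlap a discriminating junction by at
least one base (reads equidistant from the breakpoint carry no
information), and pairs wholly inside the element's internal region are
discarded because reads from other element copies elsewhere in the genome
would mimic them.

The genotype likelihood treats each supporting pair as one observation with
error probability `e = 10^(-mapq/10)`:
`P(obs | hom matching) = 1 - e`, `P(obs | other hom) = e`,
`P(obs | het) = 1/2` (the equal-weight mixture of the two homozygote terms
collapses to 1/2). Log10 likelihoods are summed and the call is the
maximum-likelihood genotype with no prior — the pipeline reports genotypes,
not posteriors. No informative pairs at all gives a missing call (`./.`),
and missing calls are excluded from the allele-frequency denominators.

## Dating

Two estimators share one clock (default rate `1.33e-9` substitutions per
site per year; `1.3e-9`, the `2.2e-9` mammalian average, and the `4.5e-9`
mouse rate are available as presets — only the default reproduces the
package's reference cluster dates, which is why it is the default):

* **LTR-pair divergence**: `age = D / (L * rate)` with `L` the ungapped 5'
  LTR length and `D` the change count from a global alignment. Gap runs of
  1-2 bp count one change per column; runs longer than 2 bp count once —
  the reading under which the "longer than 2 bp" qualifier does real work,
  and the treatment that keeps a single long duplication (e.g. 43 bp in
  one LTR) from inflating the age 43-fold. There is no factor of two: `D`
  is the total change count over the pair, and the simulator draws `D`
  with exactly that convention.
* **Identical-haplotype clusters**: loci whose LTR sequences are exactly
  identical are grouped, and the cluster is dated as the waiting time for
  one substitution over the concatenated length, `1 / (total_length *
  rate)`. For a single 457-bp LTR this degenerates to the pair formula
  with `D = 1`, a consistency the tests assert.

## Genic depletion

Insertions are intersected with gene models at windows of 0, 5, 10, 25,
50, and 100 kb (an insertion counts if any gene expanded by the window
contains its breakpoint). The null is 1000 uniform genome-wide shuffles of
the insertion positions, chromosome chosen proportional to length — the
simplest null consistent with an unconstrained shuffle; a per-chromosome
option exists. The one-sided depletion p-value is the fraction of permuted
sets with a count at or below the observed one, reported as `< 1/n_perm`
when no permutation is as small. The observed counts use interval overlap
via `GenomicRanges`; the permuted counts use a precomputed merged-interval
membership test, and the agreement of the two routes is itself tested.

## Provirus annotation

The proviral consensus is per-column majority over an input alignment
(gap-majority columns dropped; residue ties broken alphabetically and
logged). Defect positions are reported 1-based from the consensus start —
the convention in which shared defects are quoted — while everything else
in the package stays 0-based; the boundary is explicit in the return
values. Premature stops are called in the consensus reading frame of each
gene, so a frameshift indel is reported together with the downstream stops
it creates. Shared defects group records identical in kind, gene, and
indel length within +/- 3 bp of consensus position — the tolerance absorbs
alignment jitter around homopolymers. The recurrent env deletion is
detected by length (1073 +/- 10 bp) within env.

dN/dS uses Nei-Gojobori pathway counting: per-codon synonymous site
fractions from the nine single-base neighbors, with neighbors that create
stop codons excluded and the fraction renormalized (so S + N = 3 per codon
and the site counts average over the two sequences); differences averaged
over all minimal mutational pathways that avoid stop codons; Jukes-Cantor
correction `d = -(3/4) ln(1 - 4p/3)`, undefined at `p >= 3/4` and flagged
rather than clamped. Significance of `dN != dS` uses a seedable codon
bootstrap Z rather than an analytic codon-variance estimator — fewer
assumptions, same test statistic. A cohort average is the mean of pairwise
ratios over pairs where both distances are defined and `dS > 0`; excluded
pairs are listed, not silently dropped.

# Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; conversions happen only
  in the format readers/writers (BED stays 0-based; RepeatMasker `.out`,
  SAM, VCF, and consensus defect positions are 1-based).
* Alignment scoring is match +1, mismatch -1, gap open -4, gap extend
  -0.5 for LTR pairs and junction classification; the provirus-to-consensus
  alignment uses a higher open penalty (6) and lower extension (0.2) so
  long real deletions stay as single gap runs.
* The mapper's quality proxy is
  `min(60, round(-10 log10(second_best / best)))`, with unique hits capped
  at 60 and exact ties at 0; genotype error probabilities are floored at
  `1e-6` so a mapq-60 observation cannot claim infinite weight.
* The assembler breaks score ties by first-seen candidate; its consensus
  resolves 2-vs-2 column ties toward the earlier-merged contig. Order
  invariance on unique-overlap inputs is tested.
* Empty inputs return empty, typed results (not errors) wherever the
  quantity is a count or a table; malformed files and impossible requests
  (breakpoints inside a flank, mapq lists of the wrong length, gap-on-gap
  alignment columns) are errors with the offending item named.

# Problem sizes in the test suite

The shipped tests exercise the full pipeline at desk scale, chosen so the
suite states something statistically meaningful while staying quick: a
two-chromosome 100-kb reference with six implanted solo-LTR loci, twelve
diploid samples in two populations at 20x per-haplotype coverage and 0.1%
base error for the end-to-end run; 500 replicates per age for clock
recovery at 5, 10, and 20 My (where the Monte Carlo standard error of the
mean is comfortably inside the 5% bias band); 200 replicate datasets of
120 null insertions against 25 genes for permutation calibration (the
granularity keeps the discrete p-value distribution close enough to
uniform for a Kolmogorov-Smirnov check); and the complete 61 x 61
sense-codon table against an independent enumeration oracle for the
dN/dS counting.

# Known limitations

* The i.i.d. background genome understates mapping ambiguity; on real
  genomes the known-ERV exclusion list and the mapper's quality proxy do
  more work, and an external aligner is advisable.
* Solo-LTR vs provirus cannot be resolved from short reads at a single
  locus; `form` is evidence-based but defaults to the solo interpretation.
* The clock assumes neutrality and a uniform rate; CpG effects and
  post-insertion gene conversion between LTRs bias individual ages upward,
  which is why cluster dating over identical haplotypes is offered for the
  youngest loci.
* The depletion test's uniform shuffle ignores assembly gaps unless a gap
  file is supplied via the per-chromosome/controlled options.
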