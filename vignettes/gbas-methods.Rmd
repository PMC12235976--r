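---
title: "Methods: marker discovery, allele calling and population-genetic inference in gbastk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker discovery, allele calling and population-genetic inference in gbastk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbastk)
```

`gbastk` implements a genotyping-by-amplicon-sequencing (GBAS) workflow
for diploid, non-model organisms. This vignette explains the models and
procedures behind each stage, the parameters that matter, the numerical
conventions, and what the simulation-based tests do and do not establish
about real data.

## Coordinate and data conventions

All internal coordinates are 0-based half-open; conversion to and from
1-based inclusive conventions (GFF3) happens only inside the readers and
writers. Genotypes live in a `genotype_matrix`: two allele labels per
individual and locus, homozygotes repeating the label, missing calls `NA`.
Allele labels follow a length-first dialect: `"451"` where one sequence
variant exists at that amplicon length, `"451.2"` where several
equal-length variants segregate. Variant ranks are assigned by descending
global read support, which makes them stable across reruns of one dataset
but *not* comparable across datasets; `canonicalize_labels()` re-ranks
variants lexicographically by sequence for such comparisons. Minus-strand
gene models are reverse-complemented into transcript orientation at load,
because primer design reasons in mRNA orientation.

## Microsatellite mining

`scan_read()` reports every maximal perfect tandem run of a 2–5 bp unit
that (i) meets its unit-length repeat threshold — defaults 10 repeats for
2mers, 8 for 3mers, 4 for 4mers and 5mers — and (ii) has strictly more
than 20 bp of flank on both sides, so primers have somewhere to sit. Only
perfect repeats count: the thresholds are pure repeat counts, and a
perfect-repeat definition keeps the scanner equivalent to an exact
enumeration oracle, which the test suite exploits. Runs whose unit is
itself periodic (ATAT as a 4mer) are reported at the smallest period only;
homopolymers are ignored; `N` bases terminate a run. Motifs are
canonicalized to the lexicographically minimal rotation on the read strand
only — reverse-complement merging is deliberately avoided because
downstream primer design operates on the read as sequenced. Where several
phase-shifted starts describe the same run, the leftmost is reported once.
Although all unit-length classes are counted for summaries, the intended
design inputs are 4mer/5mer loci: shorter units slip more during PCR,
which is also why the stutter model below only ever shortens by one unit.

## EPIC marker mining

`select_exon_pairs()` emits every consecutive exon pair with both exons
strictly longer than 20 bp (room for a primer) and an intervening intron
strictly shorter than 400 bp (so exon–intron–exon amplicons land near 450
bp, compatible with 2 × 300 bp sequencing). Both bounds are strict as a
deliberate reading of "more than" / "shorter than"; the boundary cases are
pinned by tests. All qualifying pairs of a gene are emitted — ranking
among overlapping pairs is left to the caller, since no principled
prioritization exists without knowing the target intron length.

`map_to_target()` replaces an interactive BLAST step with a deterministic
seeded aligner: exact 15-mer seeds of the 5′ exon are looked up on both
target strands, seed diagonals within 30 bp are clustered into candidate
placements, and each candidate is verified by affine-gap local alignment
(match +1, mismatch −2, gap open −5, extend −2) in a ±50 bp window. A
placement must reach ≥70% identity over ≥80% of the exon; two placements
tying at the best score mean a suspected duplication and the pair is
dropped with an "ambiguous placement" message. The 3′ exon is then sought
downstream within the intron radius, the spanned region extracted, and
both exons re-aligned to it. The tests check this machinery against an
exhaustive Smith–Waterman oracle over whole (≤50 kb) targets.

Conserved windows — the only places primers may sit in EPIC mode — are
maximal runs of 100% donor/target identity of at least 18 bp (the minimum
primer length), inside exon footprints, with alignment gaps breaking a
run. Full identity is required because a single primer-site mismatch is
exactly the failure mode EPIC markers exist to avoid; a mismatch splits
the window and the primer must move.

## Primer design

Melting temperatures use unified nearest-neighbor thermodynamics with
terminal initiation corrections and the entropic salt adjustment
`0.368·(L−1)·ln[Na⁺]`, evaluated at 50 mM monovalent salt and 250 nM
total oligo with the CT/4 symmetry factor for non-self-complementary
duplexes. These fixed conditions stand in for an external design tool's
unstated internal calculator; the suite verifies the implementation
against an independent hand-summed ΔH/ΔS oracle.

`design_pairs()` enumerates every footprint of length 18–22 on both
strands and accepts a pair when: each primer's Tm lies in 55 ± 3 °C (an
explicit band; an "optimum" alone does not define acceptance) and the pair
differs by <5 °C; GC content is 40–60%; the two terminal bases at *each
end* of each primer contain one or two G/C ("GC clamp", read as the
common clamp setting); the product is 425–470 bp; for SSR templates the
complete motif lies inside the amplicon, within 250 bp of one end (so
overlapping read pairs merge across it), and under neither primer; for
EPIC templates both footprints fall inside conserved windows. Ranking is
by `|Tm−55|` sum, then `|product−450|`, then the 5′-most placement — an
arbitrary but deterministic tie-break, needed because the original
selection was interactive.

Two screens guard against repetitive or contaminant loci.
`duplication_screen_reads()` counts shotgun reads carrying a full-length
primer match (either strand, ≤1 substitution); more than one supporting
read suggests a multi-copy locus and flags the pair. As worded, a primer
with *zero* read support passes; a `min_support` option exists but
defaults off, since whether zero-support primers were separately removed
is unknown. `genome_screen()` requires each primer to hit a reference
genome exactly once, on opposite strands, facing inward at a
window-compatible distance; zero hits flag possible contamination,
multiple hits flag duplication. `attach_tails()` prepends the partial
Illumina adapters `TCTTTCCCTACACGACGCTCTTCCGATCT` (P5, forward) and
`CTGGAGTTCAGACGTGTGCTCTTCCGATCT` (P7, reverse) and refuses to tail twice.

## Allele calling

`merge_pairs()` merges a read pair at the ungapped overlap (≥20 bp,
mismatch fraction ≤0.1) with the fewest mismatches, ties to the longest
overlap; disagreements resolve to the higher-quality base, ties to read 1.
`demultiplex_by_primer()` assigns a merged read to the unique panel locus
whose forward and reverse primers both match within 2 substitutions;
conflicting or ambiguous reads land in an `undetermined` bin with a
reason, and a panel with a shared primer is rejected outright.

`call_genotype()` turns per-locus insert counts into at most two alleles:

1. *Error collapse* — a sequence within edit distance 1 of a ≥10× more
   abundant sequence is folded into it (a 0.1%-per-base error channel
   rarely produces the same error twice; a real allele at <10% of its
   partner is below the heterozygote ratio anyway).
2. *Stutter collapse* — with a known repeat unit, a sequence exactly one
   unit shorter than a more abundant one and below 50% of its count is
   folded in and flagged `STUTTER_COLLAPSED`.
3. Candidates need ≥10 reads; the runner-up becomes a second allele only
   at ≥25% of the top count, otherwise the call is homozygous.
4. No candidate → missing, flagged `LOW_DEPTH`.

All four thresholds are package-level stand-ins for an external
pipeline's unpublished internals; they are exposed as arguments and
conservative by construction. One consequence is worth knowing: a true
heterozygote whose alleles differ by exactly one repeat unit can be
mis-collapsed as stutter when the binomial read split is uneven (minor
allele below half the major: for a fair split of depth n this is
`2·P(Binomial(n, 1/2) < n/3)`, about 1.5% at n = 50 and under 0.5% at
n = 80). The accuracy tests therefore simulate at a mean depth of 80,
where essentially every cell meets the ≥50× premise.

`apply_study_filters()` applies, in order: samples with >30% missing
calls; then markers missing in >30% of the *remaining* samples; then
markers monomorphic across the dataset; then populations under five
individuals. Missing fractions are recomputed from the current matrix at
each stage, so the order is observable — a dedicated test constructs a
matrix where sample-first and marker-first orderings disagree. Because
later stages shrink the denominators of earlier ones, the sequence is not
mathematically idempotent for matrices sitting exactly on the 30%
boundary; on typical data a second pass changes nothing, and the
idempotence test uses simulated data away from the boundary.

## Population-genetic statistics

With allele frequencies `p` per population and locus: `Na` counts
observed alleles; `Ne = 1/Σpᵢ²`; `Ho` is the observed heterozygote
fraction; `He = 1 − Σpᵢ²` is plain gene diversity — no small-sample
correction, matching the convention of the spreadsheet tools these
summaries mirror; `FIS = (He − Ho)/He`, undefined at fixation. Population
means carry `sd/√L` standard errors over contributing loci.

The Hardy–Weinberg test is the χ² goodness-of-fit over all k(k+1)/2
genotype classes with df = k(k−1)/2, no pooling of rare classes, no
continuity correction, and no multiple-testing correction — deviation
counts are raw per-population counts at α = 0.05. At the simulated sizes
(n = 200) the type-I error stays within Monte-Carlo noise of the nominal
level, which the acceptance suite verifies over 10,000 replicates.

Pairwise FST ships in two flavors. The default Nei-style estimator
computes, per locus, `Hs` as the unweighted mean of the two populations'
gene diversities and `Ht` as the gene diversity of their unweighted mean
frequency vector, then takes the ratio of sums across loci and clamps at
zero; it is the natural companion of the `He` convention above but is
downward-bounded for two demes. Weir–Cockerham θ (variance components,
ratio of sums over loci and alleles) is unbiased for the drift parameter
itself and is the estimator the calibration tests compare against the
simulator's F. Both are exposed because reported FST tables in this field
do not always say which was used; results differ by roughly the
within-population sampling correction.

`null_allele_em()` fits the expectation–maximization estimator for a null
allele of frequency r: observed heterozygotes are what they seem; an
observed i-homozygote is split between true `pᵢ²` and null-carrying
`2pᵢr` in the E-step; blank individuals count as null homozygotes `r²`
when `include_blanks = TRUE` (the default; the toggle instead drops
blanks, the other established convention). The M-step re-estimates
frequencies from expected allele counts; iteration stops when successive
iterates move < 1e-8 (both r and every pᵢ) or at 1000 iterations. The
observed-data log-likelihood is non-decreasing by construction and is
asserted per step in tests; near r = 0 convergence is linear and slow, so
calibration runs raise `max_iter`. Markers are flagged per population at
r̂ > 0.2 (strict), and globally only when every population exceeds it.

## Clustering

DAPC proceeds exactly as its name says: one-hot allele counts (0/1/2 per
allele column), column-mean imputation of missing cells — the default of
the method's reference implementation — centering, PCA by singular value
decomposition retaining `n_pca` axes (default 4, reduced with a warning if
the design rank is lower), then linear discriminant analysis of the
retained scores on the group labels with at most `min(groups−1, n_pca)`
axes. Membership probabilities are the LDA Gaussian posteriors with
pooled covariance. Axis signs are fixed by forcing each axis's
largest-magnitude loading positive, so coordinates reproduce across runs.
The default of four retained axes reflects the K−1 rule for a five-group
analysis; it is a parameter, not a constant. `dapc_downsample()` draws
seeded samples of five per group — groups *at* the target size are kept
whole, matching the "more than five" wording — to check that unequal
sample sizes are not driving the picture.

`evanno_delta_k()` consumes any admixture program's log-likelihoods as a
K → values table and computes `ΔK = |L(K+1) − 2L(K) + L(K−1)| / sd(L(K))`,
defined only for interior K with positive run-to-run standard deviation;
the argmax is reported but no further decision is automated, because ΔK
is known to understate structure and the sensible workflow inspects
adjacent K values. A Bayesian clustering engine itself is out of scope.

## The simulators, and what the tests do not show

`simulate_genotypes()` draws ancestral allele frequencies from a
symmetric Dirichlet, population frequencies from the Balding–Nichols
distribution `Dirichlet(p·(1−F)/F)` — so E[FST] = F and F = 0 copies the
ancestral frequencies exactly — and genotypes under Hardy–Weinberg within
populations. Null alleles enter as a hidden allele of frequency
`null_rate`: null homozygotes become missing, null heterozygotes apparent
homozygotes, which is precisely the data-generating model the EM
estimator assumes. SSR allele sequences are flank + unit×k + flank with k
varying between alleles, and a `variant_rate` fraction of alleles
duplicate an existing length with a flank SNP instead, so length-only and
sequence-aware calling genuinely differ on simulated data.
`simulate_amplicons()` wraps alleles in their primers, splits
Poisson-distributed depth binomially between the two alleles, applies
uniform per-base substitution errors and one-unit stutter, and emits
overlapping read pairs at constant Q37. `simulate_genome_pair()` plants
gene models (including a non-coding decoy) and SSR motifs with
run-extension-proof flanks, then mutates exons, introns and intergenic
sequence at separate rates.

Default scale mirrors a small field study — five populations of 5–16
individuals and a few dozen loci — so fixture runs complete in seconds;
calibration tests use 2 × 100 individuals × 50 loci (FST), 500 diploids ×
100 replicates (EM), and 10,000 multinomial replicates (HWE), sizes at
which Monte-Carlo noise sits comfortably inside the asserted tolerances.

The simulators deliberately omit: indel sequencing errors, quality-score
gradients along reads, PCR chimeras, cross-sample contamination, allele
dropout correlated with length, linkage, and demographic history beyond
single-parameter drift (no bottlenecks, no admixture). Passing tests
therefore establish internal correctness — each algorithm does what this
document says on data matching its assumptions — not that the defaults
are optimal for any particular sequencing chemistry. On real data the
calling thresholds, in particular, should be revisited against known
control genotypes.

## Numerical conventions

Frequencies sum to 1 within 1e-9; EM convergence is 1e-8 on successive
iterates; DAPC rank detection uses the SVD tolerance
`max(dim)·eps·d₁`; FST estimates are clamped at 0; degenerate inputs
(monomorphic loci in the HWE test, He = 0 in FIS, zero-variance DAPC
designs, sd = 0 in ΔK) are reported as not-testable/undefined rather than
silently dropped or errored, except where nothing sensible remains (an
all-identical DAPC design is an error). Every stochastic routine takes an
explicit seed and is bit-reproducible under it.
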