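---
title: "Methods: satellite array annotation and chromatin profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite array annotation and chromatin profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices and numerical
decisions behind `centrosat`. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The problem

Mouse centromeric regions are tandem repeat landscapes: 120-bp minor
satellite (MiSat) arrays at centromeres (with 112-mer and 112–64-dimer
length variants), 234-bp major satellite (MaSat) arrays at pericentromeres,
telocentric TLC satellite and the telomeric `(TTAGGG)n` repeat at the
chromosome ends. Long reads span whole arrays, so a per-read analysis can
recover array organization (continuous "Type 1" vs TE-interrupted
"Type 2", strand direction switches, junctions between satellite
families), per-monomer sequence variation, CENP-B box integrity, and —
after mapping MNase ChIP data onto array references — the chromatin state
and nucleosome conformation of each array class.

## Coordinates and identity

All coordinates are 0-based half-open everywhere inside the package (the
BED/bedGraph convention). 1-based inclusive coordinates appear only at the
BLAST-tabular and RepeatMasker import boundaries, and importers are tested
by round trips. Percent identity is matches / alignment columns, with gap
columns counted — the convention of BLAST-style searches, which the
scanner emulates. For Jukes–Cantor distances the mismatch proportion `p`
is computed over columns where both sequences have a base (gaps excluded),
because the JC model describes substitutions only. Whether the
divergent-MaSat rule ("more than 10 monomers below 75% similarity")
counts gaps is not settled usage; we use the gap-inclusive identity and
expose both thresholds (`divergent_identity`, `divergent_min_monomers`).

## Consensus library and motif are configuration

The published consensus sequences are maintained in external references,
so the package treats consensi as inputs: `load_consensus_library()` reads
a tagged FASTA (`class=`, `box_offset=`, `subunits=` header grammar) and
`synthetic_consensus_library()` builds a seeded stand-in with the correct
monomer lengths (120 / 112 / 112+64 / 234 / 146 / 6n bp) for simulation
and testing. The CENP-B box motif is likewise configuration: a 17-symbol
IUPAC string (default `NTTCGNNNNANNCGGGN`, the published degenerate
consensus) plus an essential-position set that always contains positions
15–17; further conserved positions can be added via
`essential_positions`.

## Scanner and segmentation

`scan_read()` replaces an external BLAST binary with a deterministic
seed-and-extend search: exact 11-mers shared between consensus and read
vote for candidate diagonals; candidates with at least 3 votes are refined
by a semi-global alignment (consensus global, read local; match +1,
mismatch −1, gap open 4, extend 1) on both strands; hits below the 70%
identity floor are dropped. Word size 11 keeps the expected seed count per
monomer high up to ~20% divergence; the BLAST-parameter word size 6 is
available via `word_size` for sensitivity parity with external searches,
and externally produced tabular hits can be imported instead.

`segment_and_type()` merges same-class, same-strand hits across gaps below
half a monomer, requires at least 2 hits per block (one noisy hit is not
an array), labels internal unexplained gaps ≥ `gap_min` = 100 bp as
non-satellite blocks (Type 2), and never lets terminal unannotated margins
create Type 2, because reads truncate arrays arbitrarily. The 100 bp
threshold separates real interruptions from alignment slop while staying
below the smallest annotated TE fragments; it is configurable.

## Monomer decomposition

`decompose_array()` is consensus-anchored tiling: align the consensus
semi-globally into a ~1.7-monomer window, accept the placement if its
divergence is at most `max_divergence` = 0.40 (the screening cap used for
tandem-repeat decomposition tools), emit the monomer with its difference
list, and continue from its end; rejected stretches advance by one monomer
length and stay as gaps. Monomer lengths float with indels, which is what
captures 220-mer/250-mer MaSat variants and the dimer sub-unit structure
(the 112–64 dimer is decomposed at its 176-bp frame with the observed
sub-unit boundary recorded). Insertions are charged to the left-flank
consensus position so variation profiles keep a fixed length. Reverse
strand blocks are decomposed on their reverse complement and mirrored
back, making identities strand-invariant (tested).

## Period estimation

The repeat period is estimated from the shift-match score: the fraction
of positions where the sequence equals itself shifted by a lag, over lags
50–400 bp. Two numerical decisions matter. First, under the generator's
mutation model (each monomer mutated independently from the consensus)
the expected score at harmonic lags (2L, 3L …) *equals* the score at L,
so a raw argmax would land on a harmonic roughly half the time; the
period is therefore the smallest lag statistically indistinguishable
(within 3 standard errors) from the maximum — exact ties also resolve to
the smallest lag. Second, with ~350 lags tested, a "peak above background
+ 3 SD" rule would fire on pure noise in roughly a third of random
sequences; the no-period threshold is a robust (median/MAD) z of 5,
i.e. a multiplicity-aware version of the classical 3-SD rule. Both
choices are exposed as arguments.

## Synthetic data generator

The generator is first-class, tested code; its defaults are the study
conditions used throughout the tests.

* **Mutation model.** Per-monomer divergence `d` is realized as an exact
  count `round(d * L)` of substitutions at positions sampled without
  replacement (uniform over the three alternative bases); indels are
  single-base events at `indel_rate` (default 0). The exact-count choice
  makes the recorded truth identical to the realized mismatch fraction,
  so identity recovery can be asserted to ±1% without binomial noise
  (at `d = 0.203`, `L = 120`, Bernoulli sampling alone would blur the
  maximum by ±3.7 points).
* **CENP-B boxes.** With `intact_box_fraction = f`, exactly `round(f·n)`
  monomers have their box window masked from mutation; every other
  monomer carries at least one forced substitution at a non-degenerate
  motif position (inside its substitution budget when possible). Without
  the forced hit, low-divergence monomers would remain intact by chance
  and the fraction would not be exactly recoverable.
* **Structure.** Cassettes (TE-like random sequence) insert after stated
  monomer positions; a direction switch reverse-complements the array
  tail as one segment; a junction partner appends a second array. Truth
  blocks tile every base exactly once (tested).
* **ChIP model.** Input fragments fall uniformly over the annotated
  references plus a background decoy; ChIP fragment mass on class `c` is
  `fold_c ×` its input mass, with the decoy absorbing the remainder.
  This is the unique placement model under which the fragment-count
  quotient `E_c = f_c / g_c` equals the specified fold in expectation —
  without a background class the quotient is only proportional to it.
  The decoy length must be shared between a ChIP sample and its matched
  input (`chip_background_length()`); infeasible fold/background
  combinations raise an error rather than silently rescaling. `depth` is
  the target mean input fragment coverage over the satellite references.
  Fragment lengths are Gaussian 150 ± 15 bp (MNase mononucleosomes);
  emitted pairs are 75 bp. Phased placement draws fragment midpoints
  from Gaussians (SD 15 bp) centered once per nucleosome period — truth
  is defined on midpoints, not reads, so the phasing statistic has an
  unambiguous null and alternative.

What the generator does *not* emulate: long-read sequencing error beyond
substitutions/indels (HiFi-scale accuracy makes this secondary), PCR
duplicates, chromatin accessibility biases, and cross-array mapping
ambiguity within a class (fragments are placed on their true array).
Passing tests therefore demonstrate correctness of the measurement path
under a clean generative model, not robustness to every artifact of real
libraries.

## Enrichment, phasing and spacing

Enrichment uses fragment-count fractions rather than base coverage —
equivalent in expectation and exactly conserved (class counts sum to the
mapped total, tested). No IgG subtraction is applied; an IgG control is
just another mark. Per-array folds are reported alongside the pooled
class quotient and averaged over three or more arrays per class where
available; zero input fractions flag the fold as undefined rather than
infinite.

`phasing()` computes mean-subtracted coverage autocorrelation over lags
50–400 bp. Fragment-span coverage is intrinsically autocorrelated below
the fragment length (a triangular component vanishing at ~150 bp), so the
dominant period is the best *local* maximum of the lightly smoothed
autocorrelation, not the raw argmax — otherwise every unphased track
would report a 50-bp "period". The score
`S = (ρ(T) − median) / (1 − median)` is clipped to [0, 1] and compared to
a 0.3 threshold; peaks within 5% of the best resolve to the smallest lag
(harmonics). Flat tracks score 0. `particle_spacing()` calls peaks on the
smoothed track above `median + 0.5·MAD` (capped at the median–maximum
midpoint so strongly phased bimodal tracks keep their peaks) and reports
the modal inter-peak distance in rounded monomer units; fewer than three
peaks is undefined.

The built-in paired-end mapper is an exact-seed (25-mer) lookup with
full-length verification, best single concordant placement per pair
(insert 10–700 bp), ties broken to the lowest reference then leftmost.
Near-miss placements beyond the insert bound are counted as discarded,
unplaceable pairs as unmapped. Real alignments (SAM-derived fragment
tables) can be supplied instead; cross-array multi-mapping within highly
similar arrays is a documented limitation of any such mapper.

## Phylogeny

Neighbor joining is implemented in the package (Saitou–Nei Q criterion,
standard branch-length formulas, negative lengths clamped to zero) with a
deterministic tie-break toward the smallest pair of node indices in input
order, so trees are reproducible on degenerate (e.g. equidistant) inputs.
`ape` supplies serialization and the independent oracle in tests (random
additive matrices, `ape::nj` agreement). Distances are Jukes–Cantor with
saturation (`p ≥ 0.75`) either raised as an error or capped (default cap
5 in `pairwise_distances()`, with a warning). Class-level trees subsample
30 monomers per class under a fixed seed, the usual convention for
cross-class comparisons. Length-variant monomers are compared by pairwise
alignment rather than a multiple alignment; this keeps distances
well-defined for 220/250-mers at the cost of slight non-additivity noise.

## Pipeline and problem sizes

`run_pipeline()` executes generate → annotate → monomers → boxes → trees
→ chip from one YAML config; every threshold above is surfaced there with
these defaults, seeds are recorded in the JSON report, and identical
config + seed gives byte-identical outputs (tested). The test suite and
acceptance script run at deliberately modest sizes — arrays of 40–200
monomers, cohorts of ~100 reads, ChIP samples of 10⁴–10⁶ fragments —
chosen so the full suite completes in a few minutes while keeping
sampling error far inside the asserted tolerances (fold recovery at these
sizes has a relative standard error below 2%).

## Known limitations

* Per-read annotation only; no assembly of reads into chromosome-scale
  arrays.
* The scanner is tuned for monomers ≥ ~50 bp; the telomeric repeat is
  handled via a multi-copy consensus unit rather than its 6-bp unit.
* Enrichment assumes the reference set (plus decoy) captures the mapped
  fragment universe; it does not model genome-wide mappability.
* No bootstrap support on trees; none is needed for the clade-partition
  checks the package performs.
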