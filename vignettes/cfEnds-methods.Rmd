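---
title: "cfEnds: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cfEnds: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfEnds)
```

This vignette is the package's account of the science it implements: the
quantities, their assumptions, the tunable parameters, what the built-in
simulator does and does not emulate, and the numerical decisions taken
where the design was genuinely open.

## The end-motif model

A sequenced cfDNA fragment is an interval on a reference genome together
with the strand of the sequenced molecule. All motif logic works in the
molecule's own 5'→3' frame: for a minus-strand fragment the locus is
reverse-complemented before any motif is read. Four motif classes are
defined per fragment: the measured 5' and 3' end k-mers (EM5, EM3) and
the flanking k-mers deduced from the reference immediately upstream of
the 5' end (PREM) and downstream of the 3' end (POEM). The biological
premise is that a nuclease footprint spans the cleavage site, so both the
retained and the removed side of each cut carry signal; because one
molecule's PREM is, under clean single-cut fragmentation, another
molecule's EM3 (and POEM another's EM5), the package ships a partition
identity test that checks this correspondence exactly on abutting
fragments.

A per-sample spectrum is the frequency vector over all `4^k` motifs of
one class, normalised by the number of *usable* ends: ends within `k` of
a contig boundary or containing N are excluded from numerator and
denominator alike, which keeps the frequencies summing to 1. Each class
is normalised independently. The default `k = 4` (256 motifs) balances
resolution against counting noise; `k` from 1 to 5 is supported.

Fragment sizes are measured in nt of the sequenced strand
(`width` of the interval). The default size strata [42,70), [70,166)
and [166,601) nt follow the structure of the cfDNA size distribution: a
sub-mononucleosomal short population, the range up to the
mononucleosome peak, and longer material. Strata are half-open, so a
166-nt fragment falls in the third stratum; the 601 upper bound encodes
the inclusive 20–600 retention filter applied at load time.

### Sonicated-control correction

Sonication fragments DNA without sequence preference, so the end motifs
of a sonicated library measure the pre-analytical bias of the
preparation (ligation, amplification, sequencing) rather than biology.
The correction multiplies, motif-wise, the plasma frequency by
`expected / sonicated`, where `expected` is the sliding-window k-mer
composition of both genome strands, then renormalises to sum 1. Three
points the formula leaves open are decided as follows: windows are
counted on **both** strands (fragment ends arise from both); when a
sonicated spectrum is supplied as counts containing zeros, a pseudocount
of 0.5 is added to every sonicated count before forming the ratio (a
pseudocount applied unconditionally would break the algebraic identities
`sonicated == expected ⇒ corrected == plasma` and
`plasma == sonicated ⇒ corrected == expected`, which the tests assert on
zero-free input); and the corrected vector is renormalised because the
motif-wise formula does not preserve the unit sum. The correction only
does something useful when the bias is genuinely shared between the
plasma and sonicated preparations — correcting against a control that
already matches the genome composition is a no-op, and the test suite
constructs its fixtures accordingly.

## Differential motifs, EMR and heatmap statistics

Group comparisons are per-motif two-sided Wilcoxon rank-sum tests on
sample-level frequencies, adjusted by Benjamini-Hochberg within the
motif class (256 tests at `k = 4`); `stats::wilcox.test` supplies exact
p values for small tie-free groups and the continuity-corrected normal
approximation otherwise. Fold change is the ratio of group medians; a
zero median is replaced by a pseudo-frequency of `1/(2·nEnds)` so the
ratio stays finite. Relative percentage change
(`(median_case − median_control)/median_control × 100`) is the ranking
key for the top-motif lists; motifs with a zero control median are
excluded from ranking rather than ranked at infinity. The end-motif
ratio (EMR) of a sample is the cumulative frequency of the
case-increased motif set over the case-decreased set; the sets default
to the significant motifs of the case-vs-control comparison and the
ratio is undefined (NA, with a warning) when the denominator is zero.
Heatmap standardisation uses the sample (n−1) SD — cohorts are small —
and maps zero-variance rows to all-zero rows.

## Cleavage profiles and FRAGMA

The cleavage proportion at a genomic site is the percentage of covering
fragments whose 5' (or 3') terminal base lies exactly at the site, in
the molecule's own orientation. Profiles are computed in a ±5-nt window
anchored at the **cytosine** of the Watson-strand CpG (position 0); the
anchor base is a convention the output metadata records, since a CpG
spans two bases. CpG methylation is generally symmetric across strands,
so minus-strand fragments are folded in through the mirrored frame
anchored at the G before positions are averaged. Per-site proportions
are averaged unweighted across CpGs (robust to coverage heterogeneity);
a pooled mode (summing ends and depths before dividing) is available by
flag, and a configurable minimum depth (default 1) excludes uncovered
cells from the mean.

CpG sites are classed by methylation density: tissue-wide
hypermethylated (> 70 % in every configured tissue), tissue-wide
hypomethylated (< 30 % in all), and HCC-specific hyper/hypo (> 70 % in
tumour with < 30 % in buffy coat, and vice versa). The HCC-specific
labels take precedence when both an HCC-specific and a tissue-wide rule
fire, since they are the rarer, more informative class. The tissue list
is configuration, not hard-coded. The FRAGMA feature vector concatenates
the 11-position profiles of the four categories (44 features per end
type) in fixed category-then-position order.

## The duplex (4-end) model

A duplex molecule is two strand intervals on the same locus; each side
is blunt or carries a 5'/3' overhang whose length follows from the
geometry (e.g. on the left side, a Watson start upstream of the Crick
start means the Watson 5' end protrudes). The stem-loop adapter pool
contains 41 entries — 1 blunt, plus 5' and 3' overhangs of 1–20 nt —
each identified by a 6-bp barcode. Barcodes are synthesised by a
deterministic greedy lexicographic scan enforcing pairwise Hamming
distance ≥ 3: distance 3 (not 2) is what makes single-substitution
rescue provably unambiguous, because with distance 2 a one-error word
can be equidistant from two codewords. Decoding rescues barcodes with at
most one mismatch and rejects anything else; molecules with overhangs
longer than 20 nt have no adapter and are dropped as unligatable.

The 4-end motif notation `a→b d←c` reads the Watson 5' a-mer and 3'
b-mer left to right in the numerator and displays the Crick strand
antiparallel (3'-end first) in the denominator; a blunt duplex whose
Watson strand is ACGT renders as `A→TT←A` under the 1→1 1←1 spec.
Watson orientation is fixed by the reference, and spectra cover the full
`4^(a+b+c+d)` domain.

Nuclease attribution looks up the 5' dinucleotide of one strand and the
3' dinucleotide of the complementary strand at the same fragment side in
the shipped signature table (DNASE1L3: 5' GG / 3' CT; DNASE1: 5' CT /
3' CG; DFFB: 5' {AC, AT, AA, AG, GA} / 3' {GC, GT, AG, GG, TC});
unordered pairs give six categories, and unmatched or ambiguous motifs
are `unassigned` rather than an error. The observed/expected
normalisation redraws 10× as many molecules uniformly from the genome —
crucially **preserving the observed (size, left-offset, right-offset)
geometry tuples**, because a blunt redraw locks the two strands' end
motifs into reverse complements and assigns expected frequency 0 to
every cross-strand signature pair. Duplex "size" is the Watson strand
length, matching the single-strand convention; the default size bins
[20,130), [130,200), [200,400), [400,600), [600,1000) bp bracket the
mono-nucleosomal range and the long tail with round landmarks.

## Classification harness

The canonical feature matrix concatenates, in deterministic order, the
per-class per-stratum motif frequencies — 4 × 256 × 3 = 3,072 features —
optionally extended with FRAGMA vectors. Classification is
leave-one-out: for each sample a linear-kernel SVM (cost 1) is trained
on the rest, with feature standardisation fitted on the training split
only. Within-fold scaling is the leakage-safe choice; kernel and cost
are package defaults since nothing in the problem fixes them, and linear
SVMs are the conservative option at these dimensionalities.
"Probability of having cancer" is the Platt-scaled score fitted within
the training fold. AUC is the Mann-Whitney pair-count statistic (ties
0.5), cross-checked in the tests against an independent implementation;
AUPR is average precision; sensitivity at a specificity threshold takes
the best sensitivity among operating points meeting the threshold.
DeLong comparisons are delegated to pROC; bootstrap confidence intervals
resample within class (percentile, 1,000 draws) so no resample is
single-class.

## The simulator: what it emulates, and what it does not

`simConfig()` fixes the generative conditions. The size distribution is
a two-component Gaussian mixture with means 52 and 166 nt (SDs 6 and
15, weights 0.35/0.65) and a mild 10-nt cosine comb (amplitude 0.3) on
the short component, reflecting the bimodal, weakly periodic single-
strand size profile. The case group multiplies the density by 0.6 in
[42,70), 1.2 in [70,166) and 0.9 above 166 nt — the three
characteristic directions of the cancer size shift. Cut placement is
rejection sampling against 4-mer context weights at both fragment ends
(defaults enrich CCCA-type 5' and TTTT-type 3' contexts); case samples
apply additional per-motif multipliers (`groupEffect5`/`groupEffect3`).
A configurable fraction of fragments (default 5 %) is re-anchored at
hypermethylated CpGs with 5' ends at the C and 3' ends 1 nt before it,
the offsets that make methylation legible in cleavage profiles. Duplex
simulation draws jagged ends from a blunt/5'/3' mixture and can
constrain cut sites so both strands of a side match a chosen nuclease's
signatures. Strand emission is balanced 50/50. All randomness flows from
the seed; identical seeds give byte-identical cohorts.

The simulator does **not** emulate nucleosome positioning, sequencing
error, PCR duplication, GC-coverage bias, tissue-specific methylomes or
fragment-length-dependent motif composition. Consequently, passing tests
demonstrate that the implementations recover what the generator planted
under realistic noise — not that any particular clinical performance
would be attained on patient data.

Two classifier-level behaviours deserve explicit notes. First, at desk
scale (tens of samples, thousands of fragments) the 3,072-feature model
pays a real dimensionality penalty: with sparse injected effects it can
lose to the 256-feature EM5 model through the well-known small-n/large-p
LOOCV pathology. The comparison test therefore uses broad case effects
(40 motifs per end class, echoing the dozens-to-hundreds of differential
motifs seen in practice) with the stronger shift on 3' contexts — the
regime where 3' ends carry information a 5'-only model cannot see, which
is precisely the holistic argument; there the combined model wins
strictly. Second, the downsampling experiment needs enough samples
(12 per group in the tests) for the full-depth model to escape the same
pathology; the 500-fragment endpoint is then dominated by counting
noise and the 40,000-fragment endpoint by the true effect.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open in all files (BED convention) and
  1-based closed inside `GRanges`; loaders convert, and a flag declares
  1-based input.
* Size-profile modes are raw local maxima refined by a two-pass
  windowed centroid — the raw argmax of a broad peak wanders several nt
  under Poisson noise, the centroid does not.
* Empty spectra (no usable ends) flag `nEnds = 0` and return NA
  frequencies with a warning rather than dividing by zero.
* `differentialMotifs` returns p = 1 and fold change 1 for motifs
  constant and equal in both groups; q is always ≥ p.
* `cleavageProportion` at a depth-0 site is NA and the site is excluded
  from profile means.
* Filters with absent optional columns are skipped with a message;
  filtering is idempotent and the removal report sums to input − output.
* Duplicate fragments are never collapsed — fragment multiplicity is
  signal in end-motif counting.
* Problem sizes in the test-suite experiments (genome 100 kb, 20
  samples per group at 5,000 fragments, 12 per group at 40,000 for the
  downsampling curve, 1,000 bootstrap draws, 20 label permutations) were
  chosen as the smallest cohorts at which the measured properties are
  stable under the fixed seeds.

## Known limitations

Cleavage-profile computation is per-site and loops over CpGs, which is
comfortable for thousands of sites but not genome-wide methylome scans.
The SVM harness deliberately offers no feature selection or nonlinear
kernels. The duplex simulator constrains nuclease signatures by
searching real genomic context near the target cut, so extreme
signature models on very short genomes can reject many candidate sites.
Barcode rescue corrects exactly one substitution; indel errors in
barcodes are not modelled.
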