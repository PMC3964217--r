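---
title: "Methods: promoter architecture and ETS motif geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter architecture and ETS motif geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(etsgeo)
```

This vignette documents the statistical procedures implemented in
`etsgeo`, the assumptions behind them, the numerical and design choices
made where a convention had to be picked, and what the synthetic-data
generator does and does not emulate.

## Coordinates and annotation

All tables use 0-based, half-open intervals (BED convention), which keeps
interval arithmetic unambiguous. A gene's promoter is the 1 kb immediately
upstream of its transcription start site: `[tss - 1000, tss)` on the plus
strand, `[tss + 1, tss + 1001)` on the minus strand. For genes annotated
with several transcripts only the most 5′ TSS is kept — the smallest
`txStart` on the plus strand and, by strand symmetry, the largest
`txEnd - 1` on the minus strand (annotation sources rarely state which
base they consider "the" start of a minus-strand gene; the rightmost
transcribed base is the consistent choice under the half-open convention).
Promoters that would run off the chromosome start are truncated at 0 and
flagged rather than dropped.

Two genes on opposite strands of one chromosome form a *bidirectional*
(divergent) pair when the minus-strand TSS lies at or left of the
plus-strand TSS and the TSSs are within 1 kb: their promoters then overlap
and the region between the TSSs is shared regulatory DNA. When the
plus-strand TSS is the left one the genes converge (*face-to-face*); their
promoters are disjoint, and the class is kept separate precisely because
it is the negative control for the bidirectional association. Each gene
joins at most one pair; when several partners qualify the nearest TSS
wins, with lexicographically smaller gene ids breaking exact ties. This
greedy nearest-partner matching makes the classification invariant to
input row order.

For region-level counting a bidirectional pair is one region, not two:
universe size `N = n_genes - n_pairs`, class size `K = n_pairs`, and a
region is bound if either member promoter is. Whether a gene-level
universe (pairs counted twice) is more appropriate depends on how the
promoter universe was defined upstream, so both modes are exposed
(`count_pairs_once`); the p-value is universe-dependent and should be
read as order-of-magnitude.

## Coverage, normalization and binding calls

Coverage is accumulated per strand at base resolution and scaled by a
single factor so the genome-wide mean of normalized coverage per kb is 1.
Signal is the base-overlap sum over an interval — a read straddling a
promoter edge contributes only its overlapping bases — which is robust to
read-length differences between libraries, and replicates of different
sequencing depth become directly comparable.

Because ChIP fragments are sequenced from their 5′ ends, the forward- and
reverse-strand profiles flank the true binding position. The offset is
estimated as the shift `k` in 0..500 (1-bp grid) maximizing the Pearson
correlation between forward coverage and reverse coverage translated left
by `k`, pooled over chromosomes; reads are then shifted `k/2` toward the
midpoint. The implementation evaluates the exact overlap Pearson
correlation for every lag at once, using an FFT for the lagged cross
products and cumulative sums for the moment terms — identical (to floating
rounding, ~1e-9 relative) to the naive grid search, which the tests run as
the independent oracle on small tracks. Degenerate inputs (a flat strand)
return offset 0 with a warning.

Binding calls are non-parametric. The threshold `s*` is the smallest
observed signal such that at most a fraction `fdr` (default 0.005) of
*pooled* negative-control promoter signals reaches it; pooling the control
replicates uses all available null signal and makes the threshold stable
when individual controls are shallow. A promoter is bound only if every
treatment replicate reaches `s*` (replicate intersection); promoters that
also reach `s*` in every control replicate are flagged as bias and
removed. If no observed signal attains the requested control fraction the
threshold is `+Inf` and nothing is called — this keeps the bound set
monotone non-increasing as `fdr` decreases. With identically zero
controls the threshold falls back to the smallest positive treatment
signal, with a warning.

The largest peak of a promoter is the 145-bp window with the maximal
normalized coverage sum; ties go to the leftmost window, and promoters
shorter than the window (truncated ones) are scored as a single window.

## Motif statistics

7-mer over-representation compares bound promoters against all promoters
by presence/absence: for each of the 4^7 words, `K` promoters of the `N`
total contain the word on either strand, `k` of the `n` bound ones do,
and the upper-tail hypergeometric probability P(X ≥ k) is the p-value.
Presence/absence rather than occurrence counts keeps the test at the
promoter level, matching the contingency framing of the downstream
association analyses; occurrence counting would let a single repetitive
promoter dominate. Windows containing non-ACGT letters never match.
Evaluation goes through `phyper`, which is stable in log space, so
p-values far below double-precision underflow are still reported on the
log10 scale; Bonferroni-adjusted values over the 16384 words are emitted
alongside the raw ones. The tests verify the implementation against
direct combinatorial enumeration for every parameter combination with
N ≤ 12 at 1e-12.

Motif scanning accepts IUPAC degeneracy codes in the pattern (the default
is the canonical ETS 7-mer `CCGGAAG`; the fuller ETS consensus is not
published as a matrix, so the pattern is a configurable input). A
minus-strand hit is a position where the reverse complement of the
pattern matches the forward sequence; ambiguity codes in the *subject*
never match, so planted or masked `N` runs cannot create hits.

## Motif-pair geometry

For promoters with exactly two motifs on opposite strands, the signed
distance is measured center-to-center (symmetric, and the natural input
for the phase computation): negative when the left motif points right and
the right motif points left (face-to-face), positive for the converse
(back-to-back). Coincident centers — impossible for a non-palindromic
7-mer but reachable for degenerate patterns — are tie-broken
face-to-face at distance 0. Note that reverse-complementing a promoter
mirrors offsets *and* flips strands, so orientation classes and signed
distances are invariant; this strand symmetry is asserted in the tests.

The density track counts, at every position p in −1000..+1000, the pairs
whose signed distance lies in the half-open 100-bp window
`[p - 50, p + 50)`; each pair contributes to exactly 100 positions.

Positional significance uses a resampling null: 2500 draws (tests and
script use 500 where runtime matters) of `sample_size` pairs with
replacement from the full pair set, each converted to a density track; at
each position a normal distribution is fitted by moments to the resampled
counts and the observed count's upper-tail p-value is
`1 − Φ((obs − μ)/σ)` (the depletion tail is available as an option).
The corrected significance line is Bonferroni, `0.05/2001`. Positions with
zero resampled variance return p = 1 (or the machine minimum if the
observation exceeds the constant null) and are flagged. Calibration under
the null is good in the bulk — with the observed track itself drawn from
the null, ~5–6% of positions fall below p = 0.05 — but the extreme tail
of a discrete windowed count is slightly heavier than the fitted normal,
so the track-wide minimum p dips below the corrected alpha in a few
percent of null tracks (measured at ~4% over thousands of trials at the
default study scale of 425 sampled pairs). The acceptance test therefore
estimates that trial fraction with 2000 trials, where the estimator's own
noise no longer straddles the 95% bound.

Helical phase assumes B-DNA pitch 10.4 bp/turn:
`φ = 360·(d mod 10.4)/10.4` mapped to (−180°, 180°]. Supercoiling and
nucleosome winding perturb the pitch by up to ~1 bp/turn — more than a
full turn of uncertainty across 100 bp — so phase profiles indicate
pattern, not a measured geometry. The binding profile takes, on a 10°
grid with a 40° circular window, the fraction of pairs in the window that
are bound, normalizes the profile to mean 1, and overlays a least-squares
harmonic fit `1 + Σ_{h=1,2} (a_h cos hφ + b_h sin hφ)` as the smooth
curve (two harmonics: the first captures face preference, the second the
twofold symmetry of the double helix; higher harmonics would chase grid
noise).

## Copy-number curves

The probability curve is the bound fraction among promoters with exactly
k motifs, k = 0..6; promoters with more motifs (up to 13 occur) sit in
bins too small to estimate and are excluded. No standard errors are
attached: calls are intersections, not averages. The exponential fit is
log-linear least squares on the positive-valued points, with R the
Pearson correlation of ln(value) with k (R on the raw values is reported
too, since either convention is found in practice); zero bins are
excluded from the fit but listed, and an explicit `exclude_k` reproduces
fits that drop a visibly departing trailing point, rather than any
automatic outlier rule. When the planted law `min(1, a·e^{bk})` saturates
at 1 in the top bins, the log-linear estimate of b is biased low — with
a = 0.02 and b = 0.8, end-to-end recovery settles near 0.65–0.75 — so
unsaturated benchmarks use a = 0.005.

The signal curve divides each replicate's promoter signals by that
replicate's mean (grand mean of normalized signals is exactly 1),
summarizes each promoter by its replicate mean, and averages within
copy-number bins with across-promoter standard errors. Replicate scaling
cancels exactly; a replicate scaled ×10 changes nothing.

## The synthetic-data generator

The generator's defaults are the study conditions the analyses assume:
1000 genes on one chromosome in 4-kb units (no accidental promoter
contacts), ~4.5% of promoter regions bidirectional with TSS distances
2..1000 (distance ≥ 2 keeps the member promoters genuinely overlapping),
2% of genes in face-to-face pairs, a decaying motif copy-number
distribution over 0..13 (relative mass 0.40/0.25/0.18/0.08/0.04/0.02 at
k = 0..5, with a thin tail to 13 so the exclusion rule is exercised), and
an inter-motif spacing mixture with 60% of pairs sharply concentrated
near zero (half-normal, SD 25, |d| ≥ 7 so two 7-mers can physically
coexist) and 40% in uniform shoulders to ±990. Three factor archetypes
are configured: a p53-like factor (P(bound|k) = min(1, 0.02·e^{0.8k}),
flat signal law, spacing preference at −200/−100/+100 with suppression of
close spacing, 90° phase preference), an ETS1-like factor (similar, with
−50/+200 kernels) and a GABPA-like factor (zero-centred spacing
preference without suppression, signal proportional to k). Reads are
Poisson: uniform background at 0.02 reads/bp per replicate, plus
10× background mass at bound promoters (scaled by k/2 under the
proportional law), with fragment centers scattered SD 35 bp around the
motif-region midpoint and strand-split placement that produces a 120-bp
forward/reverse offset. Binding positions are clamped ~165 bp inside the
promoter so the measured signal does not depend on where in the promoter
the motifs happen to sit — otherwise edge losses masquerade as a
copy-number trend.

The suppression window at distance 0 is a Hill-type dip,
`|d|^γ / (|d|^γ + d0^γ)` with d0 = 120, γ = 4. A Gaussian dip cannot
express the observed biology here: its suppression ratio between two
small distances approaches `(d1/d2)^2`, which is never small enough for a
valley at 0 to survive the overwhelming abundance of closely spaced
pairs; the Hill form reaches ratios of order `(d1/d2)^γ` and does.

What the generator does *not* emulate: fragment-length distributions, GC
or mappability bias, duplicate reads, copy-number variation, sequence
composition beyond uniform base frequencies, and promoter sequence
sharing between overlapping bidirectional promoters (each promoter's
sequence is planted independently; the genomic splice lets the later
promoter win the overlap, and motif analyses read the per-promoter
sequences). Passing tests on this generator therefore demonstrate the
statistical machinery, not robustness to real-library artifacts. One
consequence of genomically overlapping pair promoters is worth noting:
reads from a bound promoter also cover its partner, so the partner is
often called bound too. That is faithful to real data (the shared region
*is* bound) but means caller precision is evaluated on layouts without
overlapping promoters.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen to keep
every stochastic check far from its decision boundary: 400–2000 genes for
end-to-end runs, 20 000 planted pairs for spacing/phase recovery,
2000 promoters per bin for curve fits, 10 200 pairs / 425 sampled for the
resampling null (mirroring the ~24:1 universe-to-bound ratio of a typical
study), 500 resampling runs in tests versus the 2500 default, and three
pooled simulations for the signal-law contrast (inverse-variance pooling
of the slope keeps the test's false-alarm rate below the per-simulation
t-statistic's).

## Known limitations

* The FDR thresholding is an empirical control-quantile rule; it controls
  the control-exceedance fraction, not a model-based FDR, and its
  behaviour with very few control promoters is coarse.
* Bonferroni across 2001 heavily overlapping window positions is
  conservative; the effective number of independent windows is ~20.
* The hypergeometric association tests condition on the chosen universe;
  with ambiguous universes (gene- versus region-level) only the order of
  magnitude of extreme p-values is meaningful.
* Exponential fits are log-linear and exclude zero bins; they are not
  maximum-likelihood fits of a binomial model, and saturation near
  probability 1 biases the exponent downward.
* The helical-phase analysis inherits the pitch uncertainty discussed
  above and is descriptive only.
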