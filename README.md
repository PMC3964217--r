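# etsgeo

Promoter architecture and ETS motif geometry in transcription-factor
ChIP-Seq data.

Some transcription factors do not recognise DNA directly but ride on
sequence-specific partners — the textbook case being gain-of-function mutant
p53, which associates with chromatin through ETS-family factors (ETS1,
GABPA) bound at ETS motifs (canonical 7-mer `CCGGAAG`). For such factors the
*architecture* of a promoter — how many ETS motifs it carries, how the
motifs are spaced and oriented relative to each other, whether the promoter
is part of a divergent (bidirectional) gene pair — predicts binding better
than any single site does. `etsgeo` packages the analyses needed to
establish that, end to end, for anyone with a gene annotation, promoter
sequences and aligned ChIP-Seq reads (plus negative controls):

* **Annotation** — 1-kb upstream promoters from a RefSeq-style gene table
  (most 5′ TSS per gene) and classification of promoter pairs as
  *bidirectional* (divergent TSSs back-to-back within 1 kb, overlapping
  promoters) or *face-to-face* (convergent, disjoint promoters).
* **Signal** — strand-aware read coverage normalized to a genome-wide mean
  of 1 read-equivalent per kb; forward/reverse offset estimated by
  maximizing the Pearson correlation between the strand profiles, with
  reads shifted half the offset toward the fragment midpoint; per-promoter
  signal; binding calls at a control-derived false-discovery threshold
  (the smallest signal *s\** with ≤ 0.5% of pooled control signals above
  it) intersected across replicates, with control-positive promoters
  removed as bias; largest 145-bp peak per promoter.
* **Motifs** — 7-mer over-representation in bound promoters by the
  upper-tail hypergeometric test on presence/absence counts,
  P(X ≥ k | N, K, n); IUPAC motif scanning on both strands.
* **Association** — contingency statistics: binding versus isolated
  single/dimer ETS-site regions (2-kb isolation rule), factor co-binding,
  and bidirectional-promoter enrichment with pairs counted as one region.
* **Multiplicity** — binding probability and relative binding signal as
  functions of motif copy number k = 0..6, with log-linear exponential fits
  (value ≈ a·e^(bk)) and ordinary linear fits, both with Pearson R.
* **Geometry** — signed spacing of inverted motif pairs (negative =
  face-to-face, positive = back-to-back), 100-bp sliding-window density
  tracks over −1000..+1000, positional p-values from a resampling null
  (2500 draws with replacement, normal fit per position, Bonferroni-
  corrected alpha 0.05/2001), and helical-phase profiles (pitch 10.4
  bp/turn, 40° windows).
* **Synth** — a seeded generator of annotation, motif-planted promoter
  sequences and simulated ChIP-Seq reads with known ground truth, used by
  the test suite and available for benchmarking.

## Worked example

A fully synthetic study: 500 genes, ~4.5% bidirectional promoter regions,
planted `CCGGAAG` motifs, and a p53-like factor whose binding probability
grows exponentially with motif count but is suppressed for closely spaced
inverted motif pairs.

```r
library(etsgeo)

cfg     <- synth_config(n_genes = 500)
ann     <- generate_annotation(cfg, seed = 7)
planted <- plant_motifs(cfg, ann, seed = 8)
reads   <- simulate_chip_reads(cfg, ann, planted, seed = 9)

pairs <- classify_promoter_pairs(ann$genes)
table(pairs$kind)
#> bidirectional  face_to_face
#>            22             5

fr     <- reads$p53like
track1 <- normalize_coverage(fr$treatment[[1]], ann$chrom_lengths)
offset <- estimate_strand_offset(track1)
offset
#> [1] 119          # the simulator's true strand shift is 120 bp

tracks   <- lapply(fr$treatment, \(r) normalize_coverage(shift_reads(r, offset), ann$chrom_lengths))
controls <- lapply(fr$controls,  \(r) normalize_coverage(shift_reads(r, offset), ann$chrom_lengths))
calls <- call_bound_promoters(signal_matrix(tracks,   planted$promoters),
                              signal_matrix(controls, planted$promoters),
                              fdr = 0.005)
sum(calls$bound)
#> [1] 59           # of 500 promoters

counts <- motif_counts(scan_motifs(planted$promoter_seqs),
                       names(planted$promoter_seqs))
probability_curve(calls, counts)
#>   k      value   n
#> 1 0 0.01932367 207
#> 2 1 0.07826087 115
#> 3 2 0.00000000  92
#> 4 3 0.30303030  33
#> 5 4 0.46875000  32
#> 6 5 1.00000000   7
#> 7 6 1.00000000   7
```

The probability of binding rises steeply with motif count — except at
k = 2, where almost all promoters carry a closely spaced inverted pair and
the planted spacing suppression keeps the factor off. Exactly this
valley-at-zero-spacing behaviour is what the geometry module measures:
`spacing_density()` of the bound subset against all pairs, with
`resample_pvalues()` giving positional significance and `phase_profile()`
the helical-phase view.

```r
bidirectional_overlap(calls, pairs, planted$promoters)[ ,
    c("K", "n", "k", "frac_of_bound", "frac_of_class", "log10_p")]
#>    K  n k frac_of_bound frac_of_class   log10_p
#> 1 22 55 5    0.09090909     0.2272727 -1.019863
```

Five of the 22 bidirectional regions are bound — 23% of them, versus 11% of
promoter regions overall — a 2-fold enrichment that at this toy scale does
not reach significance (log10 p ≈ −1), but reproduces the analysis as run
at genome scale.

`run_pipeline(cfg, seed, outdir = "out")` executes all stages in dependency
order and writes every table/BED/FASTA artifact plus an md5 manifest;
reruns with the same config and seed are byte-identical.

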