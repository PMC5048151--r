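# cryptax

Integrative delimitation of cryptic species from morphometric and
DNA-barcode data.

Cryptic species — good biological species that are morphologically almost
indistinguishable — are routinely flagged by DNA barcoding, but turning a
barcode cluster into a formally diagnosable species takes corroboration
from several independent data types. `cryptax` implements the statistical
toolkit used to split a parasitoid-wasp species complex (*Encyrtus
sasakii*, Hymenoptera: Encyrtidae) into three species, as a reusable,
tested R pipeline:

* **Morphometric statistics** — per-character boxplot summaries (whiskers
  at the 2.5th/97.5th percentiles) and Tukey HSD post-hoc comparisons of
  all species pairs at a 95% family-wise confidence level
  (Tukey–Kramer form for unequal group sizes).
* **Multivariate ratio analysis (MRA)** — every specimen's 25
  log-measurements are split into an isometric size
  (`isosize = mean(log x)`) and a zero-sum shape vector; the package
  computes the shape PCA, PCA ratio spectra and the allometry ratio
  spectrum (with specimen-bootstrap CIs), and an LDA ratio extractor that
  scores every character pair (i, j) by the standard distance of its
  log-ratio, `D = |mean_A - mean_B| / s_pooled` for `r = ln(x_i/x_j)`,
  plus a size-vs-shape statistic δ (δ = 1 for pure size separation, near 0
  when shape separates the groups).
* **Geometric morphometrics (GMA)** — TPS I/O for 7-landmark forewing
  configurations, generalized least-squares Procrustes superimposition
  (reflections excluded), tangent-space PCA, canonical variate analysis,
  and a covariance-matrix correlation permutation test over landmarks.
* **DNA barcoding** — uncorrected *p* and Kimura 2-parameter distances
  under pairwise deletion
  (`d_K2P = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)`), haplotype collapsing,
  intra/interspecific distance summaries, barcode-gap detection,
  neighbor-joining trees with column-bootstrap support, and pure
  ("simple") diagnostic characters: position/state pairs fixed in one
  species and absent from all others.
* **Synthetic data generator** — a three-species scenario with planted,
  fully known structure (lognormal allometric measurements, mean wing
  shapes under arbitrary similarity transforms, COI-like alignments with
  species-fixed diagnostic states), so every downstream stage can be
  tested against ground truth.

## Worked example

```r
library(cryptax)

scn   <- default_scenario(seed = 7)        # three species, n = 17/48/55
meas  <- gen_measurements(scn)
space <- to_shape_space(meas)
lda_ratio_extract(space, "sasakii", "rhodococcusiae")
#> <lda_ratio_result> sasakii vs rhodococcusiae
#>   best   F2L/F5W  D = 2.88
#>   second OV/PVL  D = 2.14
#>   delta = 0.0395  D_full = 4.75
```

The best body ratio separating the two synthetic species is F2L/F5W
(second funicle segment length over fifth segment width) at a standard
distance of 2.88 pooled standard deviations — the same order as reported
for the real complex (2.6–4.9) — and δ ≈ 0.04 says the separation is
almost entirely shape, not size.

```r
sq  <- gen_sequences(scn)
gap <- barcode_gap(sq$seqs, sq$partition, metric = "k2p")
sprintf("max intra %.2f%%  min inter %.2f%%  gap: %s",
        100 * gap$max_intra, 100 * gap$min_inter, gap$gap)
#> "max intra 2.57%  min inter 4.64%  gap: TRUE"

head(pure_diagnostic_characters(sq$seqs, sq$partition)$diagnostics, 4)
#>         species position state
#> 1 eulecaniumiae       14     A
#> 2 eulecaniumiae       47     G
#> 3 eulecaniumiae       68     A
#> 4 eulecaniumiae      134     A
```

The barcode gap (largest within-species distance < smallest
between-species distance) holds, and the recovered diagnostic characters
are exactly the states planted by the generator at that polymorphism
level (38 of the 48 planted survive within-species polymorphism at the
default rate).

The whole analysis can be driven from one config:

```r
run_pipeline(run_config(seed = 7, out_dir = "run1"))
# writes measurements.csv, landmarks.tps, alignment.fasta, tukey_comparisons.csv,
# ratio_spectra.csv, lda_ratios.csv, aligned_landmarks.csv, cva_scores.csv,
# distances_*.csv, diagnostics.csv, nj_tree.nwk and summary.json
```

or from the shell via `inst/exec/cryptax`:

```sh
cryptax all --config config.json --out run1 --seed 7
```

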