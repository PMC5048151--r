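---
title: "Methods: integrative delimitation of cryptic species with cryptax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative delimitation of cryptic species with cryptax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptax)
```

## The problem

Cryptic species are reproductively isolated lineages whose external
morphology overlaps so strongly that classical diagnosis fails. The
modern integrative workflow attacks the problem from several directions
at once: distributional statistics of linear measurements, multivariate
ratio analysis (MRA) of body proportions, geometric morphometrics of
landmark configurations, and DNA-barcode evidence (distances, trees and
diagnostic characters). `cryptax` implements that workflow for the
three-species structure typified by the *Encyrtus sasakii* complex of
encyrtid parasitoid wasps, together with a synthetic-data generator that
plants known structure so that every stage can be verified against ground
truth.

## Morphometric statistics

Each of the 25 linear characters (antennal segments, tibiae, ovipositor,
wing veins; see `morpho_characters`) is summarized per species by median,
quartiles and whiskers. The whiskers are the 2.5th and 97.5th
percentiles — they cover 95% of the distribution — rather than the more
common 1.5·IQR convention; this choice matches the boxplot convention the
workflow standardizes on and is symmetric in probability.

Pairwise species differences use Tukey's HSD at family-wise level
`alpha = 0.05` per character. With unequal group sizes the Tukey–Kramer
form applies: the simultaneous interval half-width is

    q(1 - alpha; g, N - g) / sqrt(2) * s_pooled * sqrt(1/n_i + 1/n_j)

with `q` the studentized-range quantile. Significance, the adjusted
p-value and the interval are mutually consistent by construction
(significant ⇔ 0 outside the interval ⇔ p < alpha). The studentized-range
distribution is evaluated numerically (`ptukey`/`qtukey`); the test suite
cross-checks it against direct numerical integration of the distribution
to 1e-4. Missing values are dropped per character, not per specimen, and
each drop is logged; this keeps every character's sample as large as the
data allow, at the price of slightly different n across characters.

## Multivariate ratio analysis

For strictly positive measurements `x`, write `y = ln x`. Each specimen
decomposes as

    isosize = mean_k(y_k),    shape_k = y_k - isosize

so `shape` lies in the zero-sum hyperplane and `shape + isosize`
reconstructs the log-measurements exactly. Multiplying a specimen's
measurements by a constant changes only its isosize — ratios of
measurements are functions of shape alone, which is what makes this
coordinate system natural for ratio analysis.

* **Shape PCA** is the eigendecomposition of the covariance of the shape
  vectors; at most p − 1 = 24 eigenvalues are nonzero and percent
  variance is reported over the nonzero spectrum. Eigenvector signs are
  fixed by making the largest-magnitude loading positive. PCA is computed
  on the pooled sample ignoring species labels (it is an unsupervised
  summary).
* **PCA ratio spectrum**: the loadings of one shape PC, ordered. Because
  the coefficient of `ln(x_i/x_j)` along a PC is `v_i - v_j`, the two
  characters at opposite ends of the ordering form the ratio most aligned
  with that component. Confidence intervals come from a nonparametric
  bootstrap over specimens (the resampling unit is the specimen, the most
  defensible reading of a bootstrap "of the original values"); each
  resampled eigenvector is matched to the original by component index and
  sign-aligned to it before quantiles are taken. The point estimate is
  clamped into its interval, so CIs always contain it even at extreme
  bootstrap skew.
* **Allometry ratio spectrum**: the OLS slope of each shape variable on
  isosize. The slopes sum to zero algebraically (the shape variables do),
  and vanish exactly under isometric growth.
* **LDA ratio extractor**: for two groups (single species or pooled
  unions), every unordered character pair is scored by the standard
  distance of its log-ratio, `D = |mean_A(r) - mean_B(r)| / s_pooled(r)`.
  The best pair maximizes D; the second-best is the maximal pair sharing
  no character with the best, mirroring the convention of reporting two
  disjoint ratios per comparison. The observed per-group min–max ranges
  of the ratios are reported so that overlap can be judged. Alongside the
  per-ratio D, the standard distance along the full multivariate LDA axis
  is reported, since it is ambiguous which of the two a given published
  table contains; both are in the output.

**The δ statistic.** δ summarizes whether group separation is size- or
shape-driven. It is implemented as the absolute cosine between the
two-group LDA discriminant and the isometric direction (1, …, 1),
measured in the Mahalanobis geometry of the pooled within-group
covariance Σ:

    delta = |dmu' S⁻ 1| / sqrt((dmu' S⁻ dmu)(1' S⁻ 1))

where `dmu` is the group mean difference of the log-measurements. The
Euclidean cosine was considered and rejected: only the Mahalanobis form
makes δ exactly 1 for groups that differ by a pure size factor (mean
difference proportional to the isometric vector) regardless of the
covariance — which is the defining behavior of the statistic — while
pure-shape separation drives it toward 0. A singular pooled covariance
(fewer specimens than characters) falls back to the Moore–Penrose
pseudo-inverse with a logged warning.

## Geometric morphometrics

Landmark data enter and leave in the plain-text TPS format (LM=/ID=
records; IMAGE=/SCALE= lines are ignored). The seven forewing landmarks
follow the standard venation scheme (submarginal, marginal, postmarginal
and stigmal veins, wing tip, posterior margin).

Generalized Procrustes analysis iterates: center; scale to unit centroid
size (full Procrustes scaling); rotate each configuration onto the
current consensus by the SVD-optimal rotation with reflections excluded
(wings come from one body side — a reflection would be anatomical
nonsense); update the consensus as the rescaled mean. Convergence is a
consensus RMS change below 1e-10 (cap 100 iterations; typical data
converge in fewer than 10). The objective — summed squared distance of
the aligned configurations to their mean — is non-increasing across
iterations because each half-step is an exact minimizer. Because GPA is
only defined up to a joint rotation, the final fit is reported in a
canonical frame (consensus principal axes on the coordinate axes, sign
fixed by the farthest landmark), which makes the output invariant to
similarity transforms of the input to numerical precision.

Downstream analyses use the orthogonal projection of the aligned
configurations onto the tangent plane at the consensus. The projection
linearizes the unit-size constraint, so the coordinate covariance has
rank at most 2k − 4 = 10 (two translations, one rotation, one scale
removed) and PCA/CVA operate on a well-defined shape space. CVA first
projects onto as many principal components as the pooled within-group
covariance has rank (raw Procrustes coordinates are singular), then
solves the between- versus within-group generalized eigenproblem,
returning at most g − 1 axes.

The covariance-matrix correlation test compares two groups' coordinate
covariance structures: Pearson correlation over the lower-triangle
entries whose row and column belong to *different* landmarks (diagonal
2×2 landmark blocks are excluded as trivially shared), with a null
distribution obtained by permuting landmark labels — x and y of a
landmark move together — in one matrix. The p-value is
`(1 + #{perm ≥ obs}) / (n_perm + 1)`; at least 99 permutations are
required for usable resolution, and identity permutations are redrawn so
the self-comparison p-value attains its theoretical minimum.

## DNA barcoding

Distances use pairwise deletion: a site contributes to a pair only when
both sequences carry an unambiguous base (this is the convention that
tolerates ragged Ns and matches mainstream distance software). The
uncorrected p-distance is the proportion of differing comparable sites;
the Kimura 2-parameter distance is

    d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)

with P and Q the transition and transversion proportions. Saturated
pairs (non-positive logarithm arguments) are undefined: the scalar
function raises an error, the matrix routine returns NA with a warning,
and bootstrap replicates hit by saturation are dropped and counted (more
than 10% dropped triggers a warning).

Haplotype collapsing merges, within species only, sequences that agree
wherever both are unambiguous (greedy, in input order). Distance
summaries (mean, SE = SD of the pairwise values over √#pairs, min, max
per species and species pair) follow the haplotype-based convention;
tree building supports both the haplotype mode and the every-specimen
mode via a flag. The barcode gap compares the largest intraspecific with
the smallest interspecific distance and reports the realizing pairs.

Neighbor joining is canonical (Q-matrix criterion, ties broken by the
smallest index pair); a negative branch length is clamped to zero with
the deficit moved to its sister edge so path lengths through the joined
node are preserved. On additive matrices topology and branch lengths are
recovered exactly — the suite verifies this on 200 random trees.
Bootstrap support resamples alignment columns, rebuilds the tree, and
scores each internal edge of the full-data tree by the percentage of
replicates containing the same bipartition; labels below 75% are omitted
from the rendered tree by default but all values are returned.

A pure ("simple") diagnostic character is a position/state pair carried
by every member of one species and by no specimen outside it, in 1-based
alignment coordinates. Members with an ambiguous base at a position are
ignored there, but any within-species polymorphism (two or more
unambiguous states) disqualifies the position for that species; the full
per-position state context is reported alongside. All-gap columns are
skipped and counted.

## The synthetic generator: what it emulates, and what it does not

A `scenario` fixes three species models and a master seed. Draws are
taken per artifact and per species from fixed seed offsets, so adding a
species never perturbs the other species' data.

* **Measurements**: specimen log-size `s ~ N(0, size_sd)`; character
  `c = exp(mu_log + slope·s + eps)`, `eps ~ N(0, 0.05)` — small relative
  measurement noise typical of linear morphometrics. The default species
  differ by shifts of 0.06–0.10 log units on a few ratio-defining
  characters, chosen so the best discriminating ratios reach standard
  distances in the low single digits, the regime reported for real
  cryptic wasp complexes; they are not calibrated to reproduce any
  published table.
* **Landmarks**: species mean shape plus isotropic N(0, noise_sd = 0.01)
  per coordinate, then a random similarity transform (rotation uniform on
  [0, 2π), translation uniform in [-1, 1]², scale log-uniform in
  [0.5, 2]) whose parameters are recorded — exercising the full
  invariance GPA must deliver.
* **Sequences**: a fixed synthetic 557-nt ancestor stored with the
  package (pseudo-random, AT-rich; *not* a real accession) receives each
  species' planted diagnostic states — the published per-species COI
  diagnostic map of the *Encyrtus* complex, with the one polymorphic
  position excluded for the affected species — and then per-site
  polymorphism at rate 0.006 with transition:transversion odds 4:1,
  giving mean intraspecific distances near 1%. At every position where
  exactly one species is planted, the ancestor is pinned to the state the
  other two species share, so the planted map is *exactly* the
  recoverable pure-diagnostic map. Default sample sizes 17/48/55 follow
  the published per-species COI sample counts.

The generator targets the statistical structure the analyses assume, not
biological realism: there is no coalescent or tree-based sequence
evolution, no correlated measurement error, no landmark digitization
bias. Between-species sequence divergence comes only from the planted
diagnostics plus noise (≈5–7%), deliberately below the ≈10% seen in real
COI data, since variable-but-not-diagnostic positions are out of the
generator's scope. A green test therefore establishes that the
*algorithms* recover planted truth under the stated noise model — not
that the defaults mimic any particular empirical dataset.

## Numerical choices

* Eigen-spectra treat eigenvalues below `1e-10 × max` as zero; percent
  variance is over the nonzero spectrum.
* `lda_ratio_extract` reports non-separability when the maximal standard
  distance is below 1e-8 (exact zeros are unattainable in floating
  point).
* Ratio-spectrum bootstrap CIs use the 2.5%/97.5% empirical quantiles.
* GPA convergence: consensus RMS change < 1e-10, max 100 iterations.
* NJ ties: smallest index pair in the current matrix, making results
  order-deterministic.
* Degenerate inputs fail loudly: coincident landmarks, all-zero
  within-group variance, constant isosize, saturated distance pairs,
  conflicting planted diagnostics.

## Pipeline determinism

`run_pipeline()` executes generator → morphometrics → MRA → GMA →
barcode from a single JSON-serializable config. All seeds are explicit
(derived from the config seed by fixed offsets per stage); identical
configs produce byte-identical `summary.json` files, which the test
suite asserts. A stage failure aborts with a stage-scoped error and
leaves a `STALE` marker listing partial outputs; `run.log` records md5
hashes of all inputs and outputs.

## Known limitations

* The Tukey stage assumes approximate normality within species on the raw
  measurement scale; heavy-tailed measurement error will inflate the
  family-wise error.
* δ is a summary of one discriminant direction; with more than two
  groups it is defined per comparison, not globally.
* The covariance-correlation permutation test conditions on the observed
  group covariances; with very small groups the matrices themselves are
  noisy and the test is conservative.
* Bootstrap support is computed on the NJ tree only; no likelihood or
  Bayesian tree inference is included (out of scope), and no multiple
  sequence alignment — inputs must be pre-aligned and trimmed.
* TPS parsing supports the LM=/ID=/IMAGE=/SCALE= subset of the format;
  curves and semilandmarks are not supported.
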