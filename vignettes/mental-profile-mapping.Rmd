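---
title: "Mental profile mapping: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mental profile mapping: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmap)
```

## The model

`mpmap` treats an author's verified documents as repeated multivariate
measurements of one mind. Documents are scored against a category
dictionary — each variable is the percent of the document's words falling
in one psychological category — and the variables are grouped into 13
clusters of psychological processes (`default_cluster_scheme()`). Within
each cluster the author's documents are assumed to scatter around a
stable *psychological center*: a multivariate mean μ with covariance Σ
capturing both the author's natural variation over time and the
substantial inter-correlation of language measures (positive and negative
emotion are not orthogonal; pronoun classes covary). The Mahalanobis
distance is used precisely because it absorbs that covariance structure;
a Euclidean distance would double-count correlated variables.

For a document x in cluster c with p member variables,

* D² = (x − μ̂)ᵀ Σ̂⁺ (x − μ̂),
* score = 100 · P(χ²_p > D²).

If x is truly a draw from N(μ, Σ) and μ, Σ were known, D² ~ χ²_p and the
score is exactly uniform on (0, 100); with estimated centers it is
approximately so (this calibration is tested, see below). The score
therefore reads as a typicality percentile: 100 at the center, near 0 for
gross outliers. The 13 scores are aggregated by their **median** (the
*grand score*). The median, not the mean, is deliberate: one or two
extreme clusters can reflect superficial differences (theme, setting)
rather than a different mind, and the median resists them. The
mean–median correlation is reported by `internal_consistency()` so users
can verify the choice is immaterial on their data.

The same function reports raw (covariance-based) Cronbach's alpha over
the 13 scores. A coherent profile — documents drifting from the center in
unison across processes — justifies collapsing 13 scores into one; alpha
quantifies that coherence. Raw alpha is the default because it is the
conventional default of the major statistics packages; the standardized
variant is computed alongside for comparison.

### Verification by insertion

A questioned work is **inserted** into the candidate's feature table and
the whole analysis is rerun (`insert_and_score()`). The inserted work
participates in center and covariance estimation — the "leave-in"
convention — because that is the operational situation: the investigator
entertains the hypothesis that the candidate wrote it. Leave-in is also
conservative: the insertion pulls the center toward itself, so a genuine
outlier must stand out despite having contaminated the estimate. Its rank
by ascending grand score (1 = worst fit in the map) is the headline
output; rank ties are broken against the insertion so detection is never
inflated. A base-only reference analysis under the same seed is always
computed alongside, so averaging base-work scores across several
insertion runs (`average_runs()`) can be compared against the
no-insertion map.

## Estimation choices

**Bootstrapped center.** The center is the mean of B = 1000 bootstrap
resample means (rows resampled with replacement, resample size = number
of documents). In expectation this equals the sample mean; the bootstrap
layer buys robustness of the procedure as published and a natural route
to resampling diagnostics. B is configurable; 1000 is the default
throughout.

**Covariance.** Σ̂ is the ordinary n−1 sample covariance of the original
(non-resampled) rows. It is *not* bootstrapped: with 16–21 documents
against clusters of up to 13 variables, resampled covariances are
frequently singular and their pseudo-inverses unstable, whereas the
deterministic sample covariance keeps D² reproducible.

**Pseudo-inverse.** Because the number of documents is close to the
largest cluster dimensionality, Σ̂ can be singular or nearly so. The
Moore–Penrose pseudo-inverse is used, discarding eigenvalues below 10⁻⁸
of the largest. An optional ridge term (`ridge · mean(diag(Σ̂))` added to
the diagonal, default 0) is available for users who prefer shrinkage to
truncation. Degenerate corner cases are defined, not errors: an
all-identical cluster has Σ̂ = 0, whose pseudo-inverse is 0, so every
document sits at distance 0 and scores 100.

**Chi-square orientation and df.** The mapping is made explicit as the
*upper-tail* probability times 100, with df = the cluster's
dimensionality. This is the only orientation consistent with the score's
published endpoints (center → 100, far → 0), and df = p is the exact null
distribution for known parameters. Negative D² can arise from floating
point noise and is clamped to zero with a warning.

**Projection.** The 2-D map is a principal components analysis of the
column-standardized score matrix, signs fixed so each component's
largest-magnitude loading is positive (deterministic orientation).
It exists for visualization only; the projection distorts distances and
no inference is based on it.

## Text processing conventions

The reference scoring software's exact tokenizer is unpublished, so the
package fixes conventions and documents them: tokens are maximal runs of
letters with internal apostrophes ("it's" is one token, "'tis" loses its
leading apostrophe), hyphens and digits separate tokens, and everything
is lowercased. Dictionary entries match literally or, with a trailing
`*`, as prefixes; when the same string is both a literal entry and a
prefix stem, the literal wins for tokens equal to it. Documents are
segmented into chunks of ~250 words for unmasking; a final remainder
shorter than half the target merges into the previous chunk, since a
50-word tail is not a usable classification unit. The four proprietary
summary variables (Analytic, Clout, Authentic, Tone) cannot be computed
from an open dictionary; `Sixltr` is computed directly (percent of tokens
longer than six letters), the other four are accepted as externally
supplied columns and otherwise dropped from the scheme with a warning.
Clusters left with fewer than two variables after drops are a
configuration error — with the default scheme this means dictionary-only
tables run on the 11 clusters that need no proprietary input
(`mpmap:::reduced_default_scheme()`).

## The unmasking baseline

The baseline models the *depth of difference* between two segment sets.
Per iteration: 5-fold stratified cross-validated accuracy of a linear SVM
(C = 1, features standardized per comparison), then removal of the k = 2
most positive and k = 2 most negative weights of an SVM refit on all
current data — the classical elimination scheme, chosen over averaging
the CV models' weights because it is simpler and deterministic. Ten
iterations are run by default ("folds" in the original description are
read as elimination iterations, which is what the cited algorithm does;
CV fold count is a separate, configurable parameter). The meta-learner's
curve features are the f accuracies, linear and quadratic least-squares
trend coefficients, and the lag-1/lag-2 accuracy differences — the
published "degradation Δ scores" are not defined precisely, and
first/second-lag drops are the plain reading adopted here. Verdict
probabilities are Platt-calibrated SVM outputs averaged over 20
randomized repetitions by default.

## What the synthetic generators emulate

Generators are fully seeded and record their parameters (corpus writers
emit a `GENERATOR` sidecar file).

* `gen_author_feature_table()`: documents as multivariate normal draws
  around an author-specific mean, clipped to the [0, 100] score range.
  Defaults place means around 50 with between-author SD = 5 and
  within-author SD = 2.5 — authors distinct but overlapping, the 2:1
  ratio mirroring the handful-of-contemporaries setting of the case
  study (6 authors, 15 documents each in the default benchmark).
* `gen_segment_corpus()`: adds the layer unmasking exploits — per-work
  "superficial" offsets (default: 4 randomly chosen variables, SD = 3×
  the segment noise) on top of the author profile. Same-author
  comparisons are then separable mainly through a few variables whose
  removal collapses accuracy; different-author comparisons stay
  separable profile-wide.
* `gen_toy_corpus()`: renders actual text with known expected category
  rates, so the tokenizer–scorer path is testable end to end against
  binomial error bounds.

What they do **not** emulate: real word-frequency distributions (category
scores are drawn directly, not counted from Zipfian text), genre and
period effects, spelling variation, non-normal and skewed score
distributions, or correlated covariance structure across clusters.
Passing the synthetic checks therefore demonstrates that the machinery is
correct and calibrated under its own assumptions — not that any
particular real corpus satisfies those assumptions.

## Calibration evidence and problem sizes

The test suite and `scripts/acceptance.R` compute (sizes chosen to keep a
full run within a few minutes on one CPU):

* the packaged reference matrix reproduces its published arithmetic
  exactly (all 21 grand scores are the medians of their 13 cluster
  scores; verified-play mean/SD 48.56/16.41);
* a candidate offset 3 within-author SDs from the center ranks worst in
  ≥ 90% of 100 seeded insertion runs (16-work base corpora, B = 1000),
  with power monotone in the offset;
* same-author degradation exceeds different-author degradation in ≥ 90%
  of 50 seeded runs, and the curve meta-learner holds accuracy ≥ 0.85
  and kappa ≥ 0.6 on the default benchmark (6 authors × 15 works × 8
  segments, 5 works per author held out, 3 randomized repetitions);
* under null single-author sampling (n = 500 documents) no cluster's
  score distribution is rejected as non-uniform by a Kolmogorov–Smirnov
  test at the 0.01 level.

One caveat surfaced by the reference matrix: statistics recomputed from
scores printed at two decimals can shift in the last digit relative to
values computed on unrounded data (the published alpha of .66 computes to
0.646 from the printed matrix). The package reports what it computes.

## Limitations

* Low grand scores flag *difference*, not non-authorship: illness, genre
  shifts, heavy revision or collaboration also move a document away from
  the center. The package reports scores, ranks and flags — never
  verdicts about people.
* With n documents close to the cluster dimensionality the covariance is
  near-singular; scores remain defined via the pseudo-inverse but become
  sensitive to single insertions. Stability (averaged insertion runs vs
  base-only map) is assessed at 20 works, where every cluster is
  comfortably full-rank.
* The Mahalanobis score is direction-blind: it says a cluster's
  composition is atypical, not how. Interpretation requires returning to
  the underlying variables after `decompose_profile()` (cutoff 20 ≈ the
  bottom fifth of the typicality scale, as published).
* Chi-square calibration assumes approximate multivariate normality of
  the cluster scores; heavy-tailed real features will make low scores
  more common than the nominal uniform rate.
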