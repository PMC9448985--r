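---
title: "Methods: geometric-complement prediction of lncRNA-disease associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric-complement prediction of lncRNA-disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Experimentally confirmed associations between long non-coding RNAs (lncRNAs)
and diseases are scarce: a typical curated collection covers a few thousand
pairs over hundreds of lncRNAs and diseases, so the lncRNA-disease adjacency
matrix `LD` (here `l = 240` lncRNAs by `d = 412` diseases with 2697 ones,
about 2.7% density, in the canonical configuration) is overwhelmingly zeros —
and a zero means *unobserved*, not *absent*. The package scores the
unobserved pairs by combining two auxiliary evidence layers that are much
easier to obtain: lncRNA-miRNA interactions `LM` (l x m) and miRNA-disease
associations `MD` (m x d), with `m = 495` miRNAs shared between them.

## The model

**Geometric complement.** Two-hop evidence through shared miRNAs is
propagated into the lncRNA-disease matrix:

$$\mathrm{LMD}_{ij} = \frac{\mathrm{LM}_{i\cdot} \cdot \mathrm{MD}_{\cdot j}}
{\lVert \mathrm{LM}_{i\cdot}\rVert_1 + \lVert \mathrm{MD}_{\cdot j}\rVert_1},
\qquad
\mathrm{LD}^{new}_{ij} = \max(\mathrm{LD}_{ij}, \mathrm{LMD}_{ij}).$$

The numerator counts miRNAs interacting with lncRNA *i* and associated with
disease *j*; the denominator is the pair's total miRNA degree. Because a dot
product of binary vectors cannot exceed the smaller of the two L1 norms,
`LMD` is provably bounded in `[0, 0.5]`, so the max-merge never alters an
observed positive: `LD_new == 1` exactly where `LD == 1`. When a pair has no
miRNA evidence on either side the ratio is 0/0; we define it as 0 and count
such cells in a warning rather than produce NaN.

**Similarity fusion.** Each entity is described by how its association
profile relates to the others':

- Jaccard similarity on the binary profiles,
  `|supp(a) ∩ supp(b)| / |supp(a) ∪ supp(b)|`. The union denominator is the
  standard reading of the coefficient; a Dice-like variant dividing by
  `|supp(a)| + |supp(b)|` is available as `denominator = "sum"` because the
  verbal description of the coefficient ("the sum of the number of partners")
  admits that reading too. Two all-zero profiles score 0, not NaN: absence of
  evidence is not evidence of similarity.
- Gaussian interaction profile (GIP) kernel,
  `exp(-λ ||p_i - p_j||²)` with `λ = λ̃ / mean_i ||p_i||²`. The
  normalization makes the bandwidth scale-free; the raw control `λ̃`
  defaults to 1. An all-zero matrix leaves `λ` undefined and is rejected.

The two are fused per entity kind by elementwise maximum (`fuse_max()`),
yielding the lncRNA similarity LFJ and disease similarity DSJ. Similarities
are computed from the *original* `LD` by default: the kernel definitions
reference the observed association profiles, and computing them after
complementation would mix score scales into the binary profiles. Since this
ordering is a genuinely open choice, `similarity_source = "complemented"`
computes them from `LD_new` instead (GIP on the real-valued profiles,
Jaccard on their support).

**Feature representation.** lncRNA *i* is the concatenation of row *i* of
`LD_new` (length d) and row *i* of LFJ (length l); disease *j* is column *j*
of `LD_new` (length l) followed by column *j* of DSJ (length d). Both widths
are `l + d` (652 at the canonical scale). Each entity kind is compressed by
its own single-hidden-layer autoencoder
`input(p) -> hidden(latent, sigmoid) -> output(p, sigmoid)` trained to
minimize the mean squared reconstruction error. The layer vocabulary in
descriptions of such models is ambiguous between one and two hidden layers;
we implement the minimal one-hidden-layer reading — the encoder *is* the
hidden layer — and note that a deeper stack is a strict extension, not a
different model. All feature values already lie in `[0, 1]` (binary entries,
complement scores ≤ 0.5, similarities ≤ 1), so the sigmoid output range
needs no rescaling.

Training hyperparameters are not part of the model definition, so they are
plain arguments with conventional defaults: Adam with learning rate `1e-3`,
200 epochs, batch size 32, Glorot-uniform initialization. The full-data MSE
is recorded every epoch; tests assert a strict first-to-last decrease and
non-increase after 5-epoch smoothing (mini-batch noise makes per-epoch
monotonicity too strong a claim). Training and encoding are exactly
reproducible for a fixed seed. The default latent width is 256 per side — the
optimum of the 16/32/64/128/256/512 sweep exposed by
`run_dimension_sweep()` — giving 512-dimensional pair features.

**Classification.** All observed pairs are positives; an equal number of
unobserved pairs is drawn uniformly without replacement as negatives (the
balanced set has 5394 rows when `LD` has 2697 ones). A classification random
forest (ranger engine) is trained with the classical defaults, 500 trees and
`mtry = floor(sqrt(p))` — "default values" are implementation-relative, so we
pin these explicitly and record them in every report. A pair's score is the
fraction of trees voting positive. Alternative classifiers plug in through
`forest_classifier()`'s interface (a `fit`/`score` pair); only the forest
ships enabled.

## Evaluation protocol and leakage

`gclda_cv()` runs stratified k-fold cross-validation (default k = 5) of the
balanced sample set. AUC is the normalized Mann-Whitney rank statistic —
exactly the concordant-pair count, which is how the tests verify it — and
AUPR is step-wise precision-recall integration; recall, accuracy and F1 use
a 0.5 score cutoff (the cutoff is a reporting convention, not a fitted
parameter). Fold-averaged metrics are the default; `pooled = TRUE` computes
them once over all held-out scores, since which of the two a published
average refers to is often unstated.

Two protocol details materially affect the numbers and are explicit flags:

- **Negative resampling.** The default draws one negative set before
  splitting, mirroring a single fixed training set of 5394 samples;
  `per_fold_negatives = TRUE` re-draws negatives within each fold.
- **Feature leakage.** By default the complement, similarities and
  autoencoders are computed from the *full* `LD` — the natural reading of a
  pipeline that builds features once, but it leaks test-pair membership into
  the features (a held-out positive contributes its own 1 to `LD_new` and to
  the similarity profiles). `strict = TRUE` rebuilds the entire feature
  pipeline per fold from the training folds' positives only. Every report
  carries a `leakage` field naming the protocol that produced it, and the
  paired test asserts the expected direction: strict AUC does not exceed
  default AUC on average.

## The synthetic generator

`generate_network()` plants a shared low-rank structure: non-negative latent
factors `U (l x r)`, `V (m x r)`, `W (d x r)` with gamma(2, 2) entries
generate propensities `U Wᵀ`, `U Vᵀ`, `V Wᵀ`, binarized by the quantile
threshold that hits each layer's target density. Gamma factors keep the
propensities non-negative association intensities; quantile thresholding
controls density exactly regardless of scale. Defaults are the canonical
scale — `l = 240`, `m = 495`, `d = 412`, LD density `2697/(240·412)` — with
rank 6. The auxiliary layer densities are not dictated by the canonical
data, so both default to 3%, the same order of sparsity as the LD layer and
typical of curated interactomes. A configurable fraction of LD ones can be
flipped as noise, and a held-out fraction is removed into a truth set that
stays among the prediction candidates — the same situation as discovering a
novel association.

Because all three layers share factors, the geometric complement correlates
positively with the held-out truth (a tested invariant), which is the
mechanism that makes end-to-end recovery measurable: at the canonical scale
with rank 6 and 10% holdout, mean 5-fold CV AUC across five seeds exceeds
0.85 while a label-permuted control stays near 0.5, and held-out pairs rank
well above random among their diseases' candidates. The permutation control
is run on one seed: the null needs calibration, not averaging, and a
noise-label forest is by far the slowest fit in the suite. What passing
these tests does *not* show: real networks are not low-rank plus uniform
noise — their degree distributions are heavy-tailed, their ascertainment is
biased toward well-studied diseases, and their layers disagree more than
shared factors allow. Recovery here validates the machinery, not clinical
performance.

## Numerical choices and degenerate inputs

- 0/0 conventions: Jaccard of two empty profiles is 0; a complement cell
  with no miRNA evidence is 0 (warned and counted); an all-zero `LD` makes
  the GIP bandwidth undefined and is an error, not a silent 1.
- Candidate ranking breaks score ties by lncRNA name so rankings are
  deterministic and reproducible byte-for-byte.
- Registry alignment defaults to union-with-zero-fill: the complement
  tolerates zero rows/columns, whereas intersection silently discards
  evidence. How identifiers should be matched across source files is not
  derivable from the data, so union is a package choice, surfaced as
  `mode`.
- Mid-ranks make the AUC exact under ties; the AUPR integration treats a
  tie group as one threshold.
- All randomness (weights, shuffles, sampling, folds, trees) derives from
  user-visible seeds; two runs with one configuration are identical.

Test problem sizes: property tests run on networks of 2-9 entities per kind
where brute-force oracles are exact; pipeline behaviour tests use 30-40
entities per kind with reduced epochs and trees; the recovery tests run the
full canonical scale with default settings across five seeds.

## Known limitations

- The geometric complement is a single two-hop product; no multi-hop or
  iterative propagation.
- No disease semantic (ontology-based) or lncRNA functional similarity; the
  profile kernels only see the association matrix.
- The default protocol's feature leakage (above) inflates CV metrics
  relative to a prospective setting; use `strict = TRUE` for honest
  held-out numbers at extra cost.
- Negative "samples" are unlabeled pairs, some of which are true
  associations; balanced sampling treats them as negatives regardless.
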