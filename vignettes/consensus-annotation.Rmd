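---
title: "Consensus GO annotation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus GO annotation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Automated protein function predictors disagree: deep-learning methods,
sequence-similarity transfer and domain scans each have characteristic
blind spots, and their probability scores are not comparable across tools.
`goconsensus` treats the union of their gene-term annotations as a set of
candidates and re-scores every candidate with a supervised model whose
features describe how strongly the *other* methods agree with it, measured
through the Gene Ontology's own graph structure. The output is a single
consensus set split into confident and rejected annotations.

## The re-scoring model

**Ontology.** The GO is three rooted DAGs (molecular function, biological
process, cellular component). Only the `is_a` and `part_of` relations are
used for ancestor propagation; `regulates`-family edges are parsed but
never traversed, and propagation never crosses a namespace boundary.
Ancestor closures are reflexive: a term is its own ancestor, which makes a
term a perfect support for itself.

**Information content.** For a propagated reference corpus (a GAF file or
any annotation table), the information content of a term is

$$\mathrm{IC}(t) = -\log_2 \frac{n_t}{n_{\mathrm{root}(t)}}$$

where $n_t$ counts proteins annotated with $t$ after propagation. Counting
*after* propagation makes IC monotone non-increasing toward the root,
which is what bounds Lin similarity by 1; normalising by the namespace
root's count pins every root at IC 0. The alternative normalisation by the
corpus' total annotation count (the literal relative-frequency reading) is
available via `compute_ic(denominator = "corpus")`; it shifts all ICs by a
namespace constant, leaves Lin similarity unchanged, and is provided for
comparability with tools that report corpus-frequency ICs. The default
log base is 2, so ICs and Smin are in bits; Lin similarity is base-invariant
(tested explicitly against base $e$).

Terms absent from the reference receive the IC of a single pseudo-count,
$\log_2 n_{\mathrm{root}}$, so that similarities stay defined for novel
predictor terms.

**Lin similarity.** For two terms in the same namespace,

$$\mathrm{Sim}(a, b) = \frac{2\,\mathrm{IC}(\mathrm{MICA})}{\mathrm{IC}(a) + \mathrm{IC}(b)}$$

with the MICA the most informative common ancestor over the reflexive
closure. Boundary conventions, applied identically in the implementation
and in the brute-force test oracle: identical non-root terms score 1 even
at IC 0 (an identical term is a perfect match however common it is);
root-against-root and distinct zero-IC pairs score 0. MICA ties break to
the lexicographically smallest accession.

**Support features.** Every unique (protein, term) predicted by any input
method becomes one candidate row. The row's *source* is the predicting
method with the highest score (ties resolved by registry order; methods
that co-predicted the identical term become supports with similarity 1 and
their own score). Every other method contributes its most similar term for
the same protein — provided the similarity reaches the floor of 0.5 — as a
4-tuple (present, score, IC, similarity); methods with nothing similar
enough contribute an all-zero slot. The numeric layout is fixed by the
method registry: a source one-hot, the source score and IC, then one
support slot per registered method in registry order (the source's own
slot stays zero). Support search ties break by higher similarity, then
higher candidate IC, then lexicographic accession, so feature tables are
invariant to input record order.

Inputs are used as the predictors emit them (leaf-level); propagating them
first would flood every row with shared ancestors and destroy the support
signal.

**Classifier.** One model per namespace, because score scales and class
balance differ strongly across the three ontologies and the evaluation
thresholds are per-ontology anyway. Each model is adaptive boosting
(SAMME) over depth-2 CART base learners at learning rate 1 — for two
classes SAMME is exactly discrete AdaBoost — with probabilities calibrated
by 10-fold cross-validated sigmoid (Platt) scaling: ten boosted ensembles
are fit on nine folds each, a logistic map from ensemble margin to
probability is fit on the held-out fold, and prediction averages the ten
calibrated probabilities. Training labels come from a propagated gold
standard: a row is positive when its term lies in the propagated gold set
of its protein; proteins absent from the gold standard are dropped rather
than treated as negatives.

The boosting round cap defaults to 500, which is past the point of
diminishing returns on corpora of a few thousand feature rows; the cap is
a plain argument (`n_estimators`) and can be raised to the hundreds of
thousands the algorithm tolerates for very large corpora. Rounds also stop
early when a base tree fits perfectly or does no better than chance.
Fitted trees are stored as plain split/leaf parameters, so saved models
contain no code objects and round-trip exactly.

**Consensus split.** Scored candidates at or above 0.5 are confident, the
rest rejected; both are reported, since the rejected set is what a user
audits. Per-namespace threshold overrides are supported because the
Fmax-optimal cutoffs per ontology typically sit near but not exactly at
0.5.

## Evaluation

Protein-centric, in the CAFA style. Predictions and gold standard are
propagated and namespace roots removed; at each threshold of a descending
grid (step 0.01, endpoints included) precision is averaged over proteins
with at least one surviving prediction and recall over *all* benchmark
proteins. Fmax is the maximum F1 over the grid (ties at the lowest
threshold); AUPR is the trapezoidal area over recall-sorted points,
anchored at zero recall with the precision of the highest covered
threshold, which renders a constant-score predictor (a single curve point)
as a rectangle. Smin is $\min_\tau \sqrt{ru(\tau)^2 + mi(\tau)^2}$ with
remaining uncertainty and misinformation as per-protein averages of IC
mass, unweighted, in bits. Bootstrap confidence intervals resample
proteins (the metrics' sampling unit) with replacement, 10,000 replicates
by default, percentiles 2.5/97.5.

Re-evaluation accounting classifies each input method's candidates as
TP/FP/TN/FN at the method's own threshold (its Fmax argmax, typically),
then re-classifies them at the consensus threshold. Truth is fixed, so
flows stay within truth strata and flows out of each class sum exactly to
the baseline class counts.

## The synthetic benchmark

The generator builds what the pipeline needs and nothing more: three
random rooted DAGs (one per namespace, ~150 terms each by default, depth
6, one `is_a` parent per term plus occasional `part_of` shortcuts), a gold
standard of 1000 proteins with on average 4 deep-leaning leaf terms per
namespace (sampling weight grows with depth squared, mimicking the
specificity of curated annotation), and four predictors spanning the
realistic failure modes: a reliable method (recall 0.8 / precision 0.8), a
decent one (0.7 / 0.6), a noisy one (0.5 / 0.3) and a constant-score
domain-scan-style method (0.4 / 0.5, every score 1). Scores are two-level
(centred on the method's positive predictive value) with Gaussian noise,
so a perfect noise-free method emits exactly the gold leaves at score 1.
False positives are drawn uniformly from non-gold terms by default; a
"hard" mode draws them from the semantic neighbourhood (Lin ≥ 0.2) of the
true terms to stress the support features. The gold standard doubles as
the IC reference corpus, mirroring how an annotation database serves both
roles in practice.

Everything is a pure function of (config, seed): generation runs under a
private RNG state and restores the caller's stream.

What passing on this benchmark does **not** show: real GO topology (45k
terms, heavy multiple inheritance, inter-ontology links) is not mimicked;
real predictors err in correlated, protein-family-structured ways rather
than independently per term; and real scores are far worse calibrated than
the simulated ones. Results on the benchmark demonstrate that the
machinery is correct and that the consensus logic extracts agreement
signal — not that any particular Fmax will transfer to a real proteome.

## Numerical choices and degenerate inputs

* Duplicate (predictor, protein, term) records collapse to the maximum
  score everywhere, making all readers order-independent.
* Propagation carries the maximum score over descendants, preserving the
  probability interpretation; it is idempotent.
* Obsolete terms are remapped via `replaced_by` when present, otherwise
  dropped with a reported count; alternate accessions resolve to their
  primary term before any computation.
* Calibration folds with a single class or constant margin fall back to a
  Laplace-smoothed intercept instead of a degenerate logistic fit.
* Empty inputs are legal where they are meaningful (empty GAF, empty
  feature table) and errors where they are not (empty gold standard,
  empty IC reference).
* Training uses one integer seed for fold assignment; the experiment
  driver derives large-offset sub-seeds for ontology, gold and each
  predictor so the stages are independently reproducible.

## Problem sizes

The test suite exercises the full pipeline at the study scale of the
recovery experiment — 1000 proteins, ~150 terms per namespace, four
methods, a 50/50 train/held-out split, 500 boosting rounds — and verifies
oracle equivalences (ancestors, Lin similarity, feature rows, evaluation
metrics) on fixtures up to ~200 terms and 20 proteins where brute force is
exact and fast. Bootstrap checks in the suite use a few hundred replicates;
the default for analysis remains 10,000.

## Known limitations

* Calibration is evaluated in decile bins on held-out data; at the default
  study scale the maximum bin deviation is well under 0.1, but the middle
  bins are sparse (the score distribution is strongly bimodal) and the
  deviation fluctuates by a few hundredths across seeds.
* The labelling rule (propagated gold membership) treats unannotated terms
  of annotated proteins as negatives; under the open-world reality of GO
  annotation some of these are unknown positives, so trained models are
  conservative near the root of sparsely annotated branches.
* `part_of` edges crossing namespaces (rare in real GO) are ignored for
  propagation by design; annotations relying on them will evaluate as
  namespace-local.
* The CLI reads whole tables into memory; proteome-scale runs are bounded
  by the all-pairs similarity step within each protein's term set, which
  is quadratic in terms-per-protein (cached per pair, so cheap in
  practice).
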