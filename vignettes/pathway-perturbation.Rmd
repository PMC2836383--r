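---
title: "Pathway perturbation scoring: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway perturbation scoring: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmarker)
```

## The model

`pathmarker` works at the level of *pathway activity*. For sample $i$ and
pathway $k$ with member genes $g \in MP_k$, the activity level is the
arithmetic mean of the sample's expression values over the pathway's
measured member genes,

$$L_{i,k} = \frac{1}{|M_{i,k}|}\sum_{g \in M_{i,k}} x_{g,i},
\qquad M_{i,k} = \{\,g \in MP_k:\ g\ \text{measured in sample } i\,\},$$

and the perturbation score of a pathway is the unsigned two-sample
$t$-statistic comparing its $L$ values between the two clinical classes,
$\mathrm{psc}_k = |t_k|$. The signed $t$ is retained throughout so users can
separate pathways whose mean expression rises in class A from those where it
falls.

Two modelling assumptions are worth making explicit:

* **Input expression is taken as-is.** Values are assumed log-scale and
  normalized; no background correction, normalization or variance
  stabilization is applied. The method starts from a processed matrix.
* **The plain mean is deliberate.** No gene-level standardization or
  rank transformation precedes averaging (in contrast to rank-based
  single-sample scores such as ssGSEA/GSVA, which we intentionally do not
  reimplement). A mean-shift of a pathway's member genes is exactly the
  signal the score is designed to detect; the simulator plants exactly that
  structure, which keeps the estimator and the generator honest about one
  another.

Genes appearing in several pathways contribute to each independently; shared
genes are instead surfaced explicitly by `overlap_graph()`, which links any
two pathways with a non-empty gene intersection.

### Missing data

The collection-level rule drops only pathways with *no* measured gene in the
matrix. Per-sample gaps are handled by averaging over measured member genes
only; a (sample, pathway) cell with zero measured genes is flagged undefined
(`NA`, `n_genes_used = 0`) and excluded from that pathway's $t$-statistic. A
pathway needs at least two defined $L$ values per class to be scorable;
otherwise it is excluded from ranking with a warning rather than silently
assigned a number.

## Permutation calibration

P-values come from class-label permutation. Design choices:

* **Pooled-variance Student $t$ by default, Welch via `var_equal = FALSE`.**
  "The t-statistic" classically denotes the pooled form, and with balanced
  16/16 classes the two are close; both are exposed because the choice is a
  genuine degree of freedom.
* **One shared set of permutations for all pathways.** All pathway columns
  are evaluated under the same $B$ label permutations (class sizes are
  preserved automatically, since permuting a fixed label multiset cannot
  change its composition). This keeps p-values comparable across pathways
  and is $B$-fold cheaper than independent streams per pathway.
* **Add-one smoothing.** $p = (c+1)/(B+1)$, where $c$ counts permutations
  with $\mathrm{psc}_{null} \ge \mathrm{psc}$. This avoids $p = 0$, gives
  the estimator floor $1/(B+1)$ (about $10^{-4}$ at the default
  $B = 10000$), and is the standard finite-sample permutation estimator.
* **Exhaustive mode.** For small cohorts all
  $\binom{n}{n_A}$ class-A assignments are enumerated and
  $p = c'/T$ with the observed assignment included in the count; a guard
  (default 20 samples) prevents accidental combinatorial blow-ups.
* **Degenerate variance.** A zero pooled variance with zero mean difference
  gives $t = 0$; zero variance with a non-zero difference gives an infinite
  sentinel that ranks above every finite score and enters the permutation
  counting through the same $\ge$ rule. Variance sums below
  $10^{-20}\max(1, \overline{x^2})$ are treated as exactly zero, so constant
  columns hit these rules instead of producing huge $t$ values from rounding
  noise.

One numerical subtlety: the observed assignment is evaluated *inside the
same matrix operation* as the permutations, and the class-B sums are direct
products rather than "total minus class A". Both choices make tied
assignments — the observed one and its mirror image — compare as exact
floating-point ties in the $\ge$ count, which an exact enumeration oracle
requires.

Ranking sorts by descending psc, breaking ties by ascending p-value and then
lexicographic pathway name, so output order is fully deterministic.

## Encoding and classification

Samples are encoded by the $L$ values of the top-$k$ ranked pathways
(default $k = 10$), optionally mixed with individual gene expression rows
for integrated pathway + gene panels. Evaluation is leave-one-out
cross-validation: for each fold, features are z-scored using the training
samples only, and a score for the held-out sample is produced by an
instance-based scorer. No statistic of the held-out sample enters its own
fold; an independently coded fold loop in the test suite asserts this
exactly.

The reference method in this family is KStar, an entropy-based
instance-based learner whose continuous-attribute transform reduces to an
exponential-kernel distance weighting. Its exact blend parameterization is
not reproducible from the literature, so the default scorer here is the
transparent member of the same family: a Gaussian-kernel distance-weighted
nearest-neighbour model with bandwidth $h$ equal to the median pairwise
training distance (parameterless; $h = 0$ degrades to uniform weights). The
scorer is pluggable via the `scorer` argument, so a faithful KStar can be
dropped in.

Class evidence is the *mean* kernel weight per class, and the emitted score
is $\bar w_A / (\bar w_A + \bar w_B)$. Normalizing by class size rather than
summing raw weights keeps the no-information case (all features identical)
at exactly 0.5 for every sample regardless of the fold-wise class imbalance
that leave-one-out induces; with raw sums, held-out members of the larger
class would be scored systematically lower for no informational reason.

AUC uses the Mann–Whitney form — concordant positive/negative pairs plus
half-credit for ties — computed from midranks. `evaluate_combinations()`
exhaustively evaluates every non-empty feature subset up to `max_size`
(guarded at 4), sorted by AUC with deterministic tie-breaking, supporting
single-versus-integrated panel comparisons. No hyperparameter search is
performed anywhere.

## Clustering

`hierarchical_cluster()` is plain agglomerative clustering of samples
(labels unused), defaulting to Euclidean distance and average linkage —
reasonable neutral defaults for activity profiles; complete and single
linkage and a correlation distance are available. Features are z-scored per
pathway by default so large-mean pathways do not dominate the metric.
Samples are sorted lexicographically by id before the distance computation,
which makes the merge tree exactly invariant to input order even under tied
heights. `two_group_purity()` cuts the tree into two clusters at the root
and reports per-cluster class composition; `export_newick()` writes the
tree with branch lengths derived from merge heights for standard viewers.

## The simulator

`simulate_dataset()` emulates the study shape the package targets:

* two balanced classes (default 16 + 16 samples),
* 639 gene sets of 10–100 genes drawn from a 15000-gene background, with a
  small shared gene pool controlling cross-set overlap (default 10% of each
  set),
* 2 sets composed entirely of unmeasured gene ids, exercising the
  at-least-one-measured-gene filter,
* per-gene baselines $\mu_g \sim N(7, 1.5^2)$ and i.i.d. Gaussian noise
  (default $\sigma = 1$) on a log-like intensity scale,
* a mean shift $\delta$ (default 1, in expression units) added to every
  member gene of the planted pathways in class A samples.

All randomness flows from a single seed through separate sub-streams for
membership, baselines and noise, so changing the sample count does not
perturb pathway membership, and identical seeds give bit-identical output.

What it does **not** emulate: gene–gene correlation beyond planted-set
co-shifting, platform artifacts, heavy-tailed or intensity-dependent noise,
probe-level redundancy, or the correlation structure of any real cohort.
Passing tests on this generator therefore demonstrates correctness of the
algorithms and calibration under the stated noise model — not clinical
performance on real expression data, whose headline AUCs depend on the
cohort and cannot be certified here.

The effect is planted at the gene level (not via a latent pathway factor)
because a member-gene mean shift is the minimal structure the $L$-mean
statistic is designed to detect; this keeps recovery tests interpretable.

## Numerical and format choices

* TSV/GCT/GMT/CLS parsers reject malformed input (ragged rows, duplicate
  ids, short GMT lines, dimension mismatches, >2 classes) with positional
  error messages; nothing is silently repaired.
* Gene matching between gene sets and expression rows is exact string match
  after uppercasing both sides (configurable off); duplicate symbols after
  uppercasing are collapsed by mean (or max) before any pathway
  computation.
* All numeric output is written with 12 significant digits, so write/read
  round trips reproduce values well within $10^{-9}$ and fixed-seed runs
  are byte-identical.
* The test and acceptance workloads run at reduced scale (hundreds to a few
  thousand genes, 40–639 pathways, $B$ = 300–2000, 20-seed replicates) —
  sizes chosen so the full suite completes in seconds while leaving every
  statistical check well-powered; the defaults users see remain the
  study-scale values above.

## Known limitations

* The KStar scorer is approximated by a kernel nearest-neighbour model; the
  original entropic transform is not reimplemented.
* Pathway p-values are reported raw (as permutation estimates); no
  FDR/Benjamini–Hochberg adjustment is applied, matching the method's use
  of raw permutation P for pathway ranking.
* Gene-rank-based enrichment (GSEA) is out of scope; externally derived
  gene lists enter only as user-supplied gene features.
* `evaluate_combinations()` is exhaustive and intentionally capped at
  subsets of 4 features; it is a panel comparison tool, not a feature
  selection procedure.
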