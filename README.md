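# pathmarker

Pathway-centric biomarker discovery from two-class expression data.

Given a genes × samples expression matrix (log-scale, normalized), a
collection of gene sets (GMT, e.g. the MSigDB C2 canonical pathways) and a
binary clinical class for each sample (CLS) — for example patients with
post-infarction ventricular dysfunction (EF ≤ 40%) versus without —
`pathmarker` asks which *pathways*, rather than which individual genes, are
most perturbed between the classes, and whether those pathway signals can
encode patients for prognosis.

## Model

For sample *i* and pathway *k* with member genes *g* ∈ MP<sub>k</sub>, the
**pathway activity level** is the plain mean over the pathway's measured
member genes:

&nbsp;&nbsp;&nbsp;&nbsp;L<sub>i,k</sub> = mean { x<sub>g,i</sub> : g ∈ MP<sub>k</sub>, g measured }

A pathway with no measured gene in any sample is dropped (with 32 samples
and 639 pathways of which 637 have at least one measured gene, the
32 × 639 = 20448 mapped sample–pathway instances reduce to
32 × 637 = 20384).

The **perturbation score** of pathway *k* is the unsigned two-sample
t-statistic comparing its L values between the classes:

&nbsp;&nbsp;&nbsp;&nbsp;psc<sub>k</sub> = | t( L<sub>·,k</sub> | class A, class B ) |

(pooled-variance Student form by default; Welch selectable). Significance is
calibrated by permuting the class labels: one shared set of B permutations
(default B = 10000) is applied to all pathways and
P<sub>k</sub> = (c + 1)/(B + 1), with c the number of permutations whose
null psc reaches the observed one; an exact exhaustive mode enumerates all
label assignments for small cohorts. Pathways are ranked by psc, the top-k
(default 10) activity profiles become patient features, and single or
integrated pathway + gene biomarker panels are evaluated with leave-one-out
cross-validated instance-based classification summarized by AUC
(Mann–Whitney form, ties half-credited). Unsupervised hierarchical
clustering of the encoded samples, with Newick export and a two-group
class-purity summary, covers the unsupervised side.

A seeded simulator (`simulate_dataset()`) generates study-shaped synthetic
data — two balanced classes, Gaussian noise on a log-like scale, planted
pathway mean shifts, sets with no measured gene — so the whole pipeline is
testable without external data.

## Worked example

```r
library(pathmarker)

cfg <- sim_config(n_genes = 2000, n_pathways = 120,
                  pathway_size_range = c(5, 30), n_planted = 3,
                  effect_size = 1.5, n_unmeasured_pathways = 2, seed = 42)
paths <- run_simulate(cfg, "demo")
rc <- run_config(paths["expression"], paths["gmt"], paths["cls"],
                 out_dir = "demo/out", B = 2000, seed = 7, top_k = 5)
res <- run_score(rc)
head(res$table, 5)
```

```
  pathway t_signed    psc   p_value rank n_genes_in_data
1  PW0003   24.932 24.932 0.0004998    1              25
2  PW0002   21.492 21.492 0.0004998    2              20
3  PW0001   15.995 15.995 0.0004998    3              11
4  PW0096    7.646  7.646 0.0004998    4              10
5  PW0019    4.702  4.702 0.0004998    5               6
```

The three planted pathways (PW0001–PW0003) take the top ranks, each at the
smallest attainable permutation p-value 1/(B + 1) = 1/2001. `run_score`
also reports the instance accounting (here 32 × 120 = 3840 mapped,
32 × 118 = 3776 after dropping the two unmeasured sets). Panel evaluation
and clustering then read:

```r
ec <- run_encode_classify(res, rc, max_combo = 2)  # subsets of top-5 L values
cl <- run_cluster(res, rc)
cl$purity
```

```
  cluster size  A  B majority_class majority_count
1       1   16 16  0              A             16
2       2   16  0 16              B             16
```

i.e. the unsupervised two-group cut recovers the two clinical classes
16/16 and 16/16 on this synthetic cohort, and the single-pathway panels
built on planted pathways reach LOOCV AUC = 1.

A command-line front end with `simulate | score | encode-classify | cluster`
subcommands lives at `inst/scripts/pathmarker.R` (exit codes: 0 success,
2 usage/input error, 1 internal error).

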