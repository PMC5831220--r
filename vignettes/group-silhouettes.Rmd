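---
title: "Group silhouettes for expression data: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group silhouettes for expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupsil)
```

## The question the package answers

Hierarchical sample clustering (HSC) of an expression matrix is routinely
inspected by eye to judge whether samples separate by some grouping of
interest — sex, strain, disease state, treatment. groupsil replaces that
visual judgement with a number: the silhouette score computed against the
*predefined* groups rather than against clusters found by an algorithm. For
sample $i$ with group $g(i)$,

$$u_i = \underset{j \in g(i),\, j \neq i}{\text{mean}}\, d(i,j), \qquad
  v_i = \min_{h \neq g(i)} \; \underset{j \in h}{\text{mean}}\, d(i,j), \qquad
  s_i = \frac{v_i - u_i}{\max(u_i, v_i)},$$

and the average silhouette $AS = \text{mean}_i\, s_i \in [-1, 1]$. $AS$
near 1 means tight, well-separated groups; near 0, intermingled groups (the
situation in which a two-group differential-expression analysis finds few or
no genes); negative values mean samples sit closer to the other group than
to their own.

Two conventions close the degenerate cases: a sample alone in its group
scores $s_i = 0$, and $s_i = 0$ when $\max(u_i, v_i) = 0$. Both mark the
sample as "indifferent" rather than favouring either sign. With more than
two groups, $v_i$ is the nearest-other-group mean (the standard silhouette
definition); with exactly two it reduces to the mean distance to the other
group.

## Distance and filtering

The sample distance is fixed at $d = 1 - \rho$ with $\rho$ Spearman's rank
correlation over genes (average ranks for ties, which count data guarantee).
It lives in $[0, 2]$, is invariant under monotone transforms of each
sample — so raw counts need no variance-stabilising transform — and makes
distances comparable across datasets. No alternative distances are offered.

Two gene filters precede every analysis:

1. **zero filter** — genes with zero counts (or signals) in *all* samples are
   removed; they carry no information and are required to be absent by the
   DE engine.
2. **unique filter** — genes with exactly identical row vectors are collapsed
   to their first occurrence. In count data the duplicate classes are
   dominated by low-count patterns, so the collapse reduces the weight of
   the low-expression regime in the rank correlation. Identity is exact
   equality of stored values: counts are integers and quantified signals are
   exact in storage, so no tolerance is needed, and which representative
   survives cannot matter because the collapsed rows are identical.

The pipeline convention is: DE analysis on the zero-filtered matrix;
distances, silhouettes and clustering on the zero-then-unique-filtered
matrix. `score_groups()` applies this automatically; `filter_genes()`
exposes it. For microarray signals, `log2_floor()` applies the standard
floor-at-1 log2 transform first (`score_groups(..., log2_transform = TRUE)`);
note that the *ranks*, and hence all distances, are unchanged by this
monotone map — it is provided so that exported matrices match the scale
microarray practitioners expect.

Missing values are a hard error everywhere: the filters and the rank
correlation assume complete matrices, and silently imputing would bias the
distances.

## The count simulator

`simulate_counts()` generates two-group RNA-seq-like counts from the
negative binomial with the dispersion parameterization
$V = \mu + \phi\mu^2$ ($\phi = 0$ is the Poisson limit; sampling uses
`size` $= 1/\phi$, continuous at the limit). The study design it emulates:
`n_genes` genes of which a fraction `p_deg` are true DEGs, each DEG's mean
multiplied by `fold_change` (default 4) in exactly one group, a fraction
`frac_up_a` (default 0.5) of DEGs up in group A. DEG counts are exact by
construction (`round(n_genes * p_deg)`), so simulated truth is never itself
random.

Per-gene parameters come from `sim_nb_params()`. The default synthetic
source draws $\log_{10}\mu \sim N(1.0,\, 0.7)$ truncated to
$\mu \in [0.5, 10^5]$ and $\phi \sim \text{Gamma}(\text{shape } 2,
\text{ mean } 0.15)$ truncated to $[0.001, 2.0]$: a median mean of 10 reads
with a heavy right tail and moderate biological-replicate overdispersion,
the shape seen in bulk RNA-seq moment estimates. Empirical $(\mu, \phi)$
tables estimated from a real dataset can be supplied instead
(`source = "table"`, resampled with replacement). Truncation is by rejection
resampling so the tails are genuinely removed rather than piled onto the
bounds.

Library depths are equal by construction unless a `depth` multiplier vector
is supplied; the DE engine estimates normalization factors regardless, so
depth variation is exercised through that path when wanted.

What the simulator does *not* emulate: gene–gene correlation, outlying
samples, batch effects, and count–mean relationships beyond the NB
two-moment model. Passing tests on simulated data therefore demonstrate the
internal consistency of the methodology — AS tracking the planted group
separation, P_DEG tracking the planted DEG fraction — not robustness to
those real-data complications.

## The DE engine

`nb_exact_test()` is a self-contained exact NB test for two-group count
comparisons:

1. **Normalization** (`norm_factors()`): factors are relative effective
   depths with geometric mean 1 — `"libsize"` (column sums), `"tmm"`
   (column sums times TMM scaling factors; the default), or `"degespipe"`,
   which iterates normalize → test → drop genes at $q \le 0.1$ → re-TMM for
   three rounds so the factors are estimated on putatively non-DE genes.
   Three rounds is where the retained gene set stops changing materially on
   simulated data; the iteration is optional and off by default.
2. **Dispersion**: per-gene method of moments on the depth-equalized
   pseudo-counts, pooled within groups (so true DE does not inflate
   $\phi$), floored at 0, then shrunk 50/50 toward the 10%-trimmed mean
   dispersion across genes. The equal-weights shrinkage is deliberately
   simple; it is what stabilizes the $n = 3$ replicate regime, and the
   weight is a documented constant rather than a tuned one.
3. **Exact split test**: group totals $(y_A, y_B)$ of the pseudo-counts are
   rounded to integers; under the null the split of $t = y_A + y_B$ follows
   the conditional distribution of two NB sums with shared mean, and the
   two-sided p-value is the total probability of all splits no more likely
   than the observed one (the "small-p" exact convention; a binomial split
   when $\phi = 0$). The enumeration is over $0 \dots t$, in log space for
   stability; relative probability ties are admitted with a $1 + 10^{-8}$
   factor so exact symmetric cases return $p = 1$ rather than
   $1 - \epsilon$.
4. **Multiplicity and summaries**: Benjamini–Hochberg q-values; `p_deg` is
   the percentage of tested genes with $q$ at or below the FDR threshold
   (default 0.10, with 0.01–0.40 supported); `p_true_deg`
   $= P_{DEG} \times (1 - \text{FDR})$ is the statistically expected
   true-positive share of the declarations; with simulated truth, the AUC
   is the Mann–Whitney probability that a true DEG out-ranks a non-DEG in
   ascending p-value order, ties at half credit.

This engine intentionally does not reproduce any particular published
pipeline byte-for-byte; the properties the package's claims rest on —
calibrated type-I error at the null, AUC near 1 and $P_{DEG}$ near the true
fraction at large replicate numbers, $P_{DEG} \to 0$ when $AS \to 0$ — hold
for any reasonably powerful calibrated NB test, and the test suite checks
exactly those properties plus agreement of the split p-value with an
independent small-p implementation.

## The sweep harness

`run_sweep()` reproduces the bootstrap design of the replicate-number
study: from a baseline matrix, draw `n_rep` samples per group *without
replacement*, re-filter, compute AS, run DE, and record
(`p_deg`, `as_value`, `auc`) — independently for each of `n_iter`
iterations at each grid value. Per-iteration seeds are derived
deterministically from (master seed, n_rep, iteration) by a fixed affine
map modulo $2^{31} - 1$ and stored in the records, so any single record can
be re-run in isolation. Subsampling is independent across iterations;
"without replacement" applies within an iteration only.

The headline behaviours this harness exposes, each asserted by the test
suite at the sizes noted below:

- $P_{DEG}$ and AUC increase with $N_{rep}$ while the mean AS is flat
  (|least-squares slope| < 0.005 per replicate, `slope_as_vs_nrep()`);
- on null data ($p_{deg} = 0$) both mean $P_{DEG}$ (< 1%) and |mean AS|
  (< 0.05) are near zero at every $N_{rep}$;
- across true-DEG fractions at fixed $N_{rep} = 3$, $P_{DEG}$ and AS are
  strongly positively correlated (Spearman > 0.9, `pdeg_as_scatter()`).

## Numerical and design choices

- **Ties in ranks**: average ranks (midranks) throughout, the standard
  Spearman convention; count data make ties certain.
- **UPGMA tie-breaks**: `cluster_samples()` delegates to
  `stats::hclust(method = "average")`, which is deterministic; on the
  continuous distances used here exact merge ties have probability zero.
- **Newick export**: node heights are halved so the leaf-to-leaf path
  length equals the cophenetic distance of the clustering (the usual
  dendrogram convention, e.g. a two-leaf tree merged at 0.4 serializes as
  `(A1:0.2,B1:0.2);`). Leaf names containing Newick metacharacters are
  single-quoted.
- **Percent scales**: $P_{DEG}$ and $P_{trueDEG}$ are reported on the
  0–100 scale; AS on the −1..1 scale.
- **Problem sizes**: the test suite exercises the full baseline design
  (10,000 genes, 40 + 40 samples) once, and uses 2,000-gene baselines with
  50, 30 and 20 iterations for the sweep, null and scatter studies — sizes
  at which the Monte-Carlo standard errors are comfortably inside the
  asserted margins while a full run of the suite stays in the minutes
  range.

## Worked example

```{r example}
sim <- simulate_counts(n_genes = 2000, p_deg = 0.2, fold_change = 4,
                       n_rep_a = 6, n_rep_b = 6, seed = 1)
score_groups(sim$counts, sim$groups)
de <- nb_exact_test(filter_zero(sim$counts)$matrix, sim$groups,
                    truth = sim$truth)
de
```

```{r sweep}
sw <- run_sweep(sim, n_rep_grid = c(3, 6), n_iter = 5, seed = 2)
summary(sw)
```

## Known limitations

- Two-group designs only in the simulator and DE engine (the silhouette and
  clustering side handles any number of groups); no multi-factor designs,
  no continuous-response models, and no limma-style pipeline for microarray
  DE — continuous matrices are accepted by the distance/silhouette/cluster
  path only.
- The exact test conditions on rounded pseudo-count totals; with very
  unequal depths the rounding is a small approximation.
- No outlier detection: AS quantifies separation of the groups as given,
  and outlying samples lower it — flagging them is the user's task.
- Real-dataset results obtained with other normalization/DE pipelines will
  differ in absolute $P_{DEG}$; the package's claims are about the joint
  behaviour of AS and $P_{DEG}$, not about matching any specific pipeline's
  gene list.
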