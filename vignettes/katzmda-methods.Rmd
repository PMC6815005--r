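---
title: "Methods: KATZ scoring of metabolite-disease associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: KATZ scoring of metabolite-disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(katzmda)
```

## The problem and the model

Known metabolite-disease associations form a sparse bipartite network: a 0/1
matrix $M$ with $n_d$ disease rows and $n_m$ metabolite columns, where
$M_{ij} = 1$ records a curated association. The prediction task is to rank
the unobserved cells of $M$ so that true-but-unrecorded associations surface
near the top. `katzmda` does this with the KATZ index on a heterogeneous
network that augments the bipartite graph with a metabolite-metabolite and a
disease-disease similarity layer:

$$
M^* \;=\; \begin{bmatrix} SM & M' \\ M'^T & SD \end{bmatrix},
\qquad
Z \;=\; \Big[\textstyle\sum_{l \ge 1} \delta^l (M^*)^l\Big]_{\text{met} \times \text{dis}},
$$

where $M'$ is $M$ oriented metabolite-rows $\times$ disease-columns,
$\delta \in (0, 1)$ attenuates longer walks geometrically (a walk of length
$l$ contributes $\delta^l$), and the score of a metabolite-disease pair
gathers every walk connecting the two nodes through associations and through
similarity edges. The model's single structural assumption is *transitivity*:
metabolites associated with similar diseases, and diseases sharing similar
metabolite profiles, are likely to share further associations.

In practice the series is truncated at walk length $k$
(`katz_truncated()`); the closed form
$(I - \delta M^*)^{-1} - I$ (`katz_closed()`) is available whenever
$\delta$ is below the reciprocal spectral radius of $M^*$. Truncated scores
are always finite, so the default pipeline uses $k = 2$ even when $\delta$
exceeds the closed-form bound.

## Similarity layers

**Metabolite similarity** is the Gaussian Interaction Profile (GIP) kernel
on the columns of $M$:
$SM(u, v) = \exp(-\omega_m \lVert IP(u) - IP(v)\rVert^2)$ with bandwidth
$\omega_m = \omega'_m / \overline{\lVert IP \rVert^2}$, the mean squared
profile norm over all metabolites. $\omega'_m = 1$ follows the common GIP
convention.

**Disease similarity** integrates two sources:

1. *Semantic similarity* from disease DAGs. Each disease $D$ comes with the
   directed acyclic graph of itself and its ancestor terms (MeSH-style,
   parent $\to$ child edges). The contribution of term $t$ to $D$ is 1 at
   $D$ itself and $\Delta \cdot \max_{\text{children } c}$ contribution$(c)$
   elsewhere, so contributions decay geometrically with distance from $D$;
   the pairwise similarity sums the contributions of shared terms and
   normalizes by the two semantic values (sums over each DAG's term set).
   $\Delta$ defaults to 0.5, the convention of the Wang-style semantic
   similarity lineage this construction belongs to.
2. *GIP kernel on disease rows*, sharpened by the logistic transform
   $s \mapsto 1 / (1 + e^{a s + b})$ with $a = -15$, $b = \log 9999$. These
   defaults pin the image of 0 at exactly $10^{-4}$ and of 1 at
   $\approx 0.997$, stretching the informative upper range of the kernel
   while flattening the noise floor near zero.

The integrated disease similarity is

$$
SD(i, j) =
\begin{cases}
GDL(i, j) & \text{if } DSS(i, j) = 0,\\[2pt]
(1 - \gamma)\, DSS(i, j) + \gamma\, G(i, j) & \text{otherwise,}
\end{cases}
$$

with weight $\gamma$ (default 0.1). Where no DAG is available for a disease,
its semantic row is all zero and the fallback branch applies throughout. The
weighted branch uses the logistic-transformed kernel $G = GDL$ by default;
the package exposes `kernel = "gd"` to use the raw kernel instead, because
both variants appear in the KATZ-on-heterogeneous-network literature and
they differ by one flag. We default to `gdl` for consistency with the
fallback branch and with the stated motivation of the logistic improvement.

## Tunable parameters

| parameter | meaning | default | range notes |
|---|---|---|---|
| `delta` | per-step walk attenuation | 0.1 | truncated scores finite for any $\delta > 0$; closed form needs $\delta < 1/\rho(M^*)$ |
| `k` | maximum walk length | 2 | 2-4; cross-validated AUC degrades beyond 2 on our benchmarks |
| `gamma` | GIP weight in integrated disease similarity | 0.1 | $[0, 1]$; 0 = purely semantic where defined |
| `Delta` | semantic decay per DAG level | 0.5 | $(0, 1)$ |
| `omega_prime` | GIP bandwidth multiplier | 1 | $> 0$; scales the kernel exponent linearly |
| `a`, `b` | logistic transform | $-15$, $\log 9999$ | $a < 0$ keeps the transform increasing |

The two attenuation bounds reported by `delta_bound()` deserve a note: the
mathematically correct convergence condition for the closed form is
$\delta \cdot \rho(M^*) < 1$ on the *heterogeneous* matrix. A looser rule of
thumb, $\delta < 1 / \lVert M \rVert^2$ on the bipartite block alone,
circulates in the KATZ literature; it is neither necessary nor sufficient
once similarity blocks are added, so the package enforces the spectral
condition and merely reports (and warns about) the literal one.

## Evaluation protocol

`loocv()` masks each known pair in turn; `kfold_cv()` masks shuffled folds
(seeded, near-equal sizes, optionally repeated). In every trial the scorer
receives the *masked* matrix and rebuilds both GIP kernels and the
integrated disease similarity from it — masking therefore propagates into
the similarity layers and there is no information leakage. The semantic
matrix is computed once, since ontology ancestry does not depend on the
association data. A `static_M` option freezes the similarities at the full
matrix, reproducing the leaky protocol some studies use, for comparison
only.

Each held-out positive is ranked among itself plus all pairs unknown in the
*full* dataset (other held-out positives are excluded from the candidate
set); tied scores receive fractional mid-ranks. The ROC curve sweeps a rank
threshold; its trapezoidal area equals the mid-rank Mann-Whitney statistic
averaged over trials when every trial has the same candidate count, which is
the case in both protocols. `balance_negatives` optionally subsamples the
candidate pool (seeded) to the number of positives, the standard remedy when
the negative class overwhelms the positive one; defaults keep the full pool
because that is the protocol the headline numbers of this method family are
computed under.

Baselines run the identical protocol on the identical network: `rwr_score()`
iterates a random walk with restart (restart 0.7, tolerance $10^{-10}$, at
most 1000 iterations) from each disease node over the column-normalized
$M^*$; `pagerank_score()` is damped personalized PageRank (damping 0.85)
with dangling mass redistributed to the personalization vector. The two are
the same fixed-point family (restart $= 1 -$ damping) and are kept separate
only because their conventional parameters differ; a unit test checks the
PageRank fixed point against igraph's independent implementation.

## The synthetic benchmark

`synth_generate()` plants the transitive structure KATZ exploits: diseases
and metabolites are partitioned into clusters, pairs are sampled with
probability `within_cluster_assoc_prob` (0.5) inside a cluster and
`background_assoc_prob` (0.02) outside, and each cluster owns a branch of a
shared disease-term tree so that same-cluster diseases have high semantic
similarity while cross-cluster diseases share only the root. The standing
benchmark configuration is 30 diseases $\times$ 90 metabolites, 3 clusters,
generator seed 7; a sampling matrix of independent uniforms is drawn
row-major under a single seeded generator, so a configuration reproduces its
dataset byte for byte. Every disease and metabolite is guaranteed at least
one association; within-cluster cells left unsampled are returned as
`truth`, the plantable positives.

What the generator does *not* emulate: the heavy-tailed degree distribution
of curated metabolomics databases (a handful of hub diseases with hundreds
of associations), correlated annotation biases, and the depth and branching
irregularity of real MeSH ancestry. Passing the planted-recovery tests
therefore demonstrates that the implementation exploits transitive cluster
structure correctly — not that any particular AUC will be attained on a
specific database snapshot, which depends on the snapshot's size, sparsity
and curation style.

One protocol interaction is worth recording. Recovery AUC is *not* monotone
in the within-cluster rate: lowering it leaves many same-cluster cells
unsampled, and the ranking protocol counts exactly those cells — which a
correct model scores high — as negatives, depressing measured AUC in the
mid-density regime. The signal-dial property test therefore varies the
planted gap through the background rate at a fixed within-cluster rate,
where the confound is absent and AUC rises cleanly with the gap.

## Numerical choices and degenerate inputs

- Dense base-R linear algebra throughout: at the scale this model is used
  (a few thousand nodes) dense BLAS is faster and simpler than sparse
  iterative methods. Truncated KATZ propagates only the disease columns of
  successive powers of $M^*$, so no full matrix power is ever formed; the
  closed form uses a linear solve, never an explicit inverse.
- GIP kernels clamp tiny negative squared distances (floating-point
  artifacts of the Gram-matrix expansion) to zero, symmetrize, and set the
  diagonal to exactly 1. An all-zero association matrix has no defined
  bandwidth and raises an error.
- The logistic transform caps its exponent at 700 before `exp()` to avoid
  overflow for extreme (non-default) parameters.
- Candidate ranking breaks score ties lexicographically on the metabolite
  id, making exports stable across platforms; CV ranks use mid-ranks
  instead, so ties are credited half in the AUC.
- DAG terms from which the disease cannot be reached are excluded from the
  term set with a warning; cycles are an error naming the disease.
- `k` is restricted to 2-4 in `katz_truncated()`: beyond 4 the truncation
  argument loses its point and the closed form is the appropriate tool.

## Problem sizes used in the shipped checks

The test-suite benchmarks run the full pipeline on the 30 $\times$ 90
planted preset (5-fold CV, seconds) and one database-scale random instance of
216 diseases $\times$ 2262 metabolites with roughly 4.5k associations
(score plus one 5-fold CV), a size the dense pipeline completes in well
under a minute on one core. The acceptance script recomputes the benchmark
AUCs (KATZ, permuted null, RWR, PageRank), a leave-one-out AUC on the
bundled 20 $\times$ 60 toy fixture, and the attenuation bound of the
benchmark network.

## Known limitations

- Node universes come from the association table: a disease or metabolite
  with no known association cannot be represented, let alone ranked.
- Semantic similarity requires externally supplied DAGs; the package does
  not parse ontology releases or map between disease vocabularies.
- All-pairs candidate sets make LOOCV quadratic-ish in practice; it is
  intended for datasets up to a few hundred pairs, with k-fold CV the tool
  for larger ones.
- The KATZ score is unnormalized: scores are comparable within a run, not
  across datasets or parameter settings.
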