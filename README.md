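# katzmda

Prioritizing candidate metabolite–disease associations by KATZ path counting
on a heterogeneous similarity network.

## The problem

Metabolite concentrations shift with disease, and curated resources record
thousands of metabolite–disease associations — but the recorded pairs are a
thin sample of the true association structure, and testing candidates in the
lab is slow and expensive. Given a bipartite 0/1 association matrix `M`
(diseases × metabolites), `katzmda` ranks the *unobserved* pairs so that
likely-but-unrecorded associations surface first. It is aimed at
computational biologists who have a pair table (e.g. extracted from a
metabolomics database) and, optionally, MeSH-style ancestry DAGs for the
diseases.

## The method

The score of a metabolite–disease pair counts every walk connecting the two
nodes in a heterogeneous network, geometrically down-weighting longer walks:

```
M* = [ SM   M' ]        Z = [ Σ_{l=1..k} δ^l (M*)^l ]  (metabolite × disease block)
     [ M'ᵀ  SD ]
```

* `M'` — the association matrix (metabolite rows × disease columns);
* `SM` — metabolite Gaussian Interaction Profile (GIP) kernel
  `exp(−ω‖IP(u)−IP(v)‖²)`, bandwidth normalized by the mean squared profile
  norm;
* `SD` — disease similarity integrating DAG-based semantic similarity `DSS`
  (Wang-style decay, factor `Δ = 0.5`) with a logistic-sharpened disease GIP
  kernel `GDL`: `SD = (1−γ)·DSS + γ·GDL`, falling back to `GDL` wherever
  `DSS = 0`;
* `δ = 0.1`, `k = 2`, `γ = 0.1` by default; the closed form
  `(I − δM*)⁻¹ − I` is available below the spectral convergence bound.

Evaluation utilities run leave-one-out and repeated k-fold cross-validation
with rank-based ROC/AUC (similarities rebuilt from the masked matrix inside
every fold — no leakage), alongside random-walk-with-restart and
personalized PageRank baselines on the same network, and a seeded synthetic
generator with planted cluster structure for download-free benchmarking.

## Worked example

Score the bundled toy fixture (20 diseases × 60 metabolites, 150 pairs,
synthetic) and list novel candidates for one disease:

```r
library(katzmda)
paths <- toy_fixture_paths()
res <- run_score(paths$associations, paths$dags, top = 5, disease = "D001")
#> network: 60 metabolites x 20 diseases, 150 known pairs
#> delta = 0.1; convergence bound 1/rho(M*) = 0.06562; literal 1/||M||^2 = 0.03763
#> note: delta is at or above the closed-form convergence bound; truncated scores remain finite
res$candidates$D001
#>  metabolite_id      score rank
#>           M004 0.03071117    1
#>           M028 0.03011552    2
#>           M034 0.02870479    3
#>           M001 0.02719567    4
#>           M010 0.02704341    5
```

The scores are KATZ walk sums: `M004` tops the list because it shares many
length-2 and length-3 paths with `D001` through co-associated metabolites
and similar diseases; metabolites already associated with `D001` are
excluded. The logged bound shows `δ = 0.1` is above this small network's
closed-form convergence radius, which is why the default truncated series
(`k = 2`, always finite) is used.

Cross-validate the full pipeline on the planted-cluster benchmark:

```r
gen <- synth_generate(synth_config())   # 30 × 90, 3 clusters, seed 7
kfold_cv(gen$dataset, katz_scorer(gen$dags), k_folds = 5, seed = 1)
#> <mda_eval> katz / 5fold: AUC 0.8609 (per-fold mean 0.8609 +/- 0.0101, 5 folds)
```

An AUC of 0.86 means a held-out true association outranks a random unknown
pair 86% of the time. A label-permuted null scorer on the same folds sits
near 0.5.

A thin command-line wrapper over the same functions ships in
`inst/cli/katzmda.R` (subcommands `synth`, `score`, `eval`, `grid`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","katzmda.R",package="katzmda"))')" \
  score --associations pairs.csv --dags dags.csv --k 2 --delta 0.1 --out scores.csv
```

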