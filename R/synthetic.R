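# Seeded synthetic datasets with planted cluster structure.

#' Configuration for the synthetic benchmark generator
#'
#' Diseases and metabolites are partitioned into `n_clusters` groups; a pair
#' is associated with probability `within_cluster_assoc_prob` when disease
#' and metabolite share a cluster, `background_assoc_prob` otherwise. Each
#' cluster additionally gets its own branch of a shared disease-term tree,
#' so same-cluster diseases share ancestor terms (high semantic similarity)
#' while cross-cluster diseases share only the root. This planted transitive
#' structure is exactly what KATZ path counting exploits, so the signal
#' strength is dialled by the gap between the two probabilities.
#'
#' @param n_d,n_m number of diseases / metabolites.
#' @param n_clusters number of planted clusters (at most `min(n_d, n_m)`).
#' @param within_cluster_assoc_prob,background_assoc_prob association
#'   probabilities inside / outside a cluster (within > background for a
#'   planted signal).
#' @param dag_depth depth of each cluster's shared term chain/tree.
#' @param dag_branching children per internal term node of the cluster tree
#'   (1 = a chain).
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_d = 30, n_m = 90, n_clusters = 3,
                         within_cluster_assoc_prob = 0.5,
                         background_assoc_prob = 0.02,
                         dag_depth = 3, dag_branching = 1, seed = 7) {
  stopifnot(n_d >= 1, n_m >= 1,
            n_clusters >= 1, n_clusters <= min(n_d, n_m),
            within_cluster_assoc_prob >= 0, within_cluster_assoc_prob <= 1,
            background_assoc_prob >= 0, background_assoc_prob <= 1,
            within_cluster_assoc_prob > background_assoc_prob,
            dag_depth >= 1, dag_branching >= 1)
  structure(list(n_d = n_d, n_m = n_m, n_clusters = n_clusters,
                 within_cluster_assoc_prob = within_cluster_assoc_prob,
                 background_assoc_prob = background_assoc_prob,
                 dag_depth = dag_depth, dag_branching = dag_branching,
                 seed = seed),
            class = "synth_config")
}

# cluster-c term tree: a root shared by all clusters, then `depth` levels of
# cluster-private terms with `branching` children each; returns, for leaf
# slot `leaf`, the root-to-leaf path (term ids, most general first)
.cluster_term_path <- function(cluster, depth, branching, leaf) {
  path <- "T_ROOT"
  idx <- leaf - 1L
  rev_levels <- integer(depth)
  for (lev in depth:1) {
    rev_levels[lev] <- idx %% branching
    idx <- idx %/% branching
  }
  at <- 0L
  for (lev in seq_len(depth)) {
    at <- at * branching + rev_levels[lev]
    path <- c(path, sprintf("T_C%d_L%d_%d", cluster, lev, at + 1L))
  }
  path
}

#' Generate a seeded synthetic association dataset with planted clusters
#'
#' See [synth_config()] for the generative model. Draw order is fixed (one
#' uniform per disease-metabolite cell, row-major), so a given seed always
#' yields the same dataset. Every disease and metabolite is guaranteed at
#' least one association (a deterministic within-cluster pair is added where
#' sampling left a node empty). The global RNG state is left untouched.
#'
#' @param config a [synth_config()].
#' @return List with `dataset` (an [association_dataset()]), `dags` (named
#'   list of [disease_dag()]s, one per disease), `truth` (data.frame of
#'   within-cluster pairs that were \emph{not} sampled — plantable held-out
#'   positives), and `config`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_d <- config$n_d; n_m <- config$n_m; k <- config$n_clusters
  disease_ids <- sprintf("D%03d", seq_len(n_d))
  metabolite_ids <- sprintf("M%03d", seq_len(n_m))
  cl_d <- ((seq_len(n_d) - 1L) %% k) + 1L
  cl_m <- ((seq_len(n_m) - 1L) %% k) + 1L
  same <- outer(cl_d, cl_m, "==")
  P <- ifelse(same, config$within_cluster_assoc_prob,
              config$background_assoc_prob)
  U <- .with_seed(config$seed,
                  matrix(runif(n_d * n_m), n_d, n_m, byrow = TRUE))
  A <- U < P
  # guarantee coverage: first same-cluster partner for any empty row/column
  for (i in which(rowSums(A) == 0L)) {
    A[i, which(cl_m == cl_d[i])[1L]] <- TRUE
  }
  for (j in which(colSums(A) == 0L)) {
    A[which(cl_d == cl_m[j])[1L], j] <- TRUE
  }
  if (!any(A)) stop("synthetic config produced an empty pair set")
  idx <- which(t(A))  # row-major over diseases
  pairs <- data.frame(
    disease_id = disease_ids[(idx - 1L) %/% n_m + 1L],
    metabolite_id = metabolite_ids[(idx - 1L) %% n_m + 1L],
    stringsAsFactors = FALSE)
  dataset <- association_dataset(pairs)

  n_leaves <- config$dag_branching^config$dag_depth
  leaf_of <- integer(n_d)
  for (c in seq_len(k)) {
    members <- which(cl_d == c)
    leaf_of[members] <- ((seq_along(members) - 1L) %% n_leaves) + 1L
  }
  dags <- lapply(seq_len(n_d), function(i) {
    path <- .cluster_term_path(cl_d[i], config$dag_depth,
                               config$dag_branching, leaf_of[i])
    chain <- c(path, disease_ids[i])
    disease_dag(disease_ids[i], chain,
                data.frame(parent = chain[-length(chain)],
                           child = chain[-1L], stringsAsFactors = FALSE))
  })
  names(dags) <- disease_ids

  truth_idx <- which(t(same & !A))
  truth <- data.frame(
    disease_id = disease_ids[(truth_idx - 1L) %/% n_m + 1L],
    metabolite_id = metabolite_ids[(truth_idx - 1L) %% n_m + 1L],
    stringsAsFactors = FALSE)
  list(dataset = dataset, dags = dags, truth = truth, config = config)
}

#' Pair of chain DAGs with a known closed-form semantic similarity
#'
#' Builds two chain-shaped disease DAGs sharing a prefix of
#' `shared_depth` terms, each followed by `private_depth` private nodes (the
#' last private node being the disease itself). The expected semantic
#' similarity follows from geometric sums of powers of `delta`:
#' with `p = private_depth` and `s = shared_depth`,
#' `DSS = sum(delta^(p:(p+s-1))) / sum(delta^(0:(p+s-1)))`;
#' `shared_depth = 0` gives fully disjoint DAGs (DSS 0) and
#' `private_depth = 0` gives identical DAGs (DSS 1).
#'
#' @param shared_depth number of shared prefix terms (>= 0).
#' @param private_depth number of private terms per DAG including the
#'   disease node itself (>= 0; 0 means the two DAGs are identical).
#' @param delta semantic decay factor.
#' @return List with `dag1`, `dag2` ([disease_dag()]s) and `expected_dss`.
#' @export
generate_dag_pair <- function(shared_depth, private_depth, delta = 0.5) {
  stopifnot(shared_depth >= 0, private_depth >= 0,
            shared_depth + private_depth >= 1)
  shared <- if (shared_depth > 0) sprintf("S%d", seq_len(shared_depth)) else character()
  chain_dag <- function(terms, disease) {
    chain <- c(terms, disease)
    edges <- if (length(chain) > 1L) {
      data.frame(parent = chain[-length(chain)], child = chain[-1L],
                 stringsAsFactors = FALSE)
    } else NULL
    disease_dag(disease, chain, edges)
  }
  if (private_depth == 0L) {
    dag <- chain_dag(shared[-shared_depth], shared[shared_depth])
    return(list(dag1 = dag, dag2 = dag, expected_dss = 1))
  }
  priv <- function(tag) {
    c(if (private_depth > 1L) sprintf("P%s_%d", tag, seq_len(private_depth - 1L)),
      paste0("D", tag))
  }
  dag1 <- chain_dag(c(shared, head(priv("1"), -1L)), paste0("D", 1L))
  dag2 <- chain_dag(c(shared, head(priv("2"), -1L)), paste0("D", 2L))
  p <- private_depth; s <- shared_depth
  expected <- if (s == 0L) 0 else
    sum(delta^(p:(p + s - 1L))) / sum(delta^(0:(p + s - 1L)))
  list(dag1 = dag1, dag2 = dag2, expected_dss = expected)
}
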