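# Shared builders and independent oracles for the test suite.

tiny_dataset <- function() {
  association_dataset(data.frame(
    disease_id = c("d1", "d1", "d2"),
    metabolite_id = c("m1", "m2", "m2"),
    stringsAsFactors = FALSE))
}

chain_dag_for <- function(terms) {
  # terms most general first, last term is the disease
  disease <- terms[length(terms)]
  edges <- if (length(terms) > 1L) {
    data.frame(parent = terms[-length(terms)], child = terms[-1L],
               stringsAsFactors = FALSE)
  } else NULL
  disease_dag(disease, terms, edges)
}

# random symmetric matrix with entries in [0, 1]
rand_sym <- function(n) {
  A <- matrix(runif(n * n), n, n)
  (A + t(A)) / 2
}

# random heterogeneous network: symmetric similarity blocks, 0/1 adjacency
rand_net <- function(n_m, n_d, p = 0.4) {
  M <- matrix(rbinom(n_d * n_m, 1L, p), n_d, n_m,
              dimnames = list(paste0("d", seq_len(n_d)),
                              paste0("m", seq_len(n_m))))
  build_hetero(rand_sym(n_m), rand_sym(n_d), M)
}

# oracle: metabolite x disease block of sum_{l=1..k} delta^l Mstar^l by
# naive repeated full-matrix multiplication
katz_block_oracle <- function(net, delta, k) {
  n_m <- length(net$metabolite_ids)
  n_d <- length(net$disease_ids)
  acc <- matrix(0, nrow(net$Mstar), ncol(net$Mstar))
  P <- diag(nrow(net$Mstar))
  for (l in seq_len(k)) {
    P <- P %*% net$Mstar
    acc <- acc + delta^l * P
  }
  acc[seq_len(n_m), n_m + seq_len(n_d), drop = FALSE]
}

# random DAG on n nodes in which every node reaches the disease: node n is
# the disease; each earlier node gets >= 1 child with a higher index
rand_reaching_dag <- function(n) {
  nodes <- paste0("t", seq_len(n))
  edges <- NULL
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      later <- seq(i + 1L, n)
      kids <- unique(c(later[sample.int(length(later), 1L)],
                       which(runif(n) < 0.3 & seq_len(n) > i)))
      edges <- rbind(edges, data.frame(parent = nodes[i], child = nodes[kids],
                                       stringsAsFactors = FALSE))
    }
  }
  disease_dag(nodes[n], nodes, edges)
}

# oracle: contribution of each term = max over all parent->child paths from
# the term to the disease of delta^(path length), by exhaustive recursive
# path enumeration (no memoization)
semantic_oracle <- function(dag, delta) {
  D <- dag$disease_id
  kids <- split(dag$edges$child, dag$edges$parent)
  path_max <- function(node) {
    if (node == D) return(1)
    ch <- kids[[node]]
    if (is.null(ch)) return(-Inf)
    delta * max(vapply(ch, path_max, numeric(1L)))
  }
  v <- vapply(dag$nodes, path_max, numeric(1L))
  v[v > 0]
}

# oracle: materialize explicit scores realizing integer ranks, then count
# positive-vs-negative wins pairwise (brute-force Mann-Whitney)
auc_oracle <- function(ranks, n_candidates) {
  wins <- 0
  total <- 0
  for (r in ranks) {
    pos_score <- n_candidates - r + 1
    neg_scores <- setdiff(seq_len(n_candidates), pos_score)
    for (s in neg_scores) {
      wins <- wins + (pos_score > s) + 0.5 * (pos_score == s)
      total <- total + 1
    }
  }
  wins / total
}

toy_dataset <- function() load_associations(toy_fixture_paths()$associations)
toy_dags <- function() load_dags(toy_fixture_paths()$dags)
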