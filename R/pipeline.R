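# End-to-end pipeline: data -> similarities -> KATZ -> exports / CV grids.

.as_dataset <- function(x, dialect = "csv", header = FALSE) {
  if (inherits(x, "association_dataset")) x
  else load_associations(x, dialect, header)
}

.as_dags <- function(x, dialect = "csv", header = FALSE) {
  if (is.null(x) || is.list(x)) x
  else load_dags(x, dialect, header)
}

#' Score every metabolite-disease pair and export candidate rankings
#'
#' Runs the full pipeline: load (or accept) the association table and DAGs,
#' build the metabolite GIP similarity, the integrated disease similarity
#' and the heterogeneous network, score all pairs with KATZ, and optionally
#' write a long-format CSV (`disease_id, metabolite_id, score,
#' rank_within_disease`) plus per-disease top candidate lists with known
#' associations excluded.
#'
#' @param associations an [association_dataset()] or path to a pair table.
#' @param dags named list of [disease_dag()]s, path to a DAG file, or `NULL`.
#' @param out optional path for the long-format score CSV.
#' @param top optional integer: also return `top` novel candidates per
#'   disease (for `disease` only, if given).
#' @param disease optional disease id restricting the candidate tables.
#' @param delta,k,gamma,Delta,omega_prime,a,b,kernel pipeline parameters,
#'   see [katz_scorer()]. `k` may be `"closed"`.
#' @param dialect,header file dialect when `associations`/`dags` are paths.
#' @param verbose print matrix shapes and the attenuation bound check?
#' @return List (invisibly) with `Z` (score matrix), `net`, `bounds`
#'   (from [delta_bound()]), `dataset`, and `candidates` (list of
#'   data.frames when `top` was requested).
#' @export
run_score <- function(associations, dags = NULL, out = NULL, top = NULL,
                      disease = NULL, delta = 0.1, k = 2, gamma = 0.1,
                      Delta = 0.5, omega_prime = 1, a = -15, b = log(9999),
                      kernel = c("gdl", "gd"), dialect = "csv",
                      header = FALSE, verbose = TRUE) {
  kernel <- match.arg(kernel)
  dataset <- .as_dataset(associations, dialect, header)
  dag_list <- .as_dags(dags, dialect, header)
  M <- adjacency(dataset)
  DSS <- .dss_for(dag_list, Delta, dataset$disease_ids)
  net <- .mda_network(M, DSS, gamma, omega_prime, a, b, kernel)
  bounds <- delta_bound(net)
  if (verbose) {
    message(sprintf("network: %d metabolites x %d diseases, %d known pairs",
                    ncol(M), nrow(M), sum(M)))
    message(sprintf(
      "delta = %g; convergence bound 1/rho(M*) = %.4g; literal 1/||M||^2 = %.4g",
      delta, bounds$spectral, bounds$adjacency_norm))
    if (delta >= bounds$spectral) {
      message("note: delta is at or above the closed-form convergence bound; ",
              "truncated scores remain finite")
    }
  }
  Z <- if (identical(k, "closed")) katz_closed(net, delta)
       else katz_truncated(net, delta, k)
  if (!is.null(out)) {
    long <- data.frame(
      disease_id = rep(colnames(Z), each = nrow(Z)),
      metabolite_id = rep(rownames(Z), times = ncol(Z)),
      score = as.vector(Z),
      stringsAsFactors = FALSE)
    rk <- apply(-Z, 2, rank, ties.method = "first")
    long$rank_within_disease <- as.vector(rk)
    write.table(long, out, sep = ",", row.names = FALSE, quote = FALSE)
    if (verbose) message("wrote ", nrow(long), " scores to ", out)
  }
  candidates <- NULL
  if (!is.null(top)) {
    targets <- if (is.null(disease)) dataset$disease_ids else disease
    candidates <- lapply(setNames(targets, targets), function(d)
      rank_candidates(Z, dataset, d, top = top))
  }
  invisible(list(Z = Z, net = net, bounds = bounds, dataset = dataset,
                 candidates = candidates))
}

#' Cross-validated AUC over a parameter grid
#'
#' Evaluates the KATZ pipeline by k-fold cross-validation for every
#' combination of the integration weight `gamma`, the attenuation `delta`
#' and the truncation length `k`, all cells sharing the same fold split
#' (same `seed`), so cells are directly comparable and a 1x1x1 grid equals a
#' single [kfold_cv()] call.
#'
#' @inheritParams run_score
#' @param gamma_grid,delta_grid,k_set parameter values to sweep.
#' @param k_folds,repeats,seed cross-validation settings, see [kfold_cv()].
#' @return data.frame with columns `gamma`, `delta`, `k`, `auc_mean`,
#'   `auc_sd`.
#' @export
run_param_grid <- function(associations, dags = NULL,
                           gamma_grid = seq(0.1, 0.9, by = 0.1),
                           delta_grid = seq(0.1, 0.9, by = 0.1),
                           k_set = c(2, 3, 4), k_folds = 5, repeats = 1,
                           seed = 1L, Delta = 0.5, omega_prime = 1,
                           a = -15, b = log(9999), kernel = c("gdl", "gd"),
                           dialect = "csv", header = FALSE) {
  kernel <- match.arg(kernel)
  dataset <- .as_dataset(associations, dialect, header)
  dag_list <- .as_dags(dags, dialect, header)
  grid <- expand.grid(gamma = gamma_grid, delta = delta_grid, k = k_set,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- katz_scorer(dag_list, delta = grid$delta[i], k = grid$k[i],
                      gamma = grid$gamma[i], Delta = Delta,
                      omega_prime = omega_prime, a = a, b = b,
                      kernel = kernel)
    ev <- kfold_cv(dataset, sc, k_folds = k_folds, repeats = repeats,
                   seed = seed)
    c(auc_mean = ev$auc_mean, auc_sd = ev$auc_sd)
  })
  cbind(grid, do.call(rbind, res))
}
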