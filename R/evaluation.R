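# Cross-validation protocols, rank-based ROC/AUC, and diffusion baselines.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# mid-rank of each score in `s` against the candidate pool `pool`
# (rank 1 = best; ties counted half)
.mid_ranks <- function(s, pool) {
  sp <- sort(pool)
  n <- length(sp)
  n_le <- findInterval(s, sp)
  n_lt <- findInterval(s, sp, left.open = TRUE)
  1 + (n - n_le) + (n_le - n_lt) / 2
}

.mda_eval <- function(method, protocol, folds, roc, auc, ranks, n_candidates,
                      params = list()) {
  structure(list(method = method, protocol = protocol, params = params,
                 folds = folds, auc_mean = mean(folds),
                 auc_sd = if (length(folds) > 1L) sd(folds) else NA_real_,
                 auc = auc, roc = roc, ranks = ranks,
                 n_candidates = n_candidates),
            class = "mda_eval")
}

#' @export
print.mda_eval <- function(x, ...) {
  cat(sprintf("<mda_eval> %s / %s: AUC %.4f", x$method, x$protocol, x$auc))
  if (length(x$folds) > 1L) {
    cat(sprintf(" (per-fold mean %.4f +/- %.4f, %d folds)",
                x$auc_mean, x$auc_sd, length(x$folds)))
  }
  cat("\n")
  invisible(x)
}

#' ROC curve and AUC from ranks of held-out positives
#'
#' Every cross-validation trial leaves one (or one fold of) known
#' association(s) out and records the rank of each held-out positive within
#' its candidate set of `n_candidates` pairs (the positive itself plus the
#' unknown pairs). Sweeping a rank threshold over all trials yields the ROC
#' curve; the AUC is the trapezoidal area, which for a common candidate count
#' equals the mid-rank Mann-Whitney statistic averaged over trials. Tied
#' scores enter as fractional (mid) ranks and are credited half.
#'
#' @param positive_ranks numeric vector of (possibly fractional mid-) ranks,
#'   each in `[1, n_candidates]`.
#' @param n_candidates size of the candidate set each positive was ranked in.
#' @return List with `roc` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(positive_ranks, n_candidates) {
  r <- as.numeric(positive_ranks)
  if (length(r) == 0L) stop("no held-out positive ranks supplied")
  stopifnot(n_candidates >= 2, all(r >= 1), all(r <= n_candidates))
  ts <- sort(unique(pmin(pmax(c(0, n_candidates, r - 1, r), 0), n_candidates)))
  cov <- vapply(ts, function(t) mean(pmin(pmax(t - r + 1, 0), 1)), numeric(1L))
  neg <- vapply(ts, function(t) mean(t - pmin(pmax(t - r + 1, 0), 1)), numeric(1L))
  fpr <- neg / (n_candidates - 1)
  tpr <- cov
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

.candidate_pool_idx <- function(Mp, balance_negatives = FALSE, seed = 1L) {
  unknown <- which(Mp == 0)
  if (balance_negatives) {
    n_pos <- sum(Mp != 0)
    if (n_pos < length(unknown)) {
      unknown <- .with_seed(seed, sample(unknown, n_pos))
    }
  }
  unknown
}

#' Leave-one-out cross-validation of a scoring pipeline
#'
#' Each known association is masked in turn (its entry of the adjacency
#' matrix set to 0), the scorer is re-run on the masked matrix — which for
#' the bundled scorers rebuilds the GIP similarities from the masked data —
#' and the rank of the held-out pair among itself plus all unknown pairs is
#' recorded. The ranks are converted to a ROC curve and AUC with
#' [roc_auc()].
#'
#' @param dataset an [association_dataset()] with at least two known pairs.
#' @param scorer function taking a (masked) disease x metabolite 0/1 matrix
#'   and returning a metabolite x disease score matrix; see [katz_scorer()],
#'   [rwr_scorer()], [pagerank_scorer()].
#' @param balance_negatives if `TRUE`, the candidate set is a seeded random
#'   subsample of the unknown pairs, of the same size as the positive set.
#' @param seed used only for `balance_negatives` subsampling.
#' @return An object of class `mda_eval`.
#' @export
loocv <- function(dataset, scorer, balance_negatives = FALSE, seed = 1L) {
  stopifnot(inherits(dataset, "association_dataset"))
  M <- dataset$M
  Mp <- t(M)
  pos <- which(Mp != 0)  # indices in metabolite x disease orientation
  if (length(pos) < 2L) stop("LOOCV needs at least two known associations")
  pool_idx <- .candidate_pool_idx(Mp, balance_negatives, seed)
  ranks <- numeric(length(pos))
  for (i in seq_along(pos)) {
    mj <- (pos[i] - 1L) %% nrow(Mp) + 1L
    di <- (pos[i] - 1L) %/% nrow(Mp) + 1L
    M2 <- M
    M2[di, mj] <- 0L
    Z <- scorer(M2)
    ranks[i] <- .mid_ranks(Z[mj, di], Z[pool_idx])
  }
  n_cand <- length(pool_idx) + 1L
  ra <- roc_auc(ranks, n_cand)
  .mda_eval(attr(scorer, "method_name") %||% "custom", "loocv",
            folds = ra$auc, roc = ra$roc, auc = ra$auc, ranks = ranks,
            n_candidates = n_cand)
}

#' Repeated k-fold cross-validation of a scoring pipeline
#'
#' The known pairs are shuffled by a seeded RNG and split into `k_folds`
#' near-equal parts. Each part is masked jointly, the scorer re-run on the
#' masked matrix, and every held-out positive is ranked among itself plus
#' all unknown pairs (other held-out positives are not candidates). One AUC
#' is recorded per fold; with `repeats > 1` the shuffle/split is repeated,
#' giving `k_folds * repeats` AUCs whose mean and standard deviation are
#' reported. The pooled ranks across all folds also yield an overall
#' ROC/AUC.
#'
#' @inheritParams loocv
#' @param k_folds number of folds (e.g. 5 or 10); at most the number of
#'   known pairs.
#' @param repeats number of independent shuffle/split repetitions.
#' @param seed RNG seed controlling the shuffles (same seed, same folds).
#' @return An object of class `mda_eval`.
#' @export
kfold_cv <- function(dataset, scorer, k_folds = 5, repeats = 1, seed = 1L,
                     balance_negatives = FALSE) {
  stopifnot(inherits(dataset, "association_dataset"),
            k_folds >= 2, repeats >= 1)
  M <- dataset$M
  Mp <- t(M)
  pos <- which(Mp != 0)
  if (k_folds > length(pos)) {
    stop("k_folds exceeds the number of known associations")
  }
  pool_idx <- .candidate_pool_idx(Mp, balance_negatives, seed)
  n_cand <- length(pool_idx) + 1L
  assignments <- .with_seed(seed, lapply(seq_len(repeats), function(r) {
    split(sample(pos), rep_len(seq_len(k_folds), length(pos)))
  }))
  fold_aucs <- numeric(0)
  all_ranks <- numeric(0)
  for (rep_folds in assignments) {
    for (fold in rep_folds) {
      M2 <- M
      mj <- (fold - 1L) %% nrow(Mp) + 1L
      di <- (fold - 1L) %/% nrow(Mp) + 1L
      M2[cbind(di, mj)] <- 0L
      Z <- scorer(M2)
      ranks <- .mid_ranks(Z[cbind(mj, di)], Z[pool_idx])
      fold_aucs <- c(fold_aucs, roc_auc(ranks, n_cand)$auc)
      all_ranks <- c(all_ranks, ranks)
    }
  }
  ra <- roc_auc(all_ranks, n_cand)
  .mda_eval(attr(scorer, "method_name") %||% "custom",
            sprintf("%dfold", k_folds),
            folds = fold_aucs, roc = ra$roc, auc = ra$auc, ranks = all_ranks,
            n_candidates = n_cand,
            params = list(k_folds = k_folds, repeats = repeats, seed = seed))
}

# Similarity stack shared by all scorers: metabolite GIP kernel as SM,
# semantic + logistic-GIP integration as SD.
.mda_similarities <- function(M, DSS, gamma, omega_prime, a, b, kernel) {
  SM <- gip_kernel(M, "metabolite", omega_prime)
  GD <- gip_kernel(M, "disease", omega_prime)
  GDL <- logistic_transform(GD, a, b)
  SD <- integrate_disease_similarity(DSS, GDL, GD, gamma, kernel)
  list(SM = SM, SD = SD)
}

.mda_network <- function(M, DSS, gamma, omega_prime, a, b, kernel) {
  sim <- .mda_similarities(M, DSS, gamma, omega_prime, a, b, kernel)
  build_hetero(sim$SM, sim$SD, M)
}

.dss_for <- function(dags, Delta, disease_ids) {
  if (is.null(dags) || length(dags) == 0L) {
    matrix(0, length(disease_ids), length(disease_ids),
           dimnames = list(disease_ids, disease_ids))
  } else {
    semantic_similarity_matrix(dags, Delta, disease_ids)
  }
}

#' KATZ scoring pipeline as a reusable scorer
#'
#' Returns a function mapping a (possibly masked) disease x metabolite 0/1
#' matrix to the KATZ score matrix. The disease semantic similarity is
#' computed once from the DAGs (masking associations does not change disease
#' ontology); the GIP kernels, their logistic transform and the integrated
#' disease similarity are recomputed from the matrix handed to each call, so
#' cross-validation masking carries no similarity leakage. Setting
#' `static_M` freezes the GIP similarities to those of the given full matrix
#' instead (the leaky variant, for comparison only).
#'
#' @param dags named list of [disease_dag()]s (may be `NULL`: semantic
#'   similarity is then all-zero and disease similarity is purely
#'   GIP-derived).
#' @param delta KATZ per-step attenuation (default 0.1).
#' @param k truncation length 2, 3 or 4, or `"closed"` for the closed form.
#' @param gamma weight of the GIP-derived term in the integrated disease
#'   similarity (default 0.1).
#' @param Delta semantic decay factor (default 0.5).
#' @param omega_prime GIP bandwidth multiplier (default 1).
#' @param a,b logistic transform parameters (defaults -15, log(9999)).
#' @param kernel `"gdl"` or `"gd"`, see [integrate_disease_similarity()].
#' @param static_M optional full disease x metabolite matrix from which to
#'   compute the similarities once, ignoring per-call masking.
#' @return Function `f(M)` returning a metabolite x disease score matrix.
#' @export
katz_scorer <- function(dags = NULL, delta = 0.1, k = 2, gamma = 0.1,
                        Delta = 0.5, omega_prime = 1, a = -15, b = log(9999),
                        kernel = c("gdl", "gd"), static_M = NULL) {
  kernel <- match.arg(kernel)
  cache <- new.env(parent = emptyenv())
  f <- function(M) {
    ids <- rownames(M) %||% paste0("d", seq_len(nrow(M)))
    key <- paste(ids, collapse = "\r")
    if (is.null(cache$dss) || !identical(cache$key, key)) {
      cache$dss <- .dss_for(dags, Delta, ids)
      cache$key <- key
    }
    sim <- .mda_similarities(if (is.null(static_M)) M else static_M,
                             cache$dss, gamma, omega_prime, a, b, kernel)
    # with static_M the similarities are frozen, but walks still use the
    # masked adjacency handed to this call
    net <- build_hetero(sim$SM, sim$SD, M)
    if (identical(k, "closed")) katz_closed(net, delta)
    else katz_truncated(net, delta, k)
  }
  attr(f, "method_name") <- "katz"
  f
}

# shared personalized diffusion on the heterogeneous network:
# p <- (1 - restart) * (W p + e * dangling_mass) + restart * e, per seed disease
.diffuse <- function(net, restart, max_iter, tol, allow_dangling, full) {
  Mstar <- net$Mstar
  cs <- colSums(Mstar)
  dangling <- cs == 0
  if (any(dangling) && !allow_dangling) {
    stop("network has zero-degree node(s): transition matrix not column-normalizable")
  }
  cs[dangling] <- 1
  W <- Mstar / rep(cs, each = nrow(Mstar))
  n <- nrow(Mstar)
  n_m <- length(net$metabolite_ids)
  n_d <- length(net$disease_ids)
  E <- matrix(0, n, n_d)
  E[cbind(n_m + seq_len(n_d), seq_len(n_d))] <- 1
  P <- E
  for (iter in seq_len(max_iter)) {
    mass <- colSums(P[dangling, , drop = FALSE])
    P_new <- (1 - restart) * (W %*% P + E * rep(mass, each = n)) + restart * E
    res <- max(colSums(abs(P_new - P)))
    P <- P_new
    if (res < tol) {
      out <- if (full) P else P[seq_len(n_m), , drop = FALSE]
      if (!full) dimnames(out) <- list(net$metabolite_ids, net$disease_ids)
      return(out)
    }
  }
  stop(sprintf("diffusion did not converge in %d iterations (residual %.3g)",
               max_iter, res))
}

#' Random walk with restart on the heterogeneous network
#'
#' For every disease, a walker starts at the disease node of the
#' heterogeneous network, follows the column-normalized network weights with
#' probability `1 - restart_prob`, and teleports back to the seed with
#' probability `restart_prob`; iteration runs until the L1 change falls
#' below `tol`. Each stationary vector is a probability distribution (sums
#' to 1); the metabolite entries are returned as scores.
#'
#' @param net a [build_hetero()] network.
#' @param restart_prob restart probability in (0, 1\] (default 0.7).
#' @param max_iter maximum iterations before a non-convergence error.
#' @param tol L1 convergence tolerance.
#' @param full if `TRUE`, return the full node x disease stationary matrix
#'   (metabolites then diseases) instead of the metabolite block.
#' @return Numeric score matrix (`n_m x n_d`, or `(n_m+n_d) x n_d` when
#'   `full`).
#' @export
rwr_score <- function(net, restart_prob = 0.7, max_iter = 1000, tol = 1e-10,
                      full = FALSE) {
  stopifnot(inherits(net, "hetero_network"),
            restart_prob > 0, restart_prob <= 1)
  .diffuse(net, restart_prob, max_iter, tol, allow_dangling = FALSE,
           full = full)
}

#' Personalized PageRank on the heterogeneous network
#'
#' Standard damped PageRank on the weighted heterogeneous graph,
#' personalized to each disease node in turn (teleport vector = that
#' disease); mass of dangling nodes is redistributed to the personalization
#' vector. Equivalent to [rwr_score()] with restart `1 - damping` plus
#' dangling handling; kept separate because the two baselines use different
#' conventional parameters.
#'
#' @inheritParams rwr_score
#' @param damping damping factor in \[0, 1) (default 0.85).
#' @return Numeric score matrix as in [rwr_score()].
#' @export
pagerank_score <- function(net, damping = 0.85, max_iter = 1000, tol = 1e-10,
                           full = FALSE) {
  stopifnot(inherits(net, "hetero_network"), damping >= 0, damping < 1)
  .diffuse(net, 1 - damping, max_iter, tol, allow_dangling = TRUE,
           full = full)
}

#' @rdname katz_scorer
#' @param restart_prob,max_iter,tol see [rwr_score()].
#' @export
rwr_scorer <- function(dags = NULL, restart_prob = 0.7, gamma = 0.1,
                       Delta = 0.5, omega_prime = 1, a = -15, b = log(9999),
                       kernel = c("gdl", "gd"), max_iter = 1000, tol = 1e-10) {
  kernel <- match.arg(kernel)
  cache <- new.env(parent = emptyenv())
  f <- function(M) {
    ids <- rownames(M) %||% paste0("d", seq_len(nrow(M)))
    key <- paste(ids, collapse = "\r")
    if (is.null(cache$dss) || !identical(cache$key, key)) {
      cache$dss <- .dss_for(dags, Delta, ids)
      cache$key <- key
    }
    net <- .mda_network(M, cache$dss, gamma, omega_prime, a, b, kernel)
    rwr_score(net, restart_prob, max_iter, tol)
  }
  attr(f, "method_name") <- "rwr"
  f
}

#' @rdname katz_scorer
#' @param damping see [pagerank_score()].
#' @export
pagerank_scorer <- function(dags = NULL, damping = 0.85, gamma = 0.1,
                            Delta = 0.5, omega_prime = 1, a = -15,
                            b = log(9999), kernel = c("gdl", "gd"),
                            max_iter = 1000, tol = 1e-10) {
  kernel <- match.arg(kernel)
  cache <- new.env(parent = emptyenv())
  f <- function(M) {
    ids <- rownames(M) %||% paste0("d", seq_len(nrow(M)))
    key <- paste(ids, collapse = "\r")
    if (is.null(cache$dss) || !identical(cache$key, key)) {
      cache$dss <- .dss_for(dags, Delta, ids)
      cache$key <- key
    }
    net <- .mda_network(M, cache$dss, gamma, omega_prime, a, b, kernel)
    pagerank_score(net, damping, max_iter, tol)
  }
  attr(f, "method_name") <- "pagerank"
  f
}

#' Label-permuted null version of a scorer
#'
#' Wraps a scorer and randomly permutes the metabolite rows of every score
#' matrix it produces, destroying any association between scores and the
#' true pairs while preserving the score distribution. The permutation
#' sequence is deterministic under `seed` (one fresh permutation per call).
#' Used as the chance baseline that a real scorer must beat.
#'
#' @param scorer a scorer function, e.g. from [katz_scorer()].
#' @param seed RNG seed for the permutation sequence.
#' @return A scorer function with method name `"<name>_null"`.
#' @export
null_scorer <- function(scorer, seed = 1L) {
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  f <- function(M) {
    Z <- scorer(M)
    counter$i <- counter$i + 1L
    perm <- .with_seed(seed + counter$i, sample.int(nrow(Z)))
    Z2 <- Z[perm, , drop = FALSE]
    rownames(Z2) <- rownames(Z)
    Z2
  }
  attr(f, "method_name") <-
    paste0(attr(scorer, "method_name") %||% "custom", "_null")
  f
}
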