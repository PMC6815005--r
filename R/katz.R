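# Heterogeneous network assembly and KATZ scoring.

#' Assemble the heterogeneous metabolite-disease network
#'
#' Stacks the metabolite similarity block `SM`, the disease similarity block
#' `SD` and the bipartite association matrix into one symmetric block matrix
#' with metabolite nodes first:
#' \deqn{M^* = \begin{bmatrix} SM & M' \\ M'^T & SD \end{bmatrix}}
#' where `M'` is the association matrix oriented metabolite-rows by
#' disease-columns (the transpose of the data-module convention, converted
#' here).
#'
#' @param SM metabolite similarity matrix (`n_m x n_m`, symmetric).
#' @param SD disease similarity matrix (`n_d x n_d`, symmetric).
#' @param M 0/1 association matrix, diseases in rows, metabolites in columns.
#' @param tol symmetry tolerance for `SM`/`SD`.
#' @return An object of class `hetero_network`: list with `SM`, `SD`, `M`
#'   (metabolite x disease orientation), `Mstar`, `metabolite_ids`,
#'   `disease_ids`.
#' @export
build_hetero <- function(SM, SD, M, tol = 1e-8) {
  stopifnot(is.matrix(SM), is.matrix(SD), is.matrix(M))
  n_d <- nrow(M); n_m <- ncol(M)
  if (n_m == 0L || n_d == 0L) stop("empty association matrix")
  if (!identical(dim(SM), c(n_m, n_m))) stop("SM shape does not match ncol(M)")
  if (!identical(dim(SD), c(n_d, n_d))) stop("SD shape does not match nrow(M)")
  if (max(abs(SM - t(SM))) > tol) stop("SM is not symmetric")
  if (max(abs(SD - t(SD))) > tol) stop("SD is not symmetric")
  Mp <- t(M)  # metabolite rows x disease columns
  storage.mode(Mp) <- "double"
  Mstar <- rbind(cbind(SM, Mp), cbind(t(Mp), SD))
  metabolite_ids <- colnames(M) %||% paste0("m", seq_len(n_m))
  disease_ids <- rownames(M) %||% paste0("d", seq_len(n_d))
  dimnames(Mstar) <- NULL
  structure(list(SM = unname(SM), SD = unname(SD), M = unname(Mp),
                 Mstar = Mstar, metabolite_ids = metabolite_ids,
                 disease_ids = disease_ids),
            class = "hetero_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hetero_network <- function(x, ...) {
  cat(sprintf("<hetero_network> %d metabolites + %d diseases (%d nodes)\n",
              length(x$metabolite_ids), length(x$disease_ids), nrow(x$Mstar)))
  invisible(x)
}

.score_matrix <- function(Z, net, params) {
  dimnames(Z) <- list(net$metabolite_ids, net$disease_ids)
  attr(Z, "params") <- params
  Z
}

#' KATZ score by truncated path-length series
#'
#' Sums walk counts of length up to `k` on the heterogeneous network,
#' down-weighting a walk of length `l` by `delta^l`, and returns the
#' metabolite x disease block:
#' \deqn{Z = \sum_{l=1}^{k} \delta^l \left[(M^*)^l\right]_{m,d}.}
#' For `k = 2` this is exactly `delta*M + delta^2*(SM %*% M + M %*% SD)`;
#' higher orders are computed as the exact block of the matrix-power sum
#' (only the disease columns of each power are propagated, so no full power
#' is ever materialized).
#'
#' @param net a [build_hetero()] network.
#' @param delta positive per-step attenuation factor (default 0.1).
#' @param k maximum walk length, one of 2, 3, 4 (default 2).
#' @return Numeric score matrix `n_m x n_d` with an attribute `params`.
#' @export
katz_truncated <- function(net, delta = 0.1, k = 2) {
  stopifnot(inherits(net, "hetero_network"), delta > 0)
  if (!(length(k) == 1L && k %in% c(2, 3, 4))) {
    stop("k must be one of 2, 3, 4")
  }
  n_m <- length(net$metabolite_ids)
  n_d <- length(net$disease_ids)
  d_cols <- n_m + seq_len(n_d)
  # C holds the disease columns of (Mstar)^l
  C <- net$Mstar[, d_cols, drop = FALSE]
  S <- delta * C
  for (l in seq_len(k - 1L)) {
    C <- net$Mstar %*% C
    S <- S + delta^(l + 1L) * C
  }
  .score_matrix(S[seq_len(n_m), , drop = FALSE], net,
                list(method = "katz_truncated", k = k, delta = delta))
}

#' KATZ score in closed form
#'
#' The infinite path-length series converges to
#' `(I - delta * Mstar)^{-1} - I` whenever `delta` is below the reciprocal
#' spectral radius of the network; the metabolite x disease block of that
#' limit is returned (computed by a linear solve on the disease columns, not
#' by explicit inversion). An error is raised when the series diverges; a
#' warning is emitted when `delta` exceeds the literal adjacency-norm bound
#' `1 / sigma_max(M)^2` some authors quote (see [delta_bound()]).
#'
#' @inheritParams katz_truncated
#' @return Numeric score matrix `n_m x n_d`.
#' @export
katz_closed <- function(net, delta = 0.1) {
  stopifnot(inherits(net, "hetero_network"), delta > 0)
  bounds <- delta_bound(net)
  if (delta * (1 / bounds$spectral) >= 1) {
    stop(sprintf("series divergent: delta * rho(Mstar) = %.4f >= 1",
                 delta / bounds$spectral))
  }
  if (delta > bounds$adjacency_norm) {
    warning(sprintf(
      "delta = %g exceeds the literal adjacency-norm bound 1/||M||^2 = %g",
      delta, bounds$adjacency_norm))
  }
  n <- nrow(net$Mstar)
  n_m <- length(net$metabolite_ids)
  n_d <- length(net$disease_ids)
  A <- diag(n) - delta * net$Mstar
  E <- diag(n)[, n_m + seq_len(n_d), drop = FALSE]
  X <- solve(A, E)  # disease columns of (I - delta Mstar)^{-1}
  # subtracting I only touches the diagonal blocks, not the m x d block
  .score_matrix(X[seq_len(n_m), , drop = FALSE], net,
                list(method = "katz_closed", delta = delta))
}

#' Convergence bound for the KATZ attenuation factor
#'
#' The closed-form KATZ series converges iff `delta < 1 / rho(Mstar)` where
#' `rho` is the spectral radius of the heterogeneous matrix; that value is
#' returned as `spectral`. For reference the literal bound
#' `1 / sigma_max(M)^2` on the bipartite association block alone (quoted in
#' parts of the KATZ literature, but neither necessary nor sufficient on the
#' similarity-augmented network) is returned as `adjacency_norm`.
#'
#' @param net a [build_hetero()] network.
#' @return List with numeric elements `spectral` and `adjacency_norm`.
#' @export
delta_bound <- function(net) {
  stopifnot(inherits(net, "hetero_network"))
  rho <- max(abs(eigen(net$Mstar, symmetric = TRUE, only.values = TRUE)$values))
  smax <- if (all(net$M == 0)) 0 else max(svd(net$M, nu = 0, nv = 0)$d)
  list(spectral = if (rho > 0) 1 / rho else Inf,
       adjacency_norm = if (smax > 0) 1 / smax^2 else Inf)
}

#' Rank novel candidate metabolites for one disease
#'
#' Sorts metabolites by descending KATZ score for the requested disease,
#' excluding metabolites already known to be associated with it. Ties are
#' broken lexicographically on the metabolite id (stable and documented).
#'
#' @param Z score matrix from [katz_truncated()]/[katz_closed()]
#'   (metabolites x diseases, dimnames set).
#' @param dataset the [association_dataset()] the scores were computed from
#'   (supplies the known pairs to exclude).
#' @param disease_id disease to rank candidates for.
#' @param top optional integer: return only the strongest `top` candidates.
#' @return data.frame with columns `metabolite_id`, `score`, `rank`.
#' @export
rank_candidates <- function(Z, dataset, disease_id, top = NULL) {
  stopifnot(inherits(dataset, "association_dataset"))
  if (!(disease_id %in% colnames(Z))) {
    stop("unknown disease id: ", disease_id)
  }
  known <- dataset$pairs$metabolite_id[dataset$pairs$disease_id == disease_id]
  ids <- setdiff(rownames(Z), known)
  s <- Z[ids, disease_id]
  ord <- order(-s, ids)
  out <- data.frame(metabolite_id = ids[ord], score = unname(s[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  if (!is.null(top)) out <- head(out, top)
  out
}
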