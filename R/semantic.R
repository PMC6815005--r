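# Disease semantic similarity from disease DAGs (Wang-style decay model).

#' Semantic contribution of every ancestor term to a disease
#'
#' The disease term itself contributes 1. Any other term `d` in the DAG
#' contributes `delta * max(contribution of its children)` over children that
#' lie within the disease's term set, so contributions decay geometrically
#' along ancestor chains: terms far from the disease contribute less, and
#' terms at the same level on isomorphic chains contribute the same amount.
#' The semantic value `dv` of the disease is the sum of all contributions.
#'
#' Terms in the DAG from which the disease cannot be reached along
#' parent-to-child edges are not ancestors of the disease; they are excluded
#' from the term set with a warning.
#'
#' @param dag a [disease_dag()].
#' @param delta decay factor in (0, 1) applied per parent-child step.
#' @return An object of class `semantic_contribution`: list with
#'   `disease_id`, `contrib` (named numeric over the term set), `dv`
#'   (semantic value, sum of `contrib`) and `delta`.
#' @export
semantic_contributions <- function(dag, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"), delta > 0, delta < 1)
  D <- dag$disease_id
  # term set T(D): D plus every node that reaches D along parent->child edges
  parents_of <- split(dag$edges$parent, dag$edges$child)
  reach <- D
  frontier <- D
  while (length(frontier)) {
    up <- unique(unlist(parents_of[frontier], use.names = FALSE))
    frontier <- setdiff(up, reach)
    reach <- c(reach, frontier)
  }
  dropped <- setdiff(dag$nodes, reach)
  if (length(dropped)) {
    warning("term(s) not ancestral to ", D, " excluded: ",
            paste(dropped, collapse = ", "))
  }
  children_of <- split(dag$edges$child, dag$edges$parent)
  memo <- new.env(parent = emptyenv())
  contrib_of <- function(term) {
    if (!is.null(got <- memo[[term]])) return(got)
    val <- if (term == D) 1 else {
      ch <- intersect(children_of[[term]], reach)
      delta * max(vapply(ch, contrib_of, numeric(1L)))
    }
    memo[[term]] <- val
    val
  }
  contrib <- vapply(reach, contrib_of, numeric(1L))
  structure(list(disease_id = D, contrib = contrib, dv = sum(contrib),
                 delta = delta),
            class = "semantic_contribution")
}

#' Semantic similarity between two diseases
#'
#' The similarity is the summed contribution of shared ancestor terms in both
#' DAGs, normalized by the two semantic values:
#' `sum over shared t of (C_i(t) + C_j(t)) / (DV_i + DV_j)`. It is symmetric,
#' lies in \[0, 1\], equals 1 for identical term sets and 0 when the term
#' sets are disjoint.
#'
#' @param sc_i,sc_j [semantic_contributions()] computed with the same `delta`.
#' @return A single numeric similarity.
#' @export
semantic_similarity <- function(sc_i, sc_j) {
  stopifnot(inherits(sc_i, "semantic_contribution"),
            inherits(sc_j, "semantic_contribution"))
  if (!isTRUE(all.equal(sc_i$delta, sc_j$delta))) {
    stop("semantic contributions computed with different delta values")
  }
  shared <- intersect(names(sc_i$contrib), names(sc_j$contrib))
  if (length(shared) == 0L) return(0)
  sum(sc_i$contrib[shared] + sc_j$contrib[shared]) / (sc_i$dv + sc_j$dv)
}

#' Pairwise disease semantic similarity matrix
#'
#' Diseases for which no DAG is available get an all-zero row and column
#' (including the diagonal); downstream similarity integration then falls
#' back to the GIP-derived similarity for those entries. The returned matrix
#' carries a logical attribute `has_dag` marking which diseases had a DAG.
#'
#' @param dags named list of [disease_dag()] objects (names = disease ids).
#' @param delta decay factor, see [semantic_contributions()].
#' @param disease_ids ids ordering the rows/columns; defaults to
#'   `names(dags)`. May include diseases absent from `dags`.
#' @return Symmetric numeric matrix (`length(disease_ids)` square) with unit
#'   diagonal for diseases that have a DAG.
#' @export
semantic_similarity_matrix <- function(dags, delta = 0.5,
                                       disease_ids = names(dags)) {
  stopifnot(length(disease_ids) > 0L)
  n <- length(disease_ids)
  DSS <- matrix(0, n, n, dimnames = list(disease_ids, disease_ids))
  has_dag <- disease_ids %in% names(dags)
  sc <- lapply(dags[intersect(disease_ids, names(dags))],
               semantic_contributions, delta = delta)
  idx <- which(has_dag)
  for (a in seq_along(idx)) {
    i <- idx[a]
    DSS[i, i] <- 1
    if (a < length(idx)) {
      for (b in (a + 1L):length(idx)) {
        j <- idx[b]
        s <- semantic_similarity(sc[[disease_ids[i]]], sc[[disease_ids[j]]])
        DSS[i, j] <- s
        DSS[j, i] <- s
      }
    }
  }
  attr(DSS, "has_dag") <- setNames(has_dag, disease_ids)
  DSS
}
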