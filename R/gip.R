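# Gaussian Interaction Profile kernel similarities and disease-similarity
# integration.

#' Gaussian Interaction Profile (GIP) kernel similarity
#'
#' Each node's interaction profile is its 0/1 slice of the association
#' matrix: rows for diseases, columns for metabolites. The kernel is
#' `K(u, v) = exp(-omega * ||IP(u) - IP(v)||^2)` with bandwidth
#' `omega = omega_prime / mean(||IP||^2)` over all profiles of that node
#' type. The result is a valid RBF kernel: symmetric, positive semidefinite,
#' unit diagonal, entries in (0, 1].
#'
#' @param M 0/1 association matrix, diseases in rows, metabolites in columns.
#' @param axis `"metabolite"` (profiles = columns of `M`) or `"disease"`
#'   (profiles = rows).
#' @param omega_prime positive bandwidth multiplier (field convention: 1).
#' @return Symmetric similarity matrix over the chosen node type, dimnames
#'   taken from `M`.
#' @export
gip_kernel <- function(M, axis = c("metabolite", "disease"), omega_prime = 1) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(M), omega_prime > 0)
  P <- if (axis == "metabolite") t(M) else M  # profiles in rows
  storage.mode(P) <- "double"
  sq <- rowSums(P^2)
  msq <- mean(sq)
  if (msq == 0) {
    stop("all-zero association matrix: GIP bandwidth cannot be normalized")
  }
  omega <- omega_prime / msq
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0
  K <- exp(-omega * D2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  K
}

#' Logistic transform of a disease GIP similarity matrix
#'
#' Applies `1 / (1 + exp(a * s + b))` elementwise. With the defaults
#' `a = -15`, `b = log(9999)` a raw similarity of 0 maps to exactly 1e-4 and
#' a raw similarity of 1 maps to about 0.997, sharpening the contrast of the
#' kernel. For `a < 0` the transform is strictly increasing, so entry
#' ordering (and symmetry) is preserved.
#'
#' @param S similarity matrix (typically the disease GIP kernel).
#' @param a slope; negative for a monotonically increasing transform.
#' @param b offset; `log(9999)` pins the image of 0 at 1e-4.
#' @return Matrix of the same shape with entries in (0, 1).
#' @export
logistic_transform <- function(S, a = -15, b = log(9999)) {
  x <- a * S + b
  x[x > 700] <- 700  # exp() overflow guard; result underflows to 0 anyway
  1 / (1 + exp(x))
}

#' Integrate semantic and GIP-derived disease similarity
#'
#' Where the semantic similarity is zero (no shared ancestry, or no DAG
#' available for one of the diseases) the integrated similarity falls back
#' to the logistic-transformed GIP similarity `GDL`. Everywhere else it is
#' the convex combination `(1 - gamma) * DSS + gamma * G`, where `G` is
#' `GDL` by default (`kernel = "gdl"`) or the raw GIP kernel `GD`
#' (`kernel = "gd"`).
#'
#' @param DSS disease semantic similarity matrix.
#' @param GDL logistic-transformed disease GIP similarity.
#' @param GD raw disease GIP kernel; required when `kernel = "gd"`.
#' @param gamma weight in \[0, 1\] of the GIP-derived term.
#' @param kernel which GIP-derived matrix enters the weighted branch.
#' @return Symmetric integrated disease similarity matrix.
#' @export
integrate_disease_similarity <- function(DSS, GDL, GD = NULL, gamma = 0.1,
                                         kernel = c("gdl", "gd")) {
  kernel <- match.arg(kernel)
  stopifnot(gamma >= 0, gamma <= 1, identical(dim(DSS), dim(GDL)))
  if (!is.null(dimnames(DSS)) && !is.null(dimnames(GDL)) &&
      !identical(dimnames(DSS), dimnames(GDL))) {
    stop("DSS and GDL disease orderings differ")
  }
  G <- if (kernel == "gdl") GDL else {
    if (is.null(GD)) stop("kernel = \"gd\" requires the raw GIP matrix GD")
    stopifnot(identical(dim(GD), dim(DSS)))
    GD
  }
  SD <- (1 - gamma) * DSS + gamma * G
  zero <- DSS == 0
  SD[zero] <- GDL[zero]
  (SD + t(SD)) / 2
}
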