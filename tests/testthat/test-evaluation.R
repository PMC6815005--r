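test_that("rank-threshold ROC/AUC agrees with brute-force Mann-Whitney", {
  expect_equal(roc_auc(c(1, 1, 1), 10)$auc, 1)
  expect_equal(roc_auc(2, 3)$auc, 0.5)
  expect_error(roc_auc(numeric(), 10), "no held-out")

  set.seed(31)
  for (rep in 1:50) {
    n <- sample(2:20, 1)
    p <- sample(1:6, 1)
    ranks <- sample(n, p, replace = TRUE)
    expect_equal(roc_auc(ranks, n)$auc, auc_oracle(ranks, n),
                 tolerance = 1e-12)
  }
})

test_that("ROC curves start at (0,0), end at (1,1) and are monotone", {
  set.seed(32)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    ranks <- sample(n, sample(1:8, 1), replace = TRUE)
    roc <- roc_auc(ranks, n)$roc
    expect_equal(roc$fpr[1], 0)
    expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1)
    expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= -1e-12))
    expect_true(all(diff(roc$tpr) >= -1e-12))
  }
})

test_that("uniformly random ranks give chance-level AUC", {
  set.seed(33)
  ranks <- sample(50, 1e4, replace = TRUE)
  expect_equal(roc_auc(ranks, 50)$auc, 0.5, tolerance = 0.02)
})

test_that("tied scores receive fractional mid-ranks", {
  expect_equal(.mid_ranks <- katzmda:::.mid_ranks(1, c(1, 1, 0)), 2)
  expect_equal(katzmda:::.mid_ranks(0.5, c(1, 0, 0)), 2)
})

test_that("LOOCV masks exactly one association per trial and never leaks", {
  ds <- tiny_dataset()
  seen <- new.env(); seen$sums <- integer()
  spy <- function(M) {
    seen$sums <- c(seen$sums, sum(M))
    matrix(runif(length(M)), ncol(M), nrow(M),
           dimnames = list(colnames(M), rownames(M)))
  }
  ev <- loocv(ds, spy)
  expect_length(seen$sums, 3L)            # one trial per known pair
  expect_true(all(seen$sums == 2L))       # |pairs| - 1 ones in each
  expect_length(ev$ranks, 3L)
  expect_equal(ev$n_candidates, 2L)       # 1 unknown pair + the held-out
})

test_that("an oracle scorer achieves AUC 1 and a wrecked one AUC 0.5-ish", {
  gen <- synth_generate(synth_config(n_d = 8, n_m = 16, n_clusters = 2,
                                     within_cluster_assoc_prob = 0.6,
                                     background_assoc_prob = 0.05, seed = 9))
  ds <- gen$dataset
  full <- t(adjacency(ds))
  oracle <- function(M) full        # knows every true pair, masked or not
  expect_equal(loocv(ds, oracle)$auc, 1)
})

test_that("k-fold splits are seeded, near-equal and mask whole folds", {
  ds <- toy_dataset()
  counting <- new.env(); counting$sums <- integer()
  spy <- function(M) {
    counting$sums <- c(counting$sums, sum(M))
    set.seed(sum(M * seq_along(M)) %% 1000L)  # deterministic pseudo-scores
    matrix(runif(length(M)), ncol(M), nrow(M),
           dimnames = list(colnames(M), rownames(M)))
  }
  ev1 <- kfold_cv(ds, spy, k_folds = 5, seed = 99)
  sums1 <- counting$sums
  counting$sums <- integer()
  ev2 <- kfold_cv(ds, spy, k_folds = 5, seed = 99)
  expect_identical(ev1$folds, ev2$folds)
  expect_identical(sums1, counting$sums)
  expect_length(ev1$folds, 5L)
  expect_true(all(150L - sums1 == 30L))   # every fold masks |pairs|/k ones
  expect_error(kfold_cv(ds, spy, k_folds = 151), "exceeds")
})

test_that("k-fold with one pair per fold reduces to the LOOCV ranks", {
  ds <- tiny_dataset()
  det_scorer <- function(M) {
    (t(M) * 0.5 + 0.1) + outer(seq_len(ncol(M)), seq_len(nrow(M))) / 100
  }
  wrap <- function(M) {
    Z <- det_scorer(M); dimnames(Z) <- list(colnames(M), rownames(M)); Z
  }
  lo <- loocv(ds, wrap)
  kf <- kfold_cv(ds, wrap, k_folds = 3, seed = 1)
  expect_equal(sort(kf$ranks), sort(lo$ranks))
})

test_that("GIP similarity is rebuilt from the masked matrix inside folds", {
  gen <- synth_generate(synth_config(n_d = 6, n_m = 12, n_clusters = 2,
                                     within_cluster_assoc_prob = 0.7,
                                     background_assoc_prob = 0.05, seed = 3))
  M <- adjacency(gen$dataset)
  masked <- M; masked[1, which(masked[1, ] == 1)] <- 0L
  # the masked disease's GIP profile collapses, so its kernel row changes
  expect_gt(max(abs(gip_kernel(M, "disease") -
                    gip_kernel(masked, "disease"))), 0.01)
  dynamic <- katz_scorer(gen$dags)
  static <- katz_scorer(gen$dags, static_M = M)
  expect_gt(max(abs(dynamic(masked) - static(masked))), 1e-6)
  # on the unmasked matrix the two variants coincide
  expect_equal(unclass(dynamic(M)), unclass(static(M)), tolerance = 1e-12)
})

test_that("restart probability one keeps all mass on the seed nodes", {
  set.seed(35)
  net <- rand_net(4, 3)
  P <- rwr_score(net, restart_prob = 1, full = TRUE)
  E <- matrix(0, 7, 3); E[cbind(4 + 1:3, 1:3)] <- 1
  expect_equal(P, E, tolerance = 1e-12)
})

test_that("RWR matches the direct linear-system solution on a small network", {
  set.seed(36)
  net <- rand_net(2, 2)
  r <- 0.6
  W <- net$Mstar / rep(colSums(net$Mstar), each = 4)
  for (j in 1:2) {
    e <- numeric(4); e[2 + j] <- 1
    expected <- solve(diag(4) - (1 - r) * W, r * e)
    got <- rwr_score(net, r, full = TRUE)[, j]
    expect_equal(got, expected, tolerance = 1e-8)
  }
})

test_that("RWR stationary vectors conserve probability", {
  set.seed(37)
  net <- rand_net(6, 4)
  P <- rwr_score(net, full = TRUE)
  expect_equal(unname(colSums(P)), rep(1, 4), tolerance = 1e-9)
})

test_that("PageRank agrees with igraph's personalized implementation", {
  set.seed(38)
  net <- rand_net(4, 3)
  # directed graph so that self-loop weights are not double-counted in the
  # node strengths igraph normalizes by
  g <- igraph::graph_from_adjacency_matrix(net$Mstar, mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  P <- pagerank_score(net, damping = 0.85, full = TRUE)
  for (j in 1:3) {
    pers <- numeric(7); pers[4 + j] <- 1
    ig <- igraph::page_rank(g, damping = 0.85, personalized = pers,
                            weights = igraph::E(g)$weight)$vector
    expect_equal(unname(P[, j]), unname(ig), tolerance = 1e-6)
  }
})

test_that("zero damping returns the personalization vectors", {
  set.seed(39)
  net <- rand_net(3, 2)
  P <- pagerank_score(net, damping = 0, full = TRUE)
  E <- matrix(0, 5, 2); E[cbind(3 + 1:2, 1:2)] <- 1
  expect_equal(P, E, tolerance = 1e-12)
})

test_that("symmetric metabolites receive identical diffusion scores", {
  # two metabolites with identical connectivity are interchangeable
  M <- matrix(c(1, 1, 0), 1, 3,
              dimnames = list("d1", c("m1", "m2", "m3")))
  SM <- diag(3); SD <- diag(1)
  net <- build_hetero(SM, SD, M)
  s <- rwr_score(net, 0.5)
  expect_equal(s["m1", 1], s["m2", 1], tolerance = 1e-10)
  p <- pagerank_score(net, 0.85)
  expect_equal(p["m1", 1], p["m2", 1], tolerance = 1e-10)
})

test_that("diffusion errors on non-normalizable or non-converging input", {
  M <- matrix(c(1, 0), 1, 2, dimnames = list("d1", c("m1", "m2")))
  net <- build_hetero(matrix(0, 2, 2), matrix(0, 1, 1), M)  # m2 isolated
  expect_error(rwr_score(net), "normalizable")
  net2 <- rand_net(3, 2)
  expect_error(rwr_score(net2, restart_prob = 1e-9, max_iter = 2),
               "converge")
})

test_that("the label-permuted null scorer is deterministic and chance-level", {
  gen <- synth_generate(synth_config(n_d = 8, n_m = 20, n_clusters = 2,
                                     within_cluster_assoc_prob = 0.6,
                                     background_assoc_prob = 0.05, seed = 5))
  base <- katz_scorer(gen$dags)
  n1 <- null_scorer(base, seed = 4)
  n2 <- null_scorer(base, seed = 4)
  e1 <- kfold_cv(gen$dataset, n1, k_folds = 3, seed = 2)
  e2 <- kfold_cv(gen$dataset, n2, k_folds = 3, seed = 2)
  expect_identical(e1$folds, e2$folds)
  expect_equal(e1$method, "katz_null")
  expect_gt(e1$auc, 0.2)
  expect_lt(e1$auc, 0.8)
})
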