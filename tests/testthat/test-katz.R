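test_that("heterogeneous matrix assembles blocks in the documented order", {
  SM <- diag(2); SD <- diag(1)
  M <- matrix(c(1, 0), nrow = 1,
              dimnames = list("d1", c("m1", "m2")))  # disease x metabolite
  net <- build_hetero(SM, SD, M)
  expect_equal(dim(net$Mstar), c(3L, 3L))
  expect_true(isSymmetric(net$Mstar))
  expect_equal(diag(net$Mstar), rep(1, 3))
  expect_equal(net$Mstar[1, 3], 1)  # metabolite m1 <-> disease d1
  expect_equal(net$Mstar[2, 3], 0)
  expect_equal(net$metabolite_ids, c("m1", "m2"))
  expect_equal(net$disease_ids, "d1")

  expect_error(build_hetero(SM, SD, matrix(numeric(), 1, 0)), "empty")
  asym <- matrix(c(1, 0.5, 0, 1), 2, 2)
  expect_error(build_hetero(asym, SD, M), "not symmetric")
  # identity blocks with no associations give the identity network
  net0 <- build_hetero(diag(2), diag(1), matrix(0, 1, 2))
  expect_equal(net0$Mstar, diag(3))
})

test_that("truncated KATZ reproduces the k = 2 closed expression", {
  # with zero similarity blocks only length-1 paths survive
  M <- matrix(c(1, 0, 1, 1), 2, 2,
              dimnames = list(c("d1", "d2"), c("m1", "m2")))
  net <- build_hetero(matrix(0, 2, 2), matrix(0, 2, 2), M)
  Z <- katz_truncated(net, delta = 0.3, k = 2)
  expect_equal(unname(unclass(Z)), 0.3 * t(M), ignore_attr = TRUE)

  # 1 metabolite, 1 disease, identity similarities: delta + 2 delta^2
  net1 <- build_hetero(diag(1), diag(1),
                       matrix(1, 1, 1, dimnames = list("d1", "m1")))
  Z1 <- katz_truncated(net1, delta = 0.1, k = 2)
  expect_equal(Z1[1, 1], 0.1 + 0.01 * 2)

  expect_error(katz_truncated(net1, 0.1, k = 5), "k must be")
})

test_that("higher-order increments equal the exact matrix-power block", {
  set.seed(21)
  net <- rand_net(5, 4)
  d <- 0.2
  Z2 <- katz_truncated(net, d, 2)
  Z3 <- katz_truncated(net, d, 3)
  Z4 <- katz_truncated(net, d, 4)
  P3 <- katz_block_oracle(net, 1, 3) - katz_block_oracle(net, 1, 2)  # block of Mstar^3
  P4 <- katz_block_oracle(net, 1, 4) - katz_block_oracle(net, 1, 3)
  expect_equal(unclass(Z3 - Z2), d^3 * P3, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unclass(Z4 - Z3), d^4 * P4, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("the corrected k = 3 block expansion holds", {
  set.seed(22)
  net <- rand_net(6, 3)
  d <- 0.15
  SM <- net$SM; SD <- net$SD; Mp <- net$M
  expected <- d^3 * (SM %*% SM %*% Mp + Mp %*% t(Mp) %*% Mp +
                     SM %*% Mp %*% SD + Mp %*% SD %*% SD)
  got <- katz_truncated(net, d, 3) - katz_truncated(net, d, 2)
  expect_equal(unclass(got), expected, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("closed form equals the series limit and flags divergence", {
  # two-node geometric case: scores delta*c / (1 - delta^2 c^2)
  cval <- 0.8; d <- 0.5
  net <- build_hetero(matrix(0, 1, 1), matrix(0, 1, 1),
                      matrix(cval, 1, 1, dimnames = list("d1", "m1")))
  Z <- katz_closed(net, d)
  expect_equal(Z[1, 1], d * cval / (1 - d^2 * cval^2), tolerance = 1e-12)

  set.seed(23)
  net <- rand_net(4, 2)
  rho <- 1 / delta_bound(net)$spectral
  d <- 0.5 / rho
  series <- 0
  for (l in 1:40) series <- series + d^l *
      (katz_block_oracle(net, 1, l) - if (l > 1) katz_block_oracle(net, 1, l - 1) else 0)
  expect_equal(unclass(suppressWarnings(katz_closed(net, d))), series,
               ignore_attr = TRUE, tolerance = 1e-8)

  expect_error(suppressWarnings(katz_closed(net, 1.5 / rho)), "divergent")
  # zero network: no paths, zero scores
  net0 <- build_hetero(matrix(0, 2, 2), matrix(0, 1, 1), matrix(0, 1, 2))
  expect_equal(unname(unclass(katz_closed(net0, 0.5))), matrix(0, 2, 1),
               ignore_attr = TRUE)
})

test_that("delta bound matches an independent spectral-norm computation", {
  net <- build_hetero(diag(2), diag(1), matrix(0, 1, 2))
  expect_equal(delta_bound(net)$spectral, 1)
  net2 <- build_hetero(2 * diag(2), 2 * diag(1), matrix(0, 1, 2))
  expect_equal(delta_bound(net2)$spectral, 0.5)
  set.seed(24)
  net3 <- rand_net(5, 4)
  expect_equal(delta_bound(net3)$spectral,
               1 / max(svd(net3$Mstar)$d), tolerance = 1e-10)
  expect_equal(delta_bound(net3)$adjacency_norm,
               1 / max(svd(net3$M)$d)^2, tolerance = 1e-10)
})

test_that("candidate ranking excludes knowns and breaks ties lexicographically", {
  ds <- tiny_dataset()
  Z <- matrix(c(0.5, 0.5, 0.9, 0.1), 2, 2,
              dimnames = list(c("m1", "m2"), c("d1", "d2")))
  # d2 knows m2 only; m1 is the sole candidate
  r <- rank_candidates(Z, ds, "d2")
  expect_equal(r$metabolite_id, "m1")
  expect_equal(r$score, 0.9)
  expect_error(rank_candidates(Z, ds, "d9"), "unknown disease")

  ds2 <- association_dataset(data.frame(disease_id = "d1",
                                        metabolite_id = "m9"))
  Zt <- matrix(0.4, 3, 1, dimnames = list(c("mC", "mA", "mB"), "d1"))
  expect_equal(rank_candidates(Zt, ds2, "d1")$metabolite_id,
               c("mA", "mB", "mC"))
})

test_that("adding an association never decreases any KATZ score", {
  set.seed(25)
  for (rep in 1:20) {
    n_m <- sample(3:6, 1); n_d <- sample(2:5, 1)
    M <- matrix(rbinom(n_d * n_m, 1, 0.3), n_d, n_m)
    zero <- which(M == 0)
    if (!length(zero)) next
    SM <- rand_sym(n_m); SD <- rand_sym(n_d)
    Z1 <- katz_truncated(build_hetero(SM, SD, M), 0.1, sample(2:4, 1))
    M2 <- M; M2[sample(zero, 1)] <- 1
    Z2 <- katz_truncated(build_hetero(SM, SD, M2), 0.1,
                         attr(Z1, "params")$k)
    expect_true(all(Z2 - Z1 >= -1e-12))
  }
})

test_that("scores are invariant under a metabolite relabelling", {
  set.seed(26)
  net_M <- matrix(rbinom(12, 1, 0.5), 3, 4,
                  dimnames = list(paste0("d", 1:3), paste0("m", 1:4)))
  SM <- rand_sym(4); SD <- rand_sym(3)
  Z <- katz_truncated(build_hetero(SM, SD, net_M), 0.2, 3)
  perm <- sample(4)
  Zp <- katz_truncated(build_hetero(SM[perm, perm], SD,
                                    net_M[, perm]), 0.2, 3)
  expect_equal(unclass(Zp), unclass(Z)[perm, ], ignore_attr = TRUE,
               tolerance = 1e-12)
})
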