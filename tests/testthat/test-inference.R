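test_that("squared_distance matches its definition and checks alignment", {
  P <- equivProfiles:::new_contracted_profile(c("A", "B"), c(0.75, 0.5), 4)
  Q <- equivProfiles:::new_contracted_profile(c("A", "B"), c(0.5, 0.75), 4)
  expect_equal(squared_distance(P, P), 0)
  expect_equal(squared_distance(c(1, 0), c(0, 1)), 2)
  expect_equal(squared_distance(P, Q), 0.125)
  expect_equal(squared_distance(P, Q), squared_distance(Q, P))
  R <- equivProfiles:::new_contracted_profile(c("A", "C"), c(0.5, 0.75), 4)
  expect_error(squared_distance(P, R), "not aligned")
})

test_that("contracted_covariance: degenerate and exact multinomial cases", {
  epd <- ep_from_counts(c(5, 0, 0), canonical_subsets(2, 2), c("A", "B"))
  expect_equal(contracted_covariance(epd), matrix(0, 2, 2), ignore_attr = TRUE)

  # pi = (1/3, 1/3, 1/3) on {A}, {B}, {A,B}, n = 3: p_A = (X1 + X3)/3 with
  # X1 + X3 ~ Binom(3, 2/3), so Var(p_A) = 3 * (2/3) * (1/3) / 9 = 2/27
  ep <- ep_from_counts(c(1, 1, 1), canonical_subsets(2, 2), c("A", "B"))
  V <- contracted_covariance(ep)
  expect_equal(V[1, 1], 2 / 27)
  expect_equal(V[2, 2], 2 / 27)
})

test_that("contracted_covariance matches Monte-Carlo covariance", {
  subsets <- canonical_subsets(2, 2)
  pi <- c(0.2, 0.5, 0.3)
  n <- 40
  ep <- ep_from_counts(pi * n, subsets, c("A", "B"))
  V <- contracted_covariance(ep)

  set.seed(101)
  B <- 50000
  M <- contraction_matrix(2, subsets)
  Z <- t(M %*% rmultinom(B, n, pi) / n)          # B x 2 contracted resamples
  Vmc <- stats::cov(Z)
  ctr <- sweep(Z, 2, colMeans(Z))
  for (i in 1:2) for (j in 1:2) {
    mc_se <- sd(ctr[, i] * ctr[, j]) / sqrt(B)
    expect_lt(abs(V[i, j] - Vmc[i, j]), 3 * mc_se + 1e-12)
  }
})

test_that("distance_se vanishes for identical sample profiles", {
  ann <- toy_ann()
  ep <- build_expanded_profile(c("g1", "g2", "g3"), ann)
  cp <- contract_profile(ep)
  des <- pair_design(3, 3, 0)
  expect_equal(distance_se(cp, cp, ep, ep, NULL, des), 0)
})

test_that("distance_se matches a parametric bootstrap for disjoint lists", {
  s <- 6; k <- 2
  subsets <- canonical_subsets(s, k)
  g <- length(subsets)
  cats <- LETTERS[1:s]
  M <- contraction_matrix(s, subsets)
  n <- 1000; m <- 1000

  set.seed(2024)
  XP <- as.vector(rmultinom(1, n, geometric_profile(0.7, g)))
  XQ <- as.vector(rmultinom(1, m, geometric_profile(0.3, g)))
  epP <- ep_from_counts(XP, subsets, cats)
  epQ <- ep_from_counts(XQ, subsets, cats)
  Pc <- contract_profile(epP); Qc <- contract_profile(epQ)
  se <- distance_se(Pc, Qc, epP, epQ, NULL, pair_design(n, m, 0))

  B <- 20000
  RP <- M %*% (rmultinom(B, n, XP / n) / n)
  RQ <- M %*% (rmultinom(B, m, XQ / m) / m)
  d_star <- colSums((RP - RQ)^2)
  expect_lt(abs(se - sd(d_star)) / sd(d_star), 0.10)
})

test_that("distance_se matches Monte-Carlo sd in shared-feature designs", {
  s <- 6; k <- 2
  subsets <- canonical_subsets(s, k)
  g <- length(subsets)
  cats <- LETTERS[1:s]
  M <- contraction_matrix(s, subsets)
  piP1 <- geometric_profile(0.7, g)
  piQ1 <- geometric_profile(0.3, g)
  piR <- geometric_profile(0.5, g)

  mc_sd <- function(n, m, n0, B = 20000) {
    n1 <- n - n0; m1 <- m - n0
    XP <- rmultinom(B, n1, piP1)
    XQ <- rmultinom(B, m1, piQ1)
    XR <- rmultinom(B, n0, piR)
    D <- M %*% ((XP + XR) / n - (XQ + XR) / m)
    sd(colSums(D * D))
  }
  se_pop <- function(n, m, n0) {
    # delta-method se evaluated at the population profiles via expected counts
    n1 <- n - n0; m1 <- m - n0
    epP <- ep_from_counts(n1 * piP1 + n0 * piR, subsets, cats)
    epQ <- ep_from_counts(m1 * piQ1 + n0 * piR, subsets, cats)
    epR <- ep_from_counts(n0 * piR, subsets, cats)
    distance_se(contract_profile(epP), contract_profile(epQ),
                epP, epQ, epR, pair_design(n, m, n0))
  }

  set.seed(99)
  # balanced shared design (shared covariance term cancels when n == m)
  expect_lt(abs(se_pop(1000, 1000, 100) - mc_sd(1000, 1000, 100)) /
              mc_sd(1000, 1000, 100), 0.10)
  # unbalanced shared design exercises the n0 (1/n - 1/m)^2 term
  expect_lt(abs(se_pop(1000, 500, 200) - mc_sd(1000, 500, 200)) /
              mc_sd(1000, 500, 200), 0.10)
})

test_that("se scales as 1/sqrt(c) in the total sample size", {
  s <- 4
  subsets <- canonical_subsets(s, 2)
  g <- length(subsets)
  cats <- LETTERS[1:s]
  piP <- geometric_profile(0.6, g)
  piQ <- geometric_profile(0.4, g)
  se_at <- function(n, m) {
    epP <- ep_from_counts(n * piP, subsets, cats)
    epQ <- ep_from_counts(m * piQ, subsets, cats)
    distance_se(contract_profile(epP), contract_profile(epQ),
                epP, epQ, NULL, pair_design(n, m, 0))
  }
  expect_equal(se_at(400, 400) / se_at(100, 100), 0.5, tolerance = 1e-10)
})

test_that("equivalence_test_stat reproduces the normal-theory example", {
  res <- equivalence_test_stat(d_hat = 0.1, se_hat = 0.05, delta = 0.25,
                               alpha = 0.05)
  expect_equal(res$t_stat, -3)
  expect_equal(res$p_value, pnorm(-3), tolerance = 1e-12)
  expect_equal(res$p_value, 0.001350, tolerance = 1e-4)
  expect_equal(res$d_upper, 0.1 + qnorm(0.95) * 0.05, tolerance = 1e-12)
  expect_equal(res$d_upper, 0.18224, tolerance = 1e-4)
  expect_true(res$equivalent)

  # boundary: Delta = d_hat gives p = 0.5, never equivalent below alpha 0.5
  b <- equivalence_test_stat(0.2, 0.01, delta = 0.2, alpha = 0.05)
  expect_equal(b$t_stat, 0)
  expect_equal(b$p_value, 0.5)
  expect_false(b$equivalent)

  # degenerate identical profiles
  dg <- equivalence_test_stat(0, 0, delta = 0.1, alpha = 0.05)
  expect_equal(dg$p_value, 0)
  expect_equal(dg$d_upper, 0)
  expect_true(dg$equivalent)

  expect_error(equivalence_test_stat(0.1, 0.05, delta = -1), "delta")
  expect_error(equivalence_test_stat(0.1, 0.05, delta = 0.1, alpha = 1.2),
               "alpha")
})

test_that("interval-inclusion duality holds exactly on random tuples", {
  set.seed(314)
  for (i in 1:1000) {
    d_hat <- runif(1, 0, 2)
    se_hat <- runif(1, 1e-4, 0.5)
    delta <- runif(1, 1e-3, 2.5)
    alpha <- runif(1, 0.001, 0.4)
    res <- equivalence_test_stat(d_hat, se_hat, delta, alpha)
    expect_identical(res$d_upper <= delta, res$p_value <= alpha)
    expect_identical(res$equivalent, res$p_value <= alpha)
    expect_gte(res$d_upper, res$d_hat)
  }
})

test_that("p(Delta) is continuous, strictly decreasing; d_upper -> d_hat as alpha -> 0.5", {
  deltas <- seq(0.01, 1, by = 0.01)
  p <- vapply(deltas,
              function(d) equivalence_test_stat(0.3, 0.07, d)$p_value,
              numeric(1))
  expect_true(all(diff(p) < 0))
  expect_equal(equivalence_test_stat(0.3, 0.07, 0.5, alpha = 0.5 - 1e-12)$d_upper,
               0.3, tolerance = 1e-9)
})

test_that("compare_feature_lists wires profiles, overlap and design together", {
  set.seed(5)
  sim <- simulate_annotation_map(60, s = 4, k = 2, theta = 0.6)
  ids1 <- sim$features[1:40]
  ids2 <- sim$features[21:60]          # 20 shared
  res <- compare_feature_lists(ids1, ids2, sim$ann, delta = 0.5)
  expect_s3_class(res, "pair_equivalence")
  expect_equal(res$design$n0, 20)
  expect_equal(res$design$n, 40)
  expect_gte(res$d_hat, 0)
  # identical lists are equivalent at any positive limit
  res2 <- compare_feature_lists(ids1, ids1, sim$ann, delta = 0.01)
  expect_equal(res2$d_hat, 0)
  expect_equal(res2$se_hat, 0)
  expect_true(res2$equivalent)
})
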