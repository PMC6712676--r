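random_pairs <- function(h) {
  list(d_hat = runif(h, 0, 0.6), se_hat = runif(h, 0.005, 0.2))
}

test_that("holm_decisions implements the step-down rule", {
  # thresholds at alpha = 0.05, h = 3: 0.0167, 0.025, 0.05
  expect_equal(holm_decisions(c(0.01, 0.02, 0.2), 0.05),
               c(TRUE, TRUE, FALSE))
  expect_equal(holm_decisions(rep(1, 4), 0.05), rep(FALSE, 4))
  expect_equal(holm_decisions(0.04, 0.05), TRUE)
  # once one ordered p fails, everything after it is retained even if small
  expect_equal(holm_decisions(c(0.001, 0.03, 0.026), 0.05),
               c(TRUE, FALSE, FALSE))
  expect_error(holm_decisions(numeric(0)), "empty")
})

test_that("holm rejections are monotone in alpha and contain bonferroni", {
  set.seed(11)
  for (i in 1:50) {
    h <- sample(2:8, 1)
    p <- runif(h)
    a1 <- runif(1, 0.01, 0.2)
    a2 <- a1 + runif(1, 0, 0.3)
    r1 <- holm_decisions(p, a1)
    r2 <- holm_decisions(p, a2)
    expect_true(all(r2[r1]))                      # rejections grow with alpha
    expect_true(all(r1[p <= a1 / h]))             # contains Bonferroni
  }
})

test_that("min_delta_all matches the h = 1 and tied h = 2 closed forms", {
  d <- 0.12; se <- 0.03; alpha <- 0.05
  expect_equal(min_delta_all(d, se, alpha, tol = 1e-10),
               d + qnorm(1 - alpha) * se, tolerance = 1e-8)
  expect_equal(min_delta_all(c(d, d), c(se, se), alpha, tol = 1e-10),
               d + qnorm(1 - alpha / 2) * se, tolerance = 1e-8)
})

test_that("min_delta_all matches dense grid search on random h <= 3 instances", {
  set.seed(23)
  for (i in 1:25) {
    h <- sample(1:3, 1)
    ps <- random_pairs(h)
    alpha <- runif(1, 0.02, 0.2)
    got <- min_delta_all(ps$d_hat, ps$se_hat, alpha, tol = 1e-8)
    ref <- oracle_min_delta_grid(ps$d_hat, ps$se_hat, alpha)
    expect_lt(abs(got - ref), 1e-5 + 1e-8)
  }
})

test_that("the feasibility set of min_delta_all is an up-set", {
  set.seed(31)
  for (i in 1:25) {
    h <- sample(2:5, 1)
    ps <- random_pairs(h)
    alpha <- 0.05
    dh <- min_delta_all(ps$d_hat, ps$se_hat, alpha)
    feas <- function(delta)
      equivProfiles:::.all_rejected(ps$d_hat, ps$se_hat, delta, alpha)
    expect_true(feas(dh))
    for (bump in c(1e-4, 0.01, 0.1, 1)) expect_true(feas(dh + bump))
    expect_false(feas(dh - 1e-4))
    expect_gte(dh, max(ps$d_hat))
  }
})

test_that("min_delta_all handles degenerate se = 0 pairs", {
  # all degenerate: threshold is the largest point estimate
  expect_equal(min_delta_all(c(0.1, 0.3), c(0, 0), 0.05), 0.3)
  # mixed: the degenerate pair's p is 0 past its d_hat, so it takes the
  # stringent first Holm slot and the live pair faces plain alpha
  d <- c(0.05, 0.2); se <- c(0, 0.04)
  got <- min_delta_all(d, se, 0.05, tol = 1e-10)
  expect_equal(got, 0.2 + qnorm(1 - 0.05) * 0.04, tolerance = 1e-8)
})

test_that("iterative_delta_matrix: s = 2 reduces to the pair's d_U", {
  cs <- comparison_set(cbind(1, 2), 0.15, 0.04, c("A", "B"))
  dm <- iterative_delta_matrix(cs, alpha = 0.05, tol = 1e-10)
  expect_equal(dm$delta["A", "B"], 0.15 + qnorm(0.95) * 0.04,
               tolerance = 1e-8)
  expect_equal(dm$delta["A", "B"], dm$delta["B", "A"])
  expect_equal(diag(dm$delta), c(A = 0, B = 0))
})

test_that("iterative_delta_matrix removes the most distant pair first", {
  cs <- comparison_set(rbind(c(1, 2), c(1, 3), c(2, 3)),
                       d_hat = c(0.05, 0.8, 0.07),
                       se_hat = c(0.02, 0.05, 0.02),
                       labels = c("A", "B", "C"))
  dm <- iterative_delta_matrix(cs, alpha = 0.05)
  expect_equal(dm$sequence$h, c(3, 2, 1))
  expect_equal(dm$sequence[1, c("i", "j")], data.frame(i = 1L, j = 3L),
               ignore_attr = TRUE)                 # pair (A,C) = d 0.8
  expect_equal(max(dm$delta), dm$delta["A", "C"])
  expect_true(all(diff(dm$sequence$delta) <= 1e-12))
})

test_that("iterative_delta_matrix matches the brute-force oracle on random s = 3", {
  set.seed(47)
  for (i in 1:10) {
    ps <- random_pairs(3)
    cs <- comparison_set(rbind(c(1, 2), c(1, 3), c(2, 3)),
                         ps$d_hat, ps$se_hat, c("A", "B", "C"))
    dm <- iterative_delta_matrix(cs, alpha = 0.05, tol = 1e-8)
    ref <- oracle_iterative_matrix(cs, alpha = 0.05)
    expect_equal(dm$delta, ref, tolerance = 5e-5)
    # every threshold sits at or above the point estimate of its pair
    df <- as.data.frame(cs)
    for (r in seq_len(nrow(df)))
      expect_gte(dm$delta[df$i[r], df$j[r]], df$d_hat[r])
    expect_true(all(diff(dm$sequence$delta) <= 1e-12))
  }
})

test_that("complete_linkage follows max-linkage and reference heights", {
  labs <- c("A", "B", "C")
  D <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3, dimnames = list(labs, labs))
  hc <- complete_linkage(D)
  expect_equal(hc$height, c(1, 5))
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))     # A and B merge first

  expect_error(complete_linkage(matrix(0, 1, 1)), "2 leaves")

  set.seed(53)
  for (i in 1:10) {
    n <- 4
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 2)
    m <- m + t(m)
    dimnames(m) <- list(LETTERS[1:n], LETTERS[1:n])
    hc <- complete_linkage(m)
    expect_equal(sort(hc$height), oracle_complete_linkage_heights(m))
    expect_true(all(diff(hc$height) >= 0))         # complete linkage is monotone
  }
})

test_that("dendrogram_to_newick emits parseable ultrametric trees", {
  labs <- c("A", "B", "C")
  D <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3, dimnames = list(labs, labs))
  hc <- complete_linkage(D)
  nwk <- dendrogram_to_newick(hc)
  expect_match(nwk, ";$")
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, labs)
  # tip-to-tip path through each internal node equals its merge height
  expect_equal(sort(newick_node_heights(nwk)), c(1, 5))

  # two leaves at height 2 -> branch lengths 1 each
  D2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  nwk2 <- dendrogram_to_newick(complete_linkage(D2))
  tr2 <- ape::read.tree(text = nwk2)
  expect_equal(unname(tr2$edge.length), c(1, 1))

  # round-trip: parse then re-emit preserves topology and heights
  again <- ape::write.tree(ape::read.tree(text = nwk))
  expect_equal(sort(newick_node_heights(again)), sort(newick_node_heights(nwk)))
})

test_that("delta matrix TSV IO round-trips at full precision", {
  set.seed(61)
  ps <- random_pairs(3)
  cs <- comparison_set(rbind(c(1, 2), c(1, 3), c(2, 3)),
                       ps$d_hat, ps$se_hat, c("x", "y", "z"))
  dm <- iterative_delta_matrix(cs)
  path <- tempfile(fileext = ".tsv")
  write_delta_matrix_tsv(dm, path)
  back <- read_delta_matrix_tsv(path)
  expect_equal(back$delta, dm$delta, tolerance = 1e-12)
  expect_equal(back$labels, dm$labels)
})
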