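# Simulation engine for the profile equivalence test.
#
# Population model.  The expanded probability vectors of the exclusive parts
# of two lists and of their shared part follow a truncated-geometric model on
# the g canonical subsets (g = sum_{j<=k} choose(s, j)):
#   p_i = theta (1 - theta)^(i-1) / (1 - (1 - theta)^g),  i = 1..g.
# List 1's exclusive component uses parameter theta, list 2's uses 1 - theta
# and the shared component a fixed theta0 (0.5 by default).  The population
# contracted profiles are P = M (n1 P1 + n0 R)/n and Q = M (m1 Q1 + n0 R)/m,
# so the squared distance is a smooth function D(theta), strictly 0 at
# theta = 0.5 by symmetry; inverting D gives profile pairs at any prescribed
# population distance.  Each replicate draws three independent multinomials
# of sizes n1, m1, n0, builds the list-level profiles, contracts and tests.

#' Simulation scenario
#'
#' Fixes the design of one simulation run: list sizes and overlap, the
#' annotation universe (s categories, at most k simultaneous annotations),
#' the geometric parameter of the shared component, the equivalence limit
#' and the level.
#'
#' @param n,m sizes of the two lists.
#' @param n0 number of shared features (<= min(n, m)).
#' @param s number of ontology categories.
#' @param k maximum number of simultaneous annotations (k <= s).
#' @param theta0 geometric parameter of the shared component (default 0.5).
#' @param delta equivalence limit Delta.
#' @param alpha significance level.
#' @param reps default number of replicates for this scenario.
#' @param seed default RNG seed.
#' @return An object of class `scenario`; includes the derived quantities
#'   `n1`, `m1`, `g`, the canonical `subsets` and the contraction matrix `M`.
#' @export
scenario <- function(n, m, n0, s, k, theta0 = 0.5, delta = 0.25,
                     alpha = 0.05, reps = 10000L, seed = 1L) {
  stopifnot(n >= 1, m >= 1, n0 >= 0, n0 <= min(n, m),
            s >= 1, k >= 1, k <= s,
            theta0 > 0, theta0 < 1, delta > 0, alpha > 0, alpha < 1, reps >= 1)
  subsets <- canonical_subsets(s, k)
  structure(list(n = as.integer(n), m = as.integer(m), n0 = as.integer(n0),
                 n1 = as.integer(n - n0), m1 = as.integer(m - n0),
                 s = as.integer(s), k = as.integer(k),
                 g = length(subsets), subsets = subsets,
                 M = contraction_matrix(s, subsets),
                 theta0 = theta0, delta = delta, alpha = alpha,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario: n=%d m=%d n0=%d | s=%d k=%d (g=%d) | theta0=%g Delta=%g alpha=%g\n",
              x$n, x$m, x$n0, x$s, x$k, x$g, x$theta0, x$delta, x$alpha))
  invisible(x)
}

#' Truncated-geometric expanded probability vector
#'
#' `p_i = theta (1 - theta)^(i - 1) / (1 - (1 - theta)^g)` for `i = 1..g`:
#' positive, summing to one, strictly decreasing.  Computed in log space so
#' that parameters very close to 0 or 1 stay accurate.
#'
#' @param theta geometric parameter in (0, 1).
#' @param g vector length (>= 1).
#' @return Probability vector of length `g`.
#' @export
geometric_profile <- function(theta, g) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1)
    stop("theta must lie strictly between 0 and 1")
  stopifnot(g >= 1)
  g <- as.integer(g)
  if (g == 1L) return(1)
  lq <- log1p(-theta)                       # log(1 - theta)
  num <- exp(log(theta) + (seq_len(g) - 1) * lq)
  denom <- -expm1(g * lq)                   # 1 - (1 - theta)^g, no cancellation
  p <- num / denom
  p / sum(p)                                # absorb residual rounding
}

#' Population profiles of a scenario at a given theta
#'
#' Exclusive components use `geometric_profile(theta, g)` for list 1 and
#' `geometric_profile(1 - theta, g)` for list 2; the shared component uses
#' `theta0`.  Returns the contracted population profiles and the three
#' expanded probability vectors.
#'
#' @param theta geometric parameter of list 1's exclusive component.
#' @param sc a `scenario`.
#' @return List with `P`, `Q` (contracted probability vectors of length s)
#'   and `piP1`, `piQ1`, `piR` (expanded vectors of length g).
#' @export
population_profiles <- function(theta, sc) {
  stopifnot(inherits(sc, "scenario"))
  piP1 <- geometric_profile(theta, sc$g)
  piQ1 <- geometric_profile(1 - theta, sc$g)
  piR <- geometric_profile(sc$theta0, sc$g)
  expP <- (sc$n1 * piP1 + sc$n0 * piR) / sc$n
  expQ <- (sc$m1 * piQ1 + sc$n0 * piR) / sc$m
  list(P = as.vector(sc$M %*% expP), Q = as.vector(sc$M %*% expQ),
       piP1 = piP1, piQ1 = piQ1, piR = piR)
}

#' Population squared distance as a function of theta
#'
#' `D(theta) = ||P(theta) - Q(theta)||^2` on the contracted scale; zero at
#' `theta = 0.5` and symmetric under `theta -> 1 - theta` for balanced
#' designs.
#'
#' @inheritParams population_profiles
#' @return Non-negative scalar.
#' @export
scenario_distance <- function(theta, sc) {
  pp <- population_profiles(theta, sc)
  sum((pp$P - pp$Q)^2)
}

#' Invert the distance map: find theta with D(theta) = target_d
#'
#' Bracketed root finding on `theta in [0.5, 1 - 1e-9]`, where `D(0.5) = 0`
#' gives the natural lower bracket end.  Errors when `target_d` exceeds the
#' attainable maximum, reporting that maximum.
#'
#' @param target_d desired population squared distance (>= 0).
#' @param sc a `scenario`.
#' @return theta in `[0.5, 1)` with `|D(theta) - target_d| <= 1e-10`.
#' @export
solve_theta <- function(target_d, sc) {
  stopifnot(target_d >= 0)
  if (target_d == 0) return(0.5)
  upper <- 1 - 1e-9
  dmax <- scenario_distance(upper, sc)
  if (target_d > dmax)
    stop(sprintf("target distance %g unattainable; maximum attainable is %g",
                 target_d, dmax))
  f <- function(th) scenario_distance(th, sc) - target_d
  r <- stats::uniroot(f, interval = c(0.5, upper), tol = 1e-13)
  theta <- r$root
  if (abs(scenario_distance(theta, sc) - target_d) > 1e-10) {
    # polish with a few bisection steps on the original bracket
    lo <- 0.5; hi <- upper
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (scenario_distance(mid, sc) < target_d) lo <- mid else hi <- mid
      if (abs(scenario_distance(mid, sc) - target_d) <= 1e-10) {
        theta <- mid; break
      }
    }
  }
  theta
}

# Vectorized replicate engine: draws `reps` triples of multinomial expanded
# counts and returns per-replicate (d_hat, se_hat, p_value).  Mirrors
# distance_se()/equivalence_test_stat() exactly (asserted by tests) but
# operates on g x reps matrices for speed.
.simulate_stats <- function(sc, theta, reps, chunk = 2000L) {
  pp <- population_profiles(theta, sc)
  n <- sc$n; m <- sc$m; n0 <- sc$n0; n1 <- sc$n1; m1 <- sc$m1
  M <- sc$M; Mt <- t(M)
  d_hat <- numeric(reps); se_hat <- numeric(reps)
  done <- 0L
  qf_cols <- function(Pi, V) colSums(Pi * V * V) - colSums(Pi * V)^2
  while (done < reps) {
    r <- min(chunk, reps - done)
    XP <- if (n1 > 0) stats::rmultinom(r, n1, pp$piP1) else matrix(0, sc$g, r)
    XQ <- if (m1 > 0) stats::rmultinom(r, m1, pp$piQ1) else matrix(0, sc$g, r)
    XR <- if (n0 > 0) stats::rmultinom(r, n0, pp$piR) else matrix(0, sc$g, r)
    EP <- (XP + XR) / n
    EQ <- (XQ + XR) / m
    Pc <- M %*% EP
    Qc <- M %*% EQ
    Dif <- Pc - Qc
    d <- colSums(Dif * Dif)
    V <- Mt %*% (2 * Dif)
    se2 <- numeric(r)
    if (n1 > 0) se2 <- se2 + n1 / n^2 * qf_cols(XP / n1, V)
    if (m1 > 0) se2 <- se2 + m1 / m^2 * qf_cols(XQ / m1, V)
    if (n0 > 0 && n != m) se2 <- se2 + n0 * (1 / n - 1 / m)^2 * qf_cols(XR / n0, V)
    idx <- done + seq_len(r)
    d_hat[idx] <- d
    se_hat[idx] <- sqrt(pmax(se2, 0))
    done <- done + r
  }
  list(d_hat = d_hat, se_hat = se_hat)
}

#' Empirical rejection probability of the equivalence test
#'
#' Simulates `reps` replicates of the scenario at the population distance
#' `true_d` (theta found by [solve_theta()]), applies the one-sided
#' equivalence test with the scenario's `delta` and `alpha` to each, and
#' returns the rejection fraction (the probability of declaring equivalence)
#' with its binomial Monte-Carlo standard error.
#'
#' @param sc a `scenario`.
#' @param true_d population squared distance to simulate at.
#' @param reps number of replicates (default: the scenario's).
#' @param seed RNG seed (default: the scenario's).
#' @return List with `estimate`, `mc_se`, `reps`, `theta`, `true_d`.
#' @export
simulate_rejection_probability <- function(sc, true_d, reps = sc$reps,
                                           seed = sc$seed) {
  stopifnot(inherits(sc, "scenario"), reps >= 1)
  theta <- solve_theta(true_d, sc)
  set.seed(seed)
  st <- .simulate_stats(sc, theta, reps)
  p <- ifelse(st$se_hat > 0,
              stats::pnorm((st$d_hat - sc$delta) / st$se_hat),
              ifelse(st$d_hat < sc$delta, 0, 1))
  est <- mean(p <= sc$alpha)
  list(estimate = est,
       mc_se = sqrt(est * (1 - est) / reps),
       reps = as.integer(reps), theta = theta, true_d = true_d)
}

#' Power curve of the equivalence test over a grid of true distances
#'
#' Runs [simulate_rejection_probability()] at each grid point with the same
#' seed (common random numbers across grid points, which sharpens the
#' monotonicity of the estimated curve without biasing any single point).
#'
#' @param sc a `scenario`.
#' @param d_grid numeric vector of population squared distances; should span
#'   values below, at and above the scenario's `delta`.
#' @param reps replicates per grid point.
#' @param seed RNG seed reused at every grid point.
#' @return A data.frame with columns `d`, `rejection_prob`, `mc_se`,
#'   `theta`.
#' @export
power_curve <- function(sc, d_grid, reps = sc$reps, seed = sc$seed) {
  stopifnot(length(d_grid) >= 1)
  rows <- lapply(d_grid, function(d) {
    r <- simulate_rejection_probability(sc, d, reps = reps, seed = seed)
    data.frame(d = d, rejection_prob = r$estimate, mc_se = r$mc_se,
               theta = r$theta)
  })
  do.call(rbind, rows)
}

#' Synthetic annotation data generator
#'
#' Builds an annotation universe of `s` categories where each feature draws
#' its annotation subset from the truncated-geometric expanded model with
#' parameter `theta`.  Useful for fixtures and demonstrations: the resulting
#' `annotation_map` feeds the profile and clustering machinery exactly like a
#' real ontology slice.
#'
#' @param n_features number of features to create.
#' @param s number of categories.
#' @param k maximum simultaneous annotations.
#' @param theta geometric parameter of the subset distribution.
#' @param prefix feature id prefix (ids are `prefix1..prefixN`).
#' @param categories optional category ids (default `"C01".."Cs"`).
#' @return List with `ann` (the `annotation_map`) and `features` (ids in
#'   creation order).
#' @export
simulate_annotation_map <- function(n_features, s, k, theta = 0.7,
                                    prefix = "g", categories = NULL) {
  stopifnot(n_features >= 1, s >= 1, k >= 1, k <= s)
  subsets <- canonical_subsets(s, k)
  pi <- geometric_profile(theta, length(subsets))
  if (is.null(categories)) categories <- sprintf("C%02d", seq_len(s))
  stopifnot(length(categories) == s)
  ids <- paste0(prefix, seq_len(n_features))
  cells <- sample.int(length(subsets), n_features, replace = TRUE, prob = pi)
  rows <- do.call(rbind, lapply(seq_len(n_features), function(i) {
    data.frame(feature_id = ids[i],
               category_id = categories[subsets[[cells[i]]]])
  }))
  # keep the category axis complete and in order even if some category was
  # never drawn: seed the map with one dummy row per category, then drop it
  ann <- build_annotation_map(rbind(
    data.frame(feature_id = ".axis", category_id = categories), rows))
  ann$entries <- ann$entries[setdiff(names(ann$entries), ".axis")]
  list(ann = ann, features = ids)
}
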