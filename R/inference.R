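# One-pair inference: squared Euclidean dissimilarity between contracted
# profiles, its asymptotic (delta-method) standard error under the
# multinomial sampling model, and the one-sided equivalence test by the
# interval-inclusion rule.
#
# Sampling model.  List 1 holds n annotated features of which n0 are shared
# with list 2 (n1 = n - n0 exclusive); list 2 holds m (m1 = m - n0
# exclusive).  The expanded count vectors of the exclusive parts and of the
# shared part are modelled as independent multinomials of sizes n1, m1, n0,
# so the list-level expanded frequency vectors are
#   Phat = (n1 * Phat1 + n0 * Rhat) / n,   Qhat = (m1 * Qhat1 + n0 * Rhat) / m.
# The contracted profiles are M Phat, M Qhat for the contraction matrix M.
# With d = ||P - Q||^2 and gradient g = 2 (Phat_c - Qhat_c), the first-order
# variance of dhat is g' [Cov(P_c) + Cov(Q_c) - 2 Cov(P_c, Q_c)] g, where each
# covariance is a multinomial covariance pushed through M.  The shared
# component contributes n0 (1/n - 1/m)^2 to the quadratic form weight, hence
# cancels exactly for balanced designs (n == m).

#' Pairwise list design
#'
#' Records the sizes of two annotated feature lists and their overlap.
#'
#' @param n size of list 1 (annotated, de-duplicated features).
#' @param m size of list 2.
#' @param n0 number of annotated features common to both lists (0 if the
#'   lists are disjoint).
#' @return An object of class `pair_design` with fields `n`, `m`, `n0`,
#'   `n1 = n - n0`, `m1 = m - n0`.
#' @export
pair_design <- function(n, m, n0 = 0) {
  stopifnot(n >= 1, m >= 1, n0 >= 0, n0 <= min(n, m))
  structure(list(n = as.integer(n), m = as.integer(m), n0 = as.integer(n0),
                 n1 = as.integer(n - n0), m1 = as.integer(m - n0)),
            class = "pair_design")
}

#' Squared Euclidean dissimilarity between contracted profiles
#'
#' `d(P, Q) = sum_i (p_i. - q_i.)^2`.  A dissimilarity, not a metric (the
#' triangle inequality can fail).  The two profiles must be expressed on the
#' identical category axis.
#'
#' @param P,Q `contracted_profile` objects, or plain numeric vectors of equal
#'   length.
#' @return Non-negative scalar.
#' @export
squared_distance <- function(P, Q) {
  if (inherits(P, "contracted_profile") && inherits(Q, "contracted_profile")) {
    if (!identical(P$categories, Q$categories)) stop("profiles not aligned")
    return(sum((P$p - Q$p)^2))
  }
  P <- as.numeric(P); Q <- as.numeric(Q)
  if (length(P) != length(Q)) stop("profiles not aligned")
  sum((P - Q)^2)
}

#' Covariance of a contracted profile estimate
#'
#' The multinomial covariance of the expanded relative frequencies,
#' `(diag(pi) - pi pi') / n`, pushed through the contraction matrix:
#' `Cov(Phat_c) = M (diag(pi) - pi pi') M' / n`.
#'
#' @param ep an `expanded_profile` (supplies `pi = probs` and `n`).
#' @param M contraction matrix for `ep$subsets` (computed when omitted).
#' @return An `s x s` covariance matrix.
#' @export
contracted_covariance <- function(ep, M = NULL) {
  stopifnot(inherits(ep, "expanded_profile"), ep$n >= 1)
  if (is.null(M)) M <- contraction_matrix(length(ep$categories), ep$subsets)
  pi <- ep$probs
  mp <- as.vector(M %*% pi)
  (M %*% (pi * t(M)) - tcrossprod(mp)) / ep$n
}

# quadratic form v' (diag(pi) - pi pi') v  for a multinomial prob vector pi
.qform <- function(pi, v) {
  pv <- pi * v
  sum(pv * v) - sum(pv)^2
}

# align expanded profiles sharing a category axis onto the union of their
# observed subsets; returns list(subsets, counts = list of aligned vectors)
.align_expanded <- function(...) {
  eps <- list(...)
  eps <- eps[!vapply(eps, is.null, logical(1))]
  cats <- eps[[1L]]$categories
  for (e in eps) {
    if (!identical(e$categories, cats)) stop("profiles not aligned")
  }
  all_subsets <- list()
  seen <- character(0)
  for (e in eps) {
    k <- vapply(e$subsets, subset_key, character(1))
    new <- !(k %in% seen)
    all_subsets <- c(all_subsets, e$subsets[new])
    seen <- c(seen, k[new])
  }
  ord <- order_subsets(all_subsets)
  all_subsets <- all_subsets[ord]
  keys <- vapply(all_subsets, subset_key, character(1))
  counts <- lapply(eps, function(e) {
    out <- numeric(length(keys))
    out[match(vapply(e$subsets, subset_key, character(1)), keys)] <- e$counts
    out
  })
  list(categories = cats, subsets = all_subsets, keys = keys, counts = counts)
}

#' Delta-method standard error of the estimated squared distance
#'
#' Standard error of `dhat = ||Phat_c - Qhat_c||^2` under the multinomial
#' model with an optional shared component (see the package vignette).  When
#' `epShared` is `NULL` the lists are treated as disjoint and the formula
#' reduces to the plain two-sample multinomial delta method.
#'
#' @param Phat,Qhat contracted profiles of the two full lists.
#' @param epP,epQ expanded profiles of the two full lists (shared features
#'   included).
#' @param epShared expanded profile of the shared features, or `NULL`.
#' @param design a `pair_design`; must agree with the profile sizes.
#' @return Non-negative scalar; legitimately 0 when `Phat == Qhat`.
#' @export
distance_se <- function(Phat, Qhat, epP, epQ, epShared = NULL, design) {
  stopifnot(inherits(design, "pair_design"))
  if (!identical(Phat$categories, Qhat$categories)) stop("profiles not aligned")
  # tolerant comparison: profiles may carry fractional expected counts
  if (abs(epP$n - design$n) > 1e-6 || abs(epQ$n - design$m) > 1e-6)
    stop("design inconsistent with profile sizes")
  if (!is.null(epShared) && abs(epShared$n - design$n0) > 1e-6)
    stop("design inconsistent with shared profile size")
  if (is.null(epShared) && design$n0 != 0)
    stop("design declares shared features but epShared is missing")

  al <- .align_expanded(epP, epQ, epShared)
  cP <- al$counts[[1L]]
  cQ <- al$counts[[2L]]
  if (is.null(epShared)) {
    cS <- numeric(length(al$keys))
  } else {
    cS <- al$counts[[3L]]
    if (any(cP - cS < -1e-9) || any(cQ - cS < -1e-9))
      stop("shared profile is not nested within the list profiles")
  }
  cP1 <- pmax(cP - cS, 0)
  cQ1 <- pmax(cQ - cS, 0)

  M <- contraction_matrix(length(al$categories), al$subsets)
  gc <- 2 * (Phat$p - Qhat$p)
  v <- as.vector(crossprod(M, gc))

  n <- design$n; m <- design$m; n0 <- design$n0
  n1 <- design$n1; m1 <- design$m1
  se2 <- 0
  if (n1 > 0) se2 <- se2 + n1 / n^2 * .qform(cP1 / n1, v)
  if (m1 > 0) se2 <- se2 + m1 / m^2 * .qform(cQ1 / m1, v)
  if (n0 > 0 && n != m) se2 <- se2 + n0 * (1 / n - 1 / m)^2 * .qform(cS / n0, v)
  sqrt(max(se2, 0))
}

# p-value of the one-sided equivalence test given the summary statistics;
# the se = 0 degenerate case is a step function in delta
.equiv_pvalue <- function(d_hat, se_hat, delta) {
  if (se_hat > 0) return(stats::pnorm((d_hat - delta) / se_hat))
  if (delta > d_hat) 0 else 1
}

#' Equivalence test from summary statistics
#'
#' The one-sided test of H0: d >= Delta against H1: d < Delta via the
#' interval-inclusion rule: equivalence is declared when the (1 - alpha)
#' upper confidence limit `d_U = d_hat + z_{1-alpha} * se_hat` falls below
#' `Delta`, equivalently when `p(Delta) = Phi((d_hat - Delta)/se_hat) <=
#' alpha`.  With `se_hat == 0` (identical sample profiles) equivalence is
#' declared for any `Delta > d_hat` with p-value 0.
#'
#' @param d_hat estimated squared distance (>= 0).
#' @param se_hat its estimated standard error (>= 0).
#' @param delta equivalence limit Delta (> 0).
#' @param alpha significance level in (0, 1).
#' @return An object of class `pair_equivalence` with fields `d_hat`,
#'   `se_hat`, `delta`, `alpha`, `t_stat`, `p_value`, `d_upper`,
#'   `equivalent`.
#' @export
equivalence_test_stat <- function(d_hat, se_hat, delta, alpha = 0.05) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a positive number")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  stopifnot(d_hat >= 0, se_hat >= 0)
  if (se_hat > 0) {
    t_stat <- (d_hat - delta) / se_hat
    p_value <- stats::pnorm(t_stat)
    d_upper <- d_hat + stats::qnorm(1 - alpha) * se_hat
  } else {
    t_stat <- if (d_hat < delta) -Inf else Inf
    p_value <- .equiv_pvalue(d_hat, 0, delta)
    d_upper <- d_hat
  }
  structure(list(d_hat = d_hat, se_hat = se_hat, delta = delta, alpha = alpha,
                 t_stat = t_stat, p_value = p_value, d_upper = d_upper,
                 equivalent = (p_value <= alpha)),
            class = "pair_equivalence")
}

#' Equivalence test between two profile pairs
#'
#' Computes the squared distance, its delta-method standard error and the
#' one-sided equivalence decision for two lists described by their expanded
#' and contracted profiles.
#'
#' @inheritParams distance_se
#' @inheritParams equivalence_test_stat
#' @return A `pair_equivalence` result (see [equivalence_test_stat()]),
#'   augmented with the `design`.
#' @export
equivalence_test <- function(Phat, Qhat, epP, epQ, epShared = NULL, design,
                             delta, alpha = 0.05) {
  d_hat <- squared_distance(Phat, Qhat)
  se_hat <- distance_se(Phat, Qhat, epP, epQ, epShared, design)
  res <- equivalence_test_stat(d_hat, se_hat, delta, alpha)
  res$design <- design
  res
}

#' Compare two feature lists end to end
#'
#' Builds expanded and contracted profiles for both lists on the annotation
#' map's category axis, detects shared features as the intersection of the
#' de-duplicated annotated id sets, and runs the equivalence test.
#'
#' @param ids1,ids2 character vectors of feature identifiers.
#' @param ann an `annotation_map`.
#' @param delta equivalence limit (> 0).
#' @param alpha significance level.
#' @return A `pair_equivalence` result with the `design` attached.
#' @export
compare_feature_lists <- function(ids1, ids2, ann, delta, alpha = 0.05) {
  epP <- build_expanded_profile(ids1, ann)
  epQ <- build_expanded_profile(ids2, ann)
  ann_ids1 <- unique(as.character(ids1)); ann_ids1 <- ann_ids1[ann_ids1 %in% names(ann$entries)]
  ann_ids2 <- unique(as.character(ids2)); ann_ids2 <- ann_ids2[ann_ids2 %in% names(ann$entries)]
  shared <- intersect(ann_ids1, ann_ids2)
  epShared <- if (length(shared)) build_expanded_profile(shared, ann) else NULL
  design <- pair_design(epP$n, epQ$n, length(shared))
  equivalence_test(contract_profile(epP), contract_profile(epQ),
                   epP, epQ, epShared, design, delta, alpha)
}

#' Per-pair distance and standard error for two feature lists
#'
#' Like [compare_feature_lists()] but without fixing an equivalence limit:
#' returns only `d_hat` and `se_hat`, the inputs of the multiple-comparison
#' machinery.
#'
#' @inheritParams compare_feature_lists
#' @return List with `d_hat`, `se_hat`, `design`.
#' @export
pair_statistics <- function(ids1, ids2, ann) {
  res <- compare_feature_lists(ids1, ids2, ann, delta = 1, alpha = 0.05)
  list(d_hat = res$d_hat, se_hat = res$se_hat, design = res$design)
}

#' @export
print.pair_equivalence <- function(x, ...) {
  cat("One-sided profile equivalence test (H0: d >= Delta)\n")
  cat(sprintf("  d_hat = %.6g   se = %.6g\n", x$d_hat, x$se_hat))
  cat(sprintf("  Delta = %.6g   alpha = %.3g\n", x$delta, x$alpha))
  cat(sprintf("  T = %.4g   p = %.6g   d_U = %.6g\n", x$t_stat, x$p_value, x$d_upper))
  cat(sprintf("  equivalence %s\n",
              if (x$equivalent) "DECLARED" else "not declared"))
  invisible(x)
}

#' Serialize a pair result as JSON
#'
#' @param x a `pair_equivalence` result.
#' @param path output path.
#' @export
write_result_json <- function(x, path) {
  stopifnot(inherits(x, "pair_equivalence"))
  obj <- x[c("d_hat", "se_hat", "delta", "alpha", "t_stat", "p_value",
             "d_upper", "equivalent")]
  if (!is.null(x$design)) obj$design <- unclass(x$design)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
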