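# Multiplicity-adjusted equivalence over h >= 2 pairwise comparisons, the
# iterative minimal-threshold algorithm, and dendrogram construction.
#
# For h pairwise tests at a common limit Delta, familywise error is
# controlled by the Holm step-down rule on the p-values p_l(Delta).  The
# minimal threshold Delta_h is the smallest Delta at which Holm rejects all h
# non-equivalence hypotheses; since every p_l(Delta) is non-increasing in
# Delta the feasibility set is an up-set and bisection applies.  The
# iterative algorithm repeatedly computes Delta_h over the remaining pairs,
# assigns it to the pair holding the largest p-value at that Delta, removes
# the pair, and decrements h; the resulting symmetric matrix of thresholds is
# a dissimilarity fed to complete-linkage clustering.

#' Holm-Bonferroni step-down decisions
#'
#' Sorts the p-values ascending, compares the l-th order statistic with
#' `alpha / (h + 1 - l)`, and rejects the hypotheses at ordered positions
#' before the first failure (all of them when no comparison fails).
#' Rejection uses the non-strict inequality `p_(l) <= alpha / (h + 1 - l)`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param alpha familywise significance level in (0, 1).
#' @return Logical vector of rejections, in the input order.
#' @export
holm_decisions <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) stop("empty p-value list")
  stopifnot(all(p_values >= 0 & p_values <= 1), alpha > 0, alpha < 1)
  h <- length(p_values)
  ord <- order(p_values)
  thr <- alpha / (h + 1 - seq_len(h))
  fail <- which(p_values[ord] > thr)
  k <- if (length(fail)) fail[1L] else h + 1L
  rejected_sorted <- seq_len(h) < k
  out <- logical(h)
  out[ord] <- rejected_sorted
  out
}

#' Benjamini-Hochberg decisions
#'
#' Step-up false-discovery-rate alternative offered for large families of
#' comparisons; Holm remains the default everywhere.
#'
#' @inheritParams holm_decisions
#' @return Logical vector of rejections in input order.
#' @export
bh_decisions <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) stop("empty p-value list")
  stats::p.adjust(p_values, method = "BH") <= alpha
}

# p-values of the remaining pairs at a trial Delta
.pvals_at_delta <- function(d_hat, se_hat, delta) {
  mapply(.equiv_pvalue, d_hat, se_hat, MoreArgs = list(delta = delta))
}

# TRUE iff Holm rejects all remaining hypotheses at this Delta
.all_rejected <- function(d_hat, se_hat, delta, alpha, method = "holm") {
  p <- .pvals_at_delta(d_hat, se_hat, delta)
  if (method == "bh") return(all(bh_decisions(p, alpha)))
  h <- length(p)
  all(sort(p) <= alpha / (h + 1 - seq_len(h)))
}

#' Minimal equivalence threshold for a family of comparisons
#'
#' The smallest `Delta` (to within `tol`) at which the Holm rule rejects all
#' `h` non-equivalence null hypotheses, i.e. at which every ordered p-value
#' satisfies `p_(l)(Delta) <= alpha / (h + 1 - l)`.  Found by bisection on
#' the bracket `[max_l d_hat_l, max_l (d_hat_l + z_{1 - alpha/h} se_hat_l)]`;
#' the upper end is feasible because `alpha/h` is the most stringent Holm
#' threshold any pair can face.  For `h = 1` this is exactly the upper
#' confidence limit `d_hat + z_{1-alpha} se_hat`.
#'
#' @param d_hat,se_hat numeric vectors of per-pair estimates (same length h).
#' @param alpha familywise level in (0, 1).
#' @param tol bisection tolerance on Delta (default 1e-8).
#' @param method `"holm"` (default) or `"bh"`.
#' @return The minimal feasible Delta (upper end of the final bracket, hence
#'   always feasible).
#' @export
min_delta_all <- function(d_hat, se_hat, alpha = 0.05, tol = 1e-8,
                          method = c("holm", "bh")) {
  method <- match.arg(method)
  stopifnot(length(d_hat) == length(se_hat), length(d_hat) >= 1,
            all(se_hat >= 0), tol > 0, alpha > 0, alpha < 1)
  h <- length(d_hat)
  lo <- max(d_hat)
  hi <- max(d_hat + stats::qnorm(1 - alpha / h) * se_hat)
  if (hi <= lo) {
    # every pair degenerate (se = 0): the infimum of feasible Delta is max(d)
    return(lo)
  }
  # guard: expand upward in the (theoretically impossible) infeasible case
  while (!.all_rejected(d_hat, se_hat, hi, alpha, method)) hi <- lo + 2 * (hi - lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.all_rejected(d_hat, se_hat, mid, alpha, method)) hi <- mid else lo <- mid
  }
  hi
}

#' Comparison set over s lists
#'
#' Bundles per-pair estimates for the multiple-comparison machinery.
#'
#' @param pairs two-column matrix or data.frame of list indices (i < j).
#' @param d_hat,se_hat per-pair squared distances and standard errors.
#' @param labels character vector of list names (length s).
#' @return An object of class `comparison_set` (a data.frame with columns
#'   `i`, `j`, `d_hat`, `se_hat`, plus a `labels` attribute).
#' @export
comparison_set <- function(pairs, d_hat, se_hat, labels) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L, nrow(pairs) == length(d_hat),
            length(d_hat) == length(se_hat), all(pairs[, 1] < pairs[, 2]),
            !anyDuplicated(paste(pairs[, 1], pairs[, 2])))
  s <- length(labels)
  stopifnot(all(pairs >= 1), all(pairs <= s),
            nrow(pairs) <= s * (s - 1) / 2)
  df <- data.frame(i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]),
                   d_hat = as.numeric(d_hat), se_hat = as.numeric(se_hat))
  structure(df, labels = as.character(labels),
            class = c("comparison_set", "data.frame"))
}

#' Iterative minimal-threshold dissimilarity matrix
#'
#' Starting from all `h = s(s-1)/2` pairs, repeatedly: compute the minimal
#' familywise threshold `Delta_h` over the remaining pairs, assign it to the
#' pair occupying the last position of the ordered p-value vector at
#' `Delta_h`, remove that pair, decrement `h`.  Ties on the maximal p-value
#' are broken by the larger `d_hat`, then by label order.  The assigned
#' sequence `Delta_h` is non-increasing.
#'
#' @param cs a `comparison_set` containing all `s(s-1)/2` pairs.
#' @param alpha familywise level.
#' @param tol bisection tolerance passed to [min_delta_all()].
#' @param method `"holm"` (default) or `"bh"`.
#' @return An object of class `delta_matrix`: list with `labels`, `delta`
#'   (symmetric matrix, zero diagonal) and `sequence` (a data.frame tracing
#'   the algorithm: `h`, `i`, `j`, `delta`).
#' @export
iterative_delta_matrix <- function(cs, alpha = 0.05, tol = 1e-8,
                                   method = c("holm", "bh")) {
  method <- match.arg(method)
  stopifnot(inherits(cs, "comparison_set"))
  labels <- attr(cs, "labels")
  s <- length(labels)
  if (nrow(cs) != s * (s - 1) / 2)
    stop("comparison set must contain all s(s-1)/2 pairs")
  D <- matrix(0, s, s, dimnames = list(labels, labels))
  remaining <- as.data.frame(cs)
  seq_log <- data.frame(h = integer(0), i = integer(0), j = integer(0),
                        delta = numeric(0))
  while (nrow(remaining) > 0L) {
    h <- nrow(remaining)
    delta_h <- min_delta_all(remaining$d_hat, remaining$se_hat, alpha, tol, method)
    p <- .pvals_at_delta(remaining$d_hat, remaining$se_hat, delta_h)
    cand <- which(p == max(p))
    if (length(cand) > 1L) {
      cand <- cand[remaining$d_hat[cand] == max(remaining$d_hat[cand])]
      if (length(cand) > 1L) {
        key <- paste(labels[remaining$i[cand]], labels[remaining$j[cand]])
        cand <- cand[order(key)][1L]
      }
    }
    sel <- cand[1L]
    i <- remaining$i[sel]; j <- remaining$j[sel]
    D[i, j] <- D[j, i] <- delta_h
    seq_log <- rbind(seq_log, data.frame(h = h, i = i, j = j, delta = delta_h))
    remaining <- remaining[-sel, , drop = FALSE]
  }
  structure(list(labels = labels, delta = D, sequence = seq_log),
            class = "delta_matrix")
}

#' @export
print.delta_matrix <- function(x, ...) {
  cat("Minimal equivalence threshold matrix:\n")
  print(round(x$delta, 6))
  invisible(x)
}

#' Complete-linkage dendrogram from a threshold matrix
#'
#' Agglomerative clustering with the maximum-distance (complete linkage)
#' criterion: the distance between two groups is the distance between their
#' two farthest members, so a merge height is the threshold at which every
#' pair across the merged groups is declared equivalent.
#'
#' @param dm a `delta_matrix`, or a symmetric numeric matrix with labels.
#' @param method linkage passed to [stats::hclust()]; `"complete"` is the
#'   supported default (single/average are available but untested).
#' @return An `hclust` object.
#' @export
complete_linkage <- function(dm, method = "complete") {
  m <- if (inherits(dm, "delta_matrix")) dm$delta else as.matrix(dm)
  if (nrow(m) < 2L) stop("need at least 2 leaves")
  stats::hclust(stats::as.dist(m), method = method)
}

#' Export a dendrogram as a Newick string
#'
#' Ultrametric conversion: each merge height `h` becomes a node whose two
#' child subtrees have tip depth `h / 2`, so the tip-to-tip path through a
#' node equals its merge height.  The output is parseable by any standard
#' Newick reader and ends with `';'`.
#'
#' @param hc an `hclust` object (e.g. from [complete_linkage()]).
#' @return A single Newick string.
#' @export
dendrogram_to_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Write a threshold matrix as TSV
#'
#' Square matrix with a labeled header row and a leading label column, full
#' precision.
#'
#' @param dm a `delta_matrix`.
#' @param path output path.
#' @export
write_delta_matrix_tsv <- function(dm, path) {
  stopifnot(inherits(dm, "delta_matrix"))
  m <- format(dm$delta, digits = 17, trim = TRUE, scientific = FALSE)
  df <- cbind(data.frame(list = dm$labels), as.data.frame(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a threshold matrix TSV written by [write_delta_matrix_tsv()]
#'
#' @param path input path.
#' @return A `delta_matrix` (with an empty `sequence`).
#' @export
read_delta_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(m) <- list(labels, labels)
  storage.mode(m) <- "double"
  structure(list(labels = labels, delta = m,
                 sequence = data.frame(h = integer(0), i = integer(0),
                                       j = integer(0), delta = numeric(0))),
            class = "delta_matrix")
}

#' Full multi-list equivalence analysis
#'
#' Computes all pairwise `(d_hat, se_hat)` statistics for a set of feature
#' lists, runs the iterative minimal-threshold algorithm and returns the
#' threshold matrix together with the complete-linkage clustering.
#'
#' @param lists named list of character vectors of feature ids.
#' @param ann an `annotation_map`.
#' @param alpha familywise level.
#' @param tol bisection tolerance.
#' @param method multiplicity rule, `"holm"` or `"bh"`.
#' @return List with components `delta_matrix`, `hclust`, `newick` and
#'   `comparisons` (the `comparison_set`).
#' @export
equiv_cluster <- function(lists, ann, alpha = 0.05, tol = 1e-8,
                          method = c("holm", "bh")) {
  method <- match.arg(method)
  stopifnot(is.list(lists), length(lists) >= 2L)
  labels <- names(lists)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- paste0("L", seq_along(lists))
  s <- length(lists)
  pr <- utils::combn(s, 2)
  d_hat <- numeric(ncol(pr)); se_hat <- numeric(ncol(pr))
  for (cc in seq_len(ncol(pr))) {
    st <- pair_statistics(lists[[pr[1, cc]]], lists[[pr[2, cc]]], ann)
    d_hat[cc] <- st$d_hat; se_hat[cc] <- st$se_hat
  }
  cs <- comparison_set(t(pr), d_hat, se_hat, labels)
  dm <- iterative_delta_matrix(cs, alpha = alpha, tol = tol, method = method)
  hc <- complete_linkage(dm)
  list(delta_matrix = dm, hclust = hc,
       newick = dendrogram_to_newick(hc), comparisons = cs)
}
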