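# Shared fixtures and independent oracles.  Everything here is deliberately
# naive (grid searches, per-feature counting, O(n^3) clustering) so it can
# serve as a reference for the package's faster implementations.

# --- fixtures ---------------------------------------------------------------

# the 3-subset toy map used across modules: g1:{A}, g2:{A,B}, g3:{B}
toy_ann <- function() {
  build_annotation_map(data.frame(
    f = c("g1", "g2", "g2", "g3"),
    c = c("A", "A", "B", "B")))
}

# random annotation map over <= s categories with every feature annotated
random_tiny_ann <- function(n_features, s, k = min(2L, s)) {
  cats <- LETTERS[seq_len(s)]
  rows <- do.call(rbind, lapply(seq_len(n_features), function(i) {
    sz <- sample.int(k, 1L)
    data.frame(f = paste0("g", i), c = sample(cats, sz))
  }))
  # seed the axis so category order is stable regardless of draws
  ann <- build_annotation_map(rbind(data.frame(f = ".axis", c = cats), rows))
  ann$entries <- ann$entries[setdiff(names(ann$entries), ".axis")]
  ann
}

# 20-term fixture ontology: 1 root, 6 level-1 terms, 13 level-2 terms,
# including a diamond (T14 has two level-1 parents)
fixture_dag <- function() {
  terms <- sprintf("T%02d", 0:19)
  edges <- data.frame(
    child = c(sprintf("T%02d", 1:6),
              "T07", "T08", "T09", "T10", "T11", "T12", "T13",
              "T14", "T14", "T15", "T16", "T17", "T18", "T19"),
    parent = c(rep("T00", 6),
               "T01", "T01", "T02", "T02", "T03", "T03", "T04",
               "T04", "T05", "T05", "T06", "T06", "T01", "T02"))
  ontology_from_edges(terms, edges)
}

# expanded profile straight from a count vector on a fixed subset universe
ep_from_counts <- function(counts, subsets, categories) {
  nz <- which(counts > 0)
  equivProfiles:::new_expanded_profile(categories, subsets[nz], counts[nz])
}

# --- oracles ----------------------------------------------------------------

# direct per-feature contracted profile: fraction of features annotated in
# each category (the definition, bypassing the expanded representation)
oracle_contracted <- function(feature_ids, ann) {
  ids <- unique(feature_ids)
  ids <- ids[ids %in% names(ann$entries)]
  sapply(ann$categories, function(cat) {
    mean(vapply(ids, function(f) cat %in% ann$entries[[f]], logical(1)))
  })
}

# dense grid search for the minimal familywise-feasible Delta
oracle_min_delta_grid <- function(d_hat, se_hat, alpha, step = 1e-5) {
  h <- length(d_hat)
  feasible <- function(delta) {
    p <- ifelse(se_hat > 0, pnorm((d_hat - delta) / se_hat),
                ifelse(delta > d_hat, 0, 1))
    all(sort(p) <= alpha / (h + 1 - seq_len(h)))
  }
  hi <- max(d_hat + qnorm(1 - alpha / h) * se_hat) + step
  grid <- seq(max(d_hat), hi, by = step)
  grid[which(vapply(grid, feasible, logical(1)))[1L]]
}

# brute-force re-implementation of the iterative threshold matrix using the
# grid-search oracle at every step
oracle_iterative_matrix <- function(cs, alpha, step = 1e-5) {
  labels <- attr(cs, "labels")
  s <- length(labels)
  D <- matrix(0, s, s, dimnames = list(labels, labels))
  rem <- as.data.frame(cs)
  while (nrow(rem) > 0L) {
    h <- nrow(rem)
    dh <- oracle_min_delta_grid(rem$d_hat, rem$se_hat, alpha, step)
    p <- ifelse(rem$se_hat > 0, pnorm((rem$d_hat - dh) / rem$se_hat),
                ifelse(dh > rem$d_hat, 0, 1))
    cand <- which(p == max(p))
    if (length(cand) > 1L)
      cand <- cand[which.max(rem$d_hat[cand])]
    sel <- cand[1L]
    D[rem$i[sel], rem$j[sel]] <- D[rem$j[sel], rem$i[sel]] <- dh
    rem <- rem[-sel, , drop = FALSE]
  }
  D
}

# naive O(n^3) agglomerative max-linkage: returns sorted merge heights
oracle_complete_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      h <- max(d[clusters[[a]], clusters[[b]]])
      if (h < best_h) { best_h <- h; best <- c(a, b) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# brute-force BFS depths (root depth 0) on a parents list
oracle_bfs_depths <- function(term_ids, parents) {
  depth <- setNames(rep(Inf, length(term_ids)), term_ids)
  roots <- term_ids[lengths(parents[term_ids]) == 0L]
  depth[roots] <- 0
  repeat {
    changed <- FALSE
    for (id in term_ids) {
      for (p in parents[[id]]) {
        if (depth[p] + 1 < depth[id]) { depth[id] <- depth[p] + 1; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  depth
}

# tip-to-tip based merge heights of an ultrametric newick string
newick_node_heights <- function(nwk) {
  tr <- ape::read.tree(text = nwk)
  dd <- ape::dist.nodes(tr)
  ntip <- length(tr$tip.label)
  internal <- (ntip + 1):(ntip + tr$Nnode)
  vapply(internal, function(nd) 2 * min(dd[nd, seq_len(ntip)]), numeric(1))
}
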