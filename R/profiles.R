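# Expanded and contracted functional profiles.
#
# A feature list annotated in s categories C_1, ..., C_s yields a frequency
# table that may sum to more than n because features can carry several
# annotations.  The expanded profile removes the multiplicity by counting
# features on the partition of non-empty category subsets: each feature falls
# in exactly one cell, the cell equal to its full annotation set.  The
# contracted profile recovers per-category annotation probabilities through a
# binary linear map (the "contraction").

#' Canonical enumeration of category subsets
#'
#' Enumerates all non-empty subsets of `1:s` of cardinality at most `k`, in
#' canonical order: by cardinality ascending, then lexicographically on the
#' sorted indices (singletons first, then pairs, and so on).  This order fixes
#' the coordinate system of expanded profiles and contraction matrices.
#'
#' @param s number of categories (>= 1).
#' @param k maximum subset cardinality (1 <= k <= s).
#' @return A list of strictly increasing integer vectors, of length
#'   `sum(choose(s, 1:k))`.
#' @examples
#' canonical_subsets(3, 2)
#' @export
canonical_subsets <- function(s, k) {
  stopifnot(is.numeric(s), length(s) == 1L, s >= 1,
            is.numeric(k), length(k) == 1L, k >= 1, k <= s)
  s <- as.integer(s); k <- as.integer(k)
  out <- vector("list", sum(choose(s, seq_len(k))))
  pos <- 1L
  for (j in seq_len(k)) {
    cm <- utils::combn(s, j)
    for (cc in seq_len(ncol(cm))) {
      out[[pos]] <- cm[, cc]
      pos <- pos + 1L
    }
  }
  out
}

# stable string key for a sorted index subset
subset_key <- function(idx) paste(idx, collapse = ",")

# canonical order (cardinality, then lexicographic on indices) for a list of
# sorted integer subsets
order_subsets <- function(subsets) {
  card <- lengths(subsets)
  key <- vapply(subsets, function(x) paste(sprintf("%06d", x), collapse = ""),
                character(1))
  order(card, key)
}

#' Build an annotation map from (feature, category) pairs
#'
#' Collapses duplicate pairs and collects, for each feature, the set of
#' categories it is annotated in.  The category axis is the first-appearance
#' order of category ids in `rows`.
#'
#' @param rows a two-column data.frame (feature_id, category_id), or any
#'   object coercible to one (matrix, list of two character vectors).
#' @return An object of class `annotation_map` with components `entries`
#'   (named list: feature id -> character vector of category ids) and
#'   `categories` (the ordered distinct category ids).
#' @examples
#' build_annotation_map(data.frame(f = c("g1", "g1", "g2"),
#'                                 c = c("A", "B", "A")))
#' @export
build_annotation_map <- function(rows) {
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no annotations")
  if (ncol(df) < 2L) stop("annotation rows need two columns (feature_id, category_id)")
  feature <- as.character(df[[1L]])
  category <- as.character(df[[2L]])
  bad <- which(is.na(feature) | is.na(category) | !nzchar(feature) | !nzchar(category))
  if (length(bad)) {
    stop(sprintf("malformed annotation at row %d: empty or missing id", bad[1L]))
  }
  keep <- !duplicated(paste0(feature, "\r", category))
  feature <- feature[keep]; category <- category[keep]
  categories <- unique(category)
  entries <- split(category, factor(feature, levels = unique(feature)))
  entries <- lapply(entries, function(x) x[order(match(x, categories))])
  structure(list(entries = entries, categories = categories),
            class = "annotation_map")
}

#' Read an annotation map from a two-column TSV file
#'
#' The file has columns `feature_id<TAB>category_id`; a header line is
#' detected (and skipped) when the first line literally starts with
#' `feature_id`.  Lines starting with `#` are ignored.
#'
#' @param path path to the TSV file.
#' @return An `annotation_map`.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) && identical(tolower(df[1L, 1L]), "feature_id")) {
    df <- df[-1L, , drop = FALSE]
  }
  build_annotation_map(df)
}

#' Read a feature list file
#'
#' One feature identifier per line; blank lines and `#` comments are ignored.
#'
#' @param path path to the plain-text list.
#' @return Character vector of identifiers (duplicates retained; profile
#'   construction de-duplicates).
#' @export
read_feature_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

# internal constructor; subsets must already be sorted-ascending index sets
new_expanded_profile <- function(categories, subsets, counts, dropped = 0L) {
  ord <- order_subsets(subsets)
  subsets <- subsets[ord]
  counts <- as.numeric(counts[ord])
  n <- sum(counts)
  structure(list(categories = as.character(categories),
                 subsets = subsets,
                 counts = counts,
                 n = n,
                 probs = counts / n,
                 dropped = as.integer(dropped)),
            class = "expanded_profile")
}

#' Build an expanded profile for a feature list
#'
#' Identifiers are de-duplicated; features missing from the annotation map are
#' dropped (their number is recorded in the `dropped` component).  Each
#' retained feature adds one count to the subset cell equal to its full
#' category set.  Zero-count subsets are omitted from storage.
#'
#' @param feature_ids character vector of feature identifiers.
#' @param ann an `annotation_map`.
#' @return An object of class `expanded_profile` with components `categories`
#'   (the full category axis of `ann`), `subsets` (observed index subsets in
#'   canonical order), `counts`, `n` (number of annotated features), `probs`
#'   and `dropped`.
#' @export
build_expanded_profile <- function(feature_ids, ann) {
  stopifnot(inherits(ann, "annotation_map"))
  ids <- unique(as.character(feature_ids))
  ids <- ids[!is.na(ids) & nzchar(ids)]
  if (!length(ids)) stop("no annotated features in list")
  annotated <- ids[ids %in% names(ann$entries)]
  dropped <- length(ids) - length(annotated)
  if (!length(annotated)) stop("no annotated features in list")
  idx_sets <- lapply(ann$entries[annotated],
                     function(cats) sort(match(cats, ann$categories)))
  keys <- vapply(idx_sets, subset_key, character(1))
  uk <- unique(keys)
  counts <- tabulate(match(keys, uk), nbins = length(uk))
  subsets <- idx_sets[match(uk, keys)]
  names(subsets) <- NULL
  new_expanded_profile(ann$categories, subsets, counts, dropped)
}

#' Contraction matrix for a set of category subsets
#'
#' The binary matrix `m` with `m[i, c] = 1` iff category `i` belongs to the
#' c-th subset.  Left-multiplying an expanded probability vector by `m`
#' produces the contracted (per-category) probabilities.
#'
#' @param s number of categories.
#' @param subsets list of integer index subsets (indices in `1:s`).
#' @return A numeric `s x length(subsets)` 0/1 matrix.
#' @export
contraction_matrix <- function(s, subsets) {
  stopifnot(s >= 1)
  s <- as.integer(s)
  m <- matrix(0, nrow = s, ncol = length(subsets))
  for (cc in seq_along(subsets)) {
    idx <- subsets[[cc]]
    if (!length(idx) || any(idx < 1L | idx > s))
      stop("subset index out of range")
    m[idx, cc] <- 1
  }
  m
}

#' Contract an expanded profile
#'
#' Computes the per-category annotation probabilities
#' `p_i. = sum over subsets containing i of probs[subset]`.  Because a feature
#' can be annotated in several categories, the contracted components may sum
#' to more than 1.
#'
#' @param ep an `expanded_profile`.
#' @return An object of class `contracted_profile` with components
#'   `categories`, `p` and `n`.
#' @export
contract_profile <- function(ep) {
  stopifnot(inherits(ep, "expanded_profile"))
  m <- contraction_matrix(length(ep$categories), ep$subsets)
  p <- as.vector(m %*% ep$probs)
  new_contracted_profile(ep$categories, p, ep$n)
}

new_contracted_profile <- function(categories, p, n) {
  structure(list(categories = as.character(categories),
                 p = as.numeric(p), n = n),
            class = "contracted_profile")
}

#' @export
print.expanded_profile <- function(x, ...) {
  cat(sprintf("Expanded functional profile: n = %d annotated features, %d occupied subsets over %d categories (%d dropped)\n",
              as.integer(x$n), length(x$subsets), length(x$categories), x$dropped))
  invisible(x)
}

#' @export
print.contracted_profile <- function(x, ...) {
  cat(sprintf("Contracted functional profile (n = %d):\n", as.integer(x$n)))
  print(stats::setNames(round(x$p, 4), x$categories))
  invisible(x)
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("Annotation map: %d features over %d categories\n",
              length(x$entries), length(x$categories)))
  invisible(x)
}

#' Write a contracted profile as TSV
#'
#' Columns `category_id`, `count`, `proportion`.  Counts are the per-category
#' annotation counts `n * p_i.` rounded to integers.
#'
#' @param cp a `contracted_profile`.
#' @param path output file path.
#' @export
write_profile_tsv <- function(cp, path) {
  stopifnot(inherits(cp, "contracted_profile"))
  df <- data.frame(category_id = cp$categories,
                   count = round(cp$p * cp$n),
                   proportion = cp$p)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expanded profile as JSON
#'
#' Serializes categories, subsets (1-based index vectors), counts and n.
#'
#' @param ep an `expanded_profile`.
#' @param path output file path.
#' @export
write_profile_json <- function(ep, path) {
  stopifnot(inherits(ep, "expanded_profile"))
  obj <- list(categories = ep$categories,
              subsets = lapply(ep$subsets, as.integer),
              counts = ep$counts,
              n = ep$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
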