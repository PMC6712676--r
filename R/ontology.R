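# Ontology level slicing: read a DAG from an OBO flat file, compute term
# depths (shortest path to a namespace root along subsumption edges), slice
# at a fixed depth and project feature->term annotations up to that level.
# The "level" convention is root = depth 0 and depth = shortest is_a path;
# part_of edges can be included with a flag.

#' Read an ontology DAG from an OBO 1.2/1.4 flat file
#'
#' Parses `[Term]` stanzas, keeping `id`, `name`, `namespace`, `is_a` and
#' (optionally) `relationship: part_of` links.  Obsolete terms are skipped.
#' Edges pointing at terms outside the file are dropped.
#'
#' @param path path to the OBO file.
#' @param namespace optional namespace filter (e.g. `"biological_process"`).
#' @param include_part_of also treat `part_of` as a subsumption edge
#'   (default FALSE: `is_a` only).
#' @return An object of class `ontology_dag`: list with `terms` (data.frame
#'   id, name, namespace), `parents` (named list of parent id vectors) and
#'   `roots`.
#' @export
read_obo <- function(path, namespace = NULL, include_part_of = FALSE) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanzas found")
  bounds <- c(term_starts, length(lines) + 1L)
  ids <- character(0); names_ <- character(0); ns <- character(0)
  parents <- list()
  for (t in seq_along(term_starts)) {
    block <- lines[(bounds[t] + 1L):(bounds[t + 1L] - 1L)]
    block <- block[nzchar(block) & !startsWith(block, "[")]
    get1 <- function(tag) {
      hit <- block[startsWith(block, paste0(tag, ":"))]
      if (!length(hit)) return(NA_character_)
      trimws(sub("!.*$", "", sub(paste0("^", tag, ":"), "", hit[1L])))
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    par <- block[startsWith(block, "is_a:")]
    par <- trimws(sub("!.*$", "", sub("^is_a:", "", par)))
    if (include_part_of) {
      rel <- block[startsWith(block, "relationship:")]
      rel <- trimws(sub("!.*$", "", sub("^relationship:", "", rel)))
      rel <- rel[startsWith(rel, "part_of ")]
      par <- c(par, sub("^part_of ", "", rel))
    }
    ids <- c(ids, id)
    names_ <- c(names_, get1("name"))
    ns <- c(ns, get1("namespace"))
    parents[[id]] <- par
  }
  keep <- rep(TRUE, length(ids))
  if (!is.null(namespace)) keep <- !is.na(ns) & ns == namespace
  ids <- ids[keep]; names_ <- names_[keep]; ns <- ns[keep]
  parents <- parents[ids]
  parents <- lapply(parents, function(p) unique(p[p %in% ids]))
  new_ontology_dag(data.frame(id = ids, name = names_, namespace = ns,
                              stringsAsFactors = FALSE),
                   parents)
}

# constructor + acyclicity check
new_ontology_dag <- function(terms, parents) {
  stopifnot(is.data.frame(terms), all(terms$id %in% names(parents)))
  g <- .dag_graph(terms$id, parents)
  if (!igraph::is_dag(g)) stop("cycle detected in ontology graph")
  roots <- terms$id[lengths(parents[terms$id]) == 0L]
  if (!length(roots)) stop("ontology has no root term")
  structure(list(terms = terms, parents = parents, roots = roots),
            class = "ontology_dag")
}

# igraph with child -> parent directed edges
.dag_graph <- function(ids, parents) {
  from <- rep(ids, lengths(parents[ids]))
  to <- unlist(parents[ids], use.names = FALSE)
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
}

#' Build an ontology DAG from explicit edges
#'
#' Convenience constructor for fixtures and tests: terms and child->parent
#' edges given directly.
#'
#' @param term_ids character vector of term ids.
#' @param edges two-column data.frame (child, parent).
#' @param names optional term names.
#' @param namespace namespace label applied to all terms.
#' @return An `ontology_dag`.
#' @export
ontology_from_edges <- function(term_ids, edges,
                                names = term_ids, namespace = "fixture") {
  parents <- lapply(stats::setNames(term_ids, term_ids), function(id) {
    unique(as.character(edges[[2L]][as.character(edges[[1L]]) == id]))
  })
  new_ontology_dag(data.frame(id = term_ids, name = names,
                              namespace = namespace, stringsAsFactors = FALSE),
                   parents)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("Ontology DAG: %d terms, %d roots (%s)\n",
              nrow(x$terms), length(x$roots),
              paste(unique(x$terms$namespace), collapse = ", ")))
  invisible(x)
}

#' Shortest-path depth of every term
#'
#' Depth of a term is the length of the shortest directed path from the term
#' to any root; roots have depth 0.
#'
#' @param dag an `ontology_dag`.
#' @return Named integer vector of depths.
#' @export
term_depths <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  g <- .dag_graph(dag$terms$id, dag$parents)
  dist <- igraph::distances(g, v = dag$terms$id, to = dag$roots,
                            mode = "out")
  depths <- apply(dist, 1L, min)
  if (any(!is.finite(depths)))
    stop("terms not connected to any root: ",
         paste(utils::head(dag$terms$id[!is.finite(depths)], 5), collapse = ", "))
  stats::setNames(as.integer(depths), dag$terms$id)
}

#' Slice the ontology at a fixed level
#'
#' @param dag an `ontology_dag`.
#' @param level depth at which to cut (>= 1).
#' @return An object of class `level_slice`: list with `level` and
#'   `categories` (term ids at exactly that depth, sorted).
#' @export
slice_at_level <- function(dag, level) {
  stopifnot(level >= 1)
  depths <- term_depths(dag)
  cats <- sort(names(depths)[depths == level])
  if (!length(cats)) stop(sprintf("no terms at level %d", level))
  structure(list(level = as.integer(level), categories = cats),
            class = "level_slice")
}

#' Project feature annotations onto a fixed ontology level
#'
#' Each (feature, term) pair contributes the term's ancestors (including the
#' term itself) whose depth equals `level`.  Features left with no category
#' at that level (all their terms shallower than the level, or unreachable)
#' are dropped; their number is recorded in the `dropped_features` attribute.
#'
#' @param gene2term two-column data.frame (feature_id, term_id).
#' @param dag an `ontology_dag`.
#' @param level target depth (>= 1).
#' @return An `annotation_map` whose category axis is the sorted level slice,
#'   with attribute `dropped_features`.
#' @export
annotations_to_level <- function(gene2term, dag, level) {
  stopifnot(inherits(dag, "ontology_dag"))
  sl <- slice_at_level(dag, level)
  depths <- term_depths(dag)
  g <- .dag_graph(dag$terms$id, dag$parents)
  # ancestors at the level: slice terms reachable from each term going up
  dist <- igraph::distances(g, v = dag$terms$id, to = sl$categories,
                            mode = "out")
  anc <- lapply(dag$terms$id, function(id) {
    sl$categories[is.finite(dist[id, ])]
  })
  names(anc) <- dag$terms$id

  feat <- as.character(gene2term[[1L]])
  term <- as.character(gene2term[[2L]])
  known <- term %in% dag$terms$id
  feat <- feat[known]; term <- term[known]
  rows <- data.frame(feature_id = rep(feat, lengths(anc[term])),
                     category_id = unlist(anc[term], use.names = FALSE),
                     stringsAsFactors = FALSE)
  n_input <- length(unique(as.character(gene2term[[1L]])))
  if (!nrow(rows)) stop("no features annotated at the requested level")
  # seed with the slice axis so the category order is the full sorted slice
  ann <- build_annotation_map(rbind(
    data.frame(feature_id = ".axis", category_id = sl$categories), rows))
  ann$entries <- ann$entries[setdiff(names(ann$entries), ".axis")]
  attr(ann, "dropped_features") <- n_input - length(ann$entries)
  ann
}

#' Read a feature-to-term table
#'
#' Accepts a 2-column TSV (`feature_id<TAB>term_id`, optional header,
#' `#` comments ignored) or a GAF 2.x file, from which only columns 2
#' (DB Object ID) and 5 (ontology term ID) are used.
#'
#' @param path input path.
#' @param format `"tsv"` (default) or `"gaf"`.
#' @return Two-column data.frame (feature_id, term_id).
#' @export
read_gene2term <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (format == "gaf") {
    df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                            comment.char = "!", stringsAsFactors = FALSE,
                            fill = TRUE, colClasses = "character")
    return(data.frame(feature_id = df[[2L]], term_id = df[[5L]],
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) && identical(tolower(df[1L, 1L]), "feature_id"))
    df <- df[-1L, , drop = FALSE]
  data.frame(feature_id = df[[1L]], term_id = df[[2L]],
             stringsAsFactors = FALSE)
}
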