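#' Construct an ontology graph
#'
#' Directed acyclic graph of terms connected by child -> parent `is_a` edges.
#' Edges never cross namespaces; namespaces behave as disjoint DAGs with one
#' or more roots each.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent` (term ids).
#' @return object of class `ontology_graph` with precomputed adjacency lists.
#' @export
ontology_graph <- function(terms, edges) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "namespace") %in% names(terms)))
  terms <- data.frame(id = as.character(terms$id), name = as.character(terms$name),
                      namespace = as.character(terms$namespace),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(terms$id)) stop("duplicate term ids in ontology")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(child = character(0), parent = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(child = as.character(edges$child),
                        parent = as.character(edges$parent),
                        stringsAsFactors = FALSE)
  }
  unknown <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(unknown) > 0) {
    stop("is_a references unknown term id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  ns <- stats::setNames(terms$namespace, terms$id)
  cross <- ns[edges$child] != ns[edges$parent]
  if (any(cross)) {
    stop(sprintf("is_a edge crosses namespaces: %s -> %s",
                 edges$child[which(cross)[1]], edges$parent[which(cross)[1]]))
  }
  g <- structure(
    list(
      terms = terms,
      edges = edges,
      parents = split_adjacency(edges$child, edges$parent, terms$id),
      children = split_adjacency(edges$parent, edges$child, terms$id)
    ),
    class = "ontology_graph"
  )
  cyc <- find_cycle(g)
  if (!is.null(cyc)) {
    stop("ontology is cyclic; one cycle: ", paste(cyc, collapse = " -> "))
  }
  g
}

split_adjacency <- function(from, to, ids) {
  adj <- split(to, factor(from, levels = ids))
  lapply(adj, function(v) sort(unique(v)))
}

# Depth-first search for a cycle over child -> parent edges; returns the
# cycle as a vector of ids, or NULL when the graph is acyclic.
find_cycle <- function(g) {
  state <- stats::setNames(rep(0L, nrow(g$terms)), g$terms$id) # 0 new, 1 open, 2 done
  stack <- character(0)
  visit <- function(id) {
    state[id] <<- 1L
    stack <<- c(stack, id)
    for (p in g$parents[[id]]) {
      if (state[p] == 1L) {
        i <- match(p, stack)
        return(c(stack[i:length(stack)], p))
      }
      if (state[p] == 0L) {
        res <- visit(p)
        if (!is.null(res)) return(res)
      }
    }
    state[id] <<- 2L
    stack <<- stack[-length(stack)]
    NULL
  }
  for (id in g$terms$id) {
    if (state[id] == 0L) {
      res <- visit(id)
      if (!is.null(res)) return(res)
    }
  }
  NULL
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms, %d is_a edges, %d namespace(s)\n",
              nrow(x$terms), nrow(x$edges), length(unique(x$terms$namespace))))
  invisible(x)
}

#' Parse an OBO 1.2 flat file
#'
#' Reads `[Term]` stanzas, keeping `id`, `name`, `namespace` and `is_a`
#' lines. Obsolete terms (`is_obsolete: true`) are dropped together with any
#' edges touching them; only `is_a` relations are retained. The resulting
#' graph is validated to be acyclic.
#'
#' @param path path to an OBO file.
#' @return an [ontology_graph()].
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function() if (!is.null(cur) && !is.null(cur$id)) stanzas[[length(stanzas) + 1L]] <<- cur
  for (line in lines) {
    line <- sub("\\s*!.*$", "", line) # trailing comments
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush()
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) cur <- list(is_a = character(0), obsolete = FALSE)
      next
    }
    if (!in_term) next
    kv <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (length(kv) != 3) next
    key <- kv[2]; val <- kv[3]
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, sub("\\s.*$", "", val))
    else if (key == "is_obsolete" && tolower(val) == "true") cur$obsolete <- TRUE
  }
  flush()
  keep <- Filter(function(s) !s$obsolete, stanzas)
  if (length(keep) == 0) stop("no usable [Term] stanzas in ", path)
  terms <- data.frame(
    id = vapply(keep, `[[`, "", "id"),
    name = vapply(keep, function(s) s$name %||% s$id, ""),
    namespace = vapply(keep, function(s) s$namespace %||% "default", ""),
    stringsAsFactors = FALSE
  )
  edges <- do.call(rbind, lapply(keep, function(s) {
    if (length(s$is_a) == 0) return(NULL)
    data.frame(child = s$id, parent = s$is_a, stringsAsFactors = FALSE)
  }))
  # edges into obsolete terms are dropped silently with the term
  if (!is.null(edges)) {
    obsolete_ids <- setdiff(vapply(stanzas, function(s) s$id %||% "", ""), terms$id)
    edges <- edges[!(edges$parent %in% obsolete_ids), , drop = FALSE]
  }
  ontology_graph(terms, edges)
}

#' Write an ontology graph as OBO 1.2
#'
#' Inverse of [parse_obo()] for graphs produced in this package:
#' `parse_obo(write_obo(g))` reproduces `g`.
#'
#' @param graph an [ontology_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  nm <- stats::setNames(graph$terms$name, graph$terms$id)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", graph$terms$name[i]),
                 paste0("namespace: ", graph$terms$namespace[i])), con)
    for (p in graph$parents[[id]]) {
      writeLines(paste0("is_a: ", p, " ! ", nm[[p]]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Distance-1 neighborhood of a term
#'
#' The neighbor relation used for sphere expansion: the union of a term's
#' direct parents and direct children in the `is_a` DAG. Adjacency is
#' symmetric and never includes the term itself.
#'
#' @param graph an [ontology_graph()].
#' @param term a term id present in the graph.
#' @return character vector of neighboring term ids (sorted).
#' @export
neighbors <- function(graph, term) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (!term %in% graph$terms$id) stop("unknown term: ", term)
  sort(unique(c(graph$parents[[term]], graph$children[[term]])))
}

#' Ontology diagnostics
#'
#' Reports per-namespace term counts, root terms, maximum depth (longest
#' root-to-leaf is_a path per namespace) and, when an abundance table is
#' supplied, feature ids absent from the ontology.
#'
#' @param graph an [ontology_graph()].
#' @param table optional `abundance_table` of kind `"go_term"`.
#' @return a list of class `ontology_diagnostics`.
#' @export
validate_ontology <- function(graph, table = NULL) {
  stopifnot(inherits(graph, "ontology_graph"))
  roots <- graph$terms$id[vapply(graph$terms$id,
                                 function(id) length(graph$parents[[id]]) == 0, TRUE)]
  depth <- term_depths(graph)
  res <- list(
    n_terms = nrow(graph$terms),
    terms_per_namespace = table(graph$terms$namespace),
    roots = roots,
    max_depth = if (length(depth)) max(depth) else 0L,
    missing_from_ontology = character(0)
  )
  if (!is.null(table)) {
    res$missing_from_ontology <- setdiff(rownames(table$values), graph$terms$id)
  }
  class(res) <- "ontology_diagnostics"
  res
}

# Longest path from any root, per term, via topological order.
term_depths <- function(graph) {
  ids <- graph$terms$id
  indeg <- vapply(ids, function(id) length(graph$parents[[id]]), 0L)
  # Kahn's algorithm from roots downward over parent -> child edges
  depth <- stats::setNames(rep(0L, length(ids)), ids)
  remaining <- indeg
  queue <- ids[remaining == 0L]
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (ch in graph$children[[v]]) {
      depth[ch] <- max(depth[ch], depth[v] + 1L)
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  depth
}

#' @export
print.ontology_diagnostics <- function(x, ...) {
  cat(sprintf("%d terms; max depth %d; %d root(s): %s\n", x$n_terms, x$max_depth,
              length(x$roots), paste(utils::head(x$roots, 5), collapse = ", ")))
  print(x$terms_per_namespace)
  if (length(x$missing_from_ontology)) {
    cat("features missing from ontology:",
        paste(utils::head(x$missing_from_ontology, 10), collapse = ", "), "\n")
  }
  invisible(x)
}
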