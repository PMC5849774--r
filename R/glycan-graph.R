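#' Construct a glycan graph
#'
#' A `glycan_graph` is a finite, simple, undirected, connected graph with
#' opaque character vertex ids, an optional accession identifier and
#' optional vertex labels.  Validation enforces the simple-graph and
#' connectivity invariants; disconnected input is an error rather than being
#' silently split into components.
#'
#' @param edges two-column matrix or data frame of vertex ids (character),
#'   one row per undirected edge.  May be `NULL` for a single-vertex graph.
#' @param vertices character vector of vertex ids.  Optional when `edges`
#'   covers all vertices; required to represent the single-vertex graph.
#'   Ids not incident to any edge are only legal when the graph has exactly
#'   one vertex (otherwise the graph would be disconnected).
#' @param labels optional named character vector mapping vertex id to a
#'   label token (used by labelled canonical forms and labelled search).
#' @param accession identifier carried through all downstream outputs;
#'   defaults to `""`.
#' @return an object of class `glycan_graph`.
#' @examples
#' p3 <- glycan_graph(rbind(c("a", "b"), c("b", "c")))
#' n_vertices(p3)
#' classify(p3)
#' @export
glycan_graph <- function(edges = NULL, vertices = NULL, labels = NULL,
                         accession = "") {
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (length(edges) == 0L) edges <- NULL
  }
  if (!is.null(edges)) {
    if (ncol(edges) != 2L)
      stop("`edges` must have exactly two columns", call. = FALSE)
    storage.mode(edges) <- "character"
    if (anyNA(edges) || any(edges == ""))
      stop("vertex ids must be non-empty strings", call. = FALSE)
    if (any(edges[, 1L] == edges[, 2L]))
      stop("validation error: self-loop on vertex '",
           edges[edges[, 1L] == edges[, 2L], 1L][1L], "'", call. = FALSE)
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]), sep = "\r")
    if (anyDuplicated(key))
      stop("validation error: duplicate edge {",
           gsub("\r", ", ", key[duplicated(key)][1L]), "}", call. = FALSE)
  }
  ids <- unique(c(as.character(vertices),
                  if (!is.null(edges)) as.character(t(edges))))
  if (length(ids) == 0L)
    stop("validation error: graph must have at least one vertex",
         call. = FALSE)
  ig <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = ids)
  if (!is.null(edges))
    ig <- igraph::add_edges(ig, rbind(match(edges[, 1L], ids),
                                      match(edges[, 2L], ids)))
  if (!igraph::is_connected(ig))
    stop("validation error: graph is disconnected", call. = FALSE)
  if (!is.null(labels)) {
    labels <- vapply(labels, as.character, character(1))
    if (is.null(names(labels)) || !all(names(labels) %in% ids))
      stop("`labels` must be named by vertex ids present in the graph",
           call. = FALSE)
    lab <- rep(NA_character_, length(ids))
    lab[match(names(labels), ids)] <- unname(labels)
    ig <- igraph::set_vertex_attr(ig, "label", value = lab)
  }
  new_glycan_graph(ig, accession)
}

# Internal fast path: wrap an already-validated igraph object.
new_glycan_graph <- function(ig, accession = "") {
  structure(list(graph = ig, accession = as.character(accession)),
            class = "glycan_graph")
}

#' @export
print.glycan_graph <- function(x, ...) {
  cat(sprintf("<glycan_graph> %s: %d vertices, %d edges (%s)\n",
              if (nzchar(x$accession)) x$accession else "<unnamed>",
              n_vertices(x), n_edges(x), classify(x)))
  invisible(x)
}

#' Basic accessors for glycan graphs
#'
#' @param g a [glycan_graph].
#' @return `n_vertices()` and `n_edges()` return integer counts;
#'   `vertex_ids()` a character vector; `vertex_labels()` a named character
#'   vector (or `NULL` when the graph is unlabelled); `edge_table()` a
#'   two-column character matrix of edges.
#' @export
n_vertices <- function(g) as.integer(igraph::vcount(g$graph))

#' @rdname n_vertices
#' @export
n_edges <- function(g) as.integer(igraph::ecount(g$graph))

#' @rdname n_vertices
#' @export
vertex_ids <- function(g) {
  nm <- igraph::vertex_attr(g$graph, "name")
  if (is.null(nm)) as.character(seq_len(n_vertices(g))) else nm
}

#' @rdname n_vertices
#' @export
vertex_labels <- function(g) {
  lab <- igraph::vertex_attr(g$graph, "label")
  if (is.null(lab)) return(NULL)
  names(lab) <- vertex_ids(g)
  lab
}

#' @rdname n_vertices
#' @export
edge_table <- function(g) {
  el <- igraph::as_edgelist(g$graph, names = FALSE)
  ids <- vertex_ids(g)
  cbind(ids[el[, 1L]], ids[el[, 2L]])
}

# 0-based integer edge list, the form the compiled tree routines take.
edge_index0 <- function(g) {
  el <- igraph::as_edgelist(g$graph, names = FALSE)
  list(from = as.integer(el[, 1L]) - 1L, to = as.integer(el[, 2L]) - 1L)
}

is_tree <- function(g) n_edges(g) == n_vertices(g) - 1L

#' Read and write glycan edge-list files
#'
#' The edge-list dialect is UTF-8 text with one record per line: `#` starts
#' a comment, a line `v <id>` declares a vertex with no edges (needed to
#' represent the single-vertex graph), and any other non-blank line must
#' hold exactly two whitespace-separated vertex ids forming an edge.
#' Vertex ids are opaque tokens.  The accession defaults to the file's base
#' name without extension.
#'
#' @param path file to read or write.
#' @param labels optional named character vector of vertex labels, or a path
#'   to a two-column TSV `vertex<TAB>label` sidecar (see
#'   [read_vertex_labels()]).
#' @param accession overrides the default accession.
#' @return `read_edge_list()` returns a [glycan_graph];
#'   `write_edge_list()` invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("# a 3-path", "a b", "b c"), f)
#' read_edge_list(f)
#' @export
read_edge_list <- function(path, labels = NULL, accession = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  declared <- character(0)
  edges <- NULL
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) == 2L && tk[1L] == "v") {
      declared <- c(declared, tk[2L])
    } else if (length(tk) == 2L) {
      edges <- rbind(edges, tk)
    } else {
      stop("parse error in ", path, ": line '", lines[i],
           "' does not have two tokens", call. = FALSE)
    }
  }
  if (is.character(labels) && length(labels) == 1L && is.null(names(labels)) &&
      file.exists(labels))
    labels <- read_vertex_labels(labels)
  if (is.null(accession))
    accession <- sub("\\.[^.]*$", "", basename(path))
  glycan_graph(edges, vertices = declared, labels = labels,
               accession = accession)
}

#' @rdname read_edge_list
#' @param g a [glycan_graph] to write.
#' @export
write_edge_list <- function(g, path) {
  et <- edge_table(g)
  lines <- character(0)
  deg <- igraph::degree(g$graph)
  iso <- vertex_ids(g)[deg == 0L]
  if (length(iso)) lines <- paste("v", iso)
  if (nrow(et)) lines <- c(lines, paste(et[, 1L], et[, 2L]))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname read_edge_list
#' @export
read_vertex_labels <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "",
                    comment.char = "#")
  if (ncol(tab) != 2L)
    stop("label file must have two tab-separated columns", call. = FALSE)
  structure(tab[[2L]], names = tab[[1L]])
}

#' Structural classification of a glycan graph
#'
#' Every connected graph falls in exactly one of four classes: `"linear"`
#' (a path, i.e. a tree with maximum degree at most 2), `"branched_tree"`
#' (a tree with a vertex of degree 3 or more), `"pure_cycle"` (all degrees
#' equal 2), or `"cyclic_branched"` (contains a cycle but is not itself a
#' cycle).  The first two make up the trees, the last two the graphs with at
#' least one cycle.  The single vertex and the single edge count as linear.
#'
#' @param g a [glycan_graph].
#' @return one of `"linear"`, `"branched_tree"`, `"pure_cycle"`,
#'   `"cyclic_branched"`.
#' @export
classify <- function(g) {
  deg <- igraph::degree(g$graph)
  if (is_tree(g)) {
    if (max(deg) >= 3L) "branched_tree" else "linear"
  } else if (all(deg == 2L)) {
    "pure_cycle"
  } else {
    "cyclic_branched"
  }
}

#' Diameter and triangle-freeness
#'
#' `graph_diameter()` is the largest hop distance between any two vertices,
#' with every edge of length one (the roughly 1.5-times-longer chemical
#' linkages, e.g. 1-6 bonds, are deliberately treated as unit length).
#' A single vertex has diameter 0.  Trees use an exact double-sweep BFS;
#' other graphs the all-pairs BFS of igraph.  `is_triangle_free()` reports
#' whether the graph has no 3-cycle; in a triangle-free graph every clique
#' has at most two vertices, which fixes the clique-cover route.
#'
#' @param g a [glycan_graph].
#' @return `graph_diameter()` a non-negative integer; `is_triangle_free()`
#'   a logical.
#' @examples
#' graph_diameter(glycan_graph(cbind(letters[1:6], letters[2:7])))  # P_7: 6
#' @export
graph_diameter <- function(g) {
  n <- n_vertices(g)
  if (n == 1L) return(0L)
  if (is_tree(g)) {
    e <- edge_index0(g)
    .cpp_tree_diameter(n, e$from, e$to)
  } else {
    as.integer(igraph::diameter(g$graph, weights = NA))
  }
}

#' @rdname graph_diameter
#' @export
is_triangle_free <- function(g) {
  if (is_tree(g)) return(TRUE)
  sum(igraph::count_triangles(g$graph)) == 0L
}

#' Relabel the vertices of a glycan graph
#'
#' Applies a bijection to the vertex ids; the result is isomorphic to the
#' input.  Mostly useful for invariance checks.
#'
#' @param g a [glycan_graph].
#' @param map named character vector, old id to new id, covering all ids.
#' @return a [glycan_graph].
#' @export
relabel <- function(g, map) {
  ids <- vertex_ids(g)
  if (!all(ids %in% names(map)) || anyDuplicated(map[ids]))
    stop("`map` must be a bijection over the vertex ids", call. = FALSE)
  et <- edge_table(g)
  et[] <- map[et]
  lab <- vertex_labels(g)
  if (!is.null(lab)) names(lab) <- map[names(lab)]
  verts <- if (nrow(et) == 0L) unname(map[ids]) else NULL
  glycan_graph(et, vertices = verts, labels = lab, accession = g$accession)
}
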