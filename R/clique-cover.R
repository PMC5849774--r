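#' Clique cover number
#'
#' The clique cover number is the smallest number of cliques (vertex sets of
#' diameter 1) whose union is the whole vertex set.  The computation
#' dispatches on graph structure, each later route strictly more expensive
#' than the previous:
#'
#' 1. single vertex: 1;
#' 2. complete graph: 1;
#' 3. tree: the independence number via a linear-time dynamic program
#'    (trees are perfect, and on perfect graphs the clique cover number
#'    equals the independence number — Lovász);
#' 4. triangle-free graph: `n` minus the size of a maximum matching
#'    (cliques are edges or singletons, so an optimal cover keeps a maximum
#'    matching and covers the rest by singletons);
#' 5. otherwise: exact branch-and-bound minimum clique partition, permitted
#'    only up to `exact_cap` vertices.
#'
#' Perfection is not tested: a non-tree perfect graph that contains a
#' triangle goes through the exact route.  When a triangle-containing graph
#' exceeds `exact_cap` the function throws an error of class
#' `glycodim_cover_infeasible` rather than approximating.
#'
#' @param g a [glycan_graph].
#' @param exact_cap largest vertex count admitted to the exact
#'   branch-and-bound route (default 64; glycan cycles are tiny).
#' @return a positive integer.  The route taken and, on the matching route,
#'   the matching size are attached as attributes `"route"` and
#'   `"matching_size"`.
#' @examples
#' clique_cover_number(glycan_graph(cbind(letters[1:10], letters[2:11])))  # 6
#' @export
clique_cover_number <- function(g, exact_cap = 64L) {
  n <- n_vertices(g)
  if (n == 1L)
    return(structure(1L, route = "single_vertex"))
  if (n_edges(g) == as.numeric(n) * (n - 1) / 2)
    return(structure(1L, route = "complete"))
  if (is_tree(g)) {
    e <- edge_index0(g)
    return(structure(.cpp_tree_alpha(n, e$from, e$to), route = "tree"))
  }
  if (is_triangle_free(g)) {
    nu <- maximum_matching(g)$size
    return(structure(n - nu, route = "matching", matching_size = nu))
  }
  if (n > exact_cap)
    stop(structure(class = c("glycodim_cover_infeasible", "error",
                             "condition"),
                   list(message = sprintf(
                     paste0("exact clique cover infeasible: graph has %d",
                            " vertices, exact_cap is %d"), n, exact_cap),
                     call = NULL)))
  structure(exact_clique_cover(g), route = "exact")
}

# Exact minimum clique partition by branch and bound.  Vertices are
# considered in an order that starts with a maximal independent set (its
# members are pairwise non-adjacent, so each forces a new clique: an
# immediate lower bound); each vertex is placed in every compatible open
# clique, or opens a new one, pruning once the clique count reaches the
# best complete solution found so far.
exact_clique_cover <- function(g) {
  n <- n_vertices(g)
  am <- as.matrix(igraph::as_adjacency_matrix(g$graph, type = "both")) > 0
  # greedy maximal independent set, low-degree first
  ord <- order(rowSums(am))
  mis <- integer(0)
  for (v in ord) if (!any(am[v, mis])) mis <- c(mis, v)
  rest <- setdiff(order(rowSums(am), decreasing = TRUE), mis)
  vs <- c(mis, rest)

  # greedy cover for the initial upper bound
  cliques <- list()
  for (v in vs) {
    placed <- FALSE
    for (k in seq_along(cliques)) {
      if (all(am[v, cliques[[k]]])) {
        cliques[[k]] <- c(cliques[[k]], v)
        placed <- TRUE
        break
      }
    }
    if (!placed) cliques[[length(cliques) + 1L]] <- v
  }
  best <- length(cliques)
  if (best == length(mis)) return(best)  # greedy met the lower bound

  recurse <- function(i, cliques) {
    if (length(cliques) >= best) return(invisible(NULL))
    if (i > n) {
      best <<- length(cliques)
      return(invisible(NULL))
    }
    v <- vs[i]
    for (k in seq_along(cliques)) {
      if (all(am[v, cliques[[k]]])) {
        nk <- cliques
        nk[[k]] <- c(nk[[k]], v)
        recurse(i + 1L, nk)
      }
    }
    if (length(cliques) + 1L < best)
      recurse(i + 1L, c(cliques, list(v)))
    invisible(NULL)
  }
  recurse(1L, list())
  best
}
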