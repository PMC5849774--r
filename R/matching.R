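# Maximum matching in a general graph: Edmonds' blossom algorithm,
# array-based O(V^3) formulation.  Needed because the clique cover number of
# a triangle-free graph equals n minus the maximum matching size, and
# triangle-free glycan graphs (odd cycles in particular) are not bipartite.

#' Maximum matching of a glycan graph
#'
#' Computes a maximum matching (largest set of pairwise non-incident edges)
#' of an arbitrary graph with Edmonds' blossom algorithm.  For a
#' triangle-free graph the clique cover number is `n_vertices(g) - size`,
#' since every clique is an edge or a single vertex.
#'
#' @param g a [glycan_graph].
#' @return a list with `size` (integer) and `mate`, an integer vector where
#'   `mate[v]` is the vertex matched to `v` (0 when unmatched), in the order
#'   of [vertex_ids()].
#' @examples
#' maximum_matching(glycan_graph(cbind(letters[1:4], letters[2:5])))$size
#' @export
maximum_matching <- function(g) {
  n <- n_vertices(g)
  el <- igraph::as_edgelist(g$graph, names = FALSE)
  adj <- vector("list", n)
  if (nrow(el)) {
    adj <- lapply(seq_len(n), function(v)
      c(el[el[, 1L] == v, 2L], el[el[, 2L] == v, 1L]))
  }
  blossom_matching(n, adj)
}

blossom_matching <- function(n, adj) {
  mate <- integer(n)        # 0 = unmatched
  p <- integer(n)           # alternating-tree parent
  base <- integer(n)        # blossom base of each vertex
  used <- logical(n)
  blossom <- logical(n)
  qu <- integer(0)

  lca <- function(a, b) {
    seen <- logical(n)
    v <- a
    repeat {
      v <- base[v]
      seen[v] <- TRUE
      if (mate[v] == 0L) break
      v <- p[mate[v]]
    }
    v <- b
    repeat {
      v <- base[v]
      if (seen[v]) return(v)
      v <- p[mate[v]]
    }
  }

  mark_path <- function(v, b, child) {
    while (base[v] != b) {
      blossom[base[v]] <<- TRUE
      blossom[base[mate[v]]] <<- TRUE
      p[v] <<- child
      child <- mate[v]
      v <- p[mate[v]]
    }
  }

  find_path <- function(root) {
    used[] <<- FALSE
    p[] <<- 0L
    base <<- seq_len(n)
    used[root] <<- TRUE
    qu <<- root
    while (length(qu)) {
      v <- qu[1L]
      qu <<- qu[-1L]
      for (to in adj[[v]]) {
        if (base[v] == base[to] || mate[v] == to) next
        if (to == root || (mate[to] != 0L && p[mate[to]] != 0L)) {
          # odd cycle: contract the blossom
          curbase <- lca(v, to)
          blossom[] <<- FALSE
          mark_path(v, curbase, to)
          mark_path(to, curbase, v)
          for (i in seq_len(n)) {
            if (blossom[base[i]]) {
              base[i] <<- curbase
              if (!used[i]) {
                used[i] <<- TRUE
                qu <<- c(qu, i)
              }
            }
          }
        } else if (p[to] == 0L) {
          p[to] <<- v
          if (mate[to] == 0L) {
            # augmenting path found: flip matched edges along it
            while (to != 0L) {
              pv <- p[to]
              ppv <- mate[pv]
              mate[to] <<- pv
              mate[pv] <<- to
              to <- ppv
            }
            return(TRUE)
          }
          used[mate[to]] <<- TRUE
          qu <<- c(qu, mate[to])
        }
      }
    }
    FALSE
  }

  size <- 0L
  for (v in seq_len(n)) {
    if (mate[v] == 0L && find_path(v)) size <- size + 1L
  }
  list(size = size, mate = mate)
}
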