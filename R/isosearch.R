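#' AHU canonical form of a tree
#'
#' Computes the Aho–Hopcroft–Ullman string encoding of a tree, rooted at
#' the tree's center; for bicentral trees both rootings are computed and
#' the lexicographically smaller form kept.  Two trees have equal forms iff
#' they are isomorphic (respecting vertex labels when `use_labels` is
#' `TRUE`).  Child forms are sorted by subtree size, then by form string.
#' Graphs that are not trees get the `NONTREE` sentinel (`form = NA`):
#' those few are compared by exact isomorphism search instead (see
#' [db_lookup()]).
#'
#' @param g a [glycan_graph].
#' @param use_labels include the vertex label token inside each node's
#'   parenthesized form (unlabelled vertices contribute an empty token).
#' @return an object of class `canonical_code`: a list with `form`
#'   (character or `NA` for non-trees), `tree` and `labelled` flags.
#' @examples
#' canonical_code(glycan_graph(cbind(c("a", "b"), c("b", "c"))))
#' @export
canonical_code <- function(g, use_labels = FALSE) {
  if (!is_tree(g)) {
    return(structure(list(form = NA_character_, tree = FALSE,
                          labelled = use_labels),
                     class = "canonical_code"))
  }
  n <- n_vertices(g)
  lab <- if (use_labels) {
    l <- vertex_labels(g)
    if (is.null(l)) rep("", n) else ifelse(is.na(l), "", unname(l))
  } else rep("", n)
  adj <- igraph::as_adj_list(g$graph)
  centers <- tree_centers(n, adj)
  forms <- vapply(centers, function(r) ahu_form(r, adj, lab), character(1))
  structure(list(form = min(forms), tree = TRUE, labelled = use_labels),
            class = "canonical_code")
}

#' @export
print.canonical_code <- function(x, ...) {
  if (!x$tree) cat("<canonical_code> NONTREE\n")
  else cat(sprintf("<canonical_code>%s %s\n",
                   if (x$labelled) " [labelled]" else "", x$form))
  invisible(x)
}

# Centers of a tree by iterative leaf pruning (1 or 2 vertices).
tree_centers <- function(n, adj) {
  if (n <= 2L) return(seq_len(n))
  deg <- lengths(adj)
  alive <- rep(TRUE, n)
  remaining <- n
  leaves <- which(deg <= 1L)
  while (remaining > 2L) {
    nxt <- integer(0)
    for (v in leaves) {
      alive[v] <- FALSE
      remaining <- remaining - 1L
      for (w in adj[[v]]) {
        if (alive[w]) {
          deg[w] <- deg[w] - 1L
          if (deg[w] == 1L) nxt <- c(nxt, w)
        }
      }
    }
    leaves <- nxt
  }
  which(alive)
}

# AHU form of the tree rooted at `root`, iterative over a reverse BFS
# order so every child is finished before its parent.
ahu_form <- function(root, adj, lab) {
  n <- length(adj)
  parent <- integer(n)
  order <- integer(n)
  order[1L] <- root
  parent[root] <- -1L
  head <- 1L
  tail <- 1L
  while (head <= tail) {
    v <- order[head]
    head <- head + 1L
    for (w in adj[[v]]) {
      if (parent[w] == 0L && w != root) {
        parent[w] <- v
        tail <- tail + 1L
        order[tail] <- w
      }
    }
  }
  form <- character(n)
  size <- rep(1L, n)
  kids <- vector("list", n)
  for (i in n:1) {
    v <- order[i]
    ch <- kids[[v]]
    if (is.null(ch)) {
      form[v] <- paste0("(", lab[v], ")")
    } else {
      o <- order(size[ch], form[ch])
      form[v] <- paste0("(", lab[v], paste(form[ch][o], collapse = ""),
                        ")")
    }
    p <- parent[v]
    if (p > 0L) {
      kids[[p]] <- c(kids[[p]], v)
      size[p] <- size[p] + size[v]
    }
  }
  form[root]
}

#' Count isomorphism classes in a collection of graphs
#'
#' Groups trees by their AHU canonical form; the few non-tree members are
#' partitioned by exact pairwise isomorphism (VF2), within buckets sharing
#' vertex and edge counts.
#'
#' @param graphs list of [glycan_graph] objects.
#' @param use_labels label-respecting grouping.
#' @return a data frame with one row per class: `class` (the canonical
#'   form, or a `nontree:` id), `count`, and `representative` (accession of
#'   the first member).  The number of classes is `nrow()` of the result.
#' @export
count_classes <- function(graphs, use_labels = FALSE) {
  if (length(graphs) == 0L)
    return(data.frame(class = character(0), count = integer(0),
                      representative = character(0)))
  istree <- vapply(graphs, is_tree, logical(1))
  rows <- list()
  if (any(istree)) {
    tg <- graphs[istree]
    forms <- vapply(tg, function(g) canonical_code(g, use_labels)$form,
                    character(1))
    accs <- vapply(tg, function(g) g$accession, character(1))
    for (f in unique(forms)) {
      idx <- which(forms == f)
      rows[[length(rows) + 1L]] <-
        data.frame(class = f, count = length(idx),
                   representative = accs[idx[1L]],
                   stringsAsFactors = FALSE)
    }
  }
  if (any(!istree)) {
    ng <- graphs[!istree]
    reps <- list()
    counts <- integer(0)
    for (g in ng) {
      hit <- 0L
      for (k in seq_along(reps)) {
        if (graphs_isomorphic(reps[[k]], g, use_labels)) {
          hit <- k
          break
        }
      }
      if (hit > 0L) counts[hit] <- counts[hit] + 1L
      else {
        reps[[length(reps) + 1L]] <- g
        counts <- c(counts, 1L)
      }
    }
    for (k in seq_along(reps)) {
      rows[[length(rows) + 1L]] <-
        data.frame(class = sprintf("nontree:%d", k), count = counts[k],
                   representative = reps[[k]]$accession,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Exact isomorphism of two glycan graphs (VF2), optionally label-aware.
graphs_isomorphic <- function(g1, g2, use_labels = FALSE) {
  if (n_vertices(g1) != n_vertices(g2) || n_edges(g1) != n_edges(g2))
    return(FALSE)
  if (!use_labels)
    return(igraph::isomorphic(g1$graph, g2$graph, method = "vf2"))
  l1 <- vertex_labels(g1)
  l2 <- vertex_labels(g2)
  if (is.null(l1)) l1 <- rep(NA_character_, n_vertices(g1))
  if (is.null(l2)) l2 <- rep(NA_character_, n_vertices(g2))
  lv <- unique(c(l1, l2))
  igraph::isomorphic(g1$graph, g2$graph, method = "vf2",
                     vertex.color1 = match(unname(l1), lv),
                     vertex.color2 = match(unname(l2), lv))
}

# Code key of a Glycan Space bucket: dimension-equivalence class + diameter.
space_code_key <- function(fd) {
  paste0(dim_state_key(fd$state, fd$N, fd$D), "@", fd$D)
}

#' Build a code-then-isomorphism search index
#'
#' Indexes a dataset for membership queries: graphs are bucketed by their
#' Glycan Space code (dimension-equivalence class plus diameter); inside a
#' bucket, trees are keyed by AHU canonical form and the few non-tree
#' members kept for exact isomorphism comparison.
#'
#' @param graphs list of [glycan_graph] objects.
#' @param use_labels build a label-respecting index.
#' @param exact_cap passed to [clique_cover_number()].
#' @return an object of class `glycan_index`.
#' @export
build_search_index <- function(graphs, use_labels = FALSE,
                               exact_cap = 64L) {
  buckets <- list()
  for (g in graphs) {
    fd <- finite_dimension(g, exact_cap = exact_cap)
    key <- space_code_key(fd)
    if (is.null(buckets[[key]]))
      buckets[[key]] <- list(forms = list(), nontrees = list())
    cc <- canonical_code(g, use_labels)
    if (cc$tree) {
      buckets[[key]]$forms[[cc$form]] <-
        c(buckets[[key]]$forms[[cc$form]], g$accession)
    } else {
      buckets[[key]]$nontrees <- c(buckets[[key]]$nontrees, list(g))
    }
  }
  structure(list(buckets = buckets, use_labels = use_labels,
                 n_graphs = length(graphs)),
            class = "glycan_index")
}

#' @export
print.glycan_index <- function(x, ...) {
  sizes <- vapply(x$buckets, function(b)
    sum(lengths(b$forms)) + length(b$nontrees), integer(1))
  cat(sprintf(paste0("<glycan_index> %d graph(s) in %d code bucket(s);",
                     " largest bucket %d%s\n"),
              x$n_graphs, length(x$buckets),
              if (length(sizes)) max(sizes) else 0L,
              if (x$use_labels) "; labelled" else ""))
  invisible(x)
}

#' Database membership lookup
#'
#' Stepwise search mirroring the coding/decoding scheme: (1) encode the
#' query; if no indexed graph shares its code, it cannot be in the
#' database (`reason = "code_absent"`); (2) within the code bucket, look
#' for an isomorphic graph — AHU form equality for trees, VF2 for
#' non-trees; none found means `reason = "no_isomorph"`; (3) a match
#' returns the accessions of the isomorphic entries.
#'
#' @param index a [build_search_index()] result.
#' @param query a [glycan_graph].
#' @param use_labels label-respecting comparison; defaults to how the
#'   index was built (a labelled query against an unlabelled index is an
#'   error).
#' @param exact_cap passed to [clique_cover_number()].
#' @return an object of class `db_verdict`: list with `present` (logical),
#'   `reason` (`NA`, `"code_absent"` or `"no_isomorph"`), `accessions` and
#'   `code_key`.
#' @export
db_lookup <- function(index, query, use_labels = index$use_labels,
                      exact_cap = 64L) {
  stopifnot(inherits(index, "glycan_index"))
  if (use_labels && !index$use_labels)
    stop("index was built without labels", call. = FALSE)
  fd <- finite_dimension(query, exact_cap = exact_cap)
  key <- space_code_key(fd)
  verdict <- function(present, reason, accessions)
    structure(list(present = present, reason = reason,
                   accessions = accessions, code_key = key),
              class = "db_verdict")
  bucket <- index$buckets[[key]]
  if (is.null(bucket))
    return(verdict(FALSE, "code_absent", character(0)))
  cc <- canonical_code(query, use_labels)
  if (cc$tree) {
    hit <- bucket$forms[[cc$form]]
    if (is.null(hit)) return(verdict(FALSE, "no_isomorph", character(0)))
    return(verdict(TRUE, NA_character_, hit))
  }
  hits <- character(0)
  for (g in bucket$nontrees) {
    if (graphs_isomorphic(g, query, use_labels))
      hits <- c(hits, g$accession)
  }
  if (length(hits)) verdict(TRUE, NA_character_, hits)
  else verdict(FALSE, "no_isomorph", character(0))
}

#' @export
print.db_verdict <- function(x, ...) {
  if (x$present)
    cat(sprintf("<db_verdict> PRESENT: %s\n",
                paste(x$accessions, collapse = ", ")))
  else
    cat(sprintf("<db_verdict> NOT_PRESENT (%s)\n", x$reason))
  invisible(x)
}

#' Serialize a search index to JSON, and read it back
#'
#' The index is written as plain JSON: per code bucket, the map from AHU
#' form to accession list, plus edge lists for the non-tree members.
#'
#' @param index a [build_search_index()] result.
#' @param path output (input) file.
#' @return `write_search_index()` invisibly returns `path`;
#'   `read_search_index()` returns a `glycan_index`.
#' @export
write_search_index <- function(index, path) {
  ser <- list(
    use_labels = index$use_labels,
    n_graphs = index$n_graphs,
    buckets = lapply(index$buckets, function(b) {
      list(forms = b$forms,
           nontrees = lapply(b$nontrees, function(g) {
             et <- edge_table(g)
             list(accession = g$accession,
                  edges = apply(et, 1L, paste, collapse = " "),
                  labels = as.list(vertex_labels(g)))
           }))
    }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_search_index
#' @export
read_search_index <- function(path) {
  ser <- jsonlite::read_json(path)
  buckets <- lapply(ser$buckets, function(b) {
    forms <- lapply(b$forms, function(a) unlist(a, use.names = FALSE))
    nontrees <- lapply(b$nontrees, function(ng) {
      edges <- do.call(rbind, strsplit(unlist(ng$edges), " ", fixed = TRUE))
      labels <- if (length(ng$labels)) unlist(ng$labels) else NULL
      glycan_graph(edges, labels = labels, accession = ng$accession)
    })
    list(forms = forms, nontrees = nontrees)
  })
  structure(list(buckets = buckets,
                 use_labels = isTRUE(ser$use_labels),
                 n_graphs = as.integer(ser$n_graphs)),
            class = "glycan_index")
}
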