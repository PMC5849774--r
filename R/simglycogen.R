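#' Specification of the synthetic glycogen generator
#'
#' The generator emulates glycogen as a caterpillar-like branched tree: a
#' long spine path from which short pendant paths (branches) sprout at
#' roughly regular intervals.  The defaults are the study conditions:
#' spine lengths uniform on 1,900–70,900 nodes, branches of 20–23 nodes
#' sprouting every 12–19 nodes, and a hard cap of 120,000 nodes per
#' molecule.  All draws are uniform over the inclusive integer ranges (the
#' ranges are given; no other distribution is implied).
#'
#' @param spine_length integer interval (length-2 vector) of spine lengths
#'   in nodes.
#' @param branch_length integer interval of branch lengths in nodes.
#' @param sprout_gap integer interval of gaps, in spine nodes, between
#'   successive branch attachment points.
#' @param node_cap hard upper bound on the molecule's node count.
#' @param seed integer RNG seed (required; every draw is derived from it).
#' @return an object of class `glycogen_spec`.
#' @examples
#' glycogen_spec(seed = 42)
#' @export
glycogen_spec <- function(spine_length = c(1900L, 70900L),
                          branch_length = c(20L, 23L),
                          sprout_gap = c(12L, 19L),
                          node_cap = 120000L,
                          seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  chk <- function(x, nm) {
    x <- as.integer(x)
    if (length(x) != 2L || anyNA(x) || x[1L] < 1L || x[1L] > x[2L])
      stop("`", nm, "` must be an integer interval with 1 <= low <= high",
           call. = FALSE)
    x
  }
  spine_length <- chk(spine_length, "spine_length")
  branch_length <- chk(branch_length, "branch_length")
  sprout_gap <- chk(sprout_gap, "sprout_gap")
  node_cap <- as.integer(node_cap)
  if (is.na(node_cap) || node_cap < spine_length[1L])
    stop("`node_cap` must be at least the spine lower bound", call. = FALSE)
  structure(list(spine_length = spine_length,
                 branch_length = branch_length,
                 sprout_gap = sprout_gap,
                 node_cap = node_cap,
                 seed = as.integer(seed)),
            class = "glycogen_spec")
}

#' @export
print.glycogen_spec <- function(x, ...) {
  cat(sprintf(paste0("<glycogen_spec> spine %d-%d, branches %d-%d every",
                     " %d-%d nodes, cap %d, seed %d\n"),
              x$spine_length[1L], x$spine_length[2L],
              x$branch_length[1L], x$branch_length[2L],
              x$sprout_gap[1L], x$sprout_gap[2L], x$node_cap, x$seed))
  invisible(x)
}

runifint <- function(k, range) {
  if (range[1L] == range[2L]) rep(range[1L], k)
  else sample(seq.int(range[1L], range[2L]), k, replace = TRUE)
}

#' Simulate one glycogen-like molecule
#'
#' Builds a spine path whose length is drawn from the spec's spine range,
#' then walks the spine: after each gap drawn from the sprout range a
#' pendant path of length drawn from the branch range is attached.  When a
#' branch would push the node count past `node_cap`, that branch and all
#' later ones are dropped whole (a branch is never truncated).  The result
#' is a tree with maximum degree 3.
#'
#' @param spec a [glycogen_spec()].
#' @param seed optional integer overriding `spec$seed` (used by
#'   [simulate_cohort()] to give each molecule its own stream).
#' @param accession accession of the generated graph.
#' @return a [glycan_graph] (a tree) with attributes `"spine_length"` and
#'   `"n_branches"`.
#' @examples
#' g <- simulate_glycogen(glycogen_spec(spine_length = c(60, 80), seed = 1))
#' classify(g)
#' @export
simulate_glycogen <- function(spec, seed = spec$seed,
                              accession = sprintf("glycogen_s%d", seed)) {
  stopifnot(inherits(spec, "glycogen_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  S <- runifint(1L, spec$spine_length)
  S <- min(S, spec$node_cap)
  # attachment points: cumulative sums of gap draws along the spine
  n_gap <- ceiling(S / spec$sprout_gap[1L]) + 1L
  pos <- cumsum(runifint(n_gap, spec$sprout_gap))
  pos <- pos[pos <= S]
  blen <- if (length(pos)) runifint(length(pos), spec$branch_length)
          else integer(0)
  # atomically drop the first branch exceeding the cap, and all after it
  over <- which(S + cumsum(blen) > spec$node_cap)
  if (length(over)) {
    keep <- over[1L] - 1L
    pos <- pos[seq_len(keep)]
    blen <- blen[seq_len(keep)]
  }
  n <- S + sum(blen)
  from <- to <- integer(0)
  if (S > 1L) {
    from <- seq_len(S - 1L)
    to <- from + 1L
  }
  if (length(blen)) {
    ends <- S + cumsum(blen)
    starts <- ends - blen + 1L
    # attachment edges spine -> first branch node
    from <- c(from, pos)
    to <- c(to, starts)
    # chain edges inside each branch: consecutive new ids, minus boundaries
    if (any(blen > 1L)) {
      ids <- seq.int(S + 1L, n)
      chain_from <- ids[-length(ids)]
      chain_to <- ids[-1L]
      keep <- !(chain_from %in% ends)
      from <- c(from, chain_from[keep])
      to <- c(to, chain_to[keep])
    }
  }
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  ig <- igraph::add_edges(ig, rbind(from, to))
  g <- new_glycan_graph(ig, accession)
  attr(g, "spine_length") <- S
  attr(g, "n_branches") <- length(blen)
  g
}

#' Simulate a cohort of glycogen molecules
#'
#' Generates `count` independent molecules (each with its own seed, drawn
#' once from the cohort seed via `sample.int`), computes every finite
#' dimension through the tree route, and summarises the cohort as
#' min / 1st quartile / median / mean / 3rd quartile / max of `dim_f`.
#'
#' @param spec a [glycogen_spec()]; `spec$seed` seeds the whole cohort.
#' @param count number of molecules, integer `>= 1`.
#' @param keep_graphs keep the generated [glycan_graph] objects in the
#'   result (default `TRUE`; set to `FALSE` to save memory on very large
#'   cohorts).
#' @return an object of class `glycogen_cohort`: a list with `graphs`
#'   (possibly `NULL`), `dims` (data frame `accession,n,N,D,dim`),
#'   `summary` (named numeric vector) and `spec`.
#' @examples
#' co <- simulate_cohort(glycogen_spec(spine_length = c(60, 120), seed = 7),
#'                       count = 5)
#' co$summary
#' @export
simulate_cohort <- function(spec, count, keep_graphs = TRUE) {
  stopifnot(inherits(spec, "glycogen_spec"))
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop("need count >= 1", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, count)
  graphs <- if (keep_graphs) vector("list", count) else NULL
  rows <- vector("list", count)
  for (i in seq_len(count)) {
    g <- simulate_glycogen(spec, seed = seeds[i],
                           accession = sprintf("glycogen_%04d", i))
    fd <- finite_dimension(g)
    rows[[i]] <- data.frame(accession = fd$accession, n = fd$n,
                            N = fd$N, D = fd$D, dim = fd$value,
                            stringsAsFactors = FALSE)
    if (keep_graphs) graphs[[i]] <- g
  }
  dims <- do.call(rbind, rows)
  s <- c(min = min(dims$dim),
         `1st Qu.` = unname(quantile(dims$dim, 0.25)),
         median = stats::median(dims$dim),
         mean = mean(dims$dim),
         `3rd Qu.` = unname(quantile(dims$dim, 0.75)),
         max = max(dims$dim))
  structure(list(graphs = graphs, dims = dims, summary = s, spec = spec),
            class = "glycogen_cohort")
}

#' @export
print.glycogen_cohort <- function(x, ...) {
  cat(sprintf("<glycogen_cohort> %d molecule(s), %d-%d nodes\n",
              nrow(x$dims), min(x$dims$n), max(x$dims$n)))
  print(round(x$summary, 4))
  invisible(x)
}
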