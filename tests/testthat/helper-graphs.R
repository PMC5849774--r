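# Graph makers -------------------------------------------------------------

make_path <- function(n, prefix = "v") {
  if (n == 1L) return(glycan_graph(vertices = paste0(prefix, 1L)))
  glycan_graph(cbind(paste0(prefix, 1:(n - 1)), paste0(prefix, 2:n)))
}

make_cycle <- function(n) {
  glycan_graph(cbind(paste0("v", 1:n), paste0("v", c(2:n, 1))))
}

make_star <- function(n) {
  glycan_graph(cbind("hub", paste0("leaf", 1:(n - 1))))
}

make_complete <- function(n) {
  glycan_graph(t(combn(paste0("v", 1:n), 2)))
}

# t triangles sharing one hub (friendship/windmill graph), diameter 2
make_friendship <- function(t) {
  e <- NULL
  for (i in 1:t)
    e <- rbind(e, c("hub", paste0("a", i)), c("hub", paste0("b", i)),
               c(paste0("a", i), paste0("b", i)))
  glycan_graph(e)
}

# the 12-vertex caterpillar of the worked example: path v0..v10 + leaf on v2
make_caterpillar12 <- function() {
  glycan_graph(rbind(cbind(paste0("v", 0:9), paste0("v", 1:10)),
                     c("v2", "leaf")))
}

# Decode a Pruefer sequence over 1..n (n >= 2) to a tree edge matrix.
prufer_tree <- function(seq, n) {
  if (n == 2L) return(cbind("t1", "t2"))
  deg <- rep(1L, n)
  for (s in seq) deg[s] <- deg[s] + 1L
  edges <- matrix("", n - 1L, 2L)
  k <- 1L
  for (s in seq) {
    leaf <- which(deg == 1L)[1L]
    edges[k, ] <- c(paste0("t", leaf), paste0("t", s))
    k <- k + 1L
    deg[leaf] <- deg[leaf] - 1L
    deg[s] <- deg[s] - 1L
  }
  last <- which(deg == 1L)
  edges[k, ] <- paste0("t", last)
  edges
}

random_tree <- function(n) {
  if (n <= 2L) return(make_path(n))
  glycan_graph(prufer_tree(sample.int(n, n - 2L, replace = TRUE), n))
}

# random connected graph: random tree plus extra random edges
random_connected_graph <- function(n, extra = 2L) {
  g <- random_tree(n)
  if (n < 3L) return(g)
  et <- edge_table(g)
  ids <- vertex_ids(g)
  have <- paste(pmin(et[, 1], et[, 2]), pmax(et[, 1], et[, 2]))
  all_pairs <- t(combn(ids, 2))
  keys <- paste(pmin(all_pairs[, 1], all_pairs[, 2]),
                pmax(all_pairs[, 1], all_pairs[, 2]))
  free <- which(!keys %in% have)
  if (length(free) && extra > 0L) {
    add <- free[sample.int(length(free), min(extra, length(free)))]
    et <- rbind(et, all_pairs[add, , drop = FALSE])
  }
  glycan_graph(et)
}

# random connected triangle-free graph: tree plus edges that close no 3-cycle
random_triangle_free <- function(n, extra = 2L) {
  g <- random_tree(n)
  if (n < 4L) return(g)
  et <- edge_table(g)
  ids <- vertex_ids(g)
  adj <- lapply(ids, function(v)
    c(et[et[, 1] == v, 2], et[et[, 2] == v, 1]))
  names(adj) <- ids
  added <- 0L
  for (try in seq_len(20L * extra)) {
    uv <- sample(ids, 2L)
    u <- uv[1L]; v <- uv[2L]
    if (v %in% adj[[u]]) next
    if (length(intersect(adj[[u]], adj[[v]]))) next  # would close a triangle
    et <- rbind(et, c(u, v))
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
    added <- added + 1L
    if (added >= extra) break
  }
  glycan_graph(et)
}

random_relabel <- function(g) {
  ids <- vertex_ids(g)
  map <- paste0("w", sample(seq_along(ids)))
  names(map) <- ids
  relabel(g, map)
}

# Oracles ------------------------------------------------------------------

adj_bitmask <- function(g) {
  n <- n_vertices(g)
  el <- edge_table(g)
  ids <- vertex_ids(g)
  adj <- integer(n)
  for (k in seq_len(nrow(el))) {
    i <- match(el[k, 1], ids)
    j <- match(el[k, 2], ids)
    adj[i] <- bitwOr(adj[i], bitwShiftL(1L, j - 1L))
    adj[j] <- bitwOr(adj[j], bitwShiftL(1L, i - 1L))
  }
  adj
}

# independence number by subset DP over bitmasks (n <= ~20)
brute_alpha <- function(g) {
  n <- n_vertices(g)
  adj <- adj_bitmask(g)
  best <- 0L
  sz <- integer(bitwShiftL(1L, n))  # sz[S+1] = popcount, indep only
  ok <- logical(bitwShiftL(1L, n))
  ok[1L] <- TRUE
  for (S in seq_len(bitwShiftL(1L, n) - 1L)) {
    low <- bitwAnd(S, -S)
    v <- as.integer(log2(low)) + 1L
    rest <- S - low
    if (ok[rest + 1L] && bitwAnd(adj[v], rest) == 0L) {
      ok[S + 1L] <- TRUE
      sz[S + 1L] <- sz[rest + 1L] + 1L
      if (sz[S + 1L] > best) best <- sz[S + 1L]
    }
  }
  best
}

# minimum clique cover by subset DP (n <= ~10)
brute_clique_cover <- function(g) {
  n <- n_vertices(g)
  adj <- adj_bitmask(g)
  full <- bitwShiftL(1L, n) - 1L
  is_clq <- logical(full + 1L)
  is_clq[1L] <- TRUE
  for (S in seq_len(full)) {
    low <- bitwAnd(S, -S)
    v <- as.integer(log2(low)) + 1L
    rest <- S - low
    is_clq[S + 1L] <- is_clq[rest + 1L] &&
      bitwAnd(adj[v], rest) == rest
  }
  f <- rep(n + 1L, full + 1L)
  f[1L] <- 0L
  for (S in seq_len(full)) {
    low <- bitwAnd(S, -S)
    sub <- S
    repeat {
      if (bitwAnd(sub, low) != 0L && is_clq[sub + 1L]) {
        cand <- f[S - sub + 1L] + 1L
        if (cand < f[S + 1L]) f[S + 1L] <- cand
      }
      if (sub == 0L) break
      sub <- bitwAnd(sub - 1L, S)
    }
  }
  f[full + 1L]
}

# maximum matching by recursion over edges (small graphs)
brute_matching <- function(g) {
  el <- edge_table(g)
  ids <- vertex_ids(g)
  m <- nrow(el)
  rec <- function(k, used) {
    if (k > m) return(0L)
    best <- rec(k + 1L, used)
    u <- el[k, 1]; v <- el[k, 2]
    if (!(u %in% used) && !(v %in% used))
      best <- max(best, 1L + rec(k + 1L, c(used, u, v)))
    best
  }
  rec(1L, character(0))
}

# graph isomorphism by exhaustive permutation (n <= 8), label-blind
brute_isomorphic <- function(g1, g2) {
  n <- n_vertices(g1)
  if (n != n_vertices(g2) || n_edges(g1) != n_edges(g2)) return(FALSE)
  ids1 <- vertex_ids(g1)
  ids2 <- vertex_ids(g2)
  e1 <- edge_table(g1)
  a <- match(e1[, 1], ids1)
  b <- match(e1[, 2], ids1)
  e2 <- edge_table(g2)
  key2 <- sort(paste(pmin(match(e2[, 1], ids2), match(e2[, 2], ids2)),
                     pmax(match(e2[, 1], ids2), match(e2[, 2], ids2))))
  perms <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  P <- perms(seq_len(n))
  for (r in seq_len(nrow(P))) {
    pa <- P[r, a]
    pb <- P[r, b]
    if (identical(sort(paste(pmin(pa, pb), pmax(pa, pb))), key2))
      return(TRUE)
  }
  FALSE
}

# all-pairs shortest path diameter via repeated BFS in plain R
brute_diameter <- function(g) {
  n <- n_vertices(g)
  if (n == 1L) return(0L)
  adj <- adj_bitmask(g)
  best <- 0L
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    dist[s] <- 0L
    q <- s
    while (length(q)) {
      v <- q[1L]
      q <- q[-1L]
      nb <- which(bitwAnd(adj[v], bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
      for (w in nb) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          q <- c(q, w)
        }
      }
    }
    best <- max(best, max(dist))
  }
  best
}
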