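#' Finite dimension value from an exact (N, D) pair
#'
#' Wraps the dimension formula `ln(N)/ln(D)` applied to a clique cover
#' number `N` and a diameter `D`.  The state is `"zero"` when the pair is
#' that of a single vertex (N = 1, D = 0), `"infinite"` when the diameter is
#' at most 1 on two or more vertices (complete graphs), and `"finite"`
#' otherwise, in which case the real value is defined and positive.
#'
#' @param N clique cover number, positive integer.
#' @param D diameter, non-negative integer.
#' @return an object of class `glycan_dim` with fields `state`
#'   (`"zero"`, `"finite"` or `"infinite"`), `N`, `D` and `value` (`NA`
#'   unless finite).
#' @examples
#' dim_value(15, 10)  # ln(15)/ln(10) = 1.17609
#' @export
dim_value <- function(N, D) {
  N <- as.integer(N)
  D <- as.integer(D)
  if (is.na(N) || is.na(D) || N < 1L || D < 0L)
    stop("need N >= 1 and D >= 0", call. = FALSE)
  if (D == 0L) {
    if (N != 1L) stop("diameter 0 forces N = 1", call. = FALSE)
    state <- "zero"
    value <- NA_real_
  } else if (D == 1L) {
    if (N != 1L) stop("diameter 1 forces N = 1 (complete graph)",
                      call. = FALSE)
    state <- "infinite"
    value <- NA_real_
  } else {
    if (N < 2L)
      stop("a graph of diameter >= 2 cannot be covered by one clique",
           call. = FALSE)
    state <- "finite"
    value <- log(N) / log(D)
  }
  structure(list(state = state, N = N, D = D, value = value),
            class = "glycan_dim")
}

#' @export
print.glycan_dim <- function(x, ...) {
  cat(switch(x$state,
             zero = "<glycan_dim> 0 (single vertex)\n",
             infinite = sprintf("<glycan_dim> Inf (N = %d, D = %d)\n",
                                x$N, x$D),
             finite = sprintf("<glycan_dim> %.5f = ln(%d)/ln(%d)\n",
                              x$value, x$N, x$D)))
  invisible(x)
}

#' Finite dimension of a glycan graph
#'
#' Computes `dim_f = ln(N)/ln(D)` with `N` the clique cover number (see
#' [clique_cover_number()] for the route dispatch) and `D` the diameter.
#' A single vertex has dimension zero; a complete graph on two or more
#' vertices (diameter at most 1) has infinite dimension; every other graph
#' gets a positive real value.
#'
#' @param g a [glycan_graph].
#' @param exact_cap passed to [clique_cover_number()].
#' @return an object of class `glycan_findim`: a [dim_value()] plus the
#'   accession, vertex count, graph class, cover route and (when the
#'   matching route ran) the maximum matching size.
#' @examples
#' cat9 <- glycan_graph(cbind(paste0("v", 0:8), paste0("v", 1:9)))
#' finite_dimension(cat9)
#' @export
finite_dimension <- function(g, exact_cap = 64L) {
  D <- graph_diameter(g)
  n <- n_vertices(g)
  N <- if (D <= 1L) 1L else clique_cover_number(g, exact_cap = exact_cap)
  dv <- dim_value(N, D)
  structure(c(unclass(dv),
              list(accession = g$accession,
                   n = n,
                   class = classify(g),
                   route = if (D <= 1L) {
                     if (n == 1L) "single_vertex" else "complete"
                   } else attr(N, "route"),
                   matching_size =
                     if (!is.null(attr(N, "matching_size")))
                       attr(N, "matching_size") else NA_integer_)),
            class = c("glycan_findim", "glycan_dim"))
}

#' @export
print.glycan_findim <- function(x, ...) {
  cat(sprintf("<glycan_findim> %s (n = %d, %s)\n",
              if (nzchar(x$accession)) x$accession else "<unnamed>",
              x$n, x$class))
  cat(switch(x$state,
             zero = "  dim_f = 0 (single vertex)\n",
             infinite = sprintf("  dim_f = Inf (D = %d)\n", x$D),
             finite = sprintf("  dim_f = %.5f  (N = %d, D = %d, via %s)\n",
                              x$value, x$N, x$D, x$route)))
  invisible(x)
}

#' @export
as.data.frame.glycan_findim <- function(x, ...) {
  data.frame(accession = x$accession, n = x$n, class = x$class,
             N = x$N, D = x$D,
             dim = if (x$state == "finite") x$value else NA_real_,
             state = x$state, stringsAsFactors = FALSE)
}

#' Closed-form finite dimension of standard graph families
#'
#' Closed forms, all derivable from the cover/diameter definition:
#' paths `P_n` (n >= 3) have `ln(ceiling(n/2))/ln(n-1)`, always below 1
#' except `P_3` where it equals 1; cycles `C_n` (n >= 4) have
#' `ln(ceiling(n/2))/ln(floor(n/2))`, equal to 1 for even n and above 1 for
#' odd n; stars `St_n` (n >= 3) have `ln(n-1)/ln(2)`; complete graphs are
#' infinite.  `P_1` is the single vertex (zero), `P_2 = K_2` and
#' `C_3 = K_3` are infinite.
#'
#' @param family one of `"path"`, `"cycle"`, `"star"`, `"complete"`.
#' @param n number of vertices: `n >= 1` for paths, `n >= 3` for cycles and
#'   stars, `n >= 2` for complete graphs.
#' @return a [dim_value()] object.
#' @examples
#' closed_form_dimension("cycle", 5)  # ln(3)/ln(2) = 1.58496
#' @export
closed_form_dimension <- function(family = c("path", "cycle", "star",
                                             "complete"), n) {
  family <- match.arg(family)
  n <- as.integer(n)
  switch(family,
    path = {
      if (n < 1L) stop("path needs n >= 1", call. = FALSE)
      if (n == 1L) dim_value(1L, 0L)
      else if (n == 2L) dim_value(1L, 1L)
      else dim_value(ceiling(n / 2), n - 1L)
    },
    cycle = {
      if (n < 3L) stop("cycle needs n >= 3", call. = FALSE)
      if (n == 3L) dim_value(1L, 1L)
      else dim_value(ceiling(n / 2), floor(n / 2))
    },
    star = {
      if (n < 3L) stop("star needs n >= 3", call. = FALSE)
      dim_value(n - 1L, 2L)
    },
    complete = {
      if (n < 2L) stop("complete graph needs n >= 2", call. = FALSE)
      dim_value(1L, 1L)
    })
}

#' Exact equality of two finite dimensions
#'
#' Compares states; for two finite values compares the cross products
#' `ln(N1)*ln(D2)` and `ln(N2)*ln(D1)` to within `1e-9`, which avoids the
#' division and treats e.g. (N=4, D=2) and (N=9, D=3) as equal (both 2).
#'
#' @param d1,d2 [dim_value()] (or [finite_dimension()]) objects.
#' @return logical.
#' @export
dims_equal <- function(d1, d2) {
  if (d1$state != d2$state) return(FALSE)
  if (d1$state != "finite") return(TRUE)
  abs(log(d1$N) * log(d2$D) - log(d2$N) * log(d1$D)) <= 1e-9
}

# Canonical grouping key for a finite (N, D) pair: two pairs share a key
# iff their log-ratios coincide.  Decompose N = a^p and D = b^q with a, b
# minimal (not proper powers).  If a == b the value is the rational p/q,
# keyed by the reduced fraction alone; otherwise the key is
# (a, b, p/gcd, q/gcd).
dim_pair_key <- function(N, D) {
  root <- function(x) {
    for (k in rev(seq_len(floor(log2(x) + 1e-9)))) {
      b <- round(x^(1 / k))
      for (bb in c(b - 1, b, b + 1)) {
        if (bb >= 2 && bb^k == x) return(c(bb, k))
      }
    }
    c(x, 1L)
  }
  rn <- as.integer(root(N))
  rd <- as.integer(root(D))
  g <- gcd_int(rn[2L], rd[2L])
  p <- rn[2L] %/% g
  q <- rd[2L] %/% g
  if (rn[1L] == rd[1L]) sprintf("rat:%d/%d", p, q)
  else sprintf("irr:%d^%d/%d^%d", rn[1L], p, rd[1L], q)
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

# Key for any dimension state (used by histograms, indexes, exclusivity).
dim_state_key <- function(state, N, D) {
  switch(state,
         zero = "zero",
         infinite = "inf",
         finite = dim_pair_key(N, D))
}
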