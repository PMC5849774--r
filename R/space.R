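#' Encode a glycan graph as a point of Glycan Space
#'
#' Glycan Space is the image of the lattice map
#' `phi(n, m) = (ln(n)/ln(m), m)` over integers `n, m >= 2`; every graph is
#' coded by the point `(dim_f, diameter)`.  `encode()` computes the code of
#' one graph, keeping the exact (N, D) provenance; [glycan_space()] encodes
#' a collection into the tabular form the rest of the package consumes.
#'
#' @param g a [glycan_graph].
#' @param exact_cap passed to [clique_cover_number()].
#' @return an object of class `space_code`: a [finite_dimension()] result
#'   with a `diameter` field (equal to `D`).
#' @examples
#' encode(glycan_graph(cbind(c("a", "b"), c("b", "c"))))  # (1.0, 2)
#' @export
encode <- function(g, exact_cap = 64L) {
  fd <- finite_dimension(g, exact_cap = exact_cap)
  fd$diameter <- fd$D
  class(fd) <- c("space_code", class(fd))
  fd
}

#' @export
print.space_code <- function(x, ...) {
  cat(sprintf("<space_code> %s: ",
              if (nzchar(x$accession)) x$accession else "<unnamed>"))
  cat(switch(x$state,
             zero = "excluded (single vertex, dim 0)\n",
             infinite = sprintf("excluded (dim Inf, D = %d)\n", x$D),
             finite = sprintf("(%.5f, %d)  [N = %d]\n",
                              x$value, x$diameter, x$N)))
  invisible(x)
}

#' Encode a collection of glycan graphs
#'
#' @param graphs a list of [glycan_graph] objects (or a single one).
#' @param exact_cap passed to [clique_cover_number()].
#' @return a data frame with columns `accession`, `n`, `class`, `N`, `D`,
#'   `dim`, `state` and `diameter` — one row per graph.  Rows with state
#'   `"zero"` or `"infinite"` carry `NA` in `dim`.
#' @export
glycan_space <- function(graphs, exact_cap = 64L) {
  if (inherits(graphs, "glycan_graph")) graphs <- list(graphs)
  rows <- lapply(graphs, function(g)
    as.data.frame(finite_dimension(g, exact_cap = exact_cap)))
  out <- do.call(rbind, rows)
  out$diameter <- out$D
  rownames(out) <- NULL
  out
}

#' Theoretical left endpoint of a triangle-free D-line
#'
#' Restricted to triangle-free graphs, the leftmost point of the horizontal
#' line of Glycan Space at diameter `D` is the code of the path `P_{D+1}`:
#' `ln(ceiling((D+1)/2))/ln(D)`.  For graphs that may contain triangles
#' (and `D >= 3`) the left endpoint is the constant `ln(2)/ln(3)`.
#'
#' @param D diameter, integer `>= 2`.
#' @return the dimension of `P_{D+1}`, a positive real.
#' @examples
#' triangle_free_LD(10)  # 0.77815
#' @export
triangle_free_LD <- function(D) {
  D <- as.integer(D)
  if (is.na(D) || D < 2L) stop("need D >= 2", call. = FALSE)
  log(ceiling((D + 1) / 2)) / log(D)
}

#' Diameter threshold forcing the dimension of a ramified tree above b
#'
#' A ramified (branched) tree with diameter `D` satisfies `D + 2 <= n` and,
#' being triangle-free, `n <= 2N`; so `dim_f <= b` (i.e. `N <= D^b`) forces
#' `D + 2 <= 2 D^b`.  Conversely `D + 2 > 2 D^b` implies `dim_f > b`.
#' This function returns the smallest integer `D0 >= 4` such that the
#' strict inequality holds for every `D >= D0`.  The gap function
#' `D + 2 - 2 D^b` has a single interior minimum at `D = (2b)^{1/(1-b)}`,
#' so it suffices to scan past that minimum for the first sign change.
#'
#' @param b target dimension bound, real in (0, 1).
#' @param scan_limit upper limit of the integer scan (default `1e7`);
#'   exceeded limit is an error.
#' @return the threshold diameter, an integer.
#' @examples
#' ramified_lower_threshold(0.8)  # 20
#' @export
ramified_lower_threshold <- function(b, scan_limit = 1e7) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0 || b >= 1)
    stop("need 0 < b < 1", call. = FALSE)
  gap <- function(D) D + 2 - 2 * D^b
  dstar <- (2 * b)^(1 / (1 - b))
  if (gap(dstar) > 0) return(4L)  # positive at the minimum: holds everywhere
  D <- max(4, ceiling(dstar))
  while (gap(D) <= 0) {
    D <- D + 1
    if (D > scan_limit)
      stop("threshold scan exceeded scan_limit = ", scan_limit,
           call. = FALSE)
  }
  as.integer(D)
}

#' Largest vertex count keeping the dimension below a at diameter D
#'
#' The bound `N <= n - 1` holds for every graph on two or more vertices, so
#' `dim_f >= a` (i.e. `D^a <= N`) requires `D^a <= n - 1`.  Conversely any
#' graph of diameter `D` with at most the returned number of vertices has
#' `dim_f < a`.  The returned value is the largest integer `n` with
#' `n - 1 < D^a`.
#'
#' @param D diameter, integer `>= 2`.
#' @param a target dimension, real `> 1`.
#' @return an integer vertex count.
#' @examples
#' max_nodes_at(10, 1.5)  # 32
#' @export
max_nodes_at <- function(D, a) {
  D <- as.integer(D)
  if (is.na(D) || D < 2L) stop("need D >= 2", call. = FALSE)
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 1)
    stop("need a > 1", call. = FALSE)
  x <- D^a
  n <- floor(x) + 1
  while (n - 1 >= x) n <- n - 1
  as.integer(n)
}

#' Necessary realizability condition for a Glycan Space lattice point
#'
#' A graph with clique cover number `N` and diameter `D` must cover a
#' diametral path of `D + 1` vertices, and a clique contains at most two of
#' its vertices, hence `N >= ceiling((D + 1)/2)`.  A pair failing this
#' cannot be the code of any graph — e.g. `phi(2, 10)` is not realizable.
#' The condition is necessary, not sufficient: `TRUE` means only that the
#' pair is not excluded by this argument.
#'
#' @param N candidate clique cover number, integer `>= 1`.
#' @param D candidate diameter, integer `>= 0`.
#' @return logical.
#' @examples
#' realizable_necessary(2, 10)  # FALSE
#' realizable_necessary(6, 10)  # TRUE (P_11)
#' @export
realizable_necessary <- function(N, D) {
  N <- as.integer(N)
  D <- as.integer(D)
  if (is.na(N) || is.na(D) || N < 1L || D < 0L)
    stop("need N >= 1 and D >= 0", call. = FALSE)
  N >= ceiling((D + 1) / 2)
}

#' 2D histogram of Glycan Space codes
#'
#' Counts codes per cell.  In `"exact"` mode the cells are the exact
#' (N, D)-equivalence classes (two codes share a cell iff [dims_equal()]
#' holds and the diameters agree); in `"uniform"` mode the dimension axis is
#' cut into bins of width `binwidth`.  Codes with state `"zero"` or
#' `"infinite"` are excluded; their count is attached as attribute
#' `"excluded"` and a warning is raised when it is non-zero.
#'
#' @param codes a data frame from [glycan_space()] (columns `N`, `D`,
#'   `dim`, `state`, `diameter`).
#' @param mode `"exact"` (default) or `"uniform"`.
#' @param binwidth dimension bin width for `"uniform"` mode.
#' @return a data frame of class `glycan_hist2d` with columns `dim`
#'   (representative or bin-midpoint value), `diameter` and `count`.
#' @export
histogram2d <- function(codes, mode = c("exact", "uniform"),
                        binwidth = 0.05) {
  mode <- match.arg(mode)
  fin <- codes[codes$state == "finite", , drop = FALSE]
  excluded <- nrow(codes) - nrow(fin)
  if (excluded > 0L)
    warning(excluded, " code(s) with zero/infinite dimension excluded")
  if (nrow(fin) == 0L) {
    out <- data.frame(dim = numeric(0), diameter = integer(0),
                      count = integer(0))
  } else if (mode == "exact") {
    key <- paste(mapply(dim_pair_key, fin$N, fin$D), fin$diameter)
    agg <- tapply(seq_len(nrow(fin)), key, identity)
    out <- do.call(rbind, lapply(agg, function(idx)
      data.frame(dim = fin$dim[idx[1L]], diameter = fin$diameter[idx[1L]],
                 count = length(idx))))
  } else {
    bin <- floor(fin$dim / binwidth)
    key <- paste(bin, fin$diameter)
    agg <- tapply(seq_len(nrow(fin)), key, identity)
    out <- do.call(rbind, lapply(agg, function(idx)
      data.frame(dim = (bin[idx[1L]] + 0.5) * binwidth,
                 diameter = fin$diameter[idx[1L]],
                 count = length(idx))))
  }
  out <- out[order(out$diameter, out$dim), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, excluded = excluded, mode = mode,
            class = c("glycan_hist2d", "data.frame"))
}

#' Plot a Glycan Space histogram
#'
#' Renders the (dimension, diameter) cells as filled points scaled and
#' coloured by count — a static base-graphics export of the 2D histogram.
#'
#' @param x a [histogram2d()] result.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.glycan_hist2d <- function(x, ...) {
  if (nrow(x) == 0L) {
    graphics::plot.new()
    return(invisible(x))
  }
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  cl <- pal[pmax(1L, ceiling(64 * x$count / max(x$count)))]
  graphics::plot(x$dim, x$diameter, pch = 16, col = cl,
                 cex = 0.5 + 1.5 * sqrt(x$count / max(x$count)),
                 xlab = "finite dimension", ylab = "diameter", ...)
  invisible(x)
}

#' Endpoints of a D-line
#'
#' Reports, for the horizontal line of Glycan Space at diameter `D`, the
#' theoretical left endpoints (triangle-free: the code of `P_{D+1}`; with
#' triangles allowed: the constant `ln(2)/ln(3)`) together with the
#' empirical leftmost/rightmost finite dimensions among the supplied codes
#' at that diameter (`NA` when no code lies on the line).
#'
#' @param codes a data frame from [glycan_space()].
#' @param D diameter of the line, integer `>= 2`.
#' @return an object of class `dline_report`: a list with fields `D`,
#'   `left_theoretical`, `left_with_triangles`, `empirical_left`,
#'   `empirical_right` and `n_on_line`.
#' @export
dline_endpoints <- function(codes, D) {
  D <- as.integer(D)
  if (is.na(D) || D < 2L) stop("need D >= 2", call. = FALSE)
  on_line <- codes[codes$state == "finite" & codes$diameter == D, ,
                   drop = FALSE]
  structure(list(
    D = D,
    left_theoretical = triangle_free_LD(D),
    left_with_triangles = log(2) / log(3),
    empirical_left = if (nrow(on_line)) min(on_line$dim) else NA_real_,
    empirical_right = if (nrow(on_line)) max(on_line$dim) else NA_real_,
    n_on_line = nrow(on_line)), class = "dline_report")
}

#' @export
print.dline_report <- function(x, ...) {
  cat(sprintf("<dline_report> D = %d\n", x$D))
  cat(sprintf("  L_D (triangle-free) = %.5f;  L_D (with triangles) = %.5f\n",
              x$left_theoretical, x$left_with_triangles))
  if (x$n_on_line > 0L)
    cat(sprintf("  empirical: [%.5f, %.5f] over %d code(s)\n",
                x$empirical_left, x$empirical_right, x$n_on_line))
  else cat("  empirical: no codes on this line\n")
  invisible(x)
}

#' Universal dimension bounds of a dataset
#'
#' With `a` and `b` the smallest and largest finite dimension over a
#' dataset, every member satisfies `D^a <= N <= D^b`; this is the exact
#' power-law restatement of `a <= dim_f <= b`.  The function computes the
#' empirical `a`, `b` and verifies the inequality row by row.
#'
#' @param codes a data frame from [glycan_space()].
#' @param tol numerical slack on the power inequalities.
#' @return a list with `a`, `b`, `n` (finite codes used) and `holds`
#'   (logical, `TRUE` when every member satisfies the bounds).
#' @export
universal_bounds <- function(codes, tol = 1e-9) {
  fin <- codes[codes$state == "finite", , drop = FALSE]
  if (nrow(fin) == 0L)
    return(list(a = NA_real_, b = NA_real_, n = 0L, holds = TRUE))
  a <- min(fin$dim)
  b <- max(fin$dim)
  # compare in log space: a*ln(D) <= ln(N) <= b*ln(D), stable for large D^b
  holds <- all(a * log(fin$D) <= log(fin$N) + tol) &&
    all(log(fin$N) <= b * log(fin$D) + tol)
  list(a = a, b = b, n = nrow(fin), holds = holds)
}
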