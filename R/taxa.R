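#' Read a taxonomy table
#'
#' Reads a two-column TSV `accession<TAB>domain`, the domain being one of
#' `EU` (Eukaryota), `BA` (Bacteria), `AR` (Archaea).  Accessions mapped to
#' more than one domain are not uniquely categorized and are removed before
#' any analysis; their count is attached as attribute `"dropped"`.
#'
#' @param path TSV file.
#' @return a data frame with columns `accession`, `domain`.
#' @export
read_taxonomy <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "",
                    comment.char = "#")
  if (ncol(tab) != 2L)
    stop("taxonomy file must have two tab-separated columns", call. = FALSE)
  names(tab) <- c("accession", "domain")
  taxon_records(tab)
}

#' @rdname read_taxonomy
#' @param records data frame with columns `accession` and `domain`
#'   (already in memory rather than on disk).
#' @export
taxon_records <- function(records) {
  records <- records[, c("accession", "domain")]
  if (!all(records$domain %in% c("EU", "BA", "AR")))
    stop("domain must be one of EU, BA, AR", call. = FALSE)
  records <- unique(records)
  multi <- unique(records$accession[duplicated(records$accession)])
  out <- records[!records$accession %in% multi, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, dropped = length(multi))
}

#' Cross-tabulate biological domain against graph class
#'
#' Builds the domain-by-structure contingency table: rows `EU`, `BA`, `AR`,
#' columns `B` (branched trees), `L` (linear trees) and `Cy` (graphs that
#' are or contain cycles), with row/column margins.  Glycans without a
#' (unique) taxonomy record are counted in an `uncategorized` row.
#'
#' @param records a [read_taxonomy()] / [taxon_records()] table.
#' @param codes a data frame from [glycan_space()] (needs `accession` and
#'   `class` columns).
#' @return an object of class `glycan_partition`: list with `table` (the
#'   3x3 matrix plus margins), `uncategorized` (per-structure counts) and
#'   `dropped` (non-uniquely categorized accessions removed upstream).
#' @export
partition_table <- function(records, codes) {
  cls3 <- c(branched_tree = "B", linear = "L",
            pure_cycle = "Cy", cyclic_branched = "Cy")[codes$class]
  dom <- records$domain[match(codes$accession, records$accession)]
  doms <- c("EU", "BA", "AR")
  strs <- c("B", "L", "Cy")
  tab <- matrix(0L, 3L, 3L, dimnames = list(doms, strs))
  known <- !is.na(dom)
  if (any(known)) {
    t0 <- table(factor(dom[known], doms), factor(cls3[known], strs))
    tab[] <- as.integer(t0)
  }
  tab <- cbind(tab, total = rowSums(tab))
  tab <- rbind(tab, total = colSums(tab))
  uncat <- table(factor(cls3[!known], strs))
  structure(list(table = tab,
                 uncategorized = as.integer(uncat),
                 dropped = attr(records, "dropped") %||% 0L),
            class = "glycan_partition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.glycan_partition <- function(x, ...) {
  cat("<glycan_partition> domain x structure\n")
  print(x$table)
  cat(sprintf("uncategorized: B=%d L=%d Cy=%d; dropped (multi-domain): %d\n",
              x$uncategorized[1L], x$uncategorized[2L],
              x$uncategorized[3L], x$dropped))
  invisible(x)
}

#' Dimension exclusivity between two sets of glycans
#'
#' A member of set A is *exclusive* iff no member of set B has an equal
#' finite dimension (equality in the exact sense of [dims_equal()]);
#' symmetrically for B; the remainder is shared.  The report carries both
#' the member counts and the counts of distinct dimension values exclusive
#' to each side or shared, plus the point sets of the two exclusive sides.
#' Codes with zero/infinite dimension are filtered out and counted.
#'
#' @param setA,setB data frames from [glycan_space()].
#' @return an object of class `dim_exclusivity`: list with
#'   `exclusive_A`, `exclusive_B`, `shared` (member counts),
#'   `values_A`, `values_B`, `values_shared` (distinct-value counts),
#'   `points_A`, `points_B` (the exclusive point sets) and
#'   `filtered` (non-finite codes removed).
#' @export
dim_exclusivity <- function(setA, setB) {
  finA <- setA[setA$state == "finite", , drop = FALSE]
  finB <- setB[setB$state == "finite", , drop = FALSE]
  filtered <- (nrow(setA) - nrow(finA)) + (nrow(setB) - nrow(finB))
  keyA <- if (nrow(finA)) mapply(dim_pair_key, finA$N, finA$D)
          else character(0)
  keyB <- if (nrow(finB)) mapply(dim_pair_key, finB$N, finB$D)
          else character(0)
  exclA <- !keyA %in% keyB
  exclB <- !keyB %in% keyA
  uA <- unique(keyA)
  uB <- unique(keyB)
  structure(list(
    exclusive_A = sum(exclA),
    exclusive_B = sum(exclB),
    shared = sum(!exclA) + sum(!exclB),
    values_A = sum(!uA %in% uB),
    values_B = sum(!uB %in% uA),
    values_shared = length(intersect(uA, uB)),
    points_A = finA[exclA, , drop = FALSE],
    points_B = finB[exclB, , drop = FALSE],
    filtered = filtered), class = "dim_exclusivity")
}

#' @export
print.dim_exclusivity <- function(x, ...) {
  cat("<dim_exclusivity>\n")
  cat(sprintf("  exclusive to A: %d glycan(s), %d distinct value(s)\n",
              x$exclusive_A, x$values_A))
  cat(sprintf("  exclusive to B: %d glycan(s), %d distinct value(s)\n",
              x$exclusive_B, x$values_B))
  cat(sprintf("  shared: %d glycan(s), %d distinct value(s)\n",
              x$shared, x$values_shared))
  if (x$filtered > 0L)
    cat(sprintf("  (%d non-finite code(s) filtered)\n", x$filtered))
  invisible(x)
}
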