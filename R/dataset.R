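#' Read a directory of glycan edge-list files
#'
#' A dataset is a directory holding one edge-list file per glycan
#' (`.tsv` or `.txt`; see [read_edge_list()] for the dialect).  An optional
#' labels directory provides `accession.labels.tsv` sidecar files
#' (`vertex<TAB>label`).
#'
#' @param dir directory of edge-list files.
#' @param labels_dir optional directory of label sidecars.
#' @param pattern file-name filter, default `"\\.(tsv|txt)$"`.
#' @return a list of [glycan_graph] objects, named by accession.
#' @export
read_glycan_dir <- function(dir, labels_dir = NULL,
                            pattern = "\\.(tsv|txt)$") {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0L)
    stop("no edge-list files in ", dir, call. = FALSE)
  graphs <- lapply(files, function(f) {
    acc <- sub("\\.[^.]*$", "", basename(f))
    lab <- NULL
    if (!is.null(labels_dir)) {
      lf <- file.path(labels_dir, paste0(acc, ".labels.tsv"))
      if (file.exists(lf)) lab <- read_vertex_labels(lf)
    }
    read_edge_list(f, labels = lab)
  })
  names(graphs) <- vapply(graphs, function(g) g$accession, character(1))
  graphs
}

#' Write batch result tables
#'
#' Thin CSV writers for the standard artifacts: the per-glycan dimension
#' table (`accession,n,class,N,D,dim,state`), the Glycan Space point set
#' (`accession,N,D,dim,diameter`), and the classification summary
#' (`accession,n_vertices,n_edges,class`).
#'
#' @param codes a data frame from [glycan_space()].
#' @param graphs a list of [glycan_graph] objects.
#' @param path output CSV file.
#' @return invisibly, `path`.
#' @export
write_dim_csv <- function(codes, path) {
  out <- codes[, c("accession", "n", "class", "N", "D", "dim", "state")]
  out$dim <- ifelse(is.na(out$dim), "", sprintf("%.5f", out$dim))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dim_csv
#' @export
write_points_csv <- function(codes, path) {
  fin <- codes[codes$state == "finite", , drop = FALSE]
  out <- fin[, c("accession", "N", "D", "dim", "diameter")]
  out$dim <- sprintf("%.5f", out$dim)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dim_csv
#' @export
write_class_csv <- function(graphs, path) {
  out <- data.frame(
    accession = vapply(graphs, function(g) g$accession, character(1)),
    n_vertices = vapply(graphs, n_vertices, integer(1)),
    n_edges = vapply(graphs, n_edges, integer(1)),
    class = vapply(graphs, classify, character(1)))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
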