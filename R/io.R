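# Delimited-text I/O for panels, connectivity matrices and expression tables.
# Region ids are 0-based in edge-list output; expression tables carry a
# header row of region ids and gene ids in the first column.

.read_delim_matrix <- function(path, header = FALSE, rownames_col = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = header, sep = sep, row.names = NULL,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (rownames_col) {
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
    m <- as.matrix(df)
    rownames(m) <- rn
  } else {
    m <- as.matrix(df)
    dimnames(m) <- NULL
  }
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  m
}

#' Read a matrix from delimited text
#'
#' @param path TSV (whitespace-delimited) or CSV file.
#' @param kind `"timeseries"` (returns a standardized [as_panel()]),
#'   `"connectivity"` (returns a symmetrized matrix; asymmetry beyond 1e-6
#'   relative is an error naming the worst entry), or `"expression"`
#'   (gene-by-region matrix; header row of region ids, gene ids in the first
#'   column).
#' @return a `ts_panel` or a numeric matrix, by `kind`.
#' @export
read_matrix <- function(path, kind = c("timeseries", "connectivity", "expression")) {
  kind <- match.arg(kind)
  if (kind == "expression") {
    return(.read_delim_matrix(path, header = TRUE, rownames_col = TRUE))
  }
  m <- .read_delim_matrix(path)
  if (kind == "timeseries") return(as_panel(m))
  if (nrow(m) != ncol(m)) stop("connectivity matrix in ", path, " is not square")
  scale <- max(abs(m), 1e-300)
  asym <- abs(m - t(m)) / scale
  if (max(asym) > 1e-6) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop("asymmetry ", signif(max(asym), 3), " at entry (", w[1], ", ", w[2],
         ") of ", path, " exceeds 1e-6 relative tolerance")
  }
  (m + t(m)) / 2
}

#' Write a matrix as tab-separated text
#'
#' @param M numeric matrix (or `sparse_graph` / `conn_estimate`).
#' @param path output file.
#' @export
write_matrix <- function(M, path) {
  if (inherits(M, "sparse_graph")) M <- M$adjacency
  if (inherits(M, "conn_estimate")) M <- M$matrix
  utils::write.table(M, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a sparse graph as a weighted edge list
#'
#' Three-column TSV `i, j, w` with 0-based node ids, upper triangle only.
#'
#' @param G a `sparse_graph`.
#' @param path output file.
#' @export
write_edgelist <- function(G, path) {
  A <- .graph_adj(G)
  up <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  df <- data.frame(i = up[, 1] - 1L, j = up[, 2] - 1L,
                   w = A[up])
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write nested partitions as two-column TSV files
#'
#' One file per `m` (`partition_m<m>.tsv`: region id, module id), 0-based
#' region ids.
#'
#' @param partitions a `hierarchy_partitions`.
#' @param dir output directory (created if missing).
#' @export
write_partitions <- function(partitions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(partitions$m_values)) {
    m <- partitions$m_values[k]
    df <- data.frame(region = seq_len(nrow(partitions$labels_by_m)) - 1L,
                     module = partitions$labels_by_m[, k])
    utils::write.table(df, file.path(dir, sprintf("partition_m%02d.tsv", m)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
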