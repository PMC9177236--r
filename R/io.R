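# Plain-text file formats: TSV time series (header row of parcel ids), TSV
# partition (parcel id, module label), graphs as directed edge-list TSV and
# square 0/1 adjacency-matrix TSV. All writers round-trip through the
# readers.

#' Read parcellated time series
#'
#' Reads one or more TSV files (header row of parcel ids, one sample per
#' row). With multiple paths each run is z-scored per column and the runs
#' are concatenated row-wise, the standard treatment of multi-run
#' resting-state sessions.
#'
#' @param path character vector of one or more TSV paths.
#' @return Samples x parcels numeric matrix with parcel-id column names.
#' @export
read_timeseries <- function(path) {
  runs <- lapply(path, function(f) {
    df <- read.delim(f, check.names = FALSE)
    bad <- which(!vapply(df, is.numeric, logical(1)))
    if (length(bad)) {
      stopf("%s: non-numeric values in column(s) %s", f,
            paste(names(df)[bad], collapse = ", "))
    }
    if (anyDuplicated(names(df))) {
      stopf("%s: duplicate parcel id(s): %s", f,
            paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
    }
    as.matrix(df)
  })
  ids <- colnames(runs[[1]])
  for (r in runs[-1]) {
    if (!identical(colnames(r), ids)) stopf("runs have differing parcel ids")
  }
  if (length(runs) == 1) return(runs[[1]])
  do.call(rbind, lapply(runs, function(r) standardize_columns(r)))
}

#' Write a time-series matrix as TSV
#' @param ts samples x parcels matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  df <- as.data.frame(ts)
  if (is.null(colnames(ts))) names(df) <- node_names(ncol(ts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a parcel-to-module partition table
#'
#' Two-column TSV (parcel id, module label). When `parcels` is supplied the
#' partition is checked for full coverage and returned in that order.
#'
#' @param path TSV path.
#' @param parcels optional character vector of parcel ids the partition
#'   must cover.
#' @return Character vector of module labels named by parcel id.
#' @export
read_partition <- function(path, parcels = NULL) {
  df <- read.delim(path, colClasses = "character")
  if (ncol(df) < 2) stopf("%s: expected two columns (parcel, module)", path)
  out <- stats::setNames(df[[2]], df[[1]])
  if (!is.null(parcels)) {
    missing <- setdiff(parcels, names(out))
    if (length(missing)) {
      stopf("partition is missing parcel(s): %s",
            paste(missing, collapse = ", "))
    }
    out <- out[parcels]
  }
  out
}

#' Write a partition as two-column TSV
#' @param partition labels named by parcel id (names default to V1..Vp).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  ids <- names(partition)
  if (is.null(ids)) ids <- node_names(length(partition))
  write.table(data.frame(parcel = ids, module = as.character(partition)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph to disk
#'
#' Directed connectomes and weighted DAGs are written as edge-list TSV
#' (source, target, and weight for DAGs); `format = "matrix"` writes a
#' square 0/1 adjacency matrix TSV instead (rows = sources). Patterns are
#' written as edge lists with an edge-type column (`directed` /
#' `undirected`).
#'
#' @param g a `gango_connectome`, `gango_dag`, or `gango_pattern`.
#' @param path output path.
#' @param format `"edgelist"` (default) or `"matrix"` (connectomes only).
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path, format = c("edgelist", "matrix")) {
  format <- match.arg(format)
  if (format == "matrix") {
    stopifnot(inherits(g, "gango_connectome"))
    m <- matrix(0L, g$p, g$p, dimnames = list(g$nodes, g$nodes))
    if (nrow(g$edges)) m[g$edges] <- 1L
    write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
    return(invisible(path))
  }
  df <- if (inherits(g, "gango_dag")) {
    data.frame(source = g$nodes[g$edges[, 1]], target = g$nodes[g$edges[, 2]],
               weight = g$weights)
  } else if (inherits(g, "gango_pattern")) {
    dir_idx <- which(g$amat == 1L & t(g$amat) == 0L, arr.ind = TRUE)
    und <- which(g$amat == 1L & t(g$amat) == 1L, arr.ind = TRUE)
    und <- und[und[, 1] < und[, 2], , drop = FALSE]
    data.frame(
      source = g$nodes[c(dir_idx[, 1], und[, 1])],
      target = g$nodes[c(dir_idx[, 2], und[, 2])],
      type = rep(c("directed", "undirected"), c(nrow(dir_idx), nrow(und))))
  } else {
    stopifnot(inherits(g, "gango_connectome"))
    data.frame(source = g$nodes[g$edges[, 1]], target = g$nodes[g$edges[, 2]])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a directed connectome from an edge-list TSV
#'
#' @param path edge-list TSV with `source` and `target` columns.
#' @param nodes character vector of all parcel ids (fixes `p` and the
#'   index order; required because isolated nodes carry no edges).
#' @param two_cycles_ok allow both directions of an adjacency (see
#'   [connectome()]).
#' @return A `gango_connectome`.
#' @export
read_graph <- function(path, nodes, two_cycles_ok = FALSE) {
  df <- read.delim(path, colClasses = "character")
  from <- match(df$source, nodes)
  to <- match(df$target, nodes)
  if (anyNA(from) || anyNA(to)) {
    bad <- unique(c(df$source[is.na(from)], df$target[is.na(to)]))
    stopf("edge list refers to unknown parcel(s): %s",
          paste(bad, collapse = ", "))
  }
  new_connectome(length(nodes), cbind(from, to), nodes, two_cycles_ok)
}

#' Write a data frame as TSV
#' @param rows data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
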