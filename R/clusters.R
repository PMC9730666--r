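#' Cluster sets
#'
#' A cluster is an ordered, oriented list of contigs representing one
#' scaffold (ideally one chromosome); a cluster read in reverse with all
#' orientations flipped denotes the same scaffold. A `cluster_set` is a list
#' of contig-disjoint clusters, each a list with elements `contig`
#' (character), `orient` (`"+"`/`"-"`), `length` (bp) and `robustness`
#' (frequency across consensus grid runs, `NA` before merging).
#'
#' @param clusters list of clusters.
#' @param contigs contigs eligible at this run (for coverage bookkeeping).
#' @param lengths named contig lengths in bp.
#' @return a `cluster_set`.
#' @export
cluster_set <- function(clusters, contigs = NULL, lengths = NULL) {
  clusters <- .sort_clusters(clusters)
  structure(clusters, class = "cluster_set",
            contigs = contigs, lengths = lengths)
}

# total length descending, then first contig name (byte order)
.sort_clusters <- function(clusters) {
  if (length(clusters) <= 1L) return(clusters)
  len <- vapply(clusters, function(cl) cl$length, 0)
  first <- vapply(clusters, function(cl) cl$contig[1L], "")
  clusters[order(-len, first, method = "radix")]
}

#' Canonical form of a cluster
#'
#' Returns the lexicographically smaller (byte order over
#' `"<contig><orient>"` tokens) of the cluster's forward representation and
#' its reversal (reverse order, flipped orientations). Idempotent; used to
#' identify identical cluster units across parameter-grid runs.
#'
#' @param cluster a cluster (list with `contig` and `orient`).
#' @return the canonicalized cluster.
#' @export
canonicalize_cluster <- function(cluster) {
  stopifnot(length(cluster$contig) > 0L)
  fwd <- paste0(cluster$contig, cluster$orient)
  rev_orient <- .flip_orient(rev(cluster$orient))
  bwd <- paste0(rev(cluster$contig), rev_orient)
  if (.tokens_lt(bwd, fwd)) {
    cluster$contig <- rev(cluster$contig)
    cluster$orient <- rev_orient
  }
  cluster
}

# canonical identity string of a cluster, e.g. "ctgA+;ctgB-"
.cluster_key <- function(cluster) {
  cl <- canonicalize_cluster(cluster)
  paste(paste0(cl$contig, cl$orient), collapse = ";")
}

#' Write a cluster table
#'
#' One row per cluster: id, contig count, total length (bp), robustness, and
#' the semicolon-joined ordered `contig+`/`contig-` member tokens.
#'
#' @param clusters a `cluster_set`.
#' @param path output file.
#' @export
write_cluster_table <- function(clusters, path) {
  rows <- vapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    paste(sprintf("cluster_%02d", k), length(cl$contig),
          format(cl$length, scientific = FALSE),
          ifelse(is.na(cl$robustness), 0L, cl$robustness),
          paste(paste0(cl$contig, cl$orient), collapse = ";"),
          sep = "\t")
  }, "")
  writeLines(c("#cluster_id\tcontig_count\tlength_bp\trobustness\tmembers",
               rows), path)
  invisible(path)
}

#' Read a cluster table written by [write_cluster_table()]
#'
#' @param path cluster table file.
#' @return a `cluster_set`.
#' @export
read_cluster_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  clusters <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 5L) stop("malformed cluster table line: ", ln)
    toks <- strsplit(f[5L], ";", fixed = TRUE)[[1L]]
    orient <- substr(toks, nchar(toks), nchar(toks))
    if (!all(orient %in% c("+", "-")))
      stop("malformed member token in cluster table: ", f[5L])
    list(contig = substr(toks, 1L, nchar(toks) - 1L), orient = orient,
         length = as.numeric(f[3L]), robustness = as.integer(f[4L]))
  })
  contigs <- unlist(lapply(clusters, `[[`, "contig"))
  structure(clusters, class = "cluster_set", contigs = contigs,
            lengths = NULL)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x), "clusters,",
      sum(vapply(x, function(cl) length(cl$contig), 0L)), "contigs\n")
  for (k in seq_len(min(length(x), 8L))) {
    cl <- x[[k]]
    cat(sprintf("  %2d. [%s] %.1f Mb, robustness %s\n", k,
                paste(paste0(cl$contig, cl$orient), collapse = ";"),
                cl$length / 1e6,
                ifelse(is.na(cl$robustness), "-", cl$robustness)))
  }
  if (length(x) > 8L) cat("  ...\n")
  invisible(x)
}
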