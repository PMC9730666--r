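#' Build the scaffolding graph at a contact cutoff
#'
#' Nodes are contig ends; the two ends of one contig are tied by an
#' implicit, unbreakable sister edge. A link edge joins two ends of
#' different contigs whenever their end-pair contact value is strictly
#' larger than the cutoff.
#'
#' @param table an `end_contact_table` from [compute_end_contacts()].
#' @param cutoff contact cutoff (> 0); comparison is strict (`>`).
#' @return a `scaffold_graph`: `$ends` (data.frame `contig`, `side`, `key`)
#'   and `$edges` (data.frame `key1`, `key2`, `weight`).
#' @export
build_link_graph <- function(table, cutoff) {
  stopifnot(cutoff > 0)
  V <- table$values
  idx <- which(upper.tri(V) & !is.na(V) & V > cutoff, arr.ind = TRUE)
  edges <- data.frame(key1 = table$ends$key[idx[, 1L]],
                      key2 = table$ends$key[idx[, 2L]],
                      weight = V[idx], stringsAsFactors = FALSE)
  if (nrow(edges) > 0L)
    edges <- edges[.radix_order(edges$key1, edges$key2), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(ends = table$ends, edges = edges),
            class = "scaffold_graph", cutoff = cutoff)
}

#' Keep only reciprocal-best link edges
#'
#' A link edge survives iff its weight is the unique maximum among the link
#' edges incident to each of its two endpoints. A tie at either endpoint
#' drops all tied edges (conservative: no arbitrary joins). Afterwards every
#' end carries at most one link edge.
#'
#' @param graph a `scaffold_graph`.
#' @return the filtered `scaffold_graph`.
#' @export
reciprocal_best_filter <- function(graph) {
  e <- graph$edges
  if (nrow(e) > 0L) {
    nodes <- c(e$key1, e$key2)
    w <- rep(e$weight, 2L)
    mx <- tapply(w, nodes, max)
    at_max <- w == mx[nodes]
    n_at_max <- tapply(at_max, nodes, sum)
    keep <- e$weight == mx[e$key1] & e$weight == mx[e$key2] &
      n_at_max[e$key1] == 1L & n_at_max[e$key2] == 1L
    e <- e[keep, , drop = FALSE]
    rownames(e) <- NULL
  }
  graph$edges <- e
  graph
}

# partner[key] -> linked key or NA; requires link degree <= 1
.link_partner <- function(graph) {
  p <- stats::setNames(rep(NA_character_, nrow(graph$ends)), graph$ends$key)
  e <- graph$edges
  if (nrow(e) > 0L) {
    deg <- table(c(e$key1, e$key2))
    if (any(deg > 1L))
      stop("inconsistent scaffolding graph: an end has more than one link ",
           "edge (run reciprocal_best_filter first)")
    p[e$key1] <- e$key2
    p[e$key2] <- e$key1
  }
  p
}

.sister <- function(key) .end_key(.key_contig(key), .other_side(.key_side(key)))

#' Break circular paths at their weakest link
#'
#' After reciprocal-best filtering the graph is a union of simple paths and
#' (rarely) cycles, e.g. when the two ends of a chromosome are linked. Each
#' alternating sister/link cycle loses its minimum-weight link edge; ties go
#' to the edge with the lexicographically smallest end key.
#'
#' @param graph a reciprocal-best-filtered `scaffold_graph`.
#' @return an acyclic `scaffold_graph` (union of simple paths).
#' @export
break_cycles <- function(graph) {
  partner <- .link_partner(graph)
  visited <- character(0)
  # walk every path starting from a free end, marking contigs
  free <- names(partner)[is.na(partner)]
  for (start in free) {
    ctg <- .key_contig(start)
    if (ctg %in% visited) next
    cur <- start
    repeat {
      visited <- c(visited, .key_contig(cur))
      nxt <- partner[[.sister(cur)]]
      if (is.na(nxt)) break
      cur <- nxt
    }
  }
  drop <- character(0)
  all_ctg <- unique(graph$ends$contig)
  remaining <- setdiff(all_ctg, visited)
  edge_lab <- function(k1, k2) {
    if (.str_lt(k2, k1)) paste(k2, k1) else paste(k1, k2)
  }
  wt <- stats::setNames(graph$edges$weight,
                        mapply(edge_lab, graph$edges$key1, graph$edges$key2))
  while (length(remaining) > 0L) {
    start <- .end_key(remaining[1L], "head")
    cyc <- character(0)
    cur <- start
    repeat {
      remaining <- setdiff(remaining, .key_contig(cur))
      ex <- .sister(cur)
      nxt <- partner[[ex]]
      cyc <- c(cyc, edge_lab(ex, nxt))
      if (.key_contig(nxt) == .key_contig(start)) break
      cur <- nxt
    }
    wmin <- min(wt[cyc])
    cand <- cyc[wt[cyc] == wmin]
    cand <- cand[.radix_order(cand)][1L]
    drop <- c(drop, cand)
  }
  if (length(drop) > 0L) {
    labs <- mapply(edge_lab, graph$edges$key1, graph$edges$key2)
    graph$edges <- graph$edges[!(labs %in% drop), , drop = FALSE]
    rownames(graph$edges) <- NULL
  }
  graph
}

#' Extract ordered, oriented clusters from a path graph
#'
#' Traverses each linear path of the cleaned scaffolding graph and converts
#' it to an ordered, oriented contig list. A link leaving a contig's tail
#' marks it `+`, leaving its head marks it `-`; a link entering a contig's
#' head marks it `+`, entering its tail `-`. Isolated contigs become
#' singleton `+` clusters. Each cluster is returned in canonical form (see
#' [canonicalize_cluster()]); clusters are sorted by total length descending,
#' then by first contig name.
#'
#' @param graph an acyclic `scaffold_graph` (after [break_cycles()]).
#' @param lengths named vector of contig lengths in bp.
#' @return a `cluster_set`: list of clusters, each a list with `contig`,
#'   `orient`, `length`, `robustness`.
#' @export
extract_clusters <- function(graph, lengths) {
  partner <- .link_partner(graph)
  clusters <- list()
  visited <- character(0)
  ctgs <- unique(graph$ends$contig)
  free <- names(partner)[is.na(partner)]
  free <- free[.radix_order(free)]
  for (start in free) {
    if (.key_contig(start) %in% visited) next
    contig <- character(0)
    orient <- character(0)
    cur <- start # entry end of current contig
    repeat {
      ctg <- .key_contig(cur)
      contig <- c(contig, ctg)
      orient <- c(orient, if (.key_side(cur) == "head") "+" else "-")
      visited <- c(visited, ctg)
      nxt <- partner[[.sister(cur)]]
      if (is.na(nxt)) break
      cur <- nxt
    }
    clusters[[length(clusters) + 1L]] <-
      list(contig = contig, orient = orient,
           length = sum(lengths[contig]), robustness = NA_integer_)
  }
  if (length(setdiff(ctgs, visited)) > 0L)
    stop("inconsistent scaffolding graph: cycle not broken before cluster ",
         "extraction")
  clusters <- lapply(clusters, canonicalize_cluster)
  cluster_set(clusters, contigs = ctgs, lengths = lengths[ctgs])
}
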