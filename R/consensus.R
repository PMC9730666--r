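#' Consensus parameter grid
#'
#' Default grid: end-window sizes 500 kb to 2.5 Mb in steps of 500 kb,
#' cutoff multipliers 1 to 5 in steps of 0.5, both raw and normalized
#' matrices - 5 x 9 x 2 = 90 cells, the robustness maximum of a one-round
#' run.
#'
#' @param end_sizes end-window sizes in bp (multiples of the bin size).
#' @param multipliers positive cutoff multipliers applied to the turning
#'   point.
#' @param flavors matrix flavors to use.
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(end_sizes = seq(5e5, 2.5e6, by = 5e5),
                      multipliers = seq(1, 5, by = 0.5),
                      flavors = c("raw", "normalized")) {
  stopifnot(all(end_sizes > 0), all(multipliers > 0), length(flavors) > 0)
  flavors <- match.arg(flavors, c("raw", "normalized"), several.ok = TRUE)
  structure(list(end_sizes = end_sizes, multipliers = multipliers,
                 flavors = flavors), class = "grid_spec")
}

#' Grid cardinality (maximum robustness)
#' @param grid a `grid_spec`.
#' @return number of grid cells.
#' @export
grid_cardinality <- function(grid) {
  length(grid$end_sizes) * length(grid$multipliers) * length(grid$flavors)
}

#' Run the scaffolding chain over every grid cell
#'
#' For each (flavor, end size) the end-contact table and its turning point
#' are computed once; each multiplier then yields a cutoff and a cleaned
#' graph whose clusters form one cell result. Cells whose turning point is
#' degenerate (too few or identical contact values) yield an empty cluster
#' set and are recorded with `NA` in the summary.
#'
#' @param bins a [bin_table].
#' @param raw,normalized the two [contact_matrix] flavors (either may be
#'   passed for both if only one flavor is in the grid).
#' @param grid a [grid_spec()].
#' @return a `grid_result`: `$cluster_sets` (list, one per cell) and
#'   `$cells` (summary data.frame: end_size, flavor, multiplier,
#'   turning_point, cutoff, n_clusters, n_contigs).
#' @export
run_parameter_grid <- function(bins, raw, normalized, grid = grid_spec()) {
  b <- attr(bins, "bin_size")
  lengths <- contig_lengths(bins)
  sets <- list()
  cells <- list()
  for (flavor in grid$flavors) {
    mat <- if (flavor == "raw") raw else normalized
    for (es in grid$end_sizes) {
      w <- as.integer(round(es / b))
      ends <- make_end_windows(bins, w)
      table <- compute_end_contacts(mat, ends)
      tp <- tryCatch(find_turning_point(table), error = function(e) NULL)
      for (m in grid$multipliers) {
        if (is.null(tp) || nrow(ends$ends) == 0L) {
          cs <- cluster_set(list(), contigs = character(0),
                            lengths = numeric(0))
          cut <- NA_real_
        } else {
          cut <- derive_cutoffs(tp, m)
          g <- build_link_graph(table, cut)
          g <- break_cycles(reciprocal_best_filter(g))
          cs <- extract_clusters(g, lengths)
        }
        sets[[length(sets) + 1L]] <- cs
        cells[[length(cells) + 1L]] <- data.frame(
          end_size = es, flavor = flavor, multiplier = m,
          turning_point = if (is.null(tp)) NA_real_ else tp$value,
          cutoff = cut, n_clusters = length(cs),
          n_contigs = length(attr(cs, "contigs")),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(cluster_sets = sets, cells = do.call(rbind, cells),
                 grid = grid),
            class = "grid_result")
}

#' Merge parallel cluster results into a consensus
#'
#' Canonical cluster units are counted across all grid-cell results and
#' emitted greedily by frequency (ties: total length descending, then
#' canonical key): a unit is emitted only if none of its contigs has been
#' used by a previously emitted unit. Any eligible contig still unplaced is
#' emitted as a `+` singleton carrying its observed singleton frequency
#' (possibly 0). The frequency of each emitted unit is its robustness; the
#' maximum possible robustness is the number of runs.
#'
#' @param results a `grid_result` or plain list of `cluster_set`s.
#' @return a consensus `cluster_set` with attribute `max_robustness`.
#' @export
merge_cluster_results <- function(results) {
  if (inherits(results, "grid_result")) results <- results$cluster_sets
  stopifnot(length(results) >= 1L)
  n_runs <- length(results)
  units <- new.env(parent = emptyenv())
  eligible <- character(0)
  lengths <- numeric(0)
  for (cs in results) {
    eligible <- union(eligible, attr(cs, "contigs"))
    ln <- attr(cs, "lengths")
    if (!is.null(ln)) lengths[names(ln)] <- ln
    for (cl in cs) {
      cl <- canonicalize_cluster(cl)
      k <- paste(paste0(cl$contig, cl$orient), collapse = ";")
      u <- units[[k]]
      if (is.null(u)) u <- list(cluster = cl, freq = 0L)
      u$freq <- u$freq + 1L
      units[[k]] <- u
    }
  }
  keys <- ls(units, sorted = FALSE)
  if (length(keys) > 0L) {
    freq <- vapply(keys, function(k) units[[k]]$freq, 0L)
    len <- vapply(keys, function(k) units[[k]]$cluster$length, 0)
    ord <- order(-freq, -len, keys, method = "radix")
    keys <- keys[ord]
  }
  used <- character(0)
  out <- list()
  for (k in keys) {
    cl <- units[[k]]$cluster
    if (any(cl$contig %in% used)) next
    cl$robustness <- units[[k]]$freq
    used <- c(used, cl$contig)
    out[[length(out) + 1L]] <- cl
  }
  leftover <- setdiff(eligible, used)
  for (ctg in leftover[.radix_order(leftover)]) {
    k <- paste0(ctg, "+")
    f <- if (!is.null(units[[k]])) units[[k]]$freq else 0L
    out[[length(out) + 1L]] <- list(
      contig = ctg, orient = "+",
      length = if (ctg %in% names(lengths)) lengths[[ctg]] else NA_real_,
      robustness = f)
  }
  res <- cluster_set(out, contigs = eligible, lengths = lengths)
  attr(res, "max_robustness") <- n_runs
  res
}

#' One full scaffolding round: grid, consensus, outputs
#'
#' Runs the complete single-round pipeline: end windows, end-contact tables,
#' turning points, graph construction and cleaning over the whole parameter
#' grid, followed by the consensus merge. When `out_prefix` is given, writes
#' `<prefix>.cluster.tsv` (the consensus), `<prefix>.cells.tsv` (per-cell
#' grid summary), raw and cleaned GFA for a representative mid-grid cell
#' (median end size, multiplier closest to 1.5, first flavor),
#' `<prefix>.agp`, and `<prefix>.fasta` when contig sequences are supplied.
#'
#' @param bins a [bin_table].
#' @param raw,normalized the two [contact_matrix] flavors.
#' @param grid a [grid_spec()].
#' @param out_prefix optional output path prefix.
#' @param fasta optional contig FASTA path (enables scaffold FASTA output).
#' @param gap_len AGP gap length between consecutive contigs (bp).
#' @return the consensus `cluster_set` (attribute `cells` holds the grid
#'   summary).
#' @export
scaffold_once <- function(bins, raw, normalized, grid = grid_spec(),
                          out_prefix = NULL, fasta = NULL, gap_len = 100) {
  gr <- run_parameter_grid(bins, raw, normalized, grid)
  cons <- merge_cluster_results(gr)
  attr(cons, "cells") <- gr$cells
  if (!is.null(out_prefix)) {
    write_cluster_table(cons, paste0(out_prefix, ".cluster.tsv"))
    utils::write.table(gr$cells, paste0(out_prefix, ".cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    lengths <- contig_lengths(bins)
    # representative mid-grid cell for the graph exports
    es <- grid$end_sizes[ceiling(length(grid$end_sizes) / 2)]
    m <- grid$multipliers[which.min(abs(grid$multipliers - 1.5))]
    flavor <- grid$flavors[1L]
    mat <- if (flavor == "raw") raw else normalized
    w <- as.integer(round(es / attr(bins, "bin_size")))
    table <- compute_end_contacts(mat, make_end_windows(bins, w))
    tp <- tryCatch(find_turning_point(table), error = function(e) NULL)
    if (!is.null(tp)) {
      g <- build_link_graph(table, derive_cutoffs(tp, m))
      write_gfa(g, lengths, paste0(out_prefix, ".raw.gfa"))
      g <- break_cycles(reciprocal_best_filter(g))
      write_gfa(g, lengths, paste0(out_prefix, ".cleaned.gfa"))
    }
    agp <- write_agp(cons, lengths, paste0(out_prefix, ".agp"),
                     gap_len = gap_len)
    if (!is.null(fasta))
      emit_scaffold_fasta(agp, fasta, paste0(out_prefix, ".fasta"))
  }
  cons
}
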