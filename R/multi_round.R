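#' End-window schedule for iterative rounds
#'
#' Round 1 uses end sizes 0.5-2.5 Mb; each later round shifts the block up
#' by 2.5 Mb (3-5 Mb, 5.5-7.5 Mb, 8-10 Mb). Accuracy decreases as end
#' windows grow, so at most three rounds (end size <= 10 Mb) are
#' recommended.
#'
#' @param n_rounds number of round blocks to generate.
#' @param step in-round step and between-round increment in bp.
#' @return a `round_schedule`: list of end-size vectors (bp).
#' @export
round_schedule <- function(n_rounds = 4L, step = 5e5) {
  lapply(seq_len(n_rounds), function(r)
    seq(5e5, 2.5e6, by = step) + (r - 1L) * 2.5e6)
}

#' End sizes of one iterative round
#'
#' @param round_index 1-based round number.
#' @param schedule a [round_schedule()].
#' @return end sizes (bp) of that round.
#' @export
round_end_sizes <- function(round_index, schedule = round_schedule()) {
  stopifnot(round_index >= 1L)
  if (round_index > length(schedule))
    stop("round ", round_index, " is beyond the schedule; a round number no ",
         "larger than 3 (end size <= 10 Mb) is recommended - review the ",
         "previous round's clusters manually instead")
  schedule[[round_index]]
}

#' Collapse clusters into super-contigs for the next round
#'
#' Each cluster becomes one super-contig whose bins are the member contigs'
#' bins in path order (bin order reversed inside `-`-oriented members). Bin
#' ids are untouched, so the contact matrix is reused unchanged; local
#' coordinates are recomputed cumulatively and gaps occupy zero bin space.
#'
#' @param clusters a `cluster_set` partitioning the eligible contigs.
#' @param bins the current [bin_table].
#' @param prefix naming prefix for super-contigs.
#' @return list with `bins` (the super [bin_table]) and `members` (named
#'   list: super-contig -> data.frame `contig`, `orient`).
#' @export
build_super_assembly <- function(clusters, bins, prefix = "super") {
  b <- attr(bins, "bin_size")
  known <- unique(bins$contig)
  rows_of <- split(seq_len(nrow(bins)), factor(bins$contig, levels = known))
  new_rows <- list()
  members <- list()
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    miss <- setdiff(cl$contig, known)
    if (length(miss) > 0L)
      stop("cluster contig absent from bin table: ",
           paste(miss, collapse = ", "))
    sid <- sprintf("%s_%03d", prefix, k)
    members[[sid]] <- data.frame(contig = cl$contig, orient = cl$orient,
                                 stringsAsFactors = FALSE)
    seg <- list()
    for (q in seq_along(cl$contig)) {
      r <- bins[rows_of[[cl$contig[q]]], , drop = FALSE]
      if (cl$orient[q] == "-") r <- r[rev(seq_len(nrow(r))), , drop = FALSE]
      seg[[q]] <- r
    }
    seg <- do.call(rbind, seg)
    w <- seg$end - seg$start
    seg$contig <- sid
    seg$end <- cumsum(w)
    seg$start <- seg$end - w
    new_rows[[length(new_rows) + 1L]] <- seg
  }
  out <- do.call(rbind, new_rows)
  # a reversed member puts its short terminal bin mid-contig; widths are
  # preserved, so skip the strict width check and keep ids as-is
  sup <- bin_table(out, bin_size = b, validate = FALSE)
  list(bins = sup, members = members)
}

# Expand a cluster over super-contigs to original contigs via a member map.
.expand_cluster <- function(cl, expand_map) {
  contig <- character(0)
  orient <- character(0)
  for (q in seq_along(cl$contig)) {
    e <- expand_map[[cl$contig[q]]]
    if (is.null(e))
      e <- data.frame(contig = cl$contig[q], orient = "+",
                      stringsAsFactors = FALSE)
    if (cl$orient[q] == "-")
      e <- data.frame(contig = rev(e$contig), orient = .flip_orient(rev(e$orient)),
                      stringsAsFactors = FALSE)
    contig <- c(contig, e$contig)
    orient <- c(orient, e$orient)
  }
  cl$contig <- contig
  cl$orient <- orient
  canonicalize_cluster(cl)
}

#' Iterative scaffolding with increasing end windows
#'
#' Runs one consensus round per schedule entry, feeding each round's
#' clusters back as super-contigs. Larger end windows span repeat-suppressed
#' member junctions that defeated the previous round. Stops early when the
#' cluster count stops decreasing or reaches `target_n` (the known
#' chromosome number). The final clusters are expanded back to
#' original-contig order and orientation.
#'
#' @param bins a [bin_table].
#' @param raw,normalized the two [contact_matrix] flavors.
#' @param schedule a [round_schedule()].
#' @param max_rounds maximum rounds to run (>= 1; at most 3 recommended).
#' @param target_n optional known chromosome number (stop when reached).
#' @param multipliers,flavors grid dimensions reused in every round.
#' @return consensus `cluster_set` over original contigs; attribute
#'   `round_counts` holds the per-round cluster counts.
#' @export
run_iterative <- function(bins, raw, normalized, schedule = round_schedule(),
                          max_rounds = 3L, target_n = NULL,
                          multipliers = seq(1, 5, by = 0.5),
                          flavors = c("raw", "normalized")) {
  stopifnot(max_rounds >= 1L)
  cur_bins <- bins
  expand_map <- list()
  counts <- integer(0)
  final <- NULL
  prev_n <- Inf
  for (r in seq_len(max_rounds)) {
    grid <- grid_spec(end_sizes = round_end_sizes(r, schedule),
                      multipliers = multipliers, flavors = flavors)
    cons <- merge_cluster_results(
      run_parameter_grid(cur_bins, raw, normalized, grid))
    n <- length(cons)
    counts <- c(counts, n)
    expanded <- lapply(cons, .expand_cluster, expand_map = expand_map)
    lengths <- contig_lengths(bins)
    eligible <- unique(unlist(lapply(expanded, `[[`, "contig")))
    final <- cluster_set(expanded, contigs = eligible,
                         lengths = lengths[eligible])
    attr(final, "max_robustness") <- attr(cons, "max_robustness")
    if (!is.null(target_n) && n <= target_n) break
    if (n >= prev_n) break
    prev_n <- n
    if (r < max_rounds) {
      sup <- build_super_assembly(cons, cur_bins,
                                  prefix = sprintf("round%d", r))
      cur_bins <- sup$bins
      expand_map <- lapply(sup$members, function(mem) {
        do.call(rbind, lapply(seq_len(nrow(mem)), function(q) {
          e <- expand_map[[mem$contig[q]]]
          if (is.null(e))
            e <- data.frame(contig = mem$contig[q], orient = "+",
                            stringsAsFactors = FALSE)
          if (mem$orient[q] == "-")
            e <- data.frame(contig = rev(e$contig),
                            orient = .flip_orient(rev(e$orient)),
                            stringsAsFactors = FALSE)
          e
        }))
      })
    }
  }
  attr(final, "round_counts") <- counts
  final
}

#' Assign small contigs to scaffolds by maximum total Hi-C links
#'
#' Contigs too small for end windows are attached to the cluster maximizing
#' the summed whole-contig contact; ordering and orientation are not
#' attempted. Ties and contigs with zero total links stay unassigned.
#'
#' @param mat a [contact_matrix].
#' @param bins a [bin_table] covering both clustered and small contigs.
#' @param clusters a `cluster_set`.
#' @param small character vector of small contig ids (must not appear in
#'   `clusters`).
#' @return named character vector: small contig -> cluster id (format
#'   `cluster_<k>`), `NA` when unassigned.
#' @export
assign_small_contigs <- function(mat, bins, clusters, small) {
  placed <- unlist(lapply(clusters, `[[`, "contig"))
  if (any(small %in% placed))
    stop("small contigs must be absent from the clusters")
  ctg_of <- stats::setNames(bins$contig, as.character(bins$bin))
  cl_of <- character(0)
  for (k in seq_along(clusters))
    cl_of[clusters[[k]]$contig] <- sprintf("cluster_%02d", k)
  ci <- ctg_of[as.character(mat$i)]
  cj <- ctg_of[as.character(mat$j)]
  res <- stats::setNames(rep(NA_character_, length(small)), small)
  gi <- cl_of[ci]
  gj <- cl_of[cj]
  # links between a small contig and a clustered contig, either orientation
  sel1 <- ci %in% small & !is.na(gj)
  sel2 <- cj %in% small & !is.na(gi) & ci != cj
  sc <- c(ci[sel1], cj[sel2])
  gr <- c(gj[sel1], gi[sel2])
  vv <- c(mat$value[sel1], mat$value[sel2])
  if (length(vv) > 0L) {
    tot <- tapply(vv, list(sc, gr), sum)
    for (ctg in intersect(rownames(tot), small)) {
      v <- tot[ctg, ]
      v[is.na(v)] <- 0
      if (max(v) > 0 && sum(v == max(v)) == 1L)
        res[[ctg]] <- names(v)[which.max(v)]
    }
  }
  res
}
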