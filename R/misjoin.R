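#' Intra-contig contact profile at a fixed bin gap
#'
#' For each in-contig bin pair `(k, k + gap_bins)` (500 kb apart at the
#' defaults), records the raw contact value and the contig-local midpoint. A
#' mis-join shows up as a trough in this profile because few Hi-C links cross
#' the junction of two non-neighbor genomic segments.
#'
#' @param contig contig id.
#' @param bins a [bin_table].
#' @param mat a raw [contact_matrix].
#' @param gap_bins gap between the paired bins, in bins (default 5).
#' @return a `contact_profile` data.frame (`left_bin`, `right_bin`,
#'   `midpoint`, `value`), empty when the contig has `<= gap_bins` bins;
#'   attributes `contig` and `gap_bins`.
#' @export
adjacent_contact_profile <- function(contig, bins, mat, gap_bins = 5L) {
  rows <- bins[bins$contig == contig, , drop = FALSE]
  n <- nrow(rows)
  if (n <= gap_bins) {
    prof <- data.frame(left_bin = integer(), right_bin = integer(),
                       midpoint = numeric(), value = numeric())
  } else {
    k <- seq_len(n - gap_bins)
    prof <- data.frame(left_bin = rows$bin[k],
                       right_bin = rows$bin[k + gap_bins],
                       midpoint = (rows$start[k] + rows$end[k + gap_bins]) / 2,
                       value = .lookup_values(mat, rows$bin[k],
                                              rows$bin[k + gap_bins]))
  }
  structure(prof, class = c("contact_profile", "data.frame"),
            contig = contig, gap_bins = gap_bins)
}

#' Genome-wide median contact at a fixed bin gap
#'
#' Median over all in-contig bin pairs `gap_bins` apart, across all contigs.
#' This is the reference level against which mis-join troughs are judged.
#'
#' @inheritParams adjacent_contact_profile
#' @return the median contact value.
#' @export
genome_median_gap_contact <- function(bins, mat, gap_bins = 5L) {
  qi <- integer(0)
  qj <- integer(0)
  idx <- split(seq_len(nrow(bins)),
               factor(bins$contig, levels = unique(bins$contig)))
  for (rows in idx) {
    n <- length(rows)
    if (n > gap_bins) {
      k <- seq_len(n - gap_bins)
      qi <- c(qi, bins$bin[rows[k]])
      qj <- c(qj, bins$bin[rows[k + gap_bins]])
    }
  }
  if (length(qi) == 0L)
    stop("no in-contig bin pair ", gap_bins, " bins apart exists genome-wide")
  stats::median(.lookup_values(mat, qi, qj))
}

#' Detect mis-join breakpoints in a contact profile
#'
#' Maximal runs of consecutive profile points with value below
#' `frac * median` are each collapsed to one breakpoint, placed at the bin
#' boundary nearest the run's minimum-value midpoint (among tied minima, the
#' point closest to the run centre; earlier on ties). When a unitig map is
#' supplied, only breakpoints with a unitig boundary within one bin are
#' retained (`unitig_confirmed` set), since correctly assembled regions can
#' also have locally low Hi-C coverage; without a map all Hi-C-only
#' breakpoints are returned.
#'
#' @param profile a `contact_profile`.
#' @param median genome-wide reference from [genome_median_gap_contact()].
#' @param unitigs optional `unitig_map`.
#' @param frac threshold fraction of the median (default 0.1).
#' @param bin_size bin width in bp (for the boundary grid and the
#'   corroboration window).
#' @return data.frame of breakpoints: `contig`, `position` (bp, a bin
#'   boundary), `min_value`, `unitig_confirmed`.
#' @export
detect_misjoins <- function(profile, median, unitigs = NULL, frac = 0.1,
                            bin_size = 1e5) {
  stopifnot(frac > 0, frac < 1)
  contig <- attr(profile, "contig")
  empty <- data.frame(contig = character(), position = numeric(),
                      min_value = numeric(), unitig_confirmed = logical())
  if (nrow(profile) == 0L) return(empty)
  low <- profile$value < frac * median
  if (!any(low)) return(empty)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (q in which(r$values)) {
    idx <- seq.int(starts[q], ends[q])
    vmin <- min(profile$value[idx])
    cand <- idx[profile$value[idx] == vmin]
    centre <- mean(range(profile$midpoint[idx]))
    pick <- cand[which.min(abs(profile$midpoint[cand] - centre))]
    pos <- round(profile$midpoint[pick] / bin_size) * bin_size
    out[[length(out) + 1L]] <- data.frame(
      contig = contig, position = pos, min_value = vmin,
      unitig_confirmed = FALSE, stringsAsFactors = FALSE)
  }
  bp <- do.call(rbind, out)
  if (!is.null(unitigs)) {
    bounds <- .unitig_boundaries(unitigs, contig)
    ok <- vapply(bp$position, function(p) {
      length(bounds) > 0L && any(abs(bounds - p) <= bin_size)
    }, TRUE)
    bp <- bp[ok, , drop = FALSE]
    bp$unitig_confirmed <- rep(TRUE, nrow(bp))
    rownames(bp) <- NULL
  }
  bp
}

#' Break contigs at detected mis-join positions
#'
#' Each broken contig is replaced by children `<id>_1`, `<id>_2`, ... The
#' bin table reassigns the existing bins to the children with recomputed
#' local coordinates; bin ids are stable, so the contact matrix is unchanged.
#' If contig sequences are supplied they are split exactly at the break
#' positions.
#'
#' @param assembly optional named [Biostrings::DNAStringSet] of contig
#'   sequences (or `NULL`).
#' @param bins a [bin_table].
#' @param mat a [contact_matrix] (returned unchanged).
#' @param breaks breakpoint data.frame from [detect_misjoins()].
#' @return list with elements `assembly`, `bins`, `matrix`.
#' @export
apply_breaks <- function(assembly, bins, mat, breaks) {
  if (is.null(breaks) || nrow(breaks) == 0L)
    return(list(assembly = assembly, bins = bins, matrix = mat))
  df <- as.data.frame(bins)
  new_rows <- list()
  for (ctg in unique(df$contig)) {
    rows <- df[df$contig == ctg, , drop = FALSE]
    pos <- sort(breaks$position[breaks$contig == ctg])
    if (length(pos) == 0L) {
      new_rows[[length(new_rows) + 1L]] <- rows
      next
    }
    bounds <- rows$end[-nrow(rows)]
    if (!all(pos %in% bounds))
      stop("breakpoint not on an internal bin boundary of contig '", ctg, "'")
    cuts <- c(0, pos, rows$end[nrow(rows)])
    for (s in seq_len(length(cuts) - 1L)) {
      seg <- rows[rows$start >= cuts[s] & rows$end <= cuts[s + 1L], ,
                  drop = FALSE]
      seg$contig <- paste0(ctg, "_", s)
      seg$start <- seg$start - cuts[s]
      seg$end <- seg$end - cuts[s]
      new_rows[[length(new_rows) + 1L]] <- seg
    }
    if (!is.null(assembly) && ctg %in% names(assembly)) {
      pieces <- lapply(seq_len(length(cuts) - 1L), function(s)
        Biostrings::subseq(assembly[[ctg]], cuts[s] + 1L, cuts[s + 1L]))
      pieces <- Biostrings::DNAStringSet(pieces)
      names(pieces) <- paste0(ctg, "_", seq_along(pieces))
      assembly <- c(assembly[setdiff(names(assembly), ctg)], pieces)
    }
  }
  out <- do.call(rbind, new_rows)
  list(assembly = assembly,
       bins = bin_table(out, bin_size = attr(bins, "bin_size"),
                        validate = TRUE, increasing_ids = FALSE),
       matrix = mat)
}

#' Scan every contig for mis-joins
#'
#' Convenience wrapper: profiles each contig, computes the genome-wide
#' median once, and concatenates the per-contig breakpoint calls.
#'
#' @inheritParams adjacent_contact_profile
#' @inheritParams detect_misjoins
#' @return breakpoint data.frame over all contigs.
#' @export
detect_misjoins_genome <- function(bins, mat, unitigs = NULL, gap_bins = 5L,
                                   frac = 0.1) {
  b <- attr(bins, "bin_size")
  ctg_levels <- unique(bins$contig)
  idx <- split(seq_len(nrow(bins)), factor(bins$contig, levels = ctg_levels))
  qi <- integer(0); qj <- integer(0); qc <- character(0); qm <- numeric(0)
  for (ctg in ctg_levels) {
    rows <- idx[[ctg]]
    n <- length(rows)
    if (n > gap_bins) {
      k <- seq_len(n - gap_bins)
      qi <- c(qi, bins$bin[rows[k]])
      qj <- c(qj, bins$bin[rows[k + gap_bins]])
      qm <- c(qm, (bins$start[rows[k]] + bins$end[rows[k + gap_bins]]) / 2)
      qc <- c(qc, rep(ctg, n - gap_bins))
    }
  }
  if (length(qi) == 0L)
    stop("no in-contig bin pair ", gap_bins, " bins apart exists genome-wide")
  v <- .lookup_values(mat, qi, qj) # one vectorized lookup for all contigs
  med <- stats::median(v)
  out <- lapply(ctg_levels, function(ctg) {
    sel <- qc == ctg
    if (!any(sel)) return(NULL)
    prof <- structure(
      data.frame(left_bin = qi[sel], right_bin = qj[sel],
                 midpoint = qm[sel], value = v[sel]),
      class = c("contact_profile", "data.frame"),
      contig = ctg, gap_bins = gap_bins)
    detect_misjoins(prof, med, unitigs = unitigs, frac = frac, bin_size = b)
  })
  do.call(rbind, out)
}
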