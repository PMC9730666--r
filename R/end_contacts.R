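#' Define head/tail end windows for every sufficiently large contig
#'
#' The head window of a contig is its first `w` bins, the tail window its
#' last `w` bins. Only contigs whose two windows do not overlap are kept;
#' smaller contigs are reported in the `small_contigs` attribute and left for
#' post-hoc assignment (see [assign_small_contigs()]). A contig's short
#' terminal bin counts as a full bin.
#'
#' @param bins a [bin_table].
#' @param w end-window size in bins (>= 1).
#' @param strict if `TRUE` (default) contigs with exactly `2w` bins are
#'   included (their windows touch but do not overlap); if `FALSE`, more than
#'   `2w` bins are required.
#' @return a `contig_ends` object: `$ends` (data.frame `contig`, `side`,
#'   `key`) and `$bin_ids` (list of bin-id vectors per end, head windows in
#'   contig order, tail windows likewise); attributes `w` and
#'   `small_contigs`.
#' @export
make_end_windows <- function(bins, w, strict = TRUE) {
  stopifnot(w >= 1)
  ctgs <- unique(bins$contig)
  nb <- vapply(ctgs, function(c) sum(bins$contig == c), 0L)
  need <- if (strict) 2L * w else 2L * w + 1L
  keep <- ctgs[nb >= need]
  small <- ctgs[nb < need]
  ends <- data.frame(contig = rep(keep, each = 2L),
                     side = rep(c("head", "tail"), times = length(keep)),
                     stringsAsFactors = FALSE)
  ends$key <- .end_key(ends$contig, ends$side)
  bin_ids <- vector("list", nrow(ends))
  for (k in seq_along(keep)) {
    ids <- bins$bin[bins$contig == keep[k]]
    bin_ids[[2L * k - 1L]] <- ids[seq_len(w)]
    bin_ids[[2L * k]] <- ids[seq.int(length(ids) - w + 1L, length(ids))]
  }
  structure(list(ends = ends, bin_ids = bin_ids),
            class = "contig_ends", w = w, small_contigs = small)
}

#' Compute the contact table over all cross-contig end pairs
#'
#' The contact value of an end pair is the sum of matrix entries over all bin
#' pairs with one bin in each window. Same-contig pairs are excluded
#' wholesale (their entries are `NA` in the value matrix).
#'
#' @param mat a [contact_matrix].
#' @param ends a `contig_ends` object from [make_end_windows()].
#' @return an `end_contact_table`: `$ends` (data.frame), `$values` (dense
#'   symmetric matrix keyed by end, `NA` on same-contig pairs); attributes
#'   `w` and `flavor`.
#' @export
compute_end_contacts <- function(mat, ends) {
  m <- nrow(ends$ends)
  ids <- sort(unique(unlist(ends$bin_ids)))
  V <- matrix(0, m, m, dimnames = list(ends$ends$key, ends$ends$key))
  if (m > 0L && nrow(mat) > 0L) {
    sub <- mat[mat$i %in% ids & mat$j %in% ids, , drop = FALSE]
    if (nrow(sub) > 0L) {
      n <- length(ids)
      M <- Matrix::sparseMatrix(i = match(sub$i, ids), j = match(sub$j, ids),
                                x = sub$value, dims = c(n, n),
                                symmetric = TRUE)
      E <- Matrix::sparseMatrix(i = match(unlist(ends$bin_ids), ids),
                                j = rep(seq_len(m), lengths(ends$bin_ids)),
                                x = 1, dims = c(n, m))
      V <- as.matrix(Matrix::crossprod(E, M %*% E))
      dimnames(V) <- list(ends$ends$key, ends$ends$key)
    }
  }
  same <- outer(ends$ends$contig, ends$ends$contig, `==`)
  V[same] <- NA_real_
  structure(list(ends = ends$ends, values = V),
            class = "end_contact_table",
            w = attr(ends, "w"), flavor = attr(mat, "flavor"))
}

#' Look up an end-pair contact value
#'
#' @param table an `end_contact_table`.
#' @param key1,key2 end keys (`"contig:side"`); symmetric access.
#' @return numeric value (`NA` for same-contig pairs).
#' @export
end_contact_value <- function(table, key1, key2) {
  table$values[cbind(match(key1, table$ends$key),
                     match(key2, table$ends$key))]
}

# All cross-contig end-pair values (upper triangle), optionally nonzero only.
.end_pair_values <- function(table, nonzero = FALSE) {
  v <- table$values[upper.tri(table$values)]
  v <- v[!is.na(v)]
  if (nonzero) v <- v[v > 0]
  v
}

#' Signal-to-noise ratio of an end-contact table
#'
#' SNR = median contact over truly adjacent end pairs (signal) divided by the
#' median over all other cross-contig end pairs (noise). Used to diagnose
#' how well a given end-window size separates neighbor from non-neighbor
#' contig linkages; it degrades as the window grows.
#'
#' @param table an `end_contact_table`.
#' @param truth_adjacent data.frame of truly adjacent end pairs with columns
#'   `contig1`, `side1`, `contig2`, `side2` (pairs whose contigs are absent
#'   from the table are ignored).
#' @return the SNR (``Inf`` when the noise median is 0).
#' @export
compute_snr <- function(table, truth_adjacent) {
  k1 <- .end_key(truth_adjacent$contig1, truth_adjacent$side1)
  k2 <- .end_key(truth_adjacent$contig2, truth_adjacent$side2)
  present <- k1 %in% table$ends$key & k2 %in% table$ends$key
  k1 <- k1[present]
  k2 <- k2[present]
  if (length(k1) == 0L) stop("no signal (adjacent) end pairs in the table")
  sig <- end_contact_value(table, k1, k2)
  # noise = every other cross-contig pair, zeros included
  sig_idx <- cbind(pmin(match(k1, table$ends$key), match(k2, table$ends$key)),
                   pmax(match(k1, table$ends$key), match(k2, table$ends$key)))
  V <- table$values
  V[sig_idx] <- NA_real_
  noise <- V[upper.tri(V)]
  noise <- noise[!is.na(noise)]
  if (length(noise) == 0L) stop("no noise (non-adjacent) end pairs in the table")
  ms <- stats::median(sig)
  mn <- stats::median(noise)
  if (mn == 0) return(Inf)
  ms / mn
}
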