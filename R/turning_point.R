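#' Locate the signal/noise turning point of sorted contact values
#'
#' Sorts the contact values in descending order, min-max normalizes both the
#' rank axis and the value axis to `[0, 1]` (so the curve runs from `(0, 1)`
#' to `(1, 0)`), rotates the curve 45 degrees anticlockwise, and returns the
#' point with the lowest rotated ordinate - the knee separating the few large
#' adjacent-pair (signal) values from the background (noise) values. On the
#' normalized descending curve this is exactly `argmin(x + y)`; ties go to
#' the smaller rank (larger value), which yields the more conservative,
#' higher cutoff.
#'
#' Zero values are excluded before ranking (only materialized nonzero
#' contacts are informative).
#'
#' @param values numeric vector of contact values (an `end_contact_table` is
#'   also accepted, in which case its nonzero cross-contig values are used).
#' @return a `turning_point`: list with `rank` (1-based index in the
#'   descending-sorted vector), `value` (the basic cutoff T) and `n` (number
#'   of ranked values).
#' @export
find_turning_point <- function(values) {
  if (inherits(values, "end_contact_table"))
    values <- .end_pair_values(values, nonzero = TRUE)
  values <- values[!is.na(values)]
  values <- values[values > 0]
  n <- length(values)
  if (n < 3L || max(values) == min(values))
    stop("cannot locate a turning point (need >= 3 non-identical nonzero ",
         "contact values); set the contact cutoff manually")
  v <- sort(values, decreasing = TRUE)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (v - v[n]) / (v[1L] - v[n])
  r <- which.min(x + y) # first minimum = smallest rank on ties
  structure(list(rank = r, value = v[r], n = n), class = "turning_point")
}

#' Derive contact cutoffs from a turning point
#'
#' The turning point usually falls in the top part of the noise values, so
#' cutoffs are taken as multiples of it; the consensus grid spans multipliers
#' 1 to 5 in steps of 0.5.
#'
#' @param tp a `turning_point` (or a single basic cutoff value).
#' @param multipliers positive multipliers, order preserved.
#' @return numeric vector of cutoffs `multiplier * T`.
#' @export
derive_cutoffs <- function(tp, multipliers = seq(1, 5, by = 0.5)) {
  stopifnot(all(multipliers > 0))
  t0 <- if (inherits(tp, "turning_point")) tp$value else as.numeric(tp)
  multipliers * t0
}

#' @export
print.turning_point <- function(x, ...) {
  cat("turning point: value ", format(x$value), " at rank ", x$rank, " of ",
      x$n, " sorted contact values\n", sep = "")
  invisible(x)
}
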