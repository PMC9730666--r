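#' Construct a bin table
#'
#' A bin table maps each fixed-width genome bin (100 kb by default, the
#' HiC-Pro convention) to its contig and contig-local coordinates.
#' Coordinates are BED-style 0-based half-open; bin ids are taken verbatim
#' from the source (HiC-Pro uses 1-based ids).
#'
#' @param df data.frame with columns `contig`, `start`, `end`, `bin`.
#' @param bin_size bin width in bp (default 100,000).
#' @param validate check invariants: unique ids, contiguous tiling within
#'   each contig, full-width bins except possibly the last of a contig.
#' @param increasing_ids additionally require bin ids to be strictly
#'   increasing in row order (true for HiC-Pro files; super-assemblies built
#'   between scaffolding rounds reorder bins and set this to `FALSE`).
#' @return a `bin_table` (data.frame with attribute `bin_size`).
#' @export
bin_table <- function(df, bin_size = 1e5, validate = TRUE,
                      increasing_ids = TRUE) {
  df <- data.frame(contig = as.character(df$contig),
                   start = as.numeric(df$start),
                   end = as.numeric(df$end),
                   bin = as.integer(df$bin),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "bin_size") <- bin_size
  class(df) <- c("bin_table", "data.frame")
  if (validate) validate_bin_table(df, increasing_ids = increasing_ids)
  df
}

#' @rdname bin_table
#' @param x a `bin_table`.
#' @export
validate_bin_table <- function(x, increasing_ids = TRUE) {
  if (nrow(x) == 0L) return(invisible(x))
  b <- attr(x, "bin_size")
  if (anyDuplicated(x$bin)) stop("bin ids are not unique")
  if (increasing_ids && is.unsorted(x$bin, strictly = TRUE))
    stop("bin ids are not strictly increasing")
  if (any(x$start >= x$end)) stop("bin with start >= end")
  for (ctg in unique(x$contig)) {
    rows <- x[x$contig == ctg, , drop = FALSE]
    if (rows$start[1L] != 0)
      stop("bins of contig '", ctg, "' do not start at 0")
    if (nrow(rows) > 1L && any(rows$start[-1L] != rows$end[-nrow(rows)]))
      stop("bins of contig '", ctg, "' do not tile contiguously")
    w <- rows$end - rows$start
    if (any(w[-nrow(rows)] != b))
      stop("non-terminal bin of contig '", ctg, "' has width != bin_size")
    if (w[nrow(rows)] > b)
      stop("terminal bin of contig '", ctg, "' wider than bin_size")
  }
  invisible(x)
}

#' Read a HiC-Pro bin definition file
#'
#' Parses the HiC-Pro `*_abs.bed` file: tab-separated `contig start end
#' bin_id`, 0-based half-open coordinates, one row per bin.
#'
#' @param path file path.
#' @param bin_size expected bin width in bp.
#' @return a [bin_table].
#' @examples
#' tf <- tempfile()
#' writeLines(c("ctgA\t0\t100000\t1", "ctgA\t100000\t150000\t2"), tf)
#' read_bin_table(tf)
#' @export
read_bin_table <- function(path, bin_size = 1e5) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(bin_table(data.frame(contig = character(), start = numeric(),
                                end = numeric(), bin = integer())))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 4L)
  if (length(bad) > 0L)
    stop("malformed bin table line ", bad[1L], ": expected >= 4 tab-separated",
         " fields, got ", nf[bad[1L]])
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bin <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(bin))
  if (length(bad) > 0L)
    stop("malformed bin table line ", bad[1L], ": non-numeric coordinate or id")
  bin_table(data.frame(contig = vapply(parts, `[[`, "", 1L),
                       start = start, end = end, bin = bin),
            bin_size = bin_size)
}

#' Contig lengths implied by a bin table
#'
#' @param bins a [bin_table].
#' @return named numeric vector of contig lengths in bp (order of first
#'   appearance).
#' @export
contig_lengths <- function(bins) {
  ctg <- unique(bins$contig)
  len <- vapply(ctg, function(c) max(bins$end[bins$contig == c]), 0)
  names(len) <- ctg
  len
}

# Row indices of a contig's bins, in stored (contig-local) order.
.contig_rows <- function(bins, contig) which(bins$contig == contig)

#' @export
print.bin_table <- function(x, ...) {
  cat("bin_table:", nrow(x), "bins,", length(unique(x$contig)),
      "contigs, bin size", attr(x, "bin_size"), "bp\n")
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}
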