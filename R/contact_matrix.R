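#' Construct a sparse contact matrix
#'
#' Triplet representation of the symmetric bin-pair contact matrix, as
#' written by HiC-Pro: one `(i, j, value)` row per nonzero pair. Triplets are
#' normalized so `i <= j`; mirrored or duplicate entries are collapsed by
#' summation. Access is symmetric: `value(i, j) == value(j, i)`.
#'
#' @param df data.frame with columns `i`, `j`, `value`.
#' @param flavor `"raw"` (integer counts) or `"normalized"` (ICE-balanced).
#' @param bins optional [bin_table]; if given, every bin id must exist in it.
#' @return a `contact_matrix` (data.frame with attribute `flavor`).
#' @export
contact_matrix <- function(df, flavor = c("raw", "normalized"), bins = NULL) {
  flavor <- match.arg(flavor)
  if (nrow(df) == 0L) {
    out <- data.frame(i = integer(), j = integer(), value = numeric())
  } else {
    if (any(df$value < 0)) stop("negative contact value")
    i <- pmin(df$i, df$j)
    j <- pmax(df$i, df$j)
    dt <- data.table::data.table(i = as.integer(i), j = as.integer(j),
                                 value = as.numeric(df$value))
    dt <- dt[, list(value = sum(value)), by = c("i", "j")]
    data.table::setorder(dt, i, j)
    out <- as.data.frame(dt)
  }
  if (!is.null(bins)) {
    miss <- setdiff(unique(c(out$i, out$j)), bins$bin)
    if (length(miss) > 0L)
      stop("contact matrix references bin ids absent from the bin table: ",
           paste(utils::head(miss, 5L), collapse = ", "))
  }
  attr(out, "flavor") <- flavor
  class(out) <- c("contact_matrix", "data.frame")
  out
}

#' Read a HiC-Pro sparse matrix file
#'
#' Parses the HiC-Pro `.matrix` file: tab-separated `bin_i bin_j value`
#' triplets (raw counts or ICE-normalized intensities). Mirrored duplicates
#' are collapsed by summation so the result stores the upper triangle only.
#'
#' @param path file path.
#' @param bins companion [bin_table]; all bin ids must exist in it.
#' @param flavor `"raw"` or `"normalized"`.
#' @return a [contact_matrix].
#' @export
read_contact_matrix <- function(path, bins, flavor = c("raw", "normalized")) {
  flavor <- match.arg(flavor)
  if (file.size(path) == 0L)
    return(contact_matrix(data.frame(i = integer(), j = integer(),
                                     value = numeric()), flavor, bins))
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      col.names = c("i", "j", "value"),
                      colClasses = list(integer = 1:2, numeric = 3)),
    error = function(e) stop("malformed contact matrix file '", path, "': ",
                             conditionMessage(e)))
  contact_matrix(as.data.frame(dt), flavor, bins)
}

#' Symmetric contact value lookup
#'
#' @param mat a [contact_matrix].
#' @param i,j bin id vectors (recycled); order is irrelevant.
#' @return numeric vector of values, 0 where no triplet is stored.
#' @export
contact_value <- function(mat, i, j) .lookup_values(mat, i, j)

#' Zero out all contacts touching a set of bins
#'
#' Emulates unmappable (repeat-suppressed) genomic regions by removing every
#' triplet involving the given bins, as used for fixtures whose contig-end
#' link density is suppressed.
#'
#' @param mat a [contact_matrix].
#' @param bin_ids bins whose contacts are removed.
#' @return the filtered [contact_matrix].
#' @export
mask_bins <- function(mat, bin_ids) {
  keep <- !(mat$i %in% bin_ids | mat$j %in% bin_ids)
  out <- as.data.frame(mat)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flavor") <- attr(mat, "flavor")
  class(out) <- c("contact_matrix", "data.frame")
  out
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix (", attr(x, "flavor"), "): ", nrow(x),
      " nonzero bin pairs\n", sep = "")
  invisible(x)
}
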