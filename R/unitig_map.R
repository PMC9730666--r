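#' Read a unitig-to-contig map (TSV)
#'
#' The canonical internal form of the unitig map: four tab-separated columns
#' `contig unitig start end` (contig-local, 0-based half-open). Intervals of
#' one contig must be sorted and non-overlapping.
#'
#' @param path file path.
#' @return a `unitig_map` data.frame.
#' @export
read_unitig_map <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("contig", "unitig", "start", "end"))
  unitig_map(as.data.frame(dt))
}

#' @rdname read_unitig_map
#' @param df data.frame with columns `contig`, `unitig`, `start`, `end`.
#' @export
unitig_map <- function(df) {
  df <- data.frame(contig = as.character(df$contig),
                   unitig = as.character(df$unitig),
                   start = as.numeric(df$start),
                   end = as.numeric(df$end), stringsAsFactors = FALSE)
  df <- df[.radix_order(df$contig, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (ctg in unique(df$contig)) {
    rows <- df[df$contig == ctg, , drop = FALSE]
    if (any(rows$start < 0) || any(rows$start >= rows$end))
      stop("invalid unitig interval on contig '", ctg, "'")
    if (nrow(rows) > 1L && any(rows$start[-1L] < rows$end[-nrow(rows)]))
      stop("overlapping unitig intervals on contig '", ctg, "'")
  }
  class(df) <- c("unitig_map", "data.frame")
  df
}

#' Derive the unitig-to-contig map from assembler GFA files
#'
#' Reads the unitig-level and contig-level GFA files of a string-graph
#' assembler (the hifiasm `*.noseq.gfa` dialect) and infers, from shared
#' read placements (`A` lines), which interval of each contig is covered by
#' each unitig. A unitig whose reads land on several contigs is reported on
#' each over its local interval.
#'
#' @param utg_gfa unitig-level GFA file (`A` lines place reads on unitigs).
#' @param ctg_gfa contig-level GFA file (`A` lines place reads on contigs).
#' @return a `unitig_map` data.frame with columns `contig`, `unitig`,
#'   `start`, `end` (contig-local bp).
#' @export
parse_unitig_map <- function(utg_gfa, ctg_gfa) {
  utg <- .read_gfa_placements(utg_gfa)
  ctg <- .read_gfa_placements(ctg_gfa)
  if (nrow(utg) == 0L || nrow(ctg) == 0L)
    stop("no read-placement ('A') lines found; this GFA dialect is not ",
         "supported - supply a 4-column TSV map via read_unitig_map() instead")
  read2utg <- utg[, c("read", "seg")]
  names(read2utg)[2L] <- "unitig"
  m <- merge(ctg, read2utg, by = "read")
  if (nrow(m) == 0L)
    return(unitig_map(data.frame(contig = character(), unitig = character(),
                                 start = numeric(), end = numeric())))
  dt <- data.table::as.data.table(m)
  res <- dt[, list(start = min(start), end = max(end)),
            by = c("seg", "unitig")]
  names(res)[1L] <- "contig"
  res <- as.data.frame(res)
  res <- res[.radix_order(res$contig, res$start), , drop = FALSE]
  # clip rare overlaps from reads spanning unitig joins
  for (ctg_id in unique(res$contig)) {
    rows <- which(res$contig == ctg_id)
    if (length(rows) > 1L) {
      for (k in seq_along(rows)[-1L]) {
        prev_end <- res$end[rows[k - 1L]]
        if (res$start[rows[k]] < prev_end) res$start[rows[k]] <- prev_end
      }
    }
  }
  res <- res[res$start < res$end, , drop = FALSE]
  unitig_map(res)
}

# Parse GFA 'A' lines: A <seg> <pos> <strand> <read> <read_start> <read_end>
.read_gfa_placements <- function(path) {
  lines <- readLines(path)
  a <- lines[startsWith(lines, "A\t")]
  if (length(a) == 0L)
    return(data.frame(seg = character(), read = character(),
                      start = numeric(), end = numeric()))
  parts <- strsplit(a, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 7L))
    stop("malformed GFA 'A' line in '", path, "' (fewer than 7 fields)")
  pos <- as.numeric(vapply(parts, `[[`, "", 3L))
  qs <- as.numeric(vapply(parts, `[[`, "", 6L))
  qe <- as.numeric(vapply(parts, `[[`, "", 7L))
  data.frame(seg = vapply(parts, `[[`, "", 2L),
             read = vapply(parts, `[[`, "", 5L),
             start = pos, end = pos + (qe - qs), stringsAsFactors = FALSE)
}

# Internal unitig boundaries (bp positions strictly inside the contig).
.unitig_boundaries <- function(umap, contig, contig_length = NULL) {
  rows <- umap[umap$contig == contig, , drop = FALSE]
  if (nrow(rows) == 0L) return(numeric(0))
  b <- sort(unique(c(rows$start, rows$end)))
  b <- b[b > 0]
  if (!is.null(contig_length)) b <- b[b < contig_length]
  b
}
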