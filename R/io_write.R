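#' Write a scaffolding graph as GFA1
#'
#' One `S` line per contig (sequence `*`, `LN` tag) and one `L` line per
#' link edge with a 0-length overlap (`0M`), viewable in Bandage. Strands
#' follow the end-pair geometry: for the left contig, a link at its tail
#' gives `+` and at its head gives `-`; the opposite rule applies to the
#' right contig (a link at its head gives `+`, at its tail `-`). The left
#' contig of an edge is the one with the smaller name (byte order).
#'
#' @param graph a `scaffold_graph`.
#' @param contig_lengths named vector of contig lengths in bp.
#' @param path output file.
#' @export
write_gfa <- function(graph, contig_lengths, path) {
  ctgs <- unique(graph$ends$contig)
  ctgs <- ctgs[.radix_order(ctgs)]
  s_lines <- sprintf("S\t%s\t*\tLN:i:%d", ctgs,
                     as.integer(contig_lengths[ctgs]))
  l_lines <- character(0)
  e <- graph$edges
  if (!is.null(e) && nrow(e) > 0L) {
    l_lines <- vapply(seq_len(nrow(e)), function(k) {
      k1 <- e$key1[k]; k2 <- e$key2[k]
      if (.str_lt(.key_contig(k2), .key_contig(k1))) { tmp <- k1; k1 <- k2; k2 <- tmp }
      s1 <- if (.key_side(k1) == "tail") "+" else "-"
      s2 <- if (.key_side(k2) == "head") "+" else "-"
      sprintf("L\t%s\t%s\t%s\t%s\t0M", .key_contig(k1), s1, .key_contig(k2), s2)
    }, "")
  }
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), path)
  invisible(path)
}

#' Write clusters as AGP v2.1
#'
#' `W` components in cluster order and orientation, separated by `U` gap
#' records (gap type `scaffold`, linkage `yes`, evidence
#' `proximity_ligation`).
#'
#' @param clusters a `cluster_set`.
#' @param contig_lengths named vector of contig lengths in bp.
#' @param path output file (`NULL` to only return the records).
#' @param gap_len gap length in bp between consecutive components.
#' @return (invisibly) the AGP records as a data.frame; columns 6-9 hold the
#'   component fields for `W` rows and the gap fields for `U` rows.
#' @export
write_agp <- function(clusters, contig_lengths, path, gap_len = 100) {
  recs <- list()
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    if (any(!cl$contig %in% names(contig_lengths)))
      stop("unknown contig length for: ",
           paste(setdiff(cl$contig, names(contig_lengths)), collapse = ", "))
    obj <- sprintf("scaffold_%02d", k)
    pos <- 0
    part <- 0L
    for (q in seq_along(cl$contig)) {
      if (q > 1L) {
        part <- part + 1L
        recs[[length(recs) + 1L]] <- data.frame(
          object = obj, object_beg = pos + 1, object_end = pos + gap_len,
          part_number = part, component_type = "U",
          f6 = as.character(gap_len), f7 = "scaffold", f8 = "yes",
          f9 = "proximity_ligation", stringsAsFactors = FALSE)
        pos <- pos + gap_len
      }
      len <- as.numeric(contig_lengths[[cl$contig[q]]])
      part <- part + 1L
      recs[[length(recs) + 1L]] <- data.frame(
        object = obj, object_beg = pos + 1, object_end = pos + len,
        part_number = part, component_type = "W",
        f6 = cl$contig[q], f7 = "1", f8 = format(len, scientific = FALSE),
        f9 = cl$orient[q], stringsAsFactors = FALSE)
      pos <- pos + len
    }
  }
  agp <- if (length(recs) > 0L) do.call(rbind, recs) else
    data.frame(object = character(), object_beg = numeric(),
               object_end = numeric(), part_number = integer(),
               component_type = character(), f6 = character(),
               f7 = character(), f8 = character(), f9 = character())
  if (!is.null(path)) {
    lines <- c("##agp-version\t2.1",
               sprintf("%s\t%s\t%s\t%d\t%s\t%s\t%s\t%s\t%s",
                       agp$object,
                       format(agp$object_beg, scientific = FALSE, trim = TRUE),
                       format(agp$object_end, scientific = FALSE, trim = TRUE),
                       agp$part_number, agp$component_type,
                       agp$f6, agp$f7, agp$f8, agp$f9))
    writeLines(lines, path)
  }
  invisible(agp)
}

#' Read an AGP file written by [write_agp()]
#' @param path AGP file.
#' @return AGP records data.frame.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L)) stop("malformed AGP record")
  data.frame(object = vapply(parts, `[[`, "", 1L),
             object_beg = as.numeric(vapply(parts, `[[`, "", 2L)),
             object_end = as.numeric(vapply(parts, `[[`, "", 3L)),
             part_number = as.integer(vapply(parts, `[[`, "", 4L)),
             component_type = vapply(parts, `[[`, "", 5L),
             f6 = vapply(parts, `[[`, "", 6L),
             f7 = vapply(parts, `[[`, "", 7L),
             f8 = vapply(parts, `[[`, "", 8L),
             f9 = vapply(parts, `[[`, "", 9L), stringsAsFactors = FALSE)
}

#' Assemble scaffold sequences from AGP records
#'
#' Concatenates contig sequences per AGP scaffold, reverse-complementing
#' `-` components and inserting `N` runs for `U` gap records. The resulting
#' sequence length always equals the scaffold's final `object_end`.
#'
#' @param agp AGP records (data.frame from [write_agp()] / [read_agp()]) or
#'   a path to an AGP file.
#' @param contigs_fasta path to the contig FASTA (or a
#'   [Biostrings::DNAStringSet]).
#' @param path output FASTA file.
#' @export
emit_scaffold_fasta <- function(agp, contigs_fasta, path) {
  if (is.character(agp)) agp <- read_agp(agp)
  seqs <- if (inherits(contigs_fasta, "DNAStringSet")) contigs_fasta
          else Biostrings::readDNAStringSet(contigs_fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- Biostrings::DNAStringSet()
  for (obj in unique(agp$object)) {
    rows <- agp[agp$object == obj, , drop = FALSE]
    pieces <- character(nrow(rows))
    for (k in seq_len(nrow(rows))) {
      if (rows$component_type[k] == "U") {
        pieces[k] <- strrep("N", as.integer(rows$f6[k]))
      } else {
        id <- rows$f6[k]
        if (!id %in% names(seqs))
          stop("component sequence missing from FASTA: ", id)
        s <- Biostrings::subseq(seqs[[id]], as.numeric(rows$f7[k]),
                                as.numeric(rows$f8[k]))
        if (rows$f9[k] == "-") s <- Biostrings::reverseComplement(s)
        pieces[k] <- as.character(s)
      }
    }
    sc <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
    names(sc) <- obj
    out <- c(out, sc)
  }
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Write a HiC-Pro-format fixture to disk
#'
#' Writes `<prefix>_abs.bed`, `<prefix>_raw.matrix` and
#' `<prefix>_iced.matrix`, byte-compatible with [read_bin_table()] and
#' [read_contact_matrix()] (triplets sorted by `(i, j)`).
#'
#' @param bins a [bin_table].
#' @param raw,normalized the two [contact_matrix] flavors.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return named character vector of the three file paths.
#' @export
write_hicpro_fixture <- function(bins, raw, normalized, dir,
                                 prefix = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bed <- file.path(dir, paste0(prefix, "_abs.bed"))
  writeLines(sprintf("%s\t%s\t%s\t%d", bins$contig,
                     format(bins$start, scientific = FALSE, trim = TRUE),
                     format(bins$end, scientific = FALSE, trim = TRUE),
                     bins$bin), bed)
  .write_matrix <- function(mat, p) {
    m <- as.data.frame(mat)
    m <- m[order(m$i, m$j), , drop = FALSE]
    writeLines(sprintf("%d\t%d\t%s", m$i, m$j,
                       format(m$value, scientific = FALSE, trim = TRUE,
                              digits = 10)), p)
  }
  rawp <- file.path(dir, paste0(prefix, "_raw.matrix"))
  icedp <- file.path(dir, paste0(prefix, "_iced.matrix"))
  .write_matrix(raw, rawp)
  .write_matrix(normalized, icedp)
  c(bed = bed, raw = rawp, iced = icedp)
}
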