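#' Simulation specification for synthetic Hi-C fixtures
#'
#' Defines a multi-chromosome genome, its fragmentation into contigs, and a
#' distance-decay contact model: same-chromosome bin pairs at distance `d`
#' bins draw `Poisson(cis_scale * d^-decay_exponent)` links (contig
#' junctions included), different-chromosome pairs draw
#' `Poisson(trans_rate)`. Contig naming and bin numbering follow a shuffled
#' contig order so adjacency is hidden from bin ids.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_sizes chromosome sizes in bp; default: evenly spaced from
#'   30 Mb down to 15 Mb (plant-like mid-size chromosomes), rounded up to
#'   bin multiples.
#' @param bin_size bin width in bp.
#' @param contigs_per_chrom inclusive range `c(min, max)` of contigs per
#'   chromosome.
#' @param min_contig minimum contig size in bp.
#' @param decay_exponent power-law exponent of the cis distance decay.
#' @param cis_scale expected cis count at distance 1 bin.
#' @param trans_rate expected trans count per bin pair (default
#'   `cis_scale / 1000`).
#' @param seed RNG seed for the whole fixture.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_chrom = 5L, chrom_sizes = NULL, bin_size = 1e5,
                     contigs_per_chrom = c(1L, 6L), min_contig = 1e6,
                     decay_exponent = 1, cis_scale = 100,
                     trans_rate = cis_scale / 1000, seed = 1L) {
  if (is.null(chrom_sizes))
    chrom_sizes <- round(seq(30e6, 15e6, length.out = n_chrom))
  stopifnot(length(chrom_sizes) == n_chrom, all(chrom_sizes > 0),
            bin_size > 0, min_contig >= bin_size,
            length(contigs_per_chrom) == 2L,
            contigs_per_chrom[1L] >= 1L,
            contigs_per_chrom[2L] >= contigs_per_chrom[1L],
            decay_exponent > 0, cis_scale > 0, trans_rate > 0,
            trans_rate < cis_scale)
  structure(list(n_chrom = as.integer(n_chrom), chrom_sizes = chrom_sizes,
                 bin_size = bin_size,
                 contigs_per_chrom = as.integer(contigs_per_chrom),
                 min_contig = min_contig, decay_exponent = decay_exponent,
                 cis_scale = cis_scale, trans_rate = trans_rate,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Chromosome layout of a simulated genome
#'
#' @param spec a [sim_spec()].
#' @return data.frame `chrom`, `size` (bp, rounded up to a bin multiple,
#'   with a warning when rounding occurred), `n_bins`.
#' @export
simulate_genome_layout <- function(spec) {
  b <- spec$bin_size
  sz <- ceiling(spec$chrom_sizes / b) * b
  if (any(sz != spec$chrom_sizes))
    warning("chromosome sizes rounded up to bin multiples")
  data.frame(chrom = sprintf("chr%02d", seq_len(spec$n_chrom)),
             size = sz, n_bins = as.integer(sz / b),
             stringsAsFactors = FALSE)
}

#' Fragment chromosomes into contigs
#'
#' Each chromosome is split at uniformly drawn bin boundaries into
#' `k` contigs (k drawn from `contigs_per_chrom`, redrawn when infeasible),
#' all at least `min_contig` long (cut points rejection-resampled). All true
#' orientations are `+`; bin numbering later hides adjacency, so orientation
#' recovery is still exercised downstream.
#'
#' @param layout from [simulate_genome_layout()].
#' @param spec a [sim_spec()].
#' @return a `sim_truth` data.frame: `contig`, `chrom`, `ord` (position in
#'   chromosome), `start`, `end` (chromosome bp), `n_bins`. Contig names are
#'   assigned in shuffled order.
#' @export
fragment_chromosomes <- function(layout, spec) {
  b <- spec$bin_size
  min_bins <- as.integer(ceiling(spec$min_contig / b))
  pieces <- list()
  for (c_idx in seq_len(nrow(layout))) {
    nb <- layout$n_bins[c_idx]
    kmax_feasible <- nb %/% min_bins
    ks <- seq.int(spec$contigs_per_chrom[1L], spec$contigs_per_chrom[2L])
    if (all(ks > kmax_feasible))
      stop("chromosome ", layout$chrom[c_idx], " cannot hold ", min(ks),
           " contigs of at least ", spec$min_contig, " bp")
    repeat {
      k <- ks[sample.int(length(ks), 1L)] # guard the scalar-sample gotcha
      if (k <= kmax_feasible) break
    }
    # uniform over bin-boundary compositions with all parts >= min_bins
    # (stars and bars on the surplus bins; no rejection loop)
    seg <- rep(min_bins, k)
    extra <- nb - k * min_bins
    if (k > 1L && extra > 0L) {
      bars <- sort(sample.int(extra + k - 1L, k - 1L))
      seg <- seg + diff(c(0L, bars, extra + k)) - 1L
    } else if (k == 1L) {
      seg <- nb
    }
    bnd <- cumsum(c(0L, seg))
    for (q in seq_len(k)) {
      pieces[[length(pieces) + 1L]] <- data.frame(
        chrom = layout$chrom[c_idx], ord = q,
        start = bnd[q] * b, end = bnd[q + 1L] * b,
        n_bins = bnd[q + 1L] - bnd[q], stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, pieces)
  perm <- sample(nrow(truth))
  truth$contig <- NA_character_
  truth$contig[perm] <- sprintf("ctg%03d", seq_len(nrow(truth)))
  truth <- truth[, c("contig", "chrom", "ord", "start", "end", "n_bins")]
  class(truth) <- c("sim_truth", "data.frame")
  truth
}

#' Simulate the HiC-Pro style bin table and contact matrices
#'
#' Cis counts follow the power-law decay across the whole chromosome
#' (junction-crossing pairs included); trans counts are uniform background.
#' Bins are numbered in shuffled contig order. The normalized flavor is a
#' single row-balancing pass (each entry divided by the geometric mean of
#' its two row sums and rescaled to the mean row sum) standing in for ICE.
#'
#' @param layout from [simulate_genome_layout()].
#' @param truth from [fragment_chromosomes()].
#' @param spec a [sim_spec()].
#' @return list with `bins` ([bin_table]), `raw` and `normalized`
#'   ([contact_matrix]).
#' @export
simulate_contact_matrix <- function(layout, truth, spec) {
  b <- spec$bin_size
  # bin table rows in shuffled-contig order; ids sequential
  ord <- .radix_order(truth$contig)
  rows <- list()
  nxt <- 1L
  gstart <- cumsum(c(0L, layout$n_bins))[match(truth$chrom, layout$chrom)]
  g_of_id <- integer(sum(truth$n_bins)) # bin id -> genomic bin index
  for (t in ord) {
    nb <- truth$n_bins[t]
    ids <- seq.int(nxt, nxt + nb - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = truth$contig[t], start = (seq_len(nb) - 1L) * b,
      end = seq_len(nb) * b, bin = ids, stringsAsFactors = FALSE)
    g_of_id[ids] <- gstart[t] + truth$start[t] / b + seq_len(nb)
    nxt <- nxt + nb
  }
  bins <- bin_table(do.call(rbind, rows), bin_size = b)
  id_of_g <- integer(length(g_of_id))
  id_of_g[g_of_id] <- bins$bin # row order == id order by construction
  # cis: per chromosome, per distance d (accumulated in lists, bound once)
  acc_i <- list(); acc_j <- list(); acc_v <- list()
  off <- cumsum(c(0L, layout$n_bins))
  for (c_idx in seq_len(nrow(layout))) {
    nc <- layout$n_bins[c_idx]
    for (d in seq_len(nc - 1L)) {
      lam <- spec$cis_scale * d^(-spec$decay_exponent)
      cnt <- stats::rpois(nc - d, lam)
      nz <- which(cnt > 0L)
      if (length(nz) > 0L) {
        g1 <- off[c_idx] + nz
        acc_i[[length(acc_i) + 1L]] <- id_of_g[g1]
        acc_j[[length(acc_j) + 1L]] <- id_of_g[g1 + d]
        acc_v[[length(acc_v) + 1L]] <- cnt[nz]
      }
    }
  }
  # trans: all cross-chromosome pairs, chunked per chromosome pair
  for (a in seq_len(max(nrow(layout) - 1L, 0L))) {
    for (cb in seq.int(a + 1L, nrow(layout))) {
      na <- layout$n_bins[a]; nb2 <- layout$n_bins[cb]
      cnt <- stats::rpois(na * nb2, spec$trans_rate)
      nz <- which(cnt > 0L)
      if (length(nz) > 0L) {
        g1 <- off[a] + ((nz - 1L) %% na) + 1L
        g2 <- off[cb] + ((nz - 1L) %/% na) + 1L
        acc_i[[length(acc_i) + 1L]] <- id_of_g[g1]
        acc_j[[length(acc_j) + 1L]] <- id_of_g[g2]
        acc_v[[length(acc_v) + 1L]] <- cnt[nz]
      }
    }
  }
  raw <- contact_matrix(data.frame(i = unlist(acc_i), j = unlist(acc_j),
                                   value = unlist(acc_v)), "raw", bins)
  normalized <- .balance_matrix(raw, bins)
  list(bins = bins, raw = raw, normalized = normalized)
}

# One balancing pass: v' = v * mean(rowsum) / sqrt(r_i * r_j).
.balance_matrix <- function(raw, bins) {
  n <- nrow(bins)
  if (nrow(raw) == 0L)
    return(contact_matrix(as.data.frame(raw), "normalized", bins))
  r <- numeric(max(bins$bin))
  agg_i <- tapply(raw$value, raw$i, sum)
  agg_j <- tapply(raw$value[raw$i != raw$j], raw$j[raw$i != raw$j], sum)
  r[as.integer(names(agg_i))] <- r[as.integer(names(agg_i))] + agg_i
  if (length(agg_j) > 0L)
    r[as.integer(names(agg_j))] <- r[as.integer(names(agg_j))] + agg_j
  target <- mean(r[bins$bin])
  v <- raw$value * target / sqrt(r[raw$i] * r[raw$j])
  contact_matrix(data.frame(i = raw$i, j = raw$j, value = v),
                 "normalized", bins)
}

#' Generate a complete synthetic assembly fixture
#'
#' Seeds the RNG from `spec$seed` and runs layout, fragmentation and matrix
#' simulation. Also tabulates the truly adjacent contig-end pairs (tail of
#' each contig to head of its right neighbor) used as signal truth.
#'
#' @param spec a [sim_spec()].
#' @return list: `spec`, `layout`, `truth`, `bins`, `raw`, `normalized`,
#'   `adjacent` (data.frame `contig1`, `side1`, `contig2`, `side2`).
#' @export
simulate_assembly <- function(spec = sim_spec()) {
  set.seed(spec$seed)
  layout <- suppressWarnings(simulate_genome_layout(spec))
  truth <- fragment_chromosomes(layout, spec)
  sim <- simulate_contact_matrix(layout, truth, spec)
  adj <- list()
  for (ch in unique(truth$chrom)) {
    tr <- truth[truth$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$ord), , drop = FALSE]
    if (nrow(tr) > 1L) {
      for (q in seq_len(nrow(tr) - 1L)) {
        adj[[length(adj) + 1L]] <- data.frame(
          contig1 = tr$contig[q], side1 = "tail",
          contig2 = tr$contig[q + 1L], side2 = "head",
          stringsAsFactors = FALSE)
      }
    }
  }
  adjacent <- if (length(adj) > 0L) do.call(rbind, adj) else
    data.frame(contig1 = character(), side1 = character(),
               contig2 = character(), side2 = character())
  c(sim, list(spec = spec, layout = layout, truth = truth,
              adjacent = adjacent))
}

#' Inject mis-join errors into a simulated assembly
#'
#' Each error concatenates two whole contigs drawn from non-adjacent genomic
#' loci (different chromosomes) into one erroneous contig, the junction
#' falling on a bin boundary. Bin ids are untouched, so the matrices remain
#' valid for the true layout and the junction shows a contact trough.
#'
#' @param sim a fixture from [simulate_assembly()].
#' @param n_errors number of erroneous contigs to create.
#' @param seed RNG seed for the pairing.
#' @return list: `bins` (rewritten [bin_table]), `breakpoints` (truth:
#'   `contig`, `position` bp), `erroneous`, `clean` (contig name vectors).
#' @export
inject_misjoins <- function(sim, n_errors, seed = 1L) {
  if (n_errors == 0L)
    return(list(bins = sim$bins, breakpoints = data.frame(
      contig = character(), position = numeric()),
      erroneous = character(0), clean = unique(sim$bins$contig)))
  set.seed(seed)
  truth <- sim$truth
  pool <- truth$contig[sample(nrow(truth))]
  chrom_of <- stats::setNames(truth$chrom, truth$contig)
  pairs <- list()
  used <- character(0)
  for (a in pool) {
    if (length(pairs) == n_errors) break
    if (a %in% used) next
    partner <- setdiff(pool[chrom_of[pool] != chrom_of[a]], c(used, a))
    if (length(partner) == 0L) next
    pairs[[length(pairs) + 1L]] <- c(a, partner[1L])
    used <- c(used, a, partner[1L])
  }
  if (length(pairs) < n_errors)
    stop("cannot form ", n_errors, " non-adjacent contig pairs")
  df <- as.data.frame(sim$bins)
  bp <- list()
  err <- character(0)
  for (p in pairs) {
    ra <- df[df$contig == p[1L], , drop = FALSE]
    rb <- df[df$contig == p[2L], , drop = FALSE]
    la <- max(ra$end)
    new_id <- paste0(p[1L], "m", p[2L])
    rb$start <- rb$start + la
    rb$end <- rb$end + la
    seg <- rbind(ra, rb)
    seg$contig <- new_id
    df <- rbind(df[!(df$contig %in% p), , drop = FALSE], seg)
    bp[[length(bp) + 1L]] <- data.frame(contig = new_id, position = la,
                                        stringsAsFactors = FALSE)
    err <- c(err, new_id)
  }
  bins <- bin_table(df, bin_size = attr(sim$bins, "bin_size"),
                    validate = TRUE, increasing_ids = FALSE)
  list(bins = bins, breakpoints = do.call(rbind, bp), erroneous = err,
       clean = setdiff(unique(bins$contig), err))
}
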