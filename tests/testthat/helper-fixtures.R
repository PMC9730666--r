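# Shared fixture builders and independent oracles. Everything is generated
# in code; no files ship with the tests.

# hand-built bin table: two contigs (10 + 4 bins of 100 kb)
tiny_bins <- function() {
  bin_table(data.frame(
    contig = c(rep("ctgA", 10), rep("ctgB", 4)),
    start = c(0:9, 0:3) * 1e5,
    end = c(1:10, 1:4) * 1e5,
    bin = 1:14))
}

mk_matrix <- function(i, j, value, flavor = "raw") {
  contact_matrix(data.frame(i = i, j = j, value = value), flavor)
}

# scaffold graph built directly from an edge list
mk_graph <- function(contigs, key1 = character(0), key2 = character(0),
                     weight = numeric(0)) {
  ends <- data.frame(contig = rep(contigs, each = 2),
                     side = rep(c("head", "tail"), length(contigs)),
                     stringsAsFactors = FALSE)
  ends$key <- paste(ends$contig, ends$side, sep = ":")
  structure(list(ends = ends,
                 edges = data.frame(key1 = key1, key2 = key2,
                                    weight = weight,
                                    stringsAsFactors = FALSE)),
            class = "scaffold_graph")
}

# default-condition synthetic assembly used by the desk-scale checks:
# 5 chromosomes (40/35/30/30/25 Mb), 3-6 contigs each, contigs >= 5 Mb so
# every contig clears twice the largest default end window
recovery_spec <- function(seed) {
  sim_spec(n_chrom = 5, chrom_sizes = c(40e6, 35e6, 30e6, 30e6, 25e6),
           contigs_per_chrom = c(3, 6), min_contig = 5e6,
           decay_exponent = 1, cis_scale = 100, trans_rate = 0.1,
           seed = seed)
}

# quick 2-chromosome variant for cheaper tests
small_spec <- function(seed) {
  sim_spec(n_chrom = 2, chrom_sizes = c(30e6, 25e6),
           contigs_per_chrom = c(3, 5), min_contig = 5e6, seed = seed)
}

# canonical cluster keys of the true chromosome partition
truth_cluster_keys <- function(sim) {
  ks <- character(0)
  for (ch in unique(sim$truth$chrom)) {
    tr <- sim$truth[sim$truth$chrom == ch, ]
    tr <- tr[order(tr$ord), ]
    ks <- c(ks, cluster_key(list(contig = tr$contig,
                                 orient = rep("+", nrow(tr)))))
  }
  sort(ks)
}

cluster_key <- function(cl) {
  cl <- canonicalize_cluster(cl)
  paste(paste0(cl$contig, cl$orient), collapse = ";")
}

consensus_keys <- function(cons) sort(vapply(cons, cluster_key, ""))

# repeat-suppressed fixture: 3 chromosomes x 3 contigs of 30 Mb; all
# contacts of the 25 bins flanking the second junction of each chromosome
# are zeroed, so round-1 windows (<= 25 bins) cannot see across it
masked_fixture <- function(seed) {
  spec <- sim_spec(n_chrom = 3, chrom_sizes = rep(90e6, 3),
                   contigs_per_chrom = c(3, 3), min_contig = 25e6,
                   cis_scale = 1000, trans_rate = 0.1, seed = seed)
  sim <- simulate_assembly(spec)
  masked <- integer(0)
  for (ch in unique(sim$truth$chrom)) {
    tr <- sim$truth[sim$truth$chrom == ch, ]
    tr <- tr[order(tr$ord), ]
    b2 <- sim$bins$bin[sim$bins$contig == tr$contig[2]]
    b3 <- sim$bins$bin[sim$bins$contig == tr$contig[3]]
    masked <- c(masked, utils::tail(b2, 25), utils::head(b3, 25))
  }
  sim$raw <- mask_bins(sim$raw, masked)
  sim$normalized <- mask_bins(sim$normalized, masked)
  sim
}

# independent oracle: literal 45-degree anticlockwise rotation of the
# normalized descending curve; index of the lowest rotated ordinate
oracle_knee <- function(values) {
  v <- sort(values[values > 0], decreasing = TRUE)
  n <- length(v)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (v - v[n]) / (v[1] - v[n])
  # sin(45deg) == cos(45deg) == 1/sqrt(2) exactly; using the shared constant
  # keeps genuine ties tied (R's sin(pi/4) and cos(pi/4) differ by 1 ulp)
  s45 <- 1 / sqrt(2)
  y_rot <- x * s45 + y * s45
  r <- which.min(y_rot)
  list(rank = r, value = v[r])
}

# independent oracle: an edge is reciprocal-best iff every other edge at
# either endpoint is strictly lighter
oracle_reciprocal_best <- function(edges) {
  keep <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    a <- edges$key1[k]; b <- edges$key2[k]; w <- edges$weight[k]
    others <- edges[-k, , drop = FALSE]
    inc_a <- others$weight[others$key1 == a | others$key2 == a]
    inc_b <- others$weight[others$key1 == b | others$key2 == b]
    keep[k] <- all(inc_a < w) && all(inc_b < w)
  }
  keep
}

# independent acyclicity check on the contig graph: every connected
# component of the link edges must have (#links == #contigs - 1)
oracle_acyclic <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0) return(TRUE)
  c1 <- sub(":(head|tail)$", "", e$key1)
  c2 <- sub(":(head|tail)$", "", e$key2)
  ctgs <- unique(c(c1, c2))
  parent <- stats::setNames(ctgs, ctgs)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_along(c1)) parent[[find(c1[k])]] <- find(c2[k])
  comp <- vapply(ctgs, find, "")
  for (cc in unique(comp)) {
    members <- ctgs[comp == cc]
    n_links <- sum(c1 %in% members)
    if (n_links != length(members) - 1) return(FALSE)
  }
  TRUE
}

# random end-contact edge list over n contigs (integer weights force ties)
random_edges <- function(n_contigs, n_edges, max_w = 20L) {
  keys <- as.vector(outer(sprintf("c%d", seq_len(n_contigs)),
                          c("head", "tail"), paste, sep = ":"))
  cand <- t(utils::combn(keys, 2))
  cross <- sub(":.*", "", cand[, 1]) != sub(":.*", "", cand[, 2])
  cand <- cand[cross, , drop = FALSE]
  pick <- sample.int(nrow(cand), min(n_edges, nrow(cand)))
  data.frame(key1 = cand[pick, 1], key2 = cand[pick, 2],
             weight = sample.int(max_w, length(pick), replace = TRUE),
             stringsAsFactors = FALSE)
}
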