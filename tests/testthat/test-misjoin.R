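misjoin_bins <- function(n_bins, contig = "ctgA") {
  bin_table(data.frame(contig = contig, start = (seq_len(n_bins) - 1) * 1e5,
                       end = seq_len(n_bins) * 1e5, bin = seq_len(n_bins)))
}

test_that("contact profiles enumerate in-contig pairs at the gap distance", {
  bins <- misjoin_bins(8)
  mat <- mk_matrix(c(1, 3), c(6, 8), c(11, 13))
  prof <- adjacent_contact_profile("ctgA", bins, mat, gap_bins = 5)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$left_bin, 1:3)
  expect_equal(prof$right_bin, 6:8)
  expect_equal(prof$value, c(11, 0, 13)) # absent pair (2,7) -> 0
  expect_equal(prof$midpoint, c(3e5, 4e5, 5e5))
  # a contig with <= gap_bins bins yields an empty profile, not an error
  expect_equal(nrow(adjacent_contact_profile("ctgA", misjoin_bins(5), mat)),
               0)
})

test_that("genome-wide gap-contact median follows the median convention", {
  mat3 <- mk_matrix(1:3, 6:8, c(10, 20, 30))
  expect_equal(genome_median_gap_contact(misjoin_bins(8), mat3), 20)
  mat4 <- mk_matrix(1:4, 6:9, c(10, 20, 30, 40))
  expect_equal(genome_median_gap_contact(misjoin_bins(9), mat4), 25)
  mat1 <- mk_matrix(1, 6, 7)
  expect_equal(genome_median_gap_contact(misjoin_bins(6), mat1), 7)
  expect_error(genome_median_gap_contact(misjoin_bins(3), mat1), "no in-contig")
})

test_that("low-contact runs collapse to one breakpoint at the trough", {
  bins <- misjoin_bins(11)
  vals <- c(50, 48, 52, 3, 49, 51)
  mat <- mk_matrix(1:6, 6:11, vals)
  prof <- adjacent_contact_profile("ctgA", bins, mat, gap_bins = 5)
  bp <- detect_misjoins(prof, median = 50, frac = 0.1)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$position, 6e5) # midpoint of the value-3 point
  expect_equal(bp$min_value, 3)
  expect_false(bp$unitig_confirmed)
  # nothing below threshold -> no calls
  flat <- mk_matrix(1:6, 6:11, rep(50, 6))
  prof2 <- adjacent_contact_profile("ctgA", bins, flat, gap_bins = 5)
  expect_equal(nrow(detect_misjoins(prof2, median = 50, frac = 0.1)), 0)
})

test_that("unitig corroboration keeps only boundary-supported breakpoints", {
  bins <- misjoin_bins(11)
  mat <- mk_matrix(1:6, 6:11, c(50, 48, 52, 3, 49, 51))
  prof <- adjacent_contact_profile("ctgA", bins, mat, gap_bins = 5)
  near <- unitig_map(data.frame(contig = "ctgA", unitig = c("u1", "u2"),
                                start = c(0, 6e5), end = c(6e5, 11e5)))
  bp <- detect_misjoins(prof, 50, unitigs = near, frac = 0.1)
  expect_equal(nrow(bp), 1)
  expect_true(bp$unitig_confirmed)
  far <- unitig_map(data.frame(contig = "ctgA", unitig = c("u1", "u2"),
                               start = c(0, 9e5), end = c(9e5, 11e5)))
  expect_equal(nrow(detect_misjoins(prof, 50, unitigs = far, frac = 0.1)), 0)
})

test_that("lowering the threshold fraction never adds breakpoints", {
  set.seed(42)
  bins <- misjoin_bins(40)
  k <- 1:35
  mat <- mk_matrix(k, k + 5, rpois(35, 20) * rbinom(35, 1, 0.8))
  prof <- adjacent_contact_profile("ctgA", bins, mat, gap_bins = 5)
  med <- 20
  fracs <- c(0.8, 0.6, 0.4, 0.2, 0.1, 0.05)
  counts <- vapply(fracs, function(f)
    nrow(detect_misjoins(prof, med, frac = f)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("apply_breaks splits bins, sequences and conserves totals", {
  bins <- misjoin_bins(10)
  mat <- mk_matrix(c(1, 2), c(6, 9), c(5, 7))
  seqs <- Biostrings::DNAStringSet(c(ctgA = paste(rep("ACGTACGTAC", 1e5),
                                                  collapse = "")))
  bp <- data.frame(contig = "ctgA", position = 4e5, min_value = 0,
                   unitig_confirmed = FALSE)
  res <- apply_breaks(seqs, bins, mat, bp)
  expect_equal(unique(res$bins$contig), c("ctgA_1", "ctgA_2"))
  expect_equal(sum(res$bins$contig == "ctgA_1"), 4)
  expect_equal(sum(res$bins$contig == "ctgA_2"), 6)
  expect_equal(nrow(res$bins), nrow(bins)) # bin count conserved
  expect_equal(sort(res$bins$bin), sort(bins$bin)) # ids stable
  expect_equal(sum(contig_lengths(res$bins)), sum(contig_lengths(bins)))
  expect_identical(as.data.frame(res$matrix), as.data.frame(mat))
  expect_equal(res$bins$start[res$bins$contig == "ctgA_2"][1], 0)
  expect_equal(as.integer(Biostrings::width(res$assembly)), c(4e5, 6e5))
  expect_equal(as.character(Biostrings::subseq(res$assembly[["ctgA_1"]], 1, 4)),
               "ACGT")
  # empty break list is the identity
  res0 <- apply_breaks(seqs, bins, mat, bp[0, ])
  expect_identical(res0$bins, bins)
  # two breaks give three ordered children
  bp2 <- data.frame(contig = "ctgA", position = c(3e5, 7e5), min_value = 0,
                    unitig_confirmed = FALSE)
  res2 <- apply_breaks(NULL, bins, mat, bp2)
  expect_equal(unique(res2$bins$contig), c("ctgA_1", "ctgA_2", "ctgA_3"))
  expect_equal(as.numeric(contig_lengths(res2$bins)), c(3e5, 4e5, 3e5))
  # off-boundary positions are rejected
  bp3 <- data.frame(contig = "ctgA", position = 450000, min_value = 0,
                    unitig_confirmed = FALSE)
  expect_error(apply_breaks(NULL, bins, mat, bp3), "boundary")
})

test_that("injected mis-joins are found within a bin of the true junction", {
  spec <- sim_spec(n_chrom = 6, chrom_sizes = rep(10e6, 6),
                   contigs_per_chrom = c(3, 4), min_contig = 2e6, seed = 31)
  sim <- simulate_assembly(spec)
  mj <- inject_misjoins(sim, 6, seed = 31)
  bp <- detect_misjoins_genome(mj$bins, sim$raw)
  hits <- merge(bp, mj$breakpoints, by = "contig",
                suffixes = c("_det", "_true"))
  expect_gte(nrow(hits), 5)
  expect_gte(mean(abs(hits$position_det - hits$position_true) <= 1e5), 0.8)
  # no calls on clean contigs
  expect_equal(sum(bp$contig %in% mj$clean), 0)
})
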