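test_that("bin tables transcribe HiC-Pro bed files, including short last bins", {
  tf <- withr::local_tempfile()
  writeLines(c("ctgA\t0\t100000\t1", "ctgA\t100000\t150000\t2"), tf)
  bt <- read_bin_table(tf)
  expect_equal(nrow(bt), 2)
  expect_equal(bt$end[2] - bt$start[2], 50000)
  expect_equal(contig_lengths(bt), c(ctgA = 150000))

  # a 1-Mb contig tiles into 10 full bins
  tf2 <- withr::local_tempfile()
  writeLines(sprintf("ctg1\t%d\t%d\t%d", 0:9 * 1e5, 1:10 * 1e5, 1:10), tf2)
  bt2 <- read_bin_table(tf2)
  expect_equal(nrow(bt2), 10)
  expect_equal(unique(bt2$contig), "ctg1")

  # empty file is a valid empty table
  tf3 <- withr::local_tempfile()
  writeLines(character(0), tf3)
  expect_equal(nrow(read_bin_table(tf3)), 0)
})

test_that("bin table validation reports the offending line or contig", {
  tf <- withr::local_tempfile()
  writeLines(c("ctgA\t0\t100000\t1", "ctgA\t100000"), tf)
  expect_error(read_bin_table(tf), "line 2")
  tf2 <- withr::local_tempfile()
  writeLines(c("ctgA\t0\t100000\t1", "ctgA\t200000\t300000\t2"), tf2)
  expect_error(read_bin_table(tf2), "tile")
  tf3 <- withr::local_tempfile()
  writeLines(c("ctgA\t0\t100000\t1", "ctgA\t100000\t200000\t1"), tf3)
  expect_error(read_bin_table(tf3), "unique")
})

test_that("contact matrices collapse mirrored triplets and keep diagonals", {
  bins <- tiny_bins()
  tf <- withr::local_tempfile()
  writeLines(c("1\t2\t10", "2\t1\t5", "3\t3\t7"), tf)
  m <- read_contact_matrix(tf, bins)
  expect_equal(contact_value(m, 1, 2), 15)
  expect_equal(contact_value(m, 2, 1), 15)
  expect_equal(contact_value(m, 3, 3), 7)
  expect_equal(contact_value(m, 5, 9), 0)

  tf2 <- withr::local_tempfile()
  file.create(tf2)
  m2 <- read_contact_matrix(tf2, bins)
  expect_equal(nrow(m2), 0)
  expect_equal(contact_value(m2, 1, 2), 0)
})

test_that("contact matrices reject unknown bins and negative values", {
  bins <- tiny_bins()
  tf <- withr::local_tempfile()
  writeLines("1\t99\t10", tf)
  expect_error(read_contact_matrix(tf, bins), "absent")
  expect_error(mk_matrix(1, 2, -3), "negative")
})

test_that("symmetrized and upper-triangular files encode the same matrix", {
  bins <- tiny_bins()
  up <- withr::local_tempfile()
  writeLines(c("1\t2\t10", "2\t5\t4", "7\t9\t2"), up)
  sym <- withr::local_tempfile()
  writeLines(c("1\t2\t5", "2\t1\t5", "2\t5\t2", "5\t2\t2", "7\t9\t1",
               "9\t7\t1"), sym)
  expect_equal(as.data.frame(read_contact_matrix(up, bins)),
               as.data.frame(read_contact_matrix(sym, bins)))
})

test_that("cluster tables round-trip exactly, including member tokens", {
  cs <- cluster_set(list(
    list(contig = c("A", "B"), orient = c("+", "-"), length = 5e6,
         robustness = 7L),
    list(contig = "C", orient = "+", length = 1e6, robustness = 90L)))
  tf <- withr::local_tempfile()
  write_cluster_table(cs, tf)
  lines <- readLines(tf)
  expect_match(lines[2], "\t2\t5000000\t7\tA\\+;B-$")
  expect_match(lines[3], "\t1\t1000000\t90\tC\\+$")
  back <- read_cluster_table(tf)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$contig, c("A", "B"))
  expect_equal(back[[1]]$orient, c("+", "-"))
  expect_equal(back[[1]]$robustness, 7L)
  expect_equal(back[[2]]$length, 1e6)
  # a Table-1-shaped member string parses back to the same tokens
  tokens <- "ptg000019l+;ptg000017l+;ptg000037l+;ptg000033l-"
  tf2 <- withr::local_tempfile()
  writeLines(c("#h", paste("cluster_01", 4, 157781296, 54, tokens,
                           sep = "\t")), tf2)
  b2 <- read_cluster_table(tf2)
  expect_equal(paste0(b2[[1]]$contig, b2[[1]]$orient),
               strsplit(tokens, ";")[[1]])
  expect_equal(b2[[1]]$robustness, 54L)
})

test_that("GFA export follows the end-side strand rules", {
  g <- mk_graph(c("c1", "c2"), "c1:tail", "c2:head", 50)
  tf <- withr::local_tempfile()
  write_gfa(g, c(c1 = 2e6, c2 = 3e6), tf)
  lines <- readLines(tf)
  expect_equal(lines[1], "H\tVN:Z:1.0")
  expect_true("S\tc1\t*\tLN:i:2000000" %in% lines)
  expect_true("L\tc1\t+\tc2\t+\t0M" %in% lines)

  g2 <- mk_graph(c("c1", "c2"), "c1:head", "c2:head", 50)
  write_gfa(g2, c(c1 = 2e6, c2 = 3e6), tf)
  expect_true("L\tc1\t-\tc2\t+\t0M" %in% readLines(tf))

  # tail-tail: right contig gets "-"
  g3 <- mk_graph(c("c1", "c2"), "c1:tail", "c2:tail", 50)
  write_gfa(g3, c(c1 = 2e6, c2 = 3e6), tf)
  expect_true("L\tc1\t+\tc2\t-\t0M" %in% readLines(tf))

  # no link edges: S lines only
  g4 <- mk_graph(c("c1", "c2"))
  write_gfa(g4, c(c1 = 2e6, c2 = 3e6), tf)
  expect_false(any(startsWith(readLines(tf), "L")))
})

test_that("AGP coordinates chain components and gaps correctly", {
  cs <- cluster_set(list(list(contig = c("A", "B"), orient = c("+", "-"),
                              length = 3e6, robustness = NA_integer_)))
  tf <- withr::local_tempfile()
  agp <- write_agp(cs, c(A = 2e6, B = 1e6), tf, gap_len = 100)
  expect_equal(nrow(agp), 3)
  expect_equal(agp$component_type, c("W", "U", "W"))
  expect_equal(agp$object_beg, c(1, 2000001, 2000101))
  expect_equal(agp$object_end, c(2e6, 2000100, 3000100))
  expect_equal(agp$f9, c("+", "proximity_ligation", "-"))
  expect_equal(agp$f7[2], "scaffold")
  # singleton cluster spans the contig in one W record
  cs1 <- cluster_set(list(list(contig = "A", orient = "+", length = 2e6,
                               robustness = NA_integer_)))
  agp1 <- write_agp(cs1, c(A = 2e6), tf)
  expect_equal(nrow(agp1), 1)
  expect_equal(agp1$object_end, 2e6)
  expect_error(write_agp(cs, c(A = 2e6), tf), "unknown contig")
})

test_that("scaffold FASTA matches AGP, with reverse-complement and gaps", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">A", "ACGT", ">B", "GG", ">C", "AAC"), fa)
  cs <- cluster_set(list(list(contig = c("A", "B"), orient = c("+", "-"),
                              length = 6, robustness = NA_integer_)))
  agp_path <- withr::local_tempfile()
  agp <- write_agp(cs, c(A = 4, B = 2), agp_path, gap_len = 2)
  out <- withr::local_tempfile(fileext = ".fa")
  emit_scaffold_fasta(agp, fa, out)
  sc <- Biostrings::readDNAStringSet(out)
  expect_equal(as.character(sc[[1]]), "ACGTNNCC")
  expect_equal(Biostrings::width(sc)[1], max(agp$object_end))
  # single + component is the identity; single - is the reverse complement
  for (case in list(c("A", "+", "ACGT"), c("C", "-", "GTT"))) {
    cs1 <- cluster_set(list(list(contig = case[1], orient = case[2],
                                 length = 4, robustness = NA_integer_)))
    agp1 <- write_agp(cs1, c(A = 4, C = 3), agp_path)
    emit_scaffold_fasta(agp1, fa, out)
    expect_equal(as.character(Biostrings::readDNAStringSet(out)[[1]]),
                 case[3])
  }
  # reading the AGP back from disk gives the same scaffold
  emit_scaffold_fasta(agp_path, fa, out)
  expect_equal(as.character(Biostrings::readDNAStringSet(out)[[1]]),
               "GTT")
  # missing component is reported by name
  csX <- cluster_set(list(list(contig = "ZZ", orient = "+", length = 4,
                               robustness = NA_integer_)))
  agpX <- write_agp(csX, c(ZZ = 4), NULL)
  expect_error(emit_scaffold_fasta(agpX, fa, out), "ZZ")
})
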