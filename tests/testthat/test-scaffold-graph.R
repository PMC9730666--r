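end_table <- function(contigs, pairs) {
  # pairs: data.frame key1, key2, value; others zero
  keys <- as.vector(t(outer(contigs, c("head", "tail"), paste, sep = ":")))
  ends <- data.frame(contig = rep(contigs, each = 2),
                     side = rep(c("head", "tail"), length(contigs)),
                     key = keys, stringsAsFactors = FALSE)
  V <- matrix(0, length(keys), length(keys), dimnames = list(keys, keys))
  for (k in seq_len(nrow(pairs))) {
    V[pairs$key1[k], pairs$key2[k]] <- pairs$value[k]
    V[pairs$key2[k], pairs$key1[k]] <- pairs$value[k]
  }
  same <- outer(ends$contig, ends$contig, `==`)
  V[same] <- NA_real_
  structure(list(ends = ends, values = V), class = "end_contact_table",
            w = 1, flavor = "raw")
}

test_that("link edges require strictly exceeding the cutoff", {
  tab <- end_table(c("A", "B"), data.frame(
    key1 = c("A:tail", "A:head"), key2 = c("B:head", "B:tail"),
    value = c(35, 1)))
  g <- build_link_graph(tab, 10)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 35)
  expect_equal(nrow(build_link_graph(tab, 100)$edges), 0)
  expect_equal(nrow(build_link_graph(tab, 35)$edges), 0) # boundary: strict
})

test_that("reciprocal-best keeps unique mutual maxima and drops ties", {
  g <- mk_graph(c("c1", "c2", "c3"),
                key1 = c("c1:tail", "c1:tail", "c2:head"),
                key2 = c("c2:head", "c3:head", "c3:head"),
                weight = c(50, 40, 30))
  f <- reciprocal_best_filter(g)
  expect_equal(nrow(f$edges), 1)
  expect_equal(f$edges$weight, 50)
  # single edge survives trivially
  g1 <- mk_graph(c("c1", "c2"), "c1:tail", "c2:head", 5)
  expect_equal(nrow(reciprocal_best_filter(g1)$edges), 1)
  # a tie at a shared endpoint eliminates both tied edges
  gt <- mk_graph(c("c1", "c2", "c3"),
                 key1 = c("c1:tail", "c1:tail"),
                 key2 = c("c2:head", "c3:head"),
                 weight = c(50, 50))
  expect_equal(nrow(reciprocal_best_filter(gt)$edges), 0)
})

test_that("cycles are broken at their weakest link, per component", {
  g <- mk_graph(c("C1", "C2", "C3"),
                key1 = c("C1:tail", "C2:tail", "C3:tail"),
                key2 = c("C2:head", "C3:head", "C1:head"),
                weight = c(100, 90, 30))
  b <- break_cycles(g)
  expect_equal(nrow(b$edges), 2)
  expect_false(30 %in% b$edges$weight)
  expect_true(oracle_acyclic(b))
  cs <- extract_clusters(b, c(C1 = 1e6, C2 = 1e6, C3 = 1e6))
  expect_equal(cs[[1]]$contig, c("C1", "C2", "C3"))
  # acyclic graphs pass through unchanged
  a <- mk_graph(c("C1", "C2"), "C1:tail", "C2:head", 10)
  expect_identical(break_cycles(a)$edges, a$edges)
  # two disjoint cycles lose one edge each
  g2 <- mk_graph(c("A", "B", "X", "Y"),
                 key1 = c("A:tail", "B:tail", "X:tail", "Y:tail"),
                 key2 = c("B:head", "A:head", "Y:head", "X:head"),
                 weight = c(10, 5, 20, 15))
  b2 <- break_cycles(g2)
  expect_equal(sort(b2$edges$weight), c(10, 20))
  expect_true(oracle_acyclic(b2))
})

test_that("path traversal assigns orientations by the end-side rules", {
  lens <- c(C1 = 3e6, C2 = 2e6, C3 = 1e6)
  g <- mk_graph(c("C1", "C2", "C3"),
                key1 = c("C1:tail", "C2:tail"),
                key2 = c("C2:head", "C3:tail"),
                weight = c(10, 10))
  cs <- extract_clusters(g, lens)
  expect_equal(length(cs), 1)
  expect_equal(cs[[1]]$contig, c("C1", "C2", "C3"))
  expect_equal(cs[[1]]$orient, c("+", "+", "-"))
  expect_equal(cs[[1]]$length, 6e6)
  # head-head link: left contig reversed
  g2 <- mk_graph(c("C1", "C2"), "C1:head", "C2:head", 10)
  cs2 <- extract_clusters(g2, lens)
  expect_equal(cs2[[1]]$contig, c("C1", "C2"))
  expect_equal(cs2[[1]]$orient, c("-", "+"))
  # no links: all singletons, "+"
  cs3 <- extract_clusters(mk_graph(c("C1", "C2", "C3")), lens)
  expect_equal(length(cs3), 3)
  expect_true(all(vapply(cs3, function(x) x$orient, "") == "+"))
  # sorted by total length descending
  expect_equal(vapply(cs3, function(x) x$contig, ""), c("C1", "C2", "C3"))
})

test_that("random graphs: filter and cycle-break agree with brute force", {
  set.seed(77)
  for (k in 1:150) {
    n <- sample(2:6, 1)
    e <- random_edges(n, sample(1:10, 1))
    g <- mk_graph(sprintf("c%d", 1:n), e$key1, e$key2, e$weight)
    f <- reciprocal_best_filter(g)
    want <- e[oracle_reciprocal_best(e), , drop = FALSE]
    expect_equal(nrow(f$edges), nrow(want))
    if (nrow(want) > 0) {
      got_lab <- sort(paste(f$edges$key1, f$edges$key2, f$edges$weight))
      want_lab <- sort(paste(want$key1, want$key2, want$weight))
      expect_equal(got_lab, want_lab)
    }
    b <- break_cycles(f)
    expect_true(oracle_acyclic(b))
    removed <- setdiff(paste(f$edges$key1, f$edges$key2),
                       paste(b$edges$key1, b$edges$key2))
    if (length(removed) > 0) {
      # each removed edge must be a minimum-weight link of its component
      # (after reciprocal-best, a component with a removed edge is a cycle)
      fc1 <- sub(":.*", "", f$edges$key1)
      fc2 <- sub(":.*", "", f$edges$key2)
      comp_min <- function(ctg) {
        members <- ctg
        repeat {
          grow <- unique(c(fc2[fc1 %in% members], fc1[fc2 %in% members]))
          if (all(grow %in% members)) break
          members <- unique(c(members, grow))
        }
        min(f$edges$weight[fc1 %in% members])
      }
      for (lab in removed) {
        sel <- paste(f$edges$key1, f$edges$key2) == lab
        expect_equal(f$edges$weight[sel], comp_min(fc1[sel]))
      }
    }
    # partition: every contig appears exactly once across clusters
    cs <- extract_clusters(b, setNames(rep(1e6, n), sprintf("c%d", 1:n)))
    got_ctg <- sort(unlist(lapply(cs, `[[`, "contig")))
    expect_equal(got_ctg, sprintf("c%d", 1:n))
  }
})

test_that("a path walked from either terminus gives the same canonical cluster", {
  set.seed(5)
  lens <- setNames(rep(1e6, 4), sprintf("c%d", 1:4))
  g <- mk_graph(sprintf("c%d", 1:4),
                key1 = c("c1:tail", "c2:tail", "c3:head"),
                key2 = c("c2:head", "c3:tail", "c4:head"),
                weight = c(9, 8, 7))
  cs <- extract_clusters(g, lens)
  # reversed cluster canonicalizes to the same key
  cl <- cs[[1]]
  rev_cl <- list(contig = rev(cl$contig),
                 orient = ifelse(rev(cl$orient) == "+", "-", "+"),
                 length = cl$length, robustness = NA_integer_)
  expect_equal(cluster_key(cl), cluster_key(rev_cl))
})
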