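test_that("ancestry links on the hand fixture match the per-tree definition", {
  tb <- fixture_f()
  la <- link_ancestors(tb, samples = c(0, 1), ancestors = c(2, 3))
  expect_equal(as.data.frame(la),
               data.frame(left = c(0, 0, 5), right = c(10, 5, 10),
                          ancestor = c(2L, 2L, 3L), sample = c(0L, 1L, 1L)))

  # most recent ancestor wins; (5,10) of sample 1 stays unassigned
  suppressMessages(la2 <- link_ancestors(tb, c(0, 1), c(2, 4)))
  expect_equal(as.data.frame(la2),
               data.frame(left = c(0, 0), right = c(10, 5),
                          ancestor = c(2L, 2L), sample = c(0L, 1L)))

  # path 0 -> 2 -> 4 when only the root is requested
  la3 <- link_ancestors(tb, 0, 4)
  expect_equal(as.data.frame(la3),
               data.frame(left = 0, right = 10, ancestor = 4L, sample = 0L))

  # only node 3 requested: sample 0 fully unassigned
  la4 <- link_ancestors(tb, c(0, 1), 3)
  expect_equal(as.data.frame(la4),
               data.frame(left = 5, right = 10, ancestor = 3L, sample = 1L))
})

test_that("a single parent-child edge yields the identity link", {
  tb <- ts_tables(nodes = data.frame(time = c(0, 1), is_sample = c(1, 0)),
                  edges = data.frame(left = 0, right = 42, parent = 1L, child = 0L),
                  sequence_length = 42)
  la <- link_ancestors(tb, 0, 1)
  expect_equal(as.data.frame(la),
               data.frame(left = 0, right = 42, ancestor = 1L, sample = 0L))
})

test_that("preconditions are enforced", {
  tb <- fixture_f()
  expect_error(link_ancestors(tb, integer(0), 2), class = "al_usage_error")
  expect_error(link_ancestors(tb, 0, integer(0)), class = "al_usage_error")
  expect_error(link_ancestors(tb, c(0, 0), 2), class = "al_usage_error")
  expect_error(link_ancestors(tb, 0, 99), class = "al_usage_error")
  expect_error(link_ancestors(tb, c(0, 2), c(2, 3)), class = "al_usage_error")
})

test_that("unsorted edges are sorted internally with a log message", {
  tb <- fixture_f()
  tb$edges <- tb$edges[c(4, 3, 2, 1), ]
  expect_message(la <- link_ancestors(tb, c(0, 1), c(2, 3)), "sorting internally")
  expect_same_links(la, link_ancestors(fixture_f(), c(0, 1), c(2, 3)))
})

test_that("heterogeneous ancestor times and internal samples are logged, not rejected", {
  tb <- fixture_f()
  expect_message(link_ancestors(tb, c(0, 1), c(2, 4)), "single census time")
  # node 2 is a parent: tracing it as a sample logs the internal-sample case
  expect_message(la <- link_ancestors(tb, c(0, 2), 4), "internal")
  expect_equal(as.data.frame(la),
               data.frame(left = c(0, 0), right = c(10, 10),
                          ancestor = c(4L, 4L), sample = c(0L, 2L)))
})

test_that("output invariants hold across random simulations", {
  for (seed in 501:510) {
    r <- small_sim(seed)
    L <- r$tables$sequence_length
    la <- link_ancestors(r$tables, r$sample_nodes, census_nodes(r, 11))
    # sorted by (sample, left, ancestor)
    expect_false(is.unsorted(order(la$sample, la$left, la$ancestor)))
    expect_identical(order(la$sample, la$left, la$ancestor), seq_len(nrow(la)))
    for (s in unique(la$sample)) {
      rows <- la[la$sample == s, ]
      o <- order(rows$left)
      # pairwise disjoint intervals, total length bounded by L
      expect_true(all(rows$right[o][-nrow(rows)] <= rows$left[o][-1]))
      expect_lte(sum(rows$right - rows$left), L)
      # no two retained rows with identical (ancestor, sample) exactly adjacent
      adj <- rows$left[o][-1] == rows$right[o][-nrow(rows)] &
        rows$ancestor[o][-1] == rows$ancestor[o][-nrow(rows)]
      expect_false(any(adj))
    }
  }
})

test_that("splitting an edge leaves the output unchanged", {
  tb <- fixture_f()
  base <- link_ancestors(tb, c(0, 1), c(2, 3))
  for (i in seq_len(nrow(tb$edges))) {
    tb2 <- tb
    e <- tb2$edges[i, ]
    m <- (e$left + e$right) / 2
    tb2$edges <- rbind(tb2$edges[-i, ],
                       data.frame(left = c(e$left, m), right = c(m, e$right),
                                  parent = e$parent, child = e$child))
    tb2 <- sort_edges(tb2)
    expect_same_links(link_ancestors(tb2, c(0, 1), c(2, 3)), base)
  }
})

test_that("identical input gives identical output (determinism)", {
  r <- small_sim(77)
  a <- link_ancestors(r$tables, r$sample_nodes, census_nodes(r, 11))
  b <- link_ancestors(r$tables, r$sample_nodes, census_nodes(r, 11))
  expect_identical(a, b)
})

test_that("coverage report decomposes [0, L) exactly", {
  tb <- fixture_f()
  la <- link_ancestors(tb, c(0, 1), c(2, 3))
  cov <- coverage_report(la)
  expect_equal(cov$summary$assigned, c(10, 10))
  expect_equal(nrow(cov$gaps), 0)

  la2 <- link_ancestors(tb, c(0, 1), 3)
  cov2 <- coverage_report(la2)
  expect_equal(cov2$summary$assigned[cov2$summary$sample == 0], 0)
  expect_equal(cov2$summary$assigned[cov2$summary$sample == 1], 5)
  expect_equal(cov2$gaps[cov2$gaps$sample == 0, c("left", "right")],
               data.frame(left = 0, right = 10), ignore_attr = TRUE)

  # empty table: every sample unassigned on [0, L)
  empty <- la[integer(0), ]
  cov3 <- coverage_report(empty, samples = c(0, 1), sequence_length = 10)
  expect_equal(cov3$summary$assigned, c(0, 0))
  expect_equal(cov3$gaps$left, c(0, 0))
  expect_equal(cov3$gaps$right, c(10, 10))
  # assigned + gaps == L per sample, also on a simulated partial query
  r <- small_sim(9)
  la4 <- link_ancestors(r$tables, r$sample_nodes,
                        census_nodes(r, 11)[seq(1, 60, by = 3)])
  cov4 <- coverage_report(la4)
  gap_tot <- tapply(cov4$gaps$right - cov4$gaps$left, cov4$gaps$sample, sum)
  for (i in seq_len(nrow(cov4$summary))) {
    s <- cov4$summary$sample[i]
    g <- if (as.character(s) %in% names(gap_tot)) gap_tot[[as.character(s)]] else 0
    expect_equal(cov4$summary$assigned[i] + g, r$tables$sequence_length)
  }
})
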