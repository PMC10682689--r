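test_that("population annotation is a pure column addition", {
  tb <- fixture_f()
  la <- link_ancestors(tb, c(0, 1), c(2, 3))
  pa <- annotate_populations(la, tb)
  expect_equal(nrow(pa), nrow(la))
  expect_equal(pa$population, c(0L, 0L, 1L))  # pops A, A, B
  expect_equal(pa[c("left", "right", "ancestor", "sample")],
               as.data.frame(la)[c("left", "right", "ancestor", "sample")],
               ignore_attr = TRUE)

  # empty in, empty out
  expect_equal(nrow(annotate_populations(la[integer(0), ], tb)), 0)

  # unlabelled ancestor is an error naming the node
  tb2 <- tb
  tb2$nodes$population[3] <- -1L
  expect_error(annotate_populations(la, tb2), "2", class = "al_domain_error")
})

test_that("squash merges exactly-adjacent same-population rows only", {
  x <- data.frame(sample = 1L, left = c(0, 5), right = c(5, 10),
                  ancestor = c(7L, 8L), population = c(0L, 0L))
  expect_equal(as.data.frame(squash(x)),
               data.frame(sample = 1L, left = 0, right = 10, population = 0L))

  y <- data.frame(sample = 1L, left = c(0, 5), right = c(5, 10),
                  ancestor = c(7L, 8L), population = c(0L, 1L))
  expect_equal(nrow(squash(y)), 2)  # no merge across populations

  # gaps are never bridged
  z <- data.frame(sample = 1L, left = c(0, 5), right = c(4, 10),
                  ancestor = c(7L, 8L), population = c(0L, 0L))
  expect_equal(nrow(squash(z)), 2)

  # overlap is a consistency error
  w <- data.frame(sample = 1L, left = c(0, 3), right = c(5, 10),
                  ancestor = c(7L, 8L), population = c(0L, 0L))
  expect_error(squash(w), class = "al_domain_error")
})

test_that("squash is idempotent, length-preserving, and equals the repaint oracle", {
  for (seed in 701:760) {
    x <- random_tract_table(seed)
    sq <- squash(x)
    expect_equal(as.data.frame(squash(sq))[c("sample", "left", "right", "population")],
                 as.data.frame(sq)[c("sample", "left", "right", "population")])
    # per-(sample, population) length preservation, exact
    len_in <- tapply(x$right - x$left, interaction(x$sample, x$population, drop = TRUE), sum)
    len_out <- tapply(sq$right - sq$left, interaction(sq$sample, sq$population, drop = TRUE), sum)
    expect_equal(len_out[order(names(len_out))], len_in[order(names(len_in))])
    # position-sweep repaint oracle
    expect_equal(as.data.frame(sq), repaint_squash(x), ignore_attr = TRUE)
  }
})

test_that("ancestry fractions are exact arithmetic and consistent with coverage", {
  sq <- structure(data.frame(sample = 1L, left = c(0, 5), right = c(5, 10),
                             population = c(0L, 1L)),
                  class = c("squashed_tracts", "data.frame"))
  fr <- ancestry_fractions(sq, sequence_length = 10)
  expect_equal(fr$fraction, c(0.5, 0.5))
  fr2 <- ancestry_fractions(
    structure(data.frame(sample = 1L, left = 0, right = 10, population = 0L),
              class = c("squashed_tracts", "data.frame")), sequence_length = 10)
  expect_equal(fr2$fraction, 1)

  # cross-module consistency: fractions sum to assigned / L from coverage_report
  for (seed in 801:810) {
    r <- small_sim(seed)
    la <- link_ancestors(r$tables, r$sample_nodes, census_nodes(r, 11))
    sq <- squash(annotate_populations(la, r$tables))
    fr <- ancestry_fractions(sq, r$tables$sequence_length)
    cov <- coverage_report(la)
    by_sample <- tapply(fr$fraction, fr$sample, sum)
    expect_equal(as.numeric(by_sample[as.character(cov$summary$sample)]),
                 cov$summary$assigned / r$tables$sequence_length)
  }
})

test_that("tract length stats match a direct recount", {
  one <- structure(data.frame(sample = 1L, left = 2, right = 9, population = 0L),
                   class = c("squashed_tracts", "data.frame"))
  st <- tract_length_stats(one)
  expect_equal(st$count, 1)
  expect_equal(st$mean, 7)
  expect_equal(nrow(tract_length_stats(one[integer(0), ])), 0)

  x <- squash(random_tract_table(900))
  st <- tract_length_stats(x)
  for (i in seq_len(nrow(st))) {
    lens <- (x$right - x$left)[x$population == st$population[i]]
    expect_equal(st$count[i], length(lens))
    expect_equal(st$mean[i], mean(lens))
    expect_equal(st$median[i], stats::median(lens))
    expect_equal(st$min[i], min(lens))
    expect_equal(st$max[i], max(lens))
  }
})

test_that("BED export writes 0-based half-open rows and parses back exactly", {
  dir <- withr::local_tempdir()
  sq <- structure(data.frame(sample = c(1L, 1L, 2L), left = c(0, 10, 3),
                             right = c(10, 20, 8), population = c(0L, 1L, 0L)),
                  class = c("squashed_tracts", "data.frame"))
  bed <- file.path(dir, "t.bed")
  write_bed(sq, bed, sample_names = c(`1` = "s1", `2` = "s2"),
            population_names = c(`0` = "A", `1` = "B"))
  expect_equal(readLines(bed)[1], "s1\t0\t10\tA")
  back <- read_bed(bed)
  expect_equal(back$chrom, c("s1", "s1", "s2"))
  expect_equal(back$left, sq$left)
  expect_equal(back$right, sq$right)
  expect_equal(back$name, c("A", "B", "A"))

  # empty table -> empty file
  write_bed(sq[integer(0), ], bed)
  expect_equal(length(readLines(bed)), 0)

  # non-integer coordinates error unless round is requested
  frac <- structure(data.frame(sample = 1L, left = 0.25, right = 3.5, population = 0L),
                    class = c("squashed_tracts", "data.frame"))
  expect_error(write_bed(frac, bed), class = "al_domain_error")
  expect_message(write_bed(frac, bed, round = TRUE), "rounding")
  expect_equal(readLines(bed), "sample_1\t0\t4\t0")
})

test_that("tract tables depend on the census choice (older census fragments more)", {
  # Fig-1-style property: across seeds, censusing one generation earlier
  # (older) gives at least as many squashed rows on average
  n_young <- n_old <- numeric(0)
  for (seed in 1:25) {
    r <- simulate_wf(sim_params(census_generations = c(11L, 15L), seed = seed))
    for (g in c(11, 15)) {
      la <- link_ancestors(r$tables, r$sample_nodes, census_nodes(r, g))
      sq <- squash(annotate_populations(la, r$tables))
      if (g == 11) n_young <- c(n_young, nrow(sq)) else n_old <- c(n_old, nrow(sq))
    }
  }
  expect_gte(mean(n_old), mean(n_young))
})
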