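# Fixtures and independent oracles shared across the suite. Everything is
# built in code; no files are shipped.

# The canonical hand fixture: two samples, two recombination-era parents,
# one grandparent, a breakpoint at 5.
#   nodes: 0,1 samples (t=0); 2,3 internal (t=1); 4 root (t=2)
#   edges: (0,10,2,0) (0,5,2,1) (5,10,3,1) (0,10,4,2)
fixture_f <- function() {
  ts_tables(
    nodes = data.frame(time = c(0, 0, 1, 1, 2), is_sample = c(1, 1, 0, 0, 0),
                       population = c(-1L, -1L, 0L, 1L, 0L)),
    edges = data.frame(left = c(0, 0, 5, 0), right = c(10, 5, 10, 10),
                       parent = c(2L, 2L, 3L, 4L), child = c(0L, 1L, 1L, 2L)),
    populations = data.frame(id = 0:1, name = c("A", "B")),
    sequence_length = 10
  )
}

# chain c -> a1 -> a2 with full-span edges (times 0 < 1 < 2)
chain_fixture <- function(L = 100) {
  ts_tables(
    nodes = data.frame(time = c(0, 1, 2), is_sample = c(1, 0, 0)),
    edges = data.frame(left = c(0, 0), right = c(L, L),
                       parent = c(1L, 2L), child = c(0L, 1L)),
    sequence_length = L
  )
}

# A layered random bundle with real-valued coordinates: nodes live on
# strictly increasing time layers; each non-top node partitions [0, L) at
# random real breakpoints and sends each piece to a random strictly older
# node (or drops it), so per-child parental intervals never overlap.
random_bundle <- function(seed, real_coords = TRUE) {
  set.seed(seed)
  L <- sample(c(10, 50, 200), 1) + if (real_coords) runif(1) else 0
  n_layers <- sample(2:5, 1)
  sizes <- sample(1:4, n_layers, replace = TRUE)
  layer <- rep(seq_len(n_layers) - 1L, sizes)
  time <- layer + if (real_coords) runif(length(layer), 0, 0.5) else 0
  n <- length(layer)
  ids <- seq_len(n) - 1L
  el <- numeric(0); er <- numeric(0); ep <- integer(0); ec <- integer(0)
  for (i in which(layer < n_layers - 1L)) {
    older <- ids[layer > layer[i]]
    k <- sample(0:3, 1)
    bp <- sort(unique(c(0, L, if (k) round(runif(k, 0, L), 3))))
    for (j in seq_len(length(bp) - 1L)) {
      if (runif(1) < 0.15) next  # leave a gap
      p <- if (length(older) == 1) older else sample(older, 1)
      el <- c(el, bp[j]); er <- c(er, bp[j + 1]); ep <- c(ep, p); ec <- c(ec, ids[i])
    }
  }
  K <- sample(1:3, 1)
  tb <- ts_tables(
    nodes = data.frame(time = time,
                       population = sample(c(-1L, seq_len(K) - 1L), n, replace = TRUE),
                       is_sample = as.integer(layer == 0L),
                       is_census = sample(0:1, n, replace = TRUE)),
    edges = data.frame(left = el, right = er, parent = ep, child = ec),
    populations = data.frame(id = seq_len(K) - 1L, name = sprintf("pop%d", seq_len(K))),
    sequence_length = L
  )
  sort_edges(tb)
}

# Position-sweep squash oracle: repaint each sample's genome position by
# position (at atomic intervals between breakpoints), then read off maximal
# constant-population runs. Gaps break runs.
repaint_squash <- function(pop_rows) {
  out <- NULL
  for (s in sort(unique(pop_rows$sample))) {
    rows <- pop_rows[pop_rows$sample == s, , drop = FALSE]
    bp <- sort(unique(c(rows$left, rows$right)))
    atom_l <- bp[-length(bp)]
    atom_r <- bp[-1]
    pops <- vapply(seq_along(atom_l), function(k) {
      mid <- (atom_l[k] + atom_r[k]) / 2
      hit <- which(rows$left <= mid & mid < rows$right)
      if (length(hit) > 1) stop("overlapping rows in repaint oracle")
      if (length(hit) == 0) -1L else as.integer(rows$population[hit])
    }, integer(1))
    runs <- rle(pops)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values >= 0L
    if (any(keep)) {
      out <- rbind(out, data.frame(sample = s, left = atom_l[starts[keep]],
                                   right = atom_r[ends[keep]],
                                   population = runs$values[keep]))
    }
  }
  if (is.null(out)) {
    out <- data.frame(sample = integer(0), left = numeric(0),
                      right = numeric(0), population = integer(0))
  }
  rownames(out) <- NULL
  out
}

# Random disjoint tract tables (squash input): atoms on an integer grid,
# some left unassigned, random populations and ancestors.
random_tract_table <- function(seed) {
  set.seed(seed)
  rows <- NULL
  for (s in seq_len(sample(1:3, 1))) {
    bp <- sort(sample(0:100, sample(3:12, 1)))
    if (length(bp) < 2) next
    for (j in seq_len(length(bp) - 1L)) {
      if (runif(1) < 0.25) next
      rows <- rbind(rows, data.frame(
        sample = s, left = bp[j], right = bp[j + 1],
        ancestor = sample(100:120, 1), population = sample(0:2, 1)))
    }
  }
  if (is.null(rows)) {
    rows <- data.frame(sample = 1L, left = 0, right = 10,
                       ancestor = 100L, population = 0L)
  }
  rows[sample(nrow(rows)), , drop = FALSE]  # shuffle row order
}

# small simulation used by many tests
small_sim <- function(seed, ...) {
  simulate_wf(sim_params(seed = seed, ...))
}

expect_same_links <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
}
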