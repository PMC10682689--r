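# User-facing interface to the single-pass ancestry-linking engine.

check_sample_ancestor_ids <- function(tables, samples, ancestors) {
  n <- nrow(tables$nodes)
  samples <- as.integer(samples)
  ancestors <- as.integer(ancestors)
  if (length(samples) == 0) stop_usage("`samples` must be non-empty")
  if (length(ancestors) == 0) stop_usage("`ancestors` must be non-empty")
  if (anyDuplicated(samples)) stop_usage("`samples` contains duplicate ids")
  if (anyDuplicated(ancestors)) stop_usage("`ancestors` contains duplicate ids")
  bad <- c(samples, ancestors)
  bad <- bad[is.na(bad) | bad < 0L | bad >= n]
  if (length(bad)) stop_usage("unknown node id(s): %s", paste(bad, collapse = ", "))
  both <- intersect(samples, ancestors)
  if (length(both)) {
    stop_usage("samples and ancestors must be disjoint (shared: %s)",
               paste(both, collapse = ", "))
  }
  anc_t <- tables$nodes$time[ancestors + 1L]
  if (length(unique(anc_t)) > 1L) {
    al_log("ancestors span multiple times (%s); local ancestry is best defined at a single census time",
           paste(sort(unique(anc_t)), collapse = ", "))
  }
  if (any(samples %in% tables$edges$parent)) {
    al_log("some samples are internal nodes (parents of edges); each is traced independently")
  }
  list(samples = samples, ancestors = ancestors)
}

# merge exactly-adjacent rows with equal (ancestor, sample), then sort
# canonically by (sample, left, ancestor)
finalize_ancestry_rows <- function(left, right, ancestor, sample, L, samples) {
  if (length(left)) {
    o <- order(sample, ancestor, left, method = "radix")
    left <- left[o]; right <- right[o]; ancestor <- ancestor[o]; sample <- sample[o]
    same <- c(FALSE,
              sample[-1] == sample[-length(sample)] &
              ancestor[-1] == ancestor[-length(ancestor)] &
              left[-1] == right[-length(right)])
    grp <- cumsum(!same)
    keep <- !duplicated(grp)
    right <- right[cumsum(tabulate(grp))]  # last row of each run
    left <- left[keep]; ancestor <- ancestor[keep]; sample <- sample[keep]
    o <- order(sample, left, ancestor, method = "radix")
    df <- data.frame(left = left[o], right = right[o],
                     ancestor = ancestor[o], sample = sample[o])
  } else {
    df <- data.frame(left = numeric(0), right = numeric(0),
                     ancestor = integer(0), sample = integer(0))
  }
  structure(df, sequence_length = L, samples = samples,
            class = c("ancestry_table", "data.frame"))
}

#' Extract ancestry links between samples and census ancestors
#'
#' For every sample genome, computes the maximal genomic intervals it has
#' inherited from each node in `ancestors`: position `x` of sample `s` is
#' linked to the first (most recent) member of `ancestors` encountered when
#' walking from `s` toward the root of the local tree covering `x`. Positions
#' whose path reaches no requested ancestor are left unassigned and absent
#' from the output.
#'
#' The computation is a single pass over the time-ordered edge table: sample
#' segments are carried upward edge by edge, splitting at recombination
#' breakpoints, and are emitted as soon as they reach a requested ancestor
#' (so when several requested ancestors lie on one path, the youngest wins).
#' This is far faster than resolving each local tree separately; the
#' tree-by-tree equivalent is available as [local_ancestry_naive()] and
#' defines the same semantics.
#'
#' @param tables a [ts_tables()] bundle; sorted internally if its edges are
#'   not in canonical order (with a log message).
#' @param samples integer vector of sample node ids (0-based), non-empty,
#'   distinct, disjoint from `ancestors`.
#' @param ancestors integer vector of ancestor node ids (0-based), typically
#'   all nodes recorded at one census time.
#' @return An `ancestry_table`: data frame with columns `left`, `right`,
#'   `ancestor`, `sample`, sorted by `(sample, left, ancestor)`; intervals of
#'   one sample are pairwise disjoint and exactly-adjacent rows with the same
#'   `(ancestor, sample)` have been merged. Attributes `sequence_length` and
#'   `samples` carry the query context.
#' @examples
#' tb <- ts_tables(
#'   nodes = data.frame(time = c(0, 0, 1, 1, 2), is_sample = c(1, 1, 0, 0, 0)),
#'   edges = data.frame(left  = c(0, 0, 5, 0), right = c(10, 5, 10, 10),
#'                      parent = c(2, 2, 3, 4), child = c(0, 1, 1, 2)),
#'   sequence_length = 10
#' )
#' link_ancestors(tb, samples = c(0, 1), ancestors = c(2, 3))
#' @export
link_ancestors <- function(tables, samples, ancestors) {
  if (!inherits(tables, "ts_tables")) stop_format("`tables` must be a ts_tables object")
  ids <- check_sample_ancestor_ids(tables, samples, ancestors)
  if (!edges_sorted(tables)) {
    al_log("edges not in canonical order; sorting internally")
    tables <- sort_edges(tables)
  }
  n <- nrow(tables$nodes)
  anc_flag <- logical(n)
  anc_flag[ids$ancestors + 1L] <- TRUE
  ed <- tables$edges
  raw <- link_ancestors_cpp(ed$left, ed$right, ed$parent, ed$child,
                            n, ids$samples, anc_flag, tables$sequence_length)
  finalize_ancestry_rows(raw$left, raw$right, raw$ancestor, raw$sample,
                         tables$sequence_length, ids$samples)
}

#' @export
as.data.frame.ancestry_table <- function(x, row.names = NULL, optional = FALSE, ...) {
  attr(x, "sequence_length") <- NULL
  attr(x, "samples") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.ancestry_table <- function(x, ...) {
  cat(sprintf("<ancestry_table> %d link(s), L = %s\n",
              nrow(x), format(attr(x, "sequence_length"))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Per-sample coverage of an ancestry table
#'
#' Decomposes `[0, L)` for each sample into the assigned length (total length
#' of its ancestry links) and the unassigned complement. With ancestors taken
#' as all nodes at a census generation, every lineage is intercepted and the
#' assigned length equals `L` exactly for every sample.
#'
#' @param links an `ancestry_table` from [link_ancestors()] or
#'   [local_ancestry_naive()].
#' @param samples sample ids to report on; defaults to the table's `samples`
#'   attribute.
#' @param sequence_length the genome length; defaults to the table's
#'   `sequence_length` attribute.
#' @return A list of class `coverage_report`: `summary` (data frame with
#'   `sample`, `assigned`, `unassigned`) and `gaps` (data frame with
#'   `sample`, `left`, `right` for every unassigned interval).
#' @export
coverage_report <- function(links, samples = attr(links, "samples"),
                            sequence_length = attr(links, "sequence_length")) {
  if (is.null(samples)) stop_usage("`samples` is required when `links` carries no samples attribute")
  if (is.null(sequence_length)) stop_usage("`sequence_length` is required")
  L <- sequence_length
  samples <- as.integer(samples)
  g_s <- integer(0); g_l <- numeric(0); g_r <- numeric(0)
  assigned <- numeric(length(samples))
  for (k in seq_along(samples)) {
    s <- samples[k]
    idx <- which(links$sample == s)
    if (!length(idx)) {
      g_s <- c(g_s, s); g_l <- c(g_l, 0); g_r <- c(g_r, L)
      next
    }
    l <- links$left[idx]; r <- links$right[idx]
    o <- order(l)
    l <- l[o]; r <- r[o]
    assigned[k] <- sum(r - l)
    bounds_l <- c(0, r)
    bounds_r <- c(l, L)
    gap <- bounds_l < bounds_r
    if (any(gap)) {
      g_s <- c(g_s, rep(s, sum(gap)))
      g_l <- c(g_l, bounds_l[gap]); g_r <- c(g_r, bounds_r[gap])
    }
  }
  structure(
    list(
      summary = data.frame(sample = samples, assigned = assigned,
                           unassigned = L - assigned),
      gaps = data.frame(sample = g_s, left = g_l, right = g_r)
    ),
    sequence_length = L,
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  L <- attr(x, "sequence_length")
  full <- sum(x$summary$assigned == L)
  cat(sprintf("<coverage_report> %d sample(s), %d fully assigned, %d gap interval(s)\n",
              nrow(x$summary), full, nrow(x$gaps)))
  print.data.frame(x$summary, ...)
  invisible(x)
}
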