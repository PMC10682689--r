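# Tree-by-tree reference engine. Reconstructs each local tree by a
# left-to-right sweep over edge insertions and removals, then climbs from
# every sample to the first requested ancestor. Deliberately simple: this
# module defines the semantics the single-pass engine must reproduce, and is
# written for clarity rather than speed.

# Internal sweep: calls fn(left, right, parent) for each region of constant
# topology. `parent` is an integer vector indexed by node id + 1 (NA = no
# parent on this interval). Intervals tile [0, L).
sweep_local_trees <- function(tables, fn) {
  ed <- tables$edges
  L <- tables$sequence_length
  n <- nrow(tables$nodes)
  bp <- sort(unique(c(0, L, ed$left, ed$right)))
  bp <- bp[bp >= 0 & bp <= L]
  parent <- rep(NA_integer_, n)
  ne <- nrow(ed)
  ord_ins <- order(ed$left, method = "radix")
  ord_rem <- order(ed$right, method = "radix")
  ii <- 1L; jj <- 1L
  for (k in seq_len(length(bp) - 1L)) {
    x <- bp[k]
    while (jj <= ne && ed$right[ord_rem[jj]] <= x) {
      parent[ed$child[ord_rem[jj]] + 1L] <- NA_integer_
      jj <- jj + 1L
    }
    while (ii <= ne && ed$left[ord_ins[ii]] <= x) {
      e <- ord_ins[ii]
      parent[ed$child[e] + 1L] <- ed$parent[e]
      ii <- ii + 1L
    }
    fn(bp[k], bp[k + 1L], parent)
  }
  invisible(NULL)
}

#' Enumerate the local trees of a tree sequence
#'
#' Sweeps left to right across the genome, inserting and removing edges at
#' recombination breakpoints, and returns each region of constant topology
#' with its parent-pointer array. The intervals partition `[0, L)`; the
#' breakpoints are exactly the distinct edge endpoints (plus 0 and L).
#'
#' @param tables a [ts_tables()] bundle.
#' @return A list with one element per local tree: `list(left, right,
#'   parent)`, where `parent[i + 1]` is the parent node id of node `i` on
#'   that interval (`NA` for roots / isolated nodes).
#' @export
local_trees <- function(tables) {
  if (!inherits(tables, "ts_tables")) stop_format("`tables` must be a ts_tables object")
  out <- list()
  sweep_local_trees(tables, function(l, r, parent) {
    out[[length(out) + 1L]] <<- list(left = l, right = r, parent = parent)
  })
  out
}

#' Climb from a sample to its most recent requested ancestor
#'
#' Follows parent pointers upward from `sample` (the sample itself excluded)
#' and returns the first node encountered that belongs to `ancestors`, or
#' `NA` if the chain ends at a root first.
#'
#' @param parent parent-pointer array as returned by [local_trees()]
#'   (`parent[i + 1]` = parent of node `i`, `NA` for none).
#' @param sample a single node id.
#' @param ancestors non-empty vector of node ids.
#' @return The ancestor node id, or `NA_integer_`.
#' @export
climb_to_ancestor <- function(parent, sample, ancestors) {
  if (length(ancestors) == 0) stop_usage("`ancestors` must be non-empty")
  cur <- parent[as.integer(sample) + 1L]
  steps <- 0L
  n <- length(parent)
  while (!is.na(cur)) {
    steps <- steps + 1L
    if (steps > n) stop_domain("cycle detected while climbing from node %d", sample)
    if (cur %in% ancestors) return(as.integer(cur))
    cur <- parent[cur + 1L]
  }
  NA_integer_
}

#' Local ancestry by exhaustive per-tree climbing (reference engine)
#'
#' Computes the same ancestry links as [link_ancestors()] by the direct
#' definition: for every local tree and every sample, climb from the sample
#' toward the root and record the first requested ancestor on the path; then
#' merge runs of consecutive intervals with the same assignment. This is the
#' behavioural reference for the single-pass engine — slow (every tree is
#' visited for every sample) but transparently correct.
#'
#' @inheritParams link_ancestors
#' @return An `ancestry_table` identical in content and ordering to the one
#'   [link_ancestors()] returns for the same query.
#' @export
local_ancestry_naive <- function(tables, samples, ancestors) {
  if (!inherits(tables, "ts_tables")) stop_format("`tables` must be a ts_tables object")
  ids <- check_sample_ancestor_ids(tables, samples, ancestors)
  samples <- ids$samples; ancestors <- ids$ancestors
  n <- nrow(tables$nodes)
  anc_flag <- logical(n)
  anc_flag[ancestors + 1L] <- TRUE
  m <- length(samples)

  iv_l <- numeric(0); iv_r <- numeric(0)
  assign_rows <- list()
  sweep_local_trees(tables, function(l, r, parent) {
    # vectorized simultaneous climb of all samples on this tree
    cur <- parent[samples + 1L]
    res <- rep(NA_integer_, m)
    act <- which(!is.na(cur))
    steps <- 0L
    while (length(act)) {
      steps <- steps + 1L
      if (steps > n) stop_domain("cycle detected in parent pointers")
      hit <- anc_flag[cur[act] + 1L]
      res[act[hit]] <- cur[act[hit]]
      act <- act[!hit]
      cur[act] <- parent[cur[act] + 1L]
      act <- act[!is.na(cur[act])]
    }
    iv_l[length(iv_l) + 1L] <<- l
    iv_r[length(iv_r) + 1L] <<- r
    assign_rows[[length(assign_rows) + 1L]] <<- res
  })

  n_iv <- length(iv_l)
  out_l <- numeric(0); out_r <- numeric(0); out_a <- integer(0); out_s <- integer(0)
  if (n_iv) {
    amat <- matrix(unlist(assign_rows), nrow = n_iv, ncol = m, byrow = TRUE)
    for (j in seq_len(m)) {
      v <- amat[, j]
      sent <- ifelse(is.na(v), -1L, v)  # ancestor ids are >= 0
      runs <- rle(sent)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      keep <- runs$values >= 0L
      if (any(keep)) {
        out_l <- c(out_l, iv_l[starts[keep]])
        out_r <- c(out_r, iv_r[ends[keep]])
        out_a <- c(out_a, runs$values[keep])
        out_s <- c(out_s, rep(samples[j], sum(keep)))
      }
    }
  }
  finalize_ancestry_rows(out_l, out_r, out_a, out_s,
                         tables$sequence_length, samples)
}
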