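# Tree-sequence table bundle: the minimal data model of a succinct tree
# sequence. Nodes are haplotypes (contemporary and ancestral), each with a
# time (generations before present) and a population; edges record that a
# child node inherited the half-open genomic interval [left, right) from a
# parent node. Node ids are 0-based row indices, following the tree-sequence
# convention.

#' Construct a tree-sequence table bundle
#'
#' Bundles a node table, an edge table and a population table together with
#' the sequence length. This is the container consumed by every other
#' function in the package. Node ids are implicit 0-based row indices of the
#' node table; all coordinates are 0-based, half-open `[left, right)` and may
#' be real-valued.
#'
#' @param nodes data frame with columns `time` (generations before present,
#'   non-negative), and optionally `population` (0-based population id or -1
#'   for unknown, default -1), `is_sample` (0/1, default 0) and `is_census`
#'   (0/1, default 0).
#' @param edges data frame with columns `left`, `right` (positions in
#'   `[0, sequence_length]`), `parent`, `child` (0-based node ids).
#' @param populations data frame with columns `id` (0-based, contiguous) and
#'   `name`, or `NULL` for no population table.
#' @param sequence_length positive scalar, the length of the genome.
#' @return An object of class `ts_tables`: a list with elements
#'   `sequence_length`, `nodes`, `edges`, `populations`.
#' @examples
#' tb <- ts_tables(
#'   nodes = data.frame(time = c(0, 0, 1), is_sample = c(1, 1, 0)),
#'   edges = data.frame(left = 0, right = c(10, 10), parent = 2, child = c(0, 1)),
#'   sequence_length = 10
#' )
#' validate_tables(tb)
#' @export
ts_tables <- function(nodes, edges, populations = NULL, sequence_length) {
  if (!is.data.frame(nodes)) stop_format("`nodes` must be a data frame")
  if (!is.data.frame(edges)) stop_format("`edges` must be a data frame")
  if (!is.numeric(sequence_length) || length(sequence_length) != 1 ||
      is.na(sequence_length)) {
    stop_format("`sequence_length` must be a single number")
  }
  if (!"time" %in% names(nodes)) stop_format("node table lacks column 'time'")
  n <- nrow(nodes)
  nodes <- data.frame(
    time       = as.numeric(nodes$time),
    population = as.integer(if ("population" %in% names(nodes)) nodes$population else rep(-1L, n)),
    is_sample  = as.integer(if ("is_sample" %in% names(nodes)) nodes$is_sample else rep(0L, n)),
    is_census  = as.integer(if ("is_census" %in% names(nodes)) nodes$is_census else rep(0L, n))
  )
  req <- c("left", "right", "parent", "child")
  miss <- setdiff(req, names(edges))
  if (length(miss)) stop_format("edge table lacks column(s): %s", paste(miss, collapse = ", "))
  edges <- data.frame(
    left   = as.numeric(edges$left),
    right  = as.numeric(edges$right),
    parent = as.integer(edges$parent),
    child  = as.integer(edges$child)
  )
  if (is.null(populations)) {
    populations <- data.frame(id = integer(0), name = character(0))
  } else {
    if (!all(c("id", "name") %in% names(populations))) {
      stop_format("population table needs columns 'id' and 'name'")
    }
    populations <- data.frame(
      id = as.integer(populations$id),
      name = as.character(populations$name)
    )
  }
  structure(
    list(sequence_length = as.numeric(sequence_length), nodes = nodes,
         edges = edges, populations = populations),
    class = "ts_tables"
  )
}

#' @export
print.ts_tables <- function(x, ...) {
  cat(sprintf(
    "<ts_tables> L = %s | %d nodes (%d samples, %d census) | %d edges | %d populations\n",
    format(x$sequence_length), nrow(x$nodes), sum(x$nodes$is_sample),
    sum(x$nodes$is_census), nrow(x$edges), nrow(x$populations)
  ))
  invisible(x)
}

#' Validate a table bundle against the tree-sequence invariants
#'
#' Checks every structural invariant of the data model: node times
#' non-negative, population references resolvable, edge intervals inside
#' `[0, sequence_length)` with `left < right`, strict time ordering
#' `time(child) < time(parent)`, no self-edges, pairwise non-overlapping
#' parental intervals for each child (each position of a genome inherits
#' from at most one parent), and canonical edge ordering by
#' `(parent time, parent, child, left)`.
#'
#' Violations are reported, not thrown, so a bundle can be inspected and
#' repaired; only structurally unusable input (not a `ts_tables` object)
#' raises an error.
#'
#' @param tables a [ts_tables()] bundle.
#' @return A data frame of class `validation_report` with columns `table`,
#'   `row` (0-based row index or `NA`), `message`; zero rows means valid.
#' @export
validate_tables <- function(tables) {
  if (!inherits(tables, "ts_tables")) stop_format("`tables` must be a ts_tables object")
  v_tab <- character(0); v_row <- integer(0); v_msg <- character(0)
  add <- function(tab, row, msg) {
    v_tab <<- c(v_tab, tab); v_row <<- c(v_row, row); v_msg <<- c(v_msg, msg)
  }
  L <- tables$sequence_length
  nd <- tables$nodes; ed <- tables$edges; pp <- tables$populations
  n <- nrow(nd)

  if (!is.finite(L) || L <= 0) add("bundle", NA_integer_, "sequence_length must be positive and finite")

  if (nrow(pp)) {
    if (!identical(pp$id, seq_len(nrow(pp)) - 1L)) {
      add("populations", NA_integer_, "population ids must be contiguous 0..K-1")
    }
    if (anyDuplicated(pp$name)) add("populations", NA_integer_, "population names must be unique")
  }

  bad <- which(!is.finite(nd$time) | nd$time < 0)
  for (i in bad) add("nodes", i - 1L, sprintf("node %d: time must be >= 0", i - 1L))
  if (nrow(pp)) {  # with no population table, population ids are unresolvable labels
    pop_ok <- nd$population == -1L | (nd$population >= 0L & nd$population < nrow(pp))
    for (i in which(!pop_ok)) {
      add("nodes", i - 1L,
          sprintf("node %d: population %d does not index the population table", i - 1L, nd$population[i]))
    }
  }

  if (nrow(ed)) {
    for (i in seq_len(nrow(ed))) {
      l <- ed$left[i]; r <- ed$right[i]; p <- ed$parent[i]; ch <- ed$child[i]
      if (!is.finite(l) || !is.finite(r) || l >= r) {
        add("edges", i - 1L, sprintf("edge %d: requires left < right (got [%s, %s))", i - 1L, l, r))
      }
      if (is.finite(L) && (l < 0 || r > L)) {
        add("edges", i - 1L, sprintf("edge %d: interval [%s, %s) outside [0, %s]", i - 1L, l, r, L))
      }
      if (is.na(p) || p < 0L || p >= n) {
        add("edges", i - 1L, sprintf("edge %d: parent %s is not a node id", i - 1L, p))
        next
      }
      if (is.na(ch) || ch < 0L || ch >= n) {
        add("edges", i - 1L, sprintf("edge %d: child %s is not a node id", i - 1L, ch))
        next
      }
      if (p == ch) add("edges", i - 1L, sprintf("edge %d: parent equals child (%d)", i - 1L, p))
      else if (nd$time[ch + 1L] >= nd$time[p + 1L]) {
        add("edges", i - 1L,
            sprintf("edge %d: child time %s >= parent time %s (need time(child) < time(parent))",
                    i - 1L, nd$time[ch + 1L], nd$time[p + 1L]))
      }
    }

    # per-child parental intervals must be pairwise non-overlapping
    ok_ref <- !is.na(ed$child) & ed$child >= 0L & ed$child < n & is.finite(ed$left) & is.finite(ed$right)
    for (ch in unique(ed$child[ok_ref])) {
      idx <- which(ed$child == ch & ok_ref)
      if (length(idx) < 2) next
      o <- idx[order(ed$left[idx], ed$right[idx])]
      for (k in seq_len(length(o) - 1L)) {
        if (ed$right[o[k]] > ed$left[o[k + 1L]]) {
          add("edges", o[k + 1L] - 1L,
              sprintf("overlapping parental intervals for child %d on [%s, %s)",
                      ch, ed$left[o[k + 1L]], min(ed$right[o[k]], ed$right[o[k + 1L]])))
        }
      }
    }

    if (!edges_sorted(tables)) {
      add("edges", NA_integer_,
          "edges not in canonical order (parent time, parent, child, left)")
    }
  }

  structure(
    data.frame(table = v_tab, row = v_row, message = v_msg, stringsAsFactors = FALSE),
    class = c("validation_report", "data.frame")
  )
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<validation_report> valid: no violations\n")
  } else {
    cat(sprintf("<validation_report> %d violation(s):\n", nrow(x)))
    for (i in seq_len(nrow(x))) cat("  - ", x$message[i], "\n", sep = "")
  }
  invisible(x)
}

edge_sort_order <- function(tables) {
  ed <- tables$edges
  pt <- tables$nodes$time[ed$parent + 1L]
  order(pt, ed$parent, ed$child, ed$left, method = "radix")
}

edges_sorted <- function(tables) {
  o <- edge_sort_order(tables)
  !is.unsorted(o, strictly = FALSE) && all(o == seq_along(o))
}

#' Sort edges into canonical order
#'
#' Orders the edge table ascending by `(parent time, parent id, child id,
#' left)`, the sortedness requirement assumed by the single-pass ancestry
#' engine (edges must be visited from youngest parents to oldest). The sort
#' is stable and idempotent.
#'
#' @param tables a [ts_tables()] bundle.
#' @return The bundle with its edge table reordered.
#' @export
sort_edges <- function(tables) {
  if (!inherits(tables, "ts_tables")) stop_format("`tables` must be a ts_tables object")
  o <- edge_sort_order(tables)
  tables$edges <- tables$edges[o, , drop = FALSE]
  rownames(tables$edges) <- NULL
  tables
}

# ---- text I/O (tab-separated, tskit text-dump dialect) -----------------------

fmt_real <- function(x) {
  # full-precision decimal so read(write(x)) round-trips exactly
  out <- vapply(x, function(v) {
    if (is.finite(v) && v == round(v) && abs(v) < 2^53) sprintf("%.0f", v)
    else sprintf("%.17g", v)
  }, character(1))
  out
}

parse_numeric_col <- function(txt, col, path) {
  suppressWarnings(num <- as.numeric(txt))
  bad <- which(is.na(num) & !is.na(txt) & txt != "")
  if (length(bad)) {
    stop_format("%s: non-numeric value '%s' in column '%s' at data line %d",
                path, txt[bad[1]], col, bad[1])
  }
  if (anyNA(txt)) stop_format("%s: missing value in column '%s'", path, col)
  num
}

read_tsv_checked <- function(path, required, optional = character(0)) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop_format("%s: empty file (no header)", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(required, header)
  if (length(miss)) stop_format("%s: missing required column '%s'", path, miss[1])
  body <- lines[-1]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  nc <- length(header)
  bad_n <- which(lengths(cells) != nc)
  if (length(bad_n)) {
    stop_format("%s: expected %d fields but found %d at data line %d",
                path, nc, lengths(cells)[bad_n[1]], bad_n[1])
  }
  mat <- if (length(cells)) do.call(rbind, cells) else matrix(character(0), 0, nc)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  df[c(required, intersect(optional, header))]
}

read_sequence_length_comment <- function(path) {
  lines <- readLines(path, n = 50)
  hit <- grep("^#sequence_length=", lines, value = TRUE)
  if (!length(hit)) return(NULL)
  as.numeric(sub("^#sequence_length=", "", hit[1]))
}

#' Read tree-sequence tables from tab-separated text files
#'
#' Reads the node, edge and (optionally) population tables in the text
#' dialect of tree-sequence dumps: tab-separated files with a header row.
#' The node file must carry columns `id`, `is_sample`, `time`, `population`
#' (an `is_census` column is honoured when present); the edge file must carry
#' `left`, `right`, `parent`, `child`. Lines starting with `#` are comments;
#' a `#sequence_length=<L>` comment in the edge file supplies the sequence
#' length when the `sequence_length` argument is omitted.
#'
#' @param node_path,edge_path,population_path file paths; `population_path`
#'   may be `NULL`.
#' @param sequence_length sequence length; if `NULL`, taken from the
#'   `#sequence_length=` comment in the edge file.
#' @return A [ts_tables()] bundle with rows in file order.
#' @export
read_text_tables <- function(node_path, edge_path, population_path = NULL,
                             sequence_length = NULL) {
  ndf <- read_tsv_checked(node_path, c("id", "is_sample", "time", "population"),
                          optional = "is_census")
  ids <- parse_numeric_col(ndf$id, "id", node_path)
  if (nrow(ndf) && !identical(as.integer(ids), seq_len(nrow(ndf)) - 1L)) {
    stop_format("%s: node ids must be contiguous 0..n-1 in file order", node_path)
  }
  nodes <- data.frame(
    time       = parse_numeric_col(ndf$time, "time", node_path),
    population = as.integer(parse_numeric_col(ndf$population, "population", node_path)),
    is_sample  = as.integer(parse_numeric_col(ndf$is_sample, "is_sample", node_path)),
    is_census  = if ("is_census" %in% names(ndf)) {
      as.integer(parse_numeric_col(ndf$is_census, "is_census", node_path))
    } else rep(0L, nrow(ndf))
  )

  edf <- read_tsv_checked(edge_path, c("left", "right", "parent", "child"))
  edges <- data.frame(
    left   = parse_numeric_col(edf$left, "left", edge_path),
    right  = parse_numeric_col(edf$right, "right", edge_path),
    parent = as.integer(parse_numeric_col(edf$parent, "parent", edge_path)),
    child  = as.integer(parse_numeric_col(edf$child, "child", edge_path))
  )

  populations <- NULL
  if (!is.null(population_path)) {
    pdf <- read_tsv_checked(population_path, c("id", "name"))
    populations <- data.frame(
      id = as.integer(parse_numeric_col(pdf$id, "id", population_path)),
      name = as.character(pdf$name)
    )
  }

  if (is.null(sequence_length)) {
    sequence_length <- read_sequence_length_comment(edge_path)
    if (is.null(sequence_length)) {
      stop_format("sequence length not given and no #sequence_length= comment in %s", edge_path)
    }
  }
  ts_tables(nodes, edges, populations, sequence_length)
}

#' Write tree-sequence tables to tab-separated text files
#'
#' Writes the bundle in the same dialect [read_text_tables()] reads.
#' Real-valued positions and times are printed with full precision so that
#' `read_text_tables(write_text_tables(x))` reproduces `x` exactly. The edge
#' file starts with a `#sequence_length=<L>` comment.
#'
#' @param tables a [ts_tables()] bundle.
#' @param node_path,edge_path,population_path output file paths;
#'   `population_path` may be `NULL` to skip the population table.
#' @return Invisibly, a character vector of the paths written.
#' @export
write_text_tables <- function(tables, node_path, edge_path, population_path = NULL) {
  if (!inherits(tables, "ts_tables")) stop_format("`tables` must be a ts_tables object")
  nd <- tables$nodes
  n_lines <- c(
    "id\tis_sample\ttime\tpopulation\tis_census",
    if (nrow(nd)) sprintf("%d\t%d\t%s\t%d\t%d", seq_len(nrow(nd)) - 1L,
                          nd$is_sample, fmt_real(nd$time), nd$population, nd$is_census)
  )
  writeLines(n_lines, node_path)

  ed <- tables$edges
  e_lines <- c(
    sprintf("#sequence_length=%s", fmt_real(tables$sequence_length)),
    "left\tright\tparent\tchild",
    if (nrow(ed)) sprintf("%s\t%s\t%d\t%d", fmt_real(ed$left), fmt_real(ed$right),
                          ed$parent, ed$child)
  )
  writeLines(e_lines, edge_path)

  written <- c(node_path, edge_path)
  if (!is.null(population_path)) {
    pp <- tables$populations
    p_lines <- c("id\tname", if (nrow(pp)) sprintf("%d\t%s", pp$id, pp$name))
    writeLines(p_lines, population_path)
    written <- c(written, population_path)
  }
  invisible(written)
}
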