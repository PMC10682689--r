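# Population-level post-processing of ancestry links: annotate each link
# with the population of its ancestor, squash exactly-adjacent same-
# population pieces into maximal tracts, and summarise tract tables.

#' Annotate ancestry links with ancestor populations
#'
#' Adds a `population` column to an ancestry table: for each link, the
#' population recorded for its ancestor node. Often only this label — not
#' the ancestor's identity — is of interest downstream; [squash()] then
#' merges neighbouring same-population pieces.
#'
#' @param links an `ancestry_table` from [link_ancestors()].
#' @param tables the [ts_tables()] bundle the links were computed from.
#' @return A data frame of class `pop_ancestry` with columns `sample`,
#'   `left`, `right`, `ancestor`, `population`; row count and order are those
#'   of `links`.
#' @export
annotate_populations <- function(links, tables) {
  if (!inherits(tables, "ts_tables")) stop_format("`tables` must be a ts_tables object")
  pop <- tables$nodes$population[links$ancestor + 1L]
  bad <- unique(links$ancestor[pop == -1L])
  if (length(bad)) {
    stop_domain("ancestor node(s) without a population label: %s",
                paste(sort(bad), collapse = ", "))
  }
  structure(
    data.frame(sample = links$sample, left = links$left, right = links$right,
               ancestor = links$ancestor, population = pop),
    sequence_length = attr(links, "sequence_length"),
    class = c("pop_ancestry", "data.frame")
  )
}

#' @export
as.data.frame.pop_ancestry <- function(x, row.names = NULL, optional = FALSE, ...) {
  attr(x, "sequence_length") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
as.data.frame.squashed_tracts <- function(x, row.names = NULL, optional = FALSE, ...) {
  attr(x, "sequence_length") <- NULL
  class(x) <- "data.frame"
  x
}

#' Squash ancestry pieces into maximal same-population tracts
#'
#' Per sample, sorts pieces by position and merges runs of exactly-adjacent
#' rows (`right[i] == left[i+1]`) that share a population, dropping the
#' ancestor column. Unassigned gaps are never bridged, so the per-sample
#' coverage decomposition is preserved, and the total length per
#' `(sample, population)` is conserved exactly. The operation is idempotent.
#'
#' @param pop_rows a `pop_ancestry` data frame from [annotate_populations()],
#'   or any data frame with columns `sample`, `left`, `right`, `population`;
#'   per-sample intervals must be pairwise disjoint.
#' @return A data frame of class `squashed_tracts` with columns `sample`,
#'   `left`, `right`, `population`, sorted by `(sample, left)`.
#' @export
squash <- function(pop_rows) {
  req <- c("sample", "left", "right", "population")
  miss <- setdiff(req, names(pop_rows))
  if (length(miss)) stop_format("squash input lacks column(s): %s", paste(miss, collapse = ", "))
  df <- pop_rows[req]
  if (nrow(df) == 0) {
    return(structure(df, sequence_length = attr(pop_rows, "sequence_length"),
                     class = c("squashed_tracts", "data.frame")))
  }
  o <- order(df$sample, df$left, method = "radix")
  df <- df[o, , drop = FALSE]
  n <- nrow(df)
  if (n > 1) {
    same_sample <- df$sample[-1] == df$sample[-n]
    overlap <- same_sample & df$left[-1] < df$right[-n]
    if (any(overlap)) {
      i <- which(overlap)[1]
      stop_domain("overlapping tracts for sample %d at [%s, %s)",
                  df$sample[i], df$left[i + 1], min(df$right[i], df$right[i + 1]))
    }
    extend <- same_sample &
      df$population[-1] == df$population[-n] &
      df$left[-1] == df$right[-n]
    grp <- cumsum(c(TRUE, !extend))
  } else {
    grp <- 1L
  }
  last <- cumsum(tabulate(grp))
  first <- c(1L, last[-length(last)] + 1L)
  out <- data.frame(sample = df$sample[first], left = df$left[first],
                    right = df$right[last], population = df$population[first])
  rownames(out) <- NULL
  structure(out, sequence_length = attr(pop_rows, "sequence_length"),
            class = c("squashed_tracts", "data.frame"))
}

#' Genome-wide ancestry fractions per sample
#'
#' Sums tract lengths per `(sample, population)` and divides by the sequence
#' length. Fractions of a sample sum to 1 when its genome is fully painted
#' (complete census coverage), and to less than 1 when gaps remain.
#'
#' @param squashed a `squashed_tracts` data frame from [squash()].
#' @param sequence_length genome length; defaults to the table's attribute.
#' @return Data frame with columns `sample`, `population`,
#'   `assigned_length`, `fraction`, sorted by `(sample, population)`.
#' @export
ancestry_fractions <- function(squashed, sequence_length = attr(squashed, "sequence_length")) {
  if (is.null(sequence_length)) stop_usage("`sequence_length` is required")
  if (nrow(squashed) == 0) {
    return(data.frame(sample = integer(0), population = integer(0),
                      assigned_length = numeric(0), fraction = numeric(0)))
  }
  len <- squashed$right - squashed$left
  agg <- stats::aggregate(len,
                          by = list(sample = squashed$sample,
                                    population = squashed$population),
                          FUN = sum)
  names(agg)[3] <- "assigned_length"
  agg$fraction <- agg$assigned_length / sequence_length
  agg <- agg[order(agg$sample, agg$population), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Tract length summaries per population
#'
#' @param squashed a `squashed_tracts` data frame from [squash()].
#' @return Data frame with one row per population: `population`, `count`,
#'   `mean`, `median`, `min`, `max` of tract lengths.
#' @export
tract_length_stats <- function(squashed) {
  if (nrow(squashed) == 0) {
    return(data.frame(population = integer(0), count = integer(0),
                      mean = numeric(0), median = numeric(0),
                      min = numeric(0), max = numeric(0)))
  }
  len <- squashed$right - squashed$left
  pops <- sort(unique(squashed$population))
  out <- do.call(rbind, lapply(pops, function(p) {
    x <- len[squashed$population == p]
    data.frame(population = p, count = length(x), mean = mean(x),
               median = stats::median(x), min = min(x), max = max(x))
  }))
  rownames(out) <- NULL
  out
}

#' Write squashed tracts as a BED file
#'
#' Each sample haplotype becomes its own BED "chromosome"; tracts are BED3+
#' rows `chrom  chromStart  chromEnd  name` with the population label in the
#' name field. BED shares the package's 0-based half-open convention, so
#' coordinates are written unchanged. Non-integer coordinates are an error
#' unless `round = TRUE` (floor start, ceil end, logged loudly), because
#' silent rounding corrupts tract lengths.
#'
#' @param squashed a `squashed_tracts` data frame.
#' @param path output file path.
#' @param sample_names named character vector mapping sample id to chromosome
#'   name, or `NULL` for `sample_<id>`.
#' @param population_names named character vector mapping population id to
#'   label, or `NULL` for the numeric id.
#' @param round logical; round non-integer coordinates outward instead of
#'   erroring.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(squashed, path, sample_names = NULL,
                      population_names = NULL, round = FALSE) {
  l <- squashed$left; r <- squashed$right
  if (nrow(squashed) && any(l != floor(l) | r != floor(r))) {
    if (!round) {
      stop_domain("non-integer coordinates; pass round = TRUE to floor starts and ceil ends")
    }
    al_log("rounding %d non-integer coordinate pair(s) outward for BED export",
           sum(l != floor(l) | r != floor(r)))
    l <- floor(l); r <- ceiling(r)
  }
  chrom <- if (is.null(sample_names)) {
    sprintf("sample_%d", squashed$sample)
  } else {
    unname(sample_names[as.character(squashed$sample)])
  }
  name <- if (is.null(population_names)) {
    as.character(squashed$population)
  } else {
    unname(population_names[as.character(squashed$population)])
  }
  lines <- if (nrow(squashed)) {
    sprintf("%s\t%s\t%s\t%s", chrom, fmt_real(l), fmt_real(r), name)
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of ancestry tracts
#'
#' Parses BED3+ rows written by [write_bed()] back into a tract data frame.
#' The chromosome and name fields are returned as written; mapping back to
#' numeric sample/population ids is the caller's concern.
#'
#' @param path BED file path.
#' @return Data frame with columns `chrom`, `left`, `right`, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), left = numeric(0),
                      right = numeric(0), name = character(0)))
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(cells) < 4)) stop_format("%s: BED rows need at least 4 fields", path)
  data.frame(
    chrom = vapply(cells, `[[`, character(1), 1),
    left = as.numeric(vapply(cells, `[[`, character(1), 2)),
    right = as.numeric(vapply(cells, `[[`, character(1), 3)),
    name = vapply(cells, `[[`, character(1), 4)
  )
}
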