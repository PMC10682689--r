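# Forward-time Wright-Fisher simulator with recombination, migration, an
# admixture pulse and census recording. Every genome of every generation is
# retained as a node (no table simplification), which makes census semantics
# exact: the nodes at a census generation intercept every genomic lineage,
# so linking samples to them paints each sample genome completely.
#
# Transmission model: each haploid child genome copies from two parent
# genomes drawn uniformly from one parent population (chosen by the
# migration / admixture rules), recombining them at Poisson(rho * l)
# breakpoints placed uniformly on the integers 1..l-1 (deduplicated), with
# segments alternating between the two parents. Integer breakpoints keep
# BED export lossless.

#' Wright-Fisher scenario parameters
#'
#' Describes a discrete-generation haploid Wright-Fisher model with
#' recombination, symmetric-or-not migration among populations, and an
#' optional single admixture pulse. The default scenario is the package's
#' demo admixture model: two source populations of 20 haploid genomes
#' exchanging migrants at rate 0.01 per generation, an admixed population
#' founded by a 50/50 pulse 10 generations ago, 30 generations simulated in
#' total, a 100 kb genome with per-base per-generation crossover rate 1e-5,
#' and a census recorded at generation 11 — the generation of the immediate
#' source-side ancestors of the pulse.
#'
#' @param pop_sizes integer vector of haploid population sizes (constant over
#'   time); names are used as population labels.
#' @param pop_names character labels, one per population.
#' @param migration K x K matrix; `migration[i, j]` is the per-generation
#'   probability that a genome of population `i` draws its parents from
#'   population `j` (`i != j`); rows must sum to at most 1, remainder = stay.
#' @param admixture `NULL`, or a list with `generation` (the first admixed
#'   cohort lives at this many generations before present; its parents, one
#'   generation older, are drawn from the sources), `proportions` (length-K
#'   probabilities over source populations, destination entry 0, summing
#'   to 1) and `destination` (0-based population id of the admixed
#'   population).
#' @param generations total number of generations G; founders live at time G,
#'   samples at time 0.
#' @param sequence_length genome length l (positive integer).
#' @param rho per-base, per-generation crossover probability; the expected
#'   number of breakpoints per transmission is `rho * sequence_length`.
#' @param census_generations integer vector of generations (each `< G`) at
#'   which every living genome is flagged as a census node.
#' @param sample_population 0-based population whose present-day genomes are
#'   the samples; defaults to the admixture destination (population 0 when
#'   there is no admixture).
#' @param sample_count number of present-day genomes flagged as samples;
#'   defaults to the full sample population.
#' @param seed integer seed; all randomness flows through it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(pop_sizes = c(20L, 20L, 20L),
                       pop_names = c("source_1", "source_2", "admixed"),
                       migration = NULL,
                       admixture = list(generation = 10L,
                                        proportions = c(0.5, 0.5, 0),
                                        destination = 2L),
                       generations = 30L,
                       sequence_length = 1e5,
                       rho = 1e-5,
                       census_generations = 11L,
                       sample_population = NULL,
                       sample_count = NULL,
                       seed = 1L) {
  K <- length(pop_sizes)
  if (K < 1 || any(pop_sizes < 1)) stop_usage("pop_sizes must be positive integers")
  if (length(pop_names) != K) stop_usage("pop_names must have one label per population")
  if (is.null(migration)) {
    migration <- matrix(0, K, K)
    if (K >= 2) {
      migration[1, 2] <- 0.01
      migration[2, 1] <- 0.01
    }
  }
  migration <- as.matrix(migration)
  if (!all(dim(migration) == c(K, K))) stop_usage("migration must be a K x K matrix")
  diag(migration) <- 0
  if (any(migration < 0) || any(rowSums(migration) > 1 + 1e-12)) {
    stop_usage("migration rates must be non-negative with row sums <= 1")
  }
  G <- as.integer(generations)
  if (G < 1) stop_usage("generations must be >= 1")
  if (!is.null(admixture)) {
    if (!all(c("generation", "proportions", "destination") %in% names(admixture))) {
      stop_usage("admixture needs fields generation, proportions, destination")
    }
    a <- as.integer(admixture$generation)
    d <- as.integer(admixture$destination)
    pr <- admixture$proportions
    if (a < 0 || a >= G) stop_usage("admixture generation must lie in [0, G)")
    if (d < 0 || d >= K) stop_usage("admixture destination must be a population id")
    if (length(pr) != K || abs(sum(pr) - 1) > 1e-9 || any(pr < 0) || pr[d + 1] != 0) {
      stop_usage("admixture proportions must be length K, sum to 1, with destination entry 0")
    }
    admixture <- list(generation = a, proportions = as.numeric(pr), destination = d)
  }
  l <- sequence_length
  if (!is.finite(l) || l < 2 || l != round(l)) {
    stop_usage("sequence_length must be an integer >= 2")
  }
  if (!is.finite(rho) || rho < 0) stop_usage("rho must be non-negative")
  census_generations <- sort(unique(as.integer(census_generations)))
  if (length(census_generations) && (any(census_generations < 1) || any(census_generations >= G))) {
    stop_usage("census generations must lie in [1, G)")
  }
  if (is.null(sample_population)) {
    sample_population <- if (is.null(admixture)) 0L else admixture$destination
  }
  sample_population <- as.integer(sample_population)
  if (sample_population < 0 || sample_population >= K) {
    stop_usage("sample_population must be a population id")
  }
  if (is.null(sample_count)) sample_count <- pop_sizes[sample_population + 1]
  sample_count <- as.integer(sample_count)
  if (sample_count < 1 || sample_count > pop_sizes[sample_population + 1]) {
    stop_usage("sample_count must lie in [1, size of sample population]")
  }
  structure(
    list(pop_sizes = as.integer(pop_sizes), pop_names = as.character(pop_names),
         migration = migration, admixture = admixture, generations = G,
         sequence_length = as.numeric(l), rho = as.numeric(rho),
         census_generations = census_generations,
         sample_population = sample_population, sample_count = sample_count,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Simulate a Wright-Fisher admixture scenario
#'
#' Runs the discrete-generation model described by [sim_params()] forward
#' from the founder generation `G` down to the present (time 0), recording
#' every genome as a node and every transmission as one or more edges.
#' Output tables are in canonical edge order and satisfy every
#' [validate_tables()] invariant. Identical parameters (including the seed)
#' give identical results.
#'
#' @param params a [sim_params()] object.
#' @return A list of class `wf_sim` with elements `tables` (a [ts_tables()]
#'   bundle), `census_nodes` (list mapping census generation to node ids),
#'   `sample_nodes` (ids of the flagged present-day samples) and `params`.
#' @export
simulate_wf <- function(params) {
  if (!inherits(params, "sim_params")) stop_usage("`params` must be a sim_params object")
  set.seed(params$seed)
  K <- length(params$pop_sizes)
  G <- params$generations
  l <- params$sequence_length
  rho <- params$rho
  sizes <- params$pop_sizes
  n_gen <- sum(sizes)
  pop_start <- c(0L, cumsum(sizes))[seq_len(K)]  # offset of each pop within a generation

  # node ids generation-major, oldest first: time t occupies
  # (G - t) * n_gen + 0:(n_gen - 1); within a generation, populations in order
  gen_offset <- function(t) (G - t) * n_gen
  node_pop <- rep(rep.int(seq_len(K) - 1L, sizes), G + 1L)
  node_time <- rep(G:0, each = n_gen)

  # per-generation migration/admixture parent-population distributions
  stay <- 1 - rowSums(params$migration)
  base_probs <- params$migration
  diag(base_probs) <- stay

  e_left <- vector("list", G)
  e_right <- vector("list", G)
  e_parent <- vector("list", G)
  e_child <- vector("list", G)

  for (t in (G - 1L):0L) {
    child_ids <- gen_offset(t) + 0:(n_gen - 1L)
    child_pop <- node_pop[child_ids + 1L]
    # choose the source population of each of the two parent genomes
    # independently (migration and admixture act per gamete)
    draw_parent_pop <- function() {
      pp <- integer(n_gen)
      for (i in seq_len(K) - 1L) {
        idx <- which(child_pop == i)
        if (!length(idx)) next
        probs <- if (!is.null(params$admixture) && t == params$admixture$generation &&
                     i == params$admixture$destination) {
          params$admixture$proportions
        } else {
          base_probs[i + 1L, ]
        }
        pp[idx] <- sample.int(K, length(idx), replace = TRUE, prob = probs) - 1L
      }
      pp
    }
    pop1 <- draw_parent_pop()
    pop2 <- draw_parent_pop()
    # a uniform parent genome within each chosen population, one generation older
    sz1 <- sizes[pop1 + 1L]
    sz2 <- sizes[pop2 + 1L]
    p1 <- gen_offset(t + 1L) + pop_start[pop1 + 1L] +
      (floor(stats::runif(n_gen) * sz1)) %% sz1
    p2 <- gen_offset(t + 1L) + pop_start[pop2 + 1L] +
      (floor(stats::runif(n_gen) * sz2)) %% sz2
    nb <- stats::rpois(n_gen, rho * l)

    plain <- nb == 0L | p1 == p2
    ll <- list(rep(0, sum(plain)))
    rr <- list(rep(l, sum(plain)))
    pp <- list(as.integer(p1[plain]))
    cc <- list(as.integer(child_ids[plain]))
    for (k in which(!plain)) {
      brk <- sort(unique(ceiling(stats::runif(nb[k]) * (l - 1))))
      bounds <- c(0, brk, l)
      ns <- length(bounds) - 1L
      pars <- rep_len(c(p1[k], p2[k]), ns)
      ll[[length(ll) + 1L]] <- bounds[-length(bounds)]
      rr[[length(rr) + 1L]] <- bounds[-1L]
      pp[[length(pp) + 1L]] <- as.integer(pars)
      cc[[length(cc) + 1L]] <- rep.int(as.integer(child_ids[k]), ns)
    }
    e_left[[G - t]] <- unlist(ll)
    e_right[[G - t]] <- unlist(rr)
    e_parent[[G - t]] <- unlist(pp)
    e_child[[G - t]] <- unlist(cc)
  }

  edges <- data.frame(left = unlist(e_left), right = unlist(e_right),
                      parent = unlist(e_parent), child = unlist(e_child))

  is_census <- as.integer(node_time %in% params$census_generations)
  sample_block <- gen_offset(0L) + pop_start[params$sample_population + 1L]
  sample_nodes <- sample_block + 0:(params$sample_count - 1L)
  is_sample <- integer(length(node_time))
  is_sample[sample_nodes + 1L] <- 1L

  nodes <- data.frame(time = as.numeric(node_time), population = node_pop,
                      is_sample = is_sample, is_census = is_census)
  populations <- data.frame(id = seq_len(K) - 1L, name = params$pop_names)
  tables <- sort_edges(ts_tables(nodes, edges, populations, l))

  census_nodes <- lapply(params$census_generations, function(g) {
    gen_offset(g) + 0:(n_gen - 1L)
  })
  names(census_nodes) <- as.character(params$census_generations)

  structure(
    list(tables = tables, census_nodes = census_nodes,
         sample_nodes = as.integer(sample_nodes), params = params),
    class = "wf_sim"
  )
}

#' @export
print.wf_sim <- function(x, ...) {
  cat(sprintf(
    "<wf_sim> %d population(s), G = %d, l = %s, rho = %g, seed = %d\n",
    length(x$params$pop_sizes), x$params$generations,
    format(x$params$sequence_length), x$params$rho, x$params$seed))
  print(x$tables)
  invisible(x)
}

#' Census nodes of a simulation result
#'
#' Returns the node ids of every genome alive at a requested census
#' generation — exactly the ancestor set that makes local ancestry fully
#' defined at that depth.
#'
#' @param result a `wf_sim` object from [simulate_wf()].
#' @param generation one of the generations censused in the parameters.
#' @return Integer vector of node ids.
#' @export
census_nodes <- function(result, generation) {
  if (!inherits(result, "wf_sim")) stop_usage("`result` must be a wf_sim object")
  key <- as.character(as.integer(generation))
  if (!key %in% names(result$census_nodes)) {
    stop_usage("generation %s was not censused (available: %s)", key,
               paste(names(result$census_nodes), collapse = ", "))
  }
  result$census_nodes[[key]]
}

#' Expected number of ancestry tracts per sample
#'
#' With per-base per-generation crossover rate `rho` on a genome of length
#' `l`, each generation back adds an expected `rho * l` recombination
#' breakpoints separating a genome from its ancestors, so a genome viewed
#' against ancestors `t` generations back is expected to fall into about
#' `1 + rho * l * t` distinct segments.
#'
#' @param rho per-base per-generation crossover rate (non-negative).
#' @param l genome length (non-negative).
#' @param t census depth in generations (non-negative); vectorized.
#' @return `1 + rho * l * t`.
#' @export
expected_tract_count <- function(rho, l, t) {
  if (any(rho < 0) || any(l < 0) || any(t < 0)) {
    stop_usage("rho, l and t must be non-negative")
  }
  1 + rho * l * t
}
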