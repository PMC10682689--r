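---
title: "Extracting local ancestry tracts from tree-sequence tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting local ancestry tracts from tree-sequence tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestrylink)
```

## The problem

A succinct tree sequence stores the full genealogical history of a set of
sampled genomes in two tables: *nodes* (haplotypes, each with a time in
generations before present) and *edges* `(left, right, parent, child)`,
each recording that the child inherited the half-open genomic interval
`[left, right)` from the parent. Simulators that output this format contain,
implicitly, everything there is to know about each sample's *local
ancestry*: for every position of every sampled genome, which ancestor — and
hence which ancestral population — it was inherited from at some reference
time in the past.

Making that information explicit is the task this package addresses. The
user picks a set of **census ancestors**: typically every node recorded at
one chosen time (the *census time*). Local ancestry is then well defined:
position `x` of sample `s` is assigned to the first member of the census set
encountered on the path from `s` toward the root of the local tree at `x`.
When several supplied ancestors lie on one path (possible when ancestors
span multiple times, or with ongoing migration), the *most recent* one wins;
this disambiguation is part of the definition, not an implementation detail.

## Two engines, one contract

`local_ancestry_naive()` implements the definition directly: sweep across
the genome, reconstruct each local tree between recombination breakpoints,
and climb from every sample to its first census ancestor. It is transparent
and easy to audit, but visits every tree for every sample.

`link_ancestors()` computes the same result in a single pass over the edge
table, which is ordered by parent time (youngest first). Every sample starts
with one segment spanning the genome; each edge `(l, r, p, c)` moves the
parts of `c`'s segments inside `[l, r)` up to `p`, splitting at breakpoints
as it goes. Because all of a node's child-edges are processed before any of
its parent-edges (child times are strictly below parent times), a node's
segment list is complete when its material moves on. Segments are *emitted*
— not forwarded — when they reach a requested ancestor, which implements the
most-recent-ancestor rule for free. Shared parts of the calculation are done
once rather than once per tree, which is where the speed comes from; the
core loop is compiled (C++), as is usual for this class of algorithm.

The test suite asserts row-for-row identity of the two engines on hand
fixtures, random layered genealogies with real-valued coordinates, and 200
simulated admixture scenarios of varying shape. The naive engine *is* the
behavioural contract; the fast engine must match it exactly, including row
order and the merging of exactly-adjacent same-ancestor pieces.

Both engines emit output sorted by `(sample, left, ancestor)` with
exactly-adjacent rows of equal `(ancestor, sample)` merged, so identical
queries give byte-identical files. Splitting any edge in two at an interior
point provably leaves the output unchanged (tested), which is why the
single-pass engine may fragment segments freely during the sweep.

## From links to population tracts

`annotate_populations()` adds the ancestor's population to each link row;
`squash()` then merges *exactly adjacent* same-population rows of a sample
into maximal tracts. Two choices matter:

* **Gaps are never bridged.** If part of a genome reaches no census
  ancestor (possible when the census set is a strict subset of a
  generation), the unassigned interval survives squashing, so the
  assigned/unassigned decomposition of `coverage_report()` is preserved
  exactly.
* **Squashing is exact interval algebra**, not an approximation: it is
  idempotent, preserves total length per `(sample, population)` to the last
  ulp (coordinates are never rounded), and equals a brute-force
  position-by-position repaint, which the tests assert on a thousand random
  tract tables.

BED export writes one BED "chromosome" per sample haplotype. Coordinates
pass through unchanged (BED shares the 0-based half-open convention);
non-integer coordinates are an error unless rounding is explicitly
requested, because silent rounding corrupts tract lengths.

## The simulator and what it emulates

`simulate_wf()` is a forward-time haploid Wright–Fisher model with
recombination, migration, an optional single admixture pulse, and census
recording. It exists so that every claim in this package can be tested
end-to-end on data whose truth is known by construction, with no external
inputs. Design choices:

* **No table simplification.** Every genome of every generation is kept as
  a node. Memory is unproblematic at the scales used here (≤ ~10^5 nodes),
  and census semantics become trivially exact: the nodes at generation `g`
  intercept *every* genomic lineage, so linking samples to a full census
  must cover each sample genome completely — an exact invariant the tests
  check, not a statistical one.
* **Transmission.** Each child genome draws two parent genomes and
  recombines them at `Poisson(rho * l)` breakpoints placed uniformly on the
  integers `1..l-1` (deduplicated), alternating parents between segments.
  The source population of *each* parent is drawn independently through the
  migration (or, at the pulse, admixture-proportion) rules — migration acts
  per gamete. This matters: if both parents always came from one
  population, population labels could never change at newly added
  breakpoints, and tract tables would be almost insensitive to census
  depth. Integer breakpoints make BED export lossless.
* **The demo scenario** (the parameter defaults) is a two-source admixture
  model: sources of 20 haploid genomes each exchanging migrants at 0.01 per
  generation, an admixed population founded by a 50/50 pulse 10 generations
  ago, 30 generations in total, a 100 kb genome with crossover rate 1e-5
  per base per generation, and a census at generation 11 — the source-side
  parents of the pulse. These sizes keep a full
  simulate–link–verify cycle well under a second while leaving room for
  hundreds of replicates in the test suite.

What the simulator does *not* emulate: diploidy and pedigrees, selection,
mutation (ancestry extraction never touches genotypes), varying population
sizes, or chromosome-scale recombination maps. Tests passing on this model
show the *algorithms* are exact on valid tables of arbitrary shape; they do
not validate any demographic realism beyond the Wright–Fisher assumptions.

## The tract-count scaling law

With per-base per-generation crossover rate `rho` on a genome of length
`l`, each generation back adds an expected `rho * l` breakpoints separating
a genome from its ancestors, so the expected number of distinct segments at
census depth `t` is about `1 + rho * l * t` (`expected_tract_count()`). The
acceptance suite regresses observed mean per-sample segment counts on
census depth (depths 5–40, one population of 500 to keep coalescent
merging mild, `rho * l = 0.5`, 180 sampled genomes over three replicates)
and requires the slope within ±25% of `rho * l` and intercept within 0.5
of 1. The observed slope sits a few percent *below* `rho * l` because
adjacent segments occasionally coalesce into the same ancestor and merge —
a real effect of finite population size, growing with `t/N`, not an
artefact.

A note on census *timing* and population tracts: moving the census deeper
refines the link table (more, shorter ancestor tracts — the scaling law
above), but after squashing to population labels the one-generation
difference under the demo's migration rate (0.01) is a near-tie: new
breakpoints separate parents that rarely lie in different populations, and
occasional whole-ancestor label flips add or remove switches with nearly
zero mean. The pipeline tests therefore assert refinement on the annotated
tract table at one-generation spacing, and the systematic growth of
squashed tract counts across a four-generation census shift, where the
migration signal is clearly positive.

## Numerical and degenerate-input policy

* Coordinates and times are doubles throughout; all interval arithmetic is
  exact comparisons and min/max — no tolerances anywhere in the core.
* Text tables print reals with up to 17 significant digits, so
  `read_text_tables(write_text_tables(x))` reproduces `x` exactly.
* Edges must satisfy `time(child) < time(parent)` strictly; zero-length
  branches and zero-length intervals are rejected by validation.
* `link_ancestors()` sorts unsorted edge tables internally (logged) rather
  than rejecting them; ancestors at heterogeneous times are accepted with a
  warning, since the most-recent rule keeps the semantics well defined.
* Samples overlapping the ancestor set are an error: same-node
  self-ancestry has no meaning in this model. Samples that are internal
  (ancestral to other samples) are supported and logged; each sample is
  traced independently.
* Empty edge tables, samples with no ancestry, and header-only files are
  all legal and produce empty (not failing) outputs.

## Problem sizes used in the checks

The shipped suites use: 200 simulated scenarios (population sizes 5–30 per
population, 2–3 populations, 8–30 generations, `rho * l = 0.5` on 100 kb)
for engine equivalence; 3 × 500-genome simulations over 41 generations for
the scaling regression; 50 demo-scenario replicates for the pipeline
properties; and a 1000-sample, ~100-tree instance on which the single-pass
engine is required to beat the per-tree engine wall-clock (typical margin
≈ 20×). `scripts/acceptance.R` recomputes a condensed version of all of
these from scratch at a chosen seed.

## Known limitations

* The per-tree engine's parent arrays are dense per-node vectors; it is
  quadratic-ish in (trees × nodes) and intended for verification, not
  production use.
* Deep censuses on large simulations grow the in-flight segment lists of
  the single-pass engine; lists are pruned as soon as a node's last
  child-edge has been processed, but no garbage collection beyond that is
  attempted.
* Only node/edge/population tables are modelled; sites, mutations and
  migration-event tables are out of scope, as is reading the binary
  `.trees` format (the text dialect is the interchange surface).
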