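# ancestrylink

Local ancestry tract extraction from succinct tree-sequence tables.

Population-genetic simulators that output succinct tree sequences record, in
their node and edge tables, the complete genealogical history of the sampled
genomes — and therefore, implicitly, each sample's *local ancestry*: which
ancestor, and which ancestral population, every part of every sampled
chromosome was inherited from at a chosen reference time. `ancestrylink`
makes that information explicit. It is aimed at people building
simulation-based inference or exploratory analyses of admixture who need
tracts of true ancestry, exactly, at scale.

## What it computes

A tree sequence is a node table (haplotypes with times *t*, in generations
before present) and an edge table of rows *(l, r, p, c)*: child *c*
inherited the interval [*l*, *r*) from parent *p*, with *t(c) < t(p)*. Given
a set of **samples** *S* and a set of **census ancestors** *A* (typically
every node alive at one past "census time"), position *x* of sample *s* is
assigned to the *first* member of *A* on the path from *s* toward the root
of the local tree at *x* — the **most recent** requested ancestor. The
output is a table of links (*l, r, a, c*): sample *c* descends from ancestor
*a* on [*l*, *r*).

Two engines implement this contract:

* `link_ancestors()` — a single pass over the time-ordered edge table,
  carrying each sample's segments upward and emitting them as soon as they
  reach a node of *A*; the core loop is compiled. Shared edges are processed
  once, not once per local tree.
* `local_ancestry_naive()` — the transparent per-tree reference:
  reconstruct each local tree, climb from each sample. Slow by design; the
  test suite requires the fast engine to match it row for row.

Downstream, `annotate_populations()` adds the ancestor's population,
`squash()` merges exactly-adjacent same-population pieces into maximal
tracts (never bridging unassigned gaps), and `ancestry_fractions()` /
`tract_length_stats()` / `write_bed()` summarise and export. Because the
expected number of breakpoints added per generation is ρ·l (recombination
rate ρ, genome length l), a genome viewed against ancestors *t* generations
back splits into about 1 + ρ·l·t segments (`expected_tract_count()`); the
package's simulator and tests verify this scaling.

A forward-time Wright–Fisher simulator with recombination, migration, an
admixture pulse and census recording (`simulate_wf()`) generates fully valid
table bundles, so the entire pipeline is testable with no external data.

## Worked example

The demo scenario: two source populations (20 haploid genomes each, gene
flow 0.01/generation) found an admixed population via a 50/50 pulse 10
generations ago; a census records every genome at generation 11, the
source-side parents of the pulse.

```r
library(ancestrylink)

result <- simulate_wf(sim_params(seed = 42))
result
#> <wf_sim> 3 population(s), G = 30, l = 1e+05, rho = 1e-05, seed = 42
#> <ts_tables> L = 1e+05 | 1860 nodes (20 samples, 60 census) | 3460 edges | 3 populations

links <- link_ancestors(result$tables, result$sample_nodes,
                        census_nodes(result, 11))
head(as.data.frame(links), 3)
#>   left right ancestor sample
#> 1    0  2287     1155   1840
#> 2 2287 19297     1141   1840
#> 3 19297 22760    1175   1840
```

Sample 1840's chromosome is a mosaic of segments inherited from specific
census genomes (nodes 1155, 1141, 1175, ...). A full census intercepts every
lineage, so every base of every sample is assigned:

```r
coverage_report(links)
#> <coverage_report> 20 sample(s), 20 fully assigned, 0 gap interval(s)
```

Replacing ancestors by their populations and squashing gives admixture
tracts, painted by source:

```r
tracts <- squash(annotate_populations(links, result$tables))
head(as.data.frame(tracts), 4)
#>   sample  left right population
#> 1   1840     0 19297          0
#> 2   1840 19297 22760          1
#> 3   1840 22760 33618          0
#> 4   1840 33618 52774          1

head(ancestry_fractions(tracts), 2)
#>   sample population assigned_length fraction
#> 1   1840          0           69194  0.69194
#> 2   1840          1           30806  0.30806
```

So 69.2% of sample 1840's genome traces to source population 0 at the
census time, in tracts whose exact breakpoints are known. `write_bed()`
exports one BED "chromosome" per sample haplotype.

The same pipeline is available from the shell via the installed script
(`system.file("cli", "ancestry-link", package = "ancestrylink")`):

```sh
ancestry-link simulate --out sim --seed 42
ancestry-link trace   --nodes sim/nodes.tsv --edges sim/edges.tsv \
                      --samples @samples.txt --ancestors @census.txt --out run
ancestry-link squash  --nodes sim/nodes.tsv --edges sim/edges.tsv \
                      --populations sim/populations.tsv --links run/links.tsv --out run
```

Exit codes: 0 success, 1 domain violation, 2 usage/format error.

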