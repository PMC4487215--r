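# lenalign

Detection of protein complexes conserved between two protein–protein
interaction (PPI) networks, for computational biologists studying
cross-species module conservation. `lenalign` implements a
dividing-and-matching **local** network alignment: instead of seeking a
global one-to-one node mapping, it divides one network into candidate
subnetworks (known complexes or clusters), maps their proteins into the
other network through homology, and extracts the common connected
components — the conserved complex pairs.

Two ideas drive the method:

* **Unbalanced bi-random walk.** With `P` the row-normalised adjacency of
  network one, `H` the column-normalised adjacency of network two, and `A`
  the binary seed matrix of homologous pairs (bidirectional BLAST E-values
  `< 10⁻⁹`), the mapping matrix is propagated as

  ```
  R₀ = A
  Rₜ = α · (λp(t)·P·Rₜ₋₁ + λh(t)·Rₜ₋₁·H) / (λp(t)+λh(t)) + (1−α)·A
  ```

  for `t = 1…max(l, r)`, where `λp(t) = 1` iff `t ≤ l` and `λh(t) = 1` iff
  `t ≤ r`. The two networks receive *unequal* numbers of walk steps,
  reflecting their different densities; `α = 0.5` weighs topology against
  prior homology.

* **Unequally lenient connectivity.** While growing a conserved pair,
  connecting paths may span up to `l` edges in network one but up to `r`
  edges in network two. `l = r = 2` reproduces the common "path length at
  most 2" criterion; unequal settings adapt to unequal networks.

Solutions are scored against reference catalogues with the overlap score
`OS(B,C) = |B∩C|²/(|B||C|)` (match threshold 0.2), summarised as
precision / recall / F-measure / coverage rate, and functionally profiled
with Resnik GO semantic similarity. A synthetic generator plants conserved
complexes in paired networks so the whole pipeline is testable without any
external downloads.

## Worked example

```r
library(lenalign)

bench <- generate_synthetic(synth_params(seed = 1))
bench$net1
#> <ppi_network 'synthetic_one': 155 proteins, 257 interactions>

A <- build_seed_matrix(bench$homology, bench$net1, bench$net2)
R <- bi_random_walk(transition_matrix(bench$net1, "row"),
                    transition_matrix(bench$net2, "column"), A)
subs <- partition_from_catalogue(bench$catalogue, bench$net1)
res  <- align_networks(bench$net1, bench$net2, subs, NULL, R, A)

glance(res)
#> # A tibble: 1 × 8
#>   n_solutions n_distinct_one n_distinct_two avg_size_one avg_size_two     l     r overlap_t
#>         <int>          <int>          <int>        <dbl>        <dbl> <int> <int>     <dbl>
#> 1          10             10             10          4.9          5.5     2     2       0.8

tidy(res)[1:3, ]
#> # A tibble: 3 × 6
#>   solution_id size_one size_two n_links origin_subnetwork direction
#> 1 S0001              4        5       5 PLANT01           forward
#> 2 S0002              7        7       7 PLANT02           forward
#> 3 S0003              2        2       2 PLANT03           forward

match_stats(distinct_complexes(res, "one"), bench$catalogue)
#> <match_report> PC=10 MPC=10 MKC=10 PM=5 | precision=1.0000 recall=1.0000
#>   F=1.0000 CR=0.8909 (known_total=10)

recovery_rate(res, bench$truth)
#> [1] 1
```

The benchmark plants 10 conserved complexes of 4–8 proteins with 10%
homolog dropout, 10% edge rewiring, 10% protein duplication and background
noise; the alignment recovers all 10 planted pairs (recovery 1, precision
and recall 1 against the planted catalogue), with the coverage rate
reporting the fraction of planted-complex protein occurrences reproduced
by the best-matching predictions. `autoplot(res)` and
`autoplot(match_stats(...))` draw the corresponding summaries.

A command-line interface wrapping the same functions is installed at
`inst/scripts/lenalign` with subcommands `simulate`, `align`, `evaluate`
and `relevance`; see `lenalign <subcommand> --help`.

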