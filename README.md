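# subnetbench

Network-conditioned simulation and benchmarking for active-subnetwork
detection.

Active-subnetwork (module) detection methods search a protein-protein
interaction (PPI) network for connected gene sets whose expression
changes jointly between two phenotypes. Benchmarking them fairly
requires simulated data in which the differential signal actually lives
on the network. `subnetbench` provides that generator plus the scoring
side of the benchmark, for method developers and reviewers who want a
controlled, seeded testbed:

1. **Planted truth** — a connected ground-truth subnetwork G₀ of *m*
   genes (default 274) grown by random-walk expansion on the network.
2. **Differential states** — binary DE/EE labels sampled by Gibbs
   updates from a Markov random field conditional
   p<sub>i</sub>(k | ·) ∝ exp(γ<sub>k</sub> − β·μ<sub>i</sub>(1−k)),
   where μ<sub>i</sub>(1−k) = (w·X<sub>i</sub><sup>1−k</sup> + Σ<sub>j∈Ni</sub>
   X<sub>j</sub><sup>1−k</sup>) / (w + |N<sub>i</sub>|) counts
   w-weighted neighborhood disagreement. β smooths states along edges;
   the retention weight w (default 50) anchors genes to their planted
   states, so label noise concentrates at the module boundary.
3. **Expression** — a hierarchical Gamma-Gamma model: per-gene latent
   scale β<sub>g</sub> ~ Gamma(α₀, ν), observations y ~ Gamma(α, β<sub>g</sub>)
   with mean αβ<sub>g</sub> (defaults α = 10, α₀ = 0.9, ν = 0.5;
   marginal mean 4.5). EE genes share one scale across phenotypes; DE
   genes draw case and control scales independently. Default 50 + 50
   samples.
4. **Scoring** — Welch tests per gene; greedy and simulated-annealing
   reference searchers over the aggregate module score
   z<sub>A</sub> = Σz<sub>i</sub>/√|A|; precision / recall / F-measure
   against the planted truth and fold enrichment
   (recovered·n<sub>network</sub>)/(n<sub>reference</sub>·selected)
   against a reference gene list — including for node lists produced by
   external tools.

## Worked example

```r
library(subnetbench)

cfg <- simulation_config(fixture_nodes = 500, m = 30, seed = 42,
                         search = search_params(iterations = 1000))
res <- run_benchmark(cfg)
#> toy network (erdos_renyi): 499 nodes, 1742 edges
#> ground truth: 30 genes
#> sweep 1: 140 DE genes (19 retained in G0, 121 outside G0)
#> greedy: 90 nodes, score 86.142
#> annealing: 169 nodes, score 76.972

res$report[, c("method", "selected", "tp", "precision", "recall", "f_measure")]
#>      method selected tp precision recall f_measure
#> 1    greedy       90 15    0.1667  0.500     0.250
#> 2 annealing      169 14    0.0828  0.467     0.141
```

Reading the log: of the 30 planted genes, 19 kept their DE label after
one Gibbs sweep and 121 background genes picked one up — the MRF's
deliberate label noise (at β = 1 roughly a quarter of background genes
flip per sweep; raise β to sharpen retention). The greedy searcher then
recovered 15 of the 30 planted genes inside a 90-gene module (recall
0.50, precision 0.17); annealing found a looser 169-gene module. The
F-measure column is the harmonic mean of the two. With the same seed,
every number reproduces exactly.

Scoring node lists from external tools against a reference gene list:

```r
tab <- evaluate_external(c(mytool = "mytool_nodes.txt"), net,
                         reference = read_gene_list("disease_genes.txt"))
```

A thin command-line front end with `fixture`, `simulate`, `search`,
`evaluate` and `benchmark` subcommands lives at `inst/cli/subnetbench`.
Configuration can come from a YAML file (`read_config()`); every flag
overrides the file, and each run writes a manifest sufficient to
reproduce it byte for byte.

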