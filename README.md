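# corneasim

Stochastic lattice simulation of corneal epithelium homeostasis.

The corneal epithelium is maintained by limbal epithelial stem cells at the
circumference of the cornea; their progenitor progeny, which carry a finite
replicative lifespan (RLS), populate the basal layer and migrate
centripetally, forming the clonal stripes seen in lineage-tracing
experiments. How far renewal reaches, how fast it completes, and what
pattern it leaves depend on three properties: whether cell replication and
cell removal are *spatially coupled* (removal within a local neighbourhood
of radius *m* around the dividing cell) or *uncoupled* (removal independent
of the division site), how strong the *centripetal bias* of removal is
(sector angle α with bias = 1 − α/2π in the coupled class, central-disk
radius ρ in the uncoupled class), and the RLS. `corneasim` implements the
full event-driven Monte-Carlo model on a disk lattice — equipotent or
hierarchical limbal stem-cell organization, rate-weighted division
selection, biased removal sampling, hole-pulling tissue reorientation —
together with the pattern statistics (renewed fraction, front depth, clonal
unmixing, post-mitotic profiles, clone counts and size distributions) and
the closed-form benchmarks that bound the dynamics:

* minimal lifespan under ideal coupled bias: `ceiling(R/m)`;
* coupled renewal-time limit: `2R/(m+1)` corneal replication times;
* zero-lifespan uncoupled renewal: `(λp/(2λs·a))(R+1)` with ideal bias and
  `(λp/(λs·a))·H_R·R` without (H_R the R-th harmonic number);
* ideal-bias uncoupled stripe-doubling bound: `log2(R)`;
* the one-step binomial front model with advance probability ≈ 3/8.

It is a research tool for quantitative stem-cell biologists and modellers
who want to test renewal scenarios, lifespans and niche organizations
against lineage-tracing observables.

## Worked example

A coupled-model run with strong centripetal bias at the default geometry
(cornea radius R = 100 cells, interaction radius m = 5, RLS = 60):

```r
library(corneasim)
cfg <- model_config(model_class = "coupled", bias = 0.95, m = 5, rls = 60,
                    R_total = 101)
tr <- run_simulation(cfg, seed = 1)
tr
#> trajectory: coupled model, seed 1, 39 checkpoints
#>   stop reason: renewed; final renewed fraction 1.000
#>   full renewal at 37.83 replication times

renewal_time(tr)                     # normalized renewal time
#> [1] 37.83381
renewal_time_limit_coupled(100, 5)   # analytic lower limit 2R/(m+1)
#> [1] 33.33333
unmixing(tr$state)                   # stripe order halfway to the centre
#> [1] 0.537428
```

The cornea is fully renewed after ~38 corneal replication times, above the
analytic limit of 33.3 (the bulk front moves at the limit's speed; the last
unlabeled lineages add the remainder), and the strong bias leaves a clearly
striped pattern (unmixing ≈ 0.54 halfway to the centre, versus 1 for
perfect stripes and ≈ 0.1 for fully mixed labels at that radius).

The closed forms are available in one table:

```r
theory_table(R = 100, m = 5, lambda_s = 0.1, lambda_p = 1, a = 0.85)
```

## Command-line interface

`inst/cli/corneasim.R` is a thin front end over the exported functions:

```sh
Rscript inst/cli/corneasim.R run --config inst/extdata/default_config.yaml \
    --seed 1 --out out/
Rscript inst/cli/corneasim.R theory --R 100 --m 5
Rscript inst/cli/corneasim.R sweep --rls 2,10,60 --bias 0,0.5,0.95 --out out/
Rscript inst/cli/corneasim.R fixtures --kind stripes --R-total 101 --out out/
```

`run` writes a tidy trajectory CSV, a state snapshot CSV and a JSON manifest
that reproduces the run bit-for-bit; `sweep` tabulates renewal time and
unmixing over an RLS × bias grid.

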