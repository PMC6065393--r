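# metapopsim

Simulation and analysis of a two-strain microbial public-goods
metapopulation under daily dilution–migration–growth cycles on heterogeneous
networks.

## The problem

A classic microbial cooperation system: budding-yeast *producers* secrete
invertase and pay a growth cost `c`, releasing monosaccharides (a public
good) that *non-producers* consume for free. Communities of the two strains
live in networks of wells. Every day each well is diluted `D`-fold into
fresh medium, exchanges a fraction `m` of its cells with its network
neighbours, and regrows as a batch culture. Within a growth period the
densities follow logistic competition throttled by public-good availability:

    dNnp/dt = r  Nnp (1 - (Np+Nnp)/K) ·  Np / (Np + kM)
    dNp/dt  = r(1-c) Np (1 - (Np+Nnp)/K) · (Np + eps) / (Np + eps + kM)

with `Np`, `Nnp` in cells/µL, maximum growth rate `r`, carrying capacity
`K`, Michaelis constant `kM` (producer density giving half-maximal growth)
and a private benefit `eps` that producers capture before the good diffuses
away. Defaults: `r = 0.5 /h`, `K = 90000`, `c = 0.07`, `eps = 14`,
`kM = 26`, 22 h of growth, `D = 650`, `m = 0.6`.

Because each node exports the same fraction `m` regardless of degree but
splits it among its neighbours, migration on heterogeneous graphs is
asymmetric: a star's side nodes send `m` of their cells to the hub and get
back only `m/n_side` of its. The package quantifies the three consequences:
producer enrichment throughout star networks, earlier collapse under
sustained dilution stress (lower tipping point), and greater resilience to
one-cycle shocks.

For whom: ecologists and evolutionary biologists studying cooperation,
Allee effects and metapopulation stability, and anyone who needs a careful
serial-dilution network simulator with tipping-point and resilience
analyses.

## Worked example

```r
library(metapopsim)

iso  <- steady_state(isolated_nodes(1), protocol(D = 650, m = 0),
                     init = uniform_state(1, fraction = 0.05))
star <- steady_state(star_topology(9), protocol(D = 650, m = 0.6),
                     init = uniform_state(10, fraction = 0.05))

producer_fraction(iso$state)
#> [1] 0.07312643
producer_fraction(star$state)
#> [1] 0.1597226

critical_dilution(isolated_nodes(1), m = 0)$D_star
#> [1] 1227.734
critical_dilution(star_topology(9), m = 0.6)$D_star
#> [1] 1038.672

max_shock(isolated_nodes(1), protocol(D = 750, m = 0, n_cycles = 100),
          "dilution_shock")$max_magnitude
#> [1] 3.546494
max_shock(star_topology(9), protocol(D = 750, m = 0.6, n_cycles = 100),
          "dilution_shock")$max_magnitude
#> [1] 16.08093
```

Reading: an isolated well equilibrates at ~7.3% producers; the 10-node star
with migration 0.6 more than doubles that (16.0% network-wide, with side
nodes at 16.7% and even the dense center at 12.0%). Under sustained
dilution stress the star collapses first (critical dilution ~1039 vs ~1228
for the isolated well), yet against a one-cycle dilution shock at `D = 750`
the star withstands a ~16× extra dilution where the isolated well fails
beyond ~3.5× — stability is set by the weakest nodes, resilience by the
strongest.

Other entry points: `phase_diagram()` (survival over a `D × m` grid),
`recovery_threshold()` (basin-of-attraction boundary),
`generate_experiment()` / `estimate_summaries()` (synthetic noisy plate
data and their analysis), `calibrate()` (constrained grid fit), and a CLI
at `inst/scripts/metapopsim.R` with subcommands `simulate`,
`phase-diagram`, `critical-D`, `resilience`, `basin`, `synth`, `calibrate`.
The methods vignette (`vignettes/metapopulation-model.Rmd`) documents the
model, numerical choices and limitations.

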