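# cpgcollab

Stochastic simulation of somatic inheritance of CpG methylation states.

## The problem

Vertebrate cells inherit the methylation status of CpG islands through
DNA replication: some islands stay hypermethylated (M) for thousands of
cell generations, others stay hypomethylated (U), and the two states of
the *same* island can coexist in different cell types. The textbook
explanation — hemimethylated CpGs left by replication are restored by a
highly efficient maintenance methylase, while unmethylated CpGs are
protected by the absence of de novo activity — treats every CpG dyad
independently. `cpgcollab` simulates that standard model and shows what
the enzymology already suggests: with any realistic de novo noise and
imperfect maintenance, an island of independent CpGs drifts to a single
mixed equilibrium and the M/U distinction is lost within at most
`1/(N_t · u+)` generations. It then simulates *collaborative* schemes, in
which a mediator CpG stimulates methylation or demethylation of a target
CpG (enzyme recruitment), and demonstrates true bistability: both island
states maintained for thousands of generations, bimodal cell
populations, and — with spatially restricted collaboration — a
hypomethylated island coexisting with a sea of methylation.

The package is aimed at chromatin modellers and epigenomics groups who
want a fast, scriptable implementation of the model family for
parameter scans, motif ablations and spatial patterning experiments.

## The model

A CpG island is a chain of `L` CpG dyads (default 80), each unmethylated
(`u`), hemimethylated (`h`) or fully methylated (`m`). Each cell
generation consists of:

1. **Replication** — positionwise `u → u`, `m → h`, and `h → h` or `u`
   with probability 1/2 (one daughter strand is followed);
2. **`N_t · L` reaction attempts** (default `N_t` = 100 per CpG). Each
   attempt draws one of 12 reactions with probability equal to its rate
   (remainder: no-op), a uniform-random target CpG and, for collaborative
   reactions, a mediator CpG; the target changes only if target (and
   mediator) states match the reaction.

The reactions move single methyl groups (`u ↔ h ↔ m`). Four are
non-collaborative (`u+`, `h+`, `h−`, `m−`); eight are collaborative,
written `u+^m` for "an m-site mediator stimulates methylation of a u
target", etc. The four self-destruction combinations (u-mediated
methylation, m-mediated demethylation) are excluded. The island state is
classified from the methylated strand-site fraction
`f = (2 n_m + n_h) / 2L`: U below 0.4, M above 0.6.

On top of the engine the package provides:

* **Scanning** (`scan()`, `ablation_scan()`, `refine()`) — log-uniform
  sampling of schemes on `[1e-4, 1 − u+]`, bistability assays with
  early-stopped replicate pairs, and survival-guided hill climbing
  towards longer stability horizons;
* **Spatial model** (`build_geometry()`, `run_spatial_trajectory()`) —
  an 80-CpG island (spacing 1) beside a 240-CpG sea (spacing 10), with
  nearest-neighbour collaborative methylation and collaborative
  demethylation whose contact probability decays as `1/(x + α)`
  (`α` = 20) with mediators restricted to the island;
* **Analysis** (`classify()`, `first_flip()`, `estimate_lifetime()`,
  `steady_densities()`, `positional_averages()`,
  `meanfield_trajectory()`, `lifetime_bound()`) — state classification,
  censoring-aware lifetime estimation, density and completion
  statistics, and the deterministic mean-field companion of the standard
  model.

## Worked example

```r
library(cpgcollab)

fx <- fixtures("fig1e_collab")      # full-feedback collaborative scheme
fx$scheme
#> Reaction scheme (motif: full_feedback)
#>   u+   0.0001
#>   h+   0.0001
#>   h-   0.001
#>   m-   0.001
#>   u+m  0.2
#>   h+m  0.2
#>   h+h  0.2
#>   m-u  0.08
#>   h-u  0.08
#>   no-op probability per attempt: 0.2378

tm <- run_trajectory(fx$init_m, fx$scheme,
                     sim_config(generations = 1000, seed = 1),
                     stop_on_flip = TRUE)
tu <- run_trajectory(fx$init_u, fx$scheme,
                     sim_config(generations = 1000, seed = 2),
                     stop_on_flip = TRUE)
tm
#> CpG island trajectory: L = 80 , generations = 1000 (horizon)
#>   final counts u/h/m: 0/1/79  (methylation level 0.994)
tu
#> CpG island trajectory: L = 80 , generations = 1000 (horizon)
#>   final counts u/h/m: 80/0/0  (methylation level 0.000)
```

Both initializations survive the full 1000 generations without a flip
(`termination = "horizon"`): the same rates maintain a hypermethylated
and a hypomethylated island — bistability that no standard
(non-collaborative) scheme achieves. The M state is not static:

```r
round(steady_densities(tm, burn_in = 100, type = "time_average"), 3)
#>     u     h     m
#> 0.001 0.055 0.945
completion_rates(tm, burn_in = 100)$total   # reactions per CpG per generation
#> [1] 1.21
completion_rates(tu, burn_in = 100)$total
#> [1] 0.02
```

Averaged over the cell cycle the M state carries ~5.5% hemimethylated
dyads (the densities hairpin-bisulfite sequencing reports), and costs
about 1.2 completed reactions per CpG per generation, versus 0.02 in the
U state. For the standard model, `lifetime_bound(100, 1e-4)` returns the
analytic ceiling of 100 generations on how long any site-independent
scheme can remember its state at the de novo noise floor.

A command-line shell over the same functions ships in
`inst/cli/cpgcollab.R` (subcommands `simulate`, `population`, `spatial`,
`scan`, `ablate`, `refine`, `meanfield`).

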