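---
title: "Modelling somatic inheritance of CpG methylation states"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgcollab)
```

This vignette is the package's account of the model it implements: the
assumptions behind the simulator, the parameters that matter and their
defaults, the design decisions taken where more than one reasonable
implementation existed, and what the shipped test problems do and do not
establish.

## The model and its assumptions

A CpG island is a one-dimensional chain of `L` CpG dyads, each in one of
three states: unmethylated (`u`), hemimethylated (`h`, one strand
methylated) or fully methylated (`m`). One cell generation is

1. semiconservative **replication**: `u -> u`, `m -> h`, and `h -> h` or
   `u` with probability 1/2 each, independently per site (the simulator
   follows one daughter strand; `population_run()` follows both); then
2. `N_t * L` stochastic **reaction attempts**. Each attempt selects one
   of the 12 reactions with probability equal to its rate — a discrete
   Gillespie-style selection among reaction channels, with the
   unassigned remainder `1 - sum(rates)` a no-op — then a
   uniform-random target CpG, and for collaborative reactions a mediator
   CpG. The target changes if and only if target (and mediator) states
   match the reaction.

All reactions transfer single methyl groups, so `u <-> h <-> m` only.
Collaborative reactions model enzyme recruitment: a mediator in a given
state stimulates the reaction at the target. The four self-destruction
combinations — u-mediated methylation and m-mediated demethylation —
are excluded from the catalogue and not representable.

Assumptions worth keeping in mind: CpGs are otherwise featureless (no
enzyme identities, no nucleosomes, no sequence context); time within a
generation is measured in attempts, not physical time; and replication
happens synchronously at the start of each generation. Measurements
reported per generation are end-of-generation snapshots, i.e. the
restored, pre-replication state.

## Rates as per-attempt probabilities

Rates are absolute per-attempt selection probabilities in `[0, 1]`.
This is the only reading under which the model's arithmetic works: with
`u+ = 1e-4` and `N_t = 100`, a u site is hit by a completed de novo
attempt with probability `1 - (1 - u+/L)^(N_t L) ~ 1%` per generation,
and the stated maximum rate `1 - u+` is meaningful. It implies the
constraint `sum(rates) <= 1`, enforced at construction
(`make_scheme()`); the scanner resamples schemes that violate it rather
than renormalizing, which would silently rescale every rate. The
alternative — treating rates as relative weights — was rejected because
it decouples the printed rate values from per-generation event counts.

Whether the constraint should be the joint `sum <= 1` or only a
per-reaction bound was genuinely open; the joint bound was chosen
because it keeps the no-op remainder a probability. It bites only in
the extreme corner of parameter space (e.g. `h+` within `2e-4` of 1
with every noise rate at its floor), which the sampler simply never
proposes.

## Parameters, defaults, and why

| parameter | default | units | rationale |
|---|---|---|---|
| `L` | 80 | CpG sites | a ~1 kb island at unit spacing |
| `N_t` | 100 | attempts / CpG / generation | makes the floor rate `1e-4` equal a 1% per-site per-generation event |
| rate floor | `1e-4` | per attempt | smallest allowed non-zero rate; also the noise floors kept on `u+` and `h+` in scans |
| classification | 0.4 / 0.6 on `f = (2n_m + n_h)/2L` | — | symmetric band bracketing the mixed state `u ~ m ~ 1/2` that standard schemes converge to |
| `alpha` | 20 | DNA distance | minimal-distance factor in the `1/(x + alpha)` contact kernel, roughly one nucleosome |
| island / sea spacing | 1 / 10 | DNA distance | relative CpG densities inside and outside islands |
| sea size | 240 | CpG sites | three island lengths of flanking sea |

The attempt count per generation is fixed at `N_t * L` by default; a
`poisson` mode (same mean) is available. At 8000 attempts per
generation the distinction is immaterial (coefficient of variation ~1%),
and the fixed mode gives exactly reproducible attempt budgets.

The non-spatial mediator is drawn uniformly over all sites *excluding
the target*: a "second" CpG is by construction a different CpG. Letting
the mediator coincide with the target would add a spurious `1/L`
self-collaboration term.

## Spatial collaboration rules

In the island-plus-sea model, collaborative methylation is local: the
mediator is the left or right neighbouring CpG (probability 1/2 each;
chain ends use their unique neighbour), regardless of region — the
island/sea boundary is not a barrier. Collaborative demethylation acts
globally with a DNA-looping contact probability decaying as
`1/(x + alpha)`.

Two implementations of that decay were considered. Normalizing the
kernel over the currently eligible mediator set makes every attempt
succeed as soon as a single eligible site exists; completion then stops
scaling with mediator density, and in simulation the entire 320-site
system collapses to the unmethylated state from an all-M start — mass
action is broken. The package therefore draws the mediator first
(uniformly over island sites when recruitment is island-restricted,
the enzyme being recruited at the island; uniformly over all other
sites otherwise), requires its state to match, and accepts the
interaction with probability `alpha/(x + alpha)` — the stated decay
normalized to 1 at zero separation, with the constant absorbed into the
rate. This reduces to the global rule as `alpha` grows with the
restriction off, and keeps completion proportional to mediator density.
The standalone `distance_weighted_mediator()` helper exposes the
normalized-kernel draw for analysis purposes.

The island restriction on demethylation mediators models
density-dependent recruitment of demethylating enzymes to CpG-rich
regions. Disabling it (`spatial_rules(restrict_demethylation = FALSE)`)
destroys the spatial pattern — the island U state decays within a few
hundred generations — which is itself a model result reproduced in the
test suite.

## Preset schemes

Presets are working points, chosen once with the package's own
machinery and then frozen.

* **`standard`** (`u+ = 1e-3`, `h+ = 0.6`, `h- = 0.025`, `m- = 0.012`):
  a typical site-independent scheme. Its mean-field fixed point is
  `u = 0.489, h = 0.010, m = 0.500` and both initializations reach it
  in roughly 13 generations — the characteristic mixed-state convergence
  of the standard model. A high-maintenance corner (`h+` near 1, noise
  at the floor) survives longest but still loses the M/U distinction
  within ~100 generations, as the analytic bound requires.
* **`full_feedback`** (collaborative methylation `u+m = h+m = h+h =
  0.2`, collaborative demethylation `h-u = m-u = 0.08`, noise
  `u+ = h+ = 1e-4`, `h- = m- = 1e-3`): the five-reaction
  positive-feedback motif at its favoured rates. The collaborative
  demethylation value sits at the upper side of its favoured region:
  at 0.05 exactly, the U state flips after order 10^3 generations in a
  minority of replicates, while 0.08 was validated flip-free over 12
  replicate pairs of 5000 generations from both initializations with
  unchanged M-state densities. Individual working schemes are always
  assay-selected; the favoured-region values are modes of a
  distribution, not a certificate.
* **`minimal`** (three collaborative methylations at 0.2 plus
  non-collaborative demethylation `h- = 0.07`, `m- = 0.05`): the
  smallest bistable motif. It is a knife-edge regime — stronger
  demethylation flips M, weaker flips U — consistent with minimal-motif
  bistability being far rarer under scanning than the full-feedback
  motif.
* **`spatial_default`** (`u+m = h+m = h+h = 0.12`, `h-u = 0.12`,
  `m-u = 0.30`, noise `u+ = h+ = 1e-4`, `h- = 3e-4`, `m- = 1e-3`):
  tuned by grid search for the island-in-a-sea geometry. Symmetric
  demethylation strong enough to carve a wide hypomethylated shore also
  ignites flips of the M island, through `h-u` acting on the
  post-replication all-h island the moment noise creates a u seed. The
  asymmetric scheme — strong `m-u`, moderate `h-u` — keeps the M island
  stable (no flip in 4 seeds x 3000 generations) while the U island
  holds a shore in which full methylation only recovers ~12 sea sites
  from the island edge, with the hemimethylation maximum in the
  boundary zone.

## Scanning, assays and refinement

`sample_scheme()` draws `u+` first, log-uniformly on `[1e-4, 0.5]`
(capped so the upper bound `1 - u+` never falls below `u+` itself),
then every other unconstrained rate log-uniformly on `[1e-4, 1 - u+]`.
Log-uniform is the natural measure for rates spanning four decades; the
originally used sampling distribution is not published, so absolute
pass likelihoods are reproduced only qualitatively, and order-of-
magnitude quantities (such as a ~0.015% bistable fraction in
unconstrained scans) are out of scope.

A scheme passes `bistability_assay()` if no replicate (default 3 per
initialization) flips within the horizon; the assay aborts on the first
flip, which already decides failure. "Flip" means the end-of-generation
classification reaches the band opposite the initialization.
`merge_generation()` measures the loss of the M/U *distinction* for
paired runs: the first generation at which the M-init run no longer
classifies M or the U-init run no longer classifies U. A state is only
"maintained" while it still classifies as that state; the laxer
criterion (both runs in the same band) would count a U-init run stuck
at `f = 0.55` as still distinct, and inflates the measured maxima past
the analytic bound.

`refine()` hill-climbs: each step multiplies every free rate by
`exp(eps)` with small Gaussian `eps`, rejects candidates violating the
floor, ceiling or sum constraints, assays the rest, and accepts when
the survival-based stability estimate does not decrease. Lifetimes are
compared via the Kaplan-Meier restricted mean of first-flip times
(`estimate_lifetime()`, built on the survival package), which remains
informative when every replicate is censored — naive averages cannot
rank schemes that never flip within the current horizon. The assay
horizon doubles toward the target whenever the current scheme survives
it. Million-generation certification is not attempted; the doubling
schedule is exercised to 10^3–10^4 generations.

## The mean-field companion

For site-independent schemes the expected dynamics factorize, and
`meanfield_trajectory()` iterates the per-generation map: replication
`(u, h, m) -> (u + h/2, h/2 + m, 0)` followed by `N_t` expected-change
sub-steps moving mass `u -> h` at `u+ * u`, `h -> m` at `h+ * h`,
`h -> u` at `h- * h`, `m -> h` at `m- * m` (per-site exposure is `N_t`
because the `1/L` target probability cancels against `L` attempts).
With all rates zero the recursion has the closed form
`u_k = 1 - 2^(1-k)`, used as an exact oracle in the tests; with any
`u+ > 0` it has a unique fixed point, which matches the stochastic
engine's long-run densities to within Monte-Carlo error (the tests
require 0.02 per component; the observed discrepancy is ~4e-4). The
analytic anchor `lifetime_bound(N_t, u_plus) = 1/(N_t * u_plus)` is the
ceiling on how long any standard scheme can hold a state distinction.

## Measurement conventions

Two density measures are provided because they answer different
questions. End-of-generation snapshots describe the restored state just
before the next replication; within-generation time averages
(`steady_densities(..., type = "time_average")`, accumulated
attempt-by-attempt in the compiled core) describe what an experiment
sampling cells at random cell-cycle positions sees. The contrast
matters for hemimethylation: the collaborative M state shows `h ~ 0.005`
in snapshots but `h ~ 0.055` time-averaged — the latter is the quantity
comparable to hairpin-bisulfite data — while the longest-lived standard
schemes stay below 0.01 on either measure. Positional profiles
(`positional_averages()`) are averages of per-generation snapshots
across thousands of generations.

Strict U-state purity (`u_state_purity_span()`) is tracked
within-generation: a generation preserves `m + h < 1%` throughout if
and only if it starts pure, ends pure and completes no u-methylating
reaction meanwhile. End-of-generation counts alone would miss
transient hemimethylation created and removed within a generation, and
overstate how long the standard model can hold a clean U state.

## Test problems: what they show and what they do not

The synthetic study conditions are the model's own: islands of 80 CpGs
(20–80 for size scaling), `N_t = 100`, schemes from the presets or from
seeded scans of 10^3 samples, horizons of 30–5000 generations
(spatial runs 1500–3000 generations on 320 sites). A two-site island
admits exhaustive enumeration of the one-attempt transition matrix,
against which the compiled kernel and the reference R implementation
are both checked cell by cell.

These conditions emulate the mathematical model, not genomic data: no
sequence heterogeneity, no replication-timing structure, no enzyme
kinetics, and population runs assume synchronous divisions without
selection. Passing tests therefore certify the simulator and the
model's internal claims — bistability, decay bounds, density contrasts,
spatial patterning — not agreement with any particular genome-wide
dataset.

Two scale limits are explicit. Scans here use 10^3 samples at horizons
up to 10^3 generations, so pass *fractions* carry wide confidence
intervals and only qualitative statements (standard scans never pass;
full-feedback scans pass at the percent level) are asserted. And
reaction-essentiality is asserted at scheme level where it is robust —
zeroing `u+m` or `h+h` collapses the preset within generations — but
not for `h+m`: at the shipped rates `h+h` alone can carry
post-replication maintenance, so removing `h+m` leaves the preset
bistable, and deciding whether *any* scheme survives its removal would
need ensemble scans far beyond these sizes.

## Known limitations

* The dyad is the atomic unit: no per-strand base-level representation,
  so strand-asymmetric mechanisms cannot be expressed.
* No physical time. Rates are per attempt; mapping to enzyme kinetics
  requires an external calibration of attempts to minutes.
* The spatial kernel is a two-parameter caricature of chromatin contact
  (`alpha`, spacings); no looping polymer model, boundary elements or
  nucleosome positions.
* The scanner's sampling law is a package choice (log-uniform); scan
  statistics depend on it and should be compared across motifs, not
  read as absolute likelihoods.
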