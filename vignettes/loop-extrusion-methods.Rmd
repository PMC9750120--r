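---
title: "Modeling chromatin loop extrusion with polyloopsim: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling chromatin loop extrusion with polyloopsim: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyloopsim)
```

# The model

`polyloopsim` simulates one chromosome as a coarse-grained bead-spring
polymer coupled to a population of loop-extruding factors (LEFs, i.e.
SMC-family complexes such as cohesin and condensin). Each monomer represents
2 kb of chromatinized DNA in a 50 nm bead (both configurable). The model has
two layers that run on a shared clock:

1. **A 1D kinetic layer.** LEFs bind to the monomer lattice, either
   uniformly or at predefined loading sites, as two legs on adjacent
   monomers. Mobile legs translocate outward — both legs in *symmetric*
   extrusion (cohesin-like), one randomly chosen leg in *asymmetric*
   extrusion (condensin-like) — at `velocity_kb_per_min / monomer_size_kb`
   steps per minute, and the whole complex detaches at
   `unbind_rate_per_min`, instantly dissolving its loop. Boundary elements
   (CTCF-like) gate the entry into their monomer with a direction
   (`blocks_rightward`, `blocks_leftward`, `blocks_both`, defined relative
   to the direction the leg is moving) and a permeability: each arrival
   attempt passes with that probability and the leg otherwise stalls and
   retries at its stepping rate. A permeability-`p` element therefore acts
   as a thinned transition with effective rate `p * step_rate`, which is
   what the exact-oracle comparison tests assert. Two legs meeting are
   either *impenetrable* (the move stalls until one LEF detaches) or
   *phantom* (they cross freely; the Z-loop regime).

   The layer is propagated by exact continuous-time (Gillespie) sampling:
   exponential waiting times over the current event set
   {bind, unbind, leg step}, one event per draw. There is no time
   discretization error, and the kinetics are directly comparable against
   an exactly enumerated continuous-time Markov chain on small lattices
   (`exact_stationary_oracle()`).

2. **A 3D polymer layer.** The chain is an off-lattice bead-spring polymer
   with harmonic bonds (`bond_k`, rest length = bead diameter), a bending
   energy `bend_k * (1 - cos theta)` per consecutive triplet, and hard-core
   excluded volume (rejection below 0.8 bead diameters). Each bound LEF
   imposes a harmonic *loop bond* between its two leg monomers. The layer
   evolves by Metropolis single-bead displacements; moves violating the
   hard constraints (excluded volume, bond window) are rejected, so
   detailed balance holds with respect to the total energy, which the test
   suite checks by Boltzmann reweighting between two temperatures.

The extrusion framework follows the standard loop-extrusion literature; the
3D representation here is an off-lattice Metropolis chain rather than a
lattice kinetic Monte-Carlo. The contract of this layer is equilibrium
contact statistics under the imposed loops (connectivity, excluded volume,
bending), not literal polymer dynamics: dynamic observables such as MSD
exponents are outside what the package claims.

## Coupling and time mapping

The two layers alternate over a coupling interval
(`coupling_interval_min`, default `min(0.1, snapshot_interval/10)` min).
After each kinetic interval the loop-bond set is refreshed
(`sync_loops()`): a leg that just advanced leaves a momentarily stretched
spring that the next sweeps contract — beads are never teleported. MC sweeps
are allotted proportionally to simulated time through `sweeps_per_min`
(default 100 sweeps per simulated minute). This time mapping is the one
deliberately loose knob in the model: there is no unambiguous conversion
between Metropolis sweeps and minutes, so the default was chosen to let a
TAD-sized chain region re-equilibrate over a few minutes of simulated time,
and it is exposed as an explicit parameter rather than hidden. Observables
that depend only on the stationary ensemble (contact maps, occupancy
profiles) are insensitive to it once snapshots are spaced beyond the
relaxation time; observables on shorter time scales are not claimed.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `monomer_size_kb` | 2 | genomic content per bead (kb) |
| `monomer_diameter_nm` | 50 | bead size, bond rest length (nm) |
| `lef_density_kb` | 60 | chain kb per bound LEF; `n_lef_target = chain/density` |
| `velocity_kb_per_min` | 100 | extrusion speed of one translocating leg |
| `unbind_rate_per_min` | 0.05 | detachment rate (20 min residence) |
| `contact_cutoff_nm` | 100 | Hi-C capture radius (2 bead diameters) |
| `hic_bin_kb` | monomer size | output map resolution |
| `sweeps_per_min` | 100 | MC sweeps per simulated minute |

The LEF density default (one bound LEF per 60 kb) and velocity default
(100 kb/min) correspond to a cohesin-like interphase regime; the 20 min
residence time is the order of magnitude reported by live-imaging studies
of chromatin-bound cohesin. The binding rate per unbound LEF is derived
from the target occupancy: with a pool of `2 n` LEFs and
`k_bind = k_unbind * n / (pool - n)`, the stationary mean bound count is
`n`. The contact radius and map normalization are documented knobs, not
claimed to match any particular experimental capture chemistry: a contact
is a hard distance cutoff, maps are raw per-pair contact probabilities (no
matrix balancing), and the uninformative diagonal is set to 1.

## Numerical choices and degenerate inputs

* Genomic coordinates are kb, 0-based half-open in `[0, chain_length_kb)`;
  positions map to monomers by integer division (the lattice resolution is
  one monomer); duplicate boundary monomers are rejected.
* Chain ends are permanent impermeable boundaries; legs never leave the
  chromosome.
* In asymmetric mode the mobile leg is drawn with probability 1/2 at each
  binding and fixed until detachment.
* After unbinding a LEF rebinds anywhere admissible (no positional
  memory). In loading-site mode the total binding flux is conserved: an
  attempt at an occupied (impenetrable) or terminal site is consumed and
  logged as rejected.
* A directional boundary leaves the non-blocked direction completely free.
* Initial conformations are grown as fixed-bond random walks with
  hard-core rejection and backtracking; growth failure raises an error
  rather than emitting an invalid chain.
* Burn-in: the bare homopolymer is relaxed for
  `equilibration_time_min * sweeps_per_min` sweeps before extrusion
  starts. Full equilibration of a long chain's global modes is
  impractical at desk scale; analyses in the package therefore either use
  chain lengths whose relevant (TAD-scale) modes relax within the burn-in,
  or average over independent replicates, and the radius-of-gyration drift
  can be checked from snapshots. This honesty matters when comparing
  absolute long-range contact levels.

## The chi-squared comparison

The comparison layer reduces a model-vs-reference pair of maps to a single
score: over off-diagonal bin pairs in a genomic-distance band (default one
bin to half the chain — the diagonal is uninformative and long-range pairs
are noise-dominated),

```
chi2 = mean( (scale * model_ij - ref_ij)^2 / sigma2_ij )
```

where `scale` aligns the mean P(s) curves by least squares (weighted by the
number of pairs per distance), and `sigma2_ij` is either the
replicate-to-replicate variance of the model map divided by the replicate
count, a Poisson approximation `ref_ij / n_snapshots`, or a user-fixed
variance. Per-pair variance estimates from a modest replicate count are
heavy-tailed — a handful of underestimated denominators can dominate the
score and turn it into a lottery — so the replicate mode offers
distance-pooled variances (`pool_variance_by_distance`), which average the
estimate over all pairs at the same genomic separation; when ranking grid
cells against one reference, the reference's own replicate variance should
be used as the common denominator so every cell is weighted identically. Identical maps score exactly zero; against independent noise of
known variance the score tends to 1. The precise definition (band,
variance estimator, scale alignment) is fixed and documented here as this
package's definition of the score; it is a chi-squared-style objective
minimized at the optimum over a parameter grid, and its absolute value
should be read relative to the same pipeline's same-parameter baseline,
not as a calibrated p-value.

## What the synthetic experiments do and do not show

The test suite and the acceptance script drive the simulator through
synthetic experiments chosen for statistical power at desk scale:

* **Oracle equivalence** (single LEF, <= 12 sites, all four
  extrusion/collision mode combinations, permeabilities 0/0.5/1):
  empirical time-averaged state frequencies against the exact stationary
  distribution, within three batch-means standard errors.
* **Closed-form loop size** (dilute limit, no boundaries): time-averaged
  loop length vs `2 v / k_off` (symmetric) and `v / k_off` (asymmetric)
  at >= 10^4 detachment events, within 5%. The measured value includes the
  one-monomer loop present at binding, a finite-size offset well inside
  that tolerance at the sizes used.
* **Insulation** (300 beads, one impermeable mid-chain boundary, strong
  extrusion): cross-boundary contact probability far below the intra-block
  probability at matched separations.
* **TAD phenomenology** (300 beads, alternating 100/200 kb boundary
  spacing — the alternating-spacing construction scaled down from the
  6 Mb / 300-600 kb illustration so its TAD-scale modes equilibrate at
  desk scale): block-diagonal enrichment and a corner-peak pixel in the
  top decile of its distance band.
* **Parameter recovery** (3x3 grid in density x velocity around a
  cohesin-like center): the generating cell attains the minimum score
  against a reference generated at that cell with a different seed. Power
  analysis during design showed three things worth recording. First,
  snapshot decorrelation is controlled by the slower of loop turnover and
  polymer relaxation, so the experiment uses a 2-minute LEF residence
  time, a chain short enough (100 beads) for its band-scale modes to relax
  within the burn-in, and 16 independent replicates sampled long enough to
  average over conformational fluctuations. Second, the grid is only
  identifiable if the velocity axis crosses the TAD scale: once
  `2 v / k_off` exceeds the TAD size every velocity saturates the domains
  with full-span loops and the axis degenerates; the recovery grid
  therefore spans loop sizes below, near, and above the TAD size. Third,
  cells must share one variance denominator — the reference's
  distance-pooled replicate variance — or the score rewards whichever cell
  is noisiest.

These experiments exercise the model's own statistical machinery on data
the model generated. They validate internal consistency, the kinetics
against exact enumeration, and the phenomenology (TADs, corner peaks,
insulation, occupancy peaks at boundaries) that loop extrusion with
boundaries is expected to produce. They do not validate the model against
experimental Hi-C: real maps carry coverage and ligation biases, balancing
choices, locus-specific chromatin states, and cell-to-cell heterogeneity
that the synthetic reference deliberately lacks.

## Known limitations

* Single chromosome, homogeneous fiber; no epigenomic heterogeneity, no
  phase separation, no multi-chromosome contacts.
* Chain crossing is prevented only by excluded volume; there is no
  explicit topology enforcement, and no hydrodynamics.
* One-sided switching extrusion, partial LEF-LEF traversal rates between
  0 and 1, and tension-dependent velocities are not modeled.
* The cooler converter writes single-resolution files through a bundled
  Python helper (h5py); multi-resolution `.mcool` pyramids are out of
  scope.
* Cluster schedulers are not integrated: replicate parallelism is local
  (forked workers) with per-replicate derived seeds, so results are
  bitwise independent of the worker count.

## Problem sizes used by the checks

The bundled tests and the acceptance script run, per invocation, chains of
24-400 beads, 1D-only kinetics up to ~3 x 10^4 simulated minutes, coupled
runs of up to ~16 replicates x 125 simulated minutes at 100 sweeps/min, and
3x3 grids at 100 beads — sizes chosen so each check has clear statistical
power while the whole suite stays comfortably within a desk-scale run.
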