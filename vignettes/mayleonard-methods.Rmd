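---
title: "Methods: off-lattice cyclic competition with a local carrying capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: off-lattice cyclic competition with a local carrying capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`mayleonard` simulates three species, A, B and C, competing cyclically
(A beats B, B beats C, C beats A) in continuous two-dimensional space: a
square box of side $L$ with periodic boundaries, so all distances are
minimum-image (torus) distances. This is a May–Leonard-type model:
selection (predation) and reproduction are *separate* stochastic events, so
the total population $N = n_A + n_B + n_C$ is not conserved — empty space is
a dynamical degree of freedom, unlike in Lotka–Volterra-type pair exchanges.

Each **elementary Monte Carlo step** draws one living individual uniformly
at random and one action from $\{$move, predate, reproduce$\}$ with
probabilities $(m, p, r)$, $m + p + r = 1$:

* **Move** — jump by exactly $\ell_m$ in a direction uniform on
  $[0, 2\pi)$; always executed.
* **Predate** — if any prey individual lies within the closed disk of
  radius $\ell_p$ around the predator, the *closest* one is removed;
  otherwise nothing happens.
* **Reproduce** — count all individuals, of any species and including the
  actor itself, within the reproduction range $\ell_r$ of the actor. If the
  count is strictly smaller than the local carrying capacity $M$, an
  offspring of the actor's species appears at a position drawn uniformly
  from the disk of radius `offspring_radius` around the parent; otherwise
  the birth fails.

A **full MC step** repeats the elementary step $N_0$ times, where $N_0$ is
the population size at the *start* of the step (frozen even as births and
deaths change $N$ mid-step); this gives a well-defined unit of time in
which every individual acts once on average. A run initialises
`init_per_species` individuals of each species uniformly in the box,
discards `relax_steps` MC steps and records $(t, n_A, n_B, n_C, N)$ for
`measure_steps` steps.

$M$ is the single knob describing the quality of the environment: a harsh
environment (small $M$) blocks most births; a benign one (large $M$)
sustains a dense population in which rotating spiral waves and coherent
oscillations of the species fractions emerge.

## Parameters

| field | meaning | default | unit |
|---|---|---|---|
| `box_length` | box side $L$ | 1 | — (all lengths are fractions of it) |
| `pred_radius` | predation range $\ell_p$ | 0.02 | box lengths |
| `repro_radius` | capacity-count range $\ell_r$ | 0.02 | box lengths |
| `move_length` | jump length $\ell_m$ | 0.01 | box lengths |
| `offspring_radius` | natal disk radius | `move_length` | box lengths |
| `capacity` | local carrying capacity $M$ | 30 | individuals |
| `prob_move`, `prob_predate`, `prob_reproduce` | $(m, p, r)$ | 0.5, 0.25, 0.25 | — |
| `init_per_species` | initial count per species | $10^4$ | individuals |
| `relax_steps`, `measure_steps` | schedule | 2000, 10000 | MC steps |

Conventions that the model statement leaves open, fixed here once:

* **The capacity count includes the actor** ("all individuals within the
  reproduction range" — the actor is within its own range at distance 0).
  Consequence: $M = 1$ forbids reproduction entirely.
* **The capacity is evaluated around the parent**, not the proposed
  offspring site.
* **Offspring placement is area-uniform** over the closed natal disk
  (radius drawn as `offspring_radius`$\cdot\sqrt{u}$), not on its perimeter.
* `offspring_radius` defaults to $\ell_m$ — the natal range is stated in
  terms of the movement length in the model's standard presentation — but
  is an independent field, since jump length and natal dispersal are
  conceptually distinct and one may wish to decouple them.
* **Boundary convention**: an individual exactly at distance = radius is
  inside the disk (closed disks); exact ties are measure-zero events.
* **Closed-disk ties in predation** are broken by smallest id, making runs
  bit-reproducible; again measure-zero in continuous space.
* $\ell_p, \ell_r$ must lie in $(0, L/2]$, which minimum-image distances
  and complete 3×3 cell-block queries require. $\ell_m$ is only required
  to be positive: a jump longer than the box simply wraps, and jumps
  comparable to $L$ are exactly how the well-mixed limit is probed.

## Numerics

**Neighbour search.** The engine keeps a uniform periodic cell list with
cell width at least $\max(\ell_p, \ell_r)$, so any radius query touches only
the 3×3 block of cells around the query point. Removal uses swap-with-last
compaction in both the population arrays and the per-cell lists, keeping
every operation $O(1)$ expected. When the box holds fewer than 3 cells per
side the engine falls back to brute-force scans. A pure-R cell grid with
incremental updates (`build_cell_grid()`, `grid_move()`, ...) and a
brute-force oracle (`neighbors_brute()`) exist alongside for testing; the
test suite asserts exact set equality between the two on random
configurations, and that full engine trajectories are bit-identical under
the cell-list and brute-force backends.

**RNG.** The compiled engine uses its own splitmix64 generator, seeded from
`params$seed`, with a fixed draw order per elementary step (actor, action,
then action-specific draws: angle for moves; angle then radius for
successful births). Runs are therefore exactly reproducible, independent of
R's RNG state and of the spatial backend. Uniform doubles are built from
the top 53 bits, so streams are platform-stable.

**Stationary summaries.** `summarize_series()` reports the mean of $N$ over
a window and a *block-averaged* standard error (default block: 100 MC
steps): successive MC steps are strongly autocorrelated and the naive iid
error would be anticonservative. Histograms of $N$ use bin width 1 unless
the range exceeds 1000 values.

**Spectra.** `dft()` is the temporal discrete Fourier transform with a
$1/N_G$ prefactor,
$$\rho(f) = \frac{1}{N_G} \sum_{t=0}^{N_G-1} \rho(t)\, e^{-2\pi i f t/N_G},$$
applied to the species *fraction* $\rho(t) = n_s(t)/N(t)$, not the raw
count. `ensemble_power_spectrum()` averages $|\rho(f)|^2$ bin-wise across
independent runs and folds to $k = 0 \dots N_G/2$ cycles per window. The
DC bin is retained (it is the squared mean fraction) but excluded from peak
searches; no mean subtraction or windowing function is applied — peak
*location* is unaffected by either. `peak_frequency()` optionally smooths
with a centred moving average before the search: with production-scale
averaging (250 replicates) no smoothing is needed, while the desk-scale
scenarios below average 5 replicates and use a 5-bin window, fixed as part
of the scenario definitions. Peak location is invariant to any overall
rescaling of the powers.

## Desk scaling

Production-scale runs (full box, $3 \times 10^4$ individuals, $10^8$
relaxation steps) are out of interactive reach. The scenario layer scales
down by **shrinking the box with all radii and probabilities unchanged**
and reducing `init_per_species` by the area ratio
(`round(1e4 * box_length^2)`). Local densities, rates, and therefore the
oscillation frequency *per MC step* are unchanged by this; what is lost is
large-scale spiral imagery, which needs many wavelengths per box and stays
qualitative here. Problem sizes used by the scripted scenarios and the
acceptance checks:

* **Spectra** (`scenario_spectrum_sweep()`): `box_length = 0.5`,
  $M \in \{10, 15, 20, 25, 30\}$, 1000 relaxation steps, $N_G = 10^4$
  recorded steps, 5 replicates per $M$, 5-bin peak smoothing. The $M = 30$
  ensemble peak is the headline number (production-scale characteristic value: 107 cycles per
  $10^4$ steps). Ensembles are conditioned on coexistence: a replicate
  whose run broke symmetry (lost a species) is discarded and replaced by a
  fresh-seed run, because a fraction series pinned at 0 or 1 floods the
  low-frequency bins with power that says nothing about the oscillation.
  In a quarter-area box this matters mainly at $M = 10$, where demographic
  fluctuations are large relative to ~800 individuals per species. The
  same fluctuations put a broadband noise floor under the small-$M$
  spectra, so while the peak *location* scales cleanly with $\ln M$, the
  peak *height* at desk scale is not a reliable proxy for the coherent
  oscillation amplitude at small $M$ — the height-grows-with-$M$ trend is
  a production-scale statement.
* **Capacity sweeps** (`scenario_capacity_sweep()`): `box_length = 0.25`,
  $M \in \{5, 10, 15, 20, 25\}$, 2000 + 4000 steps, 3 replicates,
  inverse-variance weighted line fit; repeated at $\ell_m = 0.02$ for the
  slope-robustness check.
* **Well-mixed extinction**: `box_length = 0.25`, $M = 10$, $\ell_m = 0.8$
  (vs 0.01 control), 20 seeds × 2000 steps, fraction of runs losing at
  least one species.
* **Coarse ranges** (`scenario_coarse_ranges()`): $\ell_p = \ell_r = 0.1$,
  $M \in \{30, 120, 240\}$, full box; snapshots plus the empty-space
  fraction. Emptiness is probed at radius 0.02 (the reference interaction
  scale), *not* at $\ell_r = 0.1$: disks of radius 0.1 around even a few
  hundred individuals cover the whole box, so a 0.1-range metric is
  identically zero and carries no information, whereas the 0.02-range
  fraction is large in the harsh regime and shrinks as $M$ grows.

## The synthetic generator

`make_sinusoid_fixture()` produces
$\rho(t) = 1/3 + A\cos(2\pi k t/N_G) + \varepsilon_t$, clipped to $[0,1]$,
the minimal stand-in for an oscillating species fraction: a single coherent
tone over white Gaussian noise. It validates the spectral pipeline
(planted-tone recovery within ±1 bin) independently of the simulator. What
it does *not* emulate: the 1/f-like low-frequency background of the real
dynamics, drifting phase and amplitude, and the correlation between
fractions and total $N$ — so passing planted-tone tests shows the analysis
layer is correct, not that the simulator oscillates; the simulator's own
oscillations are checked by the scenario suite.

`make_planted_configuration()` builds exact agent layouts for deterministic
micro-tests of the interaction rules (closest-prey selection, capacity
gating, seam-crossing distances).

## Known limitations

* Equal invasion rates only: no "survival of the weakest" asymmetries,
  no more than three species.
* A quarter-area box sustains $\approx 6500$ individuals at $M = 30$;
  finite-size effects broaden the spectral peak relative to production
  scale, which is why desk-scale peak checks carry a ±20% band.
* The desk-scale schedules (1000–2000 relaxation steps) are far from the
  $10^8$-step relaxations used for production snapshots; snapshot output is
  therefore qualitative.
* `mean_N` error bars rest on block averaging with a fixed 100-step block;
  for runs much shorter than ~10 blocks the estimate falls back to the
  naive one and will be optimistic.
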