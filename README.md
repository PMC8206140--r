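# mayleonard

An off-lattice, agent-based simulator for three-species cyclic competition
(rock–paper–scissors) with an environmental knob: a **local carrying
capacity** that gates reproduction. It is aimed at researchers in
theoretical ecology and statistical physics studying how environmental
quality controls spatio-temporal pattern formation — rotating spiral waves
and coherent population oscillations — in May–Leonard-type systems.

## The model

Three species A, B, C live on a periodic square of side *L* (continuous
coordinates). A preys on B, B on C, C on A. An elementary Monte Carlo step
picks a living individual uniformly at random and one action with
probabilities (*m*, *p*, *r*):

* **movement** — a jump of fixed length ℓₘ in a uniform random direction;
* **predation** — the closest prey within ℓₚ is removed, if any;
* **reproduction** — succeeds only if fewer than *M* individuals (any
  species, the parent included) lie within the reproduction range ℓᵣ of
  the parent; the offspring lands uniformly in a small disk around it.

A full MC step repeats this *N* times (*N* = population size at the start
of the step), so total population is **not** conserved — empty space is
part of the dynamics. *M* encodes the environment: small *M* is a harsh
world that suppresses births, large *M* a benign one.

The headline phenomenology, all reproducible with this package:

* ⟨*N*⟩ grows **linearly** with *M*, with a slope robust to microscopic
  details such as ℓₘ;
* the species fraction ρ(t) = nₐ(t)/N(t) oscillates; its discrete Fourier
  transform ρ(f) = (1/N_G) Σₜ ρ(t) e^(−2πift/N_G), ensemble-averaged into a
  power spectrum ⟨|ρ(f)|²⟩, shows a peak whose location grows as
  **a + b·ln M** (about 107 cycles per 10⁴ MC steps at *M* = 30 with the
  reference parameters);
* when ℓₘ becomes comparable to the box, spatial structure is destroyed
  and species go extinct (well-mixed limit); when ℓₚ = ℓᵣ are large, even
  high *M* sustains only a sparse population riddled with deserted areas.

## Worked example

```r
library(mayleonard)

p <- desk_params(box_length = 0.5, capacity = 30, relax_steps = 1000,
                 measure_steps = 10000, seed = 11)
sim <- run_simulation(p)
sim
#> <ml_sim> 10000 recorded MC steps (M = 30, box 0.5, seed 11, cell backend)
#>   final counts: A 2153, B 2451, C 1977 (N = 6581)

summarize_series(sim$series)
#> <pop_summary> mean N = 6703.10 (block stderr 36.002) over steps 1..10000

# a single run's spectrum is noisy; the characteristic frequency comes
# from a small ensemble
sc <- scenario_spectrum_sweep(M_values = 30L, replicates = 5, seed = 11)
sc$peaks
#> # A tibble: 1 × 5
#>       M f_peak peak_power replicates n_broken
#>   <int>  <int>      <dbl>      <int>    <int>
#> 1    30    103   0.000144          5        0
```

A desk-scale run of a quarter-area box at *M* = 30 settles around 6700
individuals, and the ensemble-averaged spectrum of the species-A fraction
peaks at 103 cycles per 10⁴ MC steps — the benign-environment oscillation
at its characteristic frequency (the value established for production-scale
ensembles of this model is 107). `autoplot(sim)`
draws the three count series, `autoplot(sc$spectra[["30"]])` the spectrum;
`scenario_capacity_sweep()` and `scenario_spectrum_sweep()` script the
full *M*-sweeps, and fitted objects support `tidy()`/`glance()`.

A command-line front end mirrors every parameter
(`inst/cli/mayleonard run --capacity 30 --seed 1 --out-dir out`, plus
`sweep-capacity`, `spectrum`, `scenario capacity|series|spectra|coarse`, `fixtures`).

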