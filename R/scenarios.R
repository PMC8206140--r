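#' Desk-scale parameters
#'
#' Production-scale runs (full unit box, 1e4 individuals per species, 1e8
#' relaxation steps) are far beyond interactive budgets. Desk-scale runs
#' shrink the box while keeping every interaction radius and probability
#' unchanged — local dynamics, and hence oscillation frequencies per MC
#' step, are set by local rates and survive the shrinking — and scale the
#' initial counts by the area ratio: `init_per_species =
#' round(1e4 * box_length^2)`. Large-scale spiral imagery does not survive a
#' small box and stays qualitative.
#'
#' @param box_length Reduced box side (default 0.5, a quarter-area box).
#' @param ... Further overrides passed to [sim_params()].
#' @return A `sim_params`.
#' @export
desk_params <- function(box_length = 0.5, ...) {
  over <- list(...)
  if (is.null(over$init_per_species)) {
    over$init_per_species <- max(1L, as.integer(round(1e4 * box_length^2)))
  }
  do.call(sim_params, c(list(box_length = box_length), over))
}

#' Capacity-sweep scenario (mean population vs M)
#'
#' Replicates the mean-population experiment at desk scale: sweeps the
#' carrying capacity, pools stationary means and fits the weighted line
#' through (M, mean N). The linear growth of the mean population with M,
#' with a slope robust to microscopic details such as the movement length,
#' is the benign-environment signature.
#'
#' @param M_values Capacities to sweep.
#' @param box_length Desk-scale box side.
#' @param replicates Runs per capacity.
#' @param relax_steps,measure_steps Schedule per run.
#' @param seed Master seed (per-run seeds are derived from it).
#' @param ... Further [sim_params()] overrides (e.g. `move_length`).
#' @return A list of class `ml_scenario` with `sweep` (a `capacity_sweep`),
#'   `fit` (a `wls_fit`) and `params_base`.
#' @export
scenario_capacity_sweep <- function(M_values = c(5L, 10L, 15L, 20L, 25L),
                                    box_length = 0.25, replicates = 3,
                                    relax_steps = 2000, measure_steps = 4000,
                                    seed = 1, ...) {
  base <- desk_params(box_length = box_length, relax_steps = relax_steps,
                      measure_steps = measure_steps, seed = seed, ...)
  sweep <- sweep_capacity(base, M_values, replicates = replicates)
  structure(list(sweep = sweep, fit = fit_capacity_line(sweep),
                 params_base = base, kind = "capacity_sweep"),
            class = "ml_scenario")
}

#' Spectrum-sweep scenario (oscillation frequency vs M)
#'
#' For each capacity M: `replicates` independent runs of `relax_steps`
#' relaxation plus `n_g` recorded MC steps; the species-A fraction series
#' are transformed and ensemble-averaged into one power spectrum per M; the
#' peak of each spectrum (cycles per `n_g`-step window) is located, and
#' `f_peak = a + b ln M` is fitted when at least three capacities are swept.
#'
#' The spectrum characterizes the oscillation of the *coexisting* state, so
#' replicates whose run broke symmetry (lost a species) are discarded and
#' replaced by runs with fresh seeds, up to `max_attempts_factor *
#' replicates` attempts per capacity: a fraction series pinned at 0 or 1
#' after an extinction floods the low-frequency bins and says nothing about
#' the oscillation. The number of discarded runs per capacity is reported
#' in the `peaks` table (`n_broken`). In small desk-scale boxes symmetry
#' breaking is common at low M, where demographic fluctuations are large
#' relative to the population.
#'
#' @param M_values Capacities to sweep.
#' @param n_g Recorded window length (DFT components).
#' @param replicates Independent runs per capacity.
#' @param box_length Desk-scale box side.
#' @param relax_steps Relaxation schedule (1000 steps suffices for spectra).
#' @param smoothing_window Moving-average width for peak location; ensemble
#'   spectra from few replicates are noisy, so desk scale defaults to 5 bins.
#' @param seed Master seed.
#' @param species Which species' fraction to analyse.
#' @param max_attempts_factor Cap on total runs per capacity, as a multiple
#'   of `replicates`, when discarding symmetry-broken runs.
#' @param ... Further [sim_params()] overrides.
#' @return A list of class `ml_scenario` with `spectra` (named list of
#'   `ml_spectrum`), `peaks` (tibble `M`, `f_peak`, `peak_power`,
#'   `replicates`, `n_broken`), `scaling` (a `peak_scaling` or `NULL`), and
#'   `params_base`.
#' @export
scenario_spectrum_sweep <- function(M_values = c(10L, 15L, 20L, 25L, 30L),
                                    n_g = 10000, replicates = 5,
                                    box_length = 0.5, relax_steps = 1000,
                                    smoothing_window = 5, seed = 1,
                                    species = "A", max_attempts_factor = 4,
                                    ...) {
  base <- desk_params(box_length = box_length, relax_steps = relax_steps,
                      measure_steps = n_g, seed = seed, ...)
  pool <- replicates * max_attempts_factor
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max,
                                       length(M_values) * pool))
  spectra <- list()
  rows <- list()
  for (i in seq_along(M_values)) {
    M <- M_values[i]
    runs <- list()
    broken <- 0L
    attempt <- 0L
    while (length(runs) < replicates && attempt < pool) {
      attempt <- attempt + 1L
      p <- modifyList(unclass(base),
                      list(capacity = as.integer(M),
                           seed = seeds[(i - 1) * pool + attempt]))
      class(p) <- "sim_params"
      sim <- run_simulation(p, return_state = FALSE)
      if (any(!is.na(sim$extinction))) {
        broken <- broken + 1L
        next
      }
      runs[[length(runs) + 1L]] <-
        fraction_series(sim$series, species = species, start = 1, n_g = n_g)
    }
    if (length(runs) == 0) {
      stop("no coexisting runs at M = ", M, " within ", pool, " attempts",
           call. = FALSE)
    }
    if (length(runs) < replicates) {
      warning("only ", length(runs), "/", replicates,
              " coexisting runs at M = ", M)
    }
    spec <- ensemble_power_spectrum(runs)
    spectra[[as.character(M)]] <- spec
    rows[[i]] <- tibble::tibble(
      M = as.integer(M),
      f_peak = peak_frequency(spec, smoothing_window),
      peak_power = peak_power(spec, smoothing_window),
      replicates = length(runs),
      n_broken = broken
    )
  }
  peaks <- dplyr::bind_rows(rows)
  scaling <- if (length(unique(peaks$M)) >= 3) fit_log_scaling(peaks) else NULL
  structure(list(spectra = spectra, peaks = peaks, scaling = scaling,
                 params_base = base, smoothing_window = smoothing_window,
                 kind = "spectrum_sweep"),
            class = "ml_scenario")
}

#' Coarse-interaction scenario (large predation/reproduction ranges)
#'
#' With predation and reproduction ranges five times the reference value
#' (0.1), even a large capacity M describes a poor environment: the
#' population stays small and empty space occupies a large share of the box,
#' behaving like an additional species woven into the spirals. This scenario
#' runs one simulation per capacity at those ranges, exports snapshots and
#' estimates the empty-space fraction — the share of box area farther than
#' `probe_range` from every individual, measured on a probe grid. The probe
#' range defaults to 0.02, the reference interaction scale: deserted areas
#' are regions devoid of individuals at that resolution. (Probing at the
#' enlarged reproduction range itself is uninformative — a few hundred disks
#' of radius 0.1 cover the whole box.)
#'
#' @param M_values Capacities (reference comparison uses 30, 120, 240).
#' @param box_length Box side (default full box; these radii keep N modest).
#' @param relax_steps,measure_steps Schedule per run.
#' @param seed Master seed.
#' @param probe_grid Probes per side for the empty-space estimate.
#' @param probe_range Coverage radius for the empty-space estimate.
#' @return A list of class `ml_scenario` with `snapshots` (named list of
#'   `population_state`), and `summary` (tibble `M`, `mean_N`,
#'   `empty_fraction`).
#' @export
scenario_coarse_ranges <- function(M_values = c(30L, 120L, 240L),
                                   box_length = 1, relax_steps = 2000,
                                   measure_steps = 1000, seed = 1,
                                   probe_grid = 200, probe_range = 0.02) {
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max, length(M_values)))
  snapshots <- list()
  rows <- list()
  for (i in seq_along(M_values)) {
    p <- desk_params(box_length = box_length, pred_radius = 0.1,
                     repro_radius = 0.1, move_length = 0.01,
                     capacity = M_values[i], relax_steps = relax_steps,
                     measure_steps = measure_steps, seed = seeds[i])
    sim <- run_simulation(p)
    snapshots[[as.character(M_values[i])]] <- sim$final_state
    rows[[i]] <- tibble::tibble(
      M = as.integer(M_values[i]),
      mean_N = summarize_series(sim$series)$mean_N,
      empty_fraction = empty_space_fraction(sim$final_state,
                                            range = probe_range,
                                            probes = probe_grid)
    )
  }
  structure(list(snapshots = snapshots, summary = dplyr::bind_rows(rows),
                 kind = "coarse_ranges"),
            class = "ml_scenario")
}

#' @export
print.ml_scenario <- function(x, ...) {
  cat(sprintf("<ml_scenario: %s>\n", x$kind))
  if (!is.null(x$sweep)) print(x$fit)
  if (!is.null(x$peaks)) print(x$peaks)
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Empty-space fraction
#'
#' Share of the box area farther than `range` from every individual,
#' estimated on a `probes` x `probes` grid of points with minimum-image
#' distances.
#'
#' @param state A `population_state`.
#' @param range Coverage radius (usually the reproduction range).
#' @param probes Probe-grid points per side.
#' @return A fraction in \[0, 1\].
#' @export
empty_space_fraction <- function(state, range, probes = 200) {
  cpp_empty_fraction(state$x, state$y, range,
                     attr(state, "box_length"), as.integer(probes))
}

#' Well-mixed extinction experiment
#'
#' When the movement length is comparable to the box size, spatial structure
#' is destroyed and demographic fluctuations drive species extinct. This
#' experiment runs `n_seeds` short independent simulations and reports the
#' fraction in which at least one species died out.
#'
#' @param params A `sim_params` (vary `move_length` to probe the effect).
#' @param n_seeds Number of independent runs.
#' @param seed Master seed.
#' @return A list with `extinct_fraction` and the per-run tibble `runs`.
#' @export
extinction_experiment <- function(params, n_seeds = 20, seed = params$seed) {
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_seeds))
  runs <- purrr::map(seq_len(n_seeds), function(r) {
    p <- modifyList(unclass(params), list(seed = seeds[r]))
    class(p) <- "sim_params"
    sim <- run_simulation(p, return_state = FALSE)
    tibble::tibble(run = r, seed = seeds[r],
                   any_extinct = any(!is.na(sim$extinction)))
  })
  runs <- dplyr::bind_rows(runs)
  list(extinct_fraction = mean(runs$any_extinct), runs = runs)
}

#' Synthetic sinusoidal fraction series
#'
#' A planted-tone fixture for the spectral pipeline:
#' `rho(t) = 1/3 + amplitude * cos(2 pi k t / n_g) + noise`, with Gaussian
#' noise of sd `noise_sd`, clipped to \[0, 1\]. Amplitudes above 1/3 trigger a
#' warning because clipping distorts the tone.
#'
#' @param k Planted frequency (cycles per window), `1 <= k < n_g / 2`.
#' @param n_g Series length.
#' @param amplitude Tone amplitude.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @return A numeric fraction series of length `n_g`.
#' @export
make_sinusoid_fixture <- function(k, n_g = 10000, amplitude = 0.05,
                                  noise_sd = 0, seed = 1) {
  stopifnot(k >= 1, k < n_g / 2)
  if (amplitude > 1 / 3) {
    warning("amplitude > 1/3: clipping to [0, 1] distorts the tone")
  }
  t <- 0:(n_g - 1)
  rho <- 1 / 3 + amplitude * cos(2 * pi * k * t / n_g)
  if (noise_sd > 0) {
    rho <- rho + withr::with_seed(seed, stats::rnorm(n_g, 0, noise_sd))
  }
  pmin(pmax(rho, 0), 1)
}

#' Run manifest
#'
#' Writes a flat key-value manifest (params, seed, package version, wall
#' time) sufficient to re-run a scenario exactly.
#'
#' @param params A `sim_params`.
#' @param path Output file.
#' @param extra Named list of additional keys.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, path, extra = list()) {
  kv <- c(
    lapply(unclass(params), function(v) format(v, digits = 17)),
    list(package = "mayleonard",
         version = as.character(utils::packageVersion("mayleonard")),
         written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    lapply(extra, as.character)
  )
  writeLines(sprintf("%s: %s", names(kv), unlist(kv)), path)
  invisible(path)
}
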