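#' Run a full simulation
#'
#' Initialises `init_per_species` individuals of each species uniformly in
#' the box from `params$seed`, performs `relax_steps` unrecorded Monte Carlo
#' steps, then `measure_steps` recorded ones. The counts series holds
#' `(t, n_A, n_B, n_C, N)` after each recorded MC step. Extinction of a
#' species does not stop the run (a single-species state is a legitimate,
#' absorbing outcome); the first MC step at which each species' count
#' reached zero is reported (non-positive values fall in the relaxation
#' phase, `NA` means the species survived).
#'
#' The engine is compiled and uses its own seeded generator, so runs are
#' exactly reproducible and independent of R's RNG state. All stochastic
#' choices are drawn in a fixed order (actor, action, then action-specific
#' draws), which makes the trajectory independent of the spatial backend:
#' `backend = "cell"` uses a periodic cell list with cell width at least
#' `max(pred_radius, repro_radius)` (falling back to brute force when the box
#' holds fewer than 3 cells per side), `backend = "brute"` scans all
#' individuals. Both give bit-identical trajectories.
#'
#' @param params A `sim_params` object.
#' @param backend `"cell"` (default) or `"brute"`.
#' @param return_state Keep the final population state? (default `TRUE`)
#' @param record_elementary Also record the population size after every
#'   elementary step (memory-hungry; for invariant checks on short runs).
#' @return An object of class `ml_sim`: a list with `series` (a tibble, one
#'   row per recorded MC step), `params`, `extinction` (named vector),
#'   `backend`, and optionally `final_state` / `elementary_N`.
#' @examples
#' sim <- run_simulation(sim_params(init_per_species = 50, box_length = 0.25,
#'                                  capacity = 10, relax_steps = 10,
#'                                  measure_steps = 20, seed = 7))
#' head(sim$series)
#' @export
run_simulation <- function(params, backend = c("cell", "brute"),
                           return_state = TRUE, record_elementary = FALSE) {
  params <- validate_sim_params(params)
  backend <- match.arg(backend)
  res <- cpp_run_simulation(
    params$box_length, params$pred_radius, params$repro_radius,
    params$move_length, params$offspring_radius, params$capacity,
    params$prob_move, params$prob_predate, params$init_per_species,
    params$relax_steps, params$measure_steps, as.numeric(params$seed),
    if (backend == "cell") 0L else 1L, return_state, record_elementary
  )
  series <- tibble::tibble(
    t = res$series[, 1], n_A = res$series[, 2], n_B = res$series[, 3],
    n_C = res$series[, 4], N = res$series[, 5]
  )
  ext <- res$extinct
  ext[ext == -1L] <- NA_integer_
  out <- list(series = series,
              params = params,
              extinction = setNames(as.integer(ext), c("A", "B", "C")),
              symmetry_broken = any(!is.na(ext)),
              backend = backend)
  if (return_state) {
    out$final_state <- population_state(
      species = c("A", "B", "C")[res$species + 1L],
      x = res$x, y = res$y, box_length = params$box_length
    )
  }
  if (record_elementary) out$elementary_N <- res$elementary_N
  class(out) <- "ml_sim"
  out
}

#' @export
print.ml_sim <- function(x, ...) {
  s <- x$series
  cat(sprintf("<ml_sim> %d recorded MC steps (M = %d, box %.3g, seed %d, %s backend)\n",
              nrow(s), x$params$capacity, x$params$box_length,
              x$params$seed, x$backend))
  if (nrow(s) > 0) {
    cat(sprintf("  final counts: A %d, B %d, C %d (N = %d)\n",
                s$n_A[nrow(s)], s$n_B[nrow(s)], s$n_C[nrow(s)], s$N[nrow(s)]))
  }
  if (isTRUE(x$symmetry_broken)) {
    gone <- names(x$extinction)[!is.na(x$extinction)]
    cat("  symmetry broken: extinction of", paste(gone, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Snapshot and time-series export
#'
#' Plain-text exchange formats: a snapshot is a CSV with header
#' `species,x,y`, one row per individual (coordinates in `[0, box_length)`);
#' a counts series is a CSV with header `t,nA,nB,nC,N`, one row per MC step.
#'
#' @param state A `population_state` (or the `final_state` of an `ml_sim`).
#' @param series A counts-series tibble (or an `ml_sim`).
#' @param path Output file.
#' @return The path, invisibly (writers); a `population_state` or tibble
#'   (readers).
#' @export
write_snapshot <- function(state, path) {
  if (inherits(state, "ml_sim")) state <- state$final_state
  readr::write_csv(dplyr::select(tibble::as_tibble(state),
                                 "species", "x", "y"), path)
  invisible(path)
}

#' @rdname write_snapshot
#' @param box_length Box side to attach to a read snapshot.
#' @export
read_snapshot <- function(path, box_length = 1) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  population_state(df$species, df$x, df$y, box_length)
}

#' @rdname write_snapshot
#' @export
write_counts_series <- function(series, path) {
  if (inherits(series, "ml_sim")) series <- series$series
  out <- tibble::tibble(t = series$t, nA = series$n_A, nB = series$n_B,
                        nC = series$n_C, N = series$N)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_counts_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  tibble::tibble(t = df$t, n_A = df$nA, n_B = df$nB, n_C = df$nC, N = df$N)
}
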