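#' Population state
#'
#' A population is a tibble with columns `id` (integer, unique), `species`
#' (one of `"A"`, `"B"`, `"C"`), and wrapped coordinates `x`, `y`; the box
#' side is carried in the `box_length` attribute. These reference-level
#' states drive the R implementations of the microscopic rules
#' ([attempt_predation()] and friends), used for planted micro-experiments;
#' full-length runs go through the compiled engine in [run_simulation()].
#'
#' @param species Character vector of species labels.
#' @param x,y Coordinates (wrapped into the box).
#' @param box_length Side of the periodic box.
#' @return A `population_state` tibble.
#' @examples
#' make_planted_configuration(list(c("A", .5, .5), c("B", .51, .5)))
#' @export
population_state <- function(species = character(0), x = numeric(0),
                             y = numeric(0), box_length = 1) {
  stopifnot(length(species) == length(x), length(x) == length(y))
  if (!all(species %in% c("A", "B", "C"))) {
    stop("species labels must be A, B or C", call. = FALSE)
  }
  w <- wrap_position(as.numeric(x), as.numeric(y), box_length)
  st <- tibble::tibble(id = seq_along(species),
                       species = as.character(species),
                       x = w$x, y = w$y)
  attr(st, "box_length") <- box_length
  class(st) <- c("population_state", class(st))
  st
}

#' Planted configuration
#'
#' Builds a population state from an explicit list of individuals, for
#' deterministic micro-tests of predation and reproduction. Duplicate
#' positions are allowed (ids distinguish individuals in continuous space).
#'
#' @param spec A list of `c(species, x, y)` triples (or a data frame with
#'   those columns).
#' @param box_length Side of the periodic box.
#' @return A `population_state` tibble with exactly the given individuals.
#' @export
make_planted_configuration <- function(spec, box_length = 1) {
  if (is.data.frame(spec)) {
    return(population_state(spec$species, as.numeric(spec$x),
                            as.numeric(spec$y), box_length))
  }
  if (length(spec) == 0) return(population_state(box_length = box_length))
  population_state(
    species = vapply(spec, function(s) as.character(s[[1]]), character(1)),
    x = vapply(spec, function(s) as.numeric(s[[2]]), numeric(1)),
    y = vapply(spec, function(s) as.numeric(s[[3]]), numeric(1)),
    box_length = box_length
  )
}

#' Random initial population
#'
#' `init_per_species` individuals of each species at independent uniform
#' positions in the box, as at the start of a run. Uses R's RNG, seeded
#' locally so the caller's RNG state is untouched; two calls with the same
#' seed give identical states.
#'
#' @param params A `sim_params` object.
#' @param seed Seed (defaults to `params$seed`).
#' @return A `population_state` with `3 * init_per_species` individuals.
#' @export
init_population <- function(params, seed = params$seed) {
  params <- validate_sim_params(params)
  k <- params$init_per_species
  withr::with_seed(seed, {
    population_state(
      species = rep(c("A", "B", "C"), each = k),
      x = runif(3 * k, 0, params$box_length),
      y = runif(3 * k, 0, params$box_length),
      box_length = params$box_length
    )
  })
}

#' Cyclic prey map
#'
#' The non-transitive dominance cycle: A preys on B, B on C, C on A.
#'
#' @param species Character vector of labels in `{A, B, C}`.
#' @return The prey label(s).
#' @examples
#' prey_species(c("A", "B", "C"))
#' @export
prey_species <- function(species) {
  map <- c(A = "B", B = "C", C = "A")
  if (!all(species %in% names(map))) {
    stop("unknown species label", call. = FALSE)
  }
  unname(map[species])
}

.restore_state <- function(out, template) {
  attr(out, "box_length") <- attr(template, "box_length")
  class(out) <- class(template)
  out
}

.state_counts <- function(state) {
  c(n_A = sum(state$species == "A"),
    n_B = sum(state$species == "B"),
    n_C = sum(state$species == "C"))
}

#' Microscopic processes (reference implementation)
#'
#' One attempt of each elementary process, acting on a [population_state()]:
#'
#' * `attempt_predation()`: the closest individual of the actor's prey
#'   species within `pred_radius` (closed disk, minimum-image distance) is
#'   removed; if no prey is in range, nothing happens.
#' * `attempt_reproduction()`: all individuals (any species, the actor
#'   included) within `repro_radius` of the actor are counted; if the count
#'   is strictly smaller than `capacity`, an offspring of the actor's species
#'   appears at a position drawn uniformly from the disk of radius
#'   `offspring_radius` around the actor (wrapped). With `capacity = 1` the
#'   actor alone already saturates the neighbourhood, so reproduction never
#'   succeeds.
#' * `move_individual()`: the actor jumps by exactly `move_length` in a
#'   direction uniform on `[0, 2*pi)`; always succeeds.
#'
#' Reproduction and movement draw from R's RNG (seed with `set.seed()` for
#' reproducibility); predation is deterministic given the state.
#'
#' @param state A `population_state`.
#' @param actor_id Id of the acting individual (must be alive).
#' @param params A `sim_params` object.
#' @return The updated `population_state`.
#' @export
attempt_predation <- function(state, actor_id, params) {
  i <- match(actor_id, state$id)
  if (is.na(i)) stop("actor not alive", call. = FALSE)
  L <- attr(state, "box_length")
  prey <- prey_species(state$species[i])
  cand <- which(state$species == prey)
  if (length(cand) == 0) return(state)
  d <- torus_distance(state$x[cand], state$y[cand], state$x[i], state$y[i], L)
  inrange <- cand[d <= params$pred_radius]
  if (length(inrange) == 0) return(state)
  victim <- inrange[which.min(d[d <= params$pred_radius])]
  .restore_state(state[-victim, , drop = FALSE], state)
}

#' @rdname attempt_predation
#' @export
attempt_reproduction <- function(state, actor_id, params) {
  i <- match(actor_id, state$id)
  if (is.na(i)) stop("actor not alive", call. = FALSE)
  L <- attr(state, "box_length")
  d <- torus_distance(state$x, state$y, state$x[i], state$y[i], L)
  if (sum(d <= params$repro_radius) >= params$capacity) return(state)
  ang <- runif(1) * 2 * pi
  rad <- params$offspring_radius * sqrt(runif(1))
  w <- wrap_position(state$x[i] + rad * cos(ang),
                     state$y[i] + rad * sin(ang), L)
  child <- tibble::tibble(id = max(state$id) + 1L,
                          species = state$species[i], x = w$x, y = w$y)
  .restore_state(dplyr::bind_rows(state, child), state)
}

#' @rdname attempt_predation
#' @export
move_individual <- function(state, actor_id, params) {
  i <- match(actor_id, state$id)
  if (is.na(i)) stop("actor not alive", call. = FALSE)
  L <- attr(state, "box_length")
  ang <- runif(1) * 2 * pi
  w <- wrap_position(state$x[i] + params$move_length * cos(ang),
                     state$y[i] + params$move_length * sin(ang), L)
  state$x[i] <- w$x
  state$y[i] <- w$y
  state
}

#' Elementary and full Monte Carlo steps (reference implementation)
#'
#' `elementary_step()` picks one living individual uniformly at random, draws
#' one action with probabilities `(prob_move, prob_predate, prob_reproduce)`
#' and applies it; the population changes by exactly -1 (successful
#' predation), +1 (successful reproduction) or 0. `mc_step()` repeats the
#' elementary step N0 times, where N0 is the population size at the start of
#' the step (births and deaths during the step do not change the repeat
#' count); if the population empties mid-step the MC step ends early.
#'
#' @param state A `population_state` with at least one individual
#'   (`elementary_step`).
#' @param params A `sim_params` object.
#' @return The updated `population_state`.
#' @export
elementary_step <- function(state, params) {
  n <- nrow(state)
  if (n == 0) stop("population is empty (absorbing state)", call. = FALSE)
  actor <- state$id[min(floor(runif(1) * n) + 1, n)]
  u <- runif(1)
  if (u < params$prob_move) {
    move_individual(state, actor, params)
  } else if (u < params$prob_move + params$prob_predate) {
    attempt_predation(state, actor, params)
  } else {
    attempt_reproduction(state, actor, params)
  }
}

#' @rdname elementary_step
#' @export
mc_step <- function(state, params) {
  n0 <- nrow(state)
  for (e in seq_len(n0)) {
    if (nrow(state) == 0) break
    state <- elementary_step(state, params)
  }
  state
}
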