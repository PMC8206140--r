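#' Simulation parameters
#'
#' Constructs the full parameter set of the off-lattice cyclic-competition
#' model: a unit square (side `box_length`) with periodic boundaries on which
#' three species A, B, C interact cyclically (A preys on B, B on C, C on A).
#' Each elementary Monte Carlo step picks a living individual uniformly at
#' random and draws one action: movement (probability `prob_move`, a jump of
#' fixed length `move_length` in a uniform direction, always executed),
#' predation (`prob_predate`, removes the closest prey within `pred_radius`
#' if any), or reproduction (`prob_reproduce`, places an offspring uniformly
#' in a disk of radius `offspring_radius` around the parent, but only if the
#' total number of individuals within `repro_radius` of the parent — the
#' parent included — is smaller than the local carrying capacity `capacity`).
#' A full MC step repeats the elementary step N times, N being the population
#' size at the start of the step.
#'
#' Defaults are the reference parameterisation: `prob_move = 0.5`,
#' `prob_predate = prob_reproduce = 0.25`, `pred_radius = repro_radius =
#' 0.02`, `move_length = 0.01`, `box_length = 1`, `init_per_species = 1e4`.
#' `offspring_radius` defaults to `move_length` and is kept as an independent
#' field because the two roles (jump length, natal dispersal) are conceptually
#' distinct. Default schedules (`relax_steps = 2000`, `measure_steps = 10000`)
#' are desk-scale; production-scale relaxation can be far longer.
#'
#' @param box_length Side of the periodic square box (all lengths are
#'   fractions of it).
#' @param pred_radius Predation range \eqn{\ell_p}.
#' @param repro_radius Reproduction (capacity-counting) range \eqn{\ell_r}.
#' @param move_length Movement jump length \eqn{\ell_m}.
#' @param offspring_radius Radius of the natal disk around a reproducing
#'   parent; defaults to `move_length`.
#' @param capacity Local carrying capacity M: a birth succeeds only when
#'   fewer than M individuals (any species, parent included) lie within
#'   `repro_radius` of the parent.
#' @param prob_move,prob_predate,prob_reproduce Action probabilities m, p, r;
#'   must sum to 1.
#' @param init_per_species Initial count of each species.
#' @param relax_steps MC steps discarded before measurement.
#' @param measure_steps MC steps recorded.
#' @param seed Integer RNG seed.
#' @return A validated object of class `sim_params` (a named list).
#' @seealso [validate_sim_params()], [run_simulation()]
#' @examples
#' p <- sim_params(capacity = 30, init_per_species = 100, seed = 1)
#' p$prob_move + p$prob_predate + p$prob_reproduce
#' @export
sim_params <- function(box_length = 1,
                       pred_radius = 0.02,
                       repro_radius = 0.02,
                       move_length = 0.01,
                       offspring_radius = move_length,
                       capacity = 30L,
                       prob_move = 0.5,
                       prob_predate = 0.25,
                       prob_reproduce = 0.25,
                       init_per_species = 10000L,
                       relax_steps = 2000L,
                       measure_steps = 10000L,
                       seed = 1L) {
  p <- structure(list(
    box_length = as.numeric(box_length),
    pred_radius = as.numeric(pred_radius),
    repro_radius = as.numeric(repro_radius),
    move_length = as.numeric(move_length),
    offspring_radius = as.numeric(offspring_radius),
    capacity = as.integer(capacity),
    prob_move = as.numeric(prob_move),
    prob_predate = as.numeric(prob_predate),
    prob_reproduce = as.numeric(prob_reproduce),
    init_per_species = as.integer(init_per_species),
    relax_steps = as.integer(relax_steps),
    measure_steps = as.integer(measure_steps),
    seed = as.integer(seed)
  ), class = "sim_params")
  validate_sim_params(p)
}

#' Reference parameter set
#'
#' The model's reference parameterisation (see [sim_params()] for values),
#' with desk-scale step schedules.
#'
#' @param ... Overrides passed to [sim_params()].
#' @return A `sim_params` object.
#' @examples
#' default_params()$prob_move
#' @export
default_params <- function(...) sim_params(...)

#' Validate a parameter set
#'
#' Checks every model invariant and reports the first violated one by name:
#' action probabilities must sum to 1 (tolerance 1e-12) and lie in \[0, 1\];
#' `pred_radius` and `repro_radius` must lie in (0, box_length / 2\] (required
#' for minimum-image distances and complete cell-list queries);
#' `move_length` and `offspring_radius` must be positive (a jump may exceed
#' the box — it simply wraps — which is how the well-mixed limit is reached);
#' `capacity` and `init_per_species` must be at least 1; step counts and the
#' seed must be non-negative integers with `measure_steps` at least 1.
#'
#' @param params A `sim_params` object (or a named list coercible to one).
#' @return `params`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_sim_params <- function(params) {
  p <- unclass(params)
  need <- names(formals(sim_params))
  need <- setdiff(need, "offspring_radius")
  missing <- setdiff(c(need, "offspring_radius"), names(p))
  if (length(missing) > 0) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                logical(1))
  if (!all(num)) {
    stop("non-numeric or non-finite value for: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  if (p$box_length <= 0) stop("box_length must be positive", call. = FALSE)
  probs <- c(p$prob_move, p$prob_predate, p$prob_reproduce)
  if (any(probs < 0) || any(probs > 1)) {
    stop("action probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    stop("probabilities sum != 1 (prob_move + prob_predate + prob_reproduce = ",
         format(sum(probs), digits = 15), ")", call. = FALSE)
  }
  for (f in c("pred_radius", "repro_radius")) {
    if (p[[f]] <= 0 || p[[f]] > p$box_length / 2) {
      stop(f, " radius exceeds box: must lie in (0, box_length/2]",
           call. = FALSE)
    }
  }
  if (p$move_length <= 0) stop("move_length must be positive", call. = FALSE)
  if (p$offspring_radius <= 0) {
    stop("offspring_radius must be positive", call. = FALSE)
  }
  if (p$capacity < 1) stop("capacity must be >= 1", call. = FALSE)
  if (p$init_per_species < 1) {
    stop("init_per_species must be >= 1", call. = FALSE)
  }
  if (p$relax_steps < 0) stop("relax_steps must be >= 0", call. = FALSE)
  if (p$measure_steps < 1) stop("measure_steps must be >= 1", call. = FALSE)
  invisible(structure(p, class = "sim_params"))
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  box %.4g | radii: pred %.4g, repro %.4g | move %.4g (natal %.4g)\n",
              x$box_length, x$pred_radius, x$repro_radius, x$move_length,
              x$offspring_radius))
  cat(sprintf("  capacity M = %d | probs (m, p, r) = (%.3g, %.3g, %.3g)\n",
              x$capacity, x$prob_move, x$prob_predate, x$prob_reproduce))
  cat(sprintf("  init %d/species | relax %d + measure %d MC steps | seed %d\n",
              x$init_per_species, x$relax_steps, x$measure_steps, x$seed))
  invisible(x)
}

#' Read / write a parameter file
#'
#' Flat key-value text format, one `key: value` per line, keys exactly the
#' field names of [sim_params()]. `read_sim_config()` errors on unknown keys,
#' missing keys and unparsable values, each named in the message, and
#' validates the result; the round trip `read_sim_config(write_sim_config(p))`
#' is the identity for every valid parameter set.
#'
#' @param path File path.
#' @param params A `sim_params` object.
#' @return `read_sim_config()` returns a `sim_params`; `write_sim_config()`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- names(formals(sim_params))
  vals <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("unparsable config line: ", ln, call. = FALSE)
    key <- m[2]
    if (!key %in% fields) stop("unknown key: ", key, call. = FALSE)
    v <- suppressWarnings(as.numeric(m[3]))
    if (is.na(v)) stop("unparsable value for key ", key, ": ", m[3],
                       call. = FALSE)
    vals[[key]] <- v
  }
  missing <- setdiff(fields, names(vals))
  if (length(missing) > 0) {
    stop("missing key(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(sim_params, vals)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(params, path) {
  params <- validate_sim_params(params)
  keys <- names(unclass(params))
  lines <- vapply(keys, function(k) {
    sprintf("%s: %s", k, format(params[[k]], digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
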