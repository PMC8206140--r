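#' Stationary summary of a counts series
#'
#' Mean, standard error and histogram of the total population N over the
#' steps after `burn_in`. Successive MC steps are strongly autocorrelated,
#' so the standard error uses block averaging: the window is cut into
#' consecutive blocks of `block_length` steps and the error is the standard
#' error of the block means (falling back to the naive iid estimate when
#' fewer than two complete blocks fit). The histogram uses bin width 1 (N is
#' an integer) unless the range exceeds 1000 values, in which case bins are
#' widened to keep at most 1000 of them; histogram frequencies sum to the
#' window length and the histogram mean equals the window mean.
#'
#' @param series A counts-series tibble (columns `t`, `n_A`, `n_B`, `n_C`,
#'   `N`) or an `ml_sim`.
#' @param burn_in Steps discarded from the start of the series.
#' @param block_length Block size (MC steps) for the error estimate.
#' @return An object of class `pop_summary`: list with `mean_N`, `stderr_N`,
#'   `histogram` (tibble `N`, `count`, `width`), `window`, `block_length`.
#' @examples
#' s <- tibble::tibble(t = 1:3, n_A = c(4, 8, 12), n_B = 3, n_C = 3,
#'                     N = c(10, 20, 30))
#' summarize_series(s)$mean_N
#' @export
summarize_series <- function(series, burn_in = 0, block_length = 100) {
  if (inherits(series, "ml_sim")) series <- series$series
  n <- nrow(series)
  if (burn_in >= n) stop("empty window: burn_in >= series length", call. = FALSE)
  v <- series$N[(burn_in + 1):n]
  m <- mean(v)
  nb <- length(v) %/% block_length
  se <- if (nb >= 2) {
    bm <- vapply(seq_len(nb), function(b) {
      mean(v[((b - 1) * block_length + 1):(b * block_length)])
    }, numeric(1))
    sd(bm) / sqrt(nb)
  } else {
    sd(v) / sqrt(length(v))
  }
  if (length(v) == 1) se <- 0
  rng <- range(v)
  width <- max(1, ceiling((rng[2] - rng[1] + 1) / 1000))
  bin <- floor((v - rng[1]) / width)
  tab <- table(bin)
  hist <- tibble::tibble(
    N = rng[1] + as.integer(names(tab)) * width + (width - 1) / 2,
    count = as.integer(tab),
    width = width
  )
  structure(list(mean_N = m, stderr_N = se, histogram = hist,
                 window = c(start = burn_in + 1, end = n),
                 block_length = block_length),
            class = "pop_summary")
}

#' @export
print.pop_summary <- function(x, ...) {
  cat(sprintf("<pop_summary> mean N = %.2f (block stderr %.3f) over steps %d..%d\n",
              x$mean_N, x$stderr_N, x$window[1], x$window[2]))
  invisible(x)
}

#' @export
tidy.pop_summary <- function(x, ...) {
  tibble::tibble(mean_N = x$mean_N, stderr_N = x$stderr_N,
                 window_start = x$window[1], window_end = x$window[2])
}

#' Sweep the local carrying capacity
#'
#' Runs `replicates` independent simulations for each capacity M, summarises
#' the stationary total population of each and pools the per-run means. The
#' pooled standard error combines the between-replicate spread with the
#' within-run block-averaged errors (whichever is larger, to stay
#' conservative with few replicates). The benign-environment prediction is
#' that the pooled mean grows linearly with M; fit it with
#' [fit_capacity_line()].
#'
#' @param params_base A `sim_params` giving everything except the capacity.
#' @param M_values Integer vector of capacities to sweep.
#' @param replicates Independent runs per capacity.
#' @param seeds Optional integer matrix/vector of seeds, one per (M,
#'   replicate) pair; defaults to seeds derived deterministically from
#'   `params_base$seed`.
#' @param burn_in Steps discarded from each recorded series before averaging.
#' @return A tibble of class `capacity_sweep` with columns `M`, `mean_N`,
#'   `stderr_N`, `replicates`.
#' @export
sweep_capacity <- function(params_base, M_values, replicates = 3,
                           seeds = NULL, burn_in = 0) {
  stopifnot(length(M_values) >= 1, replicates >= 1)
  nrun <- length(M_values) * replicates
  if (is.null(seeds)) {
    seeds <- withr::with_seed(params_base$seed,
                              sample.int(.Machine$integer.max, nrun))
  }
  stopifnot(length(seeds) >= nrun)
  rows <- purrr::imap(M_values, function(M, i) {
    sums <- purrr::map(seq_len(replicates), function(r) {
      p <- modifyList(unclass(params_base),
                      list(capacity = as.integer(M),
                           seed = seeds[(i - 1) * replicates + r]))
      class(p) <- "sim_params"
      sim <- run_simulation(p, return_state = FALSE)
      summarize_series(sim$series, burn_in = burn_in)
    })
    means <- purrr::map_dbl(sums, "mean_N")
    within <- sqrt(mean(purrr::map_dbl(sums, "stderr_N")^2) / replicates)
    between <- if (replicates >= 2) sd(means) / sqrt(replicates) else 0
    tibble::tibble(M = as.integer(M), mean_N = mean(means),
                   stderr_N = max(within, between),
                   replicates = as.integer(replicates))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("capacity_sweep", class(out))
  out
}

#' Weighted least-squares line
#'
#' Fits `y = intercept + slope * x` by weighted least squares via
#' [stats::lm()]. Default weights are inverse-variance (`1 / stderr^2`) when
#' a `weight` column is absent but a `stderr` column is present, else equal.
#'
#' @param data A data frame with columns `x`, `y` and optionally `weight` or
#'   `stderr`.
#' @return An object of class `wls_fit`: list with `slope`, `intercept`,
#'   their standard errors, `r_squared` and the underlying `lm` fit.
#'   `tidy()` and `glance()` methods are provided.
#' @examples
#' linear_fit(data.frame(x = 1:4, y = 2 * (1:4) + 1))$slope
#' @export
linear_fit <- function(data) {
  stopifnot(all(c("x", "y") %in% names(data)))
  if (length(unique(data$x)) < 2) {
    stop("all x identical: a line is not identifiable", call. = FALSE)
  }
  w <- if ("weight" %in% names(data)) {
    data$weight
  } else if ("stderr" %in% names(data)) {
    1 / pmax(data$stderr, 1e-12)^2
  } else {
    rep(1, nrow(data))
  }
  fit <- lm(y ~ x, data = data, weights = w)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_se = sm$coefficients[2, 2],
                 intercept_se = sm$coefficients[1, 2],
                 r_squared = sm$r.squared,
                 fit = fit),
            class = "wls_fit")
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf("<wls_fit> y = %.4g + %.4g x  (r^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @export
tidy.wls_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(x$intercept_se, x$slope_se))
}

#' @export
glance.wls_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared,
                 nobs = length(x$fit$residuals))
}

#' Fit the mean-population-vs-capacity line
#'
#' Inverse-variance weighted linear fit of the pooled mean population against
#' the carrying capacity from a [sweep_capacity()] table.
#'
#' @param sweep A `capacity_sweep` tibble (columns `M`, `mean_N`, `stderr_N`).
#' @return A `wls_fit`.
#' @export
fit_capacity_line <- function(sweep) {
  linear_fit(tibble::tibble(x = sweep$M, y = sweep$mean_N,
                            stderr = sweep$stderr_N))
}

#' @rdname write_snapshot
#' @param sweep A `capacity_sweep` tibble.
#' @export
write_capacity_sweep <- function(sweep, path) {
  readr::write_csv(
    tibble::tibble(M = sweep$M, mean_N = sweep$mean_N,
                   stderr_N = sweep$stderr_N, replicates = sweep$replicates),
    path)
  invisible(path)
}
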