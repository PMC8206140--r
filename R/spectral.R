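#' Species-fraction series
#'
#' Extracts the fraction rho(t) = n_s(t) / N(t) of one species over a window
#' of `n_g` consecutive recorded MC steps. Fractions of the three species sum
#' to 1 at every step; the window must not contain an empty population.
#'
#' @param series A counts-series tibble or an `ml_sim`.
#' @param species `"A"`, `"B"` or `"C"`.
#' @param start First row of the window (1-based).
#' @param n_g Window length (number of DFT components).
#' @return A numeric vector of length `n_g` with attribute `n_g`.
#' @export
fraction_series <- function(series, species = "A", start = 1,
                            n_g = nrow(series) - start + 1) {
  if (inherits(series, "ml_sim")) series <- series$series
  if (start + n_g - 1 > nrow(series)) {
    stop("window exceeds series length", call. = FALSE)
  }
  idx <- start:(start + n_g - 1)
  tot <- series$N[idx]
  if (any(tot == 0)) {
    stop("population empty inside the window; fractions undefined",
         call. = FALSE)
  }
  col <- switch(species, A = "n_A", B = "n_B", C = "n_C",
                stop("unknown species label", call. = FALSE))
  rho <- series[[col]][idx] / tot
  attr(rho, "n_g") <- as.integer(n_g)
  rho
}

#' Discrete Fourier transform of a fraction series
#'
#' The temporal DFT with a 1/N_G prefactor,
#' \deqn{\rho(f) = \frac{1}{N_G}\sum_{t=0}^{N_G-1} \rho(t)\, e^{-2\pi i f t / N_G},}
#' so that the f = 0 coefficient equals the time mean of the series.
#' Computed via [stats::fft()].
#'
#' @param rho Numeric vector (length at least 2).
#' @return Complex vector of the N_G coefficients, f = 0 ... N_G - 1.
#' @examples
#' Re(dft(rep(0.5, 8))[1])  # DC coefficient = mean
#' @export
dft <- function(rho) {
  if (length(rho) < 2) stop("need at least 2 components", call. = FALSE)
  fft(as.numeric(rho)) / length(rho)
}

#' Ensemble-averaged power spectrum
#'
#' For each run, the squared magnitude of the [dft()] coefficients is folded
#' to non-negative frequencies k = 0 ... N_G/2 (k in cycles per N_G-step
#' window); powers are then averaged bin-wise across runs. The DC bin (k = 0,
#' the squared mean fraction) is retained but excluded from peak searches.
#'
#' @param runs A list of fraction series (numeric vectors of equal length),
#'   or a single numeric vector.
#' @return A tibble of class `ml_spectrum` with columns `k` and `power`, and
#'   attributes `n_g` and `replicates`.
#' @export
ensemble_power_spectrum <- function(runs) {
  if (is.numeric(runs)) runs <- list(runs)
  stopifnot(length(runs) >= 1)
  n_g <- length(runs[[1]])
  if (!all(vapply(runs, length, integer(1)) == n_g)) {
    stop("fraction series have mismatched lengths", call. = FALSE)
  }
  kmax <- floor(n_g / 2)
  pw <- purrr::map(runs, function(r) Mod(dft(r))[1:(kmax + 1)]^2)
  out <- tibble::tibble(k = 0:kmax,
                        power = Reduce(`+`, pw) / length(pw))
  attr(out, "n_g") <- as.integer(n_g)
  attr(out, "replicates") <- length(runs)
  class(out) <- c("ml_spectrum", class(out))
  out
}

.smooth_power <- function(power, window) {
  if (window <= 1) return(power)
  if (window %% 2 == 0) window <- window + 1
  sm <- stats::filter(power, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- power[is.na(sm)]  # edges: keep raw values
  sm
}

#' Characteristic (peak) frequency of a spectrum
#'
#' Location of the maximum of the power over k > 0, i.e. the number of
#' oscillation cycles per N_G-step window. An optional centred moving-average
#' smoothing of `smoothing_window` bins is applied before the search (useful
#' for few-replicate spectra; 0 or 1 disables it). The result is invariant to
#' any overall rescaling of the powers. `peak_power()` returns the
#' (smoothed) power at that location.
#'
#' @param spectrum An `ml_spectrum` (or tibble with columns `k`, `power`).
#' @param smoothing_window Moving-average width in bins.
#' @return Peak location (integer k) / peak power (numeric).
#' @export
peak_frequency <- function(spectrum, smoothing_window = 0) {
  nz <- spectrum[spectrum$k > 0, , drop = FALSE]
  if (nrow(nz) < 3) stop("need at least 3 non-DC bins", call. = FALSE)
  pw <- .smooth_power(nz$power, smoothing_window)
  if (all(pw == 0)) stop("all-zero spectrum has no peak", call. = FALSE)
  nz$k[which.max(pw)]
}

#' @rdname peak_frequency
#' @export
peak_power <- function(spectrum, smoothing_window = 0) {
  nz <- spectrum[spectrum$k > 0, , drop = FALSE]
  pw <- .smooth_power(nz$power, smoothing_window)
  max(pw)
}

#' Logarithmic scaling of the peak frequency with capacity
#'
#' Least-squares fit of `f_peak = a + b * ln(M)` over at least three
#' distinct capacities, the scaling followed by the characteristic
#' oscillation frequency as the environment improves.
#'
#' @param points A data frame with columns `M` (positive) and `f_peak`.
#' @return An object of class `peak_scaling`: list with `a`, `b`,
#'   `r_squared`, the `points` and the underlying `wls_fit`; `tidy()` and
#'   `glance()` methods are provided.
#' @examples
#' fit_log_scaling(data.frame(M = c(10, 20, 40), f_peak = 3 + 2 * log(c(10, 20, 40))))
#' @export
fit_log_scaling <- function(points) {
  stopifnot(all(c("M", "f_peak") %in% names(points)))
  if (any(points$M <= 0)) stop("M must be positive for ln(M)", call. = FALSE)
  if (length(unique(points$M)) < 3) {
    stop("need at least 3 distinct M", call. = FALSE)
  }
  wf <- linear_fit(tibble::tibble(x = log(points$M), y = points$f_peak))
  structure(list(a = wf$intercept, b = wf$slope, r_squared = wf$r_squared,
                 points = tibble::as_tibble(points), fit = wf),
            class = "peak_scaling")
}

#' @export
print.peak_scaling <- function(x, ...) {
  cat(sprintf("<peak_scaling> f_peak = %.3f + %.3f ln(M)  (r^2 = %.4f, %d capacities)\n",
              x$a, x$b, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @export
tidy.peak_scaling <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b),
                 std.error = c(x$fit$intercept_se, x$fit$slope_se))
}

#' @export
glance.peak_scaling <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = nrow(x$points))
}

#' @rdname write_snapshot
#' @param spectrum An `ml_spectrum`.
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_csv(
    tibble::tibble(k = spectrum$k, power = spectrum$power,
                   replicates = attr(spectrum, "replicates"),
                   NG = attr(spectrum, "n_g")),
    path)
  invisible(path)
}
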