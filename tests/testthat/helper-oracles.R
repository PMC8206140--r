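# Independent oracles used across test files.

# exhaustive minimum over the 9 periodic images (reference for the
# minimum-image distance)
dist_nine_images <- function(x1, y1, x2, y2, L) {
  best <- Inf
  for (sx in c(-L, 0, L)) {
    for (sy in c(-L, 0, L)) {
      best <- min(best, sqrt((x1 - (x2 + sx))^2 + (y1 - (y2 + sy))^2))
    }
  }
  best
}

# direct double-loop evaluation of the normalised DFT
dft_naive <- function(rho) {
  n <- length(rho)
  t <- 0:(n - 1)
  vapply(0:(n - 1), function(f) {
    sum(rho * exp(-2i * pi * f * t / n)) / n
  }, complex(1))
}

# weighted least squares through the normal equations
wls_naive <- function(x, y, w) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  c(intercept = beta[1], slope = beta[2])
}

random_state <- function(n, L = 1, seed = 1) {
  withr::with_seed(seed, population_state(
    species = sample(c("A", "B", "C"), n, replace = TRUE),
    x = runif(n, 0, L),
    y = runif(n, 0, L),
    box_length = L
  ))
}
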