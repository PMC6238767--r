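# Shared test fixtures: noisy power-law samples and an independent
# numerical estimator used as the oracle for the closed-form fit.

# power-law SAD with multiplicative log-normal noise (uses current RNG)
random_sad <- function(S, p, sigma = 0.3, sample_id = "random") {
  a <- seq_len(S)^(-p) * exp(stats::rnorm(S, 0, sigma))
  rank_abundance(a, sample_id = sample_id)
}

# oracle: minimize the log-scale SSE by dense grid + bracketed
# golden-section/parabolic refinement, independent of the closed form
sse_oracle_p <- function(sample, lower = -10, upper = 10) {
  a <- sample$abundances
  Fr <- log(a / a[1])
  Dr <- log(seq_along(a))
  sse <- function(p) sum((-p * Dr - Fr)^2)
  grid <- seq(lower, upper, by = 0.01)
  i <- which.min(vapply(grid, sse, numeric(1)))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  stats::optimize(sse, c(lo, hi), tol = 1e-12)$minimum
}

# oracle: R^2 recomputed term by term, independent of r_squared_log
r2_oracle <- function(sample, p, centered = TRUE) {
  a <- sample$abundances
  ss_res <- 0
  fvals <- numeric(length(a))
  for (r in seq_along(a)) {
    fvals[r] <- log(a[r] / a[1])
    ss_res <- ss_res + (fvals[r] + p * log(r))^2
  }
  fbar <- if (centered) sum(fvals) / length(fvals) else 0
  ss_tot <- 0
  for (r in seq_along(a)) ss_tot <- ss_tot + (fvals[r] - fbar)^2
  1 - ss_res / ss_tot
}
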