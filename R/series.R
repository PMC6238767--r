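#' Finite generalized harmonic sum: effective species number A_T/A_1
#'
#' Under the fractal model the ratio of total to dominant abundance is the
#' partial generalized harmonic sum
#' \deqn{A_T/A_1 = \sum_{r=1}^{S} r^{-p},}
#' which is the effective number of species of order infinity for the
#' model community. It equals `S` at `p = 0` (perfect evenness) and the
#' `S`-th harmonic number at `p = 1` (Zipf's law).
#'
#' @param p exponent (any real).
#' @param S richness, integer `>= 1`.
#' @return The partial sum as a single number.
#' @examples
#' effective_species_finite(1, 6)   # 49/20 = 2.45
#' @export
effective_species_finite <- function(p, S) {
  if (!is.numeric(S) || length(S) != 1L || is.na(S) || S < 1 ||
      S != floor(S))
    stop("'S' must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p))
    stop("'p' must be a single finite number", call. = FALSE)
  sum(seq_len(S)^(-p))
}

#' Infinite generalized harmonic series (Riemann zeta limit)
#'
#' For an infinitely rich community the model's `A_T/A_1` is the series
#' `sum_{r>=1} r^-p`, which converges to the Riemann zeta value `zeta(p)`
#' exactly when `p > 1` and diverges for `p <= 1` (at `p = 1` it is the
#' ordinary harmonic series underlying Zipf's law). Divergence is part of
#' the contract: for `p <= 1` the function signals a condition of class
#' `"fractalsad_divergence"` instead of returning a number.
#'
#' The convergent case is evaluated by an explicit partial sum to `N`
#' terms plus the integral tail `N^(1-p)/(p-1)` with Euler–Maclaurin
#' correction terms; `N` is grown until the analytic bound on the
#' remainder falls below `tol`.
#'
#' @param p exponent.
#' @param tol absolute tolerance of the returned value (default `1e-12`).
#' @return `zeta(p)` to within `tol`, for `p > 1`.
#' @examples
#' effective_species_infinite(2)    # pi^2/6
#' @export
effective_species_infinite <- function(p, tol = 1e-12) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p))
    stop("'p' must be a single number", call. = FALSE)
  if (!is.numeric(tol) || length(tol) != 1L || !is.finite(tol) || tol <= 0)
    stop("'tol' must be a single positive number", call. = FALSE)
  if (p <= 1) {
    cond <- structure(
      class = c("fractalsad_divergence", "error", "condition"),
      list(message = sprintf(
             "the series sum(r^-p) diverges for p = %g (requires p > 1)", p),
           call = sys.call(-1)))
    stop(cond)
  }
  # partial sum + Euler-Maclaurin tail:
  #   zeta(p) = sum_{r=1}^N r^-p + N^(1-p)/(p-1) - N^-p/2 + p*N^(-p-1)/12 + R,
  # with |R| <= p*(p+1)*(p+2) * N^(-p-3) / 720.
  N <- 64L
  repeat {
    bound <- p * (p + 1) * (p + 2) * N^(-p - 3) / 720
    if (bound < tol || N >= 2^24) break
    N <- N * 2L
  }
  r <- seq_len(N)
  sum(r^(-p)) + N^(1 - p) / (p - 1) - N^(-p) / 2 + p * N^(-p - 1) / 12
}

#' Gap between the harmonic number and its logarithm
#'
#' At `p = 1` the effective species number of a community of richness `S`
#' is the harmonic number `H_S`, and `H_S - ln(S)` decreases monotonically
#' to the Euler–Mascheroni constant (gamma, about 0.5772157) as `S` grows.
#' This gap quantifies how far the finite Zipf community is from its
#' logarithmic asymptote.
#'
#' @param S richness, integer `>= 1`.
#' @return `H_S - ln(S)`, a single number in `(gamma, 1]`.
#' @examples
#' harmonic_gap(1)   # 1
#' harmonic_gap(1e6) # ~ 0.5772162
#' @export
harmonic_gap <- function(S) {
  if (!is.numeric(S) || length(S) != 1L || is.na(S) || S < 1 ||
      S != floor(S))
    stop("'S' must be a single integer >= 1", call. = FALSE)
  sum(1 / seq_len(S)) - log(S)
}
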