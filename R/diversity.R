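#' Hill number (effective number of species) of a sample
#'
#' The Hill number of order `a` of a community with relative abundances
#' `w_i = A_i / A_T` is
#' \deqn{{}^aN = \left(\sum_i w_i^a\right)^{1/(1-a)},}
#' the richness of a perfectly even community with the same diversity.
#' Special orders are handled analytically: `a = 0` returns the richness
#' `S`; `a = 1` the exponential of Shannon entropy (the continuity limit);
#' `a = 2` is the inverse Simpson concentration; and `a = Inf` returns
#' `1/max(w_i) = A_T/A_1`, the reciprocal dominance. The order-infinity
#' identity is the bridge between the fractal model's `A_T/A_1` and
#' classical diversity theory.
#'
#' Infinity is an explicit sentinel order (`Inf`), not a large finite
#' surrogate, and the `a = 1` case is the analytic Shannon limit rather
#' than a numerical approach to 1.
#'
#' @param sample a [rank_abundance] object or numeric abundance vector.
#' @param a non-negative order; may be `Inf`.
#' @return A single number in `[1, S]`.
#' @examples
#' hill_number(c(1, 1/2, 1/3), Inf)   # (11/6)/1
#' hill_number(c(0.5, 0.3, 0.2), 2)   # inverse Simpson
#' @export
hill_number <- function(sample, a) {
  sample <- as_rank_abundance(sample)
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0)
    stop("invalid order: 'a' must be a single number >= 0", call. = FALSE)
  if (is.infinite(a)) return(sample$A_T / sample$abundances[1L])
  if (a == 0) return(as.numeric(sample$S))
  w <- sample$abundances / sample$A_T
  if (a == 1) return(exp(-sum(w * log(w))))
  sum(w^a)^(1 / (1 - a))
}

#' Rényi entropy of a sample
#'
#' The Rényi entropy of order `a` is the natural logarithm of the Hill
#' number of the same order; at `a = 1` it is Shannon entropy.
#'
#' @inheritParams hill_number
#' @return Entropy in nats (a single non-negative number).
#' @examples
#' renyi_entropy(c(0.5, 0.3, 0.2), 1)   # Shannon entropy
#' @export
renyi_entropy <- function(sample, a) {
  log(hill_number(sample, a))
}

#' Diversity profile over a grid of orders
#'
#' Evaluates Hill numbers (and Rényi entropies) on a grid of orders,
#' producing the non-increasing diversity profile of the sample.
#'
#' @param sample a [rank_abundance] object or numeric abundance vector.
#' @param orders non-negative orders; may include `Inf` (default grid
#'   `0, 0.5, 1, 2, 4, Inf`).
#' @return A data frame with columns `order`, `hill` and `renyi`, one row
#'   per order, with the sample identifier in attribute `"sample_id"`.
#' @export
diversity_profile <- function(sample, orders = c(0, 0.5, 1, 2, 4, Inf)) {
  sample <- as_rank_abundance(sample)
  if (!is.numeric(orders) || length(orders) == 0L || anyNA(orders) ||
      any(orders < 0))
    stop("'orders' must be non-negative numbers", call. = FALSE)
  hill <- vapply(orders, function(a) hill_number(sample, a), numeric(1))
  out <- data.frame(order = orders, hill = hill, renyi = log(hill))
  attr(out, "sample_id") <- sample$sample_id
  out
}
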