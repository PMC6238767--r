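#' Configure a synthetic community generator
#'
#' A `synthetic_spec` fully determines one synthetic community, including
#' its random seed: identical specs produce identical output. Three models
#' are available.
#'
#' * `"exact_power_law"` — the noise-free fractal curve
#'   `A_r/A_1 = r^-p_true` for ranks `1..S` (deterministic; the seed is
#'   ignored).
#' * `"multinomial_power_law"` — `N` individuals drawn from the
#'   `S`-category multinomial with probabilities proportional to
#'   `r^-p_true`; species with zero draws are removed and the result
#'   re-ranked. This is the sampling-noise layer used for
#'   parameter-recovery experiments.
#' * `"fractal_accumulation"` — the stepwise species-accumulation process:
#'   each step multiplies the species total by `K = k^d` while the newly
#'   appearing species are `k` times less abundant than those of the
#'   previous step. Richness after step `j` is `ceiling(K^j)`, so
#'   non-integer `K` is supported; the output staircase approximates
#'   `A_r/A_1 = r^(-1/d)`.
#'
#' @param model one of `"exact_power_law"`, `"multinomial_power_law"`,
#'   `"fractal_accumulation"`.
#' @param p_true true exponent (power-law models).
#' @param S target richness (power-law models), integer `>= 1`
#'   (`>= 2` for multinomial sampling).
#' @param N number of individuals to draw (multinomial model), `>= 1`.
#' @param d fractal dimension `> 0` (accumulation model).
#' @param k abundance ratio between consecutive steps, `> 1`
#'   (accumulation model).
#' @param n_steps number of accumulation steps, integer `>= 0`.
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_community()]
#' @export
synthetic_spec <- function(model = c("exact_power_law",
                                     "multinomial_power_law",
                                     "fractal_accumulation"),
                           p_true = 1, S = 50L, N = 10000L,
                           d = 1, k = 2, n_steps = 8L, seed = 1L) {
  model <- match.arg(model)
  chk <- function(ok, msg) if (!ok) stop("invalid spec: ", msg, call. = FALSE)
  if (model %in% c("exact_power_law", "multinomial_power_law")) {
    chk(is.numeric(p_true) && length(p_true) == 1L && is.finite(p_true),
        "'p_true' must be a single finite number")
    chk(is.numeric(S) && length(S) == 1L && !is.na(S) && S >= 1 &&
          S == floor(S), "'S' must be an integer >= 1")
  }
  if (model == "multinomial_power_law") {
    chk(S >= 2, "'S' must be >= 2 for multinomial sampling")
    chk(is.numeric(N) && length(N) == 1L && !is.na(N) && N >= 1 &&
          N == floor(N), "'N' must be an integer >= 1")
  }
  if (model == "fractal_accumulation") {
    chk(is.numeric(d) && length(d) == 1L && is.finite(d) && d > 0,
        "'d' must be > 0")
    chk(is.numeric(k) && length(k) == 1L && is.finite(k) && k > 1,
        "'k' must be > 1")
    chk(is.numeric(n_steps) && length(n_steps) == 1L && !is.na(n_steps) &&
          n_steps >= 0 && n_steps == floor(n_steps),
        "'n_steps' must be an integer >= 0")
  }
  chk(is.numeric(seed) && length(seed) == 1L && !is.na(seed) &&
        seed == floor(seed), "'seed' must be an integer")
  structure(list(model = model, p_true = p_true, S = as.integer(S),
                 N = as.numeric(N), d = d, k = k,
                 n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic community from a spec
#'
#' Dispatches on `spec$model` to [generate_exact()],
#' [generate_multinomial()] or [generate_accumulation()].
#'
#' @param spec a [synthetic_spec] object.
#' @return A [rank_abundance] object.
#' @examples
#' generate_community(synthetic_spec("exact_power_law", p_true = 1, S = 6))
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  switch(spec$model,
         exact_power_law      = generate_exact(spec),
         multinomial_power_law = generate_multinomial(spec),
         fractal_accumulation = generate_accumulation(spec))
}

#' Noise-free power-law community
#'
#' Returns the exact curve `A_r/A_1 = r^-p_true`; deterministic, the
#' spec's seed is ignored. Applying [estimate_p()] to the output recovers
#' `p_true` to machine precision.
#'
#' @param spec a [synthetic_spec] with `model = "exact_power_law"`.
#' @return A [rank_abundance] object.
#' @export
generate_exact <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$model != "exact_power_law")
    stop("invalid spec: model is '", spec$model,
         "', expected 'exact_power_law'", call. = FALSE)
  predict_sad(spec$p_true, spec$S,
              sample_id = sprintf("exact_p%g_S%d", spec$p_true, spec$S),
              group = "synthetic")
}

#' Multinomially sampled power-law community
#'
#' Draws `N` individuals from `S` species with probabilities proportional
#' to `r^-p_true`, drops species that receive zero draws (only detected
#' species appear in real survey data) and re-ranks the counts. Output is
#' fully determined by the spec, including its seed; the caller's RNG
#' state is left untouched.
#'
#' @param spec a [synthetic_spec] with `model = "multinomial_power_law"`.
#' @return A [rank_abundance] object of integer counts.
#' @export
generate_multinomial <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$model != "multinomial_power_law")
    stop("invalid spec: model is '", spec$model,
         "', expected 'multinomial_power_law'", call. = FALSE)
  prob <- seq_len(spec$S)^(-spec$p_true)
  counts <- withr::with_seed(spec$seed,
                             stats::rmultinom(1L, size = spec$N, prob = prob))
  rank_abundance(as.numeric(counts),
                 sample_id = sprintf("multinom_p%g_S%d_N%g_seed%d",
                                     spec$p_true, spec$S, spec$N, spec$seed),
                 group = "synthetic")
}

#' Stepwise fractal accumulation community
#'
#' Simulates the accumulation hypothesis behind the fractal model: step 0
#' holds one species of abundance 1; after step `j >= 1` the community
#' holds `ceiling(K^j)` species in total (`K = k^d`), the species new at
#' step `j` each having abundance `k^-j`. The number added at step `j` is
#' `ceiling(K^j) - ceiling(K^(j-1))`, so non-integer `K` yields an exact,
#' reproducible richness schedule. The ranked output is a staircase
#' approximation of `A_r/A_1 = r^(-1/d)`; it is deterministic.
#'
#' @param spec a [synthetic_spec] with `model = "fractal_accumulation"`.
#' @return A [rank_abundance] object.
#' @examples
#' # d = 1, k = 2: richness doubles each step
#' generate_accumulation(synthetic_spec("fractal_accumulation",
#'                                      d = 1, k = 2, n_steps = 3))$abundances
#' @export
generate_accumulation <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$model != "fractal_accumulation")
    stop("invalid spec: model is '", spec$model,
         "', expected 'fractal_accumulation'", call. = FALSE)
  # richness after step j is ceiling(K^j), K = k^d; K^j is evaluated as
  # k^(d*j) with a relative guard so values that are integers in exact
  # arithmetic (e.g. k = 2, d = 1/2, j even) are not ceiled upward
  x <- spec$k^(spec$d * (0:spec$n_steps))
  totals <- ceiling(x * (1 - 1e-12))
  new_at_step <- c(1, diff(totals))
  abund <- rep(spec$k^(-(0:spec$n_steps)), times = new_at_step)
  rank_abundance(abund,
                 sample_id = sprintf("accum_d%g_k%g_steps%d",
                                     spec$d, spec$k, spec$n_steps),
                 group = "synthetic")
}
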