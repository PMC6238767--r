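#' Predicted rank-abundance curve of the fractal model
#'
#' The one-parameter fractal model of the species abundance distribution
#' states that the relative abundance of the species of rank `r` is
#' `A_r / A_1 = r^-p`, with ranks assigned in non-increasing abundance
#' order. `predict_sad()` evaluates this curve for ranks `1..S`.
#'
#' `p = 1` is Zipf's law; `p = 0` is a perfectly even community; larger `p`
#' means steeper dominance. The exponent is the reciprocal of the fractal
#' dimension `d` of the species-accumulation interpretation (`p = 1/d`).
#'
#' @param p exponent of the power law (any real).
#' @param S species richness, integer `>= 1`.
#' @param A1 abundance of the dominant species (default 1, giving relative
#'   abundances).
#' @param sample_id,group labels for the returned sample.
#' @return A [rank_abundance] object with abundances `A1 * r^-p`, kept in
#'   model rank order: for `p < 0` the curve increases with `r` and is
#'   deliberately not re-sorted, so the generating exponent stays
#'   recoverable by [estimate_p()].
#' @examples
#' predict_sad(1, 6)$abundances          # 1, 1/2, ..., 1/6
#' @export
predict_sad <- function(p, S, A1 = 1, sample_id = "predicted", group = NULL) {
  if (!is.numeric(S) || length(S) != 1L || is.na(S) || S < 1 ||
      S != floor(S))
    stop("'S' must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(A1) || length(A1) != 1L || is.na(A1) || A1 <= 0)
    stop("'A1' must be a single positive number", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p))
    stop("'p' must be a single finite number", call. = FALSE)
  r <- seq_len(S)
  a <- A1 * r^(-p)
  # keep model rank order: for p < 0 the curve increases with r, and
  # re-sorting would silently replace the curve with its mirror image
  structure(
    list(sample_id = as.character(sample_id)[1L],
         group = if (is.null(group)) NA_character_ else as.character(group)[1L],
         abundances = a, S = as.integer(S), A_T = sum(a)),
    class = "rank_abundance"
  )
}

#' Closed-form estimator of the fractal exponent p
#'
#' Estimates the exponent of `A_r/A_1 = r^-p` from a ranked sample by
#' least squares on the log-transformed variables. With
#' `F_r = ln(A_r/A_1)` and `D_r = ln(r)`, minimizing
#' `sum_r (-p * D_r - F_r)^2` over `p` gives the closed form
#'
#' \deqn{\hat p = -\frac{\sum_r D_r F_r}{\sum_r D_r^2}.}
#'
#' The regression is through the origin on the log-log scale (the model
#' forces `A_1/A_1 = 1` at rank 1), so the `r = 1` term contributes nothing
#' and at least two ranks are required. The estimate is returned as
#' computed: it can be zero or negative for flat or inverted curves.
#'
#' @param sample a [rank_abundance] object, or a numeric abundance vector
#'   which is coerced with [as_rank_abundance()].
#' @param r2_variant how the goodness of fit is computed; see
#'   [r_squared_log()]. `"centered"` (default) measures the total sum of
#'   squares about the mean of `F_r`; `"uncentered"` about zero.
#' @return An object of class `fractal_fit`: a list with elements `p`,
#'   `r_squared`, `S`, `n_used` (ranks entering the sums, equal to `S`),
#'   `A_T`, `sample_id` and `group`.
#' @examples
#' estimate_p(c(60, 30, 20, 15, 12, 10))$p   # exactly 1
#' @seealso [r_squared_log()], [predict_sad()]
#' @export
estimate_p <- function(sample, r2_variant = c("centered", "uncentered")) {
  sample <- as_rank_abundance(sample)
  r2_variant <- match.arg(r2_variant)
  if (sample$S < 2L)
    stop("insufficient ranks: at least 2 species are required to estimate p",
         call. = FALSE)
  a <- sample$abundances
  if (any(a <= 0)) stop("invalid sample: non-positive abundance", call. = FALSE)
  Fr <- log(a / a[1L])
  Dr <- log(seq_along(a))
  p <- -sum(Dr * Fr) / sum(Dr^2)
  structure(
    list(p = p,
         r_squared = r_squared_log(sample, p, variant = r2_variant),
         S = sample$S,
         n_used = sample$S,
         A_T = sample$A_T,
         sample_id = sample$sample_id,
         group = sample$group),
    class = "fractal_fit"
  )
}

#' Goodness of fit of the fractal model on the log scale
#'
#' Computes `R^2 = 1 - SS_res / SS_tot` for the through-origin regression
#' of `F_r = ln(A_r/A_1)` on `D_r = ln(r)` at a given exponent `p`, with
#' `SS_res = sum_r (F_r + p * D_r)^2`.
#'
#' Two conventions for the total sum of squares are offered: `"centered"`
#' (`SS_tot` about the mean of `F_r`, the usual coefficient of
#' determination, bounded above by 1) and `"uncentered"` (`SS_tot` about
#' zero, natural for a through-origin model). A perfectly flat sample fit
#' with `p = 0` has `SS_tot = SS_res = 0` and is defined to return 1
#' (zero residuals are a perfect fit). Pathological fits can return
#' negative values.
#'
#' @param sample a [rank_abundance] object or numeric abundance vector.
#' @param p exponent at which the residuals are evaluated (finite).
#' @param variant `"centered"` (default) or `"uncentered"`.
#' @return A single numeric value `<= 1`.
#' @export
r_squared_log <- function(sample, p, variant = c("centered", "uncentered")) {
  sample <- as_rank_abundance(sample)
  variant <- match.arg(variant)
  if (sample$S < 2L)
    stop("insufficient ranks: at least 2 species are required", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p))
    stop("'p' must be a single finite number", call. = FALSE)
  a <- sample$abundances
  Fr <- log(a / a[1L])
  Dr <- log(seq_along(a))
  ss_res <- sum((Fr + p * Dr)^2)
  ss_tot <- if (variant == "centered") sum((Fr - mean(Fr))^2) else sum(Fr^2)
  if (ss_tot == 0) {
    if (ss_res == 0) return(1)
    return(-Inf)
  }
  1 - ss_res / ss_tot
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat("Fractal SAD fit for '", x$sample_id, "'", sep = "")
  if (!is.na(x$group)) cat(" [", x$group, "]", sep = "")
  cat(sprintf(":\n  p = %.6g   R^2(log) = %.4f   S = %d   A_T = %s\n",
              x$p, x$r_squared, x$S, format(x$A_T)))
  invisible(x)
}

#' @export
as.data.frame.fractal_fit <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(sample_id = x$sample_id, group = x$group, S = x$S,
             A_T = x$A_T, p = x$p, r_squared = x$r_squared,
             stringsAsFactors = FALSE, row.names = row.names)
}
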