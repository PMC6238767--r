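#' Fit the fractal model to every sample in a collection
#'
#' Applies [estimate_p()] to each sample, preserving input order. Samples
#' that cannot be fitted (richness below 2) are excluded, counted and
#' reported rather than silently dropped, so batch totals can be audited.
#'
#' @param samples a list of [rank_abundance] objects (or numeric vectors),
#'   e.g. from [read_abundance_table()].
#' @param r2_variant passed to [estimate_p()].
#' @return A list of `fractal_fit` objects (class `fractal_fit_list`) in
#'   input order, with attribute `exclusions`: a data frame of
#'   `sample_id` and `reason` for every excluded sample.
#' @export
fit_collection <- function(samples, r2_variant = c("centered",
                                                   "uncentered")) {
  r2_variant <- match.arg(r2_variant)
  if (length(samples) == 0L)
    stop("empty input: no samples to fit", call. = FALSE)
  samples <- lapply(samples, as_rank_abundance)
  fits <- list()
  excl_id <- character(0)
  excl_reason <- character(0)
  for (s in samples) {
    if (s$S < 2L) {
      excl_id <- c(excl_id, s$sample_id)
      excl_reason <- c(excl_reason, "richness below 2")
      next
    }
    fits[[length(fits) + 1L]] <- estimate_p(s, r2_variant = r2_variant)
  }
  structure(fits, class = "fractal_fit_list",
            exclusions = data.frame(sample_id = excl_id,
                                    reason = excl_reason,
                                    stringsAsFactors = FALSE))
}

#' @export
print.fractal_fit_list <- function(x, ...) {
  excl <- attr(x, "exclusions")
  cat("Collection of", length(x), "fractal SAD fits (",
      nrow(excl), "sample(s) excluded )\n")
  invisible(x)
}

#' Summary statistics of p or R-squared over a group of fits
#'
#' Produces one survey-table row: maximum, minimum, median, mean, standard
#' error of the mean (`sd/sqrt(n)`) and sample count for the chosen
#' statistic. The median of an even number of fits is the mean of the two
#' central order statistics; a single fit has standard error 0.
#'
#' @param fits a `fractal_fit_list`, a list of `fractal_fit` objects, or a
#'   bare numeric vector of values.
#' @param which `"p"` or `"r_squared"`.
#' @param group label for the output row; defaults to the fits' common
#'   group when they share one.
#' @return A one-row data frame with columns `group`, `statistic`,
#'   `maximum`, `minimum`, `median`, `mean`, `standard_error`,
#'   `n_samples`.
#' @export
summarize_group <- function(fits, which = c("p", "r_squared"),
                            group = NULL) {
  which <- match.arg(which)
  if (is.numeric(fits)) {
    x <- fits
  } else {
    if (length(fits) == 0L)
      stop("empty input: no fits to summarize", call. = FALSE)
    x <- vapply(fits, function(f) f[[which]], numeric(1))
    if (is.null(group)) {
      g <- unique(vapply(fits, function(f) f$group, character(1)))
      if (length(g) == 1L) group <- g
    }
  }
  if (length(x) == 0L)
    stop("empty input: no values to summarize", call. = FALSE)
  n <- length(x)
  se <- if (n == 1L) 0 else stats::sd(x) / sqrt(n)
  data.frame(group = if (is.null(group)) NA_character_ else group,
             statistic = which,
             maximum = max(x), minimum = min(x),
             median = stats::median(x), mean = mean(x),
             standard_error = se, n_samples = n,
             stringsAsFactors = FALSE)
}

#' Binned frequency distribution of fitted exponents
#'
#' Bins the fitted `p` values into right-open intervals
#' `[j*w, (j+1)*w)` anchored at 0 (default width `w = 1/3`, so the bins
#' are consecutive thirds: 0–0.33, 0.33–0.67, 0.67–1, 1–1.33, ...). Bins
#' run from 0 up to the smallest multiple of `w` exceeding the largest
#' value; negative values, which the estimator can produce for inverted
#' curves, are collected in an explicit underflow count.
#'
#' @param fits a `fractal_fit_list`, list of `fractal_fit` objects, or a
#'   numeric vector of p values.
#' @param bin_width positive bin width (default `1/3`).
#' @param group label attached to the histogram.
#' @return An object of class `p_histogram`: a list with `bin_edges`
#'   (ascending, starting at 0, length `nbins + 1`), `counts` (per bin),
#'   `underflow` (count of negative values) and `group`. The counts plus
#'   the underflow always sum to the number of fits.
#' @export
p_histogram <- function(fits, bin_width = 1 / 3, group = NULL) {
  if (is.numeric(fits)) {
    x <- fits
  } else {
    if (length(fits) == 0L)
      stop("empty input: no fits to bin", call. = FALSE)
    x <- vapply(fits, function(f) f$p, numeric(1))
    if (is.null(group)) {
      g <- unique(vapply(fits, function(f) f$group, character(1)))
      if (length(g) == 1L) group <- g
    }
  }
  if (length(x) == 0L)
    stop("empty input: no values to bin", call. = FALSE)
  if (!is.numeric(bin_width) || length(bin_width) != 1L ||
      !is.finite(bin_width) || bin_width <= 0)
    stop("'bin_width' must be a single positive number", call. = FALSE)
  underflow <- sum(x < 0)
  pos <- x[x >= 0]
  # smallest multiple of w strictly exceeding max(x); at least one bin
  n_bins <- if (length(pos) == 0L) 1L else floor(max(pos) / bin_width) + 1L
  edges <- bin_width * (0:n_bins)
  idx <- pmin(floor(pos / bin_width), n_bins - 1L) + 1L  # right-open bins
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts,
                 underflow = as.integer(underflow),
                 group = if (is.null(group)) NA_character_ else group),
            class = "p_histogram")
}

#' @export
print.p_histogram <- function(x, ...) {
  cat("Frequency distribution of fitted p")
  if (!is.na(x$group)) cat(" [", x$group, "]", sep = "")
  cat("\n")
  if (x$underflow > 0) cat("  (-Inf, 0):", x$underflow, "\n")
  for (i in seq_along(x$counts))
    cat(sprintf("  [%.3f, %.3f): %d\n", x$bin_edges[i], x$bin_edges[i + 1L],
                x$counts[i]))
  invisible(x)
}

#' @export
as.data.frame.p_histogram <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(bin_left = x$bin_edges[-length(x$bin_edges)],
             bin_right = x$bin_edges[-1L],
             count = x$counts,
             group = x$group,
             stringsAsFactors = FALSE, row.names = row.names)
}

#' Survey-style summary table across dataset groups
#'
#' Convenience wrapper for batch surveys: splits a collection of fits by
#' their `group` label, summarizes the chosen statistic within each group
#' and appends a `Total` row over all fits — the layout of a classic
#' multi-dataset exponent survey.
#'
#' @param fits a `fractal_fit_list` or list of `fractal_fit` objects.
#' @param which `"p"` or `"r_squared"`.
#' @return A data frame with one row per group plus a final `Total` row.
#' @export
survey_summary <- function(fits, which = c("p", "r_squared")) {
  which <- match.arg(which)
  if (length(fits) == 0L)
    stop("empty input: no fits to summarize", call. = FALSE)
  groups <- vapply(fits, function(f) f$group, character(1))
  groups[is.na(groups)] <- "(ungrouped)"
  rows <- lapply(split(seq_along(fits), groups), function(i)
    summarize_group(fits[i], which = which, group = groups[i[1L]]))
  out <- do.call(rbind, c(rows,
                          list(summarize_group(fits, which = which,
                                               group = "Total"))))
  rownames(out) <- NULL
  out
}
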