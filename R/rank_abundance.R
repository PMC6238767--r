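#' Construct a ranked community sample
#'
#' A `rank_abundance` object holds one community sample: its abundances
#' sorted in non-increasing order (the rank-abundance or dominance curve),
#' together with the species richness `S`, the total abundance `A_T`, a
#' sample identifier and an optional dataset (group) label.
#'
#' Zero abundances are dropped before ranking (only detected species carry
#' information about the curve); negative abundances are an error because
#' the model works on `log(A_r)`. Ties in abundance are broken stably: by
#' the `species` labels when supplied, otherwise by input position, so that
#' ranks `1..S` are always strict and reproducible.
#'
#' @param abundances numeric vector of non-negative abundances (counts,
#'   densities or biomass; any positive scale).
#' @param sample_id character label for the sample.
#' @param group optional character label for the source dataset.
#' @param species optional character vector of species labels, recycled
#'   against `abundances`; used only to order tied abundances.
#' @return An object of class `rank_abundance`: a list with elements
#'   `sample_id`, `group`, `abundances` (sorted non-increasing), `S`
#'   (richness) and `A_T` (total abundance).
#' @examples
#' ra <- rank_abundance(c(10, 60, 30, 20, 12, 15), sample_id = "plot-1")
#' ra$abundances
#' @export
rank_abundance <- function(abundances, sample_id = "sample", group = NULL,
                           species = NULL) {
  if (!is.numeric(abundances) || length(abundances) == 0L)
    stop("'abundances' must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(abundances))
    stop("'abundances' contains missing values", call. = FALSE)
  if (any(abundances < 0))
    stop("negative abundance encountered; abundances must be >= 0",
         call. = FALSE)
  if (!is.null(species)) {
    species <- rep_len(as.character(species), length(abundances))
  }
  keep <- abundances > 0
  abundances <- abundances[keep]
  if (length(abundances) == 0L)
    stop("sample '", sample_id, "' has no positive abundances", call. = FALSE)
  if (!is.null(species)) {
    species <- species[keep]
    ord <- order(-abundances, species, method = "radix")
  } else {
    ord <- order(-abundances, method = "radix")  # radix sort is stable
  }
  abundances <- abundances[ord]
  structure(
    list(sample_id = as.character(sample_id)[1L],
         group = if (is.null(group)) NA_character_ else as.character(group)[1L],
         abundances = as.numeric(abundances),
         S = length(abundances),
         A_T = sum(abundances)),
    class = "rank_abundance"
  )
}

#' Coerce to a ranked community sample
#'
#' @param x a `rank_abundance` object or a numeric abundance vector.
#' @param ... passed to [rank_abundance()] for numeric input.
#' @return A `rank_abundance` object.
#' @export
as_rank_abundance <- function(x, ...) {
  if (inherits(x, "rank_abundance")) return(x)
  if (is.numeric(x)) return(rank_abundance(x, ...))
  stop("cannot coerce object of class '", class(x)[1L],
       "' to rank_abundance", call. = FALSE)
}

#' Validate the internal invariants of a ranked sample
#'
#' Checks that abundances are strictly positive and non-increasing, that
#' `S` equals their length and `A_T` their sum. Mainly used in tests and
#' after deserialization.
#'
#' @param x a `rank_abundance` object.
#' @return `x`, invisibly; signals an error when an invariant is violated.
#' @export
validate_rank_abundance <- function(x) {
  stopifnot(inherits(x, "rank_abundance"))
  a <- x$abundances
  if (any(a <= 0)) stop("invariant violated: non-positive abundance")
  if (is.unsorted(rev(a))) stop("invariant violated: abundances increase")
  if (x$S != length(a)) stop("invariant violated: S != length(abundances)")
  if (abs(x$A_T - sum(a)) > 1e-9 * max(1, x$A_T))
    stop("invariant violated: A_T != sum(abundances)")
  invisible(x)
}

#' @export
print.rank_abundance <- function(x, ...) {
  cat("Rank-abundance sample '", x$sample_id, "'", sep = "")
  if (!is.na(x$group)) cat(" [", x$group, "]", sep = "")
  cat(": S =", x$S, ", A_T =", format(x$A_T), "\n")
  cat("  top ranks:",
      paste(format(utils::head(x$abundances, 6L), digits = 4), collapse = ", "),
      if (x$S > 6L) "...\n" else "\n")
  invisible(x)
}
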