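#' Describe the column layout of a long-format abundance table
#'
#' Community survey tables arrive as flat files with one row per
#' (sample, species) pair but varying column names and separators. A
#' dialect names the three required columns, the field delimiter and an
#' optional dataset label attached to every sample read under it.
#'
#' @param sample_col,species_col,abundance_col column names in the file
#'   header; must be three distinct names.
#' @param delimiter single-character field separator (default comma).
#' @param group_label optional dataset name stored in each sample's
#'   `group` field.
#' @return An object of class `abundance_dialect`.
#' @export
abundance_dialect <- function(sample_col = "sample_id",
                              species_col = "species_id",
                              abundance_col = "abundance",
                              delimiter = ",", group_label = NULL) {
  cols <- c(sample_col, species_col, abundance_col)
  if (!is.character(cols) || length(cols) != 3L || anyNA(cols) ||
      anyDuplicated(cols))
    stop("the three column names must be distinct non-missing strings",
         call. = FALSE)
  if (!is.character(delimiter) || length(delimiter) != 1L ||
      nchar(delimiter) != 1L)
    stop("'delimiter' must be a single character", call. = FALSE)
  structure(list(sample_col = sample_col, species_col = species_col,
                 abundance_col = abundance_col, delimiter = delimiter,
                 group_label = group_label),
            class = "abundance_dialect")
}

#' Read a long-format abundance table into ranked samples
#'
#' Reads a delimited text file of (sample, species, abundance) records,
#' groups rows by sample identifier, sums duplicate (sample, species)
#' rows (surveys often split records by subplot or period), drops
#' zero-abundance rows, and ranks each sample's abundances non-increasing
#' with ties broken stably by species label. Samples left with no positive
#' abundance are omitted and counted rather than erroring.
#'
#' Abundances are accepted as non-negative reals (densities and biomass,
#' not just counts). A negative abundance or an unparseable numeric is an
#' error reporting the offending data row.
#'
#' @param path file to read (UTF-8, header row mandatory).
#' @param dialect an [abundance_dialect] describing the layout.
#' @return A list of [rank_abundance] objects (class
#'   `rank_abundance_list`), named by sample identifier and ordered by
#'   first appearance in the file, with attributes `n_omitted` (samples
#'   dropped for having no positive abundance) and `omitted_ids`.
#' @export
read_abundance_table <- function(path, dialect = abundance_dialect()) {
  stopifnot(inherits(dialect, "abundance_dialect"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$delimiter,
                           quote = "\"", colClasses = "character",
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c(dialect$sample_col, dialect$species_col, dialect$abundance_col)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L)
    stop("dialect mismatch: column(s) ",
         paste(sQuote(missing_cols), collapse = ", "),
         " not found in header of ", path, call. = FALSE)
  sample_id <- raw[[dialect$sample_col]]
  species <- raw[[dialect$species_col]]
  ab_chr <- raw[[dialect$abundance_col]]
  ab <- suppressWarnings(as.numeric(ab_chr))
  bad <- which(is.na(ab) & !is.na(ab_chr))
  if (length(bad) > 0L)
    stop("invalid record: unparseable abundance '", ab_chr[bad[1L]],
         "' at data row ", bad[1L], " of ", path, call. = FALSE)
  neg <- which(ab < 0)
  if (length(neg) > 0L)
    stop("invalid record: negative abundance at data row ", neg[1L],
         " of ", path, call. = FALSE)

  ids <- unique(sample_id)
  out <- vector("list", length(ids))
  omitted <- character(0)
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    sel <- sample_id == ids[i]
    # sum duplicate species rows, keeping first-appearance species order
    agg <- rowsum(ab[sel], group = species[sel], reorder = FALSE)
    a <- as.numeric(agg)
    sp <- rownames(agg)
    if (!any(a > 0)) {
      omitted <- c(omitted, ids[i])
      next
    }
    out[[i]] <- rank_abundance(a, sample_id = ids[i],
                               group = dialect$group_label, species = sp)
    keep[i] <- TRUE
  }
  out <- out[keep]
  names(out) <- ids[keep]
  structure(out, class = "rank_abundance_list",
            n_omitted = length(omitted), omitted_ids = omitted)
}

#' Write ranked samples back to a long-format abundance table
#'
#' Inverse of [read_abundance_table()]: one row per (sample, rank), with
#' species identifiers `sp1, sp2, ...` assigned by rank when the original
#' labels are not retained. Values are written with full double precision
#' so a read–write–read cycle preserves the abundances.
#'
#' @param samples a list of [rank_abundance] objects.
#' @param path destination file.
#' @param dialect an [abundance_dialect] naming the output columns.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(samples, path,
                                  dialect = abundance_dialect()) {
  stopifnot(inherits(dialect, "abundance_dialect"))
  samples <- lapply(samples, as_rank_abundance)
  rows <- lapply(samples, function(s)
    data.frame(sample = s$sample_id,
               species = sprintf("sp%d", seq_len(s$S)),
               abundance = format(s$abundances, digits = 17, trim = TRUE,
                                  scientific = FALSE),
               stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(sample = character(0),
                                    species = character(0),
                                    abundance = character(0))
  names(df) <- c(dialect$sample_col, dialect$species_col,
                 dialect$abundance_col)
  ok <- tryCatch({
    utils::write.table(df, path, sep = dialect$delimiter, row.names = FALSE,
                       quote = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Write a table of fractal fits to CSV
#'
#' Writes one row per fit with columns `sample_id, group, S, A_T, p,
#' r_squared`, at full double precision so values round-trip through
#' [read_fit_table()] without loss at 12 significant digits. An empty
#' collection yields a header-only file.
#'
#' @param fits a list of `fractal_fit` objects (e.g. from
#'   [fit_collection()]) or a data frame with the six columns above.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fits, path) {
  df <- if (is.data.frame(fits)) fits else fits_as_data_frame(fits)
  need <- c("sample_id", "group", "S", "A_T", "p", "r_squared")
  if (!all(need %in% names(df)))
    stop("fit table must contain columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df <- df[need]
  ok <- tryCatch({
    # write.csv renders doubles at 15 significant digits, which
    # round-trips through read_fit_table at 12 digits
    utils::write.csv(df, path, row.names = FALSE, quote = c(1L, 2L),
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a table of fractal fits written by [write_fit_table()]
#'
#' @param path CSV file to read.
#' @return A data frame with columns `sample_id, group, S, A_T, p,
#'   r_squared`.
#' @export
read_fit_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sample_id = "character",
                                 group = "character", S = "integer",
                                 A_T = "numeric", p = "numeric",
                                 r_squared = "numeric"))
}

#' Flatten a collection of fits into a data frame
#'
#' @param fits a list of `fractal_fit` objects.
#' @return A data frame with one row per fit.
#' @export
fits_as_data_frame <- function(fits) {
  if (inherits(fits, "fractal_fit")) fits <- list(fits)
  if (length(fits) == 0L)
    return(data.frame(sample_id = character(0), group = character(0),
                      S = integer(0), A_T = numeric(0), p = numeric(0),
                      r_squared = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(fits, as.data.frame))
}
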