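write_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("a single-sample file is read and ranked", {
  path <- write_lines(c("sample_id,species_id,abundance",
                        sprintf("s1,sp%d,%d", 1:6, c(10, 12, 15, 20, 30, 60))))
  res <- read_abundance_table(path)
  expect_length(res, 1L)
  expect_equal(res[["s1"]]$abundances, c(60, 30, 20, 15, 12, 10))
  expect_identical(attr(res, "n_omitted"), 0L)
})

test_that("interleaved samples, duplicates and zeros are handled", {
  path <- write_lines(c("sample_id,species_id,abundance",
                        "a,x,3", "b,x,7", "a,y,5", "b,y,1",
                        "a,x,2",      # duplicate (a, x): summed to 5
                        "b,z,0"))     # zero row: dropped
  res <- read_abundance_table(path)
  expect_identical(names(res), c("a", "b"))
  expect_equal(res[["a"]]$abundances, c(5, 5))  # tie, stable by label x < y
  expect_equal(res[["b"]]$abundances, c(7, 1))
  expect_identical(res[["b"]]$S, 2L)
})

test_that("samples with no positive abundance are omitted and counted", {
  path <- write_lines(c("sample_id,species_id,abundance",
                        "a,x,4", "empty,x,0", "empty,y,0"))
  res <- read_abundance_table(path)
  expect_length(res, 1L)
  expect_identical(attr(res, "n_omitted"), 1L)
  expect_identical(attr(res, "omitted_ids"), "empty")
})

test_that("dialect mismatches and invalid records are clear errors", {
  path <- write_lines(c("plot,taxon,count", "p1,t1,3"))
  expect_error(read_abundance_table(path), "dialect mismatch")
  d <- abundance_dialect(sample_col = "plot", species_col = "taxon",
                         abundance_col = "count")
  expect_no_error(read_abundance_table(path, d))
  bad_num <- write_lines(c("plot,taxon,count", "p1,t1,3", "p1,t2,lots"))
  expect_error(read_abundance_table(bad_num, d), "row 2")
  neg <- write_lines(c("plot,taxon,count", "p1,t1,-2"))
  expect_error(read_abundance_table(neg, d), "negative abundance.*row 1")
  expect_error(abundance_dialect(sample_col = "x", species_col = "x"),
               "distinct")
  expect_error(read_abundance_table(tempfile()), "not found")
})

test_that("reading is invariant to row order", {
  lines <- sprintf("s%d,sp%d,%d", rep(1:3, each = 4), rep(1:4, 3),
                   sample(1:100, 12))
  p1 <- write_lines(c("sample_id,species_id,abundance", lines))
  set.seed(1)
  p2 <- write_lines(c("sample_id,species_id,abundance", sample(lines)))
  r1 <- read_abundance_table(p1)
  r2 <- read_abundance_table(p2)
  for (id in names(r1))
    expect_equal(r1[[id]]$abundances, r2[[id]]$abundances)
})

test_that("abundance tables round-trip through write and read", {
  set.seed(8)
  samples <- lapply(1:5, function(i)
    random_sad(sample(2:30, 1), runif(1, 0.5, 2), sample_id = paste0("s", i)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_abundance_table(samples, path)
  back <- read_abundance_table(path)
  expect_length(back, 5L)
  for (i in 1:5)
    expect_equal(back[[samples[[i]]$sample_id]]$abundances,
                 samples[[i]]$abundances, tolerance = 1e-12)
})

test_that("fit tables round-trip, including the empty table", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fit_table(list(), path)
  empty <- read_fit_table(path)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty),
                   c("sample_id", "group", "S", "A_T", "p", "r_squared"))

  fit <- estimate_p(rank_abundance(c(60, 30, 20, 15, 12, 10),
                                   sample_id = "zipf", group = "demo"))
  write_fit_table(list(fit), path)
  back <- read_fit_table(path)
  expect_identical(nrow(back), 1L)
  expect_identical(back$sample_id, "zipf")
  expect_equal(back$p, 1)
  expect_equal(back$r_squared, 1)

  set.seed(21)
  fits <- fit_collection(lapply(1:1000, function(i)
    predict_sad(runif(1, 0.2, 3), sample(2:20, 1),
                sample_id = paste0("sim", i))))
  write_fit_table(fits, path)
  back <- read_fit_table(path)
  expect_identical(nrow(back), 1000L)
  expect_equal(back$p, vapply(fits, `[[`, numeric(1), "p"),
               tolerance = 1e-12)
})
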