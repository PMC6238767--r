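test_that("batch fitting recovers exact exponents and logs exclusions", {
  samples <- list(predict_sad(0.5, 20, sample_id = "a"),
                  predict_sad(1, 20, sample_id = "b"),
                  predict_sad(2, 20, sample_id = "c"))
  fits <- fit_collection(samples)
  expect_length(fits, 3L)
  expect_equal(vapply(fits, `[[`, numeric(1), "p"), c(0.5, 1, 2),
               tolerance = 1e-12)
  expect_true(all(vapply(fits, `[[`, numeric(1), "r_squared") == 1))
  expect_identical(nrow(attr(fits, "exclusions")), 0L)

  with_singleton <- c(samples, list(rank_abundance(5, sample_id = "lone")))
  fits2 <- fit_collection(with_singleton)
  expect_length(fits2, 3L)
  excl <- attr(fits2, "exclusions")
  expect_identical(excl$sample_id, "lone")
  expect_match(excl$reason, "richness")
  expect_error(fit_collection(list()), "empty input")
})

test_that("group summaries match hand arithmetic and base statistics", {
  s <- summarize_group(c(1, 2, 3), which = "p")
  expect_equal(s$median, 2)
  expect_equal(s$mean, 2)
  expect_equal(s$standard_error, 1 / sqrt(3), tolerance = 1e-15)
  expect_identical(s$n_samples, 3L)

  one <- summarize_group(c(1.7), which = "p")
  expect_equal(one$maximum, one$minimum)
  expect_equal(one$median, one$mean)
  expect_identical(one$standard_error, 0)

  # even n: median is the mean of the two central order statistics
  expect_equal(summarize_group(c(4, 1, 3, 2))$median, 2.5)

  # cross-check against independently coded statistics on 10,000 values
  set.seed(101)
  x <- rlnorm(10000, 0, 0.4)
  s <- summarize_group(x)
  xs <- sort(x)
  expect_equal(s$median, (xs[5000] + xs[5001]) / 2, tolerance = 1e-10)
  expect_equal(s$mean, sum(x) / 10000, tolerance = 1e-10)
  expect_equal(s$standard_error,
               sqrt(sum((x - sum(x) / 10000)^2) / 9999) / 100,
               tolerance = 1e-10)
  expect_equal(s$maximum, xs[10000])
  expect_equal(s$minimum, xs[1])
})

test_that("summaries are permutation-invariant", {
  set.seed(31)
  x <- runif(500, 0, 3)
  expect_equal(summarize_group(x), summarize_group(sample(x)))
})

test_that("histograms bin p into right-open thirds anchored at zero", {
  h <- p_histogram(c(0.9, 0.95, 1.1))
  expect_equal(h$bin_edges, (0:4) / 3, tolerance = 1e-15)
  expect_identical(h$counts, c(0L, 0L, 2L, 1L))
  expect_identical(h$underflow, 0L)

  # all values in one bin
  h1 <- p_histogram(rep(0.5, 7))
  expect_identical(sum(h1$counts > 0), 1L)
  expect_identical(max(h1$counts), 7L)

  # right-open: a value on an edge belongs to the bin on its right
  h2 <- p_histogram(c(1 / 3), bin_width = 1 / 3)
  expect_identical(h2$counts, c(0L, 1L))

  # negative estimates land in the underflow bin and are still counted
  h3 <- p_histogram(c(-0.2, 0.1, 0.2))
  expect_identical(h3$underflow, 1L)
  expect_identical(sum(h3$counts) + h3$underflow, 3L)
  expect_error(p_histogram(numeric(0)), "empty input")
  expect_error(p_histogram(c(1), bin_width = 0), "bin_width")
})

test_that("histogram counts always sum to n and match binomial scatter", {
  set.seed(77)
  x <- runif(10000, 0, 2)
  h <- p_histogram(x)
  expect_identical(sum(h$counts) + h$underflow, 10000L)
  # uniform on [0, 2]: each full third-bin expects n*w/2 counts
  n_full <- floor(2 / (1 / 3))
  expected <- 10000 * (1 / 3) / 2
  sigma <- sqrt(10000 * (1 / 6) * (5 / 6))
  expect_true(all(abs(h$counts[seq_len(n_full)] - expected) < 4 * sigma))
})

test_that("survey summary stacks per-group rows plus a total", {
  samples <- c(lapply(1:4, function(i)
                 predict_sad(1, 10, sample_id = paste0("g1-", i),
                             group = "g1")),
               lapply(1:3, function(i)
                 predict_sad(2, 10, sample_id = paste0("g2-", i),
                             group = "g2")))
  fits <- fit_collection(samples)
  tab <- survey_summary(fits, which = "p")
  expect_identical(tab$group, c("g1", "g2", "Total"))
  expect_equal(tab$mean, c(1, 2, 10 / 7), tolerance = 1e-12)
  expect_identical(tab$n_samples, c(4L, 3L, 7L))
  r2 <- survey_summary(fits, which = "r_squared")
  expect_true(all(r2$mean == 1))
})

test_that("synthetic end-to-end survey centres on the true exponent", {
  # multinomial Zipf communities: the batch mean of p-hat stays near 1
  # and the modal histogram bin contains 1
  fits <- fit_collection(lapply(1:60, function(s)
    generate_multinomial(synthetic_spec("multinomial_power_law",
                                        p_true = 1, S = 100, N = 1e5,
                                        seed = 1000 + s))))
  summ <- summarize_group(fits, which = "p")
  expect_lt(abs(summ$mean - 1), 0.05)
  h <- p_histogram(fits)
  modal <- which.max(h$counts)
  expect_true(h$bin_edges[modal] <= 1 && 1 <= h$bin_edges[modal + 1L])
})
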