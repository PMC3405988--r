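test_that("null-class m follows the Poisson zero-class closed form", {
  d <- burst_dataset(counts = c(rep(0, 37), rep(1, 63)), N = 10, B_mean = 50)
  expect_equal(null_class_m(d), log(100 / 37), tolerance = 1e-12)
  all_zero <- burst_dataset(counts = rep(0, 20), N = 10, B_mean = 50)
  expect_equal(null_class_m(all_zero), 0)
  no_zero <- burst_dataset(counts = rep(2, 20), N = 10, B_mean = 50)
  expect_error(null_class_m(no_zero), "frequency")
})

test_that("null-class and frequency rates divide by the replication events", {
  d <- burst_dataset(counts = c(0, 0, 1, 3), N = 10, B_mean = 100, B_sd = 20)
  m <- log(4 / 2)
  expect_equal(null_class_rate(d)$value, m / (10 * 100))
  expect_equal(null_class_rate(d)$sd, m / (10 * 100) * 20 / 100)
  f <- 4 / (10 * 100 * 4)
  expect_equal(frequency_rate(d)$value, f)
  expect_equal(frequency_rate(d, "both")$value, f / 2)
  zero <- burst_dataset(counts = rep(0, 5), N = 10, B_mean = 100)
  expect_equal(frequency_rate(zero)$value, 0)
})

test_that("Poisson expectations reproduce the p0 construction", {
  d <- rt_in_data()
  tab <- poisson_expectation(d)
  # zero class matches the observed count exactly, by construction
  expect_equal(tab$expected[1], 31, tolerance = 1e-12)
  # conservation: expected plaques approximately C * m
  expect_equal(sum(tab$revertants * tab$expected), d$C * null_class_m(d),
               tolerance = 0.01)
})

test_that("burst histograms and per-culture tables load equivalently", {
  d <- rt_in_data()
  expect_identical(d$C, 239L)
  expect_identical(sum(d$counts), 510L)
  expect_identical(sum(d$counts == 0), 31L)
  tmp <- tempfile(fileext = ".tsv")
  write.table(data.frame(culture = seq_along(d$counts),
                         revertants = d$counts),
              tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  d2 <- read_burst_table(tmp, N = 4560, B_mean = 328, B_sd = 93)
  expect_identical(sort(d2$counts), sort(d$counts))
  expect_identical(d2$C, d$C)
  single <- burst_dataset(counts = 0L, N = 1, B_mean = 10)
  expect_identical(single$C, 1L)
  expect_equal(mean(single$counts == 0), 1)
})

test_that("large bursts can be excluded as preexisting before analysis", {
  d <- burst_dataset(counts = c(0, 1, 2, 1254, 585), N = 100, B_mean = 300,
                     exclude_ge = 100)
  expect_identical(d$C, 3L)
  expect_identical(sort(d$excluded$count), c(585L, 1254L))
  scaled <- burst_dataset(counts = c(2, 0), N = 10, B_mean = 100,
                          plating_efficiency = 1.5)
  expect_identical(sort(scaled$counts), c(0L, 3L))
})

test_that("burst_fit couples rate, expectations, and goodness of fit", {
  fit <- burst_fit(rt_in_data())
  expect_s3_class(fit, "burst_fit")
  expect_equal(coef(fit)[["m"]], log(239 / 31), tolerance = 1e-12)
  expect_equal(coef(fit)[["mu"]], log(239 / 31) / (4560 * 328),
               tolerance = 1e-12)
  # expected column of the GOF table sums exactly to C (tail folded in)
  expect_equal(sum(fit$gof$class_table$expected), fit$data$C,
               tolerance = 1e-9)
  sims <- simulate(fit, nsim = 3, seed = 42)
  expect_length(sims, 3)
  expect_length(sims[[1]], fit$data$C)
  # a Poisson sample at the fitted mean passes the fit's own GOF
  d_sim <- burst_dataset(counts = sims[[1]], N = 4560, B_mean = 328)
  expect_gt(burst_fit(d_sim)$gof$p.value, 1e-4)
})

test_that("log-log cumulative slope separates clone-size distributions", {
  # geometric-like clone sizes: cumulative tail 2^-(k-1), slope about
  # -log2 steepness on log10 axes; exact values checked via closed form
  counts <- rep(1:4, times = c(64, 32, 16, 16))
  res <- loglog_cumulative_slope(counts)
  expect_identical(res$points$class, 1:4)
  expect_equal(res$points$cumfreq, c(128, 64, 32, 16) / 128)
  fit <- lm(log10(c(1, 0.5, 0.25, 0.125)) ~ log10(1:4))
  expect_equal(res$slope, unname(coef(fit)[2]), tolerance = 1e-10)
  # class cap drops saturating classes
  res2 <- loglog_cumulative_slope(c(counts, 100), exclude_ge = 16)
  expect_identical(max(res2$points$class), 15L)
  expect_error(loglog_cumulative_slope(rep(1, 10)), "classes")
  expect_error(loglog_cumulative_slope(rep(0, 10)), "mutants")
})
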