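test_that("degenerate mutation rates give deterministic burst contents", {
  none <- replication_model("linear", N = 20, C = 10, B = 100,
                            mu1 = 0, mu2 = 0)
  expect_true(all(simulate_bursts(none, seed = 1)$counts == 0))
  all_mut <- replication_model("linear", N = 5, C = 4, B = 100,
                               mu1 = 0, mu2 = 1)
  expect_true(all(simulate_bursts(all_mut, seed = 1)$counts == 5 * 100))
  none_exp <- replication_model("exponential", N = 10, C = 5, B = 64,
                                mu2 = 0)
  expect_true(all(simulate_bursts(none_exp, seed = 1)$counts == 0))
})

test_that("identical seeds reproduce identical simulations", {
  mod <- replication_model("linear", N = 50, C = 40, B = 200, B_sd = 60,
                           mu2 = 1e-4, f_pre = 1e-4)
  a <- simulate_bursts(mod, seed = 99)
  b <- simulate_bursts(mod, seed = 99)
  expect_identical(a$counts, b$counts)
  mod_e <- replication_model("exponential", N = 5, C = 40, B = 256,
                             mu2 = 1e-3)
  expect_identical(simulate_bursts(mod_e, seed = 3)$counts,
                   simulate_bursts(mod_e, seed = 3)$counts)
})

test_that("linear mode with mu1 = 0 yields the Poisson null fraction", {
  # closed form: counts ~ Binomial(N B, mu2), null fraction ~ exp(-N B mu2)
  mod <- replication_model("linear", N = 35, C = 498, B = 859, mu2 = 2.46e-5)
  set.seed(202)
  p0s <- replicate(60, mean(simulate_bursts(mod)$counts == 0))
  expected <- exp(-35 * 859 * 2.46e-5)
  mc_sd <- sd(p0s) / sqrt(length(p0s))
  expect_lt(abs(mean(p0s) - expected), 3 * mc_sd + 1e-4)
})

test_that("mixed mode with zero recruitment reduces to the linear mean", {
  mod <- replication_model("mixed", N = 35, C = 400, B = 859,
                           mu2 = 2.46e-5, mixed_fraction = 0)
  d <- simulate_bursts(mod, seed = 5)
  lambda <- 35 * 859 * 2.46e-5
  se <- sqrt(lambda / 400)
  expect_lt(abs(mean(d$counts) - lambda), 4 * se)
  # index of dispersion near 1 for a Poisson-like process
  expect_lt(var(d$counts) / mean(d$counts), 1.6)
})

test_that("first-round errors in linear mode produce clones", {
  # mu2 = 0: mutants only arise as whole-template clones
  mod <- replication_model("linear", N = 1, C = 400, B = 100, c1 = 10,
                           mu1 = 0.05, mu2 = 0)
  d <- simulate_bursts(mod, seed = 13)
  positive <- d$counts[d$counts > 0]
  expect_gt(length(positive), 0)
  # a single mutant template yields about B/c1 = 10 mutant progeny
  expect_gt(median(positive), 3)
})

test_that("burst-size laws respect their moments and truncation", {
  mod <- replication_model("linear", N = 1, C = 2000, B = 50, B_sd = 40,
                           burst_law = "gamma", mu2 = 1)
  d <- simulate_bursts(mod, seed = 21)
  # with mu2 = 1 every progeny is mutant, so counts are the burst sizes
  expect_gte(min(d$counts), 1)
  expect_equal(mean(d$counts), 50, tolerance = 0.06)
  expect_equal(sd(d$counts), 40, tolerance = 0.12)
})

test_that("exponential mode is over-dispersed and heavy-tailed; linear is not", {
  exp_mod <- replication_model("exponential", N = 1, C = 1000, B = 512,
                               mu2 = 1e-3)
  d_exp <- simulate_bursts(exp_mod, seed = 7)
  expect_gt(var(d_exp$counts) / mean(d_exp$counts), 1.5)
  lin_mod <- replication_model("linear", N = 1, C = 1000, B = 512,
                               mu2 = 1e-3)
  d_lin <- simulate_bursts(lin_mod, seed = 7)
  expect_lt(var(d_lin$counts) / mean(d_lin$counts), 1.5)

  sl <- loglog_cumulative_slope(d_exp$counts, exclude_ge = 16)
  expect_gt(sl$slope, -1.3)
  expect_lt(sl$slope, -0.8)
})

test_that("preexisting mutants contribute whole bursts at the expected rate", {
  mod <- replication_model("linear", N = 100, C = 200, B = 300,
                           mu2 = 0, f_pre = 5e-4)
  d <- simulate_bursts(mod, seed = 17)
  # each preexisting cell contributes a full burst of 300
  expect_true(all(d$counts %% 300 == 0))
  n_bursts <- sum(d$counts) / 300
  lambda <- expected_preexisting_bursts(5e-4, 100, 200)
  expect_lt(abs(n_bursts - lambda), 4 * sqrt(lambda))
})

test_that("simulated spectrum tables honour class weights and wild-type bases", {
  tgt <- rt_fixture_target()
  only_uc <- simulate_spectrum_table(tgt, c("U>C" = 1), n_isolates = 50,
                                     seed = 31)
  expect_identical(nrow(only_uc), 50L)
  expect_true(all(only_uc$wt == "U" & only_uc$mut == "C"))
  expect_true(all(unclass(tgt)[only_uc$position] == "U"))
  empty <- simulate_spectrum_table(tgt, c("U>C" = 1), n_isolates = 0)
  expect_identical(nrow(empty), 0L)
  expect_error(simulate_spectrum_table(mutation_target("GGG"),
                                       c("U>C" = 1), 5),
               "eligible")

  # multinomial sampling reproduces the weight proportions
  w <- c("U>C" = 16, "G>A" = 10, "A>G" = 8, "C>U" = 5)
  tab <- simulate_spectrum_table(tgt, w, n_isolates = 2000, seed = 37)
  ss <- spectrum_summary(tab, tgt)
  counts <- setNames(ss$classes$count, ss$classes$class)
  p <- w / sum(w)
  for (cl in names(w)) {
    se <- sqrt(2000 * p[cl] * (1 - p[cl]))
    expect_lt(abs(counts[cl] - 2000 * p[cl]), 3 * se + 1e-9)
  }
  # secondary marking at the requested rate
  tab2 <- simulate_spectrum_table(tgt, w, n_isolates = 500,
                                  secondary_rate = 0.5, seed = 41)
  n_sec <- sum(tab2$rank == "secondary")
  expect_lt(abs(n_sec - 250), 4 * sqrt(250))
})

test_that("null-class estimation recovers the simulated second-round rate", {
  # stamping-machine simulations at the two reversion-test scales
  set.seed(911)
  mod_sub <- replication_model("linear", N = 35, C = 498, B = 859,
                               mu2 = 2.46e-5)
  mu_sub <- replicate(100, null_class_rate(simulate_bursts(mod_sub))$value)
  expect_lt(abs(mean(mu_sub) / 2.46e-5 - 1), 0.10)

  mod_in <- replication_model("linear", N = 4560, C = 239, B = 328,
                              mu2 = 1.4e-6)
  mu_in <- replicate(40, null_class_rate(simulate_bursts(mod_in))$value)
  expect_lt(abs(mean(mu_in) / 1.4e-6 - 1), 0.10)

  # null-class and frequency estimates agree under pure second-round
  # replication (both estimate mu2)
  d <- simulate_bursts(mod_sub, seed = 53)
  expect_lt(abs(null_class_rate(d)$value / frequency_rate(d)$value - 1),
            0.15)
})
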