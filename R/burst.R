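#' Construct a single-burst dataset
#'
#' Holds per-culture revertant (mutant) counts from a single-burst
#' fluctuation experiment together with the metadata needed for rate
#' estimation: infected cells per culture N and the mean and SD of the
#' burst size B.
#'
#' @param counts Non-negative integer revertant counts, one per plated
#'   culture. Alternatively supply `histogram`.
#' @param histogram Optional two-column data frame (`revertants`,
#'   `cultures`) giving the class histogram instead of raw counts.
#' @param N Infected cells per culture.
#' @param B_mean,B_sd Mean and standard deviation of the burst size.
#' @param exclude_ge Optional cutoff: cultures with `counts >= exclude_ge`
#'   are attributed to preexisting mutants in the inoculum and removed
#'   before analysis (recorded in `$excluded`). Use
#'   `B_mean / 3` as a rule of thumb for bursts too large to be single
#'   second-round clones.
#' @param plating_efficiency Optional multiplier applied to raw counts
#'   (e.g. 1.5 when the scoring host plates the phage less efficiently);
#'   default 1 (off). Applied before exclusion; results are rounded to
#'   integers.
#' @return Object of class `burst_dataset` with elements `counts`, `N`,
#'   `B_mean`, `B_sd`, `C`, and `excluded`.
#' @export
burst_dataset <- function(counts = NULL, histogram = NULL, N, B_mean,
                          B_sd = NA_real_, exclude_ge = NULL,
                          plating_efficiency = 1) {
  if (is.null(counts) && is.null(histogram))
    stop("supply counts or histogram")
  if (!is.null(histogram)) {
    if (!all(c("revertants", "cultures") %in% names(histogram)))
      stop("histogram needs columns 'revertants' and 'cultures'")
    counts <- rep(as.integer(histogram$revertants),
                  times = as.integer(histogram$cultures))
  }
  counts <- as.integer(counts)
  if (length(counts) == 0) stop("no cultures")
  if (any(counts < 0)) stop("negative revertant counts")
  if (N <= 0 || B_mean <= 0) stop("N and B_mean must be positive")
  if (plating_efficiency != 1)
    counts <- as.integer(round(counts * plating_efficiency))
  excluded <- data.frame(count = integer(0), reason = character(0))
  if (!is.null(exclude_ge)) {
    drop <- counts >= exclude_ge
    if (any(drop)) {
      excluded <- data.frame(
        count = counts[drop],
        reason = sprintf("count >= %g attributed to preexisting mutants",
                         exclude_ge))
      counts <- counts[!drop]
      if (length(counts) == 0) stop("all cultures excluded")
    }
  }
  structure(list(counts = counts, N = N, B_mean = B_mean, B_sd = B_sd,
                 C = length(counts), excluded = excluded),
            class = "burst_dataset")
}

#' @export
print.burst_dataset <- function(x, ...) {
  cat(sprintf("<burst_dataset> %d cultures, N = %g, B = %g%s\n",
              x$C, x$N, x$B_mean,
              ifelse(is.na(x$B_sd), "", sprintf(" +/- %g", x$B_sd))))
  cat(sprintf("  null fraction p0 = %d/%d = %.4f; total revertants = %d\n",
              sum(x$counts == 0), x$C, mean(x$counts == 0), sum(x$counts)))
  if (nrow(x$excluded) > 0)
    cat(sprintf("  %d culture(s) excluded: counts %s\n", nrow(x$excluded),
                paste(x$excluded$count, collapse = ", ")))
  invisible(x)
}

#' Null-class (p0) estimate of the mean mutational events per culture
#'
#' If mutational events per culture are Poisson distributed, the
#' fraction of cultures with zero mutants is `exp(-m)`, whence
#' `m = ln(C / C0)` with `C0` zero-mutant cultures among `C`.
#'
#' @param data A [burst_dataset()].
#' @return The null-class mean m.
#' @export
null_class_m <- function(data) {
  stopifnot(inherits(data, "burst_dataset"))
  c0 <- sum(data$counts == 0)
  if (c0 == 0)
    stop("null class is empty: m is undefined; use frequency_rate()")
  log(data$C / c0)
}

# first-order (delta method) SD from the burst-size SD
propagate_b_sd <- function(value, B_mean, B_sd) {
  if (is.na(B_sd)) NA_real_ else value * B_sd / B_mean
}

#' Null-class (p0) mutation-rate estimate
#'
#' Under stamping-machine replication nearly all mutants arise in the
#' second replication round, so the total number of mutational
#' opportunities per culture is approximately N * B and
#' `mu = m / (N * B)`. The SD is propagated from the burst-size SD by
#' the first-order delta method.
#'
#' @param data A [burst_dataset()].
#' @return A [rate_estimate()] (per reversion target per replication).
#' @export
null_class_rate <- function(data) {
  m <- null_class_m(data)
  mu <- m / (data$N * data$B_mean)
  rate_estimate(mu, sd = propagate_b_sd(mu, data$B_mean, data$B_sd),
                method = "null_class",
                components = list(m = m, C = data$C,
                                  C0 = sum(data$counts == 0),
                                  N = data$N, B = data$B_mean))
}

#' Frequency-method mutation-rate estimate
#'
#' Uses the overall mutant frequency `f = sum(counts) / (N * B * C)`.
#' When all detected mutations are attributed to the second replication
#' round (`rounds_attribution = "second_only"`, the stamping-machine
#' default) `mu = f`; when errors from both rounds contribute equally,
#' `mu = f / 2`.
#'
#' @param data A [burst_dataset()].
#' @param rounds_attribution `"second_only"` or `"both"`.
#' @return A [rate_estimate()].
#' @export
frequency_rate <- function(data,
                           rounds_attribution = c("second_only", "both")) {
  stopifnot(inherits(data, "burst_dataset"))
  rounds_attribution <- match.arg(rounds_attribution)
  f <- sum(data$counts) / (data$N * data$B_mean * data$C)
  mu <- if (rounds_attribution == "second_only") f else f / 2
  rate_estimate(mu, sd = propagate_b_sd(mu, data$B_mean, data$B_sd),
                method = paste0("frequency:", rounds_attribution),
                components = list(total = sum(data$counts), C = data$C,
                                  N = data$N, B = data$B_mean, f = f))
}

#' Poisson class expectations under the p0 construction
#'
#' Expected numbers of cultures per revertant class,
#' `E_k = C * exp(-m) * m^k / k!`, with m from [null_class_m()]; by
#' construction `E_0` equals the observed zero class exactly.
#'
#' @param data A [burst_dataset()].
#' @param max_class Largest class to tabulate; defaults to the largest
#'   observed count.
#' @return Data frame with `revertants`, `observed`, `expected`.
#' @export
poisson_expectation <- function(data, max_class = NULL) {
  m <- null_class_m(data)
  if (is.null(max_class)) max_class <- max(data$counts)
  k <- 0:max_class
  expected <- data$C * dpois(k, m)
  observed <- vapply(k, function(kk) sum(data$counts == kk), integer(1))
  data.frame(revertants = k, observed = observed, expected = expected)
}

#' Poisson goodness of fit for a burst dataset
#'
#' Builds the full class table (0 up to the largest observed count,
#' with the Poisson tail beyond it folded into the top class so that
#' the expected column sums exactly to C) and applies [g_test_gof()]
#' with one estimated parameter.
#'
#' The Poisson mean can be taken from the null class (`m_method =
#' "p0"`, `m = ln(C/C0)`, the classical fluctuation-test construction,
#' under which the zero class matches by construction) or from the
#' maximum-likelihood mean of the counts (`m_method = "ml"`). The p0
#' moment estimator is not efficient, so its G statistic is
#' stochastically somewhat larger than the reference chi-square and the
#' test is mildly anticonservative; the ML variant is calibrated.
#'
#' @param data A [burst_dataset()].
#' @param m_method `"p0"` or `"ml"`.
#' @param pool_expected_min Pooling threshold, see [g_test_gof()].
#' @return A `g_test` object (with the class table before pooling in
#'   `$class_table` and the mean used in `$m`).
#' @export
poisson_gof <- function(data, m_method = c("p0", "ml"),
                        pool_expected_min = 1) {
  stopifnot(inherits(data, "burst_dataset"))
  m_method <- match.arg(m_method)
  m <- if (m_method == "p0") null_class_m(data) else mean(data$counts)
  kmax <- max(data$counts)
  k <- 0:kmax
  observed <- vapply(k, function(kk) sum(data$counts == kk), integer(1))
  expected <- data$C * dpois(k, m)
  expected[length(expected)] <- expected[length(expected)] +
    data$C * stats::ppois(kmax, m, lower.tail = FALSE)
  res <- g_test_gof(observed, expected, n_estimated_params = 1,
                    pool_expected_min = pool_expected_min)
  res$class_table <- data.frame(revertants = k, observed = observed,
                                expected = expected)
  res$m <- m
  res$m_method <- m_method
  res
}

#' Fit the single-burst fluctuation model
#'
#' The central fitting function of the package: given a
#' [burst_dataset()], estimates the mean number of mutational events per
#' culture by the null-class method, converts it to a mutation rate per
#' replication, computes the Poisson class expectations and their
#' goodness of fit (G-test with tail pooling; one df subtracted for the
#' estimated m), and the frequency-method rate for comparison. A close
#' Poisson fit supports the stamping-machine (linear) replication mode;
#' systematic excess of large classes signals first-round (clonal)
#' contributions or an exponential component.
#'
#' @param data A [burst_dataset()].
#' @param pool_expected_min Pooling threshold for the goodness-of-fit
#'   test, see [g_test_gof()].
#' @return Object of class `burst_fit` with components `m`, `mu`
#'   (null-class [rate_estimate()]), `mu_freq` (frequency-method
#'   [rate_estimate()]), `expected` (class table), `gof` ([g_test_gof()]
#'   result), and `data`.
#' @examples
#' d <- burst_dataset(histogram = data.frame(revertants = 0:3,
#'                                           cultures = c(40, 35, 18, 7)),
#'                    N = 100, B_mean = 300)
#' fit <- burst_fit(d)
#' coef(fit)
#' @export
burst_fit <- function(data, pool_expected_min = 1) {
  stopifnot(inherits(data, "burst_dataset"))
  m <- null_class_m(data)
  tab <- poisson_expectation(data)
  gof <- poisson_gof(data, m_method = "p0",
                     pool_expected_min = pool_expected_min)
  structure(list(m = m,
                 mu = null_class_rate(data),
                 mu_freq = frequency_rate(data),
                 expected = tab,
                 gof = gof,
                 data = data),
            class = "burst_fit")
}

#' @export
print.burst_fit <- function(x, ...) {
  cat("Single-burst fluctuation fit (null-class / p0 method)\n")
  cat(sprintf("  cultures C = %d, null class C0 = %d, m = %.4g events/culture\n",
              x$data$C, sum(x$data$counts == 0), x$m))
  cat(sprintf("  mu (null-class)  = %.4g%s per target per replication\n",
              x$mu$value,
              ifelse(is.na(x$mu$sd), "", sprintf(" +/- %.2g", x$mu$sd))))
  cat(sprintf("  mu (frequency)   = %.4g%s\n", x$mu_freq$value,
              ifelse(is.na(x$mu_freq$sd), "",
                     sprintf(" +/- %.2g", x$mu_freq$sd))))
  cat(sprintf("  Poisson GOF: G = %.3g, df = %s, P = %.3g\n",
              x$gof$statistic, ifelse(is.na(x$gof$df), "NA", x$gof$df),
              x$gof$p.value))
  invisible(x)
}

#' @export
summary.burst_fit <- function(object, ...) {
  print(object)
  cat("\nClass table (observed vs Poisson expected):\n")
  print(object$expected, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.burst_fit <- function(object, ...) {
  c(m = object$m, mu = object$mu$value, mu_freq = object$mu_freq$value)
}

#' @export
plot.burst_fit <- function(x, ...) {
  tab <- x$expected
  bp <- graphics::barplot(tab$observed, names.arg = tab$revertants,
                          xlab = "revertants per culture",
                          ylab = "cultures", border = NA, ...)
  graphics::points(bp, tab$expected, pch = 19)
  graphics::lines(bp, tab$expected)
  graphics::legend("topright", legend = c("observed", "Poisson expected"),
                   pch = c(15, 19), bty = "n")
  invisible(x)
}

#' @export
simulate.burst_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, rpois(object$data$C, object$m), simplify = FALSE)
}

#' Log-log cumulative clone-size slope (replication-mode diagnostic)
#'
#' Plots (numerically) the logarithm of the cumulative relative
#' frequency of bursts containing at least k mutants against log k. An
#' exponentially replicating population yields the heavy-tailed
#' Luria-Delbruck clone-size distribution, whose cumulative tail falls
#' off as about 1/k (slope near -1); stamping-machine replication
#' concentrates mutants in clones of size 1, giving a much steeper
#' (more negative) slope.
#'
#' @param counts Mutants per burst (one entry per culture).
#' @param exclude_ge Optional cap: classes with `k >= exclude_ge` are
#'   dropped before fitting (classes approaching the burst size carry
#'   saturation artefacts).
#' @return List with `slope`, `stderr`, and the fitted `points` (class
#'   size, cumulative relative frequency).
#' @export
loglog_cumulative_slope <- function(counts, exclude_ge = NULL) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("negative counts")
  kmax <- max(counts)
  if (kmax < 1) stop("no bursts contain mutants")
  k <- seq_len(kmax)
  if (!is.null(exclude_ge)) k <- k[k < exclude_ge]
  n_pos <- sum(counts >= 1)
  cumfreq <- vapply(k, function(kk) sum(counts >= kk) / n_pos, numeric(1))
  keep <- cumfreq > 0
  k <- k[keep]
  cumfreq <- cumfreq[keep]
  if (length(k) < 2)
    stop("fewer than two distinct classes: slope undefined")
  fit <- lm(log10(cumfreq) ~ log10(k))
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[2, 1]), stderr = unname(sm[2, 2]),
       points = data.frame(class = k, cumfreq = cumfreq))
}
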