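#' Log-likelihood-ratio (G) statistic
#'
#' Computes `G = 2 * sum(O * log(O / E))` over matched observed and
#' expected vectors. Classes with zero observed count contribute 0 (the
#' limit of `O log O` as `O -> 0`), the convention of Sokal & Rohlf style
#' goodness-of-fit tests.
#'
#' @param observed Non-negative observed counts.
#' @param expected Positive expected counts, same length.
#' @return The G statistic (non-negative when `sum(O) == sum(E)`).
#' @examples
#' g_statistic(c(60, 40), c(50, 50))
#' @export
g_statistic <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  if (any(expected <= 0)) stop("expected counts must be positive")
  if (any(observed < 0)) stop("observed counts must be non-negative")
  keep <- observed > 0
  2 * sum(observed[keep] * log(observed[keep] / expected[keep]))
}

#' G-test for goodness of fit, with tail pooling
#'
#' Tests observed class counts against expected counts. Classes whose
#' expected count falls below `pool_expected_min` are pooled into the
#' preceding retained class (a right-tail pooling appropriate for count
#' histograms); degrees of freedom are the number of retained classes
#' minus one, minus the number of parameters estimated from the data.
#'
#' @param observed Observed counts per class (e.g. cultures per
#'   revertant-count class, in increasing class order).
#' @param expected Expected counts per class, same length.
#' @param n_estimated_params Number of distribution parameters estimated
#'   from the same data (1 when the Poisson mean came from the data).
#' @param pool_expected_min Minimum expected count for a class to stand
#'   alone; smaller classes are pooled into the tail. Use 0 to disable
#'   pooling.
#' @return An object of class `g_test` (also `htest`-like list) with
#'   `statistic`, `df`, `p.value`, and the pooled class table.
#' @export
g_test_gof <- function(observed, expected, n_estimated_params = 0,
                       pool_expected_min = 1) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  if (sum(observed) == 0) stop("all-zero observed counts")
  obs <- as.numeric(observed)
  exp <- as.numeric(expected)
  if (pool_expected_min > 0) {
    # pool from the right tail: merge trailing classes until E >= min
    while (length(exp) > 1 && exp[length(exp)] < pool_expected_min) {
      n <- length(exp)
      exp[n - 1] <- exp[n - 1] + exp[n]
      obs[n - 1] <- obs[n - 1] + obs[n]
      exp <- exp[-n]
      obs <- obs[-n]
    }
  }
  if (any(exp <= 0)) stop("expected counts must be positive after pooling")
  g <- g_statistic(obs, exp)
  df <- length(obs) - 1L - as.integer(n_estimated_params)
  if (df < 1L) df <- NA_integer_
  p <- if (is.na(df)) NA_real_ else pchisq(g, df, lower.tail = FALSE)
  structure(list(statistic = g, df = df, p.value = p,
                 table = data.frame(observed = obs, expected = exp),
                 pooling = sprintf("tail classes pooled at E < %g",
                                   pool_expected_min)),
            class = "g_test")
}

#' G-test of independence for a contingency table
#'
#' @param x A matrix of counts (r x k contingency table).
#' @return A `g_test` object with `statistic`, `df = (r-1)(k-1)`, and
#'   `p.value`.
#' @examples
#' g_test_independence(rbind(c(10, 0), c(0, 10)))
#' @export
g_test_independence <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("counts must be non-negative")
  rs <- rowSums(x)
  cs <- colSums(x)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal in contingency table")
  n <- sum(x)
  expected <- outer(rs, cs) / n
  g <- g_statistic(as.vector(x), as.vector(expected))
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  p <- pchisq(g, df, lower.tail = FALSE)
  structure(list(statistic = g, df = df, p.value = p,
                 table = x, pooling = "none"),
            class = "g_test")
}

#' Replicated G-test for goodness of fit
#'
#' Partitions a set of replicated binomial-type goodness-of-fit tests
#' into a pooled component (G_P, do the pooled counts fit the
#' expectation?), a heterogeneity component (G_H, do the replicates agree
#' with one another?), and their total (G_T = G_P + G_H), after Sokal &
#' Rohlf. Each replicate is a row of counts over the same classes, tested
#' against shared expected proportions.
#'
#' @param counts Matrix of observed counts, one row per replicate, one
#'   column per class.
#' @param p_expected Expected class proportions (length `ncol(counts)`,
#'   summing to 1).
#' @return List of three `g_test` components: `pooled` (1 df per class
#'   minus one), `heterogeneity`, and `total`, plus the inputs.
#' @export
replicated_g_test <- function(counts, p_expected) {
  counts <- as.matrix(counts)
  if (ncol(counts) != length(p_expected))
    stop("p_expected must have one entry per class column")
  if (abs(sum(p_expected) - 1) > 1e-8)
    stop("p_expected must sum to 1")
  r <- nrow(counts)
  k <- ncol(counts)
  g_rep <- vapply(seq_len(r), function(i) {
    n <- sum(counts[i, ])
    g_statistic(counts[i, ], n * p_expected)
  }, numeric(1))
  g_total <- sum(g_rep)
  pooled <- colSums(counts)
  g_pooled <- g_statistic(pooled, sum(pooled) * p_expected)
  g_het <- g_total - g_pooled
  df_p <- k - 1L
  df_t <- r * (k - 1L)
  df_h <- df_t - df_p
  mk <- function(g, df) structure(
    list(statistic = g, df = df,
         p.value = pchisq(g, df, lower.tail = FALSE),
         table = NULL, pooling = "none"),
    class = "g_test")
  list(pooled = mk(g_pooled, df_p),
       heterogeneity = mk(g_het, df_h),
       total = mk(g_total, df_t),
       per_replicate = g_rep,
       counts = counts, p_expected = p_expected)
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("G-test: G = %.4g, df = %s, P = %.4g\n",
              x$statistic, ifelse(is.na(x$df), "NA", x$df), x$p.value))
  if (!is.null(x$pooling) && !identical(x$pooling, "none"))
    cat(" ", x$pooling, "\n")
  invisible(x)
}
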