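#' Parameterise plaque growth for mutant-loss calculations
#'
#' During plaque growth a newly arisen mutant lineage competes with its
#' wild-type siblings over a small number of infection cycles; a mutant
#' with selection coefficient `s` has effective offspring mean
#' `R * (1 - s)` per cycle and may be lost by drift even when viable.
#' This is the classical Galton-Watson extinction setting.
#'
#' @param s Selection coefficient per infection cycle, in \[0, 1\].
#' @param R Wild-type effective offspring number per cycle (successful
#'   reinfections per infected cell).
#' @param cycles Number of infection cycles per plaque (about 3 for a
#'   Q-beta plaque).
#' @param offspring_law `"poisson"` or `"geometric"` offspring
#'   distribution (geometric on 0, 1, 2, ... with the same mean).
#' @return Object of class `plaque_growth_model`.
#' @export
plaque_growth_model <- function(s, R, cycles = 3,
                                offspring_law = c("poisson", "geometric")) {
  offspring_law <- match.arg(offspring_law)
  if (s < 0 || s > 1) stop("s must lie in [0, 1]")
  if (R <= 0) stop("R must be positive")
  if (cycles < 1) stop("cycles must be at least 1")
  structure(list(s = s, R = R, cycles = as.integer(cycles),
                 offspring_law = offspring_law),
            class = "plaque_growth_model")
}

offspring_pgf <- function(model) {
  mu <- model$R * (1 - model$s)
  switch(model$offspring_law,
         poisson = function(x) exp(mu * (x - 1)),
         geometric = function(x) 1 / (1 + mu * (1 - x)))
}

#' Probability a mutant lineage is lost during plaque growth
#'
#' Iterates the offspring probability generating function `f` of the
#' mutant (mean `R * (1 - s)`) for `cycles` cycles starting from a
#' single mutant-infected cell: `q_g = f(q_{g-1})`, `q_0 = 0`. The
#' result is non-decreasing in both `s` and `cycles` and converges to
#' the classical extinction probability (smallest root of `f(x) = x`)
#' as `cycles` grows.
#'
#' @param model A [plaque_growth_model()].
#' @return Extinction probability by the end of plaque growth.
#' @examples
#' loss_probability(plaque_growth_model(s = 0, R = 2, cycles = 3))
#' @export
loss_probability <- function(model) {
  stopifnot(inherits(model, "plaque_growth_model"))
  f <- offspring_pgf(model)
  q <- 0
  for (i in seq_len(model$cycles)) q <- f(q)
  q
}

#' Ultimate extinction probability of the mutant lineage
#'
#' Smallest root of `f(x) = x` for the mutant offspring PGF, by direct
#' fixed-point iteration from 0 (monotone convergent).
#'
#' @param model A [plaque_growth_model()].
#' @param tol Convergence tolerance.
#' @param max_iter Iteration cap.
#' @return Extinction probability in \[0, 1\].
#' @export
extinction_probability <- function(model, tol = 1e-12, max_iter = 10000) {
  f <- offspring_pgf(model)
  q <- 0
  for (i in seq_len(max_iter)) {
    q_new <- f(q)
    if (abs(q_new - q) < tol) return(q_new)
    q <- q_new
  }
  q
}

#' Monte-Carlo branching simulation of mutant loss
#'
#' Direct stochastic counterpart of [loss_probability()]: simulates
#' `n_lineages` independent mutant lineages for `cycles` cycles and
#' returns the observed extinct fraction with its binomial standard
#' error.
#'
#' @param model A [plaque_growth_model()].
#' @param n_lineages Number of simulated lineages.
#' @param seed Optional RNG seed.
#' @return List with `loss` (extinct fraction), `se` (binomial SE), and
#'   `n`.
#' @export
simulate_plaque_loss <- function(model, n_lineages = 10000, seed = NULL) {
  stopifnot(inherits(model, "plaque_growth_model"))
  if (!is.null(seed)) set.seed(seed)
  mu <- model$R * (1 - model$s)
  size <- rep(1, n_lineages)
  for (i in seq_len(model$cycles)) {
    alive <- size > 0
    n_alive <- sum(alive)
    if (n_alive == 0) break
    size[alive] <- switch(model$offspring_law,
      poisson = rpois(n_alive, size[alive] * mu),
      # sum of k iid geometrics = negative binomial with size k
      geometric = stats::rnbinom(n_alive, size = size[alive],
                                 mu = size[alive] * mu))
  }
  p <- mean(size == 0)
  list(loss = p, se = sqrt(p * (1 - p) / n_lineages), n = n_lineages)
}

#' Loss-probability curve over selection coefficients
#'
#' @param s_grid Selection coefficients to evaluate.
#' @param R,cycles,offspring_law Passed to [plaque_growth_model()].
#' @return Data frame with `s` and `loss`.
#' @export
loss_curve <- function(s_grid, R, cycles = 3,
                       offspring_law = c("poisson", "geometric")) {
  offspring_law <- match.arg(offspring_law)
  loss <- vapply(s_grid, function(s)
    loss_probability(plaque_growth_model(s, R, cycles, offspring_law)),
    numeric(1))
  data.frame(s = s_grid, loss = loss)
}
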