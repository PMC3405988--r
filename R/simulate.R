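#' Parameterise an intracellular replication model
#'
#' Describes how a (+)-strand RNA phage replicates inside an infected
#' cell, for the purpose of simulating single-burst experiments.
#'
#' Under the linear (stamping-machine) mode the infecting (+) strand is
#' copied into `c1` (-)-strand templates (each copy mutating with
#' probability `mu1`), and the burst of `B` (+)-strand progeny is drawn
#' from those templates: progeny of a mutant template are all mutant,
#' progeny of a wild-type template mutate independently with probability
#' `mu2`. Every progeny genome thus experiences exactly two
#' replications. Under the exponential mode the population doubles from
#' one genome until it reaches the burst size, every replication event
#' mutating with probability `mu2`; mutants breed true. The mixed mode
#' is linear except that each newly synthesised (+) strand is recruited
#' as an additional template with probability `mixed_fraction`
#' (`mixed_fraction = 0` reduces exactly to linear).
#'
#' @param mode `"linear"`, `"exponential"`, or `"mixed"`.
#' @param N Infected cells per culture.
#' @param C Number of cultures.
#' @param B Target (mean) burst size, (+) progeny per cell.
#' @param B_sd Burst-size standard deviation (0 for a fixed burst).
#' @param burst_law Distribution of the per-cell burst size: `"fixed"`,
#'   `"gamma"` (discretised, truncated at 1), or `"truncated_normal"`.
#'   With `B_sd = 0` all laws collapse to `"fixed"`.
#' @param c1 Number of (-)-strand templates per cell (linear/mixed). The
#'   default `round(B / 10)` reflects the roughly 10:1 accumulation of
#'   (+) over (-) strands reported for Q-beta.
#' @param mu1 Per-copy mutation probability in the first, (+) to (-),
#'   round.
#' @param mu2 Per-copy mutation probability in the second, (-) to (+),
#'   round (the only rate used in exponential mode).
#' @param mixed_fraction Probability that a new (+) strand becomes an
#'   additional template (mixed mode only).
#' @param f_pre Frequency of preexisting mutants among infecting phage;
#'   a preexisting-mutant cell contributes its whole burst as mutants.
#' @param template_weights Optional relative copying weights over the
#'   `c1` templates (linear mode), replacing the default uniform
#'   multinomial allocation of progeny to templates.
#' @return Object of class `replication_model`.
#' @export
replication_model <- function(mode = c("linear", "exponential", "mixed"),
                              N, C, B, B_sd = 0,
                              burst_law = c("gamma", "fixed",
                                            "truncated_normal"),
                              c1 = max(1, round(B / 10)),
                              mu1 = 0, mu2 = 1e-6,
                              mixed_fraction = 0, f_pre = 0,
                              template_weights = NULL) {
  mode <- match.arg(mode)
  burst_law <- match.arg(burst_law)
  if (N < 1 || C < 1) stop("N and C must be at least 1")
  if (B < 1) stop("burst size must be at least 1")
  if (c1 < 1) stop("c1 must be at least 1")
  if (B < c1) stop("burst size must be at least c1")
  probs <- c(mu1 = mu1, mu2 = mu2, mixed_fraction = mixed_fraction,
             f_pre = f_pre)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (!is.null(template_weights)) {
    if (length(template_weights) != c1 || any(template_weights <= 0))
      stop("template_weights must be c1 positive values")
    template_weights <- template_weights / sum(template_weights)
  }
  structure(list(mode = mode, N = as.integer(N), C = as.integer(C),
                 B = B, B_sd = B_sd, burst_law = burst_law,
                 c1 = as.integer(c1), mu1 = mu1, mu2 = mu2,
                 mixed_fraction = mixed_fraction, f_pre = f_pre,
                 template_weights = template_weights),
            class = "replication_model")
}

#' @export
print.replication_model <- function(x, ...) {
  cat(sprintf("<replication_model> %s: N = %d cells x C = %d cultures\n",
              x$mode, x$N, x$C))
  cat(sprintf("  burst %g +/- %g (%s), c1 = %d, mu1 = %g, mu2 = %g, f_pre = %g",
              x$B, x$B_sd, x$burst_law, x$c1, x$mu1, x$mu2, x$f_pre))
  if (x$mode == "mixed") cat(sprintf(", eps = %g", x$mixed_fraction))
  cat("\n")
  invisible(x)
}

draw_burst_sizes <- function(n, model) {
  if (model$B_sd <= 0 || model$burst_law == "fixed")
    return(rep(as.integer(round(model$B)), n))
  b <- switch(model$burst_law,
    gamma = {
      shape <- (model$B / model$B_sd)^2
      rgamma(n, shape = shape, rate = shape / model$B)
    },
    truncated_normal = stats::rnorm(n, model$B, model$B_sd))
  pmax(1L, as.integer(round(b)))
}

sim_cells_linear <- function(n_cells, model) {
  b <- draw_burst_sizes(n_cells, model)
  k <- rbinom(n_cells, model$c1, model$mu1)  # mutant (-) templates
  if (is.null(model$template_weights)) {
    w <- k / model$c1
  } else {
    # total copying weight of the k mutant templates, a random subset
    w <- numeric(n_cells)
    hit <- which(k > 0)
    for (i in hit)
      w[i] <- sum(sample(model$template_weights, k[i]))
  }
  from_mut_templates <- rbinom(n_cells, b, w)
  second_round <- rbinom(n_cells, b - from_mut_templates, model$mu2)
  mut <- from_mut_templates + second_round
  if (model$f_pre > 0) {
    pre <- runif(n_cells) < model$f_pre
    mut[pre] <- b[pre]  # preexisting-mutant cell: whole burst mutant
  }
  mut
}

sim_cells_exponential <- function(n_cells, model) {
  b <- draw_burst_sizes(n_cells, model)
  g <- ceiling(log2(pmax(b, 2)))
  wt <- rep(1, n_cells)
  mut <- rep(0, n_cells)
  for (gen in seq_len(max(g))) {
    act <- gen <= g
    err <- numeric(n_cells)
    err[act] <- rbinom(sum(act), wt[act], model$mu2)
    wt[act] <- 2 * wt[act] - err[act]
    mut[act] <- 2 * mut[act] + err[act]
  }
  # burst = b genomes sampled without replacement from the 2^g pool
  out <- rhyper(n_cells, m = mut, n = wt, k = pmin(b, mut + wt))
  if (model$f_pre > 0) {
    pre <- runif(n_cells) < model$f_pre
    out[pre] <- b[pre]
  }
  out
}

sim_cells_mixed <- function(n_cells, model) {
  b <- draw_burst_sizes(n_cells, model)
  k <- rbinom(n_cells, model$c1, model$mu1)
  t_mut <- k
  t_wt <- model$c1 - k
  p_mut <- numeric(n_cells)
  p_wt <- numeric(n_cells)
  remaining <- b
  while (any(remaining > 0)) {
    act <- which(remaining > 0)
    produce <- pmin(t_mut[act] + t_wt[act], remaining[act])
    from_mut <- rhyper(length(act), m = t_mut[act], n = t_wt[act],
                       k = produce)
    err <- rbinom(length(act), produce - from_mut, model$mu2)
    new_mut <- from_mut + err
    new_wt <- produce - new_mut
    p_mut[act] <- p_mut[act] + new_mut
    p_wt[act] <- p_wt[act] + new_wt
    remaining[act] <- remaining[act] - produce
    if (model$mixed_fraction > 0) {
      t_mut[act] <- t_mut[act] + rbinom(length(act), new_mut,
                                        model$mixed_fraction)
      t_wt[act] <- t_wt[act] + rbinom(length(act), new_wt,
                                      model$mixed_fraction)
    }
  }
  out <- p_mut
  if (model$f_pre > 0) {
    pre <- runif(n_cells) < model$f_pre
    out[pre] <- b[pre]
  }
  out
}

#' Simulate a single-burst experiment
#'
#' Draws per-culture revertant counts under a [replication_model()]:
#' each of the `C` cultures contains `N` infected cells whose mutant
#' progeny are summed. Returns a [burst_dataset()] ready for
#' [burst_fit()], so that simulated and real experiments flow through
#' the identical analysis path.
#'
#' @param model A [replication_model()].
#' @param seed Optional RNG seed for reproducibility.
#' @return A [burst_dataset()] whose `B_mean`/`B_sd` carry the model's
#'   burst-size law.
#' @examples
#' mod <- replication_model("linear", N = 50, C = 30, B = 100,
#'                          mu2 = 1e-4)
#' d <- simulate_bursts(mod, seed = 1)
#' @export
simulate_bursts <- function(model, seed = NULL) {
  stopifnot(inherits(model, "replication_model"))
  if (!is.null(seed)) set.seed(seed)
  n_cells <- model$N * model$C
  cell_counts <- switch(model$mode,
                        linear = sim_cells_linear(n_cells, model),
                        exponential = sim_cells_exponential(n_cells, model),
                        mixed = sim_cells_mixed(n_cells, model))
  culture <- rep(seq_len(model$C), each = model$N)
  counts <- as.integer(rowsum(cell_counts, culture))
  burst_dataset(counts = counts, N = model$N, B_mean = model$B,
                B_sd = if (model$B_sd > 0) model$B_sd else NA_real_)
}

#' Simulate a mutation-record table from a spectrum
#'
#' Generates a synthetic mutation table with the structure assumed by
#' [spectrum_summary()]: per isolate one primary mutation drawn from the
#' supplied class weights at a position whose wild-type base matches,
#' plus a Poisson number of secondary mutations per isolate.
#'
#' @param target A [mutation_target()].
#' @param class_weights Named non-negative weights over the 12
#'   substitution classes (names like `"U>C"`) and optionally `"indel"`.
#' @param n_isolates Number of isolates (primary mutations).
#' @param secondary_rate Mean secondary mutations per isolate (Poisson).
#' @param seed Optional RNG seed.
#' @return A validated mutation record data frame (see
#'   [validate_mutation_records()]).
#' @export
simulate_spectrum_table <- function(target, class_weights, n_isolates,
                                    secondary_rate = 0, seed = NULL) {
  stopifnot(inherits(target, "mutation_target"))
  if (!is.null(seed)) set.seed(seed)
  if (any(class_weights < 0)) stop("weights must be non-negative")
  class_weights <- class_weights[class_weights > 0]
  if (length(class_weights) == 0) stop("no positive class weight")
  positions_by_base <- lapply(setNames(RNA_BASES, RNA_BASES),
                              function(b) which(unclass(target) == b))
  for (cl in names(class_weights)) {
    wt <- substr(cl, 1, 1)
    if (cl != "indel" && length(positions_by_base[[wt]]) == 0)
      stop("class ", cl, " has no eligible position in target")
  }
  draw_one <- function(isolate, rank) {
    cl <- sample(names(class_weights), 1, prob = class_weights)
    if (cl == "indel") {
      pos <- sample(length(target), 1)
      data.frame(isolate = isolate, position = pos, kind = "insertion",
                 wt = NA_character_, mut = NA_character_,
                 indel_seq = unclass(target)[pos], rank = rank)
    } else {
      wt <- substr(cl, 1, 1)
      mut <- substr(cl, 3, 3)
      cand <- positions_by_base[[wt]]
      pos <- if (length(cand) == 1) cand else sample(cand, 1)
      data.frame(isolate = isolate, position = pos, kind = "substitution",
                 wt = wt, mut = mut, indel_seq = NA_character_,
                 rank = rank)
    }
  }
  rows <- list()
  for (i in seq_len(n_isolates)) {
    id <- sprintf("sim%04d", i)
    rows[[length(rows) + 1L]] <- draw_one(id, "primary")
    n_sec <- rpois(1, secondary_rate)
    for (j in seq_len(n_sec))
      rows[[length(rows) + 1L]] <- draw_one(id, "secondary")
  }
  if (length(rows) == 0) {
    out <- data.frame(isolate = character(0), position = integer(0),
                      kind = character(0), wt = character(0),
                      mut = character(0), indel_seq = character(0),
                      rank = character(0))
  } else {
    out <- do.call(rbind, rows)
  }
  validate_mutation_records(out, target)
}
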