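#' Construct a rate estimate object
#'
#' A `rate_estimate` couples a mutation-rate value with the components
#' (mutation frequency f, infection cycles c, replications per cycle n,
#' target size T, genome size G, and where applicable the null-class mean
#' m) from which it can be recomputed exactly.
#'
#' @param value Rate per base (or per target) per replication.
#' @param sd Optional standard deviation propagated from the burst-size
#'   SD.
#' @param method Method tag, e.g. `"nonsense_path"`, `"null_class"`.
#' @param components Named list of the defining quantities.
#' @return Object of class `rate_estimate`.
#' @export
rate_estimate <- function(value, sd = NA_real_, method = "unspecified",
                          components = list()) {
  if (value < 0) stop("rate must be non-negative")
  structure(list(value = value, sd = sd, method = method,
                 components = components),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate: %s> %.4g%s\n", x$method, x$value,
              ifelse(is.na(x$sd), "", sprintf(" +/- %.2g", x$sd))))
  if (length(x$components) > 0) {
    keys <- names(x$components)
    vals <- vapply(x$components, function(v) format(v, digits = 4),
                   character(1))
    cat("  components:", paste(keys, vals, sep = " = ", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
coef.rate_estimate <- function(object, ...) {
  c(value = object$value, sd = object$sd)
}

#' Mutation rate by the nonsense-path (forward mutation) method
#'
#' Sizes the detectable base-substitution target by the number of
#' single-base paths to a stop codon (see [nonsense_paths()]): with
#' `n_nonsense` nonsense mutants among `isolates_screened` screened
#' isolates, the per-path frequency is
#' `f_path = n_nonsense / (isolates_screened * paths)`, the per-base
#' substitution frequency is `f_SUB = 3 * f_path` (each base mutates
#' along three paths), and the per-replication rate is
#' `mu_SUB = f_SUB / (c * n)` with `c` infection cycles of `n`
#' replications each. Indels, which are essentially all detectable, use
#' the full target: `f_I = n_indel / (isolates_screened * target_nt)` and
#' `mu_I = f_I / (c * n)`. The genomic rate is
#' `mu_g = (mu_SUB + mu_I) * G`.
#'
#' @param n_nonsense Number of nonsense mutations observed (a stop
#'   converted to a different, tighter stop at a leaky read-through codon
#'   counts here, matching its detectable phenotype).
#' @param n_indel Number of indel mutations observed.
#' @param isolates_screened Number of isolates screened.
#' @param paths Number of single-base paths to a stop codon in the
#'   target.
#' @param target_nt Target length in nucleotides.
#' @param c_cycles Infection cycles between infection and scoring.
#' @param n_replications Genome replications per infection cycle (2 for
#'   stamping-machine replication).
#' @param genome_nt Genome size G in nucleotides.
#' @return List of `rate_estimate` objects: `f_path`, `f_sub`, `mu_sub`,
#'   `f_indel`, `mu_indel`, and `mu_genomic`.
#' @examples
#' est <- rate_nonsense(3, 2, 7517, paths = 66, target_nt = 591,
#'                      c_cycles = 1, n_replications = 2, genome_nt = 4217)
#' est$mu_genomic
#' @export
rate_nonsense <- function(n_nonsense, n_indel, isolates_screened, paths,
                          target_nt, c_cycles = 1, n_replications = 2,
                          genome_nt) {
  if (isolates_screened <= 0 || paths <= 0 || target_nt <= 0)
    stop("screening denominators must be positive")
  if (c_cycles < 1 || n_replications < 1)
    stop("c_cycles and n_replications must be at least 1")
  if (n_nonsense < 0 || n_indel < 0) stop("counts must be non-negative")
  cn <- c_cycles * n_replications
  f_path <- n_nonsense / (isolates_screened * paths)
  f_sub <- 3 * f_path
  mu_sub <- f_sub / cn
  f_indel <- n_indel / (isolates_screened * target_nt)
  mu_indel <- f_indel / cn
  mu_genomic <- (mu_sub + mu_indel) * genome_nt
  comp <- list(n_nonsense = n_nonsense, n_indel = n_indel,
               isolates_screened = isolates_screened, paths = paths,
               target_nt = target_nt, c = c_cycles, n = n_replications,
               G = genome_nt)
  mk <- function(v, tag) rate_estimate(v, method = tag, components = comp)
  list(f_path = mk(f_path, "nonsense_path:f_path"),
       f_sub = mk(f_sub, "nonsense_path:f_sub"),
       mu_sub = mk(mu_sub, "nonsense_path:mu_sub"),
       f_indel = mk(f_indel, "nonsense_path:f_indel"),
       mu_indel = mk(mu_indel, "nonsense_path:mu_indel"),
       mu_genomic = mk(mu_genomic, "nonsense_path:mu_genomic"))
}

#' Mutation rate by the hitchhiker (secondary mutation) method
#'
#' Secondary mutations recovered from sub-isolates of driver mutants are
#' phenotype-blind, so the whole reporter is the target:
#' `f_SUB = n_secondary / (n_subisolates * target_nt)`,
#' `mu_SUB = f_SUB / (c * n)`, and `mu_SUBg = mu_SUB * G`.
#'
#' @param n_secondary Number of secondary base substitutions.
#' @param n_subisolates Number of sequenced sub-isolates.
#' @inheritParams rate_nonsense
#' @return List of `rate_estimate` objects `f_sub`, `mu_sub`,
#'   `mu_genomic`.
#' @examples
#' rate_hitchhiker(9, 112, target_nt = 591, genome_nt = 4217)$mu_genomic
#' @export
rate_hitchhiker <- function(n_secondary, n_subisolates, target_nt,
                            c_cycles = 1, n_replications = 2, genome_nt) {
  if (n_subisolates <= 0 || target_nt <= 0)
    stop("screening denominators must be positive")
  if (n_secondary < 0) stop("counts must be non-negative")
  cn <- c_cycles * n_replications
  f_sub <- n_secondary / (n_subisolates * target_nt)
  mu_sub <- f_sub / cn
  mu_genomic <- mu_sub * genome_nt
  comp <- list(n_secondary = n_secondary, n_subisolates = n_subisolates,
               target_nt = target_nt, c = c_cycles, n = n_replications,
               G = genome_nt)
  mk <- function(v, tag) rate_estimate(v, method = tag, components = comp)
  list(f_sub = mk(f_sub, "hitchhiker:f_sub"),
       mu_sub = mk(mu_sub, "hitchhiker:mu_sub"),
       mu_genomic = mk(mu_genomic, "hitchhiker:mu_genomic"))
}

#' Scale a per-target reversion rate to the genome
#'
#' A reversion test measures the rate over a handful of mutable bases;
#' the genomic component is `(G / reversion_target_bases) * mu_target`.
#' For a four-base duplication the reversion target may be taken as 4
#' bases (or argued to be 1); for a stop-codon substitution target, 3.
#'
#' @param mu_target Measured rate per reversion target per replication.
#' @param reversion_target_bases Number of mutable bases in the
#'   reversion target.
#' @param genome_nt Genome size G in nucleotides.
#' @return A `rate_estimate` (per genome per replication).
#' @export
scale_to_genome <- function(mu_target, reversion_target_bases, genome_nt) {
  if (reversion_target_bases < 1) stop("reversion target must be >= 1 base")
  value <- (genome_nt / reversion_target_bases) * mu_target
  rate_estimate(value, method = "genomic_scaling",
                components = list(mu_target = mu_target,
                                  reversion_target_bases = reversion_target_bases,
                                  G = genome_nt))
}

#' Expected revertant bursts from preexisting mutants
#'
#' In a single-burst experiment, cultures seeded with phage populations
#' already containing revertants at frequency `f_pre` yield large bursts
#' not attributable to new mutation; their expected total number across
#' the experiment is `f_pre * infected_cells_per_culture * n_cultures`.
#'
#' @param preexisting_frequency Revertant frequency in the starting
#'   population.
#' @param infected_cells_per_culture Infected cells N per culture.
#' @param n_cultures Number of cultures C.
#' @return Expected count (numeric).
#' @export
expected_preexisting_bursts <- function(preexisting_frequency,
                                        infected_cells_per_culture,
                                        n_cultures) {
  if (preexisting_frequency < 0 || preexisting_frequency > 1)
    stop("frequency must lie in [0, 1]")
  if (infected_cells_per_culture <= 0 || n_cultures <= 0)
    stop("counts must be positive")
  preexisting_frequency * infected_cells_per_culture * n_cultures
}

#' Predicted number of detectable reporter mutants
#'
#' Consistency check relating a per-cycle genomic mutation rate to the
#' observed mutant yield of a screen:
#' `round(mu_per_cycle * target_nt * isolates_screened *
#' detectable_fraction / genome_nt)`.
#'
#' @param mu_per_cycle Genomic mutation rate per infection cycle.
#' @param target_nt Reporter length in nucleotides.
#' @param isolates_screened Number of isolates screened.
#' @param detectable_fraction Fraction of random mutations that are
#'   phenotypically detectable (lethal), in (0, 1].
#' @param genome_nt Genome size in nucleotides.
#' @return Integer predicted mutant count.
#' @export
expected_detected_mutants <- function(mu_per_cycle, target_nt,
                                      isolates_screened,
                                      detectable_fraction, genome_nt) {
  if (detectable_fraction <= 0 || detectable_fraction > 1)
    stop("detectable_fraction must lie in (0, 1]")
  if (mu_per_cycle <= 0 || target_nt <= 0 || isolates_screened <= 0 ||
      genome_nt <= 0)
    stop("all quantities must be positive")
  as.integer(round(mu_per_cycle * target_nt * isolates_screened *
                     detectable_fraction / genome_nt))
}
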