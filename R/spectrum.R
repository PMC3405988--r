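#' Classify a base substitution as transition or transversion
#'
#' @param wt,mut Wild-type and mutant RNA bases (vectorised).
#' @return Character vector, `"transition"` (purine-purine or
#'   pyrimidine-pyrimidine) or `"transversion"`.
#' @examples
#' classify_substitution("U", "C")
#' @export
classify_substitution <- function(wt, mut) {
  check_rna_bases(c(wt, mut))
  if (any(wt == mut)) stop("wt and mut bases must differ")
  purine <- function(b) b %in% c("A", "G")
  ifelse(purine(wt) == purine(mut), "transition", "transversion")
}

#' Infer the template-primer mispair behind a substitution
#'
#' For a (+)-strand virus replicating through a (-)-strand intermediate,
#' a substitution observed on the (+) strand can be attributed to a
#' replication error in either round. Under second-round attribution
#' (errors during (-) -> (+) synthesis, the dominant round in
#' stamping-machine replication) the mispair is the (-)-strand template
#' base -- the complement of the wild-type (+) base -- paired against the
#' erroneous nascent (+) base. Under first-round attribution the template
#' is the wild-type (+) base itself and the erroneous nascent base is the
#' complement of the mutant.
#'
#' @inheritParams classify_substitution
#' @param round Which replication round the error is attributed to.
#' @return Character vector of mispairs in `"template.primer"` notation,
#'   e.g. `"A.C"` for an observed U to C substitution under second-round
#'   attribution.
#' @examples
#' infer_mispair("U", "C")  # "A.C"
#' infer_mispair("A", "G")  # "U.G"
#' @export
infer_mispair <- function(wt, mut, round = c("second", "first")) {
  round <- match.arg(round)
  check_rna_bases(c(wt, mut))
  if (round == "second") {
    paste(rna_complement(wt), mut, sep = ".")
  } else {
    paste(wt, rna_complement(mut), sep = ".")
  }
}

#' Validate and normalise a mutation record table
#'
#' @param records Data frame with columns `isolate`, `position`, `kind`
#'   (`substitution`, `insertion`, or `deletion`), `wt`, `mut`,
#'   `indel_seq`, `rank` (`primary` or `secondary`).
#' @param target Optional [mutation_target()] against which positions and
#'   wild-type bases are checked.
#' @return The validated data frame (invisibly classed
#'   `mutation_records`).
#' @export
validate_mutation_records <- function(records, target = NULL) {
  required <- c("isolate", "position", "kind", "wt", "mut", "indel_seq", "rank")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0)
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  records$position <- as.integer(records$position)
  if (any(is.na(records$position) | records$position < 1))
    stop("positions must be positive integers")
  if (!all(records$kind %in% c("substitution", "insertion", "deletion")))
    stop("kind must be substitution, insertion, or deletion")
  if (!all(records$rank %in% c("primary", "secondary")))
    stop("rank must be primary or secondary")
  subs <- records$kind == "substitution"
  if (any(subs)) {
    check_rna_bases(c(records$wt[subs], records$mut[subs]))
    same <- subs & records$wt == records$mut
    if (any(same))
      stop("wt equals mut at row(s): ", paste(which(same), collapse = ", "))
  }
  indel <- !subs
  if (any(indel & (is.na(records$indel_seq) | records$indel_seq == "")))
    stop("indel records must carry a non-empty indel_seq")
  if (!is.null(target)) {
    if (any(records$position > length(target)))
      stop("position(s) beyond target end")
    mism <- subs & unclass(target)[records$position] != records$wt
    if (any(mism))
      stop("wt base disagrees with target at position(s): ",
           paste(records$position[mism], collapse = ", "))
  }
  class(records) <- c("mutation_records", "data.frame")
  invisible(records)
}

#' Classify the coding effect of mutations
#'
#' Translates the affected codon before and after each substitution
#' under the standard genetic code. Substitutions creating a stop codon
#' from a sense codon are `nonsense`; a stop codon converted to a
#' different stop (possible at a leaky read-through codon) is
#' `stop_to_stop`, reported distinctly but conventionally pooled with
#' nonsense in detectable-mutation arithmetic. Indels whose length is not
#' a multiple of 3 are `frameshift`, otherwise `inframe_indel`.
#'
#' @param records Mutation record table (see
#'   [validate_mutation_records()]).
#' @param target A [mutation_target()] with codon framing.
#' @return Character vector of effects: `missense`, `synonymous`,
#'   `nonsense`, `stop_to_stop`, `frameshift`, or `inframe_indel`.
#' @export
mutation_effects <- function(records, target) {
  records <- validate_mutation_records(records, target)
  check_codon_frame(target)
  vapply(seq_len(nrow(records)), function(i) {
    if (records$kind[i] != "substitution") {
      len <- nchar(records$indel_seq[i])
      return(if (len %% 3 == 0) "inframe_indel" else "frameshift")
    }
    pos <- records$position[i]
    ci <- (pos - 1L) %/% 3L
    codon <- unclass(target)[(ci * 3L + 1L):(ci * 3L + 3L)]
    mutated <- codon
    mutated[(pos - 1L) %% 3L + 1L] <- records$mut[i]
    before <- paste(codon, collapse = "")
    after <- paste(mutated, collapse = "")
    if (before %in% STOP_CODONS) {
      if (after %in% STOP_CODONS) "stop_to_stop" else "readthrough_loss"
    } else if (after %in% STOP_CODONS) {
      "nonsense"
    } else if (translate_codon(before) == translate_codon(after)) {
      "synonymous"
    } else {
      "missense"
    }
  }, character(1))
}

#' Summarise a mutation spectrum
#'
#' Aggregates a mutation record table into the 12 substitution classes,
#' the transition and transversion totals and their ratio, the inferred
#' template-primer mispair per class, per-base normalised mutabilities
#' (class count divided by the target count of the wild-type base), indel
#' counts, and coding-effect tallies.
#'
#' @inheritParams mutation_effects
#' @param target Optional [mutation_target()]. When supplied, normalised
#'   mutabilities and effect tallies are computed; when absent only
#'   class counts are reported.
#' @param mispair_round Replication round for mispair attribution, see
#'   [infer_mispair()].
#' @return An object of class `spectrum_summary`.
#' @export
spectrum_summary <- function(records, target = NULL,
                             mispair_round = c("second", "first")) {
  mispair_round <- match.arg(mispair_round)
  records <- validate_mutation_records(records, target)
  classes <- outer(RNA_BASES, RNA_BASES, paste, sep = ">")
  classes <- classes[row(classes) != col(classes)]  # 12 X>Y classes
  subs <- records[records$kind == "substitution", , drop = FALSE]
  obs <- if (nrow(subs) > 0) paste(subs$wt, subs$mut, sep = ">") else character(0)
  class_counts <- vapply(classes, function(cl) sum(obs == cl), integer(1))
  wt_of <- substr(classes, 1, 1)
  mut_of <- substr(classes, 3, 3)
  type <- classify_substitution(wt_of, mut_of)
  mispair <- infer_mispair(wt_of, mut_of, round = mispair_round)
  n_transition <- sum(class_counts[type == "transition"])
  n_transversion <- sum(class_counts[type == "transversion"])
  tbl <- data.frame(class = classes, count = unname(class_counts),
                    type = type, mispair = mispair,
                    row.names = NULL)
  if (!is.null(target)) {
    bc <- base_counts(target)
    tbl$normalized <- ifelse(bc[wt_of] > 0, tbl$count / bc[wt_of], NA_real_)
    effects <- mutation_effects(records, target)
    effect_tally <- table(factor(effects, levels = c(
      "missense", "synonymous", "nonsense", "stop_to_stop",
      "readthrough_loss", "frameshift", "inframe_indel")))
  } else {
    tbl$normalized <- NA_real_
    effect_tally <- NULL
  }
  structure(list(
    classes = tbl,
    n_substitutions = nrow(subs),
    n_indels = sum(records$kind != "substitution"),
    n_records = nrow(records),
    transitions = n_transition,
    transversions = n_transversion,
    ts_tv_ratio = if (n_transversion > 0) n_transition / n_transversion
                  else NA_real_,
    effects = effect_tally,
    mispair_round = mispair_round
  ), class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("<spectrum_summary> %d mutations: %d substitutions (%d ts / %d tv, ratio %s), %d indels\n",
              x$n_records, x$n_substitutions, x$transitions, x$transversions,
              ifelse(is.na(x$ts_tv_ratio), "NA",
                     format(x$ts_tv_ratio, digits = 4)),
              x$n_indels))
  shown <- x$classes[x$classes$count > 0, , drop = FALSE]
  if (nrow(shown) > 0) {
    cat("  observed classes (template.primer mispair,",
        x$mispair_round, "round):\n")
    for (i in seq_len(nrow(shown)))
      cat(sprintf("    %s  %3d  %s%s\n", shown$class[i], shown$count[i],
                  shown$mispair[i],
                  if (!is.na(shown$normalized[i]))
                    sprintf("  (%.3f per wt base)", shown$normalized[i])
                  else ""))
  }
  if (!is.null(x$effects)) {
    eff <- x$effects[x$effects > 0]
    cat("  effects:", paste(names(eff), eff, sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Binomial test for a deficit of missense mutations
#'
#' Among phenotype-blind (hitchhiker) mutations the missense:synonymous
#' split should follow the codon-table expectation; a deficit of missense
#' mutations signals selection during plaque growth. Returns the exact
#' binomial point and lower-tail probabilities of the observed missense
#' count.
#'
#' @param n_missense Observed missense count.
#' @param n_total Total mutations classified (missense + synonymous).
#' @param expected_missense_fraction Expected probability that a random
#'   detected substitution is missense (codon-table derived; about 0.75
#'   for a typical coding sequence).
#' @return List with `p_point` = P(X = k) and `p_le` = P(X <= k) for
#'   X ~ Binomial(n_total, expected_missense_fraction).
#' @export
missense_deficit_test <- function(n_missense, n_total,
                                  expected_missense_fraction = 0.75) {
  if (n_missense < 0 || n_missense > n_total)
    stop("n_missense must lie in [0, n_total]")
  p <- expected_missense_fraction
  if (p <= 0 || p >= 1) stop("expected fraction must lie in (0, 1)")
  list(p_point = dbinom(n_missense, n_total, p),
       p_le = pbinom(n_missense, n_total, p))
}

#' Codon-table expected missense fraction of a target
#'
#' Fraction of all single-base substitution paths through the sense
#' codons of the target that are missense, among paths that are missense
#' or synonymous (nonsense paths excluded, since nonsense mutations are
#' screened out of a phenotype-blind hitchhiker set by their phenotype
#' only; set `include_nonsense = TRUE` to keep them in the denominator).
#'
#' @param target A [mutation_target()].
#' @param include_nonsense Keep nonsense paths in the denominator?
#' @return Expected missense fraction in (0, 1).
#' @export
expected_missense_fraction <- function(target, include_nonsense = FALSE) {
  codons <- target_codons(target)
  counts <- c(missense = 0L, synonymous = 0L, nonsense = 0L)
  for (codon in codons) {
    if (codon %in% STOP_CODONS) next
    bases <- strsplit(codon, "")[[1]]
    for (i in 1:3) {
      for (b in setdiff(RNA_BASES, bases[i])) {
        mutated <- bases
        mutated[i] <- b
        after <- paste(mutated, collapse = "")
        if (after %in% STOP_CODONS) {
          counts["nonsense"] <- counts["nonsense"] + 1L
        } else if (translate_codon(after) == translate_codon(codon)) {
          counts["synonymous"] <- counts["synonymous"] + 1L
        } else {
          counts["missense"] <- counts["missense"] + 1L
        }
      }
    }
  }
  denom <- counts["missense"] + counts["synonymous"] +
    if (include_nonsense) counts["nonsense"] else 0L
  unname(counts["missense"] / denom)
}

#' G/C content of upstream substitution contexts (replicated G-test)
#'
#' For each of the `width` sites immediately 5' of each observed
#' substitution, tallies G+C versus A+U occurrences across substitutions
#' and tests them against the target-wide G+C fraction with a replicated
#' goodness-of-fit G-test: each upstream offset is one replicate, giving
#' a pooled component G_P (1 df), a heterogeneity component G_H
#' (width - 1 df), and the total G_T (width df). Substitutions whose
#' upstream window would extend past the target start are excluded and
#' counted in `n_excluded`.
#'
#' @inheritParams mutation_effects
#' @param width Upstream window width (6 or 7 in the replicase-duplex
#'   analysis).
#' @param gc_expected Expected G+C fraction; defaults to the target's.
#' @return List with the `replicated_g_test()` components, the per-offset
#'   G+C counts, `n_used`, and `n_excluded`.
#' @export
gc_context_test <- function(records, target, width = 7,
                            gc_expected = NULL) {
  records <- validate_mutation_records(records, target)
  subs <- records[records$kind == "substitution", , drop = FALSE]
  usable <- subs$position - width >= 1
  n_excluded <- sum(!usable)
  subs <- subs[usable, , drop = FALSE]
  if (nrow(subs) < 2) stop("fewer than two usable substitutions")
  if (is.null(gc_expected)) {
    bc <- base_counts(target)
    gc_expected <- (bc["G"] + bc["C"]) / length(target)
  }
  windows <- t(vapply(subs$position,
                      function(p) upstream_window(target, p, width),
                      character(width)))
  # one replicate per upstream offset; offset 1 is the most 5' site
  gc_per_offset <- colSums(windows == "G" | windows == "C")
  counts <- cbind(gc = gc_per_offset, au = nrow(subs) - gc_per_offset)
  res <- replicated_g_test(counts, c(gc_expected, 1 - gc_expected))
  res$gc_per_offset <- unname(gc_per_offset)
  res$n_used <- nrow(subs)
  res$n_excluded <- n_excluded
  res$gc_expected <- unname(gc_expected)
  res
}
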