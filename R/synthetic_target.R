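#' The packaged RT mutation catalogue
#'
#' The 45 spontaneous mutations (32 primary + 13 secondary) recovered
#' from the Q-beta RT plaque screen, as a mutation record table with an
#' extra `impact` column giving the coding effect of each mutation.
#'
#' @return A validated mutation record data frame with 45 rows.
#' @export
rt_mutation_catalog <- function() {
  path <- system.file("extdata", "rt_mutations.tsv", package = "qmutate")
  read_mutation_table(path)
}

#' The packaged synthetic RT target sequence
#'
#' Loads the packaged 591-nt synthetic stand-in for the Q-beta RT
#' reporter (see [synthetic_rt_target()] for its construction and for
#' what is and is not faithful about it).
#'
#' @return A [mutation_target()] spanning genomic coordinates 1743-2333
#'   of a 4217-nt genome, beginning with the leaky UGA read-through
#'   codon.
#' @export
rt_target <- function() {
  path <- system.file("extdata", "rt_target_synthetic.fasta",
                      package = "qmutate")
  read_target_fasta(path, genome_offset = 1743L, genome_length = 4217L,
                    readthrough_stop_at_start = TRUE)
}

# three-letter -> one-letter amino acid names (Stop = "*")
AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
         Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
         Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
         Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
         Stop = "*")

# Expected effect category from an impact label like "Gly>Val".
effect_from_impact <- function(impact, kind, indel_seq = NA) {
  if (kind != "substitution") {
    len <- nchar(indel_seq)
    return(if (!is.na(len) && len %% 3 == 0) "inframe_indel" else "frameshift")
  }
  parts <- strsplit(impact, ">", fixed = TRUE)[[1]]
  before <- parts[1]; after <- parts[2]
  if (before == "Stop" && after == "Stop") "stop_to_stop"
  else if (after == "Stop") "nonsense"
  else if (before == after) "synonymous"
  else "missense"
}

#' Generate the synthetic RT target sequence
#'
#' The true RT reporter sequence is published only as a figure and is
#' not machine-readable here, so the package ships a synthetic stand-in
#' constructed to satisfy every published constraint on the real
#' sequence:
#' \itemize{
#'   \item 591 nt = 197 codons, genomic coordinates 1743-2333, beginning
#'     with the leaky UGA read-through codon and ending with a UAG stop;
#'     no internal stop codons;
#'   \item base composition exactly U 175 > G 147 > C 139 > A 130 (G+C
#'     fraction 0.484);
#'   \item exactly 66 single-base paths to a stop codon (counting the
#'     two paths that tighten the leaky UGA);
#'   \item at every one of the 45 catalogued mutation sites, the
#'     wild-type base and the coding effect (amino-acid change) of the
#'     mutation match the catalogue;
#'   \item homopolymeric U runs at the two single-base-insertion sites,
#'     and the UUAA motif (with its published flanks) at positions
#'     416-419 where the four-base duplication reverts.
#' }
#' All other codons are arbitrary, so analyses that depend on the actual
#' inter-site sequence (e.g. upstream G/C context of the real mutations)
#' are exercised structurally but their published outcomes are not
#' reproduced by this stand-in.
#'
#' The construction is deterministic: constrained codons are solved by
#' enumeration, free codons are filled to meet the base composition
#' exactly, and in-codon permutations of free codons are then searched
#' greedily until the stop-path count is exact.
#'
#' @param seed Seed for the (restored-on-exit) RNG used in the fill and
#'   search phases.
#' @return A [mutation_target()].
#' @export
synthetic_rt_target <- function(seed = 20120726) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  n_codons <- 197L
  comp_target <- c(A = 130L, C = 139L, G = 147L, U = 175L)
  paths_target <- 66L
  catalog <- rt_mutation_catalog()

  # --- constraint assembly -------------------------------------------------
  empty_cons <- function() list(fixed = character(0), forbid = character(0),
                                subs = list(), allow_stop = FALSE)
  cons <- replicate(n_codons, empty_cons(), simplify = FALSE)
  fix_base <- function(pos, base) {
    ci <- (pos - 1L) %/% 3L + 1L
    off <- as.character((pos - 1L) %% 3L + 1L)
    cons[[ci]]$fixed[off] <<- base
  }
  forbid_base <- function(pos, base) {
    ci <- (pos - 1L) %/% 3L + 1L
    off <- as.character((pos - 1L) %% 3L + 1L)
    cons[[ci]]$forbid[off] <<- base
  }
  # terminal codons: leaky UGA start, UAG stop end
  for (i in 1:3) fix_base(i, c("U", "G", "A")[i])
  for (i in 1:3) fix_base(588L + i, c("U", "A", "G")[i])
  cons[[1]]$allow_stop <- TRUE
  cons[[197]]$allow_stop <- TRUE
  # duplication motif U C UUAA G U at 414-421
  motif <- c("U", "C", "U", "U", "A", "A", "G", "U")
  for (i in seq_along(motif)) fix_base(413L + i, motif[i])
  # homopolymer runs at the insertion sites, bounded on both sides
  fix_base(106L, "U"); fix_base(107L, "U"); forbid_base(108L, "U")
  for (p in 221:224) fix_base(p, "U")
  forbid_base(220L, "U"); forbid_base(225L, "U")
  # substitution sites: wild-type base and coding effect
  subs <- catalog[catalog$kind == "substitution", , drop = FALSE]
  for (i in seq_len(nrow(subs))) {
    pos <- subs$position[i]
    ci <- (pos - 1L) %/% 3L + 1L
    parts <- strsplit(subs$impact[i], ">", fixed = TRUE)[[1]]
    cons[[ci]]$subs[[length(cons[[ci]]$subs) + 1L]] <-
      list(off = (pos - 1L) %% 3L + 1L, wt = subs$wt[i], mut = subs$mut[i],
           before = parts[1], after = parts[2])
  }

  # --- per-codon candidate enumeration -------------------------------------
  all_codons <- apply(expand.grid(RNA_BASES, RNA_BASES, RNA_BASES,
                                  stringsAsFactors = FALSE),
                      1, function(r) paste(rev(r), collapse = ""))
  code <- rna_codon_table()
  aa_of <- function(codon) unname(code[codon])
  satisfies <- function(codon, cn) {
    bases <- strsplit(codon, "")[[1]]
    for (off in names(cn$fixed))
      if (bases[as.integer(off)] != cn$fixed[[off]]) return(FALSE)
    for (off in names(cn$forbid))
      if (bases[as.integer(off)] == cn$forbid[[off]]) return(FALSE)
    is_stop <- codon %in% STOP_CODONS
    if (is_stop && !cn$allow_stop) return(FALSE)
    for (sp in cn$subs) {
      if (bases[sp$off] != sp$wt) return(FALSE)
      mb <- bases; mb[sp$off] <- sp$mut
      mcodon <- paste(mb, collapse = "")
      m_stop <- mcodon %in% STOP_CODONS
      ok <- if (sp$before == "Stop") {
        is_stop && m_stop
      } else if (sp$after == "Stop") {
        !is_stop && m_stop && aa_of(codon) == AA3[[sp$before]]
      } else {
        !is_stop && !m_stop &&
          aa_of(codon) == AA3[[sp$before]] && aa_of(mcodon) == AA3[[sp$after]]
      }
      if (!ok) return(FALSE)
    }
    TRUE
  }
  constrained <- which(vapply(cons, function(cn)
    length(cn$fixed) + length(cn$forbid) + length(cn$subs) > 0,
    logical(1)))
  candidates <- lapply(constrained, function(ci) {
    ok <- all_codons[vapply(all_codons, satisfies, logical(1),
                            cn = cons[[ci]])]
    if (length(ok) == 0)
      stop("no codon satisfies the constraints of codon ", ci)
    ok
  })
  names(candidates) <- as.character(constrained)

  # --- choose constrained codons, repairing composition overdraft ----------
  codons <- character(n_codons)
  for (j in seq_along(constrained))
    codons[constrained[j]] <- candidates[[j]][1]
  comp_of <- function(cds) {
    b <- unlist(strsplit(cds[cds != ""], ""))
    vapply(RNA_BASES, function(x) sum(b == x), integer(1))
  }
  n_free <- n_codons - length(constrained)
  remaining <- function() comp_target - comp_of(codons)
  guard <- 0L
  while (any(remaining() < 0) && guard < 1000L) {
    guard <- guard + 1L
    over <- names(which.min(remaining()))  # most overdrawn base
    improved <- FALSE
    for (j in seq_along(constrained)) {
      ci <- constrained[j]
      cur <- codons[ci]
      cur_n <- sum(strsplit(cur, "")[[1]] == over)
      for (alt in candidates[[j]]) {
        if (sum(strsplit(alt, "")[[1]] == over) < cur_n) {
          codons[ci] <- alt
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved)
      stop("cannot meet the target base composition under the ",
           "sequence constraints")
  }

  # --- fill free codons to the exact composition ---------------------------
  rem <- remaining()
  if (any(rem < 0) || sum(rem) != 3L * n_free)
    stop("composition bookkeeping failed")
  pool <- sample(rep(RNA_BASES, times = rem))
  free_idx <- setdiff(seq_len(n_codons), constrained)
  triples <- matrix(pool, nrow = 3)
  for (j in seq_along(free_idx)) {
    tri <- triples[, j]
    perms <- unique(apply(rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
                          1, function(p) paste(tri[p], collapse = "")))
    perms <- perms[!(perms %in% STOP_CODONS)]
    codons[free_idx[j]] <- perms[1]
  }

  # --- greedy in-codon permutation search for the exact stop-path count ----
  contrib <- function(codon, ci) {
    if (ci == 1L) codon_stop_paths(codon, count_from_stop = TRUE)
    else codon_stop_paths(codon)
  }
  totals <- vapply(seq_len(n_codons), function(ci) contrib(codons[ci], ci),
                   integer(1))
  perms_of <- function(codon) {
    b <- strsplit(codon, "")[[1]]
    p <- unique(apply(rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                            c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)),
                      1, function(i) paste(b[i], collapse = "")))
    p[!(p %in% STOP_CODONS)]
  }
  guard <- 0L
  while (sum(totals) != paths_target && guard < 500L) {
    guard <- guard + 1L
    need <- paths_target - sum(totals)
    best <- NULL
    for (ci in free_idx) {
      for (alt in perms_of(codons[ci])) {
        d <- contrib(alt, ci) - totals[ci]
        if (d == 0 || sign(d) != sign(need) || abs(d) > abs(need)) next
        if (is.null(best) || abs(d) > abs(best$d))
          best <- list(ci = ci, alt = alt, d = d)
      }
    }
    if (is.null(best))
      stop("stop-path search stuck at ", sum(totals), " paths")
    codons[best$ci] <- best$alt
    totals[best$ci] <- totals[best$ci] + best$d
  }
  if (sum(totals) != paths_target)
    stop("stop-path search did not converge")

  # --- assemble and verify -------------------------------------------------
  target <- mutation_target(unlist(strsplit(codons, "")),
                            name = "RT_synthetic",
                            genome_offset = 1743L, genome_length = 4217L,
                            readthrough_stop_at_start = TRUE)
  stopifnot(length(target) == 591L,
            identical(base_counts(target), comp_target),
            nonsense_paths(target) == paths_target)
  effects <- mutation_effects(catalog, target)
  expected <- vapply(seq_len(nrow(catalog)), function(i)
    effect_from_impact(catalog$impact[i], catalog$kind[i],
                       catalog$indel_seq[i]), character(1))
  if (!identical(effects, expected))
    stop("constructed target does not reproduce the catalogued impacts")
  target
}
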