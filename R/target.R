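#' Construct a codon-framed RNA mutation target
#'
#' A mutation target is the reporter sequence within which mutations are
#' scored, held as individual RNA residues together with its genomic
#' placement. The Q-beta RT reporter spans target positions 1-591
#' (genomic 1743-2333) and begins with the leaky UGA read-through codon
#' of the upstream coat gene.
#'
#' @param bases Character vector of single RNA residues, or a single
#'   string, over `A`, `C`, `G`, `U`. `T` is accepted with a warning and
#'   converted to `U`.
#' @param name Target name.
#' @param genome_offset 1-based genomic coordinate of target position 1.
#' @param genome_length Genome size G in nucleotides.
#' @param readthrough_stop_at_start Logical; does the target begin with a
#'   leaky (read-through) stop codon that is translated at low frequency?
#' @return An object of class `mutation_target`: the residue vector with
#'   metadata attributes.
#' @examples
#' tgt <- mutation_target("UGAUUUGGG", name = "toy")
#' nonsense_paths(tgt)
#' @export
mutation_target <- function(bases, name = "target", genome_offset = 1L,
                            genome_length = NA_integer_,
                            readthrough_stop_at_start = FALSE) {
  if (length(bases) == 1 && nchar(bases) > 1)
    bases <- strsplit(bases, "")[[1]]
  bases <- toupper(as.character(bases))
  if (any(bases == "T")) {
    warning("DNA-style 'T' residues converted to 'U'")
    bases[bases == "T"] <- "U"
  }
  check_rna_bases(bases)
  if (length(bases) == 0) stop("empty target")
  structure(bases,
            class = "mutation_target",
            name = name,
            genome_offset = as.integer(genome_offset),
            genome_length = as.integer(genome_length),
            readthrough_stop_at_start = isTRUE(readthrough_stop_at_start))
}

#' @export
print.mutation_target <- function(x, ...) {
  cat(sprintf("<mutation_target> %s: %d nt (%s codon-framed)\n",
              attr(x, "name"), length(x),
              if (length(x) %% 3 == 0) sprintf("%d codons", length(x) / 3)
              else "not"))
  cat(sprintf("  genome offset %d, genome length %s, read-through start: %s\n",
              attr(x, "genome_offset"),
              ifelse(is.na(attr(x, "genome_length")), "unknown",
                     attr(x, "genome_length")),
              attr(x, "readthrough_stop_at_start")))
  bc <- base_counts(x)
  cat("  composition:", paste(names(bc), bc, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Read a mutation target from a FASTA file
#'
#' Reads the first record of a FASTA file via Biostrings and returns a
#' [mutation_target()]. DNA-style `T` residues are converted to `U` with
#' a warning.
#'
#' @param path Path to a FASTA file.
#' @inheritParams mutation_target
#' @return A `mutation_target`.
#' @export
read_target_fasta <- function(path, genome_offset = 1L,
                              genome_length = NA_integer_,
                              readthrough_stop_at_start = FALSE) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path)
  mutation_target(as.character(seqs[[1]]), name = names(seqs)[1],
                  genome_offset = genome_offset,
                  genome_length = genome_length,
                  readthrough_stop_at_start = readthrough_stop_at_start)
}

#' Genomic coordinate of a target position
#'
#' @param target A [mutation_target()].
#' @param position 1-based target coordinate(s).
#' @return Integer genomic coordinate(s), `genome_offset + position - 1`.
#' @export
genomic_position <- function(target, position) {
  stopifnot(inherits(target, "mutation_target"))
  position <- as.integer(position)
  if (any(position < 1L | position > length(target)))
    stop("position out of target range")
  attr(target, "genome_offset") + position - 1L
}

check_codon_frame <- function(target) {
  if (length(target) %% 3 != 0)
    stop("framing error: target length ", length(target),
         " is not a multiple of 3")
  invisible(TRUE)
}

target_codons <- function(target) {
  check_codon_frame(target)
  apply(matrix(unclass(target), nrow = 3), 2, paste, collapse = "")
}

# Number of single-base substitutions of `codon` that yield a stop codon.
# A codon that is already a stop contributes only when `count_from_stop`
# (used for the leaky read-through codon, whose conversion to a tighter
# stop is phenotypically detectable); paths to the *same* stop are
# impossible by construction (wt != mut at one site).
codon_stop_paths <- function(codon, count_from_stop = FALSE) {
  if (codon %in% STOP_CODONS && !count_from_stop) return(0L)
  bases <- strsplit(codon, "")[[1]]
  n <- 0L
  for (i in 1:3) {
    for (b in setdiff(RNA_BASES, bases[i])) {
      mutated <- bases
      mutated[i] <- b
      if (paste(mutated, collapse = "") %in% STOP_CODONS) n <- n + 1L
    }
  }
  n
}

#' Count single-base paths to a stop codon (nonsense target size)
#'
#' Enumerates every (position, mutant base) pair whose single-base
#' substitution converts a codon of the target into a stop codon (UAA,
#' UAG, or UGA). The count sizes the detectable base-substitution target:
#' dividing the number of paths by three gives the equivalent number of
#' fully detectable bases, since each base can mutate along three paths.
#'
#' Codons that are already stops are skipped, with one exception: when
#' the target starts with a leaky read-through stop codon and
#' `include_readthrough_codon = TRUE` (the default), substitutions
#' converting that codon into a different, tighter stop are counted,
#' because they abolish read-through and are phenotypically detectable.
#'
#' @param target A [mutation_target()]; length must be a multiple of 3.
#' @param include_readthrough_codon Count paths converting a leading
#'   leaky stop codon into a different stop?
#' @return Integer number of nonsense paths.
#' @examples
#' nonsense_paths(mutation_target("UGG"))  # UGG -> UAG, UGG -> UGA
#' @export
nonsense_paths <- function(target, include_readthrough_codon = TRUE) {
  stopifnot(inherits(target, "mutation_target"))
  codons <- target_codons(target)
  total <- sum(vapply(codons, codon_stop_paths, integer(1)))
  if (attr(target, "readthrough_stop_at_start") &&
      codons[1] %in% STOP_CODONS && include_readthrough_codon) {
    total <- total + codon_stop_paths(codons[1], count_from_stop = TRUE)
  }
  as.integer(total)
}

#' Base composition of a target
#'
#' @param target A [mutation_target()].
#' @return Named integer vector with counts of A, C, G, U (summing to the
#'   target length).
#' @export
base_counts <- function(target) {
  stopifnot(inherits(target, "mutation_target"))
  vapply(RNA_BASES, function(b) sum(unclass(target) == b), integer(1))
}

#' Maximal homopolymer run covering a position
#'
#' Indels in mutation spectra typically arise within homopolymeric runs
#' through template-primer misalignment; this locates the run containing
#' a given site.
#'
#' @param target A [mutation_target()].
#' @param position 1-based target coordinate.
#' @return List with `base`, `start`, and `length` of the maximal run of
#'   identical residues covering `position`.
#' @export
homopolymer_run <- function(target, position) {
  stopifnot(inherits(target, "mutation_target"))
  position <- as.integer(position)
  if (position < 1L || position > length(target))
    stop("position out of target range")
  b <- target[position]
  start <- position
  while (start > 1L && target[start - 1L] == b) start <- start - 1L
  end <- position
  while (end < length(target) && target[end + 1L] == b) end <- end + 1L
  list(base = unname(b), start = start, length = end - start + 1L)
}

#' Fixed-width window immediately 5' of a position
#'
#' Returns the `width` residues ending at `position - 1`, ordered 5' to
#' 3'. Windows that would extend past the target start are rejected
#' rather than padded, so that context analyses compare fixed-width
#' oligomers only.
#'
#' @param target A [mutation_target()].
#' @param position 1-based target coordinate.
#' @param width Window width (the replicase-cavity duplex motivates 6 or
#'   7, but any positive width is accepted).
#' @return Character vector of `width` residues.
#' @export
upstream_window <- function(target, position, width) {
  stopifnot(inherits(target, "mutation_target"))
  position <- as.integer(position)
  width <- as.integer(width)
  if (width < 1L) stop("width must be positive")
  if (position > length(target) || position < 1L)
    stop("position out of target range")
  if (position - width < 1L)
    stop("boundary error: window of width ", width,
         " upstream of position ", position, " extends past the target start")
  unclass(target)[(position - width):(position - 1L)]
}
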