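# Shared fixtures for the test suite.

fixture_path <- function(file) {
  system.file("extdata", file, package = "qmutate")
}

rt_fixture_target <- function() rt_target()

rt_in_data <- function() {
  read_burst_table(fixture_path("rt_in_bursts.tsv"),
                   N = 4560, B_mean = 328, B_sd = 93)
}

rt_sub_data <- function() {
  read_burst_table(fixture_path("rt_sub_bursts.tsv"),
                   N = 35, B_mean = 859, B_sd = 165)
}

# Brute-force oracle for the nonsense-path count: mutate every position
# to every alternative base and inspect the affected codon directly.
brute_force_nonsense_paths <- function(target,
                                       include_readthrough_codon = TRUE) {
  bases <- unclass(target)
  stops <- c("UAA", "UAG", "UGA")
  n <- 0L
  for (pos in seq_along(bases)) {
    ci <- (pos - 1L) %/% 3L
    codon <- paste(bases[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    original_is_stop <- codon %in% stops
    counts_here <- !original_is_stop ||
      (include_readthrough_codon && ci == 0L &&
         attr(target, "readthrough_stop_at_start"))
    if (!counts_here) next
    for (b in setdiff(c("A", "C", "G", "U"), bases[pos])) {
      mut <- bases
      mut[pos] <- b
      mcodon <- paste(mut[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
      if (mcodon %in% stops) n <- n + 1L
    }
  }
  n
}

random_rna_target <- function(len_codons, readthrough = FALSE) {
  mutation_target(sample(c("A", "C", "G", "U"), len_codons * 3,
                         replace = TRUE),
                  readthrough_stop_at_start = readthrough)
}
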