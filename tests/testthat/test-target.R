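test_that("nonsense path counts match exhaustive check on small codons", {
  # UUU: no single substitution reaches a stop; UGG: two (UAG, UGA)
  expect_identical(nonsense_paths(mutation_target("UUU")), 0L)
  expect_identical(nonsense_paths(mutation_target("UGG")), 2L)
  # leaky UGA start: UGA -> UAA is the only one-step stop-to-stop path
  leaky <- mutation_target("UGAUGG", readthrough_stop_at_start = TRUE)
  expect_identical(nonsense_paths(leaky, include_readthrough_codon = TRUE), 3L)
  expect_identical(nonsense_paths(leaky, include_readthrough_codon = FALSE), 2L)
  # an internal stop codon never contributes paths
  expect_identical(nonsense_paths(mutation_target("UGGUAG")), 2L)
})

test_that("nonsense_paths agrees with the brute-force oracle on random sequences", {
  set.seed(101)
  for (i in 1:100) {
    len <- sample(1:100, 1)  # up to 300 nt
    rt <- runif(1) < 0.3
    tgt <- random_rna_target(len, readthrough = rt)
    expect_identical(nonsense_paths(tgt), brute_force_nonsense_paths(tgt))
    expect_identical(nonsense_paths(tgt, FALSE),
                     brute_force_nonsense_paths(tgt, FALSE))
    expect_lte(nonsense_paths(tgt), 3L * length(tgt))
  }
})

test_that("base counts are conserved and errors are raised for bad input", {
  expect_identical(unname(base_counts(mutation_target("AAAA"))),
                   c(4L, 0L, 0L, 0L))
  expect_identical(unname(base_counts(mutation_target("ACGU"))),
                   rep(1L, 4))
  set.seed(7)
  tgt <- random_rna_target(20)
  expect_identical(sum(base_counts(tgt)), length(tgt))
  expect_error(mutation_target("ACGX"), "alphabet")
  expect_error(nonsense_paths(mutation_target("ACGUA")), "framing")
  expect_warning(mutation_target("ACGT"), "T")
})

test_that("homopolymer runs and upstream windows behave at boundaries", {
  tgt <- mutation_target("AAUUUG")
  expect_equal(homopolymer_run(tgt, 4), list(base = "U", start = 3L, length = 3L))
  expect_equal(homopolymer_run(mutation_target("ACGU"), 2)$length, 1L)
  expect_equal(homopolymer_run(mutation_target("UUUU"), 1),
               list(base = "U", start = 1L, length = 4L))
  expect_error(homopolymer_run(tgt, 7), "range")

  t9 <- mutation_target("ACGUACGUA")
  expect_identical(paste(upstream_window(t9, 8, 6), collapse = ""), "CGUACG")
  expect_error(upstream_window(t9, 7, 7), "boundary")
  expect_identical(paste(upstream_window(mutation_target("GGGGGGGA"), 8, 7),
                         collapse = ""), "GGGGGGG")
})

test_that("genomic coordinates map additively from the target offset", {
  tgt <- mutation_target(strrep("ACG", 5), genome_offset = 1743)
  expect_identical(genomic_position(tgt, 1), 1743L)
  expect_identical(genomic_position(tgt, 15), 1757L)
  expect_error(genomic_position(tgt, 16), "range")
})

test_that("the synthetic RT target satisfies its published constraints", {
  tgt <- rt_fixture_target()
  expect_identical(length(tgt), 591L)
  expect_identical(base_counts(tgt), c(A = 130L, C = 139L, G = 147L, U = 175L))
  # stop-path count recorded under both read-through conventions
  expect_identical(nonsense_paths(tgt, include_readthrough_codon = TRUE), 66L)
  expect_identical(nonsense_paths(tgt, include_readthrough_codon = FALSE), 65L)
  expect_identical(brute_force_nonsense_paths(tgt), 66L)
  # begins with the leaky UGA, ends with UAG, no internal stops
  codons <- substring(paste(unclass(tgt), collapse = ""),
                      seq(1, 589, 3), seq(3, 591, 3))
  expect_identical(codons[1], "UGA")
  expect_identical(codons[197], "UAG")
  expect_false(any(codons[2:196] %in% c("UAA", "UAG", "UGA")))
  # the insertion sites sit in homopolymeric U runs
  expect_gte(homopolymer_run(tgt, 106)$length, 2L)
  expect_identical(homopolymer_run(tgt, 221),
                   list(base = "U", start = 221L, length = 4L))
  # the duplication motif and its flanks
  expect_identical(paste(unclass(tgt)[414:421], collapse = ""), "UCUUAAGU")
  # generation is deterministic and matches the shipped FASTA
  expect_identical(as.character(synthetic_rt_target()), as.character(tgt))
})
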