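test_that("generation is byte-identical for the same spec and seed", {
  g1 <- make_genome(genome_spec(seed = 5L))
  g2 <- make_genome(genome_spec(seed = 5L))
  expect_identical(g1$record$seq, g2$record$seq)
  expect_identical(g1$truth$orfs, g2$truth$orfs)
  g3 <- make_genome(genome_spec(seed = 6L))
  expect_false(identical(g1$record$seq, g3$record$seq))
})

test_that("unconstructible specs fail validation before any output", {
  expect_error(genome_spec(orf1a_len = 100L), "spec error")
  expect_error(genome_spec(orf1b_ext = 4500L), "spec error")   # wrong mod 3
  expect_error(genome_spec(orf2b_offset = 9L), "spec error")
  expect_error(genome_spec(orf4_len = 300L), "spec error")
  expect_error(genome_spec(insertion_len = 5L), "spec error")
})

test_that("evolve_sequence at d = 0 is the identity", {
  s <- rand_dna(100)
  expect_identical(evolve_sequence(s, 0, "JC-nt", 1), s)
  p <- paste(sample(mesoniv:::.AA20, 50, TRUE), collapse = "")
  expect_identical(evolve_sequence(p, 0, "WAG-aa", 1), p)
})

test_that("JC evolution matches the expected p-distance", {
  s <- rand_dna(100000)
  e <- evolve_sequence(s, 0.1, "JC-nt", seed = 12)
  p_obs <- mean(strsplit(s, "")[[1]] != strsplit(e, "")[[1]])
  expect_equal(p_obs, 3 / 4 * (1 - exp(-4 * 0.1 / 3)), tolerance = 0.003 / 0.09)
  expect_identical(evolve_sequence(s, 0.1, "JC-nt", seed = 12), e)
})

test_that("isolate sets plant exact substitution counts, disjoint across isolates", {
  sim <- canonical_sim()
  iso <- make_isolate_set(sim, substitutions = c(10L, 10L, 10L), seed = 3L)
  recs <- lapply(iso$records, trim_polya)
  base <- trim_polya(iso$base)
  for (r in recs) {
    d <- count_differences(align_global(r, base, band = 20L))
    expect_equal(d$substitutions, 10L)
  }
  for (i in 1:2) for (j in (i + 1):3) {
    d <- count_differences(align_global(recs[[i]], recs[[j]], band = 20L))
    expect_equal(d$substitutions, 20L)   # planted positions are disjoint
  }
  # planted positions avoid every protected motif
  prot <- mesoniv:::.protected_mask(sim$truth)
  for (p in iso$truth$planted)
    expect_false(any(prot[p$positions + 1L]))
})

test_that("substitutions plus planted 3- and 6-nt deletions are both recovered", {
  sim <- canonical_sim()
  iso <- make_isolate_set(sim, substitutions = 68L, indels = list(c(3L, 6L)),
                          seed = 14L)
  d <- count_differences(align_global(trim_polya(iso$records[[1]]),
                                      trim_polya(iso$base), band = 100L))
  expect_equal(d$substitutions, 68L)
  expect_equal(sort(d$indel_events), c(3L, 6L))
})

test_that("isolates with planted substitutions still annotate cleanly", {
  sim <- canonical_sim()
  iso <- make_isolate_set(sim, substitutions = 25L, seed = 9L)
  rep <- annotate_genome(iso$records[[1]])
  expect_length(rep$errors, 0L)
  arch <- rep$annotations[[1]]$architecture
  expect_length(arch_mismatches(arch, sim$truth), 0L)
})

test_that("species sets separate at the demarcation threshold", {
  ss <- make_species_set(genome_spec(seed = 21L), n_species = 3L,
                         n_per_species = 2L, within_d = 0.005,
                         between_d = 0.4, seed = 77L)
  dem <- demarcate_set(ss$records, refset = ss$refset)
  expect_length(dem$partition$clusters, 3L)
  got <- dem$partition$membership[ss$species$taxon]
  expect_true(all(tapply(ss$species$species, got,
                         function(x) length(unique(x))) == 1L))
  within <- dem$distances["sp1_iso1", "sp1_iso2"]
  between <- dem$distances["sp1_iso1", "sp2_iso1"]
  expect_lt(within, 0.032)
  expect_gt(between, 0.032)
})
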