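test_that("global alignment trivial cases and deterministic gap placement", {
  a <- align_global("ACGT", "ACGT")
  expect_equal(a$score, 20)
  expect_equal(a$rows, c("ACGT", "ACGT"))

  b <- align_global("ACGT", "AGT")
  expect_equal(sum(strsplit(b$rows[2], "")[[1]] == "-"), 1L)
  expect_equal(b$score, 3 * 5 - 10.5)

  expect_error(align_global("ACGT", "MKLV"), "mixed alphabets")
})

test_that("alignment score is symmetric and matches the Biostrings oracle", {
  set.seed(402)
  for (i in 1:15) {
    a <- rand_dna(sample(5:60, 1)); b <- rand_dna(sample(5:60, 1))
    s_ab <- align_global(a, b)$score
    expect_equal(s_ab, align_global(b, a)$score)
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 5, mismatch = -4),
      gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
    expect_equal(s_ab, ref)
  }
})

test_that("banded alignment equals the full matrix on homologous pairs", {
  set.seed(403)
  for (i in 1:8) {
    a <- rand_dna(400)
    b <- evolve_sequence(a, 0.05, "JC-nt", seed = i)
    cut <- sample(100:300, 1)
    b <- paste0(substr(b, 1, cut), substr(b, cut + 12, nchar(b)))
    f <- align_global(a, b)
    bd <- align_global(a, b, band = 60L)
    expect_equal(bd$score, f$score)
    expect_equal(bd$rows, f$rows)
  }
})

test_that("count_differences: substitutions, indel events, identity", {
  mk <- function(r1, r2) structure(list(rows = c(r1, r2), score = 0,
                                        params = align_params()),
                                   class = "meso_alignment")
  d1 <- count_differences(mk("ACGT", "ACGA"))
  expect_equal(d1$substitutions, 1L)
  expect_length(d1$indel_events, 0L)
  expect_equal(d1$aligned_identity, 3 / 4)

  d2 <- count_differences(mk("AC--GT", "ACTTGT"))
  expect_equal(d2$substitutions, 0L)
  expect_equal(d2$indel_events, 2L)
  expect_equal(d2$aligned_identity, 1)
})

test_that("planted substitutions are counted back exactly", {
  sim <- canonical_sim()
  for (k in c(5L, 57L)) {
    iso <- make_isolate_set(sim, substitutions = k, seed = k)
    a <- trim_polya(iso$records[[1]]); b <- trim_polya(iso$base)
    d <- count_differences(align_global(a, b, band = 30L))
    expect_equal(d$substitutions, k)
    expect_length(d$indel_events, 0L)
  }
})

test_that("detect_insertions finds exactly one block of the planted length", {
  for (L in c(30L, 180L, 573L, 588L)) {
    withq <- canonical_sim(seed = 9L, insertion_len = L)
    sibling <- without_insertion(withq)
    blocks <- detect_insertions(trim_polya(withq$record),
                                trim_polya(sibling),
                                region = c(0L, 4200L))
    expect_equal(nrow(blocks), 1L)
    expect_equal(blocks$length_nt, L)
    # start can wobble by a few nt where flanking bases make the gap
    # placement ambiguous
    expect_lte(abs(blocks$query_start -
                     unname(withq$truth$insertion$span["start"])), 12L)
    expect_equal(blocks$length_aa, L %/% 3L)
    expect_false(blocks$frame_disrupting)
  }
  # identical sequences: no blocks
  base <- canonical_sim(seed = 9L)
  expect_equal(nrow(detect_insertions(trim_polya(base$record),
                                      trim_polya(base$record),
                                      region = c(0L, 4200L))), 0L)
})

test_that("a simple constructed 9-nt insertion is reported", {
  ref <- genome_record("r", rand_dna(300))
  q <- genome_record("q", paste0(substr(ref$seq, 1, 150), "GGGTTTCCC",
                                 substr(ref$seq, 151, 300)))
  blocks <- detect_insertions(q, ref, min_block = 9L)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$length_nt, 9L)
})

test_that("non-alignable regions raise a homology error", {
  a <- genome_record("a", rand_dna(100))
  b <- genome_record("b", rand_dna(600))
  expect_error(detect_insertions(a, b), "homology error")
})

test_that("find_repeats equals a brute-force Hamming scan", {
  hits <- find_repeats("SKRKGKAAASKRKGK", "SKRKGK", max_mismatch = 0L)
  expect_equal(hits$position, c(0L, 9L))

  h1 <- find_repeats("SKRKGR", "SKRKGK", max_mismatch = 1L)
  expect_equal(h1$mismatches, 1L)

  set.seed(77)
  for (i in 1:10) {
    s <- rand_dna(200)
    seed <- rand_dna(6)
    got <- find_repeats(s, seed, max_mismatch = 1L)
    sc <- strsplit(s, "")[[1]]; kc <- strsplit(seed, "")[[1]]
    want <- which(vapply(seq_len(200 - 5), function(p)
      sum(sc[p:(p + 5)] != kc) <= 1L, logical(1))) - 1L
    expect_equal(got$position, want)
  }
})

test_that("insertion blocks carry imperfect repeat annotations", {
  withq <- canonical_sim(seed = 9L, insertion_len = 588L)
  blocks <- detect_insertions(trim_polya(withq$record),
                              trim_polya(without_insertion(withq)),
                              region = c(0L, 4200L))
  reps <- blocks$repeats[[1]]
  expect_gte(nrow(reps), 2L)
  expect_equal(reps$position[1], 0L)                   # copy at the 5' end
  expect_equal(max(reps$position), 588L %/% 3L - 6L)   # copy at the 3' end
})
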