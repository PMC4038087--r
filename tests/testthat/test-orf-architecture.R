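test_that("find_orfs reports ATG->stop ORFs with exact coordinates", {
  orfs <- find_orfs("ATGAAATAA", min_len_nt = 9, require_start = TRUE)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start, 0L)
  expect_equal(orfs$end, 9L)
  expect_equal(orfs$protein, "MK")

  expect_equal(nrow(find_orfs("CCCCCC", min_len_nt = 6)), 0L)
})

test_that("stop-to-stop mode contains the ATG mode by span", {
  set.seed(7)
  for (i in 1:20) {
    s <- rand_dna(400)
    with_atg <- find_orfs(s, min_len_nt = 30, require_start = TRUE)
    open <- find_orfs(s, min_len_nt = 30, require_start = FALSE)
    if (!nrow(with_atg)) next
    for (k in seq_len(nrow(with_atg))) {
      cover <- open$frame == with_atg$frame[k] &
        open$start <= with_atg$start[k] & open$end >= with_atg$end[k]
      expect_true(any(cover))
    }
  }
})

test_that("assign_architecture recovers every planted feature", {
  for (ins in c(0L, 573L)) {
    sim <- canonical_sim(seed = 42L, insertion_len = ins)
    rep <- annotate_genome(sim$record)
    arch <- rep$annotations[[1]]$architecture
    expect_length(arch_mismatches(arch, sim$truth), 0L)
    # span accounting: UTR + coding block + 3' region tile the genome
    expect_equal(unname(arch$utr5["end"]), arch$orf1a$start)
    last <- if (!is.null(arch$orf4)) arch$orf4$end else arch$orf3b$end
    expect_equal(unname(arch$term3["start"]), last)
    expect_equal(unname(arch$term3["end"]), sim$truth$body_len)
  }
})

test_that("missing ORF2a is reported by name", {
  sim <- canonical_sim()
  rec <- trim_polya(sim$record)
  o <- sim$truth$orfs
  # delete the ORF2a region entirely
  rec$seq <- paste0(substr(rec$seq, 1, o["orf2a", "start"]),
                    substr(rec$seq, o["orf2a", "end"] + 1L, nchar(rec$seq)))
  orfs <- find_orfs(rec$seq, min_len_nt = 120)
  expect_error(assign_architecture(rec, orfs), "ORF2a")
})

test_that("translate_prf matches a hand-translated 26-nt construct", {
  seq <- "ATGAAAGGATTTTCCGTTGCACTTAA"
  rec <- genome_record("toy", seq)
  up <- list(start = 0L, end = 24L, frame = 0L)
  down <- list(start = 14L, end = 26L, frame = 2L)
  fp <- translate_prf(rec, up, down, slippery_pos = 6L, name = "pp1ab")
  expect_equal(fp$join_pos, 15L)
  expect_equal(fp$protein, "MKGFSRCT")   # ATG AAA GGA TTT TCC CGT TGC ACT
  expect_equal(fp$slippery_motif, "GGATTTT")
})

test_that("translate_prf fuses the planted genome exactly, with the prefix property", {
  sim <- canonical_sim()
  rec <- trim_polya(sim$record)
  rep <- annotate_genome(sim$record)
  a <- rep$annotations[[1]]
  expect_equal(a$pp1ab$protein, sim$truth$pp1ab)
  expect_equal(a$p3ab$protein, sim$truth$p3ab)
  # fusion protein starts with the upstream ORF's protein prefix
  up_prot <- a$architecture$orf1a$protein
  npre <- (a$pp1ab$join_pos - a$architecture$orf1a$start) %/% 3L
  expect_equal(substr(a$pp1ab$protein, 1, npre), substr(up_prot, 1, npre))
  expect_gt(nchar(a$pp1ab$protein), nchar(up_prot))
  # length accounting: upstream codons before j + downstream codons from j-1
  ndown <- (a$architecture$orf1b$end - (a$pp1ab$join_pos - 1L)) %/% 3L
  expect_equal(nchar(a$pp1ab$protein), npre + ndown - 1L)  # minus the stop
})

test_that("an overlap without the heptamer is a frameshift error", {
  seq <- "ATGAAACCCTTTTCCGTTGCACTTAA"
  rec <- genome_record("toy", seq)
  up <- list(start = 0L, end = 24L, frame = 0L)
  down <- list(start = 14L, end = 26L, frame = 2L)
  expect_error(translate_prf(rec, up, down, 6L), "frameshift error")
})
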