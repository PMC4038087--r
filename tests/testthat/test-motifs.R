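test_that("scan_motif matches the two TRS pattern forms", {
  h1 <- scan_motif("ATGGTACTACTACTA", "AUxxUACUACUACUA")
  expect_equal(h1$start, 0L)
  expect_equal(h1$matched, "ATGGTACTACTACTA")

  # one-base form of the optional wildcard
  h2 <- scan_motif("AGAGACTCTCCCA", "AGAx(x)ACUCUCCCA")
  expect_equal(h2$start, 0L)
  expect_equal(h2$matched, "AGAGACTCTCCCA")

  # two-base form is preferred (longest match at a position)
  h3 <- scan_motif("AGAGGACTCTCCCA", "AGAx(x)ACUCUCCCA")
  expect_equal(h3$end - h3$start, 14L)
})

test_that("malformed patterns raise pattern errors", {
  expect_error(scan_motif("ACGT", "A(CT)G"), "pattern error")
  expect_error(scan_motif("ACGT", "AC?T"), "pattern error")
})

test_that("scan_motif agrees with a brute-force matcher on random sequences", {
  set.seed(301)
  for (pat in c("AUxxUACUACUACUA", "AGAx(x)ACUCUCCCA", "GGAUUUU", "AxG")) {
    for (i in 1:8) {
      s <- rand_dna(sample(50:500, 1))
      got <- scan_motif(s, pat)
      want <- brute_scan_motif(s, pat)
      expect_equal(got$start, want$start, info = pat)
      expect_equal(got$end, want$end, info = pat)
    }
  }
})

test_that("find_slippery finds exact heptamers inside a span", {
  expect_equal(find_slippery("GGATTTT", c(0L, 7L)), 0L)
  expect_equal(find_slippery("GGATTTT", c(0L, 7L), motif = "GGAUUUU"), 0L)
  expect_length(find_slippery("ACGTACGTACG", c(0L, 11L)), 0L)
  s <- paste0(rand_dna(20), "CACTTTT", rand_dna(20))
  expect_equal(find_slippery(s, c(10L, 40L), motif = "CACUUUU"), 20L)
  expect_length(find_slippery(s, c(0L, 10L), motif = "CACUUUU"), 0L)
  expect_error(find_slippery(s, c(0L, 10L), motif = "AAAAAAA"), "motif")
})

test_that("planted TRS and slippery sites are recovered exactly", {
  sim <- canonical_sim()
  rec <- trim_polya(sim$record)
  hits <- rbind(scan_motif(rec$seq, "AUxxUACUACUACUA"),
                scan_motif(rec$seq, "AGAx(x)ACUCUCCCA"))
  expect_equal(sort(hits$start), sort(sim$truth$trs$start))
  hp <- sim$truth$slippery
  o <- sim$truth$orfs
  expect_equal(find_slippery(rec, c(o["orf1b", "start"], o["orf1a", "end"])),
               hp$pos[hp$motif == "GGATTTT"])
  expect_equal(find_slippery(rec, c(o["orf3b", "start"], o["orf3a", "end"]),
                             motif = "CACUUUU"),
               hp$pos[hp$motif == "CACTTTT"])
})

test_that("cleavage sites follow the signalase and S1-S2 motifs", {
  cs <- find_cleavage_sites("AASLTRIDLAA")
  expect_equal(cs$kind, "signalase")
  expect_equal(cs$cut_after, 2L)         # the S before LTRIDL

  cs2 <- find_cleavage_sites("MRWDSSYVK")
  expect_equal(cs2$kind, "S1S2")
  expect_equal(cs2$cut_after, 1L)        # the R before WDSSYV

  expect_equal(nrow(find_cleavage_sites("AAAA")), 0L)
  # C-variant of the signalase site, as in the CavV S polyprotein
  cs3 <- find_cleavage_sites("MNAHCSTRIDLM")
  expect_equal(cs3$kind[1], "signalase")
  expect_equal(cs3$cut_after, 4L)
})
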