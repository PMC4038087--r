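test_that("read_fasta normalizes RNA to DNA and preserves order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGU", ">y desc", "ttgg"), f)
  recs <- read_fasta(f)
  expect_named(recs, c("x", "y"))
  expect_equal(recs$x$seq, "ACGT")
  expect_equal(recs$y$seq, "TTGG")
})

test_that("read_fasta rejects ambiguity codes by default, names the record", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGN"), f)
  expect_error(read_fasta(f), "x")
  recs <- read_fasta(f, allow_ambiguous = TRUE)
  expect_equal(recs$x$seq, "ACGN")
})

test_that("empty FASTA is a format error", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "format error")
})

test_that("write_fasta then read_fasta is identity on normalized records", {
  recs <- list(genome_record("a", rand_dna(150)),
               genome_record("b", rand_dna(71)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(vapply(back, `[[`, "", "seq"),
               vapply(recs, `[[`, "", "seq"), ignore_attr = TRUE)
  # wrapped at 70 columns
  expect_lte(max(nchar(readLines(f))), 70L)
})

test_that("trim_polya removes long tails, leaves short runs, is idempotent", {
  r <- genome_record("g", paste0("ACGT", strrep("A", 10)))
  t1 <- trim_polya(r, min_run = 5)
  expect_equal(t1$seq, "ACGT")
  expect_equal(t1$polya_len, 10L)
  expect_equal(trim_polya(t1, 5)$seq, t1$seq)

  r2 <- genome_record("g", "ACGTAAA")
  t2 <- trim_polya(r2, min_run = 5)
  expect_equal(t2$seq, "ACGTAAA")
  expect_equal(t2$polya_len, 0L)

  expect_error(trim_polya(genome_record("g", "AAAAAA")), "degenerate")
})

test_that("generator poly-A tail trims back to the planted body length", {
  sim <- canonical_sim()
  tr <- trim_polya(sim$record)
  expect_equal(nchar(tr$seq), sim$truth$body_len)
  expect_equal(tr$polya_len, sim$truth$spec$polya_len)
})

test_that("write_gff3 uses 1-based inclusive coordinates and + strand", {
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feature("g1", "ORF1a", 359L, 12000L, type = "CDS"), f)
  lines <- grep("^[^#]", readLines(f), value = TRUE)
  cols <- strsplit(lines[1], "\t")[[1]]
  expect_equal(as.integer(cols[4:5]), c(360L, 12000L))
  expect_equal(cols[7], "+")
})

test_that("empty feature list gives a valid header-only GFF3", {
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(NULL, f)
  lines <- readLines(f)
  expect_true(grepl("gff-version 3", lines[1]))
  expect_true(all(grepl("^#", lines)))
})

test_that("duplicate features are rejected", {
  fe <- rbind(feature("g", "x", 0L, 10L), feature("g", "x", 0L, 10L))
  expect_error(write_gff3(fe, tempfile()), "duplicate")
})

test_that("GFF3 write-then-read round-trips a planted architecture", {
  sim <- canonical_sim()
  rep <- annotate_genome(sim$record)
  a <- rep$annotations[[1]]
  fe <- mesoniv:::.features_of(a$record, a$architecture, a$trs)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(fe, f)
  back <- read_gff3(f)
  expect_equal(nrow(back), nrow(fe))
  o1 <- fe[order(fe$name, fe$start), c("name", "start", "end", "frame")]
  o2 <- back[order(back$name, back$start), c("name", "start", "end", "frame")]
  expect_equal(o1, o2, ignore_attr = TRUE)
  # structural validity: 9 tab-separated columns, start <= end
  lines <- grep("^[^#]", readLines(f), value = TRUE)
  expect_true(all(lengths(strsplit(lines, "\t")) == 9L))
})
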