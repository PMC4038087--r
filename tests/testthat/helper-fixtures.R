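# Shared fixtures and independent oracles used across test files.

.fixture_env <- new.env()

# memoized canonical synthetic genome (generation is deterministic per spec)
canonical_sim <- function(seed = 42L, insertion_len = 0L) {
  key <- sprintf("sim_%d_%d", seed, insertion_len)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_genome(
      genome_spec(seed = seed, insertion_len = insertion_len))
  .fixture_env[[key]]
}

# reference domain set taken from a simulation's own truth table
refset_of <- function(sim) {
  vapply(rownames(sim$truth$domains), function(dn)
    substr(sim$truth$pp1ab, sim$truth$domains[dn, "start"] + 1L,
           sim$truth$domains[dn, "end"]), character(1))
}

# compare an assigned architecture against a truth table; returns character
# vector of mismatch descriptions (empty = full agreement)
arch_mismatches <- function(arch, truth) {
  bad <- character(0)
  for (nm in rownames(truth$orfs)) {
    o <- arch[[nm]]
    if (is.null(o)) { bad <- c(bad, paste(nm, "absent")); next }
    if (o$start != truth$orfs[nm, "start"] || o$end != truth$orfs[nm, "end"])
      bad <- c(bad, sprintf("%s [%d,%d) != [%d,%d)", nm, o$start, o$end,
                            truth$orfs[nm, "start"], truth$orfs[nm, "end"]))
  }
  if (!identical(unname(arch$utr5), unname(truth$utr5)))
    bad <- c(bad, "utr5")
  if (!identical(unname(arch$term3), unname(truth$term3)))
    bad <- c(bad, "term3")
  if (!setequal(arch$slippery_sites$pos, truth$slippery$pos))
    bad <- c(bad, "slippery positions")
  bad
}

# brute-force optimal affine-gap global alignment score by explicit
# enumeration of every alignment path (exponential; for tiny sequences only)
brute_align_score <- function(a, b, match = 5, mismatch = -4,
                              gap_open = 10, gap_extend = 0.5) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  paths <- function(i, j) {
    if (i == 0L && j == 0L) return(list(character(0)))
    out <- list()
    if (i > 0L && j > 0L)
      out <- c(out, lapply(paths(i - 1L, j - 1L), function(p) c(p, "M")))
    if (i > 0L)
      out <- c(out, lapply(paths(i - 1L, j), function(p) c(p, "X")))
    if (j > 0L)
      out <- c(out, lapply(paths(i, j - 1L), function(p) c(p, "Y")))
    out
  }
  score_path <- function(ops) {
    ai <- 0L; bi <- 0L; s <- 0
    for (op in ops) {
      if (op == "M") {
        ai <- ai + 1L; bi <- bi + 1L
        s <- s + if (ca[ai] == cb[bi]) match else mismatch
      } else if (op == "X") ai <- ai + 1L else bi <- bi + 1L
    }
    r <- rle(ops)
    gaps <- r$lengths[r$values != "M"]
    s - sum(gap_open + gaps * gap_extend)
  }
  max(vapply(paths(n, m), score_path, numeric(1)))
}

# brute-force degenerate-motif matcher: expand optional symbols, compare
# character-wise at every offset, report the longest match per position
brute_scan_motif <- function(seq, pattern) {
  p <- chartr("U", "T", toupper(pattern))
  toks <- list(); i <- 1L
  pc <- strsplit(p, "")[[1]]
  while (i <= length(pc)) {
    if (pc[i] == "(") { toks[[length(toks) + 1L]] <- list(sym = pc[i + 1L],
                                                          opt = TRUE)
      i <- i + 3L
    } else { toks[[length(toks) + 1L]] <- list(sym = pc[i], opt = FALSE)
      i <- i + 1L }
  }
  opt_idx <- which(vapply(toks, `[[`, logical(1), "opt"))
  combos <- if (length(opt_idx))
    expand.grid(rep(list(c(TRUE, FALSE)), length(opt_idx)))
  else data.frame(row.names = 1)
  sc <- strsplit(toupper(seq), "")[[1]]
  hits <- list()
  for (pos in seq_along(sc)) {
    best <- -1L
    for (ci in seq_len(nrow(combos))) {
      keep <- rep(TRUE, length(toks))
      if (length(opt_idx)) keep[opt_idx] <- unlist(combos[ci, ])
      syms <- vapply(toks[keep], `[[`, character(1), "sym")
      if (pos + length(syms) - 1L > length(sc)) next
      window <- sc[pos:(pos + length(syms) - 1L)]
      ok <- all(syms == "X" | syms == window)
      if (ok && length(syms) > best) best <- length(syms)
    }
    if (best > 0L)
      hits[[length(hits) + 1L]] <- data.frame(start = pos - 1L,
                                              end = pos - 1L + best)
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer()))
  do.call(rbind, hits)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
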