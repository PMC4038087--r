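# Synthetic mesonivirus-like genomes with a fully known truth table, plus
# controlled-divergence sequence evolution. The generator is the pipeline's
# ground-truth oracle: every feature is planted by construction and the
# emitted truth table is verified against independent string scans before a
# genome is returned.

# run code under a temporary RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.TRS1_INSTANCE <- "ATGGTACTACTACTA"   # matches AUxxUACUACUACUA
.TRS2_INSTANCE <- "AGAGGACTCTCCCA"    # matches AGAx(x)ACUCUCCCA (2-base form)
.TRS1_PATTERN <- "AUxxUACUACUACUA"
.TRS2_PATTERN <- "AGAx(x)ACUCUCCCA"
# stop codons in all three frames, to terminate spurious ORFs in gaps
.TERMINATOR <- "TAAATAAATAA"

#' Specification of a synthetic mesonivirus-like genome
#'
#' Default lengths give a ~19.9-kb genome body matching the canonical plan:
#' a 360-nt 5' UTR, ORF1a of 7854 nt overlapped in the -1 frame by ORF1b
#' (GGAUUUU slippery heptamer), a nested nucleoprotein ORF (ORF2b) inside the
#' spike ORF (ORF2a), overlapping ORF3a/ORF3b with a CACUUUU heptamer, a
#' small ORF4, a 1790-nt 3' terminal region and a 25-nt poly-A tail. An
#' optional in-frame block insertion in the 5' region of ORF1a carries
#' imperfect copies of an SKRKGK-like repeat at its terminal points.
#'
#' @param utr5_len 5' UTR length (>= 60).
#' @param orf1a_len ORF1a length in nt including its stop (multiple of 3).
#' @param orf1b_ext nt from the ORF1a end to the ORF1b end (= 2 mod 3).
#' @param overlap_1ab length of the dual-frame ORF1a/1b overlap kept
#'   stop-free in both frames (multiple of 3, >= 51).
#' @param gap_1b_2a,gap_2a_3a,orf4_gap intergenic spacer lengths (>= 40).
#' @param orf2a_len,orf2b_len,orf3a_len,orf4_len ORF lengths in nt incl. stop
#'   (multiples of 3).
#' @param orf2b_offset ORF2b start relative to ORF2a start (= 1 mod 3).
#' @param orf3b_ext nt from the ORF3a end to the ORF3b end (= 2 mod 3).
#' @param term3_len 3' terminal region length.
#' @param polya_len poly-A tail length (>= 0).
#' @param insertion_len ORF1a block-insertion length in nt (multiple of 3;
#'   0, 180, 573 and 588 are typical).
#' @param insertion_offset insertion point within ORF1a, nt (multiple of 3).
#' @param repeat_seed amino-acid seed planted (imperfectly) at the insertion
#'   terminal points.
#' @param leader_trs_pos position of the leader TRS inside the 5' UTR.
#' @param seed random seed; generation is deterministic given the spec.
#' @return object of class `meso_spec` (validated).
#' @export
genome_spec <- function(utr5_len = 360L, orf1a_len = 7854L,
                        orf1b_ext = 4682L, overlap_1ab = 57L,
                        gap_1b_2a = 60L, orf2a_len = 3852L,
                        orf2b_offset = 70L, orf2b_len = 672L,
                        gap_2a_3a = 50L, orf3a_len = 603L,
                        orf3b_ext = 374L, orf4_gap = 120L, orf4_len = 150L,
                        term3_len = 1790L, polya_len = 25L,
                        insertion_len = 0L, insertion_offset = 939L,
                        repeat_seed = "SKRKGK", leader_trs_pos = 20L,
                        seed = 1L) {
  s <- as.list(environment())
  s[] <- lapply(s, function(x) if (is.numeric(x)) as.integer(x) else x)
  s$repeat_seed <- repeat_seed
  with(s, {
    if (utr5_len < 60L) stop("spec error: utr5_len must be >= 60")
    if (orf1a_len %% 3L || orf1a_len < 6000L)
      stop("spec error: orf1a_len must be a multiple of 3 and >= 6000")
    if (orf1b_ext %% 3L != 2L || orf1b_ext < 900L)
      stop("spec error: orf1b_ext must be = 2 mod 3 and >= 900")
    if (overlap_1ab %% 3L || overlap_1ab < 51L)
      stop("spec error: overlap_1ab must be a multiple of 3 and >= 51")
    if (orf2a_len %% 3L || orf2a_len < 2400L)
      stop("spec error: orf2a_len must be a multiple of 3 and >= 2400")
    if (orf2b_offset %% 3L != 1L || orf2b_offset < 10L)
      stop("spec error: orf2b_offset must be = 1 mod 3 and >= 10")
    if (orf2b_len %% 3L || orf2b_len < 330L)
      stop("spec error: orf2b_len must be a multiple of 3 and >= 330")
    if (orf2b_offset + orf2b_len > orf2a_len - 3L ||
        orf2b_offset >= orf2a_len %/% 3L)
      stop("spec error: ORF2b does not fit in the 5' third of ORF2a")
    if (orf3a_len %% 3L || orf3a_len < 300L)
      stop("spec error: orf3a_len must be a multiple of 3 and >= 300")
    if (orf3b_ext %% 3L != 2L || orf3b_ext < 100L)
      stop("spec error: orf3b_ext must be = 2 mod 3 and >= 100")
    if (orf4_len %% 3L || orf4_len < 126L || orf4_len > 198L)
      stop("spec error: orf4_len must be a multiple of 3 in [126, 198]")
    if (min(gap_1b_2a, gap_2a_3a, orf4_gap) < 40L)
      stop("spec error: intergenic gaps must be >= 40 nt")
    if (insertion_len %% 3L || insertion_len < 0L)
      stop("spec error: insertion_len must be a non-negative multiple of 3")
    if (insertion_len > 0L && insertion_len < 9L)
      stop("spec error: insertion_len must be 0 or >= 9")
    if (insertion_offset %% 3L || insertion_offset < 300L ||
        insertion_offset > orf1a_len %/% 2L)
      stop("spec error: insertion_offset must be a multiple of 3 in the 5' half")
    if (leader_trs_pos < 0L || leader_trs_pos + 15L > utr5_len - 3L)
      stop("spec error: leader TRS does not fit in the 5' UTR")
  })
  structure(s, class = "meso_spec")
}

#' @export
print.meso_spec <- function(x, ...) {
  body <- x$utr5_len + x$orf1a_len + x$insertion_len + x$orf1b_ext +
    x$gap_1b_2a + x$orf2a_len + x$gap_2a_3a + x$orf3a_len + x$orf3b_ext +
    x$orf4_gap + x$orf4_len + x$term3_len
  cat(sprintf("<meso_spec> %d-nt body + %d-nt poly-A (seed %d, insertion %d nt)\n",
              body, x$polya_len, x$seed, x$insertion_len))
  invisible(x)
}

.rand_nt <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

.sense_env <- new.env(parent = emptyenv())
.sense61 <- function() {
  if (is.null(.sense_env$s)) .sense_env$s <- .sense_codons()
  .sense_env$s
}
.rand_sense <- function(n) sample(.sense61(), n, replace = TRUE)
.rand_stop <- function(n = 1L) sample(.STOPS, n, replace = TRUE)
# T-starting sense codons (for the base after a planted heptamer)
.t_sense <- function() grep("^T", setdiff(.sense61(), .STOPS), value = TRUE)

# biased residue composition emulating the highly basic N protein (pI > 10)
.basic_codons <- function(n) {
  comp <- c(K = 0.13, R = 0.12, D = 0.02, E = 0.02, C = 0.02, Y = 0.02)
  rest <- setdiff(.AA20, names(comp))
  p <- c(comp, stats::setNames(rep((1 - sum(comp)) / length(rest),
                                   length(rest)), rest))
  aa <- sample(names(p), n, replace = TRUE, prob = p)
  cf <- .codons_for()
  vapply(aa, function(a) sample(cf[[a]], 1L), character(1))
}

# random codon encoding of a peptide
.encode_peptide <- function(aa) {
  cf <- .codons_for()
  vapply(.chars(aa), function(a) {
    cc <- cf[[a]]
    if (is.null(cc)) stop("cannot encode residue ", a)
    cc[sample.int(length(cc), 1L)]
  }, character(1))
}

# imperfect copy of a codon block: mutate k positions, never creating a stop
.imperfect_copy <- function(codons, k = 1L) {
  nt <- .chars(paste(codons, collapse = ""))
  for (i in seq_len(k)) {
    repeat {
      p <- sample.int(length(nt), 1L)
      old <- nt[p]
      nt[p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      cod <- substring(paste(nt, collapse = ""),
                       seq(1L, length(nt) - 2L, 3L), seq(3L, length(nt), 3L))
      if (!any(cod %in% .STOPS)) break
      nt[p] <- old
    }
  }
  substring(paste(nt, collapse = ""),
            seq(1L, length(nt) - 2L, 3L), seq(3L, length(nt), 3L))
}

# --- independent verification scans (plain regex/string ops) ---------------

.pos_all <- function(seq, pat, fixed = TRUE) {
  m <- gregexpr(pat, seq, fixed = fixed, perl = !fixed)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L  # 0-based
}

# ATG->stop ORFs (first ATG per open segment), via position arithmetic only
.scan_atg_orfs_indep <- function(seq) {
  stops0 <- sort(c(.pos_all(seq, "TAA"), .pos_all(seq, "TAG"),
                   .pos_all(seq, "TGA")))
  atg0 <- .pos_all(seq, "ATG")
  out <- list()
  for (f in 0:2) {
    st <- stops0[stops0 %% 3L == f]
    at <- atg0[atg0 %% 3L == f]
    if (!length(st) || !length(at)) next
    nxt <- st[findInterval(at, st) + 1L]      # first stop strictly after atg
    ok <- !is.na(nxt)
    seg <- paste0(f, "_", nxt[ok])
    first <- !duplicated(seg)
    out[[f + 1L]] <- data.frame(start = at[ok][first],
                                end = nxt[ok][first] + 3L, frame = f)
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      frame = integer()))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

.verify_truth <- function(seq, tr) {
  orfs <- .scan_atg_orfs_indep(seq)
  len <- orfs$end - orfs$start
  first_match <- function(cond) {
    i <- which(cond)[1]
    if (is.na(i)) c(NA_integer_, NA_integer_)
    else c(orfs$start[i], orfs$end[i])
  }
  eq <- function(got, want) !anyNA(got) && all(got == want)
  o <- tr$orfs
  if (!eq(first_match(len >= 3000L), o["orf1a", c("start", "end")]))
    return("orf1a rule")
  if (!eq(first_match(len >= 2000L & orfs$start >= o["orf1b", "end"]),
          o["orf2a", c("start", "end")])) return("orf2a rule")
  s2a <- o["orf2a", "start"]; e2a <- o["orf2a", "end"]
  third <- s2a + (e2a - s2a) %/% 3L
  c2b <- which(orfs$frame != s2a %% 3L & orfs$start >= s2a &
                 orfs$start < third & orfs$end <= e2a & len >= 330L)
  if (!length(c2b)) return("orf2b missing")
  best <- c2b[order(-len[c2b], orfs$start[c2b])][1]
  if (!eq(c(orfs$start[best], orfs$end[best]),
          o["orf2b", c("start", "end")])) return("orf2b rule")
  if (!eq(first_match(len >= 500L & orfs$start >= e2a),
          o["orf3a", c("start", "end")])) return("orf3a rule")
  s3a <- o["orf3a", "start"]; e3a <- o["orf3a", "end"]
  half <- s3a + (e3a - s3a) %/% 2L
  c3b <- which(orfs$frame != s3a %% 3L & orfs$start < e3a &
                 orfs$end > half & len >= 150L)
  c3b <- setdiff(c3b, c(best, which(orfs$start == s2a)))
  if (!length(c3b)) return("orf3b missing")
  b3 <- c3b[order(-len[c3b], orfs$start[c3b])][1]
  if (!eq(c(orfs$start[b3], orfs$end[b3]), o["orf3b", c("start", "end")]))
    return("orf3b rule")
  e3b <- o["orf3b", "end"]
  if (!eq(first_match(len >= 120L & len <= 200L & orfs$start >= e3b),
          o["orf4", c("start", "end")])) return("orf4 rule")
  # slippery heptamers unique within their overlaps
  hp <- tr$slippery$pos[tr$slippery$motif == "GGATTTT"]
  span1 <- substr(seq, o["orf1b", "start"] + 1L, o["orf1a", "end"])
  if (length(.pos_all(span1, "GGATTTT")) != 1L) return("GGATTTT not unique")
  span3 <- substr(seq, o["orf3b", "start"] + 1L, e3a)
  if (length(.pos_all(span3, "CACTTTT")) != 1L) return("CACTTTT not unique")
  # TRS instances unique genome-wide
  t1 <- .pos_all(seq, "AT[ACGT][ACGT]TACTACTACTA", fixed = FALSE)
  if (!identical(t1, sort(tr$trs$start[tr$trs$pattern_id == .TRS1_PATTERN])))
    return("TRS1 spurious/missing")
  t2 <- .pos_all(seq, "AGA[ACGT][ACGT]?ACTCTCCCA", fixed = FALSE)
  if (!identical(t2, tr$trs$start[tr$trs$pattern_id == .TRS2_PATTERN]))
    return("TRS2 spurious/missing")
  if (grepl("*", tr$pp1ab, fixed = TRUE)) return("pp1ab contains stop")
  if (grepl("*", tr$p3ab, fixed = TRUE)) return("p3ab contains stop")
  # ORF1b open segment: no stop in the -1 frame across the planted segment
  b1b <- o["orf1b", "start"]; e1b <- o["orf1b", "end"]
  seg <- substr(seq, b1b + 1L, e1b)
  cod <- substring(seg, seq(1L, nchar(seg) - 2L, 3L), seq(3L, nchar(seg), 3L))
  if (any(cod[-length(cod)] %in% .STOPS) || !(cod[length(cod)] %in% .STOPS))
    return("orf1b segment not open")
  NULL
}

# --- the generator ----------------------------------------------------------

# resample free ORF-frame codons until a cross-frame window set is stop-free
.repair_cross_frame <- function(chars, check_starts, resample,
                                max_iter = 500L) {
  for (it in seq_len(max_iter)) {
    win <- substring(paste(chars, collapse = ""), check_starts + 1L,
                     check_starts + 3L)
    bad <- check_starts[win %in% .STOPS]
    if (!length(bad)) return(chars)
    for (p in bad) chars <- resample(chars, p)
    if (it == max_iter) stop("dual-frame repair failed")
  }
  chars
}

#' Generate a synthetic mesonivirus-like genome with its truth table
#'
#' Plants the full canonical architecture (see [genome_spec()]): leader and
#' body TRS elements, a stop-free -1-frame ORF1b overlap with a GGAUUUU
#' heptamer, a nested basic ORF2b, overlapping ORF3a/3b with CACUUUU, ORF4,
#' an optional ORF1a block insertion with imperfect terminal repeats, and a
#' poly-A tail. Generation is deterministic for a fixed spec (including its
#' seed) and the emitted truth table is verified by independent string scans;
#' the generator retries with a derived seed in the rare event a random
#' filler region violates a uniqueness rule.
#'
#' @param spec a [genome_spec()].
#' @param id genome identifier (default derived from the seed).
#' @return list of class `meso_sim` with elements `record` (a
#'   [genome_record()], poly-A still attached) and `truth` (planted
#'   coordinates, motif positions, fusion proteins, domain spans).
#' @export
make_genome <- function(spec = genome_spec(), id = NULL) {
  stopifnot(inherits(spec, "meso_spec"))
  if (is.null(id)) id <- sprintf("synth_%d", spec$seed)
  for (attempt in 0:19) {
    seed <- (spec$seed + attempt * 1000003L) %% .Machine$integer.max
    res <- .with_seed(seed, .make_genome_once(spec, id))
    if (is.null(res$fail)) {
      res$truth$seed_used <- seed
      res$truth$attempt <- attempt + 1L
      return(res)
    }
  }
  stop("generator error: could not satisfy uniqueness rules (last: ",
       res$fail, ")")
}

.make_genome_once <- function(spec, id) {
  sp <- spec
  n_rep <- nchar(sp$repeat_seed)
  orf1a_eff <- sp$orf1a_len + sp$insertion_len
  s1a <- sp$utr5_len
  e1a <- s1a + orf1a_eff
  e1b <- e1a + sp$orf1b_ext
  s2a <- e1b + sp$gap_1b_2a
  e2a <- s2a + sp$orf2a_len
  s2b <- s2a + sp$orf2b_offset
  e2b <- s2b + sp$orf2b_len
  s3a <- e2a + sp$gap_2a_3a
  e3a <- s3a + sp$orf3a_len
  s3b <- e3a - 76L
  e3b <- e3a + sp$orf3b_ext
  hp <- e1a - 48L
  hp3 <- e3a - 45L
  s4 <- e3b + sp$orf4_gap
  e4 <- s4 + sp$orf4_len
  L <- e4 + sp$term3_len
  ov1 <- e1a - sp$overlap_1ab

  g <- .rand_nt(L)

  put <- function(g, pos0, txt) {        # plant a string at 0-based pos
    g[(pos0 + 1L):(pos0 + nchar(txt))] <- .chars(txt)
    g
  }

  # 5' UTR: leader TRS + in-frame stop guarding the ORF1a start
  g <- put(g, sp$leader_trs_pos, .TRS1_INSTANCE)
  g <- put(g, s1a - 3L, "TAA")

  # ORF1a codons (with optional insertion and the GGATTTT heptamer)
  cod1a <- .rand_sense(sp$orf1a_len %/% 3L)
  cod1a[1L] <- "ATG"
  ins_truth <- NULL
  if (sp$insertion_len > 0L) {
    n_ins <- sp$insertion_len %/% 3L
    rep_cod <- .encode_peptide(sp$repeat_seed)
    ins <- .rand_sense(n_ins)
    if (n_ins >= 2L * n_rep + 2L) {   # imperfect copies at both ends
      ins[seq_len(n_rep)] <- .imperfect_copy(rep_cod, 1L)
      ins[(n_ins - n_rep + 1L):n_ins] <- .imperfect_copy(rep_cod, 1L)
    } else {                          # short block: one (truncated) copy
      k <- min(n_rep, n_ins)
      ins[seq_len(k)] <- .imperfect_copy(rep_cod[seq_len(k)], 1L)
    }
    if (n_ins >= 3L * n_rep + 4L) {  # one extra imperfect interior copy
      mid <- n_ins %/% 2L - n_rep %/% 2L
      ins[mid:(mid + n_rep - 1L)] <- .imperfect_copy(rep_cod, 2L)
    }
    at <- sp$insertion_offset %/% 3L
    cod1a <- append(cod1a, ins, after = at)
    ins_truth <- list(span = .span(s1a + sp$insertion_offset,
                                   s1a + sp$insertion_offset + sp$insertion_len),
                      repeat_seed = sp$repeat_seed)
  }
  n1a <- length(cod1a)
  cod1a[n1a] <- .rand_stop()
  ch <- (orf1a_eff - 48L) %/% 3L + 1L
  cod1a[ch] <- "GGA"; cod1a[ch + 1L] <- "TTT"
  cod1a[ch + 2L] <- sample(.t_sense(), 1L)
  g[(s1a + 1L):e1a] <- .chars(paste(cod1a, collapse = ""))

  # dual-frame overlap [ov1, e1a): keep -1-frame codons stop-free.
  f1b_starts <- seq.int(ov1 - 1L, e1a - 3L, by = 3L)
  protected1a <- c(1L, n1a, ch, ch + 1L, ch + 2L)
  resample1a <- function(g, p) {
    # p = 0-based start of an offending -1-frame codon; resample the free
    # ORF1a codons overlapping it
    idx <- unique((c(p, p + 2L) - s1a) %/% 3L + 1L)
    idx <- setdiff(idx, setdiff(protected1a, n1a))
    for (i in idx) {
      newc <- if (i == n1a) .rand_stop() else .rand_sense(1L)
      g[(s1a + (i - 1L) * 3L + 1L):(s1a + i * 3L)] <- .chars(newc)
    }
    g
  }
  g <- .repair_cross_frame(g, f1b_starts, resample1a)

  # ORF1b tail [e1a, e1b): -1-frame codons, stop-free, terminal stop
  c0 <- repeat_c0 <- NULL
  repeat {
    cand <- paste0(g[e1a], paste(.rand_nt(2L), collapse = ""))
    if (!cand %in% .STOPS) { c0 <- cand; break }
  }
  g[(e1a + 1L):(e1a + 2L)] <- .chars(substr(c0, 2L, 3L))
  mid_starts <- seq.int(e1a + 2L, e1b - 6L, by = 3L)
  g[(e1a + 3L):(e1b - 3L)] <- .chars(paste(.rand_sense(length(mid_starts)),
                                           collapse = ""))
  g <- put(g, e1b - 3L, .rand_stop())

  # gap ORF1b -> ORF2a: terminator, body TRS, guard stop
  g <- put(g, e1b, .TERMINATOR)
  g <- put(g, s2a - 30L, .TRS1_INSTANCE)
  g <- put(g, s2a - 3L, "TAA")

  # ORF2a with nested, K/R-rich ORF2b
  cod2a <- .rand_sense(sp$orf2a_len %/% 3L)
  cod2a[1L] <- "ATG"; cod2a[length(cod2a)] <- .rand_stop()
  g[(s2a + 1L):e2a] <- .chars(paste(cod2a, collapse = ""))
  n2b_mid <- (sp$orf2b_len - 6L) %/% 3L
  g <- put(g, s2b - 3L, "TAA")                       # segment guard for ORF2b
  g <- put(g, s2b, paste0("ATG", paste(.basic_codons(n2b_mid), collapse = ""),
                          "TAA"))
  # repair ORF2a frame around the planted 2b block
  f2a_starts <- seq.int(s2a, e2a - 3L, by = 3L)
  fixed2 <- rep(FALSE, L)
  fixed2[(s2b - 3L + 1L):e2b] <- TRUE                # 2b chars + guard stop
  fixed2[(s2a + 1L):(s2a + 3L)] <- TRUE              # 2a ATG
  fixed2[(e2a - 2L):e2a] <- TRUE                     # 2a stop
  resample2 <- function(g, p) {
    pos <- (p + 1L):(p + 3L)
    free <- pos[!fixed2[pos]]
    if (!length(free)) {
      # fully fixed: resample the downstream interior 2b codon covering it
      k <- (p + 2L - s2b) %/% 3L + 1L               # 1-based 2b codon index
      k <- min(max(k, 2L), n2b_mid + 1L)            # interior only
      cstart <- s2b + (k - 1L) * 3L
      g[(cstart + 1L):(cstart + 3L)] <- .chars(.basic_codons(1L))
      return(g)
    }
    g[free] <- .rand_nt(length(free))
    g
  }
  g <- .repair_cross_frame(g, f2a_starts[-length(f2a_starts)], resample2)
  # and keep the 2b frame stop-free (interior) after any repairs
  f2b_starts <- seq.int(s2b + 3L, e2b - 6L, by = 3L)
  resample2b <- function(g, p) {
    g[(p + 1L):(p + 3L)] <- .chars(.basic_codons(1L))
    g
  }
  g <- .repair_cross_frame(g, f2b_starts, resample2b)
  # interplay between the two repairs is local; re-check 2a once more
  win <- substring(paste(g, collapse = ""), f2a_starts[-length(f2a_starts)] + 1L,
                   f2a_starts[-length(f2a_starts)] + 3L)
  if (any(win %in% .STOPS)) return(list(fail = "orf2a/2b repair"))

  # gap ORF2a -> ORF3a
  g <- put(g, e2a, .TERMINATOR)
  g <- put(g, s3a - 25L, .TRS2_INSTANCE)
  g <- put(g, s3a - 3L, "TAA")

  # ORF3a with CACTTTT heptamer, overlapped by ORF3b
  cod3a <- .rand_sense(sp$orf3a_len %/% 3L)
  cod3a[1L] <- "ATG"; cod3a[length(cod3a)] <- .rand_stop()
  ch3 <- (sp$orf3a_len - 45L) %/% 3L + 1L
  cod3a[ch3] <- "CAC"; cod3a[ch3 + 1L] <- "TTT"
  cod3a[ch3 + 2L] <- sample(.t_sense(), 1L)
  g[(s3a + 1L):e3a] <- .chars(paste(cod3a, collapse = ""))
  g <- put(g, s3b - 3L, "TAA")                       # segment guard for ORF3b
  g <- put(g, s3b, "ATG")
  # keep ORF3a frame stop-free around the planted 3b chars
  f3a_starts <- seq.int(s3a, e3a - 6L, by = 3L)
  fixed3 <- rep(FALSE, L)
  fixed3[(s3b - 3L + 1L):(s3b + 3L)] <- TRUE         # guard + 3b ATG
  fixed3[(s3a + 1L):(s3a + 3L)] <- TRUE
  fixed3[(e3a - 2L):e3a] <- TRUE
  fixed3[(s3a + (ch3 - 1L) * 3L + 1L):(s3a + (ch3 + 2L) * 3L)] <- TRUE
  resample3 <- function(g, p) {
    pos <- (p + 1L):(p + 3L)
    free <- pos[!fixed3[pos]]
    if (!length(free)) return(g)    # cannot happen: guards shown stop-safe
    g[free] <- .rand_nt(length(free))
    g
  }
  g <- .repair_cross_frame(g, f3a_starts, resample3)
  # ORF3b frame: dual region [s3b+3, e3a) stop-free, resampling free 3a codons
  f3b_dual <- seq.int(s3b + 3L, e3a - 4L, by = 3L)
  resample3b <- function(g, p) {
    idx <- unique((c(p, p + 2L) - s3a) %/% 3L + 1L)
    for (i in idx) {
      cstart <- s3a + (i - 1L) * 3L
      pos <- (cstart + 1L):(cstart + 3L)
      free <- pos[!fixed3[pos]]
      if (length(free)) g[free] <- .rand_nt(length(free))
    }
    g
  }
  for (it in 1:500) {
    win3b <- substring(paste(g, collapse = ""), f3b_dual + 1L, f3b_dual + 3L)
    win3a <- substring(paste(g, collapse = ""), f3a_starts + 1L,
                       f3a_starts + 3L)
    bad3b <- f3b_dual[win3b %in% .STOPS]
    bad3a <- f3a_starts[win3a %in% .STOPS]
    if (!length(bad3b) && !length(bad3a)) break
    for (p in bad3b) g <- resample3b(g, p)
    for (p in bad3a) g <- resample3(g, p)
    if (it == 500L) return(list(fail = "orf3a/3b repair"))
  }
  # ORF3b tail [e3a, e3b)
  repeat {
    cand <- paste0(g[e3a], paste(.rand_nt(2L), collapse = ""))
    if (!cand %in% .STOPS) break
  }
  g[(e3a + 1L):(e3a + 2L)] <- .chars(substr(cand, 2L, 3L))
  mid3 <- seq.int(e3a + 2L, e3b - 6L, by = 3L)
  g[(e3a + 3L):(e3b - 3L)] <- .chars(paste(.rand_sense(length(mid3)),
                                           collapse = ""))
  g <- put(g, e3b - 3L, .rand_stop())
  # check the -1-frame codon spanning the ORF3a stop
  sp3 <- substring(paste(g, collapse = ""), e3a - 3L, e3a - 1L)
  if (sp3 %in% .STOPS) return(list(fail = "orf3b stop-spanning codon"))

  # gap -> ORF4
  g <- put(g, e3b, .TERMINATOR)
  g <- put(g, s4 - 14L, .TERMINATOR)
  g <- put(g, s4 - 3L, "TAA")
  cod4 <- .rand_sense(sp$orf4_len %/% 3L)
  cod4[1L] <- "ATG"; cod4[length(cod4)] <- .rand_stop()
  g[(s4 + 1L):e4] <- .chars(paste(cod4, collapse = ""))

  # the body must not end in A or the poly-A tail would absorb it at trim time
  g[L] <- sample(c("C", "G", "T"), 1L)
  body <- paste(g, collapse = "")

  # -1-frame codon spanning the ORF1a stop
  sp1 <- substr(body, e1a - 3L, e1a - 1L)
  if (sp1 %in% .STOPS) return(list(fail = "orf1b stop-spanning codon"))

  # ORF1b segment start: last -1-frame stop upstream of the overlap
  f1b_phase <- (s1a + 2L) %% 3L
  scan_starts <- seq.int(f1b_phase, ov1 - 4L, by = 3L)
  scod <- substring(body, scan_starts + 1L, scan_starts + 3L)
  last_stop <- scan_starts[max(which(scod %in% .STOPS))]
  if (!length(last_stop) || is.infinite(last_stop)) last_stop <- f1b_phase - 3L
  b1b <- last_stop + 3L

  # fusion products (join arithmetic by design: j = heptamer + 9)
  j <- hp + 9L
  pp1ab <- .translate_nt(paste0(substr(body, s1a + 1L, j),
                                substr(body, j, e1b - 3L)), drop_stop = FALSE)
  j3 <- hp3 + 9L
  p3ab <- .translate_nt(paste0(substr(body, s3a + 1L, j3),
                               substr(body, j3, e3b - 3L)), drop_stop = FALSE)

  orfs <- rbind(
    orf1a = c(s1a, e1a), orf1b = c(b1b, e1b), orf2a = c(s2a, e2a),
    orf2b = c(s2b, e2b), orf3a = c(s3a, e3a), orf3b = c(s3b, e3b),
    orf4 = c(s4, e4))
  colnames(orfs) <- c("start", "end")
  orfs <- cbind(orfs, frame = orfs[, "start"] %% 3L)

  trs <- data.frame(
    pattern_id = c(.TRS1_PATTERN, .TRS1_PATTERN, .TRS2_PATTERN),
    start = c(sp$leader_trs_pos, s2a - 30L, s3a - 25L),
    end = c(sp$leader_trs_pos + 15L, s2a - 15L, s3a - 11L),
    matched = c(.TRS1_INSTANCE, .TRS1_INSTANCE, .TRS2_INSTANCE),
    class = c("leader", "body", "body"), stringsAsFactors = FALSE)

  p1 <- (orf1a_eff - 39L) %/% 3L                 # pp1ab codons before the join
  p2 <- nchar(pp1ab) - p1
  dspan <- function(a, len) .span(a, a + len)
  domains <- rbind(
    `3CLpro` = dspan(round(p1 * 0.55), 300L),
    RdRp = dspan(p1 + round(p2 * 0.25), 300L),
    ZnHel1 = dspan(p1 + round(p2 * 0.60), min(260L, p2 - round(p2 * 0.60) - 5L)))

  truth <- list(
    body_len = L,
    utr5 = .span(0L, s1a),
    term3 = .span(e4, L),
    orfs = orfs,
    proteins = list(
      orf1a = .translate_nt(substr(body, s1a + 1L, e1a)),
      orf2a = .translate_nt(substr(body, s2a + 1L, e2a)),
      orf2b = .translate_nt(substr(body, s2b + 1L, e2b)),
      orf3a = .translate_nt(substr(body, s3a + 1L, e3a)),
      orf3b = .translate_nt(substr(body, s3b + 1L, e3b)),
      orf4 = .translate_nt(substr(body, s4 + 1L, e4))),
    trs = trs,
    slippery = data.frame(motif = c("GGATTTT", "CACTTTT"),
                          pos = c(hp, hp3), join = c(j, j3),
                          stringsAsFactors = FALSE),
    insertion = ins_truth,
    pp1ab = sub("\\*$", "", pp1ab),
    p3ab = sub("\\*$", "", p3ab),
    domains = domains,
    spec = sp)
  truth$pp1ab_raw <- pp1ab

  fail <- .verify_truth(body, truth)
  if (!is.null(fail)) return(list(fail = fail))

  rec <- genome_record(id, paste0(body, strrep("A", sp$polya_len)),
                       source = "synthetic")
  structure(list(record = rec, truth = truth), class = "meso_sim")
}

#' @export
print.meso_sim <- function(x, ...) {
  cat(sprintf("<meso_sim> %s: %d-nt body + %d-nt poly-A, %d ORFs planted\n",
              x$record$id, x$truth$body_len, x$truth$spec$polya_len,
              nrow(x$truth$orfs)))
  invisible(x)
}

#' Remove the planted block insertion from a synthetic genome
#'
#' Returns the insertion-free sibling of a genome generated with
#' `insertion_len > 0`: the same genome with the planted block spliced out,
#' so insertion detection can be tested against a reference that is
#' homologous everywhere else.
#'
#' @param sim a `meso_sim` with a planted insertion.
#' @return a [genome_record()] (poly-A attached).
#' @export
without_insertion <- function(sim) {
  stopifnot(inherits(sim, "meso_sim"))
  if (is.null(sim$truth$insertion)) stop("genome has no planted insertion")
  sp <- sim$truth$insertion$span
  seq <- sim$record$seq
  genome_record(paste0(sim$record$id, "_noins"),
                paste0(substr(seq, 1L, sp["start"]),
                       substr(seq, sp["end"] + 1L, nchar(seq))),
                source = "synthetic (insertion spliced out)")
}

#' Evolve a sequence for a given evolutionary distance
#'
#' Independent and identically distributed site evolution: Jukes-Cantor for
#' nucleotides (expected proportion of observed differences
#' \eqn{(3/4)(1 - e^{-4d/3})}) or the WAG model for amino acids. Deterministic
#' for a fixed seed.
#'
#' @param seq nucleotide or amino-acid string, per `model`.
#' @param d evolutionary distance in expected substitutions/site (>= 0).
#' @param model `"JC-nt"` or `"WAG-aa"`.
#' @param seed random seed.
#' @return evolved sequence of the same length.
#' @export
evolve_sequence <- function(seq, d, model = c("JC-nt", "WAG-aa"), seed = 1L) {
  model <- match.arg(model)
  stopifnot(d >= 0)
  if (d == 0) return(seq)
  .with_seed(seed, {
    if (model == "JC-nt") {
      x <- .chars(.norm_nt(seq))
      p_same <- 0.25 + 0.75 * exp(-4 * d / 3)
      change <- stats::runif(length(x)) > p_same
      nts <- c("A", "C", "G", "T")
      x[change] <- vapply(x[change], function(b)
        sample(setdiff(nts, b), 1L), character(1))
      paste(x, collapse = "")
    } else {
      x <- .chars(toupper(seq))
      .check_protein(seq)
      P <- prob_matrix(d, "WAG")
      out <- x
      for (a in unique(x)) {
        idx <- which(x == a)
        out[idx] <- sample(.WAG_ORDER, length(idx), replace = TRUE,
                           prob = P[a, ])
      }
      paste(out, collapse = "")
    }
  })
}

# positions that substitutions must never touch (0-based), as a logical mask
.protected_mask <- function(truth) {
  m <- rep(FALSE, truth$body_len)
  prot <- function(a, b) m[(a + 1L):b] <<- TRUE     # 0-based half-open
  for (i in seq_len(nrow(truth$trs))) prot(truth$trs$start[i], truth$trs$end[i])
  for (i in seq_len(nrow(truth$slippery)))
    prot(truth$slippery$pos[i], truth$slippery$join[i] + 1L)
  o <- truth$orfs
  for (nm in rownames(o)) {
    prot(o[nm, "start"], min(o[nm, "start"] + 3L, truth$body_len))
    prot(o[nm, "end"] - 3L, o[nm, "end"])
  }
  m
}

#' Generate a set of near-identical isolates
#'
#' Plants an exact number of nucleotide substitutions per isolate (position
#' sets disjoint across isolates, avoiding planted motifs/starts/stops so
#' conservation tests stay meaningful, and never creating a stop codon in a
#' planted reading frame), plus optional deletions in the 3' terminal region.
#'
#' @param sim a `meso_sim` from [make_genome()].
#' @param substitutions integer vector: substitution count per isolate.
#' @param indels optional list (one element per isolate) of deletion lengths
#'   to plant in the 3' terminal region.
#' @param seed random seed.
#' @return list with `records` (the isolates), `base` (the untouched base
#'   record, poly-A attached) and `truth` (positions planted per isolate).
#' @export
make_isolate_set <- function(sim, substitutions, indels = NULL, seed = 1L) {
  stopifnot(inherits(sim, "meso_sim"))
  truth <- sim$truth
  body <- substr(sim$record$seq, 1L, truth$body_len)
  polya <- strrep("A", truth$spec$polya_len)
  n <- length(substitutions)
  if (!is.null(indels)) stopifnot(length(indels) == n)
  .with_seed(seed, {
    mask <- .protected_mask(truth)
    # coding-frame map: list of (start, frame) regions to keep stop-free
    regions <- truth$orfs
    avail <- which(!mask) - 1L                      # 0-based candidate sites
    recs <- list(); placed <- list()
    for (i in seq_len(n)) {
      k <- substitutions[i]
      chars <- .chars(body)
      pos_i <- integer(0)
      tries <- 0L
      while (length(pos_i) < k) {
        tries <- tries + 1L
        if (tries > 50L * max(k, 1L) + 100L)
          stop("could not place substitutions outside protected positions")
        p <- sample(avail, 1L)
        if (p %in% pos_i) next
        old <- chars[p + 1L]
        cands <- setdiff(c("A", "C", "G", "T"), old)
        # avoid creating a stop codon in any planted frame covering p
        ok_base <- function(bnew) {
          chars2 <- chars; chars2[p + 1L] <- bnew
          for (nm in rownames(regions)) {
            st <- regions[nm, "start"]; en <- regions[nm, "end"]
            if (p < st || p >= en) next
            cst <- st + ((p - st) %/% 3L) * 3L
            cod <- paste(chars2[(cst + 1L):(cst + 3L)], collapse = "")
            if (cod %in% .STOPS) return(FALSE)
          }
          TRUE
        }
        cands <- cands[vapply(cands, ok_base, logical(1))]
        if (!length(cands)) next
        chars[p + 1L] <- sample(cands, 1L)
        pos_i <- c(pos_i, p)
        avail <- setdiff(avail, p)      # disjoint across isolates
      }
      iso_body <- paste(chars, collapse = "")
      dels <- integer(0)
      if (!is.null(indels) && length(indels[[i]])) {
        t3 <- truth$term3
        at <- t3["start"] + 50L
        for (dl in indels[[i]]) {
          iso_body <- paste0(substr(iso_body, 1L, at),
                             substr(iso_body, at + dl + 1L, nchar(iso_body)))
          dels <- c(dels, dl)
          at <- at + 100L
        }
      }
      recs[[i]] <- genome_record(sprintf("%s_iso%d", sim$record$id, i),
                                 paste0(iso_body, polya),
                                 source = "synthetic isolate")
      placed[[i]] <- list(positions = sort(pos_i), deletions = dels)
    }
    list(records = recs, base = sim$record,
         truth = list(substitutions = substitutions, planted = placed))
  })
}

#' Generate a multi-species synthetic genome set
#'
#' Builds a base genome, evolves its three replicase domains under the WAG
#' model to create species ancestors at pairwise distance ~`between_d` and
#' isolates within species at ~`within_d`, and re-encodes the evolved domain
#' residues into each genome (single-frame regions only, so the planted
#' architecture is untouched).
#'
#' @param spec base [genome_spec()].
#' @param n_species number of species.
#' @param n_per_species isolates per species.
#' @param within_d,between_d target amino-acid distances within/between
#'   species (expected substitutions/site on the domain concatenation).
#' @param seed random seed.
#' @return list with `records`, `species` (data.frame taxon/species),
#'   `refset` (the base truth domains, for [extract_domains()]) and `base`
#'   (the base `meso_sim`).
#' @export
make_species_set <- function(spec = genome_spec(), n_species = 3L,
                             n_per_species = 2L, within_d = 0.005,
                             between_d = 0.4, seed = 1L) {
  base <- make_genome(spec)
  tr <- base$truth
  refset <- vapply(rownames(tr$domains), function(dn)
    substr(tr$pp1ab, tr$domains[dn, "start"] + 1L, tr$domains[dn, "end"]),
    character(1))
  # nt coordinate of pp1ab residue k (0-based), always single-frame here
  p1 <- (tr$spec$orf1a_len + tr$spec$insertion_len - 39L) %/% 3L
  s1a <- tr$orfs["orf1a", "start"]
  jnt <- tr$slippery$join[tr$slippery$motif == "GGATTTT"]
  aa_nt <- function(k) if (k < p1) s1a + 3L * k else (jnt - 1L) + 3L * (k - p1)
  body <- substr(base$record$seq, 1L, tr$body_len)
  polya <- strrep("A", tr$spec$polya_len)
  recs <- list(); taxa <- character(0); species <- integer(0)
  idx <- 0L
  for (s in seq_len(n_species)) {
    anc <- vapply(names(refset), function(dn)
      evolve_sequence(refset[[dn]], between_d / 2, "WAG-aa",
                      seed = seed + 7919L * s + match(dn, names(refset))),
      character(1))
    for (k in seq_len(n_per_species)) {
      iso <- vapply(names(refset), function(dn)
        evolve_sequence(anc[[dn]], within_d / 2, "WAG-aa",
                        seed = seed + 104729L * s + 31L * k +
                          match(dn, names(refset))),
        character(1))
      chars <- .chars(body)
      .with_seed(seed + 524287L * s + 101L * k, {
        cf <- .codons_for()
        for (dn in names(refset)) {
          a0 <- tr$domains[dn, "start"]
          new_aa <- .chars(iso[[dn]]); old_aa <- .chars(refset[[dn]])
          for (q in which(new_aa != old_aa)) {
            nt0 <- aa_nt(a0 + q - 1L)
            cc <- cf[[new_aa[q]]]
            chars[(nt0 + 1L):(nt0 + 3L)] <- .chars(cc[sample.int(length(cc), 1L)])
          }
        }
      })
      idx <- idx + 1L
      tax <- sprintf("sp%d_iso%d", s, k)
      recs[[tax]] <- genome_record(tax, paste0(paste(chars, collapse = ""),
                                               polya),
                                   source = "synthetic species set")
      taxa <- c(taxa, tax); species <- c(species, s)
    }
  }
  list(records = recs,
       species = data.frame(taxon = taxa, species = species,
                            stringsAsFactors = FALSE),
       refset = refset, base = base)
}
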