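# Pairwise global alignment, difference counting, block-insertion detection
# and imperfect-repeat search.

.DNA_CHARS <- c("A", "C", "G", "T", .IUPAC_EXTRA)

.alphabet_of <- function(s) {
  u <- unique(.chars(s))
  if (all(u %in% .DNA_CHARS)) "dna"
  else if (all(u %in% .AA20)) "protein"
  else stop("unrecognized alphabet: ", paste(setdiff(u, c(.DNA_CHARS, .AA20)),
                                             collapse = ","))
}

.nt_score_matrix <- function(match, mismatch) {
  ab <- .DNA_CHARS
  sm <- matrix(mismatch, length(ab), length(ab), dimnames = list(ab, ab))
  diag(sm) <- match
  # ambiguity codes score as mismatches everywhere, including to themselves
  amb <- .IUPAC_EXTRA
  sm[amb, ] <- mismatch; sm[, amb] <- mismatch
  sm
}

.protein_score_matrix <- function(id = "BLOSUM62") {
  e <- new.env()
  utils::data(list = id, package = "Biostrings", envir = e)
  m <- get(id, envir = e)
  m[.AA20, .AA20]
}

#' Alignment scoring parameters
#'
#' Defaults follow the common EDNAFULL-style values: match 5, mismatch -4,
#' gap open 10, gap extend 0.5 (a gap of length k costs
#' `gap_open + k * gap_extend`). Protein alignments use a log-odds
#' substitution matrix (default BLOSUM62).
#'
#' @param match,mismatch nucleotide scores.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param matrix substitution-matrix id for proteins (e.g. `"BLOSUM62"`).
#' @return list of parameters for [align_global()].
#' @export
align_params <- function(match = 5, mismatch = -4, gap_open = 10,
                         gap_extend = 0.5, matrix = "BLOSUM62") {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, matrix = matrix)
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal Needleman-Wunsch/Gotoh alignment, full-matrix by default or banded
#' (`band` = half-width around the diagonal, widened by the length
#' difference) for long genome pairs. Tie-breaking is deterministic:
#' diagonal > gap-in-b > gap-in-a.
#'
#' @param a,b sequences over one alphabet (both DNA or both protein).
#' @param params see [align_params()].
#' @param band integer band half-width, or `NULL` for the full matrix.
#' @return object of class `meso_alignment`: gapped `rows`, `score`,
#'   `params`.
#' @export
align_global <- function(a, b, params = align_params(), band = NULL) {
  if (inherits(a, "meso_genome")) a <- a$seq
  if (inherits(b, "meso_genome")) b <- b$seq
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  al_a <- .alphabet_of(a); al_b <- .alphabet_of(b)
  if (al_a != al_b) stop("mixed alphabets: ", al_a, " vs ", al_b)
  sm <- if (al_a == "dna") .nt_score_matrix(params$match, params$mismatch)
        else .protein_score_matrix(params$matrix)
  ab <- rownames(sm)
  ai <- match(.chars(a), ab) - 1L
  bi <- match(.chars(b), ab) - 1L
  res <- .nw_affine_cpp(ai, bi, sm, params$gap_open, params$gap_extend,
                        if (is.null(band)) -1L else as.integer(band))
  ops <- .chars(res$ops)
  ca <- .chars(a); cb <- .chars(b)
  ra <- rb <- character(length(ops))
  take_a <- ops != "Y"; take_b <- ops != "X"
  ra[take_a] <- ca; ra[!take_a] <- "-"
  rb[take_b] <- cb; rb[!take_b] <- "-"
  structure(list(rows = c(paste(ra, collapse = ""), paste(rb, collapse = "")),
                 score = res$score, params = params,
                 band = if (is.null(band)) NA_integer_ else as.integer(band)),
            class = "meso_alignment")
}

#' @export
print.meso_alignment <- function(x, ...) {
  w <- nchar(x$rows[1])
  cat(sprintf("<meso_alignment> %d columns, score %.2f%s\n", w, x$score,
              if (is.na(x$band)) "" else sprintf(" (band %d)", x$band)))
  if (w <= 80) cat(" ", x$rows[1], "\n ", x$rows[2], "\n")
  invisible(x)
}

#' Count substitutions and indel events in an alignment
#'
#' A substitution is a mismatching gap-free column; an indel event is one
#' maximal gap run in either row (so a 6-nt gap is a single event).
#'
#' @param aln a `meso_alignment`.
#' @return list with `substitutions`, `indel_events` (integer run lengths in
#'   column order) and `aligned_identity` = matches / (matches +
#'   substitutions).
#' @export
count_differences <- function(aln) {
  stopifnot(inherits(aln, "meso_alignment"))
  a <- .chars(aln$rows[1]); b <- .chars(aln$rows[2])
  ga <- a == "-"; gb <- b == "-"
  nogap <- !ga & !gb
  subs <- sum(nogap & a != b)
  matches <- sum(nogap & a == b)
  runs <- function(g) { r <- rle(g); r$lengths[r$values] }
  ev <- data.frame(length = c(runs(ga), runs(gb)),
                   row = c(rep(2L, length(runs(ga))),
                           rep(1L, length(runs(gb)))))
  # order events by column position
  pos <- c(cumsum(rle(ga)$lengths)[rle(ga)$values],
           cumsum(rle(gb)$lengths)[rle(gb)$values])
  ev <- ev[order(pos), , drop = FALSE]
  structure(list(substitutions = as.integer(subs),
                 indel_events = as.integer(ev$length),
                 aligned_identity = if (matches + subs > 0)
                   matches / (matches + subs) else NA_real_),
            class = "meso_diff")
}

#' @export
print.meso_diff <- function(x, ...) {
  cat(sprintf("<meso_diff> %d substitution(s), %d indel event(s)%s, identity %.4f\n",
              x$substitutions, length(x$indel_events),
              if (length(x$indel_events))
                paste0(" [", paste(x$indel_events, collapse = ","), " nt]")
              else "", x$aligned_identity))
  invisible(x)
}

#' Detect block insertions in a query genome relative to a reference
#'
#' Globally aligns a query region to the homologous reference region and
#' reports maximal reference-gap runs of at least `min_block` nt as insertion
#' blocks, annotated with imperfect repeats of `repeat_seed` (amino-acid
#' space, for in-frame blocks).
#'
#' @param query,reference [genome_record()]s.
#' @param region 0-based half-open span in the query (default: whole genome).
#' @param min_block minimum block length in nt (default 30).
#' @param identity_floor minimum aligned identity below which the regions are
#'   declared non-homologous (default 0.30).
#' @param params,band see [align_global()].
#' @param repeat_seed amino-acid seed for repeat annotation.
#' @param repeat_max_mismatch Hamming tolerance for repeat hits.
#' @return data.frame of blocks (query_start, query_end, length_nt,
#'   length_aa, frame_disrupting) with a `repeats` list-column.
#' @export
detect_insertions <- function(query, reference, region = NULL,
                              min_block = 30L, identity_floor = 0.30,
                              params = align_params(), band = 2000L,
                              repeat_seed = "SKRKGK",
                              repeat_max_mismatch = 2L) {
  stopifnot(inherits(query, "meso_genome"), inherits(reference, "meso_genome"))
  if (is.null(region)) region <- c(0L, nchar(query$seq))
  stopifnot(region[1] >= 0L, region[2] <= nchar(query$seq))
  qseq <- substr(query$seq, region[1] + 1L, region[2])
  # extend the reference window: a query insertion shifts homology rightward,
  # and equal-length windows would otherwise force compensating gaps
  slack <- min(max(1000L, 4L * min_block), nchar(reference$seq))
  rseq <- substr(reference$seq, min(region[1] + 1L, nchar(reference$seq)),
                 min(region[2] + slack, nchar(reference$seq)))
  aln <- align_global(qseq, rseq, params = params, band = band)
  rref <- .chars(aln$rows[2])
  rq <- .chars(aln$rows[1])
  # column identity (matches over all columns, gaps included) so grossly
  # non-homologous regions are refused rather than mined for gap runs
  col_id <- sum(rq == rref & rq != "-") / length(rq)
  if (col_id < identity_floor)
    stop(sprintf("homology error: column identity %.2f below floor %.2f",
                 col_id, identity_floor))
  r <- rle(rref == "-")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  # terminal gap runs are window-edge artifacts, not insertions
  keep <- r$values & r$lengths >= min_block & starts > 1L &
    ends < length(rref)
  out <- list()
  for (k in which(keep)) {
    cols <- starts[k]:ends[k]
    # query coordinate of the block start: count non-gap query chars before
    qoff <- sum(rq[seq_len(starts[k] - 1L)] != "-")
    blk_nt <- paste(rq[cols], collapse = "")
    ln <- length(cols)
    in_frame <- ln %% 3L == 0L
    reps <- if (in_frame)
      find_repeats(.translate_nt(paste0(blk_nt, ""), drop_stop = FALSE),
                   repeat_seed, repeat_max_mismatch)
    else NULL
    out[[length(out) + 1L]] <- data.frame(
      query_start = region[1] + qoff, query_end = region[1] + qoff + ln,
      length_nt = ln,
      length_aa = if (in_frame) ln %/% 3L else NA_integer_,
      frame_disrupting = !in_frame, stringsAsFactors = FALSE)
    attr(out[[length(out)]], "repeats") <- reps
  }
  if (!length(out))
    return(data.frame(query_start = integer(), query_end = integer(),
                      length_nt = integer(), length_aa = integer(),
                      frame_disrupting = logical()))
  blocks <- do.call(rbind, out)
  blocks$repeats <- I(lapply(out, attr, "repeats"))
  rownames(blocks) <- NULL
  blocks
}

#' Find imperfect repeats of a seed
#'
#' Reports every window of `nchar(seed)` with Hamming distance at most
#' `max_mismatch` to the seed, sorted by position (0-based).
#'
#' @param seq sequence to scan (nucleotide or amino-acid).
#' @param seed repeat seed, length >= 3.
#' @param max_mismatch maximum mismatches, `< nchar(seed)`.
#' @return data.frame with position, mismatches, window.
#' @export
find_repeats <- function(seq, seed, max_mismatch = 1L) {
  stopifnot(nchar(seed) >= 3L, max_mismatch < nchar(seed))
  k <- nchar(seed); L <- nchar(seq)
  empty <- data.frame(position = integer(), mismatches = integer(),
                      window = character(), stringsAsFactors = FALSE)
  if (L < k) return(empty)
  sc <- .chars(seq); kc <- .chars(seed)
  n <- L - k + 1L
  mm <- integer(n)
  for (o in seq_len(k))
    mm <- mm + (sc[o:(o + n - 1L)] != kc[o])
  hit <- which(mm <= max_mismatch)
  if (!length(hit)) return(empty)
  data.frame(position = hit - 1L, mismatches = mm[hit],
             window = substring(seq, hit, hit + k - 1L),
             stringsAsFactors = FALSE)
}
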