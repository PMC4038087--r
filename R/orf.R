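# ORF finding, canonical architecture assignment, -1 frameshift translation.

#' Find open reading frames
#'
#' Scans all three forward frames. With `require_start = TRUE` ORFs run from
#' ATG to the next in-frame stop; otherwise maximal stop-to-stop open
#' segments (terminated by a stop codon) are reported. Coordinates are
#' 0-based half-open with `end` placed after the stop codon.
#'
#' @param seq nucleotide string (A/C/G/T).
#' @param min_len_nt minimum ORF length in nt, stop included (>= 6, multiple
#'   of 3).
#' @param require_start require an initiating ATG.
#' @return data.frame with columns start, end, frame, has_start, protein,
#'   sorted by start.
#' @export
find_orfs <- function(seq, min_len_nt = 180L, require_start = TRUE) {
  stopifnot(min_len_nt >= 6L, min_len_nt %% 3L == 0L)
  seq <- .norm_nt(seq)
  L <- nchar(seq)
  out <- list()
  for (f in 0:2) {
    nc <- (L - f) %/% 3L
    if (nc < 2L) next
    starts <- seq.int(f + 1L, by = 3L, length.out = nc)
    codons <- substring(seq, starts, starts + 2L)
    stop_idx <- which(codons %in% .STOPS)
    if (!length(stop_idx)) next
    seg_from <- c(1L, head(stop_idx, -1L) + 1L)   # codon index after prev stop
    for (k in seq_along(stop_idx)) {
      s_cod <- seg_from[k]; e_cod <- stop_idx[k]  # segment incl. stop codon
      if (e_cod == s_cod) next                     # empty open segment
      if (require_start) {
        atg <- which(codons[s_cod:(e_cod - 1L)] == "ATG")
        if (!length(atg)) next
        s_cod2 <- s_cod + atg[1L] - 1L
      } else {
        s_cod2 <- s_cod
      }
      start0 <- f + (s_cod2 - 1L) * 3L
      end0 <- f + e_cod * 3L
      if (end0 - start0 < min_len_nt) next
      out[[length(out) + 1L]] <- data.frame(
        start = start0, end = end0, frame = f,
        has_start = codons[s_cod2] == "ATG",
        protein = .translate_codons(codons[s_cod2:(e_cod - 1L)]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      has_start = logical(), protein = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.arch_error <- function(which, id) {
  stop(sprintf("architecture error in '%s': missing %s", id, which),
       call. = FALSE)
}

.orf_row <- function(orfs, i) as.list(orfs[i, , drop = FALSE])

#' Assign the canonical mesonivirus architecture
#'
#' Maps ORFs onto the canonical genome plan: ORF1a (first long ORF), ORF1b
#' (-1-frame open segment overlapping the ORF1a 3' end, expressed as pp1ab),
#' ORF2a (spike) with nested ORF2b (nucleoprotein), overlapping ORF3a/ORF3b,
#' and optional ORF4 in the 3' terminal region. Thresholds come from
#' [meso_config()].
#'
#' @param rec a [genome_record()] (poly-A trimmed).
#' @param orfs ORF table from [find_orfs()] with `require_start = TRUE`.
#' @param slippery_sites integer positions (0-based) of slippery heptamers
#'   anywhere on the genome, as found by [find_slippery()]; they are filtered
#'   to the ORF1a/1b and ORF3a/3b overlaps.
#' @param config list of thresholds, see [meso_config()].
#' @return an object of class `meso_architecture`.
#' @export
assign_architecture <- function(rec, orfs, slippery_sites = integer(),
                                config = meso_config()) {
  stopifnot(inherits(rec, "meso_genome"))
  L <- nchar(rec$seq)
  len <- orfs$end - orfs$start
  used <- rep(FALSE, nrow(orfs))

  i1a <- which(orfs$has_start & len >= config$orf1a_min)[1]
  if (is.na(i1a)) .arch_error("ORF1a", rec$id)
  orf1a <- .orf_row(orfs, i1a); used[i1a] <- TRUE

  # ORF1b: stop-to-stop open segment in frame (f1a+2) %% 3 spanning the
  # ORF1a 3' boundary (contains position end1a - 1)
  f1b <- (orf1a$frame + 2L) %% 3L
  open <- find_orfs(rec$seq, min_len_nt = config$orf1b_min,
                    require_start = FALSE)
  cand <- open[open$frame == f1b & open$start < orf1a$end &
                 open$end > orf1a$end, , drop = FALSE]
  if (!nrow(cand)) .arch_error("ORF1b (-1-frame overlap)", rec$id)
  cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
  orf1b <- .orf_row(cand, 1L)

  i2a <- which(orfs$has_start & len >= config$orf2a_min &
                 orfs$start >= orf1b$end)[1]
  if (is.na(i2a)) .arch_error("ORF2a", rec$id)
  orf2a <- .orf_row(orfs, i2a); used[i2a] <- TRUE

  # ORF2b: longest alternative-frame ORF starting in the 5' third of ORF2a
  # and contained within it
  third <- orf2a$start + (orf2a$end - orf2a$start) %/% 3L
  c2b <- which(orfs$has_start & orfs$frame != orf2a$frame &
                 orfs$start >= orf2a$start & orfs$start < third &
                 orfs$end <= orf2a$end & len >= config$orf2b_min)
  if (!length(c2b)) .arch_error("ORF2b", rec$id)
  c2b <- c2b[order(-len[c2b], orfs$start[c2b])][1]
  orf2b <- .orf_row(orfs, c2b); used[c2b] <- TRUE

  i3a <- which(orfs$has_start & len >= config$orf3a_min &
                 orfs$start >= orf2a$end)[1]
  if (is.na(i3a)) .arch_error("ORF3a", rec$id)
  orf3a <- .orf_row(orfs, i3a); used[i3a] <- TRUE

  # ORF3b: longest different-frame ORF overlapping the 3' half of ORF3a
  half <- orf3a$start + (orf3a$end - orf3a$start) %/% 2L
  c3b <- which(orfs$has_start & orfs$frame != orf3a$frame &
                 orfs$start < orf3a$end & orfs$end > half &
                 len >= config$orf3b_min)
  c3b <- setdiff(c3b, which(used))
  if (!length(c3b)) .arch_error("ORF3b", rec$id)
  c3b <- c3b[order(-len[c3b], orfs$start[c3b])][1]
  orf3b <- .orf_row(orfs, c3b); used[c3b] <- TRUE

  # ORF4: first ORF of 120-200 nt 3' of ORF3b (absent in some viruses)
  r4 <- config$orf4_len_range
  i4 <- which(orfs$has_start & orfs$start >= orf3b$end &
                len >= r4[1] & len <= r4[2])[1]
  orf4 <- if (is.na(i4)) NULL else .orf_row(orfs, i4)
  if (!is.na(i4)) used[i4] <- TRUE

  last_end <- if (!is.null(orf4)) orf4$end else orf3b$end
  small <- orfs[!used & (orfs$end - orfs$start) >= config$min_orf_len, ,
                drop = FALSE]
  rownames(small) <- NULL

  # slippery sites restricted to their own overlap: GGAUUUU drives the
  # ORF1a/1b frameshift, CACUUUU the putative ORF3a/3b one
  sl <- integer(0); sl_motif <- character(0); sl_overlap <- character(0)
  for (p in slippery_sites) {
    motif <- substr(rec$seq, p + 1L, p + 7L)
    if (motif == "GGATTTT" && p >= orf1b$start && p + 7L <= orf1a$end) {
      sl <- c(sl, p); sl_motif <- c(sl_motif, motif)
      sl_overlap <- c(sl_overlap, "ORF1a/ORF1b")
    } else if (motif == "CACTTTT" && p >= orf3b$start &&
               p + 7L <= orf3a$end) {
      sl <- c(sl, p); sl_motif <- c(sl_motif, motif)
      sl_overlap <- c(sl_overlap, "ORF3a/ORF3b")
    }
  }

  structure(list(
    genome_id = rec$id,
    utr5 = .span(0L, orf1a$start),
    orf1a = orf1a, orf1b = orf1b, orf2a = orf2a, orf2b = orf2b,
    orf3a = orf3a, orf3b = orf3b, orf4 = orf4,
    term3 = .span(last_end, L),
    small_orfs = small,
    slippery_sites = data.frame(pos = sl, motif = sl_motif,
                                overlap = sl_overlap,
                                stringsAsFactors = FALSE)),
    class = "meso_architecture")
}

#' @export
print.meso_architecture <- function(x, ...) {
  cat(sprintf("<meso_architecture> %s\n", x$genome_id))
  cat(sprintf("  5'UTR: %d nt   3' region: %d nt\n",
              x$utr5["end"] - x$utr5["start"],
              x$term3["end"] - x$term3["start"]))
  for (nm in c("orf1a", "orf1b", "orf2a", "orf2b", "orf3a", "orf3b", "orf4")) {
    o <- x[[nm]]
    if (is.null(o)) { cat(sprintf("  %-6s absent\n", toupper(nm))); next }
    cat(sprintf("  %-6s [%6d, %6d) frame %d  %5d aa\n", toupper(nm),
                o$start, o$end, o$frame, nchar(o$protein)))
  }
  if (nrow(x$slippery_sites))
    cat("  slippery:", paste(sprintf("%s@%d (%s)", x$slippery_sites$motif,
                                     x$slippery_sites$pos,
                                     x$slippery_sites$overlap),
                             collapse = ", "), "\n")
  cat(sprintf("  %d unassigned small ORF(s)\n", nrow(x$small_orfs)))
  invisible(x)
}

#' Conceptual translation across a -1 ribosomal frameshift
#'
#' Fuses an upstream ORF to a downstream ORF in the -1 frame at a slippery
#' heptamer. The fused coding sequence is `genome[start_up, j)` followed by
#' `genome[j-1, end_down)` -- one nucleotide (j-1) is read twice -- where j is
#' the smallest upstream-codon boundary at least `slippery_pos + 7`, at most
#' `slippery_pos + 16`, yielding a stop-free fusion.
#'
#' @param rec a [genome_record()].
#' @param upstream,downstream ORF rows (lists with start/end/frame) as stored
#'   in a `meso_architecture`.
#' @param slippery_pos 0-based position of the slippery heptamer.
#' @param name product name, e.g. `"pp1ab"` or `"p3ab"`.
#' @return object of class `meso_fusion` with the fused protein and join.
#' @export
translate_prf <- function(rec, upstream, downstream, slippery_pos,
                          name = "pp1ab") {
  stopifnot(inherits(rec, "meso_genome"))
  if ((downstream$frame - upstream$frame) %% 3L != 2L)
    stop("frameshift error: downstream ORF is not in the -1 frame")
  motif <- substr(rec$seq, slippery_pos + 1L, slippery_pos + 7L)
  if (!motif %in% c("GGATTTT", "CACTTTT"))
    stop("frameshift error: no slippery heptamer at position ", slippery_pos)
  if (slippery_pos < upstream$start || slippery_pos + 7L > upstream$end)
    stop("frameshift error: slippery site outside the upstream ORF")
  j0 <- upstream$start +
    3L * ceiling((slippery_pos + 7L - upstream$start) / 3)
  for (j in seq.int(j0, slippery_pos + 16L, by = 3L)) {
    if (j >= downstream$end) break
    fused <- paste0(substr(rec$seq, upstream$start + 1L, j),
                    substr(rec$seq, j, downstream$end))
    prot <- .translate_nt(fused, drop_stop = FALSE)
    body <- sub("\\*$", "", prot)
    if (!grepl("*", body, fixed = TRUE)) {
      return(structure(list(name = name, join_pos = as.integer(j),
                            protein = body, slippery_motif = motif),
                       class = "meso_fusion"))
    }
  }
  stop("frameshift error: no stop-free -1 fusion within ",
       slippery_pos + 7L, "..", slippery_pos + 16L)
}

#' @export
print.meso_fusion <- function(x, ...) {
  cat(sprintf("<meso_fusion> %s: %d aa, join at %d (motif %s)\n",
              x$name, nchar(x$protein), x$join_pos, x$slippery_motif))
  invisible(x)
}
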