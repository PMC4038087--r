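# Nucleotide motif scanning (TRS elements, slippery heptamers) and protein
# sequence features (cleavage sites, sequons, cysteines, MW, pI).

# Compile the degenerate-pattern mini-language to a PCRE:
#   exact base (ACGT/U), 'x' = any base, '(c)' = optional symbol.
.compile_pattern <- function(pattern) {
  p <- chartr("U", "T", toupper(pattern))
  toks <- .chars(p)
  rx <- character(0)
  i <- 1L
  while (i <= length(toks)) {
    ch <- toks[i]
    if (ch == "(") {
      if (i + 2L > length(toks) || toks[i + 2L] != ")")
        stop("pattern error: unbalanced '(' in ", pattern)
      inner <- toks[i + 1L]
      core <- if (inner == "X") "[ACGT]" else if (inner %in% c("A", "C", "G", "T"))
        inner else stop("pattern error: bad symbol '", inner, "' in ", pattern)
      rx <- c(rx, paste0(core, "?"))
      i <- i + 3L
    } else if (ch == "X") {
      rx <- c(rx, "[ACGT]"); i <- i + 1L
    } else if (ch %in% c("A", "C", "G", "T")) {
      rx <- c(rx, ch); i <- i + 1L
    } else {
      stop("pattern error: bad symbol '", ch, "' in ", pattern)
    }
  }
  paste(rx, collapse = "")
}

#' Scan a nucleotide sequence for a degenerate motif
#'
#' Pattern mini-language: exact bases (RNA or DNA alphabet), `x` for any base,
#' a parenthesized symbol for an optional base. All (possibly overlapping)
#' hits are reported; at a given position the longest match wins.
#'
#' @param seq nucleotide string.
#' @param pattern degenerate pattern, e.g. `"AUxxUACUACUACUA"`.
#' @return data.frame with pattern_id, start, end (0-based half-open),
#'   matched, sorted by start.
#' @export
scan_motif <- function(seq, pattern) {
  seq <- .norm_nt(seq)
  rx <- .compile_pattern(pattern)
  m <- gregexpr(paste0("(?=(", rx, "))"), seq, perl = TRUE)[[1]]
  empty <- data.frame(pattern_id = character(), start = integer(),
                      end = integer(), matched = character(),
                      stringsAsFactors = FALSE)
  if (m[1] == -1L) return(empty)
  cs <- attr(m, "capture.start")[, 1L]
  cl <- attr(m, "capture.length")[, 1L]
  keep <- cl > 0L
  if (!any(keep)) return(empty)
  data.frame(pattern_id = pattern, start = cs[keep] - 1L,
             end = cs[keep] - 1L + cl[keep],
             matched = substring(seq, cs[keep], cs[keep] + cl[keep] - 1L),
             stringsAsFactors = FALSE)
}

#' Find slippery heptamers inside a span
#'
#' Exact matches of a slippery heptanucleotide (GGAUUUU at the ORF1a/ORF1b
#' overlap, CACUUUU at ORF3a/ORF3b) within a genome span.
#'
#' @param rec a [genome_record()] or plain nucleotide string.
#' @param span integer length-2 vector, 0-based half-open.
#' @param motif `"GGAUUUU"` or `"CACUUUU"` (DNA spelling accepted).
#' @return integer vector of 0-based match positions.
#' @export
find_slippery <- function(rec, span = NULL, motif = "GGAUUUU") {
  seq <- if (inherits(rec, "meso_genome")) rec$seq else .norm_nt(rec)
  motif <- .norm_nt(motif)
  if (!motif %in% c("GGATTTT", "CACTTTT"))
    stop("motif must be GGAUUUU or CACUUUU")
  if (is.null(span)) span <- c(0L, nchar(seq))
  stopifnot(span[1] >= 0L, span[2] <= nchar(seq))
  m <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  pos <- as.integer(m) - 1L
  pos[pos >= span[1] & pos + 7L <= span[2]]
}

#' Find polyprotein cleavage sites
#'
#' Signalase sites: a residue C or S immediately followed by `[L/A/S]TRIDL`
#' (cleavage after the C/S). S1-S2 sites: R immediately followed by `WDSSYV`
#' (cleavage after the R).
#'
#' @param protein amino-acid string.
#' @return data.frame with kind (`signalase` / `S1S2`), cut_after (0-based
#'   index of the residue whose following bond is cleaved), context (up to
#'   10 residues around the site).
#' @export
find_cleavage_sites <- function(protein) {
  .check_protein(protein)
  hit1 <- gregexpr("[CS](?=[LAS]TRIDL)", protein, perl = TRUE)[[1]]
  hit2 <- gregexpr("R(?=WDSSYV)", protein, perl = TRUE)[[1]]
  pos <- c(if (hit1[1] != -1L) as.integer(hit1),
           if (hit2[1] != -1L) as.integer(hit2))
  kind <- c(if (hit1[1] != -1L) rep("signalase", length(hit1)),
            if (hit2[1] != -1L) rep("S1S2", length(hit2)))
  if (!length(pos))
    return(data.frame(kind = character(), cut_after = integer(),
                      context = character(), stringsAsFactors = FALSE))
  o <- order(pos)
  L <- nchar(protein)
  data.frame(kind = kind[o], cut_after = pos[o] - 1L,
             context = substring(protein, pmax(1L, pos[o] - 3L),
                                 pmin(L, pos[o] + 6L)),
             stringsAsFactors = FALSE)
}

#' Summarize protein sequence features
#'
#' Length, average-mass molecular weight, isoelectric point, cysteine
#' positions and N-glycosylation sequons (N-X-S/T with X != P). Positions are
#' 0-based.
#'
#' @param protein amino-acid string (standard 20-letter alphabet).
#' @return object of class `meso_protein_features`.
#' @export
protein_features <- function(protein) {
  .check_protein(protein)
  cys <- as.integer(gregexpr("C", protein, fixed = TRUE)[[1]])
  cys <- if (cys[1] == -1L) integer(0) else cys - 1L
  seqm <- gregexpr("(?=N[^P][ST])", protein, perl = TRUE)[[1]]
  sequons <- if (seqm[1] == -1L) integer(0) else as.integer(seqm) - 1L
  structure(list(length_aa = nchar(protein),
                 mw_kda = protein_mw(protein),
                 pi = protein_pi(protein),
                 cys_positions = cys,
                 sequons = sequons),
            class = "meso_protein_features")
}

#' @export
print.meso_protein_features <- function(x, ...) {
  cat(sprintf(
    "<protein> %d aa, %.2f kDa, pI %.2f, %d Cys, %d sequon(s)\n",
    x$length_aa, x$mw_kda, x$pi, length(x$cys_positions), length(x$sequons)))
  invisible(x)
}

# average (not monoisotopic) residue masses, Da
.AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.H2O <- 18.0153

#' Protein molecular weight (average mass)
#'
#' Sum of average residue masses plus one water, in kilodaltons. Rounding is
#' left to report time.
#'
#' @param protein amino-acid string.
#' @return mass in kDa.
#' @export
protein_mw <- function(protein) {
  .check_protein(protein)
  (sum(.AA_MASS[.chars(protein)]) + .H2O) / 1000
}

# EMBOSS-style pKa values
.PKA <- list(nterm = 8.6, cterm = 3.6,
             pos = c(K = 10.8, R = 12.5, H = 6.5),
             neg = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

.net_charge <- function(counts, pH, pka = .PKA) {
  pos <- 1 / (1 + 10^(pH - pka$nterm)) +
    sum(counts[names(pka$pos)] / (1 + 10^(pH - pka$pos)), na.rm = TRUE)
  neg <- 1 / (1 + 10^(pka$cterm - pH)) +
    sum(counts[names(pka$neg)] / (1 + 10^(pka$neg - pH)), na.rm = TRUE)
  pos - neg
}

#' Protein isoelectric point
#'
#' pH at which the net charge is zero, found by bisection on (0, 14) to
#' |charge| < 1e-4, using an EMBOSS-style pKa table (configurable).
#'
#' @param protein amino-acid string.
#' @param pka pKa table: list with `nterm`, `cterm`, named vectors `pos`,
#'   `neg`.
#' @return isoelectric point.
#' @export
protein_pi <- function(protein, pka = .PKA) {
  .check_protein(protein)
  cc <- table(factor(.chars(protein), levels = .AA20))
  counts <- stats::setNames(as.integer(cc), names(cc))
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- .net_charge(counts, mid, pka)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}
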