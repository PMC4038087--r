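# Shared low-level helpers: alphabets, translation, codon sampling.

.STOPS <- c("TAA", "TAG", "TGA")

# 61 sense codons
.sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, .STOPS)
}

.GENETIC_CODE <- NULL

.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

# translate a vector of codons to a single AA string; stops become "*"
.translate_codons <- function(codons) {
  gc <- .genetic_code()
  aa <- unname(gc[codons])
  if (anyNA(aa)) stop("untranslatable codon: ", codons[which(is.na(aa))[1]])
  paste(aa, collapse = "")
}

# translate a nucleotide string in frame 0; drop_stop removes one trailing '*'
.translate_nt <- function(seq, drop_stop = TRUE) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return("")
  codons <- substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  p <- .translate_codons(codons)
  if (drop_stop) p <- sub("\\*$", "", p)
  p
}

# split a string into single characters
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# codons encoding each amino acid (sense codons only)
.codons_for <- function() {
  gc <- .genetic_code()
  sense <- gc[gc != "*"]
  split(names(sense), unname(sense))
}

.check_protein <- function(protein, what = "protein") {
  if (!is.character(protein) || length(protein) != 1L || is.na(protein))
    stop(what, " must be a single string")
  if (nchar(protein) == 0L) stop(what, " is empty")
  bad <- setdiff(unique(.chars(protein)), .AA20)
  if (length(bad))
    stop("non-standard residue(s) in ", what, ": ", paste(bad, collapse = ","))
  invisible(protein)
}

# normalize nucleotide text: uppercase, U->T
.norm_nt <- function(s) chartr("u", "T", chartr("U", "T", toupper(s)))

.IUPAC_EXTRA <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

.check_nt <- function(seq, allow_ambiguous = FALSE, what = "sequence") {
  ok <- c("A", "C", "G", "T", if (allow_ambiguous) .IUPAC_EXTRA)
  bad <- setdiff(unique(.chars(seq)), ok)
  if (length(bad))
    stop("format error: non-nucleotide character(s) in ", what, ": ",
         paste(bad, collapse = ","))
  invisible(seq)
}

# 0-based half-open span helper
.span <- function(start, end) c(start = as.integer(start), end = as.integer(end))
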