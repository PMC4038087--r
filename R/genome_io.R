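# Sequence and annotation I/O: FASTA in/out, poly-A trimming, GFF3 export.

#' Construct a genome record
#'
#' A genome record holds one poly-A-trimmable genome sequence in the DNA
#' alphabet (RNA input is normalized, U -> T).
#'
#' @param id character identifier.
#' @param seq nucleotide sequence (A/C/G/T after normalization).
#' @param polya_len length of a previously trimmed poly-A tail.
#' @param source free-text provenance.
#' @param allow_ambiguous accept IUPAC ambiguity codes (treated as mismatches
#'   downstream) instead of rejecting them.
#' @return an object of class `meso_genome`.
#' @export
genome_record <- function(id, seq, polya_len = 0L, source = "",
                          allow_ambiguous = FALSE) {
  seq <- .norm_nt(seq)
  .check_nt(seq, allow_ambiguous, what = paste0("record '", id, "'"))
  structure(list(id = as.character(id), seq = seq,
                 polya_len = as.integer(polya_len),
                 source = as.character(source)),
            class = "meso_genome")
}

#' @export
print.meso_genome <- function(x, ...) {
  cat(sprintf("<meso_genome> %s: %d nt (poly-A trimmed: %d)\n",
              x$id, nchar(x$seq), x$polya_len))
  invisible(x)
}

.as_record_list <- function(x) {
  if (inherits(x, "meso_genome")) return(stats::setNames(list(x), x$id))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "meso_genome")))
    return(stats::setNames(x, vapply(x, `[[`, character(1), "id")))
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(read_fasta(x))
  stop("expected a meso_genome, a list of them, or a FASTA path")
}

#' Read genome sequences from FASTA
#'
#' Entries are case-folded to uppercase and U is normalized to T. Ambiguity
#' codes are rejected unless `allow_ambiguous` is set.
#'
#' @param path path to a FASTA file.
#' @inheritParams genome_record
#' @return named list of [genome_record()] objects, in file order.
#' @export
read_fasta <- function(path, allow_ambiguous = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("format error: empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  recs <- lapply(seq_along(ss), function(i) {
    genome_record(ids[i], as.character(ss[[i]]), source = path,
                  allow_ambiguous = allow_ambiguous)
  })
  stats::setNames(recs, ids)
}

#' Write genome records to FASTA
#'
#' @param records a record, list of records, as accepted by the pipeline.
#' @param path output path.
#' @param width line width (default 70).
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- .as_record_list(records)
  ss <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "seq"))
  names(ss) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Trim the 3' poly-A tail of a genome record
#'
#' Removes a trailing maximal run of A of length at least `min_run` and
#' records its length in `polya_len`; shorter runs are left untouched.
#'
#' @param rec a [genome_record()].
#' @param min_run minimum run length to treat as a tail (default 5).
#' @return the trimmed record.
#' @export
trim_polya <- function(rec, min_run = 5L) {
  stopifnot(inherits(rec, "meso_genome"), min_run >= 1L)
  m <- regexpr("A+$", rec$seq)
  run <- if (m[1] == -1L) 0L else attr(m, "match.length")
  if (run >= nchar(rec$seq))
    stop("degenerate genome '", rec$id, "': sequence is entirely A")
  if (run >= min_run) {
    rec$seq <- substr(rec$seq, 1L, nchar(rec$seq) - run)
    rec$polya_len <- as.integer(run)
  } else {
    rec$polya_len <- 0L
  }
  rec
}

#' Build a feature table row
#'
#' Features use 0-based half-open coordinates internally; [write_gff3()]
#' converts to 1-based inclusive on output.
#'
#' @param seqid genome identifier.
#' @param name feature label (e.g. `ORF1a`, `TRS`, `slippery`).
#' @param start,end 0-based half-open genome coordinates.
#' @param frame reading-frame 0-2 (coding features: `start %% 3`).
#' @param type GFF3 feature type (default `region`).
#' @param attributes optional named character vector of extra attributes.
#' @return one-row data.frame.
#' @export
feature <- function(seqid, name, start, end, frame = start %% 3L,
                    type = "region", attributes = NULL) {
  stopifnot(start >= 0L, start < end)
  attr_str <- if (is.null(attributes)) "" else
    paste(names(attributes), unname(attributes), sep = "=", collapse = ";")
  data.frame(seqid = seqid, name = name, start = as.integer(start),
             end = as.integer(end), frame = as.integer(frame %% 3L),
             type = type, attributes = attr_str, stringsAsFactors = FALSE)
}

#' Write features as GFF3
#'
#' Coordinates are converted to 1-based inclusive; strand is always `+`
#' ((+)ssRNA genomes, single-strand analysis). Rows are ordered by
#' (seqid, start, name); identical (name, start, end) duplicates are an error.
#'
#' @param features data.frame as built by [feature()] (rows may be rbind-ed).
#' @param path output path.
#' @export
write_gff3 <- function(features, path) {
  if (is.null(features) || nrow(features) == 0L) {
    gr <- GenomicRanges::GRanges()
    rtracklayer::export(gr, path, format = "gff3")
    return(invisible(path))
  }
  stopifnot(all(c("seqid", "name", "start", "end") %in% names(features)))
  if (any(features$start < 0L) || any(features$end <= features$start))
    stop("invalid feature coordinates")
  key <- paste(features$name, features$start, features$end)
  if (anyDuplicated(key)) stop("duplicate feature(s): ", key[duplicated(key)][1])
  o <- order(features$seqid, features$start, features$name)
  features <- features[o, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = "+")
  type <- if ("type" %in% names(features)) features$type else "region"
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$phase <- ifelse(type == "CDS", 0L, NA_integer_)
  S4Vectors::mcols(gr)$Name <- features$name
  S4Vectors::mcols(gr)$frame_label <- as.character(
    if ("frame" %in% names(features)) features$frame else features$start %% 3L)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file back into the internal feature table
#'
#' Inverse of [write_gff3()]: 1-based inclusive file coordinates become
#' 0-based half-open.
#'
#' @param path a GFF3 file.
#' @return data.frame with columns seqid, name, start, end, frame, type.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L)
    return(data.frame(seqid = character(), name = character(),
                      start = integer(), end = integer(),
                      frame = integer(), type = character()))
  mc <- S4Vectors::mcols(gr)
  data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    name = as.character(mc$Name),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    frame = as.integer(if (!is.null(mc$frame_label)) mc$frame_label else
      (GenomicRanges::start(gr) - 1L) %% 3L),
    type = as.character(mc$type),
    stringsAsFactors = FALSE)
}
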