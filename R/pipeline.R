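# End-to-end orchestration: configuration, per-genome annotation reports,
# species demarcation over a genome set, TSV/JSON/GFF3 emission.

#' Pipeline configuration
#'
#' All thresholds of the annotation and demarcation stages in one list.
#' Values can be overridden by arguments or loaded from a YAML file; every
#' report embeds the resolved configuration, since several printed quantities
#' (ORF assignment, substitution counts, species partitions) are
#' threshold-sensitive.
#'
#' @param file optional YAML file with overrides.
#' @param ... named overrides applied after the file.
#' @return named list of class `meso_config`.
#' @export
meso_config <- function(file = NULL, ...) {
  cfg <- list(
    # alphabet / trimming
    allow_ambiguous = FALSE,
    polya_min_run = 5L,
    # ORF scan and canonical assignment (nt)
    min_orf_len = 180L,          # alternative-ORF scan floor (> 60 aa)
    orf1a_min = 3000L,
    orf1b_min = 600L,
    orf2a_min = 2000L,
    orf2b_min = 330L,
    orf3a_min = 500L,
    orf3b_min = 150L,
    orf4_len_range = c(120L, 200L),
    # motifs
    trs_patterns = c(leader_body = "AUxxUACUACUACUA",
                     body2 = "AGAx(x)ACUCUCCCA"),
    slippery_motifs = c("GGAUUUU", "CACUUUU"),
    # pairwise alignment
    match = 5, mismatch = -4, gap_open = 10, gap_extend = 0.5,
    protein_matrix = "BLOSUM62",
    band = 2000L,
    min_block = 30L,
    identity_floor = 0.30,
    repeat_seed = "SKRKGK",
    repeat_max_mismatch = 2L,
    # demarcation
    model = "WAG",
    threshold = 0.032,
    linkage = "single",
    domain_min_score_frac = 0.25,
    window = 100L,
    step = 25L)
  if (!is.null(file)) {
    ov <- yaml::read_yaml(file)
    cfg <- utils::modifyList(cfg, ov)
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ","))
    cfg <- utils::modifyList(cfg, dots)
  }
  structure(cfg, class = c("meso_config", "list"))
}

.align_params_of <- function(config)
  align_params(match = config$match, mismatch = config$mismatch,
               gap_open = config$gap_open, gap_extend = config$gap_extend,
               matrix = config$protein_matrix)

# architecture + motif features as a feature table for GFF3
.features_of <- function(rec, arch, trs) {
  rows <- list()
  add <- function(name, start, end, type, frame = start %% 3L)
    rows[[length(rows) + 1L]] <<- feature(rec$id, name, start, end,
                                          frame = frame, type = type)
  if (arch$utr5["end"] > 0)
    add("5'UTR", arch$utr5["start"], arch$utr5["end"], "five_prime_UTR")
  for (nm in c("orf1a", "orf1b", "orf2a", "orf2b", "orf3a", "orf3b", "orf4")) {
    o <- arch[[nm]]
    if (!is.null(o)) add(toupper(nm), o$start, o$end, "CDS", o$frame)
  }
  if (arch$term3["end"] > arch$term3["start"])
    add("3'terminal", arch$term3["start"], arch$term3["end"],
        "three_prime_UTR")
  if (nrow(arch$slippery_sites))
    for (i in seq_len(nrow(arch$slippery_sites)))
      add(paste0("slippery_", arch$slippery_sites$motif[i], "_", i),
          arch$slippery_sites$pos[i], arch$slippery_sites$pos[i] + 7L,
          "sequence_motif")
  if (!is.null(trs) && nrow(trs))
    for (i in seq_len(nrow(trs)))
      add(paste0("TRS_", trs$class[i], "_", i), trs$start[i], trs$end[i],
          "sequence_motif")
  do.call(rbind, rows)
}

.annotate_one <- function(rec, config, reference = NULL) {
  rec <- trim_polya(rec, min_run = config$polya_min_run)
  # scan low enough to catch ORF4 candidates; small_orfs are filtered to the
  # alternative-ORF floor inside assign_architecture
  scan_min <- min(config$min_orf_len, config$orf4_len_range[1])
  orfs <- find_orfs(rec$seq, min_len_nt = scan_min, require_start = TRUE)
  slips <- sort(unlist(lapply(config$slippery_motifs, function(m)
    find_slippery(rec, motif = m))))
  arch <- assign_architecture(rec, orfs, slips, config = config)

  trs <- do.call(rbind, lapply(config$trs_patterns, scan_motif, seq = rec$seq))
  if (!is.null(trs) && nrow(trs)) {
    trs$class <- ifelse(trs$end <= arch$utr5["end"], "leader", "body")
    trs <- trs[order(trs$start), , drop = FALSE]
    rownames(trs) <- NULL
  }

  sl <- arch$slippery_sites
  pp1ab <- {
    p <- sl$pos[sl$overlap == "ORF1a/ORF1b" & sl$motif == "GGATTTT"]
    if (length(p)) translate_prf(rec, arch$orf1a, arch$orf1b, p[1], "pp1ab")
    else NULL
  }
  p3ab <- tryCatch({
    p <- sl$pos[sl$overlap == "ORF3a/ORF3b" & sl$motif == "CACTTTT"]
    if (length(p)) translate_prf(rec, arch$orf3a, arch$orf3b, p[1], "p3ab")
    else NULL
  }, error = function(e) NULL)

  cleavage <- find_cleavage_sites(arch$orf2a$protein)
  n_features <- protein_features(arch$orf2b$protein)

  insertions <- if (!is.null(reference))
    detect_insertions(rec, reference,
                      min_block = config$min_block,
                      identity_floor = config$identity_floor,
                      params = .align_params_of(config), band = config$band,
                      repeat_seed = config$repeat_seed,
                      repeat_max_mismatch = config$repeat_max_mismatch)
  else NULL

  structure(list(record = rec, architecture = arch, trs = trs,
                 pp1ab = pp1ab, p3ab = p3ab, cleavage = cleavage,
                 n_protein = n_features, insertions = insertions),
            class = "meso_annotation")
}

#' @export
print.meso_annotation <- function(x, ...) {
  print(x$architecture)
  if (!is.null(x$trs))
    cat(sprintf("  TRS hits: %d (%d leader, %d body)\n", nrow(x$trs),
                sum(x$trs$class == "leader"), sum(x$trs$class == "body")))
  if (!is.null(x$pp1ab)) print(x$pp1ab)
  if (!is.null(x$p3ab)) print(x$p3ab)
  cat("  N protein: "); print(x$n_protein)
  invisible(x)
}

#' Annotate mesonivirus genomes
#'
#' Runs the full per-genome pipeline: poly-A trimming, ORF scan, canonical
#' architecture assignment, TRS and slippery-heptamer scans, conceptual
#' -1-frameshift translation (pp1ab and, when the CACUUUU site is present and
#' yields a stop-free fusion, p3ab), spike cleavage-site scan, nucleoprotein
#' features, and optional block-insertion detection against a reference
#' genome. Per-genome failures are isolated and reported.
#'
#' @param x FASTA path, a [genome_record()] or a list of them.
#' @param config a [meso_config()].
#' @param reference optional reference [genome_record()] (or FASTA path with
#'   one record) for insertion detection.
#' @param out_dir if given, a GFF3 and a JSON report are written per genome.
#' @return object of class `meso_report`: list with `annotations`, `errors`,
#'   `config`.
#' @export
annotate_genome <- function(x, config = meso_config(), reference = NULL,
                            out_dir = NULL) {
  recs <- .as_record_list(x)
  if (!is.null(reference) && !inherits(reference, "meso_genome")) {
    rl <- .as_record_list(reference)
    reference <- trim_polya(rl[[1]], min_run = config$polya_min_run)
  } else if (!is.null(reference)) {
    reference <- trim_polya(reference, min_run = config$polya_min_run)
  }
  anns <- list(); errs <- list()
  for (id in names(recs)) {
    res <- tryCatch(.annotate_one(recs[[id]], config, reference),
                    error = function(e) e)
    if (inherits(res, "error")) errs[[id]] <- conditionMessage(res)
    else anns[[id]] <- res
  }
  if (!length(anns))
    stop("all genomes failed annotation: ",
         paste(unlist(errs), collapse = "; "))
  rep <- structure(list(annotations = anns, errors = errs, config = config),
                   class = "meso_report")
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

#' @export
print.meso_report <- function(x, ...) {
  cat(sprintf("<meso_report> %d genome(s) annotated, %d failed\n",
              length(x$annotations), length(x$errors)))
  for (a in x$annotations) print(a$architecture)
  if (length(x$errors))
    for (id in names(x$errors)) cat("  FAILED", id, ":", x$errors[[id]], "\n")
  invisible(x)
}

.annotation_json <- function(a) {
  arch <- a$architecture
  orfs <- lapply(c("orf1a", "orf1b", "orf2a", "orf2b", "orf3a", "orf3b",
                   "orf4"), function(nm) {
    o <- arch[[nm]]
    if (is.null(o)) NULL
    else list(start = o$start, end = o$end, frame = o$frame,
              protein_length = nchar(o$protein))
  })
  names(orfs) <- c("ORF1a", "ORF1b", "ORF2a", "ORF2b", "ORF3a", "ORF3b",
                   "ORF4")
  list(
    genome = a$record$id,
    length = nchar(a$record$seq),
    polya_len = a$record$polya_len,
    utr5 = as.list(arch$utr5),
    term3 = as.list(arch$term3),
    orfs = orfs[!vapply(orfs, is.null, logical(1))],
    slippery = arch$slippery_sites,
    trs = a$trs,
    pp1ab_length = if (!is.null(a$pp1ab)) nchar(a$pp1ab$protein) else NULL,
    p3ab_length = if (!is.null(a$p3ab)) nchar(a$p3ab$protein) else NULL,
    cleavage = a$cleavage,
    n_protein = list(length_aa = a$n_protein$length_aa,
                     mw_kda = a$n_protein$mw_kda, pi = a$n_protein$pi,
                     n_cys = length(a$n_protein$cys_positions),
                     n_sequons = length(a$n_protein$sequons)),
    insertions = if (!is.null(a$insertions) && nrow(a$insertions))
      a$insertions[, c("query_start", "query_end", "length_nt", "length_aa",
                       "frame_disrupting")] else NULL,
    small_orfs = nrow(arch$small_orfs))
}

#' Write annotation reports to disk
#'
#' One GFF3 and one JSON per genome, plus a combined `report.json` embedding
#' the resolved configuration.
#'
#' @param report a `meso_report`.
#' @param out_dir output directory (created if missing).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all <- list()
  for (id in names(report$annotations)) {
    a <- report$annotations[[id]]
    fe <- .features_of(a$record, a$architecture, a$trs)
    write_gff3(fe, file.path(out_dir, paste0(id, ".gff3")))
    all[[id]] <- .annotation_json(a)
  }
  jsonlite::write_json(
    list(config = unclass(report$config), genomes = all,
         errors = report$errors),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(out_dir)
}

#' Demarcate species over a genome set
#'
#' Annotates each genome, translates pp1ab, extracts the conserved replicase
#' domains by local alignment to a reference set, computes the matrix of ML
#' pairwise evolutionary distances on the concatenated domains (WAG model by
#' default) and clusters taxa at the demarcation threshold. Taxa failing
#' domain extraction are excluded with a warning recorded in the output.
#'
#' @param x FASTA path(s), records, or a `meso_report`.
#' @param config a [meso_config()].
#' @param refset reference domains (see [extract_domains()]).
#' @param threshold,linkage override the config values.
#' @return object of class `meso_demarcation`: `distances`, `partition`,
#'   `domains`, `excluded`, `model`.
#' @export
demarcate_set <- function(x, config = meso_config(),
                          refset = reference_domains(),
                          threshold = config$threshold,
                          linkage = config$linkage) {
  rep <- if (inherits(x, "meso_report")) x
         else if (is.character(x) && length(x) > 1L) {
    recs <- unlist(lapply(x, read_fasta), recursive = FALSE)
    annotate_genome(recs, config)
  } else annotate_genome(x, config)
  doms <- list(); excluded <- list()
  for (id in names(rep$annotations)) {
    a <- rep$annotations[[id]]
    if (is.null(a$pp1ab)) { excluded[[id]] <- "no pp1ab"; next }
    d <- tryCatch(extract_domains(a$pp1ab, refset, taxon = id,
                                  min_score_frac = config$domain_min_score_frac),
                  error = function(e) e)
    if (inherits(d, "error")) excluded[[id]] <- conditionMessage(d)
    else doms[[id]] <- d
  }
  for (id in names(rep$errors)) excluded[[id]] <- rep$errors[[id]]
  if (length(doms) < 2L)
    stop("fewer than two genomes with extractable domains")
  m <- distance_matrix(doms, model = config$model)
  part <- cluster_species(m, t = threshold, linkage = linkage)
  structure(list(distances = m, partition = part, domains = doms,
                 excluded = excluded, model = config$model,
                 gamma = "no rate heterogeneity (no gamma)"),
            class = "meso_demarcation")
}

#' @export
print.meso_demarcation <- function(x, ...) {
  cat(sprintf("<meso_demarcation> %d taxa, model %s (%s)\n",
              nrow(x$distances), x$model, x$gamma))
  print(x$partition)
  if (length(x$excluded))
    for (id in names(x$excluded))
      cat("  excluded", id, ":", x$excluded[[id]], "\n")
  invisible(x)
}

#' Write a distance matrix as square TSV
#' @param m distance matrix.
#' @param path output path.
#' @export
write_distance_tsv <- function(m, path) {
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a species partition as two-column TSV
#' @param partition a `meso_partition`.
#' @param path output path.
#' @export
write_partition_tsv <- function(partition, path) {
  df <- data.frame(taxon = names(partition$membership),
                   species = unname(partition$membership))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sliding-window divergence profile as TSV
#' @param profile result of [sliding_window_divergence()].
#' @param path output path.
#' @export
write_window_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
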