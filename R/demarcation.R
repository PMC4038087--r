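# Conserved replicase domain extraction, distance matrices, species
# clustering at a PED threshold, and sliding-window divergence profiles.

.DOMAIN_ORDER <- c("3CLpro", "RdRp", "ZnHel1")

#' Extract conserved replicase domains from a pp1ab polyprotein
#'
#' Each domain (3CLpro, RdRp, ZnHel1) is located by optimal local alignment
#' of the reference domain sequence to the polyprotein (BLOSUM62); the hit is
#' extrapolated to the full reference length so boundary residues trimmed by
#' the local alignment do not shift the reported span. The concatenation
#' order is fixed: 3CLpro, RdRp, ZnHel1.
#'
#' @param pp1ab amino-acid sequence of the frameshift polyprotein.
#' @param refset named character vector (or list) of reference domain
#'   sequences with names `3CLpro`, `RdRp`, `ZnHel1`; default
#'   [reference_domains()].
#' @param taxon label for the sequence.
#' @param min_score_frac minimum local-alignment score as a fraction of the
#'   reference self-score (default 0.25) below which the domain is declared
#'   missing.
#' @return object of class `meso_domains` with per-domain sequences, spans
#'   (0-based, in pp1ab coordinates), scores, and the concatenation.
#' @export
extract_domains <- function(pp1ab, refset = reference_domains(),
                            taxon = "query", min_score_frac = 0.25) {
  if (inherits(pp1ab, "meso_fusion")) pp1ab <- pp1ab$protein
  .check_protein(pp1ab, "pp1ab")
  refset <- unlist(refset)
  if (!all(.DOMAIN_ORDER %in% names(refset)))
    stop("refset must provide domains: ", paste(.DOMAIN_ORDER, collapse = ", "))
  sm <- .protein_score_matrix("BLOSUM62")
  doms <- character(0); spans <- list(); scores <- numeric(0)
  for (dn in .DOMAIN_ORDER) {
    ref <- refset[[dn]]
    self <- Biostrings::pairwiseAlignment(
      ref, ref, type = "local", substitutionMatrix = sm,
      gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(
      ref, pp1ab, type = "local", substitutionMatrix = sm,
      gapOpening = 10, gapExtension = 0.5)
    sc <- Biostrings::score(pa)
    if (sc < min_score_frac * self)
      stop(sprintf("domain-missing error: %s (score %.1f < %.1f) in %s",
                   dn, sc, min_score_frac * self, taxon))
    ps <- Biostrings::start(Biostrings::pattern(pa))   # 1-based in ref
    pe <- Biostrings::end(Biostrings::pattern(pa))
    ss <- Biostrings::start(Biostrings::subject(pa))   # 1-based in pp1ab
    se <- Biostrings::end(Biostrings::subject(pa))
    # extrapolate the hit to the full reference span
    est_start <- max(1L, ss - (ps - 1L))
    est_end <- min(nchar(pp1ab), se + (nchar(ref) - pe))
    doms[dn] <- substr(pp1ab, est_start, est_end)
    spans[[dn]] <- .span(est_start - 1L, est_end)
    scores[dn] <- sc
  }
  structure(list(taxon = taxon, domains = doms,
                 spans = do.call(rbind, spans), scores = scores,
                 concat = paste(doms[.DOMAIN_ORDER], collapse = "")),
            class = "meso_domains")
}

#' @export
print.meso_domains <- function(x, ...) {
  cat(sprintf("<meso_domains> %s: %s; concat %d aa\n", x$taxon,
              paste(sprintf("%s %d aa", names(x$domains),
                            nchar(x$domains)), collapse = ", "),
              nchar(x$concat)))
  invisible(x)
}

.ref_cache <- new.env(parent = emptyenv())

#' Packaged reference replicase domains (synthetic)
#'
#' A deterministic synthetic reference domain set built from the canonical
#' default-specification genome of [make_genome()]. It stands in for a
#' curated set of real mesonivirus 3CLpro/RdRp/ZnHel1 sequences, which are
#' not shipped with the package; supply your own curated reference via the
#' `refset` argument of [extract_domains()] / [demarcate_set()] when
#' analysing real genomes.
#'
#' @return named character vector with elements `3CLpro`, `RdRp`, `ZnHel1`.
#' @export
reference_domains <- function() {
  if (!is.null(.ref_cache$ref)) return(.ref_cache$ref)
  g <- make_genome(genome_spec(seed = 104729L))
  ref <- vapply(.DOMAIN_ORDER, function(dn) {
    sp <- g$truth$domains[dn, ]
    substr(g$truth$pp1ab, sp["start"] + 1L, sp["end"])
  }, character(1))
  .ref_cache$ref <- ref
  ref
}

#' Pairwise evolutionary distance matrix
#'
#' Symmetric matrix of ML distances (see [wag_ml_distance()]) over a set of
#' sequences, typically concatenated replicase domains.
#'
#' @param seqs named character vector of amino-acid sequences (or a list of
#'   `meso_domains`, whose concatenations are used).
#' @param model `"WAG"` or `"Poisson"`.
#' @return symmetric numeric matrix with taxon dimnames.
#' @export
distance_matrix <- function(seqs, model = "WAG") {
  if (is.list(seqs) && all(vapply(seqs, inherits, logical(1), "meso_domains")))
    seqs <- stats::setNames(vapply(seqs, `[[`, character(1), "concat"),
                            vapply(seqs, `[[`, character(1), "taxon"))
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dij <- wag_ml_distance(seqs[[i]], seqs[[j]], model = model)
    d[i, j] <- d[j, i] <- as.numeric(dij)
  }
  d
}

#' Cluster taxa into putative species at a distance threshold
#'
#' Agglomerative clustering of a distance matrix cut at threshold `t`
#' (default 0.032, the proposed mesonivirus species demarcation cutoff).
#' Single linkage (default) operationalizes the pairwise criterion directly:
#' any two taxa at distance <= t end up in the same species. Clusters are
#' ordered by their smallest member (matrix order).
#'
#' @param m symmetric distance matrix with dimnames.
#' @param t distance threshold (default 0.032).
#' @param linkage `"single"` or `"complete"`.
#' @return object of class `meso_partition`: threshold, linkage, `clusters`
#'   (list of taxon character vectors) and `membership` (named integer).
#' @export
cluster_species <- function(m, t = 0.032, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  taxa <- rownames(m)
  if (nrow(m) == 1L) {
    memb <- stats::setNames(1L, taxa)
  } else {
    hc <- stats::hclust(stats::as.dist(m), method = linkage)
    # cutree() does not accept an infinite height
    h <- if (is.finite(t)) t else max(hc$height)
    memb <- stats::cutree(hc, h = h)
  }
  # renumber clusters by first appearance in taxon order
  first <- order(match(unique(memb[taxa]), memb[taxa]))
  relab <- stats::setNames(seq_along(unique(memb[taxa])), unique(memb[taxa]))
  memb <- stats::setNames(as.integer(relab[as.character(memb[taxa])]), taxa)
  clusters <- split(taxa, memb)
  names(clusters) <- NULL
  structure(list(threshold = t, linkage = linkage, clusters = clusters,
                 membership = memb),
            class = "meso_partition")
}

#' @export
print.meso_partition <- function(x, ...) {
  cat(sprintf("<meso_partition> %d cluster(s) at t = %g (%s linkage)\n",
              length(x$clusters), x$threshold, x$linkage))
  for (i in seq_along(x$clusters))
    cat(sprintf("  species %d: %s\n", i, paste(x$clusters[[i]],
                                               collapse = ", ")))
  invisible(x)
}

# pairwise p-distance on two aligned chunks, gaps/ambiguity excluded
.p_dist <- function(a, b) {
  ok <- a %in% .AA20 & b %in% .AA20
  n <- sum(ok)
  if (n == 0L) return(NA_real_)
  sum(a[ok] != b[ok]) / n
}

#' Sliding-window divergence within and between species
#'
#' Mean pairwise amino-acid p-distance per window, within each species
#' (species with at least two members) and between species, gaps excluded
#' pairwise. Windows with zero comparable sites are recorded as `NA`, not
#' zero.
#'
#' @param msa named character vector of aligned amino-acid sequences (equal
#'   lengths) or an `AAStringSet`.
#' @param partition a `meso_partition` over (a subset of) the alignment
#'   names.
#' @param w window size in residues (default 100).
#' @param step step size in residues (default 25).
#' @return data.frame with window_start (0-based), within_mean, between_mean;
#'   attributes `w` and `step`.
#' @export
sliding_window_divergence <- function(msa, partition, w = 100L, step = 25L) {
  if (methods::is(msa, "XStringSet")) {
    msa <- stats::setNames(as.character(msa), names(msa))
  }
  stopifnot(inherits(partition, "meso_partition"))
  taxa <- names(partition$membership)
  if (!all(taxa %in% names(msa)))
    stop("alignment is missing taxa: ",
         paste(setdiff(taxa, names(msa)), collapse = ", "))
  msa <- msa[taxa]
  L <- unique(nchar(msa))
  if (length(L) != 1L) stop("aligned sequences must have equal length")
  stopifnot(w <= L, step >= 1L)
  chars <- lapply(msa, function(s) .chars(toupper(s)))
  memb <- partition$membership
  pairs <- utils::combn(taxa, 2L)
  within <- memb[pairs[1L, ]] == memb[pairs[2L, ]]
  starts <- seq.int(0L, by = step, length.out = (L - w) %/% step + 1L)
  res <- lapply(starts, function(s) {
    idx <- (s + 1L):(s + w)
    pd <- vapply(seq_len(ncol(pairs)), function(k) {
      .p_dist(chars[[pairs[1L, k]]][idx], chars[[pairs[2L, k]]][idx])
    }, numeric(1))
    c(within_mean = if (any(within) && any(!is.na(pd[within])))
        mean(pd[within], na.rm = TRUE) else NA_real_,
      between_mean = if (any(!within) && any(!is.na(pd[!within])))
        mean(pd[!within], na.rm = TRUE) else NA_real_)
  })
  out <- data.frame(window_start = starts, do.call(rbind, res))
  attr(out, "w") <- w; attr(out, "step") <- step
  class(out) <- c("meso_window_profile", "data.frame")
  out
}
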