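#' @include AllClasses.R accessors.R
NULL

#' Filter probes by detection across samples
#'
#' Retains exactly the probes with a strictly positive beta value in
#' strictly more than half of the samples (zero is the probe-level
#' missing-value sentinel).  The sample set is unchanged.
#'
#' @param m a \linkS4class{ProbeBetaMatrix}.
#' @param minFraction minimum detected fraction; a probe is kept when its
#'   detected fraction is strictly greater than this (default 0.5).
#' @return the filtered \linkS4class{ProbeBetaMatrix}.
#' @export
filterProbes <- function(m, minFraction = 0.5) {
  stopifnot(is(m, "ProbeBetaMatrix"))
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("filterProbes: empty matrix")
  v <- featureValues(m)
  keep <- rowMeans(v > 0) > minFraction
  m[keep, ]
}

#' Impute probe-level missing beta values
#'
#' Replaces each zero entry by the mean of that probe's non-zero entries;
#' non-zero entries are untouched.  Probes with no non-zero value cannot be
#' imputed: run [filterProbes()] first.
#'
#' @param m a \linkS4class{ProbeBetaMatrix} (post-filtering).
#' @return the imputed \linkS4class{ProbeBetaMatrix}; no zeros remain.
#' @export
imputeProbes <- function(m) {
  stopifnot(is(m, "ProbeBetaMatrix"))
  v <- featureValues(m)
  nz <- v > 0
  nNonzero <- rowSums(nz)
  if (any(nNonzero == 0L))
    stop("imputeProbes: probe(s) with all-zero values (run filterProbes first): ",
         paste(utils::head(rownames(v)[nNonzero == 0L], 5L), collapse = ", "))
  rowMeanNz <- rowSums(v) / nNonzero
  idx <- which(!nz, arr.ind = TRUE)
  if (nrow(idx))
    v[idx] <- rowMeanNz[idx[, 1L]]
  SummarizedExperiment::assay(m, "values") <- v
  m
}

.asPromoterMap <- function(pm) {
  # accepts a two-column data.frame (probe_id, lncRNA_id) or a named list
  # lncRNA -> probes; returns the data.frame form
  if (is.list(pm) && !is.data.frame(pm)) {
    pm <- data.frame(
      probe_id = unlist(pm, use.names = FALSE),
      lncRNA_id = rep(names(pm), lengths(pm)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("probe_id", "lncRNA_id") %in% colnames(pm)))
  if (anyDuplicated(pm$probe_id))
    stop("promoter map assigns a probe to more than one lncRNA")
  pm
}

#' Average promoter probes into per-lncRNA methylation
#'
#' Collapses imputed probe-level beta values to one row per lncRNA: the
#' unweighted mean over the lncRNA's retained promoter probes, per sample.
#' lncRNAs whose probes were all filtered out are omitted (with a message),
#' not an error.
#'
#' @param m an imputed \linkS4class{ProbeBetaMatrix}.
#' @param promoterMap data.frame with columns \code{probe_id},
#'   \code{lncRNA_id}, or a named list lncRNA -> probe ids.  Each probe may
#'   belong to at most one lncRNA promoter.
#' @return a \linkS4class{FeatureMatrix} on the beta scale, one row per
#'   lncRNA with at least one retained probe.
#' @export
promoterBeta <- function(m, promoterMap) {
  stopifnot(is(m, "ProbeBetaMatrix"))
  pm <- .asPromoterMap(promoterMap)
  v <- featureValues(m)
  pm <- pm[pm$probe_id %in% rownames(v), , drop = FALSE]
  lncs <- unique(pm$lncRNA_id)
  dropped <- setdiff(unique(.asPromoterMap(promoterMap)$lncRNA_id), lncs)
  if (length(dropped))
    message(length(dropped), " lncRNA(s) had no retained promoter probe and were omitted")
  if (!length(lncs))
    stop("promoterBeta: no lncRNA has a retained probe")
  f <- factor(pm$lncRNA_id, levels = lncs)
  sums <- rowsum(v[pm$probe_id, , drop = FALSE], f)
  out <- sums / as.vector(table(f))
  FeatureMatrix(out, group = sampleGroup(m), scale = "beta")
}

#' Log-transform and presence-filter RPKM expression
#'
#' Transforms raw RPKM values to log2(RPKM + 1), keeps the features
#' observed (non-\code{NA}) in strictly more than \code{presenceFraction}
#' of the samples, and fills the remaining missing entries with the
#' feature's mean over its observed samples.
#'
#' @param raw a \linkS4class{FeatureMatrix} on the \code{"rpkm"} scale;
#'   \code{NA} marks a missing measurement.
#' @param presenceFraction strict lower bound on the observed fraction
#'   (default 0.7).
#' @return a complete \linkS4class{FeatureMatrix} on the
#'   \code{"log2rpkm"} scale.
#' @export
normalizeExpression <- function(raw, presenceFraction = 0.7) {
  stopifnot(is(raw, "FeatureMatrix"))
  if (!identical(scaleTag(raw), "rpkm"))
    stop("normalizeExpression expects an rpkm-scale matrix")
  v <- featureValues(raw)
  if (any(v < 0, na.rm = TRUE))
    stop("normalizeExpression: negative RPKM value(s)")
  keep <- rowMeans(!is.na(v)) > presenceFraction
  v <- log2(v[keep, , drop = FALSE] + 1)
  if (anyNA(v)) {
    fill <- rowMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- fill[idx[, 1L]]
  }
  FeatureMatrix(v, group = sampleGroup(raw), scale = "log2rpkm")
}

#' Harmonize feature identifiers to standard gene symbols
#'
#' Replaces feature ids according to a many-to-one mapping table; features
#' absent from the map are dropped (with a message), and features that
#' collapse onto the same standard symbol are averaged.
#'
#' @param features a \linkS4class{FeatureMatrix}.
#' @param idMap named character vector (source id -> standard symbol) or a
#'   two-column data.frame \code{source_id}, \code{symbol}.
#' @return the re-keyed \linkS4class{FeatureMatrix}.
#' @export
harmonizeIds <- function(features, idMap) {
  stopifnot(is(features, "FeatureMatrix"))
  if (is.data.frame(idMap)) {
    stopifnot(all(c("source_id", "symbol") %in% colnames(idMap)))
    idMap <- stats::setNames(as.character(idMap$symbol),
                             as.character(idMap$source_id))
  }
  if (!length(idMap)) stop("harmonizeIds: empty id map")
  if (anyDuplicated(names(idMap)))
    stop("harmonizeIds: a source id maps to more than one symbol")
  v <- featureValues(features)
  mapped <- rownames(v) %in% names(idMap)
  if (any(!mapped))
    message(sum(!mapped), " feature(s) absent from the id map were dropped")
  if (!any(mapped)) stop("harmonizeIds: no feature could be mapped")
  v <- v[mapped, , drop = FALSE]
  sym <- idMap[rownames(v)]
  f <- factor(sym, levels = unique(sym))
  out <- rowsum(v, f) / as.vector(table(f))
  FeatureMatrix(out, group = sampleGroup(features), scale = scaleTag(features))
}

#' Write lncRNA coordinates as BED
#'
#' Minimal BED3+name writer (chromosome, start, end, name; 0-based
#' half-open) so lncRNA sets can be handed to external region-based
#' enrichment tools.
#'
#' @param coords data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{name}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeBed <- function(coords, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% colnames(coords)))
  if (any(coords$end <= coords$start))
    stop("writeBed: end must exceed start (0-based half-open)")
  utils::write.table(coords[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
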