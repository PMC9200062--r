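#' @include AllClasses.R accessors.R
NULL

#' Immune gene panels for the MHC / CYT / CTL scores
#'
#' The three fixed effector panels: the nine-gene MHC class I core set
#' (antigen processing and presentation), the two-gene cytolytic-activity
#' set and the three-gene cytotoxic-T-lymphocyte set.
#'
#' @return list with components \code{mhc} (9 genes), \code{cyt} (GZMA,
#'   PRF1) and \code{ctl} (GZMA, PRF1, GZMB).
#' @export
immuneGenePanel <- function() {
  list(
    mhc = c("HLA-A", "PSMB9", "HLA-B", "PSMB8", "HLA-C", "B2M", "TAP2",
            "NLRC5", "TAP1"),
    cyt = c("GZMA", "PRF1"),
    ctl = c("GZMA", "PRF1", "GZMB")
  )
}

.panelScore <- function(expr, genes, what) {
  v <- if (is(expr, "FeatureMatrix")) featureValues(expr) else as.matrix(expr)
  miss <- setdiff(genes, rownames(v))
  if (length(miss))
    stop(what, " score: panel gene(s) missing from the matrix: ",
         paste(miss, collapse = ", "))
  colMeans(v[genes, , drop = FALSE])
}

#' Per-sample MHC score
#'
#' Arithmetic mean of the nine MHC class I core genes' expression,
#' per sample.
#'
#' @param expr gene-by-sample expression matrix or
#'   \linkS4class{FeatureMatrix} (log2(RPKM+1) scale by convention).
#' @param panel an [immuneGenePanel()].
#' @return named numeric vector, one score per sample.
#' @export
mhcScore <- function(expr, panel = immuneGenePanel()) {
  stopifnot(length(panel$mhc) == 9L)
  .panelScore(expr, panel$mhc, "MHC")
}

#' Per-sample cytolytic-activity (CYT) score
#'
#' Mean of GZMA and PRF1 expression per sample.
#'
#' @inheritParams mhcScore
#' @return named numeric vector.
#' @export
cytScore <- function(expr, panel = immuneGenePanel()) {
  stopifnot(length(panel$cyt) == 2L)
  .panelScore(expr, panel$cyt, "CYT")
}

#' Per-sample cytotoxic-T-lymphocyte (CTL) score
#'
#' Mean of GZMA, PRF1 and GZMB expression per sample.
#'
#' @inheritParams mhcScore
#' @return named numeric vector.
#' @export
ctlScore <- function(expr, panel = immuneGenePanel()) {
  stopifnot(length(panel$ctl) == 3L)
  .panelScore(expr, panel$ctl, "CTL")
}

#' All three immune scores per sample
#'
#' @inheritParams mhcScore
#' @return data.frame with columns \code{sample_id}, \code{mhc},
#'   \code{cyt}, \code{ctl}.
#' @export
immuneScores <- function(expr, panel = immuneGenePanel()) {
  data.frame(sample_id = colnames(if (is(expr, "FeatureMatrix"))
                                    featureValues(expr) else expr),
             mhc = unname(mhcScore(expr, panel)),
             cyt = unname(cytScore(expr, panel)),
             ctl = unname(ctlScore(expr, panel)),
             stringsAsFactors = FALSE)
}

#' Consensus clustering of samples over a key-feature expression profile
#'
#' The conventional consensus-clustering recipe: for each k in
#' \code{kRange}, repeatedly subsample a fraction of the samples, run a
#' partitional base clusterer (k-means) on the subsample, and accumulate
#' the frequency with which each co-sampled pair lands in the same
#' cluster.  The number of clusters is chosen by the largest relative
#' change of the area under the consensus CDF, and final labels come from
#' average-linkage hierarchical clustering of the chosen consensus matrix.
#'
#' @param x feature-by-sample matrix (e.g. the key lncRNAs) or
#'   \linkS4class{FeatureMatrix}; at least 2 features, at least 20
#'   samples.
#' @param kRange candidate cluster counts (default 2:6).
#' @param nResamples subsamples per k (default 100).
#' @param subsampleFrac fraction of samples per subsample (default 0.8).
#' @param seed integer seed; the whole procedure is reproducible.
#' @return list of class \code{"ClusterAssignment"}: \code{labels} (named
#'   by sample, in \code{1..chosenK}), \code{chosenK}, \code{consensus}
#'   (the chosen k's sample-by-sample co-clustering matrix),
#'   \code{deltaArea} (per-k relative CDF-area change), \code{unstable}
#'   (TRUE when the consensus is essentially uninformative).
#' @export
consensusCluster <- function(x, kRange = 2:6, nResamples = 100,
                             subsampleFrac = 0.8, seed = 1L) {
  v <- if (is(x, "FeatureMatrix")) featureValues(x) else as.matrix(x)
  n <- ncol(v)
  if (nrow(v) < 2L) stop("consensusCluster: need at least 2 features")
  if (n < 20L) stop("consensusCluster: need at least 20 samples")
  if (nrow(unique(t(v))) < max(kRange))
    stop("consensusCluster: degenerate input (fewer distinct sample ",
         "profiles than clusters)")
  set.seed(seed)
  nSub <- max(2L, round(subsampleFrac * n))
  consensusK <- vector("list", length(kRange))
  area <- numeric(length(kRange))
  for (ki in seq_along(kRange)) {
    k <- kRange[ki]
    conn <- matrix(0, n, n)
    both <- matrix(0, n, n)
    for (b in seq_len(nResamples)) {
      idx <- sort(sample.int(n, nSub))
      cl <- tryCatch(
        stats::kmeans(t(v[, idx, drop = FALSE]), centers = k,
                      nstart = 3, iter.max = 30)$cluster,
        error = function(e) stop("consensusCluster: base clusterer failed (",
                                 conditionMessage(e), ")"))
      same <- outer(cl, cl, "==") * 1
      conn[idx, idx] <- conn[idx, idx] + same
      both[idx, idx] <- both[idx, idx] + 1
    }
    M <- ifelse(both > 0, conn / both, 0)
    diag(M) <- 1
    dimnames(M) <- list(colnames(v), colnames(v))
    consensusK[[ki]] <- M
    # area under the empirical CDF of the off-diagonal consensus values
    vals <- sort(M[upper.tri(M)])
    cdf <- seq_along(vals) / length(vals)
    area[ki] <- sum(diff(c(0, vals)) * cdf)
  }
  deltaArea <- c(area[1], diff(area) / utils::head(area, -1))
  names(deltaArea) <- paste0("k", kRange)
  chosen <- which.max(deltaArea)
  M <- consensusK[[chosen]]
  chosenK <- kRange[chosen]
  hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
  labels <- stats::cutree(hc, k = chosenK)
  offdiag <- M[upper.tri(M)]
  structure(list(labels = labels, chosenK = chosenK, consensus = M,
                 deltaArea = deltaArea,
                 unstable = stats::sd(offdiag) < 0.05),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("consensus clustering: k = %d (%s)\n", x$chosenK,
              paste(sprintf("%s=%d", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  if (isTRUE(x$unstable)) cat("  [flagged unstable: near-uniform consensus]\n")
  invisible(x)
}

#' Wilcoxon rank-sum comparison of scores across subtypes
#'
#' Two-sided Wilcoxon rank-sum tests of a per-sample quantity (immune
#' score or mutation count) between subtypes; with more than two subtypes
#' every pair is compared separately.  The test is exact when both groups
#' have at most 10 samples and no ties occur, and uses the tie-corrected
#' normal approximation otherwise (the behavior of
#' [stats::wilcox.test()]).
#'
#' @param values numeric vector of per-sample values, named by sample id
#'   or aligned with \code{labels}.
#' @param labels a \code{ClusterAssignment} (see [consensusCluster()]) or
#'   a vector of group labels.
#' @return data.frame with one row per compared pair: \code{group1},
#'   \code{group2}, \code{n1}, \code{n2}, \code{statistic} (rank-sum W),
#'   \code{p}.
#' @export
compareGroups <- function(values, labels) {
  if (inherits(labels, "ClusterAssignment")) labels <- labels$labels
  if (!is.null(names(values)) && !is.null(names(labels))) {
    common <- intersect(names(values), names(labels))
    values <- values[common]; labels <- labels[common]
  }
  if (length(values) != length(labels))
    stop("compareGroups: values and labels do not align")
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("compareGroups: need at least two groups")
  tab <- table(labels)
  if (any(tab == 0L)) stop("compareGroups: empty group")
  pairs <- utils::combn(as.character(groups), 2)
  out <- apply(pairs, 2, function(pr) {
    x <- values[labels == pr[1]]; y <- values[labels == pr[2]]
    wt <- suppressWarnings(stats::wilcox.test(x, y,
                                              alternative = "two.sided"))
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(x), n2 = length(y),
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
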