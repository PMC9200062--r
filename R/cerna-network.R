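#' @include AllClasses.R accessors.R
NULL

#' Upper-tail hypergeometric test for shared miRNA targets
#'
#' For an lncRNA with K target miRNAs and an mRNA with M target miRNAs in
#' a universe of N miRNAs, the probability of sharing at least k targets
#' by chance: \eqn{P(X \ge k)} with \eqn{X \sim
#' \mathrm{Hypergeometric}(N, K, M)}.  Vectorized over all arguments.
#'
#' @param k observed shared-target count, \eqn{0 \le k \le \min(K, M)}.
#' @param K lncRNA target-set size.
#' @param M mRNA target-set size.
#' @param N miRNA universe size; \eqn{K, M \le N}.
#' @return upper-tail p-value(s).
#' @examples
#' hypergeomSharedTest(5, 5, 5, 10)  # 1/choose(10, 5)
#' @export
hypergeomSharedTest <- function(k, K, M, N) {
  if (any(k < 0) || any(K < 0) || any(M < 0) || any(N < 0))
    stop("hypergeomSharedTest: counts must be non-negative")
  if (any(K > N) || any(M > N))
    stop("hypergeomSharedTest: target-set sizes cannot exceed the universe")
  if (any(k > pmin(K, M)))
    stop("hypergeomSharedTest: shared count cannot exceed either set size")
  stats::phyper(k - 1, m = K, n = N - K, k = M, lower.tail = FALSE)
}

#' Pearson co-expression with a t-approximation p-value
#'
#' @param x,y numeric expression vectors of equal length (>= 3 samples),
#'   neither constant.
#' @return list with \code{r} and the two-sided \code{p} from the
#'   t-approximation on \eqn{n - 2} degrees of freedom.
#' @export
expressionCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("expressionCorrelation: unequal lengths")
  if (length(x) < 3L) stop("expressionCorrelation: need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("expressionCorrelation: correlation undefined for a constant vector")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' ceRNA screening thresholds
#'
#' @param minShared strict lower bound on the shared-miRNA count; the
#'   screening convention is "more than two", i.e. pairs need at least 3
#'   shared miRNAs (default 2, applied strictly).
#' @param maxHyperP raw hypergeometric p threshold (default 0.05).
#' @param minR strict lower bound on tumor Pearson correlation (default
#'   0.3).
#' @param maxCorP raw correlation p threshold (default 0.05).
#' @param adjustHyper optionally BH-adjust the hypergeometric p-values
#'   before thresholding (default \code{FALSE}: raw p, the screening
#'   convention).
#' @return validated threshold list.
#' @export
cernaThresholds <- function(minShared = 2, maxHyperP = 0.05, minR = 0.3,
                            maxCorP = 0.05, adjustHyper = FALSE) {
  stopifnot(minShared >= 0, maxHyperP > 0, maxHyperP <= 1,
            minR >= -1, minR <= 1, maxCorP > 0, maxCorP <= 1)
  list(minShared = minShared, maxHyperP = maxHyperP, minR = minR,
       maxCorP = maxCorP, adjustHyper = adjustHyper)
}

.targetIncidence <- function(targets, universe) {
  m <- matrix(FALSE, length(targets), length(universe),
              dimnames = list(names(targets), universe))
  for (i in seq_along(targets))
    m[i, targets[[i]]] <- TRUE
  m
}

#' Build a per-cancer ceRNA network
#'
#' Screens every lncRNA-mRNA pair in three conjunctive steps: (1) shared
#' miRNA targets strictly more than \code{minShared}; (2) upper-tail
#' hypergeometric p below \code{maxHyperP}; (3) Pearson correlation of
#' their expression across tumor samples above \code{minR} with p below
#' \code{maxCorP}.
#'
#' @param targets a \linkS4class{TargetMap}.
#' @param lncExpr,mrnaExpr log2rpkm-scale \linkS4class{FeatureMatrix}
#'   objects sharing the same samples.
#' @param thresholds a [cernaThresholds()] list.
#' @param cancer label stored on the edges (default \code{"cancer"}).
#' @param tumorOnly compute correlations on tumor samples only (default
#'   \code{TRUE}; the network describes tumor co-expression).
#' @return a \linkS4class{CeRNANetwork}.
#' @export
buildCernaNetwork <- function(targets, lncExpr, mrnaExpr,
                              thresholds = cernaThresholds(),
                              cancer = "cancer", tumorOnly = TRUE) {
  stopifnot(is(targets, "TargetMap"),
            is(lncExpr, "FeatureMatrix"), is(mrnaExpr, "FeatureMatrix"))
  emptyEdges <- data.frame(cancer = character(0), lnc = character(0),
                           mrna = character(0), shared_k = integer(0),
                           hyper_p = numeric(0), r = numeric(0),
                           p = numeric(0), stringsAsFactors = FALSE)
  lt <- lncTargets(targets); mt <- mrnaTargets(targets)
  lt <- lt[names(lt) %in% rownames(lncExpr)]
  mt <- mt[names(mt) %in% rownames(mrnaExpr)]
  if (!length(lt) || !length(mt)) {
    warning("empty target map (after matching to expression); empty network")
    return(new("CeRNANetwork", edges = emptyEdges, thresholds = thresholds))
  }
  uni <- mirnaUniverse(targets)
  N <- length(uni)
  li <- .targetIncidence(lt, uni)
  mi <- .targetIncidence(mt, uni)
  shared <- li %*% t(mi)                       # lnc x mrna shared counts
  Ksz <- rowSums(li); Msz <- rowSums(mi)

  idx <- which(shared > thresholds$minShared, arr.ind = TRUE)
  if (!nrow(idx))
    return(new("CeRNANetwork", edges = emptyEdges, thresholds = thresholds))
  k <- shared[idx]
  hp <- hypergeomSharedTest(k, Ksz[idx[, 1L]], Msz[idx[, 2L]], N)
  hpAdj <- if (isTRUE(thresholds$adjustHyper)) bhFdr(hp) else hp
  keep <- hpAdj < thresholds$maxHyperP
  idx <- idx[keep, , drop = FALSE]; k <- k[keep]; hp <- hp[keep]
  if (!nrow(idx))
    return(new("CeRNANetwork", edges = emptyEdges, thresholds = thresholds))

  samp <- intersect(colnames(lncExpr), colnames(mrnaExpr))
  if (tumorOnly) samp <- intersect(samp, tumorSamples(lncExpr))
  if (length(samp) < 3L)
    stop("buildCernaNetwork: fewer than 3 shared samples for correlation")
  lx <- featureValues(lncExpr)[, samp, drop = FALSE]
  mx <- featureValues(mrnaExpr)[, samp, drop = FALSE]
  n <- length(samp)
  lncIds <- rownames(li)[idx[, 1L]]
  mrnaIds <- rownames(mi)[idx[, 2L]]
  rmat <- stats::cor(t(lx[unique(lncIds), , drop = FALSE]),
                     t(mx[unique(mrnaIds), , drop = FALSE]))
  r <- rmat[cbind(match(lncIds, rownames(rmat)),
                  match(mrnaIds, colnames(rmat)))]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pcor <- 2 * stats::pt(-abs(tstat), df = n - 2)
  keep <- !is.na(r) & r > thresholds$minR & pcor < thresholds$maxCorP
  edges <- data.frame(cancer = rep(cancer, sum(keep)), lnc = lncIds[keep],
                      mrna = mrnaIds[keep], shared_k = as.integer(k[keep]),
                      hyper_p = hp[keep], r = r[keep], p = pcor[keep],
                      stringsAsFactors = FALSE)
  new("CeRNANetwork", edges = edges, thresholds = thresholds)
}

#' Restrict a ceRNA network to candidate lncRNAs
#'
#' @param net a \linkS4class{CeRNANetwork}.
#' @param candidates character vector of lncRNA ids.
#' @return the induced sub-network containing exactly the pairs whose
#'   lncRNA is a candidate (possibly empty).
#' @export
mapCandidates <- function(net, candidates) {
  stopifnot(is(net, "CeRNANetwork"))
  e <- cernaEdges(net)
  new("CeRNANetwork", edges = e[e$lnc %in% candidates, , drop = FALSE],
      thresholds = net@thresholds)
}

#' Pan-cancer ceRNA sub-network of shared mRNAs
#'
#' Restricts the per-cancer candidate sub-networks to mRNAs that partner
#' some candidate lncRNA in strictly more than \code{minCancers} cancers.
#'
#' @param nets named list (cancer -> \linkS4class{CeRNANetwork}).
#' @param candidates character vector of candidate lncRNA ids.
#' @param minCancers strict lower bound on the number of cancers sharing
#'   an mRNA (default 4).
#' @return list with \code{edges} (combined edge data.frame tagged by
#'   cancer) and \code{mrnaSummary} (per retained mRNA: \code{n_cancers}
#'   and per-cancer mean correlation and partner count).
#' @export
panCancerSubnetwork <- function(nets, candidates, minCancers = 4) {
  if (length(nets) < 2L)
    stop("panCancerSubnetwork: need at least two cancers")
  sub <- lapply(names(nets), function(cn) {
    e <- cernaEdges(mapCandidates(nets[[cn]], candidates))
    e$cancer <- rep(cn, nrow(e))
    e
  })
  edges <- do.call(rbind, sub)
  empty <- list(edges = edges[0, , drop = FALSE],
                mrnaSummary = data.frame(mrna = character(0),
                                         n_cancers = integer(0)))
  if (is.null(edges) || !nrow(edges)) return(empty)
  nCan <- tapply(edges$cancer, edges$mrna, function(x) length(unique(x)))
  keepM <- names(nCan)[nCan > minCancers]
  edges <- edges[edges$mrna %in% keepM, , drop = FALSE]
  if (!nrow(edges)) return(empty)
  agg <- stats::aggregate(r ~ mrna + cancer, data = edges, FUN = mean)
  cnt <- stats::aggregate(lnc ~ mrna + cancer, data = edges,
                          FUN = function(x) length(unique(x)))
  names(agg)[3] <- "mean_r"; names(cnt)[3] <- "n_lnc"
  summ <- merge(agg, cnt, by = c("mrna", "cancer"))
  summ$n_cancers <- as.integer(nCan[summ$mrna])
  list(edges = edges, mrnaSummary = summ[order(summ$mrna, summ$cancer), ])
}
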