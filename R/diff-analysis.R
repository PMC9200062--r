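#' @include AllClasses.R accessors.R
NULL

#' Thresholds for differential methylation / expression calls
#'
#' @param deltaBetaMin minimum absolute group-mean beta difference for a
#'   methylation candidate (default 0.1; strict inequality).
#' @param logfcMin minimum absolute log fold change on the test scale
#'   (default 1; strict).
#' @param fdrMax BH-adjusted FDR threshold (default 0.05; strict).
#' @param methylationScale scale on which the moderated test is run for
#'   beta matrices.  \code{"m-value"} (default) tests log2(beta/(1-beta));
#'   a fold-change criterion of |logFC| > 1 is unattainable on raw beta
#'   values in \[0, 1\], so a log-type scale is required for that filter to
#'   bite.  \code{"log2beta"} and raw \code{"beta"} are selectable.
#' @return a validated list of thresholds.
#' @export
testConfig <- function(deltaBetaMin = 0.1, logfcMin = 1, fdrMax = 0.05,
                       methylationScale = c("m-value", "log2beta", "beta")) {
  methylationScale <- match.arg(methylationScale)
  stopifnot(deltaBetaMin > 0, logfcMin > 0, fdrMax > 0, fdrMax < 1)
  list(deltaBetaMin = deltaBetaMin, logfcMin = logfcMin, fdrMax = fdrMax,
       methylationScale = methylationScale)
}

#' Absolute group-mean beta difference per feature
#'
#' The candidate-screening statistic for differential methylation: the
#' absolute difference between the mean beta of tumor samples and the mean
#' beta of normal samples, per feature.
#'
#' @param m a beta-scale \linkS4class{FeatureMatrix} with both groups
#'   non-empty.
#' @return named numeric vector of absolute differences, one per feature.
#' @export
deltaBeta <- function(m) {
  stopifnot(is(m, "FeatureMatrix"))
  if (!identical(scaleTag(m), "beta"))
    stop("deltaBeta is defined on the beta scale")
  g <- sampleGroup(m)
  if (!any(g == "tumor") || !any(g == "normal"))
    stop("deltaBeta: both tumor and normal groups must be non-empty")
  v <- featureValues(m)
  abs(rowMeans(v[, g == "tumor", drop = FALSE]) -
      rowMeans(v[, g == "normal", drop = FALSE]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) with input validation.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of BH-adjusted q-values, capped at 1.
#' @export
bhFdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("bhFdr: p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Newton solve of trigamma(x) = y, vectorized; used by the variance-prior
# moment matching.
.trigammaInverse <- function(y) {
  x <- 0.5 + 1 / y
  x[y > 1e7] <- 1 / sqrt(y[y > 1e7])
  x[y < 1e-6] <- 1 / y[y < 1e-6]
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Fit the empirical-Bayes variance prior
#'
#' Moment-matches a scaled inverse-chi-square prior to the per-feature
#' sample variances on the log scale: with \eqn{e_g = \log s_g^2 -
#' \psi(d/2) + \log(d/2)}, the prior degrees of freedom solve
#' \eqn{\psi'(d_0/2) = 2(\mathrm{var}(e) - \psi'(d/2))/2} by Newton
#' inversion of the trigamma function, and the prior variance follows from
#' the mean of \eqn{e}.  Closed-form and deterministic.
#'
#' @param s2 per-feature sample variances (pooled within groups).
#' @param df residual degrees of freedom of each \code{s2}.
#' @return list with \code{dfPrior} (possibly \code{Inf}) and
#'   \code{s2Prior}.
#' @export
fitVariancePrior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok))
    stop("fitVariancePrior: all features constant; no variance to fit")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    list(dfPrior = Inf, s2Prior = exp(mean(e)))
  } else {
    df0 <- 2 * .trigammaInverse(evar)
    list(dfPrior = df0,
         s2Prior = exp(mean(e) + digamma(df0 / 2) - log(df0 / 2)))
  }
}

.testScaleValues <- function(m, scale, epsilon = 1e-6) {
  v <- featureValues(m)
  if (identical(scaleTag(m), "beta")) {
    switch(scale,
      "m-value" = {
        b <- pmin(pmax(v, epsilon), 1 - epsilon)
        log2(b / (1 - b))
      },
      "log2beta" = log2(v + epsilon),
      "beta" = v)
  } else {
    v
  }
}

#' Empirical-Bayes moderated two-group t-test
#'
#' For each feature, the group difference of means on the test scale is
#' divided by a shrunken standard error: the per-feature pooled variance
#' \eqn{s^2} (with \eqn{d = n_t + n_n - 2} df) is combined with the fitted
#' prior as \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)}, and
#' \eqn{\tilde t = \mathrm{logfc} / (\tilde s \sqrt{1/n_t + 1/n_n})} is
#' referred to a t distribution on \eqn{d_0 + d} degrees of freedom.
#' With \code{dfPrior = 0} the statistic reduces exactly to the ordinary
#' pooled two-sample t-test.
#'
#' @param m a \linkS4class{FeatureMatrix} (beta or log2rpkm scale) with
#'   tumor and normal samples.
#' @param scale test scale for beta matrices (see [testConfig()]); ignored
#'   for expression matrices, which are tested as-is.
#' @param dfPrior optional override of the prior degrees of freedom
#'   (\code{0} disables shrinkage); by default fitted from the data by
#'   [fitVariancePrior()].
#' @param epsilon clamp used by the beta-to-M-value transform.
#' @return a \linkS4class{DiffResult} with per-feature \code{mean_tumor},
#'   \code{mean_normal} (matrix scale), \code{delta_beta} (beta scale
#'   only), \code{logfc}, \code{t}, \code{p}, \code{q} and a
#'   \code{direction} column initialized to \code{"none"}; the fitted
#'   hyperparameters sit in \code{metadata()}.
#' @export
moderatedTTest <- function(m, scale = c("m-value", "log2beta", "beta"),
                           dfPrior = NULL, epsilon = 1e-6) {
  stopifnot(is(m, "FeatureMatrix"))
  scale <- match.arg(scale)
  g <- sampleGroup(m)
  n1 <- sum(g == "tumor"); n2 <- sum(g == "normal")
  if (n1 < 1L || n2 < 1L)
    stop("moderatedTTest: both groups must be non-empty")
  d <- n1 + n2 - 2L
  if (d < 1L)
    stop("moderatedTTest: need at least 3 samples for a residual variance")
  v <- featureValues(m)
  mt <- rowMeans(v[, g == "tumor", drop = FALSE])
  mn <- rowMeans(v[, g == "normal", drop = FALSE])

  tv <- .testScaleValues(m, scale, epsilon)
  xt <- tv[, g == "tumor", drop = FALSE]
  xn <- tv[, g == "normal", drop = FALSE]
  logfc <- rowMeans(xt) - rowMeans(xn)
  ss1 <- rowSums((xt - rowMeans(xt))^2)
  ss2 <- rowSums((xn - rowMeans(xn))^2)
  s2 <- (ss1 + ss2) / d

  if (is.null(dfPrior)) {
    prior <- fitVariancePrior(s2, d)
  } else {
    stopifnot(dfPrior >= 0)
    prior <- list(dfPrior = dfPrior,
                  s2Prior = if (dfPrior > 0) fitVariancePrior(s2, d)$s2Prior
                            else NA_real_)
  }
  d0 <- prior$dfPrior
  s2tilde <- if (is.infinite(d0)) {
    rep(prior$s2Prior, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * prior$s2Prior + d * s2) / (d0 + d)
  }
  se <- sqrt(s2tilde * (1 / n1 + 1 / n2))
  tstat <- logfc / se
  tstat[se == 0 & logfc == 0] <- 0
  dfTotal <- d0 + d
  p <- if (is.infinite(dfTotal)) 2 * stats::pnorm(-abs(tstat))
       else 2 * stats::pt(-abs(tstat), df = dfTotal)
  p[se == 0 & logfc != 0] <- 0

  res <- DataFrame(
    mean_tumor = unname(mt), mean_normal = unname(mn),
    delta_beta = if (identical(scaleTag(m), "beta")) unname(abs(mt - mn))
                 else NA_real_,
    logfc = unname(logfc), t = unname(tstat), p = unname(p),
    q = unname(bhFdr(p)),
    direction = rep("none", length(p)),
    row.names = rownames(v)
  )
  out <- new("DiffResult", res)
  metadata(out) <- list(dfPrior = d0, s2Prior = prior$s2Prior,
                        dfResidual = d, s2 = s2, testScale = scale,
                        nTumor = n1, nNormal = n2,
                        matrixScale = scaleTag(m))
  out
}

.applyDirections <- function(res, config, useDeltaBeta) {
  pass <- abs(res$logfc) > config$logfcMin & res$q < config$fdrMax
  if (useDeltaBeta)
    pass <- pass & res$delta_beta > config$deltaBetaMin
  dir <- ifelse(pass & res$logfc > 0, "up",
                ifelse(pass & res$logfc < 0, "down", "none"))
  res$direction <- dir
  res
}

#' Call differentially methylated lncRNAs
#'
#' Candidates need an absolute group-mean beta difference above
#' \code{deltaBetaMin}; calls additionally require |logFC| above
#' \code{logfcMin} on the test scale and BH FDR below \code{fdrMax} (all
#' strict).  \code{direction = "up"} means methylation elevated in tumors.
#'
#' @param m a promoter-level beta-scale \linkS4class{FeatureMatrix}.
#' @param config a [testConfig()].
#' @param dfPrior optional prior-df override passed to [moderatedTTest()].
#' @return a \linkS4class{DiffResult} with direction calls.
#' @export
callDMlncs <- function(m, config = testConfig(), dfPrior = NULL) {
  if (!identical(scaleTag(m), "beta"))
    stop("callDMlncs expects a beta-scale matrix")
  res <- moderatedTTest(m, scale = config$methylationScale, dfPrior = dfPrior)
  .applyDirections(res, config, useDeltaBeta = TRUE)
}

#' Call differentially expressed lncRNAs (or mRNAs)
#'
#' As [callDMlncs()] but on the log2(RPKM+1) scale with no beta-difference
#' candidate filter: |logFC| > \code{logfcMin} and FDR < \code{fdrMax}.
#'
#' @param m a log2rpkm-scale \linkS4class{FeatureMatrix}.
#' @param config a [testConfig()].
#' @param dfPrior optional prior-df override.
#' @return a \linkS4class{DiffResult} with direction calls.
#' @export
callDELncs <- function(m, config = testConfig(), dfPrior = NULL) {
  if (!identical(scaleTag(m), "log2rpkm"))
    stop("callDELncs expects a log2rpkm-scale matrix")
  res <- moderatedTTest(m, dfPrior = dfPrior)
  .applyDirections(res, config, useDeltaBeta = FALSE)
}
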