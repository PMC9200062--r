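#' @include AllClasses.R accessors.R
#' @importFrom survival Surv survfit survdiff
NULL

.checkSurvivalTable <- function(surv) {
  stopifnot(is.data.frame(surv),
            all(c("sample_id", "time", "event") %in% colnames(surv)))
  if (any(!is.finite(surv$time)) || any(surv$time <= 0))
    stop("survival times must be positive")
  if (!all(surv$event %in% c(0, 1, TRUE, FALSE)))
    stop("event must be 0/1 (FALSE = censored)")
  surv$event <- as.integer(surv$event)
  surv
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the right-continuous product-limit survival curve
#' \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}; censored samples
#' leave the risk set without contributing an event.
#'
#' @param surv data.frame with columns \code{sample_id}, \code{time} (> 0)
#'   and \code{event} (1 = death, 0 = censored).
#' @return data.frame of class \code{"kmEstimate"} with one row per
#'   observed time: \code{time}, \code{n_risk}, \code{n_event},
#'   \code{n_censor}, \code{surv}.  Evaluate it with [survProbAt()].
#' @export
kmEstimate <- function(surv) {
  surv <- .checkSurvivalTable(surv)
  if (!nrow(surv)) stop("kmEstimate: empty survival table")
  fit <- survfit(Surv(time, event) ~ 1, data = surv)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("kmEstimate", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km a [kmEstimate()] result.
#' @param t numeric time(s).
#' @return \eqn{\hat S(t)}: 1 before the first observed time, then the
#'   right-continuous step value.
#' @export
survProbAt <- function(km, t) {
  stopifnot(inherits(km, "kmEstimate"))
  vapply(t, function(tt) {
    i <- which(km$time <= tt)
    if (!length(i)) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank comparison over the pooled
#' risk sets, with a 1-df chi-square p-value.
#'
#' @param a,b survival data.frames (see [kmEstimate()]) for the two
#'   groups, both non-empty.
#' @return list with \code{statistic} (chi-square), \code{p}, and the
#'   per-group observed/expected event counts.
#' @export
logrankTest <- function(a, b) {
  a <- .checkSurvivalTable(a); b <- .checkSurvivalTable(b)
  if (!nrow(a) || !nrow(b)) stop("logrankTest: both groups must be non-empty")
  df <- rbind(cbind(a, .grp = "a"), cbind(b, .grp = "b"))
  if (sum(df$event) == 0L)
    stop("logrankTest: no events in either group; test undefined")
  sd <- survdiff(Surv(time, event) ~ .grp, data = df)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  list(statistic = unname(sd$chisq), p = p,
       observed = sd$obs, expected = sd$exp)
}

# Log-rank (Nelson-Aalen) scores: a_i = event_i - cumulative hazard at t_i.
# Sum over samples is ~0; a linear rank statistic on these scores is the
# log-rank statistic for the corresponding split.
.logrankScores <- function(time, event) {
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  ut <- unique(t_s[e_s == 1])
  if (!length(ut)) stop("no events; log-rank scores undefined")
  d <- vapply(ut, function(u) sum(t_s == u & e_s == 1), numeric(1))
  nrisk <- vapply(ut, function(u) sum(t_s >= u), numeric(1))
  cumhaz <- cumsum(d / nrisk)
  # cumulative hazard at each sample's own time
  pos <- findInterval(time, ut)
  haz <- c(0, cumhaz)[pos + 1]
  event - haz
}

#' Maximally selected log-rank cut-point
#'
#' Scans every admissible cut between consecutive distinct expression
#' values (each side keeping at least \code{minGroupFrac} of the samples)
#' and, at each cut, computes the standardized linear log-rank-score
#' statistic \eqn{|S - E| / \sqrt{V}} for the induced high/low split.  The
#' maximizing cut is returned with a permutation p-value: expression
#' labels are permuted and the maximal statistic recomputed per
#' permutation, so the selection of the best cut is accounted for.
#'
#' @param expr per-sample expression, named by sample id (or aligned with
#'   \code{surv} rows).
#' @param surv survival data.frame (see [kmEstimate()]).
#' @param minGroupFrac minimum fraction of samples per side (default 0.1).
#' @param nPerm number of label permutations for the p-value (default
#'   1000).
#' @param seed optional integer seed for the permutations.
#' @return list of class \code{"CutpointResult"}: \code{cutpoint}
#'   (midpoint between the flanking expression values), \code{statistic},
#'   \code{p}, \code{nHigh}, \code{nLow}, and \code{cuts} (all admissible
#'   cuts with their statistics).
#' @export
maxstatCutpoint <- function(expr, surv, minGroupFrac = 0.1, nPerm = 1000,
                            seed = NULL) {
  surv <- .checkSurvivalTable(surv)
  stopifnot(minGroupFrac > 0, minGroupFrac < 0.5)
  if (!is.null(names(expr))) {
    common <- intersect(names(expr), surv$sample_id)
    expr <- expr[common]
    surv <- surv[match(common, surv$sample_id), ]
  }
  n <- length(expr)
  if (n != nrow(surv)) stop("expression and survival samples do not match")
  if (n < 10L) stop("maxstatCutpoint: need at least 10 samples")
  a <- .logrankScores(surv$time, surv$event)
  sumA <- sum(a); meanA <- sumA / n
  ssA <- sum((a - meanA)^2)
  if (ssA == 0) stop("maxstatCutpoint: degenerate scores (no variation)")

  ordE <- order(expr)
  eSorted <- expr[ordE]
  minSize <- ceiling(minGroupFrac * n)
  jAll <- seq_len(n - 1)
  admissible <- jAll >= minSize & (n - jAll) >= minSize &
    eSorted[jAll] < eSorted[jAll + 1]
  js <- jAll[admissible]
  if (length(js) < 2L)
    stop("maxstatCutpoint: fewer than 2 admissible cuts")

  stdStat <- function(scores) {
    cs <- cumsum(scores)            # low-group sums in expression order
    m <- n - js                     # high-group sizes
    S <- sum(scores) - cs[js]       # high-group score sums
    E <- m * mean(scores)
    V <- m * (n - m) / (n * (n - 1)) * sum((scores - mean(scores))^2)
    abs(S - E) / sqrt(V)
  }
  obsStats <- stdStat(a[ordE])
  best <- which.max(obsStats)
  stat <- obsStats[best]
  jBest <- js[best]
  cut <- (eSorted[jBest] + eSorted[jBest + 1]) / 2

  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  if (nPerm > 0) {
    for (b in seq_len(nPerm)) {
      if (max(stdStat(sample(a))) >= stat) exceed <- exceed + 1L
    }
  }
  p <- (1 + exceed) / (nPerm + 1)
  structure(list(cutpoint = unname(cut), statistic = unname(stat), p = p,
                 nHigh = n - jBest, nLow = jBest,
                 cuts = data.frame(
                   cut = (eSorted[js] + eSorted[js + 1]) / 2,
                   statistic = obsStats)),
            class = "CutpointResult")
}

#' @export
print.CutpointResult <- function(x, ...) {
  cat(sprintf(
    "maxstat cut-point: %.4g (statistic %.3f, perm p %.4g; high n=%d, low n=%d)\n",
    x$cutpoint, x$statistic, x$p, x$nHigh, x$nLow))
  invisible(x)
}

#' Screen candidate lncRNAs for survival association
#'
#' Runs [maxstatCutpoint()] for each candidate on tumor-sample expression,
#' flags candidates with permutation p below \code{alpha}, and records
#' whether the high-expression group fares worse (carcinogenic reading) or
#' better (suppressor reading) via the log-rank observed/expected events
#' at the chosen split.
#'
#' @param candidates character vector of lncRNA ids.
#' @param expr a log2rpkm \linkS4class{FeatureMatrix}.
#' @param surv survival data.frame over (a subset of) the tumor samples.
#' @param alpha significance level (default 0.05).
#' @param minGroupFrac,nPerm passed to [maxstatCutpoint()].
#' @param seed integer; each candidate uses \code{seed + its index}.
#' @return data.frame with one row per screened candidate: \code{lnc},
#'   \code{cutpoint}, \code{statistic}, \code{p}, \code{n_high},
#'   \code{n_low}, \code{associated}, \code{risk_direction}
#'   (\code{"high_worse"}/\code{"high_better"}).
#' @export
survivalScreen <- function(candidates, expr, surv, alpha = 0.05,
                           minGroupFrac = 0.1, nPerm = 1000, seed = 1L) {
  stopifnot(is(expr, "FeatureMatrix"))
  surv <- .checkSurvivalTable(surv)
  rows <- list()
  missing <- setdiff(candidates, rownames(expr))
  if (length(missing))
    warning("candidate(s) missing from the expression matrix, skipped: ",
            paste(missing, collapse = ", "))
  for (i in seq_along(candidates)) {
    lnc <- candidates[i]
    if (!lnc %in% rownames(expr)) next
    e <- featureValues(expr)[lnc, ]
    cp <- tryCatch(
      maxstatCutpoint(e, surv, minGroupFrac = minGroupFrac,
                      nPerm = nPerm, seed = seed + i),
      error = function(err) {
        warning("candidate ", lnc, " skipped: ", conditionMessage(err))
        NULL
      })
    if (is.null(cp)) next
    common <- intersect(names(e), surv$sample_id)
    sv <- surv[match(common, surv$sample_id), ]
    high <- e[common] > cp$cutpoint
    dirTest <- logrankTest(sv[high, ], sv[!high, ])
    rows[[lnc]] <- data.frame(
      lnc = lnc, cutpoint = cp$cutpoint, statistic = cp$statistic,
      p = cp$p, n_high = cp$nHigh, n_low = cp$nLow,
      associated = cp$p < alpha,
      risk_direction = if (dirTest$observed[1] > dirTest$expected[1])
        "high_worse" else "high_better",
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(lnc = character(0), cutpoint = numeric(0),
                      statistic = numeric(0), p = numeric(0),
                      n_high = integer(0), n_low = integer(0),
                      associated = logical(0),
                      risk_direction = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
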