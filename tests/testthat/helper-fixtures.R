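# Small in-code fixtures shared across the suite.

betaMatrix <- function(values, nTumor, nNormal, probes = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  FeatureMatrix(values,
                group = c(rep("tumor", nTumor), rep("normal", nNormal)),
                scale = "beta", probes = probes)
}

exprMatrix <- function(values, nTumor, nNormal, scale = "log2rpkm") {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  FeatureMatrix(values,
                group = c(rep("tumor", nTumor), rep("normal", nNormal)),
                scale = scale)
}

# random two-group matrix with optional planted mean shifts on the first
# features; returns a log2rpkm FeatureMatrix
randomExprMatrix <- function(nFeatures, nTumor, nNormal, shift = 0,
                             nShifted = 0, sd = 1, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(nFeatures * (nTumor + nNormal), mean = 5, sd = sd),
              nFeatures, nTumor + nNormal)
  if (nShifted > 0)
    v[seq_len(nShifted), seq_len(nTumor)] <-
      v[seq_len(nShifted), seq_len(nTumor)] + shift
  exprMatrix(v, nTumor, nNormal)
}

survTable <- function(time, event, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("p%03d", seq_along(time))
  data.frame(sample_id = ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

# pooled-variance two-sample t-test, textbook form: the no-shrinkage oracle
pooledT <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df = n1 + n2 - 2))
}

# upper-tail hypergeometric by direct pmf summation over choose():
# the brute-force oracle for the shared-miRNA test
bruteHyper <- function(k, K, M, N) {
  kk <- k:min(K, M)
  sum(choose(K, kk) * choose(N - K, M - kk)) / choose(N, M)
}

# exhaustive maxstat oracle: recomputes the standardized log-rank-score
# statistic at every admissible cut with naive loops, independent of the
# vectorized implementation
bruteMaxstat <- function(expr, time, event, minGroupFrac = 0.1) {
  n <- length(expr)
  # Nelson-Aalen scores, computed per sample from first principles
  a <- numeric(n)
  for (i in seq_len(n)) {
    ev <- sort(unique(time[event == 1]))
    ch <- 0
    for (u in ev[ev <= time[i]])
      ch <- ch + sum(time == u & event == 1) / sum(time >= u)
    a[i] <- event[i] - ch
  }
  minSize <- ceiling(minGroupFrac * n)
  cuts <- sort(unique(expr))
  best <- NULL
  for (ci in seq_len(length(cuts) - 1)) {
    cut <- (cuts[ci] + cuts[ci + 1]) / 2
    high <- expr > cut
    m <- sum(high)
    if (m < minSize || (n - m) < minSize) next
    S <- sum(a[high])
    E <- m * mean(a)
    V <- m * (n - m) / (n * (n - 1)) * sum((a - mean(a))^2)
    stat <- abs(S - E) / sqrt(V)
    if (is.null(best) || stat > best$statistic)
      best <- list(cutpoint = cut, statistic = stat)
  }
  best
}
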