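test_that("delta-beta is the absolute difference of group means", {
  v <- rbind(a = c(0.55, 0.55, 0.40, 0.40),
             b = c(0.30, 0.30, 0.30, 0.30),
             c = c(0.20, 0.20, 0.50, 0.50))
  m <- betaMatrix(v, 2, 2)
  db <- deltaBeta(m)
  expect_equal(unname(db["a"]), 0.15)
  expect_equal(unname(db["b"]), 0)
  expect_equal(unname(db["c"]), 0.30)   # absolute value

  colnames(v) <- sprintf("s%02d", 1:4)
  onlyTumor <- FeatureMatrix(v, group = rep("tumor", 4), scale = "beta")
  expect_error(deltaBeta(onlyTumor), "non-empty")
})

test_that("moderated t with zero prior df equals the pooled two-sample t", {
  set.seed(101)
  n1 <- 7; n2 <- 5
  v <- matrix(rnorm(100 * (n1 + n2), sd = runif(100, 0.5, 2)), 100)
  m <- exprMatrix(v, n1, n2)
  res <- moderatedTTest(m, dfPrior = 0)
  for (i in c(1, 17, 50, 100)) {
    oracle <- pooledT(v[i, 1:n1], v[i, (n1 + 1):(n1 + n2)])
    expect_equal(res$t[i], oracle$t, tolerance = 1e-12)
    expect_equal(res$p[i], oracle$p, tolerance = 1e-12)
  }
  expect_equal(S4Vectors::metadata(res)$dfPrior, 0)
})

test_that("moderated t agrees with an independent empirical-Bayes fit", {
  set.seed(7)
  n1 <- 6; n2 <- 4
  v <- matrix(rnorm(500 * (n1 + n2), sd = sqrt(1 / rgamma(500, 4, 4))), 500)
  m <- exprMatrix(v, n1, n2)
  res <- moderatedTTest(m)
  design <- cbind(1, c(rep(1, n1), rep(0, n2)))
  fit <- limma::eBayes(limma::lmFit(v, design))
  expect_equal(S4Vectors::metadata(res)$dfPrior, fit$df.prior,
               tolerance = 1e-6)
  expect_equal(unname(res$t), unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(res$p), unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("shrinkage pools variances toward the common value", {
  # all features share one true variance; the posterior variances should
  # concentrate near it
  set.seed(20)
  n <- 10
  v <- matrix(rnorm(5000 * n, sd = 2), 5000)
  m <- exprMatrix(v, 6, 4)
  res <- moderatedTTest(m)
  md <- S4Vectors::metadata(res)
  d0 <- md$dfPrior; d <- md$dfResidual
  s2t <- if (is.infinite(d0)) rep(md$s2Prior, 5000)
         else (d0 * md$s2Prior + d * md$s2) / (d0 + d)
  expect_true(max(abs(s2t / mean(md$s2) - 1)) < 0.10)
})

test_that("p-values are uniform under the null", {
  set.seed(33)
  v <- matrix(rnorm(2000 * 20), 2000)
  res <- moderatedTTest(exprMatrix(v, 10, 10))
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("constant matrices are rejected", {
  v <- matrix(1, 10, 8)
  rownames(v) <- paste0("f", 1:10); colnames(v) <- paste0("s", 1:8)
  m <- FeatureMatrix(v, group = rep(c("tumor", "normal"), each = 4),
                     scale = "log2rpkm")
  expect_error(moderatedTTest(m), "constant")
})

test_that("BH adjustment follows the step-up procedure", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(c(1, 1)), c(1, 1))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # never more discoveries than unadjusted p < alpha
  set.seed(5)
  p <- runif(500)^2
  expect_lte(sum(bhFdr(p) < 0.05), sum(p < 0.05))
})

test_that("DM calls are the conjunction of all three filters", {
  set.seed(9)
  nT <- 30; nN <- 20
  base <- matrix(rbeta(6 * (nT + nN), 10, 10), 6)
  # f1: clear up-methylation; f2: delta below 0.1; rest null
  base[1, 1:nT] <- rbeta(nT, 24, 6)       # mean .8 vs .5
  base[2, 1:nT] <- rbeta(nT, 220, 180)    # mean .55 vs .5 -> delta .05
  m <- betaMatrix(base, nT, nN)
  res <- callDMlncs(m)
  expect_identical(res$direction[1], "up")
  expect_identical(res$direction[2], "none")   # candidate filter bites
  expect_true(all(res$delta_beta >= 0))
  # q in [0,1]
  expect_true(all(res$q >= 0 & res$q <= 1))
})

test_that("a feature passing delta-beta and FDR but not |logfc| stays none", {
  # raw-beta test scale: logfc equals the beta difference, necessarily < 1
  set.seed(10)
  nT <- 40; nN <- 40
  v <- matrix(rbeta(10 * (nT + nN), 50, 50), 10)
  v[1, 1:nT] <- rbeta(nT, 80, 20)      # delta ~ .3, highly significant
  m <- betaMatrix(v, nT, nN)
  res <- callDMlncs(m, testConfig(methylationScale = "beta"))
  expect_lt(res$q[1], 0.05)
  expect_gt(res$delta_beta[1], 0.1)
  expect_identical(res$direction[1], "none")   # |logfc| <= 1 on raw beta
})

test_that("direction calls are antisymmetric under group swap", {
  set.seed(12)
  cfg <- simulationConfig(nCancers = 1, nLnc = 60, nMrna = 15, nTumor = 25,
                          nNormal = 15,
                          plantedDm = list(
                            list(features = 1:5, delta = 0.3,
                                 direction = "up", cancers = NULL),
                            list(features = 6:10, delta = 0.3,
                                 direction = "down", cancers = NULL)),
                          plantedCerna = list(), subtypeLncs = c(11, 12),
                          seed = 12)
  co <- simulateCohort(cfg)
  m <- promoterBeta(imputeProbes(filterProbes(cohortCancer(co, "C01")$meth)),
                    cohortPromoterMap(co))
  swapped <- FeatureMatrix(featureValues(m),
                           group = ifelse(sampleGroup(m) == "tumor",
                                          "normal", "tumor"),
                           scale = "beta")
  r1 <- callDMlncs(m); r2 <- callDMlncs(swapped)
  expect_identical(r1$direction == "up", r2$direction == "down")
  expect_identical(r1$direction == "down", r2$direction == "up")
  expect_equal(r1$logfc, -r2$logfc)
})

test_that("planted up-methylated features are recovered", {
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    cfg <- simulationConfig(nCancers = 1, nLnc = 100, nMrna = 15,
                            nTumor = 50, nNormal = 20,
                            plantedDm = list(list(features = 1:10,
                                                  delta = 0.3,
                                                  direction = "up",
                                                  cancers = NULL)),
                            plantedCerna = list(), subtypeLncs = c(11, 12),
                            seed = 100 + s)
    co <- simulateCohort(cfg)
    m <- promoterBeta(
      imputeProbes(filterProbes(cohortCancer(co, "C01")$meth)),
      cohortPromoterMap(co))
    res <- callDMlncs(m)
    planted <- sprintf("LNC%04d", 1:10)
    hits <- hits + sum(res[planted, "direction"] == "up")
    total <- total + length(planted)
  }
  expect_gte(hits / total, 0.9)
})

test_that("DE calls use strict thresholds and no delta-beta filter", {
  # logfc exactly 1 must not be called
  v <- rbind(exact1 = c(2.0, 3.0, 1.0, 2.0),
             clear  = c(9.0, 9.5, 1.0, 1.5),
             null1  = c(5.0, 5.2, 5.1, 4.9))
  m <- exprMatrix(v, 2, 2)
  res <- callDELncs(m, dfPrior = 0)
  expect_equal(res$logfc[1], 1)
  expect_identical(res$direction[1], "none")
  expect_true(all(is.na(res$delta_beta)))

  # planted 4-fold over-expression is recovered
  m2 <- randomExprMatrix(200, 50, 20, shift = 2, nShifted = 20, seed = 44)
  r2 <- callDELncs(m2)
  expect_gte(mean(r2$direction[1:20] == "up"), 0.9)
  expect_lte(mean(r2$direction[21:200] != "none"), 0.02)
})
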