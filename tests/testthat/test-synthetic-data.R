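smallConfig <- function(...) {
  simulationConfig(nCancers = 1, nLnc = 80, nMrna = 15, nTumor = 25,
                   nNormal = 12, plantedDm = list(), plantedDe = list(),
                   plantedCerna = list(), subtypeLncs = c(1, 2), ...)
}

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- simulationConfig(nCancers = 2, nLnc = 60, nMrna = 15, nTumor = 15,
                          nNormal = 8, plantedCerna = list(),
                          plantedDm = list(list(features = 1:5, delta = 0.2,
                                                direction = "up",
                                                cancers = NULL)),
                          subtypeLncs = c(6, 7), seed = 7)
  a <- simulateCohort(cfg); b <- simulateCohort(cfg)
  for (cn in cancerNames(a)) {
    expect_identical(featureValues(cohortCancer(a, cn)$meth),
                     featureValues(cohortCancer(b, cn)$meth))
    expect_identical(featureValues(cohortCancer(a, cn)$lncExpr),
                     featureValues(cohortCancer(b, cn)$lncExpr))
    expect_identical(cohortCancer(a, cn)$survival,
                     cohortCancer(b, cn)$survival)
    expect_identical(cohortCancer(a, cn)$mutations,
                     cohortCancer(b, cn)$mutations)
  }
  expect_identical(lncTargets(cohortTargetMap(a)),
                   lncTargets(cohortTargetMap(b)))
  expect_identical(cohortTruth(a), cohortTruth(b))
})

test_that("generated values respect their ranges", {
  co <- simulateCohort(smallConfig(seed = 14))
  cc <- cohortCancer(co, "C01")
  b <- featureValues(cc$meth)
  expect_true(all(b >= 0 & b <= 1))
  expect_true(all(featureValues(cc$lncExpr) >= 0))
  expect_true(all(featureValues(cc$mrnaExpr) >= 0))
  expect_true(all(cc$survival$time > 0))
  expect_true(all(cc$survival$event %in% 0:1))
  expect_true(all(cc$mutations >= 0))
  # missing sentinel present at roughly the configured rate
  expect_gt(mean(b == 0), 0.02)
  expect_lt(mean(b == 0), 0.09)
})

test_that("without planted effects the group difference is centered at zero", {
  cfg <- simulationConfig(nCancers = 1, nLnc = 500, nMrna = 15,
                          nTumor = 25, nNormal = 15, plantedDm = list(),
                          plantedCerna = list(), missingRate = 0,
                          subtypeLncs = c(1, 2), seed = 15)
  co <- simulateCohort(cfg)
  m <- promoterBeta(imputeProbes(filterProbes(cohortCancer(co, "C01")$meth)),
                    cohortPromoterMap(co))
  g <- sampleGroup(m)
  v <- featureValues(m)
  signedDiff <- rowMeans(v[, g == "tumor"]) - rowMeans(v[, g == "normal"])
  expect_lt(abs(mean(signedDiff)), 0.01)
  expect_lt(mean(abs(signedDiff)), 0.05)
})

test_that("planted delta-beta is recovered within sampling error", {
  cfg <- simulationConfig(nCancers = 1, nLnc = 500, nMrna = 15,
                          nTumor = 50, nNormal = 20,
                          plantedDm = list(list(features = 1:50,
                                                delta = 0.25,
                                                direction = "up",
                                                cancers = NULL)),
                          plantedCerna = list(), subtypeLncs = c(51, 52),
                          seed = 16)
  co <- simulateCohort(cfg)
  m <- promoterBeta(imputeProbes(filterProbes(cohortCancer(co, "C01")$meth)),
                    cohortPromoterMap(co))
  g <- sampleGroup(m)
  v <- featureValues(m)
  d <- rowMeans(v[, g == "tumor"]) - rowMeans(v[, g == "normal"])
  planted <- sprintf("LNC%04d", 1:50)
  expect_gte(mean(abs(d[planted] - 0.25) <= 0.05), 0.9)
})

test_that("an infeasible planted effect is rejected with its name", {
  expect_error(
    simulationConfig(nCancers = 1, nLnc = 20, nMrna = 15,
                     plantedDm = list(list(features = 1:2, delta = 0.97,
                                           direction = "up",
                                           cancers = NULL)),
                     plantedCerna = list(), subtypeLncs = c(3, 4)),
    "delta = 0.97")
  expect_error(
    simulationConfig(nCancers = 1, nLnc = 20, nMrna = 15,
                     plantedDm = list(list(features = 1:30, delta = 0.2,
                                           direction = "up",
                                           cancers = NULL)),
                     plantedCerna = list(), subtypeLncs = c(3, 4)),
    "outside 1..nLnc")
})

test_that("target maps guarantee planted sharing and calibrate background", {
  planted <- list(list(lnc = "LNC0001", mrna = "MRNA0001", nShared = 5))
  tm <- simulateTargetMap(40, 20, 60, backgroundDensity = 0.02,
                          plantedCerna = planted, seed = 3)
  shared <- intersect(lncTargets(tm)$LNC0001,
                      mrnaTargets(tm)[["MRNA0001"]])
  expect_gte(length(shared), 5)

  tm0 <- simulateTargetMap(10, 15, 50, backgroundDensity = 0,
                           plantedCerna = list(), seed = 4)
  expect_true(all(lengths(lncTargets(tm0)) == 0))
  expect_true(all(lengths(mrnaTargets(tm0)) == 0))
  expect_error(simulateTargetMap(10, 15, 4, plantedCerna = list(
    list(lnc = "LNC0001", mrna = "MRNA0001", nShared = 5))), "exceeds")

  # mean pairwise shared count ~ nMirna * density^2
  tmBg <- simulateTargetMap(120, 120, 200, backgroundDensity = 0.05,
                            plantedCerna = list(), seed = 5)
  li <- sapply(lncTargets(tmBg), length)
  shared <- outer(seq_len(120), seq_len(120), Vectorize(function(i, j)
    length(intersect(lncTargets(tmBg)[[i]], mrnaTargets(tmBg)[[j]]))))
  expect_equal(mean(shared), 200 * 0.05^2, tolerance = 0.15)
})

test_that("simulated survival honors censoring and hazard structure", {
  expr <- setNames(rnorm(60, 5), sprintf("p%03d", 1:60))
  s0 <- simulateSurvival(expr, hazardRatio = 2, censoringRate = 0,
                         seed = 6)
  expect_true(all(s0$event == 1))
  expect_error(simulateSurvival(numeric(0), 2), "empty")
  expect_error(simulateSurvival(expr, hazardRatio = -1), "hazardRatio")

  # censoring rate is matched in expectation
  set.seed(7)
  fr <- mean(replicate(40, {
    s <- simulateSurvival(setNames(rnorm(100), sprintf("q%03d", 1:100)),
                          hazardRatio = 1, censoringRate = 0.4,
                          seed = sample.int(1e6, 1))
    mean(s$event == 0)
  }))
  expect_equal(fr, 0.4, tolerance = 0.05)

  # HR = 3: the high group dies sooner in nearly every replicate
  wins <- 0L
  for (s in 1:40) {
    ee <- setNames(rnorm(200), sprintf("r%03d", 1:200))
    sv <- simulateSurvival(ee, hazardRatio = 3, censoringRate = 0,
                           seed = 700 + s)
    high <- ee > median(ee)
    if (median(sv$time[high]) < median(sv$time[!high])) wins <- wins + 1L
  }
  expect_gte(wins / 40, 0.95)
})

test_that("a unit hazard ratio keeps the log-rank test at its nominal level", {
  rej <- 0L
  nrep <- 200
  for (s in 1:nrep) {
    ee <- setNames(rnorm(60), sprintf("p%03d", 1:60))
    sv <- simulateSurvival(ee, hazardRatio = 1, censoringRate = 0.2,
                           seed = 900 + s)
    high <- ee > median(ee)
    p <- logrankTest(sv[high, ], sv[!high, ])$p
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / nrep, 0.01)
  expect_lte(rej / nrep, 0.10)
})

test_that("the truth record is consistent with the generated matrices", {
  cfg <- simulationConfig(seed = 18)
  co <- simulateCohort(cfg)
  tr <- cohortTruth(co)
  expect_setequal(names(tr$dm), cancerNames(co))
  lids <- rownames(featureValues(cohortCancer(co, "C01")$lncExpr))
  for (cn in cancerNames(co)) {
    expect_true(all(names(tr$dm[[cn]]) %in% lids))
    expect_true(all(tr$prognostic[[cn]] %in% lids))
  }
  expect_true(all(tr$cerna$lnc %in% lids))
  # planted ceRNA co-expression is near its target on tumor samples
  cc <- cohortCancer(co, "C01")
  lx <- log2(featureValues(cc$lncExpr) + 1)
  mx <- log2(featureValues(cc$mrnaExpr) + 1)
  rs <- mapply(function(l, m) cor(lx[l, ], mx[m, ]),
               tr$cerna$lnc, tr$cerna$mrna)
  expect_gte(mean(rs > 0.4), 0.9)
})
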