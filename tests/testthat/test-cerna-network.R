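test_that("hypergeometric shared-target test matches closed forms", {
  expect_equal(hypergeomSharedTest(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(hypergeomSharedTest(0, 5, 5, 10), 1)
  expect_equal(hypergeomSharedTest(3, 5, 5, 10), 126 / 252,
               tolerance = 1e-12)
  expect_error(hypergeomSharedTest(6, 5, 5, 10), "exceed")
  expect_error(hypergeomSharedTest(2, 11, 5, 10), "universe")
})

test_that("hypergeometric test equals brute-force pmf summation (small grid)", {
  for (N in c(5, 9, 12)) {
    for (K in 0:N) for (M in 0:N) for (k in 0:min(K, M)) {
      expect_equal(hypergeomSharedTest(k, K, M, N), bruteHyper(k, K, M, N),
                   tolerance = 1e-12)
    }
  }
})

test_that("expression correlation returns Pearson r with t-based p", {
  x <- c(1, 2, 3, 4)
  expect_equal(expressionCorrelation(x, 2 * x + 1)$r, 1)
  expect_equal(expressionCorrelation(x, -x)$r, -1)
  out <- expressionCorrelation(x, c(1, 3, 2, 4))
  expect_equal(out$r, 0.8, tolerance = 1e-12)
  expect_equal(out$p, cor.test(x, c(1, 3, 2, 4))$p.value)
  expect_error(expressionCorrelation(x, rep(1, 4)), "constant")
  expect_error(expressionCorrelation(x, 1:3), "unequal")
})

test_that("network construction is a strict conjunction of three filters", {
  mirs <- sprintf("MIR%03d", 1:40)
  # pairA: 5 shared, co-expressed -> kept
  # pairB: exactly 2 shared -> dropped whatever the correlation
  # pairC: 5 shared but anti-correlated -> dropped at the r > 0.3 filter
  # pairD: 12 of 20 shared in a small universe but each set is half the
  #        universe -> shared count high yet also co-expression controls it
  lt <- list(lncA = mirs[1:6], lncB = mirs[c(1, 2, 30)],
             lncC = mirs[11:16])
  mt <- list(mrnaA = mirs[1:5], mrnaB = mirs[c(1, 2, 31)],
             mrnaC = mirs[11:15])
  tm <- TargetMap(lt, mt, universe = mirs)
  set.seed(50)
  n <- 40
  base <- rnorm(n)
  lx <- rbind(lncA = base + rnorm(n, 0, 0.4),
              lncB = rnorm(n),
              lncC = base + rnorm(n, 0, 0.4))
  mx <- rbind(mrnaA = base + rnorm(n, 0, 0.4),
              mrnaB = rnorm(n),
              mrnaC = -base + rnorm(n, 0, 0.4))
  colnames(lx) <- colnames(mx) <- sprintf("s%02d", 1:n)
  le <- FeatureMatrix(lx, group = rep("tumor", n), scale = "log2rpkm")
  me <- FeatureMatrix(mx, group = rep("tumor", n), scale = "log2rpkm")
  net <- buildCernaNetwork(tm, le, me)
  e <- cernaEdges(net)
  expect_true(any(e$lnc == "lncA" & e$mrna == "mrnaA"))
  expect_false(any(e$lnc == "lncB" & e$mrna == "mrnaB"))  # shared_k = 2
  expect_false(any(e$lnc == "lncC" & e$mrna == "mrnaC"))  # r < 0
  expect_true(all(e$shared_k > 2 & e$hyper_p < 0.05 &
                  e$r > 0.3 & e$p < 0.05))
})

test_that("a pair with strong correlation but weak sharing is excluded", {
  mirs <- sprintf("MIR%03d", 1:10)
  # both RNAs target most of a tiny universe: sharing 5 is unremarkable
  tm <- TargetMap(list(lncA = mirs[1:8]), list(mrnaA = mirs[c(1:5, 9, 10)]),
                  universe = mirs)
  expect_gt(hypergeomSharedTest(5, 8, 7, 10), 0.2)
  set.seed(51)
  n <- 30
  base <- rnorm(n)
  lx <- rbind(lncA = base)
  mx <- rbind(mrnaA = base + rnorm(n, 0, 0.2))
  colnames(lx) <- colnames(mx) <- sprintf("s%02d", 1:n)
  le <- FeatureMatrix(lx, group = rep("tumor", n), scale = "log2rpkm")
  me <- FeatureMatrix(mx, group = rep("tumor", n), scale = "log2rpkm")
  net <- buildCernaNetwork(tm, le, me)
  expect_equal(nrow(cernaEdges(net)), 0)
})

test_that("candidate mapping induces the exact sub-network", {
  edges <- data.frame(cancer = "A",
                      lnc = c("l1", "l1", "l1", "l2"),
                      mrna = c("m1", "m2", "m3", "m1"),
                      shared_k = 5L, hyper_p = 0.01, r = 0.5, p = 0.01)
  net <- new("CeRNANetwork", edges = edges, thresholds = cernaThresholds())
  expect_equal(nrow(cernaEdges(mapCandidates(net, c("l1", "l2")))), 4)
  expect_equal(nrow(cernaEdges(mapCandidates(net, "none"))), 0)
  expect_equal(nrow(cernaEdges(mapCandidates(net, "l1"))), 3)
})

test_that("pan-cancer sub-network keeps mRNAs shared by strictly more cancers", {
  mkNet <- function(cancer, mrnas) {
    new("CeRNANetwork",
        edges = data.frame(cancer = cancer, lnc = "l1", mrna = mrnas,
                           shared_k = 5L, hyper_p = 0.01, r = 0.5,
                           p = 0.01),
        thresholds = cernaThresholds())
  }
  # m5 in 5 cancers, m4 in exactly 4
  nets <- lapply(1:5, function(i)
    mkNet(paste0("c", i), c("m5", if (i <= 4) "m4")))
  names(nets) <- paste0("c", 1:5)
  sub <- panCancerSubnetwork(nets, candidates = "l1", minCancers = 4)
  expect_setequal(unique(sub$edges$mrna), "m5")
  expect_equal(unique(sub$mrnaSummary$n_cancers), 5L)
  expect_equal(nrow(sub$edges), 5)
  # disjoint candidates give an empty result
  subEmpty <- panCancerSubnetwork(nets, candidates = "absent",
                                  minCancers = 4)
  expect_equal(nrow(subEmpty$edges), 0)
})

test_that("planted ceRNA pairs survive the screen; null pairs rarely do", {
  cfg <- simulationConfig(seed = 61)
  co <- simulateCohort(cfg)
  cc <- cohortCancer(co, "C01")
  lncN <- normalizeExpression(cc$lncExpr)
  mrnaN <- normalizeExpression(cc$mrnaExpr)
  net <- buildCernaNetwork(cohortTargetMap(co), lncN, mrnaN,
                           cancer = "C01")
  e <- cernaEdges(net)
  tr <- cohortTruth(co)$cerna
  found <- mapply(function(l, m) any(e$lnc == l & e$mrna == m),
                  tr$lnc, tr$mrna)
  expect_gte(mean(found), 0.9)
  nullPass <- nrow(e) - sum(found)
  nNull <- nrow(lncN) * nrow(mrnaN) - nrow(tr)
  expect_lte(nullPass / nNull, 0.005)
})
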