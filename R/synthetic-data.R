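#' @include AllClasses.R accessors.R
NULL

.lncIds <- function(n) sprintf("LNC%04d", seq_len(n))
.mirIds <- function(n) sprintf("MIR%04d", seq_len(n))

.mrnaIds <- function(n) {
  # the first rows carry the immune panel gene symbols so that immune
  # scoring works on the simulated mRNA matrix out of the box
  panel <- unique(unlist(immuneGenePanel()))
  if (n < length(panel))
    stop("need at least ", length(panel), " mRNAs to host the immune panel")
  c(panel, sprintf("MRNA%04d", seq_len(n - length(panel))))
}

.defaultPlantedDm <- function(nCancers, nLnc) {
  # common block (all cancers) + one disjoint specific block per cancer
  blocks <- list(
    list(features = 1:10, delta = 0.25, direction = "up", cancers = NULL),
    list(features = 11:15, delta = 0.25, direction = "down", cancers = NULL)
  )
  for (cc in seq_len(nCancers)) {
    base <- 100 + 30 * (cc - 1)
    blocks[[length(blocks) + 1]] <-
      list(features = base + 1:10, delta = 0.3, direction = "up",
           cancers = cc)
    blocks[[length(blocks) + 1]] <-
      list(features = base + 11:15, delta = 0.3, direction = "down",
           cancers = cc)
  }
  blocks
}

.defaultPlantedCerna <- function(nLnc, nMrna) {
  nPanel <- length(unique(unlist(immuneGenePanel())))
  lapply(1:10, function(i) list(
    lnc = .lncIds(nLnc)[400 + i],
    mrna = .mrnaIds(nMrna)[nPanel + 10 + i],
    nShared = 5, r = 0.6))
}

#' Configuration of the synthetic multi-cancer cohort
#'
#' Defaults encode the simulated study conditions: per cancer 50 tumor and
#' 20 normal samples, 500 lncRNAs with 3 promoter probes each, probe beta
#' values Beta-distributed around a per-lncRNA baseline, planted
#' differential-methylation blocks (a cancer-common block at delta-beta
#' 0.25 and per-cancer specific blocks at 0.3), a linear
#' methylation-to-expression coupling of -8 log2 units per unit beta on
#' the planted features (making them negatively correlated lncRNAs), ten
#' planted ceRNA pairs sharing 5 miRNAs at co-expression r = 0.6 over a
#' background target density of 0.05, exponential survival with hazard
#' ratio 3 for the planted prognostic lncRNAs and 30\% independent uniform
#' censoring, and two immune subtypes separated in two key lncRNAs and in
#' mutation burden.
#'
#' @param nCancers number of simulated cancer types.
#' @param nTumor,nNormal samples per group per cancer.
#' @param nLnc,nMrna,nMirna feature counts.
#' @param probesPerPromoter 450k-style probes per lncRNA promoter.
#' @param baselineBetaParams shape pair (alpha, beta) for the per-lncRNA
#'   baseline methylation mean.
#' @param betaConcentration concentration of the per-probe Beta draws
#'   around the (group-shifted) mean.
#' @param plantedDm list of blocks \code{list(features =, delta =,
#'   direction = "up"/"down", cancers = indices or NULL for all)}.
#' @param plantedDe list of expression-only effect blocks
#'   \code{list(features =, logfc =, direction =, cancers =)}.
#' @param couplingStrength slope of the promoter-methylation to
#'   log2-expression coupling on the planted DM features (negative gives
#'   negatively correlated lncRNAs).
#' @param exprBaseMean,exprSd baseline mean and noise SD of log2(RPKM+1)
#'   expression.
#' @param plantedCerna list of \code{list(lnc =, mrna =, nShared =, r =)}
#'   pairs.
#' @param backgroundDensity background miRNA-target inclusion probability.
#' @param survivalHr hazard ratio of the high-expression group for each
#'   planted prognostic lncRNA.
#' @param plantedPrognostic per-cancer list of prognostic lncRNA ids;
#'   \code{NULL} plants the first two specific-up features of each cancer.
#' @param baselineHazard exponential baseline hazard of the event times.
#' @param censoringRate expected fraction of censored tumor samples, in
#'   \[0, 1).
#' @param missingRate fraction of probe beta entries set to the 0
#'   missing-value sentinel, in \[0, 1).
#' @param tmbParams per-subtype mean somatic mutation counts.
#' @param subtypeLncs indices of the lncRNAs whose expression separates
#'   the immune subtypes.
#' @param subtypeEffect log2 expression shift of the second subtype on the
#'   subtype lncRNAs (half of it on the immune panel genes).
#' @param seed integer seed; identical configs give bit-identical cohorts.
#' @return validated configuration list of class
#'   \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nCancers = 3, nTumor = 50, nNormal = 20,
                             nLnc = 500, nMrna = 120, nMirna = 200,
                             probesPerPromoter = 3,
                             baselineBetaParams = c(2, 2),
                             betaConcentration = 30,
                             plantedDm = NULL, plantedDe = list(),
                             couplingStrength = -8,
                             exprBaseMean = 4, exprSd = 1,
                             plantedCerna = NULL,
                             backgroundDensity = 0.05,
                             survivalHr = 3, plantedPrognostic = NULL,
                             baselineHazard = 0.08,
                             censoringRate = 0.3, missingRate = 0.05,
                             tmbParams = c(8, 25),
                             subtypeLncs = c(16, 17), subtypeEffect = 3,
                             seed = 1L) {
  stopifnot(nCancers >= 1, nTumor >= 1, nNormal >= 1, nLnc >= 1,
            nMrna >= 1, nMirna >= 1, probesPerPromoter >= 1,
            all(baselineBetaParams > 0), betaConcentration > 0,
            exprSd > 0, backgroundDensity >= 0, backgroundDensity <= 1,
            survivalHr > 0, baselineHazard > 0,
            censoringRate >= 0, censoringRate < 1,
            missingRate >= 0, missingRate < 1,
            all(tmbParams > 0))
  if (is.null(plantedDm)) plantedDm <- .defaultPlantedDm(nCancers, nLnc)
  if (is.null(plantedCerna) && nLnc >= 410 && nMrna >= 40)
    plantedCerna <- .defaultPlantedCerna(nLnc, nMrna)
  if (is.null(plantedCerna)) plantedCerna <- list()
  for (bl in plantedDm) {
    if (any(bl$features > nLnc) || any(bl$features < 1))
      stop("planted DM block references lncRNA index outside 1..nLnc")
    if (bl$delta < 0 || bl$delta > 1)
      stop("planted delta-beta must lie in [0, 1] (block at features ",
           bl$features[1], "...)")
    if (bl$delta > 0.96)
      stop("planted effect delta = ", bl$delta, " on features starting at ",
           bl$features[1],
           " cannot keep beta values inside [0, 1] at any baseline")
    if (!bl$direction %in% c("up", "down"))
      stop("planted DM direction must be 'up' or 'down'")
  }
  lids <- .lncIds(nLnc); mids <- .mrnaIds(nMrna)
  for (pc in plantedCerna) {
    if (!pc$lnc %in% lids || !pc$mrna %in% mids)
      stop("planted ceRNA pair references an unknown id: ",
           pc$lnc, " / ", pc$mrna)
    if (pc$nShared > nMirna)
      stop("planted ceRNA pair requests ", pc$nShared,
           " shared miRNAs but the universe has only ", nMirna)
    if (abs(pc$r) > 1) stop("planted ceRNA correlation must be in [-1, 1]")
  }
  if (any(subtypeLncs > nLnc))
    stop("subtype lncRNA index outside 1..nLnc")
  structure(list(
    nCancers = nCancers, nTumor = nTumor, nNormal = nNormal, nLnc = nLnc,
    nMrna = nMrna, nMirna = nMirna, probesPerPromoter = probesPerPromoter,
    baselineBetaParams = baselineBetaParams,
    betaConcentration = betaConcentration, plantedDm = plantedDm,
    plantedDe = plantedDe, couplingStrength = couplingStrength,
    exprBaseMean = exprBaseMean, exprSd = exprSd,
    plantedCerna = plantedCerna, backgroundDensity = backgroundDensity,
    survivalHr = survivalHr, plantedPrognostic = plantedPrognostic,
    baselineHazard = baselineHazard, censoringRate = censoringRate,
    missingRate = missingRate, tmbParams = tmbParams,
    subtypeLncs = subtypeLncs, subtypeEffect = subtypeEffect,
    seed = as.integer(seed)), class = "SimulationConfig")
}

#' Simulate a bipartite miRNA target map with planted ceRNA pairs
#'
#' Background targeting is Bernoulli at \code{backgroundDensity} per
#' (RNA, miRNA) cell; each planted pair additionally receives a dedicated
#' set of \code{nShared} miRNAs added to both its lncRNA and its mRNA, so
#' the pair shares at least that many targets by construction.
#'
#' @param nLnc,nMrna,nMirna counts (ids are generated as in the cohort).
#' @param backgroundDensity background inclusion probability in \[0, 1\].
#' @param plantedCerna list of \code{list(lnc =, mrna =, nShared =)}.
#' @param seed integer seed.
#' @return a \linkS4class{TargetMap}.
#' @export
simulateTargetMap <- function(nLnc, nMrna, nMirna, backgroundDensity = 0.05,
                              plantedCerna = list(), seed = 1L) {
  stopifnot(backgroundDensity >= 0, backgroundDensity <= 1)
  for (pc in plantedCerna)
    if (pc$nShared > nMirna)
      stop("requested shared count ", pc$nShared, " exceeds nMirna = ", nMirna)
  set.seed(seed)
  uni <- .mirIds(nMirna)
  lids <- .lncIds(nLnc); mids <- .mrnaIds(nMrna)
  draw <- function(ids) {
    tg <- lapply(ids, function(i)
      uni[stats::runif(nMirna) < backgroundDensity])
    names(tg) <- ids
    tg
  }
  lt <- draw(lids); mt <- draw(mids)
  for (pc in plantedCerna) {
    sharedMirs <- sample(uni, pc$nShared)
    lt[[pc$lnc]] <- union(lt[[pc$lnc]], sharedMirs)
    mt[[pc$mrna]] <- union(mt[[pc$mrna]], sharedMirs)
  }
  TargetMap(lt, mt, universe = uni)
}

# expected censoring fraction when C ~ U(0, tau) independent of
# T ~ Exp(lambda), averaged over per-sample hazards
.censorFraction <- function(tau, lambda) {
  mean((1 - exp(-lambda * tau)) / (lambda * tau))
}

#' Simulate right-censored survival driven by expression
#'
#' Event times are exponential with per-sample hazard
#' \code{baselineHazard * hazardRatio^(expression above its median)};
#' censoring times are uniform on (0, tau) and independent of the event
#' process, with tau solved so the expected censored fraction equals
#' \code{censoringRate}.
#'
#' @param expr named per-sample expression vector (non-empty).
#' @param hazardRatio hazard ratio of the above-median group (> 0).
#' @param censoringRate expected censored fraction in \[0, 1).
#' @param seed integer seed.
#' @param baselineHazard exponential baseline hazard (default 0.08).
#' @return survival data.frame: \code{sample_id}, \code{time},
#'   \code{event}.
#' @export
simulateSurvival <- function(expr, hazardRatio, censoringRate = 0.3,
                             seed = 1L, baselineHazard = 0.08) {
  if (!length(expr)) stop("simulateSurvival: empty expression vector")
  stopifnot(hazardRatio > 0, censoringRate >= 0, censoringRate < 1)
  set.seed(seed)
  if (is.null(names(expr))) names(expr) <- sprintf("S%03d", seq_along(expr))
  high <- expr > stats::median(expr)
  lambda <- baselineHazard * hazardRatio^as.numeric(high)
  .survFromHazard(lambda, censoringRate, names(expr))
}

.survFromHazard <- function(lambda, censoringRate, ids) {
  tt <- stats::rexp(length(lambda), rate = lambda)
  if (censoringRate > 0) {
    tau <- stats::uniroot(function(x) .censorFraction(x, lambda) - censoringRate,
                          lower = 1e-8, upper = 1e8, tol = 1e-8)$root
    cc <- stats::runif(length(lambda), 0, tau)
    event <- as.integer(tt <= cc)
    time <- pmin(tt, cc)
  } else {
    event <- rep(1L, length(lambda))
    time <- tt
  }
  data.frame(sample_id = ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Simulate a multi-cancer cohort with planted ground truth
#'
#' Generates, per cancer, probe-level Beta-distributed methylation with
#' group-shifted means on the planted features, lncRNA expression
#' negatively (or positively) coupled to realized promoter methylation,
#' mRNA expression with planted ceRNA co-expression, expression-driven
#' exponential survival with independent uniform censoring, and
#' per-sample mutation burdens differing by planted immune subtype.  A
#' shared miRNA target map and promoter map tie the cancers together, and
#' the returned truth record holds every planted label for downstream
#' recovery checks.
#'
#' @param config a [simulationConfig()].
#' @return a \linkS4class{SyntheticCohort}.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  nL <- config$nLnc; nM <- config$nMrna
  lids <- .lncIds(nL); mids <- .mrnaIds(nM)
  panelGenes <- unique(unlist(immuneGenePanel()))
  ppp <- config$probesPerPromoter
  probeIds <- as.vector(t(outer(lids, seq_len(ppp),
                                function(l, j) sprintf("%s_p%d", l, j))))
  promoterMap <- data.frame(probe_id = probeIds,
                            lncRNA_id = rep(lids, each = ppp),
                            stringsAsFactors = FALSE)

  # baseline promoter means, shared across cancers; pull planted features
  # into a range where the shift keeps beta inside [0, 1]
  ab <- config$baselineBetaParams
  mu0 <- stats::rbeta(nL, ab[1], ab[2])
  mu0 <- pmin(pmax(mu0, 0.05), 0.95)
  dmByCancer <- lapply(seq_len(config$nCancers), function(cc) {
    d <- stats::setNames(numeric(nL), lids)
    for (bl in config$plantedDm) {
      inC <- is.null(bl$cancers) || cc %in% bl$cancers
      if (inC)
        d[bl$features] <- if (bl$direction == "up") bl$delta else -bl$delta
    }
    d
  })
  for (cc in seq_len(config$nCancers)) {
    d <- dmByCancer[[cc]]
    hi <- which(d > 0 & mu0 + d > 0.98)
    mu0[hi] <- 0.98 - d[hi]
    lo <- which(d < 0 & mu0 + d < 0.02)
    mu0[lo] <- 0.02 - d[lo]
  }
  for (cc in seq_len(config$nCancers)) {
    bad <- which(mu0 + dmByCancer[[cc]] < 0.02 - 1e-12 |
                 mu0 + dmByCancer[[cc]] > 0.98 + 1e-12)
    if (length(bad))
      stop("planted methylation effect on ", lids[bad[1]],
           " (cancer ", cc, ", shift ", dmByCancer[[cc]][bad[1]],
           ") pushes beta outside [0, 1]")
  }
  coupled <- unique(unlist(lapply(config$plantedDm, `[[`, "features")))

  targetMap <- simulateTargetMap(nL, nM, config$nMirna,
                                 config$backgroundDensity,
                                 config$plantedCerna,
                                 seed = config$seed + 1L)
  set.seed(config$seed + 2L)

  cancers <- list()
  truth <- list(dm = list(), de = list(), nclnc = list(), prognostic = list(),
                subtype = list(),
                cerna = if (length(config$plantedCerna))
                  do.call(rbind, lapply(config$plantedCerna, function(pc)
                    data.frame(lnc = pc$lnc, mrna = pc$mrna,
                               nShared = pc$nShared, r = pc$r,
                               stringsAsFactors = FALSE)))
                else data.frame(lnc = character(0), mrna = character(0),
                                nShared = integer(0), r = numeric(0)))
  phi <- config$betaConcentration
  for (cc in seq_len(config$nCancers)) {
    cname <- sprintf("C%02d", cc)
    nT <- config$nTumor; nN <- config$nNormal; nS <- nT + nN
    sids <- c(sprintf("%s_T%03d", cname, seq_len(nT)),
              sprintf("%s_N%03d", cname, seq_len(nN)))
    grp <- c(rep("tumor", nT), rep("normal", nN))
    d <- dmByCancer[[cc]]

    # per-feature per-sample promoter mean; probes scatter around it
    muMat <- matrix(mu0, nL, nS, dimnames = list(lids, sids))
    muMat[, grp == "tumor"] <- muMat[, grp == "tumor"] + d
    muProbe <- muMat[rep(seq_len(nL), each = ppp), , drop = FALSE]
    beta <- matrix(stats::rbeta(length(muProbe), muProbe * phi,
                                (1 - muProbe) * phi),
                   nrow(muProbe), ncol(muProbe),
                   dimnames = list(probeIds, sids))
    if (config$missingRate > 0) {
      miss <- stats::runif(length(beta)) < config$missingRate
      beta[miss] <- 0
    }
    meth <- FeatureMatrix(beta, group = grp, scale = "beta", probes = TRUE)

    # realized promoter-mean beta (from the pre-missingness draws is not
    # observable; use the per-sample generative mean for the coupling)
    bbar <- muMat + matrix(stats::rnorm(nL * nS, 0, 0.02), nL, nS)

    baseL <- stats::rnorm(nL, config$exprBaseMean, 1)
    L <- matrix(baseL, nL, nS, dimnames = list(lids, sids)) +
      matrix(stats::rnorm(nL * nS, 0, config$exprSd), nL, nS)
    L[coupled, ] <- L[coupled, ] +
      config$couplingStrength * (bbar[coupled, ] - mu0[coupled])
    deDir <- stats::setNames(rep("none", nL), lids)
    for (bl in config$plantedDe) {
      inC <- is.null(bl$cancers) || cc %in% bl$cancers
      if (!inC) next
      sgn <- if (bl$direction == "up") 1 else -1
      L[bl$features, grp == "tumor"] <- L[bl$features, grp == "tumor"] +
        sgn * bl$logfc
      deDir[bl$features] <- bl$direction
    }
    # planted subtypes among tumor samples
    subtype <- stats::setNames(sample(rep(1:2, length.out = nT)),
                               sids[grp == "tumor"])
    stL <- config$subtypeLncs
    L[stL, names(subtype)[subtype == 2]] <-
      L[stL, names(subtype)[subtype == 2]] + config$subtypeEffect

    baseM <- stats::rnorm(nM, config$exprBaseMean, 1)
    M <- matrix(baseM, nM, nS, dimnames = list(mids, sids)) +
      matrix(stats::rnorm(nM * nS, 0, config$exprSd), nM, nS)
    for (pc in config$plantedCerna) {
      z <- as.numeric(scale(L[pc$lnc, ]))
      M[pc$mrna, ] <- baseM[match(pc$mrna, mids)] +
        config$exprSd * (pc$r * z +
                         sqrt(1 - pc$r^2) * stats::rnorm(nS))
    }
    M[panelGenes, names(subtype)[subtype == 2]] <-
      M[panelGenes, names(subtype)[subtype == 2]] + config$subtypeEffect / 2

    lncExpr <- FeatureMatrix(pmax(2^L - 1, 0), group = grp, scale = "rpkm")
    mrnaExpr <- FeatureMatrix(pmax(2^M - 1, 0), group = grp, scale = "rpkm")

    # prognostic lncRNAs: planted or the first two specific-up features
    prog <- if (!is.null(config$plantedPrognostic)) {
      config$plantedPrognostic[[min(cc, length(config$plantedPrognostic))]]
    } else {
      specUp <- lids[d > 0 & !lids %in% unlist(
        lapply(seq_len(config$nCancers)[-cc],
               function(o) lids[dmByCancer[[o]] != 0]))]
      utils::head(specUp, 2)
    }
    tumorIds <- sids[grp == "tumor"]
    # hazards follow the observable expression (post RPKM floor) so the
    # planted prognostic labels stay recoverable from the emitted matrices
    lncObs <- log2(featureValues(lncExpr) + 1)
    lambda <- rep(config$baselineHazard, nT)
    for (lnc in prog) {
      e <- lncObs[lnc, tumorIds]
      lambda <- lambda * config$survivalHr^as.numeric(e > stats::median(e))
    }
    surv <- .survFromHazard(lambda, config$censoringRate, tumorIds)
    mutations <- stats::setNames(
      stats::rpois(nT, config$tmbParams[subtype]), tumorIds)

    cancers[[cname]] <- list(meth = meth, lncExpr = lncExpr,
                             mrnaExpr = mrnaExpr, survival = surv,
                             mutations = mutations)
    dmLab <- ifelse(d > 0, "up", ifelse(d < 0, "down", "none"))
    names(dmLab) <- lids
    # coupled planted-DM features shift expression opposite in sign to the
    # methylation change when the coupling is negative
    deLab <- deDir
    couplingSign <- sign(config$couplingStrength)
    deLab[d > 0 & couplingSign < 0] <- "down"
    deLab[d < 0 & couplingSign < 0] <- "up"
    deLab[d > 0 & couplingSign > 0] <- "up"
    deLab[d < 0 & couplingSign > 0] <- "down"
    # the subtype shift elevates the subtype lncRNAs in half the tumors,
    # a genuine tumor-vs-normal expression difference
    if (config$subtypeEffect != 0)
      deLab[config$subtypeLncs] <- if (config$subtypeEffect > 0) "up"
                                   else "down"
    nc <- ifelse(dmLab == "up" & deLab == "down", "UMLE",
                 ifelse(dmLab == "down" & deLab == "up", "DMOE", "none"))
    names(nc) <- lids
    truth$dm[[cname]] <- dmLab
    truth$de[[cname]] <- deLab
    truth$nclnc[[cname]] <- nc
    truth$prognostic[[cname]] <- prog
    truth$subtype[[cname]] <- subtype
  }
  truth$subtypeLncs <- lids[config$subtypeLncs]
  new("SyntheticCohort", cancers = cancers, targetMap = targetMap,
      promoterMap = promoterMap, truth = truth, config = unclass(config))
}
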