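#' @include AllClasses.R preprocess.R diff-analysis.R set-integration.R
#' @include cerna-network.R survival.R immuno.R
NULL

#' Pipeline configuration
#'
#' Bundles every stage's thresholds for a full per-cancer and pan-cancer
#' run.
#'
#' @param test differential-call thresholds ([testConfig()]).
#' @param cerna ceRNA screening thresholds ([cernaThresholds()]).
#' @param presenceFraction expression presence filter
#'   ([normalizeExpression()]).
#' @param minCommonCancers strict lower bound for the cancer-common set
#'   (default 15, the pan-cancer convention; use a small value for small
#'   cohorts).
#' @param minSubnetCancers strict lower bound on cancers sharing an mRNA
#'   in the pan-cancer sub-network (default 4).
#' @param survivalAlpha significance level of the survival screen.
#' @param survivalPerm permutations per maxstat cut-point.
#' @param minGroupFrac minimum group fraction per side of a cut.
#' @param clusterKRange candidate subtype counts (default 2:6).
#' @param clusterResamples consensus-clustering resamples.
#' @param keyLncs lncRNAs to cluster samples on; \code{NULL} uses the
#'   negatively correlated members of the cancer-common set (falling back
#'   to the two highest-variance common lncRNAs).
#' @param seed integer master seed for the seeded stages.
#' @return configuration list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(test = testConfig(), cerna = cernaThresholds(),
                           presenceFraction = 0.7, minCommonCancers = 15,
                           minSubnetCancers = 4, survivalAlpha = 0.05,
                           survivalPerm = 1000, minGroupFrac = 0.1,
                           clusterKRange = 2:6, clusterResamples = 100,
                           keyLncs = NULL, seed = 1L) {
  stopifnot(presenceFraction > 0, presenceFraction < 1,
            minCommonCancers >= 2, minSubnetCancers >= 1,
            survivalAlpha > 0, survivalAlpha < 1, survivalPerm >= 0)
  structure(list(test = test, cerna = cerna,
                 presenceFraction = presenceFraction,
                 minCommonCancers = minCommonCancers,
                 minSubnetCancers = minSubnetCancers,
                 survivalAlpha = survivalAlpha,
                 survivalPerm = survivalPerm,
                 minGroupFrac = minGroupFrac,
                 clusterKRange = clusterKRange,
                 clusterResamples = clusterResamples,
                 keyLncs = keyLncs, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full per-cancer and pan-cancer analysis
#'
#' Executes, in order: probe filtering/imputation and promoter averaging;
#' expression normalization; differential methylation and expression
#' calls; cancer-specific / cancer-common / negative-correlation set
#' integration; per-cancer ceRNA networks and the pan-cancer sub-network;
#' maxstat survival screening of the cancer-specific negatively
#' correlated lncRNAs and of the common negatively correlated lncRNAs;
#' and immune scoring with consensus-clustering subtypes and
#' Wilcoxon comparisons of scores and mutation burden.  Identical cohort
#' + config + seed give an identical report.
#'
#' @param cohort a \linkS4class{SyntheticCohort} (or a list shaped like
#'   one: per-cancer \code{meth}/\code{lncExpr}/\code{mrnaExpr}/
#'   \code{survival}/\code{mutations} plus a shared target and promoter
#'   map).
#' @param config a [pipelineConfig()].
#' @param outDir optional directory; when given, every intermediate table
#'   is written as TSV.
#' @return a list of class \code{"RunReport"}: per-cancer differential
#'   results and counts, the integration sets, ceRNA networks, survival
#'   screens, immune comparisons and provenance.
#' @export
runAll <- function(cohort, config = pipelineConfig(), outDir = NULL) {
  stopifnot(is(cohort, "SyntheticCohort"), inherits(config, "PipelineConfig"))
  if (!is.null(outDir))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cnames <- cancerNames(cohort)
  pm <- cohortPromoterMap(cohort)
  tm <- cohortTargetMap(cohort)

  promoter <- list(); lncNorm <- list(); mrnaNorm <- list()
  dmRes <- list(); deRes <- list()
  for (cn in cnames) {
    cc <- cohortCancer(cohort, cn)
    if (is.null(cc$survival) || !nrow(cc$survival))
      .stage("survival", stop("missing survival table for ", cn))
    promoter[[cn]] <- .stage("preprocess-methylation",
      promoterBeta(imputeProbes(filterProbes(cc$meth)), pm))
    lncNorm[[cn]] <- .stage("preprocess-expression",
      normalizeExpression(cc$lncExpr, config$presenceFraction))
    mrnaNorm[[cn]] <- .stage("preprocess-expression",
      normalizeExpression(cc$mrnaExpr, config$presenceFraction))
    dmRes[[cn]] <- .stage("differential-methylation",
      callDMlncs(promoter[[cn]], config$test))
    deRes[[cn]] <- .stage("differential-expression",
      callDELncs(lncNorm[[cn]], config$test))
  }

  dmCat <- dmCatalog(dmRes)
  deCat <- dmCatalog(deRes)
  specific <- if (length(cnames) >= 2L)
    .stage("set-integration", cancerSpecific(dmCat)) else NULL
  common <- .stage("set-integration",
    cancerCommon(dmCat, min(config$minCommonCancers, length(cnames) - 1L)))
  nc <- .stage("set-integration", negativeCorrelated(dmCat, deCat))
  csn <- if (!is.null(specific)) csnclncs(specific, nc) else NULL

  nets <- list()
  for (cn in cnames)
    nets[[cn]] <- .stage("cerna-network",
      buildCernaNetwork(tm, lncNorm[[cn]], mrnaNorm[[cn]], config$cerna,
                        cancer = cn))

  commonLncs <- rownames(common)
  commonNc <- lapply(cnames, function(cn)
    intersect(commonLncs, c(nc[[cn]]$UMLE, nc[[cn]]$DMOE)))
  names(commonNc) <- cnames

  survCsn <- list(); survCommon <- list()
  for (i in seq_along(cnames)) {
    cn <- cnames[i]
    cc <- cohortCancer(cohort, cn)
    candidates <- if (!is.null(csn)) csn[[cn]] else character(0)
    survCsn[[cn]] <- .stage("survival",
      survivalScreen(candidates, lncNorm[[cn]], cc$survival,
                     alpha = config$survivalAlpha,
                     minGroupFrac = config$minGroupFrac,
                     nPerm = config$survivalPerm,
                     seed = config$seed + 1000L * i))
    survCommon[[cn]] <- .stage("survival",
      survivalScreen(commonNc[[cn]], lncNorm[[cn]], cc$survival,
                     alpha = config$survivalAlpha,
                     minGroupFrac = config$minGroupFrac,
                     nPerm = config$survivalPerm,
                     seed = config$seed + 1000L * i + 500L))
  }
  survivalLncs <- unique(unlist(c(
    lapply(survCsn, function(s) s$lnc[s$associated]),
    lapply(survCommon, function(s) s$lnc[s$associated]))))

  subnet <- if (length(cnames) >= 2L && length(survivalLncs))
    .stage("cerna-network",
      panCancerSubnetwork(nets, survivalLncs,
                          min(config$minSubnetCancers,
                              length(cnames) - 1L)))
    else list(edges = data.frame(), mrnaSummary = data.frame())

  immune <- list()
  for (i in seq_along(cnames)) {
    cn <- cnames[i]
    cc <- cohortCancer(cohort, cn)
    key <- config$keyLncs
    if (is.null(key)) key <- unlist(commonNc[cn])
    lx <- featureValues(lncNorm[[cn]])
    tumors <- tumorSamples(lncNorm[[cn]])
    if (length(key) < 2L) {
      pool <- if (length(commonLncs) >= 2L) commonLncs else rownames(lx)
      vv <- apply(lx[pool, tumors, drop = FALSE], 1, stats::var)
      key <- names(sort(vv, decreasing = TRUE))[1:2]
    }
    key <- intersect(key, rownames(lx))
    cl <- .stage("immune", consensusCluster(
      lx[key, tumors, drop = FALSE], kRange = config$clusterKRange,
      nResamples = config$clusterResamples,
      seed = config$seed + 7L * i))
    scores <- .stage("immune", immuneScores(mrnaNorm[[cn]]))
    scores <- scores[scores$sample_id %in% tumors, ]
    vals <- function(col) stats::setNames(scores[[col]], scores$sample_id)
    cmp <- lapply(c(mhc = "mhc", cyt = "cyt", ctl = "ctl"),
                  function(col) compareGroups(vals(col), cl))
    cmp$tmb <- compareGroups(cc$mutations, cl)
    immune[[cn]] <- list(keyLncs = key, clusters = cl, scores = scores,
                         comparisons = cmp)
  }

  counts <- data.frame(
    cancer = cnames,
    dm_up = vapply(dmCat, function(x) length(x$up), integer(1)),
    dm_down = vapply(dmCat, function(x) length(x$down), integer(1)),
    de_up = vapply(deCat, function(x) length(x$up), integer(1)),
    de_down = vapply(deCat, function(x) length(x$down), integer(1)),
    specific = if (!is.null(specific))
      vapply(specific, function(x)
        length(x$specific_up) + length(x$specific_down), integer(1))
      else NA_integer_,
    nclnc = vapply(nc[cnames], function(x)
      length(x$UMLE) + length(x$DMOE), integer(1)),
    csnclnc = if (!is.null(csn))
      vapply(csn[cnames], length, integer(1)) else NA_integer_,
    cerna_pairs = vapply(nets, function(x) nrow(cernaEdges(x)), integer(1)),
    survival_csn = vapply(survCsn, function(s) sum(s$associated),
                          integer(1)),
    survival_common = vapply(survCommon, function(s) sum(s$associated),
                             integer(1)),
    chosen_k = vapply(immune, function(x) x$clusters$chosenK, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  report <- structure(list(
    counts = counts, dm = dmRes, de = deRes, dmCatalog = dmCat,
    deCatalog = deCat, specific = specific, common = common, nclnc = nc,
    csnclnc = csn, networks = nets, survivalCsn = survCsn,
    survivalCommon = survCommon, subnetwork = subnet, immune = immune,
    provenance = list(seed = config$seed, config = unclass(config),
                      package = as.character(
                        utils::packageVersion("LncMethDys")))),
    class = "RunReport")

  if (!is.null(outDir)) .writeReport(report, promoter, lncNorm, outDir)
  report
}

.writeReport <- function(report, promoter, lncNorm, outDir) {
  utils::write.table(report$counts, file.path(outDir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cn in names(report$dm)) {
    cdir <- file.path(outDir, cn)
    dir.create(cdir, showWarnings = FALSE)
    writeFeatureMatrix(promoter[[cn]], file.path(cdir, "promoter_beta.tsv"))
    writeFeatureMatrix(lncNorm[[cn]], file.path(cdir, "lnc_log2rpkm.tsv"))
    utils::write.table(
      data.frame(feature_id = rownames(report$dm[[cn]]),
                 as.data.frame(report$dm[[cn]])),
      file.path(cdir, "dm_results.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(feature_id = rownames(report$de[[cn]]),
                 as.data.frame(report$de[[cn]])),
      file.path(cdir, "de_results.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(cernaEdges(report$networks[[cn]]),
                       file.path(cdir, "cerna_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(report$survivalCsn[[cn]],
                       file.path(cdir, "survival_csnclnc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (nrow(report$common))
    utils::write.table(
      data.frame(lncRNA = rownames(report$common),
                 as.data.frame(report$common)),
      file.path(outDir, "common_profile.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  invisible(outDir)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Pan-cancer lncRNA methylation-dysregulation run\n")
  cat(sprintf("  %d cancer(s); seed %d\n", nrow(x$counts),
              x$provenance$seed))
  print(x$counts, row.names = FALSE)
  if (!is.null(x$common) && nrow(x$common))
    cat(sprintf("  %d cancer-common DMlnc(s)\n", nrow(x$common)))
  invisible(x)
}
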