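#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' FeatureMatrix: a feature-by-sample numeric matrix with group labels
#'
#' The central container of the package: a
#' \linkS4class{SummarizedExperiment} carrying one numeric assay
#' (\code{"values"}), a per-sample \code{group} column (\code{"tumor"} or
#' \code{"normal"}) and a scale tag recording what the numbers are:
#' \describe{
#'   \item{\code{"beta"}}{methylation beta values in \[0, 1\] (0 doubles as
#'     the missing-value sentinel at probe level)}
#'   \item{\code{"rpkm"}}{raw RPKM expression, non-negative, \code{NA} =
#'     missing}
#'   \item{\code{"log2rpkm"}}{log2(RPKM + 1) expression}
#' }
#'
#' @slot scaleTag single character string, one of \code{"beta"},
#'   \code{"rpkm"}, \code{"log2rpkm"}.
#' @seealso [FeatureMatrix()] for the constructor, [featureValues()],
#'   [sampleGroup()], [scaleTag()] for accessors.
#' @export
setClass("FeatureMatrix",
  contains = "SummarizedExperiment",
  representation(scaleTag = "character")
)

#' ProbeBetaMatrix: probe-level methylation beta values
#'
#' A \linkS4class{FeatureMatrix} whose rows are 450k-style probes rather
#' than lncRNA promoters; always on the \code{"beta"} scale, with 0 acting
#' as the missing-value sentinel until [imputeProbes()] has run.
#'
#' @export
setClass("ProbeBetaMatrix", contains = "FeatureMatrix")

.validFeatureMatrix <- function(object) {
  msg <- NULL
  if (length(object@scaleTag) != 1L ||
      !object@scaleTag %in% c("beta", "rpkm", "log2rpkm"))
    msg <- c(msg, "scaleTag must be one of 'beta', 'rpkm', 'log2rpkm'")
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'values' is required")
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (!all(colData(object)$group %in% c("tumor", "normal")))
    msg <- c(msg, "group labels must be 'tumor' or 'normal'")
  v <- assay(object, "values")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have feature rownames and sample colnames")
  if (identical(object@scaleTag, "beta")) {
    rng <- range(v, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
      msg <- c(msg, "beta-scale values must lie in [0, 1]")
  }
  if (identical(object@scaleTag, "rpkm") && any(v < 0, na.rm = TRUE))
    msg <- c(msg, "rpkm values must be non-negative")
  if (is.null(msg)) TRUE else msg
}

setValidity("FeatureMatrix", .validFeatureMatrix)

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix, features as rows (rownames required),
#'   samples as columns (colnames required).
#' @param group character vector of per-sample labels, \code{"tumor"} or
#'   \code{"normal"}, recycled names not allowed; length must equal
#'   \code{ncol(values)}.
#' @param scale scale tag: \code{"beta"}, \code{"rpkm"} or
#'   \code{"log2rpkm"}.
#' @param probes logical; wrap as a \linkS4class{ProbeBetaMatrix}
#'   (probe-level rows) rather than a plain feature matrix.
#' @return a \linkS4class{FeatureMatrix} (or
#'   \linkS4class{ProbeBetaMatrix}).
#' @examples
#' m <- matrix(runif(12), 3, 4,
#'   dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' fm <- FeatureMatrix(m, group = c("tumor", "tumor", "normal", "normal"),
#'   scale = "beta")
#' @export
FeatureMatrix <- function(values, group, scale = c("beta", "rpkm", "log2rpkm"),
                          probes = FALSE) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (length(group) != ncol(values))
    stop("length(group) must equal the number of samples (columns)")
  se <- SummarizedExperiment(
    assays = list(values = values),
    colData = DataFrame(group = as.character(group),
                        row.names = colnames(values))
  )
  new(if (probes) "ProbeBetaMatrix" else "FeatureMatrix",
      se, scaleTag = scale)
}

#' DiffResult: per-feature differential methylation / expression statistics
#'
#' A \linkS4class{DataFrame} subclass with one row per feature and columns
#' \code{mean_tumor}, \code{mean_normal} (matrix scale), \code{delta_beta}
#' (absolute group-mean difference; \code{NA} off the beta scale),
#' \code{logfc} (group difference on the test scale), \code{t} (moderated
#' t), \code{p}, \code{q} (BH-adjusted) and \code{direction}
#' (\code{"up"}/\code{"down"}/\code{"none"}).  Empirical-Bayes
#' hyperparameters and the test scale live in \code{metadata()}.
#'
#' @export
setClass("DiffResult", contains = "DFrame")

#' TargetMap: miRNA targeting relations for lncRNAs and mRNAs
#'
#' Bipartite target relations used by the ceRNA screen: which miRNAs each
#' lncRNA and each mRNA is targeted by, over a common miRNA universe.
#'
#' @slot lncTargets named list, lncRNA id -> character vector of miRNA ids.
#' @slot mrnaTargets named list, mRNA id -> character vector of miRNA ids.
#' @slot universe character vector of all distinct miRNA ids.
#' @export
setClass("TargetMap",
  representation(lncTargets = "list", mrnaTargets = "list",
                 universe = "character")
)

setValidity("TargetMap", function(object) {
  msg <- NULL
  alltg <- unique(c(unlist(object@lncTargets, use.names = FALSE),
                    unlist(object@mrnaTargets, use.names = FALSE)))
  if (length(alltg) && !all(alltg %in% object@universe))
    msg <- c(msg, "every target set must be a subset of the miRNA universe")
  if (length(object@lncTargets) && is.null(names(object@lncTargets)))
    msg <- c(msg, "lncTargets must be a named list")
  if (length(object@mrnaTargets) && is.null(names(object@mrnaTargets)))
    msg <- c(msg, "mrnaTargets must be a named list")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TargetMap
#'
#' @param lncTargets named list: lncRNA id -> character vector of miRNAs.
#' @param mrnaTargets named list: mRNA id -> character vector of miRNAs.
#' @param universe optional character vector of all miRNAs; defaults to the
#'   union of both maps.
#' @return a \linkS4class{TargetMap}.
#' @export
TargetMap <- function(lncTargets, mrnaTargets, universe = NULL) {
  if (is.null(universe))
    universe <- unique(c(unlist(lncTargets, use.names = FALSE),
                         unlist(mrnaTargets, use.names = FALSE)))
  new("TargetMap", lncTargets = lncTargets, mrnaTargets = mrnaTargets,
      universe = as.character(universe))
}

#' CeRNANetwork: filtered lncRNA-mRNA competing-endogenous-RNA pairs
#'
#' Edge list of lncRNA--mRNA pairs that passed the shared-miRNA
#' hypergeometric filter and the tumor co-expression filter, tagged by
#' cancer type.
#'
#' @slot edges data.frame with columns \code{cancer}, \code{lnc},
#'   \code{mrna}, \code{shared_k}, \code{hyper_p}, \code{r}, \code{p}.
#' @slot thresholds list of the filter thresholds the edges satisfy.
#' @export
setClass("CeRNANetwork",
  representation(edges = "data.frame", thresholds = "list")
)

setValidity("CeRNANetwork", function(object) {
  need <- c("cancer", "lnc", "mrna", "shared_k", "hyper_p", "r", "p")
  if (!all(need %in% colnames(object@edges)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' SyntheticCohort: a simulated multi-cancer cohort with planted truth
#'
#' Everything the pipeline consumes for one simulated study: per-cancer
#' probe methylation, lncRNA and mRNA expression, survival and mutation
#' burden; a shared miRNA target map and promoter map; and the planted
#' ground-truth record used as the recovery oracle.
#'
#' @slot cancers named list; each element a list with components
#'   \code{meth} (\linkS4class{ProbeBetaMatrix}), \code{lncExpr} and
#'   \code{mrnaExpr} (\linkS4class{FeatureMatrix}, rpkm scale),
#'   \code{survival} (data.frame sample_id/time/event over tumor samples)
#'   and \code{mutations} (named integer, per tumor sample).
#' @slot targetMap shared \linkS4class{TargetMap}.
#' @slot promoterMap data.frame with columns \code{probe_id},
#'   \code{lncRNA_id}.
#' @slot truth list of planted labels (see [simulateCohort()]).
#' @slot config the [simulationConfig()] that produced the cohort.
#' @export
setClass("SyntheticCohort",
  representation(cancers = "list", targetMap = "TargetMap",
                 promoterMap = "data.frame", truth = "list", config = "list")
)

setValidity("SyntheticCohort", function(object) {
  msg <- NULL
  for (cn in names(object@cancers)) {
    cc <- object@cancers[[cn]]
    need <- c("meth", "lncExpr", "mrnaExpr", "survival", "mutations")
    if (!all(need %in% names(cc)))
      msg <- c(msg, sprintf("cancer '%s' lacks components: %s", cn,
                            paste(setdiff(need, names(cc)), collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
})
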