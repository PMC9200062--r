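#' @include AllClasses.R
NULL

#' Extract the numeric values of a FeatureMatrix
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @return the feature-by-sample numeric matrix.
#' @export
featureValues <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  assay(x, "values")
}

#' Per-sample tumor/normal labels
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @return character vector of \code{"tumor"}/\code{"normal"} labels, one
#'   per sample, named by sample id.
#' @export
sampleGroup <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  g <- colData(x)$group
  names(g) <- colnames(x)
  g
}

#' Scale tag of a FeatureMatrix
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @return \code{"beta"}, \code{"rpkm"} or \code{"log2rpkm"}.
#' @export
scaleTag <- function(x) {
  stopifnot(is(x, "FeatureMatrix"))
  x@scaleTag
}

#' @describeIn featureValues sample ids of the tumor group.
#' @export
tumorSamples <- function(x) colnames(x)[sampleGroup(x) == "tumor"]

#' @describeIn featureValues sample ids of the normal group.
#' @export
normalSamples <- function(x) colnames(x)[sampleGroup(x) == "normal"]

#' @describeIn TargetMap lncRNA target sets.
#' @param x a \linkS4class{TargetMap}.
#' @export
lncTargets <- function(x) { stopifnot(is(x, "TargetMap")); x@lncTargets }

#' @describeIn TargetMap mRNA target sets.
#' @export
mrnaTargets <- function(x) { stopifnot(is(x, "TargetMap")); x@mrnaTargets }

#' @describeIn TargetMap the miRNA universe.
#' @export
mirnaUniverse <- function(x) { stopifnot(is(x, "TargetMap")); x@universe }

#' Edge list of a ceRNA network
#'
#' @param x a \linkS4class{CeRNANetwork}.
#' @return data.frame with one row per surviving lncRNA-mRNA pair.
#' @export
cernaEdges <- function(x) { stopifnot(is(x, "CeRNANetwork")); x@edges }

#' @describeIn SyntheticCohort names of the simulated cancer types.
#' @param x a \linkS4class{SyntheticCohort}.
#' @export
cancerNames <- function(x) { stopifnot(is(x, "SyntheticCohort")); names(x@cancers) }

#' @describeIn SyntheticCohort per-cancer data bundle (list with
#'   \code{meth}, \code{lncExpr}, \code{mrnaExpr}, \code{survival},
#'   \code{mutations}).
#' @param cancer cancer name.
#' @export
cohortCancer <- function(x, cancer) {
  stopifnot(is(x, "SyntheticCohort"))
  if (!cancer %in% names(x@cancers))
    stop("unknown cancer: ", cancer)
  x@cancers[[cancer]]
}

#' @describeIn SyntheticCohort the planted ground-truth record.
#' @export
cohortTruth <- function(x) { stopifnot(is(x, "SyntheticCohort")); x@truth }

#' @describeIn SyntheticCohort the shared miRNA target map.
#' @export
cohortTargetMap <- function(x) { stopifnot(is(x, "SyntheticCohort")); x@targetMap }

#' @describeIn SyntheticCohort the probe-to-lncRNA promoter map.
#' @export
cohortPromoterMap <- function(x) { stopifnot(is(x, "SyntheticCohort")); x@promoterMap }

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("%s: %d features x %d samples [%s scale]\n",
              class(object), nrow(object), ncol(object), object@scaleTag))
  g <- table(colData(object)$group)
  cat("  groups:", paste(sprintf("%s=%d", names(g), g), collapse = ", "), "\n")
})

setMethod("show", "TargetMap", function(object) {
  cat(sprintf("TargetMap: %d lncRNAs, %d mRNAs, %d miRNAs in universe\n",
              length(object@lncTargets), length(object@mrnaTargets),
              length(object@universe)))
})

setMethod("show", "CeRNANetwork", function(object) {
  e <- object@edges
  cat(sprintf("CeRNANetwork: %d pairs (%d lncRNAs, %d mRNAs, %d cancers)\n",
              nrow(e), length(unique(e$lnc)), length(unique(e$mrna)),
              length(unique(e$cancer))))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d cancers (%s)\n",
              length(object@cancers),
              paste(names(object@cancers), collapse = ", ")))
  if (length(object@cancers)) {
    cc <- object@cancers[[1]]
    cat(sprintf("  per cancer: %d probes, %d lncRNAs, %d mRNAs\n",
                nrow(cc$meth), nrow(cc$lncExpr), nrow(cc$mrnaExpr)))
  }
})
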