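#' @include AllClasses.R accessors.R
NULL

#' Write / read a feature-by-sample TSV matrix
#'
#' The exchange format used between pipeline stages: features as rows with
#' a leading \code{feature_id} column, samples as columns with a header
#' row of sample ids.  Group labels travel in a separate two-column TSV
#' (\code{sample_id}, \code{group}).
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param path output TSV path.
#' @param groupPath optional path for the sample-group TSV.
#' @return \code{path}, invisibly.
#' @export
writeFeatureMatrix <- function(x, path, groupPath = NULL) {
  stopifnot(is(x, "FeatureMatrix"))
  v <- featureValues(x)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groupPath)) {
    g <- data.frame(sample_id = colnames(v), group = unname(sampleGroup(x)))
    utils::write.table(g, groupPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @param groups character vector of per-sample labels, or the path of a
#'   group TSV written by [writeFeatureMatrix()].
#' @param scale the scale tag of the stored values.
#' @param probes read as a \linkS4class{ProbeBetaMatrix}.
#' @export
readFeatureMatrix <- function(path, groups, scale = c("beta", "rpkm",
                                                      "log2rpkm"),
                              probes = FALSE) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    g <- utils::read.delim(groups, stringsAsFactors = FALSE)
    groups <- g$group[match(colnames(v), g$sample_id)]
  }
  FeatureMatrix(v, group = groups, scale = scale, probes = probes)
}

#' Write / read a miRNA target map as two-column TSV
#'
#' Long format with columns \code{rna_id}, \code{mirna_id}; lncRNA and
#' mRNA rows share the file and are separated again on read by the id
#' lists supplied.
#'
#' @param tm a \linkS4class{TargetMap}.
#' @param path TSV path.
#' @export
writeTargetMap <- function(tm, path) {
  stopifnot(is(tm, "TargetMap"))
  allT <- c(lncTargets(tm), mrnaTargets(tm))
  df <- data.frame(rna_id = rep(names(allT), lengths(allT)),
                   mirna_id = unlist(allT, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTargetMap
#' @param lncIds,mrnaIds character vectors splitting the RNA ids back into
#'   the two sides of the map.
#' @param universe optional miRNA universe (defaults to the miRNAs seen in
#'   the file).
#' @export
readTargetMap <- function(path, lncIds, mrnaIds, universe = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  byRna <- split(df$mirna_id, df$rna_id)
  lt <- byRna[intersect(lncIds, names(byRna))]
  mt <- byRna[intersect(mrnaIds, names(byRna))]
  TargetMap(lt, mt, universe = universe)
}

#' Write / read a survival table TSV
#'
#' Columns \code{sample_id}, \code{time}, \code{event} (1 = death,
#' 0 = censored).
#'
#' @param surv survival data.frame.
#' @param path TSV path.
#' @export
writeSurvivalTable <- function(surv, path) {
  surv <- .checkSurvivalTable(surv)
  utils::write.table(surv[, c("sample_id", "time", "event")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSurvivalTable
#' @export
readSurvivalTable <- function(path) {
  .checkSurvivalTable(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a synthetic cohort to a directory of exchange files
#'
#' One sub-directory per cancer (methylation, expression, survival,
#' mutation TSVs), plus the shared promoter map, target map and a JSON
#' truth file.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohortPromoterMap(cohort),
                     file.path(dir, "promoter_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeTargetMap(cohortTargetMap(cohort), file.path(dir, "target_map.tsv"))
  for (cn in cancerNames(cohort)) {
    cc <- cohortCancer(cohort, cn)
    cdir <- file.path(dir, cn)
    dir.create(cdir, showWarnings = FALSE)
    writeFeatureMatrix(cc$meth, file.path(cdir, "methylation.tsv"),
                       file.path(cdir, "groups.tsv"))
    writeFeatureMatrix(cc$lncExpr, file.path(cdir, "lnc_expression.tsv"))
    writeFeatureMatrix(cc$mrnaExpr, file.path(cdir, "mrna_expression.tsv"))
    writeSurvivalTable(cc$survival, file.path(cdir, "survival.tsv"))
    utils::write.table(
      data.frame(sample_id = names(cc$mutations),
                 mutations = unname(cc$mutations)),
      file.path(cdir, "mutations.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  jsonlite::write_json(cohortTruth(cohort), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
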