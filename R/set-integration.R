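#' @include diff-analysis.R
NULL

#' Build a per-cancer up/down catalog from differential results
#'
#' @param results named list (cancer -> \linkS4class{DiffResult} with
#'   direction calls).
#' @return a catalog: named list, cancer -> \code{list(up =, down =)}
#'   character vectors of feature ids.
#' @export
dmCatalog <- function(results) {
  if (is.null(names(results)) || !length(results))
    stop("dmCatalog: results must be a non-empty named list")
  lapply(results, function(r) {
    list(up = rownames(r)[r$direction == "up"],
         down = rownames(r)[r$direction == "down"])
  })
}

.checkCatalog <- function(catalog) {
  if (is.null(names(catalog)))
    stop("catalog must be named by cancer")
  for (cn in names(catalog)) {
    cc <- catalog[[cn]]
    if (!all(c("up", "down") %in% names(cc)))
      stop("catalog entry for ", cn, " must have 'up' and 'down' sets")
    if (length(intersect(cc$up, cc$down)))
      stop("catalog entry for ", cn, " has features both up and down")
  }
  invisible(catalog)
}

#' Cancer-specific differentially methylated lncRNAs
#'
#' A feature is specific-up for cancer c when it is called up in c and is
#' not a DM call (in either direction, under the default strict reading)
#' in any other cancer; symmetrically for down.
#'
#' @param catalog a catalog as built by [dmCatalog()], covering at least
#'   two cancers.
#' @param perDirection if \code{TRUE}, only same-direction calls elsewhere
#'   void specificity (the looser reading); default \code{FALSE}: any DM
#'   call in another cancer does.
#' @return named list, cancer -> \code{list(specific_up =,
#'   specific_down =)}.
#' @export
cancerSpecific <- function(catalog, perDirection = FALSE) {
  .checkCatalog(catalog)
  if (length(catalog) < 2L)
    stop("cancerSpecific: specificity is undefined for a single cancer")
  out <- vector("list", length(catalog))
  names(out) <- names(catalog)
  for (cn in names(catalog)) {
    others <- catalog[setdiff(names(catalog), cn)]
    elsewhereUp <- unique(unlist(lapply(others, `[[`, "up")))
    elsewhereDown <- unique(unlist(lapply(others, `[[`, "down")))
    elsewhereAny <- union(elsewhereUp, elsewhereDown)
    voidUp <- if (perDirection) elsewhereUp else elsewhereAny
    voidDown <- if (perDirection) elsewhereDown else elsewhereAny
    out[[cn]] <- list(
      specific_up = setdiff(catalog[[cn]]$up, voidUp),
      specific_down = setdiff(catalog[[cn]]$down, voidDown)
    )
  }
  out
}

#' Cancer-common differentially methylated lncRNAs
#'
#' Features that are DM calls (either direction) in strictly more than
#' \code{minCancers} cancers, with their per-cancer direction profile.
#'
#' @param catalog a catalog as built by [dmCatalog()].
#' @param minCancers strict lower bound on the number of cancers with a DM
#'   call (default 15, the pan-cancer convention for ~23 cancers).
#' @return data.frame: one row per common feature, one column per cancer
#'   with values \code{"up"}/\code{"down"}/\code{"none"}, plus
#'   \code{n_cancers}.
#' @export
cancerCommon <- function(catalog, minCancers = 15) {
  .checkCatalog(catalog)
  stopifnot(minCancers >= 2)
  feats <- unique(unlist(lapply(catalog, function(cc) c(cc$up, cc$down))))
  if (!length(feats)) {
    prof <- as.data.frame(matrix(character(0), 0, length(catalog),
                                 dimnames = list(NULL, names(catalog))))
    prof$n_cancers <- integer(0)
    return(prof)
  }
  prof <- sapply(names(catalog), function(cn) {
    ifelse(feats %in% catalog[[cn]]$up, "up",
           ifelse(feats %in% catalog[[cn]]$down, "down", "none"))
  })
  prof <- matrix(prof, nrow = length(feats),
                 dimnames = list(feats, names(catalog)))
  n <- rowSums(prof != "none")
  keep <- n > minCancers
  out <- as.data.frame(prof[keep, , drop = FALSE], stringsAsFactors = FALSE)
  out$n_cancers <- unname(n[keep])
  out
}

#' Negatively correlated lncRNAs (UMLE / DMOE)
#'
#' Crosses methylation calls with expression calls: per cancer, UMLE =
#' methylation-up and expression-down; DMOE = methylation-down and
#' expression-up.  Same-direction combinations are excluded.  Cancers
#' present in only one catalog are skipped with a warning.
#'
#' @param dm methylation catalog ([dmCatalog()] of [callDMlncs()] results).
#' @param de expression catalog ([dmCatalog()] of [callDELncs()] results).
#' @return named list, cancer -> \code{list(UMLE =, DMOE =)} character
#'   vectors.
#' @export
negativeCorrelated <- function(dm, de) {
  .checkCatalog(dm); .checkCatalog(de)
  shared <- intersect(names(dm), names(de))
  skipped <- setdiff(union(names(dm), names(de)), shared)
  if (length(skipped))
    warning("cancer(s) present in one catalog only, skipped: ",
            paste(skipped, collapse = ", "))
  out <- lapply(shared, function(cn) {
    list(UMLE = intersect(dm[[cn]]$up, de[[cn]]$down),
         DMOE = intersect(dm[[cn]]$down, de[[cn]]$up))
  })
  names(out) <- shared
  out
}

#' Cancer-specific negatively correlated lncRNAs
#'
#' Per cancer, the intersection of the cancer-specific DM sets with the
#' negatively-correlated (UMLE/DMOE) sets from the same catalog run.
#'
#' @param specific output of [cancerSpecific()].
#' @param nc output of [negativeCorrelated()].
#' @return named list, cancer -> character vector of CSNClnc ids.
#' @export
csnclncs <- function(specific, nc) {
  shared <- intersect(names(specific), names(nc))
  out <- lapply(shared, function(cn) {
    spec <- c(specific[[cn]]$specific_up, specific[[cn]]$specific_down)
    intersect(spec, c(nc[[cn]]$UMLE, nc[[cn]]$DMOE))
  })
  names(out) <- shared
  out
}
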