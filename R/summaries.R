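#' Summary formulas for essentiality call tables
#'
#' The small arithmetic used in the pipeline's reports, exposed so the same
#' formulas can be applied to any count table: percentage of genes with a
#' determined call, prediction/annotation concordance, polymorphism rate,
#' segment-tolerance rates, and the number of unordered gene pairs.
#'
#' @param nDetermined,nUndetermined genes with and without an E/NE call.
#' @return [callRateSummary()]: list \code{pctDetermined},
#'   \code{pctUndetermined} (percent, one decimal as reported).
#' @export
callRateSummary <- function(nDetermined, nUndetermined) {
  tot <- nDetermined + nUndetermined
  list(pctDetermined = round(100 * nDetermined / tot, 1),
       pctUndetermined = round(100 * nUndetermined / tot, 1))
}

#' @param nAgree predictions matching the annotation.
#' @param nPredEssAnnNoness predicted essential but annotated nonessential.
#' @param nPredNonessAnnEss predicted nonessential but annotated essential.
#' @return [concordanceSummary()]: list of the three percentages
#'   (\code{pctAgree} to one decimal, the disparity rates to two).
#' @rdname callRateSummary
#' @export
concordanceSummary <- function(nAgree, nPredEssAnnNoness,
                               nPredNonessAnnEss) {
  tot <- nAgree + nPredEssAnnNoness + nPredNonessAnnEss
  list(pctAgree = round(100 * nAgree / tot, 1),
       pctPredEssAnnNoness = round(100 * nPredEssAnnNoness / tot, 2),
       pctPredNonessAnnEss = round(100 * nPredNonessAnnEss / tot, 2))
}

#' @param nPolymorphic genes switching essentiality in >= 1 strain.
#' @param nComparable genes with essentiality determined in >= 2 strains.
#' @return [polymorphismSummary()]: percent polymorphic, one decimal.
#' @rdname callRateSummary
#' @export
polymorphismSummary <- function(nPolymorphic, nComparable) {
  round(100 * nPolymorphic / nComparable, 1)
}

#' @param nAtLeast1,nAtLeast3 genes with >= 1 / >= 3 tolerant segments.
#' @param nGenes cohort size.
#' @return [toleranceSummary()]: list \code{pctAtLeast1},
#'   \code{pctAtLeast3}, one decimal.
#' @rdname callRateSummary
#' @export
toleranceSummary <- function(nAtLeast1, nAtLeast3, nGenes) {
  list(pctAtLeast1 = round(100 * nAtLeast1 / nGenes, 1),
       pctAtLeast3 = round(100 * nAtLeast3 / nGenes, 1))
}

#' @param n number of genes.
#' @return [genePairCount()]: n(n-1)/2 unordered pairs.
#' @rdname callRateSummary
#' @export
genePairCount <- function(n) n * (n - 1) / 2
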