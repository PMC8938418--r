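#' Ten-segment insertion counts per gene
#'
#' Divides each CDS into ten equal-length segments (remainder to the last,
#' 3'-most segment — the same partition used by the \code{free_tenths}
#' feature) and counts transposon insertions per segment, ordered 5' to 3'
#' in the gene's reading direction. Masked positions contribute no
#' insertions; segments that are fully masked are returned as NA
#' (indeterminate) rather than zero.
#'
#' @param map an \linkS4class{InsertionMap}.
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param genes optional gene ids (default: all annotated genes).
#' @param cache optional [featureCache()] for \code{ann}.
#' @return integer matrix genes x 10; \code{rowSums} (over non-NA entries)
#'   equals the gene's \code{n_tn}.
#' @export
segmentCounts <- function(map, ann, genes = NULL, cache = NULL) {
  if (is.null(cache)) cache <- featureCache(ann)
  gr <- cache$genes
  idx <- if (is.null(genes)) seq_along(gr) else match(genes, cache$geneIds)
  if (anyNA(idx)) stop("genes not in annotation: ",
                       paste(genes[is.na(idx)], collapse = ", "))
  sites <- insertionSites(map)
  if (length(cache$mask))
    sites <- sites[!overlapsAny(sites, cache$mask, ignore.strand = TRUE)]
  hits <- findOverlaps(gr[idx], sites, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  pos <- start(sites)[S4Vectors::subjectHits(hits)]
  out <- matrix(0L, nrow = length(idx), ncol = 10L,
                dimnames = list(cache$geneIds[idx], paste0("seg", 1:10)))
  gs <- start(gr)[idx]; ge <- end(gr)[idx]; minus <- cache$minus[idx]
  for (k in unique(q)) {
    p <- pos[q == k]
    seg <- .segIndex(p, gs[k], ge[k], minus[k])
    out[k, ] <- tabulate(seg, 10L)
  }
  # fully masked segments are indeterminate
  if (length(cache$mask)) {
    for (k in seq_along(idx)) {
      segGr <- .segmentRanges(as.character(seqnames(gr))[idx[k]],
                              gs[k], ge[k], minus[k])
      mw <- maskedWidth(segGr, cache$mask)
      out[k, mw >= width(segGr)] <- NA_integer_
    }
  }
  out
}

# the ten segment intervals of a CDS, 5'->3' in reading direction
.segmentRanges <- function(chrom, s, e, minus) {
  L <- e - s + 1L
  base <- L %/% 10L
  lens <- c(rep(base, 9L), L - 9L * base)
  if (minus) {
    ends <- e - c(0L, cumsum(lens[-10L]))
    starts <- ends - lens + 1L
  } else {
    starts <- s + c(0L, cumsum(lens[-10L]))
    ends <- starts + lens - 1L
  }
  GRanges(chrom, IRanges(starts, ends))
}

#' Does a gene tolerate insertions in at least one segment of one strain?
#'
#' TRUE when any of the ten segments holds at least \code{minInsertions}
#' insertions in this strain.
#'
#' @param counts integer vector of 10 segment counts (NA = indeterminate)
#'   or a genes x 10 matrix.
#' @param minInsertions minimum insertions in a segment (default 2).
#' @return logical (vector when \code{counts} is a matrix).
#' @export
perStrainTolerance <- function(counts, minInsertions = 2L) {
  if (is.matrix(counts))
    return(apply(counts, 1L, function(v)
      any(v >= minInsertions, na.rm = TRUE)))
  any(counts >= minInsertions, na.rm = TRUE)
}

#' Consensus transposon tolerance across strains
#'
#' A segment of a gene is consensus-tolerant when it holds at least
#' \code{minInsertions} insertion(s) in at least \code{minStrains} strains.
#' Summaries report, per gene, the number of tolerant segments, and for the
#' cohort the fraction of genes with >= 1 and >= 3 tolerant segments plus
#' the per-segment gene counts (their 5'/3' profile shows where essential
#' genes tolerate disruption).
#'
#' @param profiles named list (one per strain) of genes x 10 count matrices
#'   from [segmentCounts()], all with identical rownames.
#' @param minStrains strains required to call a segment tolerant
#'   (default 9).
#' @param minInsertions insertions required per strain (default 1).
#' @return list: \code{flags} (logical genes x 10; NA when a segment was
#'   indeterminate in too many strains), \code{nTolerant} (per gene),
#'   \code{summary} (list nGenes, pctAtLeast1, pctAtLeast3),
#'   \code{perSegment} (genes tolerant per segment, 5' to 3').
#' @export
consensusTolerance <- function(profiles, minStrains = 9L,
                               minInsertions = 1L) {
  if (length(profiles) < minStrains)
    stop(sprintf("only %d strain profiles for minStrains = %d",
                 length(profiles), minStrains))
  g <- rownames(profiles[[1]])
  for (p in profiles)
    if (!identical(rownames(p), g))
      stop("strain profiles have differing gene sets")
  tol <- Reduce(`+`, lapply(profiles, function(p) {
    m <- (p >= minInsertions)
    m[is.na(m)] <- FALSE
    m
  }))
  determined <- Reduce(`+`, lapply(profiles, function(p) !is.na(p)))
  flags <- tol >= minStrains
  flags[determined < minStrains & !flags] <- NA
  nTol <- rowSums(flags, na.rm = TRUE)
  list(flags = flags, nTolerant = nTol,
       summary = list(nGenes = length(g),
                      pctAtLeast1 = 100 * mean(nTol >= 1),
                      pctAtLeast3 = 100 * mean(nTol >= 3)),
       perSegment = colSums(flags, na.rm = TRUE))
}
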