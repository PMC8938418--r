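#' Precompute annotation-derived geometry for feature extraction
#'
#' Feature extraction repeatedly needs per-gene geometry that does not depend
#' on the insertion map: effective lengths, strand-aware upstream windows,
#' the surrounding noncoding neighborhood of each gene, and the ten-segment
#' partition of each CDS. Computing these once per annotation makes
#' downsampling replicates cheap.
#'
#' The neighborhood of a gene is the nearest \code{windowNoncoding} unmasked
#' noncoding nucleotides, collected walking outward from both gene ends
#' (half per side); when a chromosome end truncates one side, the deficit is
#' collected from the other side.
#'
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param windowNoncoding total noncoding nucleotides collected around each
#'   gene (default 10,000).
#' @param upstreamWindow upstream window length in nt (default 100),
#'   strand-aware (upstream of the translational start).
#' @param minLength minimum effective gene length retained (default 300 nt).
#' @return an opaque list consumed by [geneFeatures()] and [segmentCounts()].
#' @export
featureCache <- function(ann, windowNoncoding = 10000L,
                         upstreamWindow = 100L, minLength = 300L) {
  genes <- annotatedGenes(ann)
  mask <- regionMask(ann)
  sl <- chromLengths(ann)
  if (!length(sl))
    stop("annotation must carry chromosome lengths")
  eff <- effectiveLength(genes, mask, minLength = minLength)
  n <- length(genes)

  # strand-aware upstream windows, clipped to the chromosome
  gstart <- start(genes); gend <- end(genes)
  minus <- as.character(strand(genes)) == "-"
  upS <- ifelse(minus, gend + 1L, pmax(1L, gstart - upstreamWindow))
  upE <- ifelse(minus, pmin(gend + upstreamWindow,
                            sl[as.character(seqnames(genes))]), gstart - 1L)
  ok <- upE >= upS
  upstream <- GRanges(as.character(seqnames(genes))[ok],
                      IRanges(upS[ok], upE[ok]))
  upstreamIdx <- which(ok)

  # unmasked noncoding intervals per chromosome
  genome <- GRanges(names(sl), IRanges(1L, as.integer(sl)))
  covered <- reduce(c(granges(genes, use.mcols = FALSE),
                      granges(mask, use.mcols = FALSE)),
                    ignore.strand = TRUE)
  strand(covered) <- "*"
  noncoding <- GenomicRanges::setdiff(genome, covered, ignore.strand = TRUE)
  ncByChrom <- split(noncoding, as.character(seqnames(noncoding)))

  half <- as.integer(windowNoncoding %/% 2L)
  nbhdList <- vector("list", n)
  nbhdWidth <- integer(n)
  chrs <- as.character(seqnames(genes))
  for (i in seq_len(n)) {
    nc <- ncByChrom[[chrs[i]]]
    if (is.null(nc) || !length(nc)) { nbhdList[[i]] <- GRanges(); next }
    ncs <- start(nc); nce <- end(nc)
    left <- .collectFlank(ncs, nce, bound = gstart[i] - 1L, side = "left",
                          quota = half)
    right <- .collectFlank(ncs, nce, bound = gend[i] + 1L, side = "right",
                           quota = half)
    deficit <- (half - left$got) + (half - right$got)
    if (deficit > 0L) {
      if (left$got < half)
        right <- .collectFlank(ncs, nce, bound = gend[i] + 1L,
                               side = "right", quota = half + (half - left$got))
      if (right$got < half)
        left <- .collectFlank(ncs, nce, bound = gstart[i] - 1L,
                              side = "left", quota = half + (half - right$got))
    }
    ivs <- rbind(left$iv, right$iv)
    nbhdWidth[i] <- left$got + right$got
    nbhdList[[i]] <- if (nrow(ivs))
      GRanges(chrs[i], IRanges(ivs[, 1L], ivs[, 2L])) else GRanges()
  }
  nbhd <- GRangesList(nbhdList)

  list(genes = genes, mask = mask, chromLengths = sl,
       geneIds = genes$gene_id, effLength = as.integer(eff),
       discard = attr(eff, "discard"),
       cdsLength = width(genes), minus = minus,
       upstream = upstream, upstreamIdx = upstreamIdx,
       nbhd = nbhd, nbhdWidth = nbhdWidth,
       windowNoncoding = as.integer(windowNoncoding))
}

# collect up to `quota` nt of noncoding sequence on one side of `bound`,
# nearest intervals first; returns matrix of kept [start,end] + total got
.collectFlank <- function(ncStart, ncEnd, bound, side, quota) {
  if (side == "left") {
    keep <- ncStart <= bound
    s <- ncStart[keep]; e <- pmin(ncEnd[keep], bound)
    o <- order(e, decreasing = TRUE)       # nearest = largest end
  } else {
    keep <- ncEnd >= bound
    s <- pmax(ncStart[keep], bound); e <- ncEnd[keep]
    o <- order(s)                          # nearest = smallest start
  }
  s <- s[o]; e <- e[o]
  got <- 0L
  out <- matrix(integer(0), ncol = 2L)
  for (j in seq_along(s)) {
    w <- e[j] - s[j] + 1L
    take <- min(w, quota - got)
    if (take <= 0L) break
    if (side == "left")
      out <- rbind(out, c(e[j] - take + 1L, e[j]))
    else
      out <- rbind(out, c(s[j], s[j] + take - 1L))
    got <- got + take
    if (got >= quota) break
  }
  list(iv = out, got = got)
}

#' Per-gene classifier features from an insertion map
#'
#' Computes, for every gene of the annotation, the nine features used by the
#' essentiality classifier: (1) number of transposon insertions in the CDS
#' (\code{n_tn}), (2) insertion density per effective nucleotide
#' (\code{tn_density}), (3) summed read count (\code{n_reads}), (4) read
#' density (\code{read_density}), (5) length of the longest insertion-free
#' CDS stretch (\code{longest_free}), (6) that length divided by the CDS
#' length (\code{freedom_index}), (7) insertions within 100 nt upstream of
#' the translational start (\code{upstream_tn}), (8) gene insertion density
#' divided by the density of the surrounding 10,000 noncoding nucleotides
#' (\code{neighborhood_index}), and (9) the number of tenth-segments of the
#' CDS without any insertion (\code{free_tenths}).
#'
#' Masked (repetitive/unmapped) positions contribute neither insertions nor
#' length: sites inside the mask are dropped before counting and densities
#' use the effective length. A neighborhood with zero insertions is assigned
#' a pseudocount density of 0.5 insertions per collected window so the index
#' stays finite.
#'
#' @param map an \linkS4class{InsertionMap}.
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param cache optional precomputed [featureCache()] for \code{ann}.
#' @return data.frame with one row per gene: \code{gene_id}, \code{strain},
#'   the nine features, \code{effective_length} and \code{discard} (TRUE for
#'   genes with effective length < 300 nt, to be excluded downstream).
#' @examples
#' sim <- simulateSatayDataset(simulationConfig(nGenes = 40, nStrains = 2),
#'                             seed = 1)
#' head(geneFeatures(sim$maps[[1]], sim$annotation))
#' @export
geneFeatures <- function(map, ann, cache = NULL) {
  if (is.null(cache)) cache <- featureCache(ann)
  eng <- .featureEngine(map, cache)
  eng$compute(NULL)
}

# Precomputes every overlap between one map's (unmasked) sites and the
# cached gene geometry, returning a closure that evaluates the feature
# table for any kept subset of sites. Downsampling replicates reuse the
# overlaps and only redo the per-gene arithmetic.
.featureEngine <- function(map, cache) {
  sites <- insertionSites(map)
  if (length(cache$mask))
    sites <- sites[!overlapsAny(sites, cache$mask, ignore.strand = TRUE)]
  genes <- cache$genes
  n <- length(genes)
  nSites <- length(sites)
  pos <- start(sites)
  reads <- if (nSites) sites$reads else integer(0)

  gh <- findOverlaps(genes, sites, ignore.strand = TRUE)
  ghQ <- S4Vectors::queryHits(gh)
  ghS <- S4Vectors::subjectHits(gh)
  uh <- findOverlaps(cache$upstream, sites, ignore.strand = TRUE)
  uhQ <- cache$upstreamIdx[S4Vectors::queryHits(uh)]
  uhS <- S4Vectors::subjectHits(uh)
  nh <- findOverlaps(cache$nbhd, sites, ignore.strand = TRUE)
  nhQ <- S4Vectors::queryHits(nh)
  nhS <- S4Vectors::subjectHits(nh)

  gs <- start(genes); ge <- end(genes); L <- cache$cdsLength
  eff <- pmax(cache$effLength, 1L)
  strain <- strainName(map)

  compute <- function(keep = NULL) {
    if (is.null(keep)) {
      kq <- ghQ; kpos <- pos[ghS]; kr <- reads[ghS]
      up <- tabulate(uhQ, n)
      nb <- tabulate(nhQ, n)
    } else {
      kg <- keep[ghS]
      kq <- ghQ[kg]; kpos <- pos[ghS[kg]]; kr <- reads[ghS[kg]]
      up <- tabulate(uhQ[keep[uhS]], n)
      nb <- tabulate(nhQ[keep[nhS]], n)
    }
    n_tn <- tabulate(kq, n)
    n_reads <- integer(n)
    if (length(kq)) {
      agg <- rowsum(kr, kq)
      n_reads[as.integer(rownames(agg))] <- as.integer(agg)
    }
    o <- order(kq, kpos)
    kq <- kq[o]; kpos <- kpos[o]
    bounds <- c(0L, cumsum(n_tn))
    longest <- integer(n)
    tenths <- integer(n)
    for (i in seq_len(n)) {
      if (n_tn[i] == 0L) {
        longest[i] <- L[i]
        tenths[i] <- 10L
      } else {
        p <- kpos[(bounds[i] + 1L):bounds[i + 1L]]
        longest[i] <- .longestFree(p, gs[i], ge[i])
        tenths[i] <- .freeTenths(p, gs[i], ge[i], cache$minus[i])
      }
    }
    nbhdDens <- ifelse(nb > 0, nb, 0.5) / pmax(cache$nbhdWidth, 1L)
    tn_density <- n_tn / eff
    data.frame(gene_id = cache$geneIds, strain = strain,
               n_tn = n_tn, tn_density = tn_density,
               n_reads = n_reads, read_density = n_reads / eff,
               longest_free = longest, freedom_index = longest / L,
               upstream_tn = up,
               neighborhood_index = tn_density / nbhdDens,
               free_tenths = tenths,
               effective_length = cache$effLength,
               discard = cache$discard,
               stringsAsFactors = FALSE)
  }
  list(compute = compute, nSites = nSites,
       codingSiteIdx = sort(unique(ghS)))
}

#' Longest insertion-free stretch of a CDS
#'
#' Length in nucleotides of the longest run of CDS positions without a
#' transposon insertion: the maximum over the two flanks and all gaps
#' strictly between consecutive insertion positions. A gene without
#' insertions returns its full CDS length.
#'
#' @param positions integer vector of insertion positions (1-based, within
#'   the CDS; any order).
#' @param start,end 1-based closed CDS bounds.
#' @return integer length (nt).
#' @examples
#' longestFreeRegion(c(101, 901), 1, 1000)  # 799
#' @export
longestFreeRegion <- function(positions, start, end) {
  .longestFree(positions, start, end)
}

.longestFree <- function(p, s, e) {
  if (!length(p)) return(e - s + 1L)
  p <- sort.int(unique(p))
  max(p[1L] - s, e - p[length(p)],
      if (length(p) > 1L) max(diff(p)) - 1L else 0L)
}

#' Insertion-free tenth segments of a CDS
#'
#' The CDS is split into ten equal-length segments (any remainder goes to
#' the last, 3'-most segment); returns how many segments carry no insertion.
#'
#' @inheritParams longestFreeRegion
#' @param minus TRUE when the gene is on the minus strand (segments are
#'   ordered 5' to 3' in the gene's reading direction).
#' @return integer in 0..10.
#' @examples
#' freeTenths(integer(0), 1, 1000)   # 10
#' freeTenths(1003, 1, 1003)         # 9: the insertion sits in segment 10
#' @export
freeTenths <- function(positions, start, end, minus = FALSE) {
  .freeTenths(positions, start, end, minus)
}

.segIndex <- function(p, s, e, minus) {
  L <- e - s + 1L
  base <- L %/% 10L
  off <- if (minus) e - p + 1L else p - s + 1L
  pmin((off - 1L) %/% base + 1L, 10L)
}

.freeTenths <- function(p, s, e, minus = FALSE) {
  if (!length(p)) return(10L)
  10L - length(unique(.segIndex(p, s, e, minus)))
}

#' Neighborhood insertion density around a gene
#'
#' Density of insertions in the nearest \code{windowNoncoding} unmasked
#' noncoding nucleotides around one gene (see [featureCache()] for the
#' collection rule). Exposed mainly for inspection; [geneFeatures()] computes
#' the same quantity vectorized.
#'
#' @param geneId gene identifier.
#' @param map an \linkS4class{InsertionMap}.
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param windowNoncoding total noncoding window (default 10,000 nt).
#' @return density per nucleotide (pseudocount 0.5/window when empty).
#' @export
neighborhoodDensity <- function(geneId, map, ann, windowNoncoding = 10000L) {
  cache <- featureCache(ann, windowNoncoding = windowNoncoding)
  i <- match(geneId, cache$geneIds)
  if (is.na(i)) stop("gene not in annotation: ", geneId)
  sites <- insertionSites(map)
  if (length(cache$mask))
    sites <- sites[!overlapsAny(sites, cache$mask, ignore.strand = TRUE)]
  cnt <- countOverlaps(cache$nbhd[i], sites, ignore.strand = TRUE)
  ifelse(cnt > 0, cnt, 0.5) / max(cache$nbhdWidth[i], 1L)
}

#' @importFrom GenomicRanges GRangesList granges
NULL
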