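#' Collapse aligned reads into transposon insertion sites
#'
#' Reads of the same orientation mapped within two nucleotides of each other
#' are taken to originate from the same transposon. Collapsing chains
#' greedily left to right within each (chromosome, strand): a read joins the
#' current chain when its position is at most \code{maxGap} nucleotides from
#' the previous position in the chain (so a run 100, 102, 104 merges into a
#' single site). Each chain becomes one insertion site at its leftmost
#' position, with read counts summed. Opposite-strand reads never merge.
#'
#' The operation is idempotent and conserves the total read count.
#'
#' @param reads a \code{GRanges} of width-1 read positions with a
#'   \code{reads} metadata column, or a data.frame with columns \code{chrom},
#'   \code{pos} (1-based), \code{strand}, \code{reads}.
#' @param strain strain identifier for the resulting map.
#' @param chromLengths optional named vector of chromosome lengths.
#' @param maxGap maximum within-chain gap in nucleotides (default 2).
#' @return an \linkS4class{InsertionMap} of collapsed sites.
#' @examples
#' r <- data.frame(chrom = "chrI", pos = c(101, 102, 103), strand = "+",
#'                 reads = c(1L, 2L, 1L))
#' collapseReads(r, strain = "s1")   # one site at 101 with 4 reads
#' @export
collapseReads <- function(reads, strain, chromLengths = NULL, maxGap = 2L) {
  if (is.data.frame(reads)) {
    if (any(reads$pos < 1)) stop("negative or zero read position")
    if (any(reads$reads < 1)) stop("read counts must be >= 1")
    reads <- GRanges(reads$chrom, IRanges(reads$pos, width = 1L),
                     strand = reads$strand,
                     reads = as.integer(reads$reads))
  }
  if (is.null(reads$reads)) reads$reads <- 1L
  if (any(reads$reads < 1)) stop("read counts must be >= 1")
  o <- order(as.integer(seqnames(reads)), as.integer(strand(reads)),
             start(reads))
  reads <- reads[o]
  pos <- start(reads)
  grp <- paste(seqnames(reads), strand(reads))
  newChain <- c(TRUE, diff(pos) > maxGap | grp[-1] != grp[-length(grp)])
  chain <- cumsum(newChain)
  first <- which(newChain)
  sites <- GRanges(seqnames(reads)[first],
                   IRanges(pos[first], width = 1L),
                   strand = strand(reads)[first],
                   reads = as.integer(
                     tapply(reads$reads, chain, sum)[as.character(
                       seq_along(first))]),
                   seqinfo = seqinfo(reads))
  InsertionMap(strain, sites, chromLengths = chromLengths)
}

#' Effective gene length
#'
#' The effective length of a gene is its CDS length minus the masked
#' (repetitive plus unmapped) nucleotides it overlaps. Genes with effective
#' length below \code{minLength} (default 300 nt) should be discarded from
#' essentiality analysis; the returned vector carries a \code{discard}
#' attribute flagging them.
#'
#' @param genes \code{GRanges} of gene CDS intervals, or a
#'   \linkS4class{GenomeAnnotation} (whose own mask is then used).
#' @param mask \code{GRanges} of masked intervals (ignored when \code{genes}
#'   is a \code{GenomeAnnotation}).
#' @param minLength minimum effective length retained (nt).
#' @return named integer vector of effective lengths (names = gene_id when
#'   available) with attribute \code{discard} (logical).
#' @examples
#' g <- GenomicRanges::GRanges("chrI", IRanges::IRanges(1, 900))
#' m <- GenomicRanges::GRanges("chrI", IRanges::IRanges(101, 200))
#' effectiveLength(g, m)  # 800
#' @export
effectiveLength <- function(genes, mask = NULL, minLength = 300L) {
  if (is(genes, "GenomeAnnotation")) {
    mask <- regionMask(genes)
    genes <- annotatedGenes(genes)
  }
  if (is.null(mask)) mask <- GRanges()
  masked <- maskedWidth(genes, mask)
  eff <- width(genes) - masked
  names(eff) <- genes$gene_id
  attr(eff, "discard") <- eff < minLength
  eff
}

#' Scan a strain for aneuploid chromosomes
#'
#' Chromosome-gain aneuploidy roughly doubles a chromosome's transposon
#' density (every essential gene on the extra copy is insertion-tolerant).
#' A chromosome is flagged when its unmasked insertion density is at least
#' \code{ratioThreshold} times the strain's median per-chromosome density.
#' Manual flags (e.g., a chromosome with aneuploidy-like tolerance but no
#' density doubling) can be supplied downstream via
#' [buildEssentialityMatrix()]'s \code{manualMasks}.
#'
#' @param map an \linkS4class{InsertionMap}.
#' @param ann a \linkS4class{GenomeAnnotation} providing the mask and
#'   chromosome lengths.
#' @param ratioThreshold flag densities >= this multiple of the strain median
#'   (default 1.5; a gained chromosome is expected near 2).
#' @return data.frame with one row per flagged chromosome: \code{strain},
#'   \code{chrom}, \code{density}, \code{ratio}.
#' @export
aneuploidyScan <- function(map, ann, ratioThreshold = 1.5) {
  stopifnot(ratioThreshold > 1)
  sites <- insertionSites(map)
  if (!length(sites))
    stop("strain ", strainName(map), " has zero insertions")
  mask <- regionMask(ann)
  keep <- !overlapsAny(sites, mask, ignore.strand = TRUE)
  sites <- sites[keep]
  sl <- chromLengths(ann)
  if (!length(sl)) stop("annotation carries no chromosome lengths")
  maskBy <- rep(0L, length(sl))
  names(maskBy) <- names(sl)
  if (length(mask)) {
    mw <- tapply(width(mask), as.character(seqnames(mask)), sum)
    maskBy[names(mw)] <- mw
  }
  effLen <- sl - maskBy
  n <- table(factor(as.character(seqnames(sites)), levels = names(sl)))
  dens <- as.numeric(n) / effLen
  # leave-one-out median: a gained chromosome must not inflate its own
  # baseline (matters when few chromosomes are available)
  ratio <- vapply(seq_along(dens), function(i) {
    med <- stats::median(dens[-i])
    if (med <= 0) stop("median chromosome density is zero")
    dens[i] / med
  }, numeric(1))
  if (length(dens) == 1L) ratio <- 1
  hit <- which(ratio >= ratioThreshold)
  data.frame(strain = rep(strainName(map), length(hit)),
             chrom = names(sl)[hit],
             density = dens[hit], ratio = ratio[hit],
             row.names = NULL, stringsAsFactors = FALSE)
}

# per-range masked width: sum of intersection with the (reduced) mask
maskedWidth <- function(gr, mask) {
  out <- rep(0L, length(gr))
  if (!length(mask) || !length(gr)) return(out)
  red <- reduce(mask, ignore.strand = TRUE)
  hits <- findOverlaps(gr, red, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  w <- pmin(end(gr)[q], end(red)[s]) - pmax(start(gr)[q], start(red)[s]) + 1L
  agg <- tapply(w, q, sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

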