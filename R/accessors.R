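#' Construct an InsertionMap
#'
#' @param strain strain identifier.
#' @param sites \code{GRanges} of width-1 insertion positions with a
#'   \code{reads} metadata column, or a data.frame with columns \code{chrom},
#'   \code{pos} (1-based), \code{strand}, \code{reads}.
#' @param chromLengths optional named integer vector of chromosome lengths;
#'   if omitted, any seqlengths already on \code{sites} are kept.
#'
#' @return an \linkS4class{InsertionMap}. Sites are sorted by
#'   (chromosome, position).
#' @examples
#' sites <- data.frame(chrom = "chrI", pos = c(100, 500), strand = "+",
#'                     reads = c(3L, 1L))
#' InsertionMap("S288C", sites, chromLengths = c(chrI = 1000))
#' @export
InsertionMap <- function(strain, sites, chromLengths = NULL) {
  if (is.data.frame(sites)) {
    if (!all(c("chrom", "pos", "strand", "reads") %in% colnames(sites)))
      stop("site data.frame needs columns chrom, pos, strand, reads")
    if (any(sites$pos < 1))
      stop("positions must be >= 1 (1-based coordinates)")
    if (any(sites$reads < 1))
      stop("read counts must be >= 1")
    sites <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L),
                     strand = sites$strand,
                     reads = as.integer(sites$reads))
  }
  if (!is.null(chromLengths)) {
    sites <- GRanges(as.character(seqnames(sites)),
                     IRanges(start(sites), width = 1L),
                     strand = strand(sites), reads = sites$reads,
                     seqinfo = Seqinfo(names(chromLengths),
                                       as.integer(chromLengths)))
  }
  sites <- sites[order(as.integer(seqnames(sites)), start(sites))]
  new("InsertionMap", strain = as.character(strain), sites = sites)
}

#' Construct a GenomeAnnotation
#'
#' @param genes \code{GRanges} of CDS intervals with metadata columns
#'   \code{gene_id} and optionally \code{annotation}; or a data.frame with
#'   columns \code{chrom}, \code{start}, \code{end} (1-based closed),
#'   \code{strand}, \code{gene_id} and optionally \code{annotation}.
#' @param mask \code{GRanges} (or data.frame with \code{chrom},
#'   \code{start}, \code{end}) of repetitive/unmapped intervals; overlapping
#'   intervals are unioned.
#' @param chromLengths named integer vector of chromosome lengths.
#'
#' @return a \linkS4class{GenomeAnnotation}.
#' @examples
#' genes <- data.frame(chrom = "chrI", start = 1, end = 900, strand = "+",
#'                     gene_id = "g1", annotation = "essential")
#' genomeAnnotation(genes, chromLengths = c(chrI = 2000))
#' @export
genomeAnnotation <- function(genes, mask = NULL, chromLengths = NULL) {
  toGR <- function(x, withStrand = TRUE) {
    if (is.data.frame(x)) {
      gr <- GRanges(x$chrom, IRanges(x$start, x$end),
                    strand = if (withStrand && !is.null(x$strand))
                      x$strand else "*")
      extra <- setdiff(colnames(x), c("chrom", "start", "end", "strand"))
      for (cn in extra) mcols(gr)[[cn]] <- x[[cn]]
      gr
    } else x
  }
  genes <- toGR(genes)
  if (is.null(genes$annotation))
    genes$annotation <- "unknown"
  genes$annotation <- as.character(genes$annotation)
  if (is.null(mask)) {
    mask <- GRanges()
  } else {
    mask <- reduce(toGR(mask, withStrand = FALSE), ignore.strand = TRUE)
    strand(mask) <- "*"
  }
  if (!is.null(chromLengths)) {
    si <- Seqinfo(names(chromLengths), as.integer(chromLengths))
    mc <- mcols(genes)
    genes <- GRanges(as.character(seqnames(genes)),
                     IRanges(start(genes), end(genes)),
                     strand = strand(genes), seqinfo = si)
    mcols(genes) <- mc
    if (length(mask)) {
      mask <- GRanges(as.character(seqnames(mask)),
                      IRanges(start(mask), end(mask)), seqinfo = si)
    }
  }
  new("GenomeAnnotation", genes = genes, mask = mask)
}

#' Construct an SNPMatrix
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @param calls 0/1 integer matrix, sites x strains, with strain column names.
#' @return a \linkS4class{SNPMatrix}.
#' @export
snpMatrix <- function(sites, calls) {
  storage.mode(calls) <- "integer"
  new("SNPMatrix", sites = as.data.frame(sites), calls = calls)
}

#' Accessors for satayEvol containers
#'
#' Small accessor family for the package's S4 containers: strain name and
#' insertion sites of an \linkS4class{InsertionMap}; genes and mask of a
#' \linkS4class{GenomeAnnotation}; call and probability matrices of an
#' \linkS4class{EssentialityMatrix}; sites and genotype calls of a
#' \linkS4class{SNPMatrix}; thresholds, bins and FDRs of a
#' \linkS4class{CalibrationResult}.
#'
#' @param x the object.
#' @return the corresponding slot value; \code{chromLengths} returns the
#'   named vector of chromosome lengths carried by the object's seqinfo.
#' @name accessors
NULL

#' @rdname accessors
#' @export
strainName <- function(x) x@strain

#' @rdname accessors
#' @export
insertionSites <- function(x) x@sites

#' @rdname accessors
#' @export
chromLengths <- function(x) {
  gr <- if (is(x, "InsertionMap")) x@sites else x@genes
  sl <- seqlengths(gr)
  sl[!is.na(sl)]
}

#' @rdname accessors
#' @export
annotatedGenes <- function(x) x@genes

#' @rdname accessors
#' @export
regionMask <- function(x) x@mask

#' @rdname accessors
#' @export
essCalls <- function(x) x@calls

#' @rdname accessors
#' @export
essProbs <- function(x) x@probs

#' @rdname accessors
#' @export
snpSites <- function(x) x@sites

#' @rdname accessors
#' @export
snpCalls <- function(x) x@calls

#' @rdname accessors
#' @export
calibThresholds <- function(x) x@thresholds

#' @rdname accessors
#' @export
calibBins <- function(x) x@bins

#' @rdname accessors
#' @export
calibFdr <- function(x) x@fdr
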