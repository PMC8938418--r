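#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges GRangesList granges seqnames start end
#'   width strand strand<- findOverlaps countOverlaps reduce intersect
#'   setdiff gaps
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo Seqinfo
#' @importFrom BiocGenerics sort
NULL

#' InsertionMap: transposon insertions of one strain
#'
#' Container for the genome-wide transposon insertion map of a single strain.
#' Each insertion site is a width-1 \link[GenomicRanges]{GRanges} position with
#' a strand and a positive read count (metadata column \code{reads}).
#' Chromosome lengths are carried in the \code{seqinfo} of \code{sites}.
#'
#' Validity requires read counts \eqn{\ge 1}, sites sorted by (chromosome,
#' position), no duplicated (chromosome, position, strand) triple, and all
#' positions within the chromosome bounds.
#'
#' @slot strain single strain identifier.
#' @slot sites \code{GRanges} of width-1 insertion positions with integer
#'   metadata column \code{reads}.
#'
#' @seealso [InsertionMap()], [collapseReads()], [readInsertionBed()]
#' @export
setClass("InsertionMap",
  representation(strain = "character", sites = "GRanges"))

setValidity("InsertionMap", function(object) {
  msg <- character()
  if (length(object@strain) != 1L || is.na(object@strain) ||
      !nzchar(object@strain))
    msg <- c(msg, "'strain' must be a single non-empty string")
  s <- object@sites
  if (length(s)) {
    if (is.null(s$reads))
      msg <- c(msg, "sites must carry a 'reads' metadata column")
    else {
      if (any(is.na(s$reads)) || any(s$reads < 1))
        msg <- c(msg, "all read counts must be >= 1")
    }
    if (any(width(s) != 1L))
      msg <- c(msg, "insertion sites must have width 1")
    if (is.unsorted(order(as.integer(seqnames(s)), start(s))) &&
        !identical(order(as.integer(seqnames(s)), start(s)),
                   seq_along(s)))
      msg <- c(msg, "sites must be sorted by (chromosome, position)")
    key <- paste(seqnames(s), start(s), strand(s))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicated (chromosome, position, strand) sites")
    sl <- seqlengths(s)
    if (!all(is.na(sl))) {
      bad <- end(s) > sl[as.character(seqnames(s))]
      if (any(bad, na.rm = TRUE))
        msg <- c(msg, "insertion positions beyond chromosome length")
    }
  }
  if (length(msg)) msg else TRUE
})

#' GenomeAnnotation: gene models plus region mask
#'
#' Gene CDS intervals (with strand, stable \code{gene_id} and, where known,
#' deletion-based essentiality labels) together with a mask of repetitive and
#' unmapped regions. Densities and effective lengths are always computed
#' against unmasked sequence.
#'
#' @slot genes \code{GRanges} of CDS intervals; metadata columns
#'   \code{gene_id} (unique) and \code{annotation} (one of
#'   \code{"essential"}, \code{"nonessential"}, \code{"unknown"}).
#' @slot mask \code{GRanges} of disjoint masked intervals (union of
#'   repetitive and unmapped regions); strand-less.
#'
#' @seealso [genomeAnnotation()], [effectiveLength()]
#' @export
setClass("GenomeAnnotation",
  representation(genes = "GRanges", mask = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  g <- object@genes
  if (length(g)) {
    if (is.null(g$gene_id) || anyDuplicated(g$gene_id))
      msg <- c(msg, "genes need a unique 'gene_id' metadata column")
    if (is.null(g$annotation) ||
        !all(g$annotation %in% c("essential", "nonessential", "unknown")))
      msg <- c(msg,
        "gene 'annotation' must be essential/nonessential/unknown")
    sl <- seqlengths(g)
    if (!all(is.na(sl))) {
      bad <- end(g) > sl[as.character(seqnames(g))]
      if (any(bad, na.rm = TRUE))
        msg <- c(msg, "gene intervals beyond chromosome bounds")
    }
  }
  m <- object@mask
  if (length(m) && length(reduce(m, ignore.strand = TRUE)) != length(m))
    msg <- c(msg, "mask intervals must be disjoint and sorted")
  if (length(msg)) msg else TRUE
})

#' SNPMatrix: biallelic SNP calls across strains
#'
#' Complete (no missing calls) biallelic SNP genotypes, one row per site and
#' one column per strain, coded 0 = reference allele, 1 = alternative allele.
#'
#' @slot sites data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}; one row per SNP.
#' @slot calls integer matrix (sites x strains) of 0/1 allele calls; column
#'   names are strain identifiers.
#'
#' @seealso [simulateSnps()], [readSnpTsv()], [matchedSnpControl()]
#' @export
setClass("SNPMatrix",
  representation(sites = "data.frame", calls = "matrix"))

setValidity("SNPMatrix", function(object) {
  msg <- character()
  if (nrow(object@sites) != nrow(object@calls))
    msg <- c(msg, "'sites' and 'calls' must have the same number of rows")
  if (!all(c("chrom", "pos", "ref", "alt") %in% colnames(object@sites)))
    msg <- c(msg, "'sites' needs columns chrom, pos, ref, alt")
  cl <- object@calls
  if (length(cl)) {
    if (any(is.na(cl)))
      msg <- c(msg, "missing genotype calls are not allowed")
    else if (!all(cl %in% c(0L, 1L)))
      msg <- c(msg, "calls must be 0/1 (biallelic)")
    if (is.null(colnames(cl)))
      msg <- c(msg, "'calls' needs strain column names")
  }
  if (length(msg)) msg else TRUE
})

#' EssentialityMatrix: genes x strains essentiality calls
#'
#' Cross-strain gene essentiality calls, entries one of \code{"E"}
#' (essential), \code{"NE"} (nonessential) or \code{"U"} (undetermined), with
#' the classifier probability that produced each call kept alongside.
#'
#' @slot calls character matrix (genes x strains) with entries E/NE/U;
#'   dimnames are gene and strain identifiers.
#' @slot probs numeric matrix of the same shape: random-forest essentiality
#'   probabilities (NA where no prediction was attempted).
#'
#' @seealso [buildEssentialityMatrix()], [polymorphicGenes()],
#'   [imputeAndCount()]
#' @export
setClass("EssentialityMatrix",
  representation(calls = "matrix", probs = "matrix"))

setValidity("EssentialityMatrix", function(object) {
  msg <- character()
  cl <- object@calls
  if (!all(cl %in% c("E", "NE", "U")))
    msg <- c(msg, "calls must be one of E, NE, U")
  if (is.null(rownames(cl)) || is.null(colnames(cl)))
    msg <- c(msg, "calls need gene rownames and strain colnames")
  if (!identical(dim(cl), dim(object@probs)))
    msg <- c(msg, "'probs' must have the same shape as 'calls'")
  if (length(msg)) msg else TRUE
})

#' CalibrationResult: threshold calibration of the classifier
#'
#' Result of the 20-bin calibration of random-forest outputs against
#' annotated essentiality: per-bin fraction of essential genes (f_ES), the
#' fitted polynomial, the strict and relaxed probability thresholds obtained
#' by solving the fitted curve at the f_ES targets, and the false discovery
#' rates realized at the strict thresholds on the held-out test set.
#'
#' @slot bins data.frame with one row per output bin: \code{lower},
#'   \code{upper}, \code{mid}, \code{n}, \code{f_es}.
#' @slot coeffs numeric polynomial coefficients (intercept first).
#' @slot thresholds named numeric: \code{t_ess}, \code{t_noness},
#'   \code{t_ess75}, \code{t_noness25}.
#' @slot fdr named numeric: \code{fdr_ess}, \code{fdr_noness} and the relaxed
#'   \code{fdr_ess75}, \code{fdr_noness25}.
#' @slot targets named numeric f_ES targets used.
#'
#' @seealso [calibrateClassifier()], [classifyStrain()]
#' @export
setClass("CalibrationResult",
  representation(bins = "data.frame", coeffs = "numeric",
                 thresholds = "numeric", fdr = "numeric",
                 targets = "numeric"))

setValidity("CalibrationResult", function(object) {
  msg <- character()
  th <- object@thresholds
  need <- c("t_ess", "t_noness", "t_ess75", "t_noness25")
  if (!all(need %in% names(th)))
    msg <- c(msg, "thresholds must be named t_ess/t_noness/t_ess75/t_noness25")
  else {
    if (!is.na(th["t_ess"]) && !is.na(th["t_noness"]) &&
        th["t_noness"] >= th["t_ess"])
      msg <- c(msg, "t_noness must be < t_ess")
    if (!is.na(th["t_ess75"]) && !is.na(th["t_ess"]) &&
        th["t_ess75"] > th["t_ess"])
      msg <- c(msg, "t_ess75 must be <= t_ess")
    if (!is.na(th["t_noness25"]) && !is.na(th["t_noness"]) &&
        th["t_noness25"] < th["t_noness"])
      msg <- c(msg, "t_noness25 must be >= t_noness")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn InsertionMap-class display a short summary
#' @param object an \code{InsertionMap}
#' @export
setMethod("show", "InsertionMap", function(object) {
  s <- object@sites
  cat("InsertionMap for strain", object@strain, "\n")
  cat(" ", length(s), "insertion sites on",
      length(unique(as.character(seqnames(s)))), "chromosome(s);",
      if (length(s)) sum(s$reads) else 0L, "reads\n")
})

#' @describeIn GenomeAnnotation-class display a short summary
#' @param object a \code{GenomeAnnotation}
#' @export
setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", length(object@genes), "genes,",
      length(object@mask), "masked interval(s),",
      sum(!is.na(seqlengths(object@genes))), "chromosome(s)\n")
  ann <- table(object@genes$annotation)
  if (length(ann))
    cat("  annotation:", paste(names(ann), ann, sep = "=", collapse = ", "),
        "\n")
})

#' @describeIn SNPMatrix-class display a short summary
#' @param object a \code{SNPMatrix}
#' @export
setMethod("show", "SNPMatrix", function(object) {
  cat("SNPMatrix:", nrow(object@calls), "biallelic sites x",
      ncol(object@calls), "strains\n")
})

#' @describeIn EssentialityMatrix-class display a short summary
#' @param object an \code{EssentialityMatrix}
#' @export
setMethod("show", "EssentialityMatrix", function(object) {
  cl <- object@calls
  cat("EssentialityMatrix:", nrow(cl), "genes x", ncol(cl), "strains\n")
  cat("  calls: E=", sum(cl == "E"), " NE=", sum(cl == "NE"),
      " U=", sum(cl == "U"), "\n", sep = "")
  cat(" ", length(polymorphicGenes(object)), "polymorphic gene(s)\n")
})

#' @describeIn CalibrationResult-class display thresholds
#' @param object a \code{CalibrationResult}
#' @export
setMethod("show", "CalibrationResult", function(object) {
  th <- object@thresholds
  cat("CalibrationResult (20-bin polynomial calibration)\n")
  cat(sprintf("  strict : t_ess=%.4f t_noness=%.4f\n",
              th["t_ess"], th["t_noness"]))
  cat(sprintf("  relaxed: t_ess75=%.4f t_noness25=%.4f\n",
              th["t_ess75"], th["t_noness25"]))
  cat(sprintf("  FDR at strict thresholds: essential=%.4f nonessential=%.4f\n",
              object@fdr["fdr_ess"], object@fdr["fdr_noness"]))
})
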