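#' @importFrom rtracklayer import export
#' @importFrom utils read.table write.table
NULL

.ioStop <- function(file, what, e) {
  stop(sprintf("failed to parse %s (%s): %s", file, what,
               conditionMessage(e)), call. = FALSE)
}

#' Read / write insertion maps as BED
#'
#' On disk an insertion map is BED5: chrom, 0-based start, end, name, score
#' (= read count), strand. Coordinates are converted to the internal 1-based
#' representation on read and back on write (round-trip identity).
#'
#' @param file path to a BED file.
#' @param strain strain identifier to attach to the map.
#' @param chromLengths optional named vector of chromosome lengths.
#' @param collapse if TRUE, reads mapped within 2 nt on the same strand are
#'   collapsed into single insertion sites via [collapseReads()].
#' @return [readInsertionBed()]: an \linkS4class{InsertionMap};
#'   [writeInsertionBed()]: the file path, invisibly.
#' @seealso [collapseReads()]
#' @export
readInsertionBed <- function(file, strain, chromLengths = NULL,
                             collapse = FALSE) {
  gr <- tryCatch(import(file, format = "BED"),
                 error = function(e) .ioStop(file, "BED insertions", e))
  if (is.null(gr$score) || any(is.na(gr$score)))
    stop("insertion BED needs a numeric score column holding read counts")
  gr$reads <- as.integer(gr$score)
  gr$score <- NULL
  gr$name <- NULL
  message(sprintf("[satayEvol] %s: %d insertion records", file, length(gr)))
  if (collapse)
    return(collapseReads(gr, strain = strain, chromLengths = chromLengths))
  InsertionMap(strain, gr, chromLengths = chromLengths)
}

#' @param map an \linkS4class{InsertionMap}.
#' @rdname readInsertionBed
#' @export
writeInsertionBed <- function(map, file) {
  gr <- insertionSites(map)
  gr$score <- gr$reads
  gr$reads <- NULL
  export(gr, file, format = "BED")
  invisible(file)
}

#' Read / write gene annotations as GFF3
#'
#' Gene models are stored as GFF3 CDS-style records with attributes
#' \code{ID} (gene identifier) and \code{annotation} (deletion-based
#' essentiality: essential/nonessential/unknown). GFF 1-based closed
#' coordinates match the internal representation.
#'
#' @param file path to a GFF3 file.
#' @param maskFile optional BED file of repetitive/unmapped regions.
#' @param chromLengths optional named vector of chromosome lengths.
#' @return [readGenesGff()]: a \linkS4class{GenomeAnnotation};
#'   [writeGenesGff()]: the file path(s), invisibly.
#' @export
readGenesGff <- function(file, maskFile = NULL, chromLengths = NULL) {
  gr <- tryCatch(import(file, format = "GFF3"),
                 error = function(e) .ioStop(file, "GFF3 genes", e))
  gene_id <- if (!is.null(gr$ID)) gr$ID else gr$Name
  if (is.null(gene_id))
    stop("gene GFF3 needs ID (or Name) attributes")
  ann <- if (!is.null(gr$annotation)) as.character(gr$annotation)
         else rep("unknown", length(gr))
  ann[is.na(ann)] <- "unknown"
  genes <- GRanges(as.character(seqnames(gr)),
                   IRanges(start(gr), end(gr)), strand = strand(gr),
                   gene_id = as.character(gene_id), annotation = ann)
  mask <- NULL
  if (!is.null(maskFile)) {
    mask <- tryCatch(import(maskFile, format = "BED"),
                     error = function(e) .ioStop(maskFile, "BED mask", e))
    message(sprintf("[satayEvol] %s: %d mask intervals", maskFile,
                    length(mask)))
  }
  message(sprintf("[satayEvol] %s: %d gene records", file, length(genes)))
  genomeAnnotation(genes, mask = mask, chromLengths = chromLengths)
}

#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param maskOut optional path for the mask BED.
#' @rdname readGenesGff
#' @export
writeGenesGff <- function(ann, file, maskOut = NULL) {
  g <- annotatedGenes(ann)
  out <- g
  out$ID <- g$gene_id
  out$type <- "CDS"
  out$source <- "satayEvol"
  out$phase <- 0L
  export(out, file, format = "GFF3")
  if (!is.null(maskOut))
    export(regionMask(ann), maskOut, format = "BED")
  invisible(c(file, maskOut))
}

#' Read / write a strain phylogeny (newick)
#'
#' Thin wrappers over \pkg{ape} that additionally reject duplicated tip
#' labels and verify the tree is rooted with non-negative branch lengths.
#'
#' @param file path to a newick file.
#' @return [readStrainTree()]: an \code{ape::phylo};
#'   [writeStrainTree()]: the file path, invisibly.
#' @export
readStrainTree <- function(file) {
  tr <- tryCatch(ape::read.tree(file),
                 error = function(e) .ioStop(file, "newick tree", e))
  if (is.null(tr)) stop("no tree found in ", file)
  checkStrainTree(tr)
  message(sprintf("[satayEvol] %s: tree with %d tips", file,
                  length(tr$tip.label)))
  tr
}

#' @param tree an \code{ape::phylo}.
#' @rdname readStrainTree
#' @export
writeStrainTree <- function(tree, file) {
  ape::write.tree(tree, file)
  invisible(file)
}

#' Validate a strain phylogeny
#'
#' @param tree \code{ape::phylo}.
#' @param strains optional strain identifiers that must all be tree tips.
#' @return the tree, invisibly; errors on duplicated tips, missing strains,
#'   negative branch lengths or an unrooted tree.
#' @export
checkStrainTree <- function(tree, strains = NULL) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape::phylo")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths in tree")
  if (!ape::is.rooted(tree))
    stop("tree must be rooted")
  if (!is.null(strains)) {
    miss <- setdiff(strains, tree$tip.label)
    if (length(miss))
      stop("strains missing from tree: ", paste(miss, collapse = ", "))
  }
  invisible(tree)
}

#' Read / write SNP matrices as TSV
#'
#' The table holds one row per biallelic site: columns \code{chrom},
#' \code{pos} (1-based), \code{ref}, \code{alt}, then one 0/1 column per
#' strain. All calls must be present (the analysis keeps only sites that are
#' homozygous-called in every strain).
#'
#' @param file path to a TSV file.
#' @return [readSnpTsv()]: a \linkS4class{SNPMatrix};
#'   [writeSnpTsv()]: the file path, invisibly.
#' @export
readSnpTsv <- function(file) {
  df <- tryCatch(
    read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) .ioStop(file, "SNP TSV", e))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% colnames(df)))
    stop("SNP TSV needs columns chrom, pos, ref, alt + strain columns")
  strains <- setdiff(colnames(df), need)
  if (!length(strains)) stop("SNP TSV has no strain columns")
  calls <- as.matrix(df[, strains, drop = FALSE])
  if (any(is.na(calls)))
    stop(sprintf("missing SNP calls at line(s) %s of %s",
                 paste(utils::head(which(rowSums(is.na(calls)) > 0) + 1L, 5),
                       collapse = ","), file))
  message(sprintf("[satayEvol] %s: %d SNP sites x %d strains", file,
                  nrow(calls), length(strains)))
  snpMatrix(df[, need], calls)
}

#' @param snps a \linkS4class{SNPMatrix}.
#' @rdname readSnpTsv
#' @export
writeSnpTsv <- function(snps, file) {
  df <- cbind(snpSites(snps), as.data.frame(snpCalls(snps)))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
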