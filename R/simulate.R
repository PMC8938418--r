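#' Configuration of the synthetic SATAY generator
#'
#' Bundles every knob of the synthetic-data generator with defaults that
#' emulate a saturated 16-strain transposon mutagenesis study at desk scale:
#' a two-chromosome genome of 500 genes (~1.2 Mnt), insertion density one
#' transposition per 35 nt, strong among-gene variation of the essentiality
#' switch rate (gamma shape 0.113), a nonessential fraction of essential-gene
#' insertions concentrated in a 3' tolerant tail, one chromosome-gain
#' aneuploidy, and a neutral SNP matrix evolving on the same tree.
#'
#' Rates of the switch process are expressed per unit of total tree length
#' (the tree is rescaled internally so its branch lengths sum to 1), i.e.
#' \code{meanSwitches} is the expected number of essentiality switches per
#' gene across the whole phylogeny.
#'
#' @param nStrains number of strains / tree tips (default 16).
#' @param nGenes number of genes (default 500).
#' @param nChroms chromosomes the genes are spread over (default 2).
#' @param geneLengthMeanlog,geneLengthSdlog lognormal CDS length parameters
#'   (defaults log(1400) and 0.35 nt).
#' @param minGeneLength lower truncation of CDS length (default 350 nt).
#' @param intergenicMean mean intergenic gap (exponential, default 800 nt).
#' @param tree optional fixed \code{ape::phylo} or newick string; default a
#'   random coalescent tree.
#' @param lambda insertion density per unmasked nucleotide (default 1/35).
#' @param essentialLeak mean number of background ("leak") insertions per
#'   essential gene outside its tolerant tail (default 1.5).
#' @param tailProb probability that an essential gene carries a 3' tolerant
#'   tail (default 0.6); fixed per gene across strains.
#' @param tailWidth tail width as a fraction of the CDS (default 0.1).
#' @param readMean mean reads per insertion (1 + geometric; default 20).
#' @param rootEssentialFraction fraction of genes essential at the root
#'   (default 0.2).
#' @param alphaSim gamma shape of among-gene switch-rate variation
#'   (default 0.113).
#' @param meanSwitches mean of the gamma rate distribution: expected
#'   switches per gene over the tree (default 0.17, giving roughly 10%
#'   polymorphic genes).
#' @param modules list of coupled gene modules, each
#'   \code{list(size=, rho=, rate=)}: \code{size} genes share one switch
#'   event stream at rate \code{rate}, each event adopted by each member
#'   with probability \code{rho} (plus private events at rate
#'   \code{(1-rho)*rate}, so the marginal rate is \code{rate}). Default:
#'   three modules of 30/12/8 genes, rho 0.9, rate 1.5.
#' @param aneuploidy data.frame(strain, chrom) of chromosome-gain events
#'   (default: strain S02 gains chr2). Doubles insertion density and lifts
#'   essential-gene depletion on that chromosome.
#' @param nMaskIntervals,maskIntervalMean random repetitive/unmapped mask:
#'   number and mean width (exponential) of masked intervals (defaults 10
#'   and 1500 nt).
#' @param nSnps biallelic SNP sites simulated on the tree (default 2000).
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nStrains = 16L, nGenes = 500L, nChroms = 2L,
                             geneLengthMeanlog = log(1400),
                             geneLengthSdlog = 0.35,
                             minGeneLength = 350L,
                             intergenicMean = 800,
                             tree = NULL,
                             lambda = 1 / 35,
                             essentialLeak = 1.5,
                             tailProb = 0.6, tailWidth = 0.1,
                             readMean = 20,
                             rootEssentialFraction = 0.2,
                             alphaSim = 0.113, meanSwitches = 0.17,
                             modules = list(
                               list(size = 30L, rho = 0.9, rate = 1.5),
                               list(size = 12L, rho = 0.9, rate = 1.5),
                               list(size = 8L, rho = 0.9, rate = 1.5)),
                             aneuploidy = data.frame(strain = "S02",
                                                     chrom = "chr2"),
                             nMaskIntervals = 10L, maskIntervalMean = 1500,
                             nSnps = 2000L) {
  cfg <- list(nStrains = as.integer(nStrains), nGenes = as.integer(nGenes),
              nChroms = as.integer(nChroms),
              geneLengthMeanlog = geneLengthMeanlog,
              geneLengthSdlog = geneLengthSdlog,
              minGeneLength = as.integer(minGeneLength),
              intergenicMean = intergenicMean, tree = tree,
              lambda = lambda, essentialLeak = essentialLeak,
              tailProb = tailProb, tailWidth = tailWidth,
              readMean = readMean,
              rootEssentialFraction = rootEssentialFraction,
              alphaSim = alphaSim, meanSwitches = meanSwitches,
              modules = modules, aneuploidy = aneuploidy,
              nMaskIntervals = as.integer(nMaskIntervals),
              maskIntervalMean = maskIntervalMean,
              nSnps = as.integer(nSnps))
  with(cfg, {
    stopifnot(nStrains >= 2L, nGenes >= 1L, nChroms >= 1L,
              lambda >= 0, essentialLeak >= 0,
              tailProb >= 0, tailProb <= 1,
              tailWidth > 0, tailWidth <= 1,
              readMean >= 1, alphaSim > 0, meanSwitches >= 0,
              rootEssentialFraction >= 0, rootEssentialFraction <= 1)
    for (m in modules)
      stopifnot(m$size >= 2L, m$rho >= 0, m$rho <= 1, m$rate >= 0)
  })
  class(cfg) <- "SimulationConfig"
  cfg
}

# strain labels S01..Snn
.strainLabels <- function(n) sprintf("S%02d", seq_len(n))

.simTree <- function(config) {
  tr <- config$tree
  if (is.null(tr)) {
    tr <- ape::rcoal(config$nStrains, tip.label =
                       .strainLabels(config$nStrains))
  } else if (is.character(tr)) {
    tr <- ape::read.tree(text = tr)
  }
  checkStrainTree(tr)
  tr$edge.length <- tr$edge.length / sum(tr$edge.length)
  tr
}

# genome layout: genes with intergenic gaps, spread over chromosomes, plus a
# random mask
.simGenome <- function(config) {
  n <- config$nGenes
  lens <- pmax(config$minGeneLength,
               round(stats::rlnorm(n, config$geneLengthMeanlog,
                                   config$geneLengthSdlog)))
  gaps <- pmax(100L, round(rexp(n, 1 / config$intergenicMean)))
  chrom <- sort(rep_len(seq_len(config$nChroms), n))
  starts <- integer(n); ends <- integer(n)
  chromLen <- integer(config$nChroms)
  for (c in seq_len(config$nChroms)) {
    idx <- which(chrom == c)
    pos <- 1L
    for (i in idx) {
      pos <- pos + gaps[i]
      starts[i] <- pos
      ends[i] <- pos + lens[i] - 1L
      pos <- ends[i] + 1L
    }
    chromLen[c] <- pos + 500L   # trailing intergenic stub
  }
  chromNames <- paste0("chr", seq_len(config$nChroms))
  sl <- setNames(chromLen, chromNames)
  genes <- GRanges(chromNames[chrom], IRanges(starts, ends),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   gene_id = sprintf("g%04d", seq_len(n)),
                   annotation = "unknown")
  mask <- GRanges()
  if (config$nMaskIntervals > 0L) {
    mc <- sample(seq_len(config$nChroms), config$nMaskIntervals,
                 replace = TRUE)
    mw <- pmax(50L, round(rexp(config$nMaskIntervals,
                               1 / config$maskIntervalMean)))
    ms <- vapply(seq_len(config$nMaskIntervals), function(i)
      sample.int(max(chromLen[mc[i]] - mw[i], 1L), 1L), integer(1))
    mask <- reduce(GRanges(chromNames[mc], IRanges(ms, ms + mw - 1L)),
                   ignore.strand = TRUE)
  }
  genomeAnnotation(genes, mask = mask, chromLengths = sl)
}

#' Simulate essentiality histories on a tree
#'
#' Every gene gets a switch rate: module members share a module rate and a
#' common event stream (coupling \code{rho}); other genes draw their rate
#' from a gamma distribution with shape \code{alphaSim} and mean
#' \code{meanSwitches}. Binary essentiality evolves by a two-state flip
#' process: events arrive along each branch as a Poisson process, and every
#' event flips the gene's state. The true change count of a gene is its
#' total number of events on the tree.
#'
#' @param tree rooted strain phylogeny (branch lengths rescaled to sum 1).
#' @param config a [simulationConfig()].
#' @param seed optional RNG seed.
#' @return list: \code{states} (character E/NE matrix genes x strains),
#'   \code{changeCounts} (true events per gene), \code{rates},
#'   \code{modules} (data.frame gene_id, module), \code{rootStates}.
#' @export
simulateHistory <- function(tree, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$nGenes
  ids <- sprintf("g%04d", seq_len(n))
  rates <- if (config$meanSwitches > 0)
    rgamma(n, shape = config$alphaSim,
           rate = config$alphaSim / config$meanSwitches)
    else rep(0, n)
  names(rates) <- ids

  moduleOf <- rep(NA_integer_, n)
  pool <- seq_len(n)
  for (mi in seq_along(config$modules)) {
    m <- config$modules[[mi]]
    take <- sample(pool, min(m$size, length(pool)))
    moduleOf[take] <- mi
    rates[take] <- m$rate
    pool <- setdiff(pool, take)
  }

  edge <- tree$edge
  elen <- tree$edge.length
  nTip <- length(tree$tip.label)
  nEdge <- nrow(edge)

  # per-gene per-edge event counts
  events <- matrix(0L, nrow = n, ncol = nEdge)
  solo <- which(is.na(moduleOf))
  if (length(solo))
    events[solo, ] <- matrix(
      rpois(length(solo) * nEdge, outer(rates[solo], elen)),
      nrow = length(solo))
  for (mi in seq_along(config$modules)) {
    m <- config$modules[[mi]]
    members <- which(moduleOf == mi)
    if (!length(members)) next
    shared <- rpois(nEdge, m$rho * m$rate * elen)
    for (g in members) {
      adopt <- rbinom(nEdge, shared, prob = 1)  # shared events adopted
      priv <- rpois(nEdge, (1 - m$rho) * m$rate * elen)
      events[g, ] <- adopt + priv
    }
  }

  rootState <- as.integer(runif(n) < config$rootEssentialFraction)
  # module members share one root state: coupled switching is concordant in
  # direction (a complex that becomes essential does so for all members)
  for (mi in seq_along(config$modules)) {
    members <- which(moduleOf == mi)
    if (length(members))
      rootState[members] <- as.integer(
        runif(1) < config$rootEssentialFraction)
  }
  # propagate parity from root to tips (preorder over edges)
  ord <- ape::reorder.phylo(tree, "postorder")
  preorder <- rev(seq_len(nEdge))
  edgeIdx <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                   paste(edge[, 1], edge[, 2]))
  nodeState <- matrix(0L, nrow = n, ncol = nTip + tree$Nnode)
  root <- ord$edge[nrow(ord$edge), 1L]
  nodeState[, root] <- rootState
  for (k in preorder) {
    p <- ord$edge[k, 1L]; ch <- ord$edge[k, 2L]
    e <- edgeIdx[k]
    nodeState[, ch] <- (nodeState[, p] + events[, e]) %% 2L
  }
  states <- nodeState[, seq_len(nTip), drop = FALSE]
  states <- ifelse(states == 1L, "E", "NE")
  dimnames(states) <- list(ids, tree$tip.label)
  list(states = states,
       changeCounts = setNames(as.integer(rowSums(events)), ids),
       rates = rates,
       modules = data.frame(gene_id = ids, module = moduleOf,
                            stringsAsFactors = FALSE),
       rootStates = setNames(rootState, ids))
}

#' Simulate per-strain insertion maps
#'
#' Nonessential CDS and noncoding sequence receive insertions as a Poisson
#' process at density \code{lambda} per unmasked nucleotide. Essential CDS
#' receive only leak insertions (Poisson with mean \code{essentialLeak})
#' plus, for genes carrying a 3' tolerant tail, full-density insertions
#' confined to the tail. On aneuploid (strain, chromosome) pairs the density
#' doubles and essential depletion is lifted (the extra chromosome copy
#' buffers disruption). Reads per insertion are 1 + geometric with mean
#' \code{readMean}.
#'
#' @param states E/NE character matrix (genes x strains) from
#'   [simulateHistory()].
#' @param ann the simulated \linkS4class{GenomeAnnotation}.
#' @param config a [simulationConfig()].
#' @param tailTolerant named logical: which essential genes have a 3' tail.
#' @param seed optional RNG seed.
#' @return named list of \linkS4class{InsertionMap}, one per strain.
#' @export
simulateInsertions <- function(states, ann, config, tailTolerant,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- annotatedGenes(ann)
  mask <- regionMask(ann)
  sl <- chromLengths(ann)
  ids <- genes$gene_id
  minus <- as.character(strand(genes)) == "-"

  geneChrom <- as.character(seqnames(genes))
  # boolean masked / coding vectors per chromosome make pool extraction O(1)
  maskedV <- lapply(names(sl), function(ch) {
    v <- logical(sl[[ch]])
    mm <- mask[as.character(seqnames(mask)) == ch]
    for (k in seq_along(mm)) v[start(mm)[k]:end(mm)[k]] <- TRUE
    v
  })
  names(maskedV) <- names(sl)
  codingV <- lapply(names(sl), function(ch) logical(sl[[ch]]))
  names(codingV) <- names(sl)
  for (i in seq_along(genes))
    codingV[[geneChrom[i]]][start(genes)[i]:end(genes)[i]] <- TRUE

  cdsPos <- lapply(seq_along(genes), function(i) {
    p <- start(genes)[i]:end(genes)[i]
    p[!maskedV[[geneChrom[i]]][p]]
  })
  tailPos <- lapply(seq_along(genes), function(i) {
    L <- width(genes)[i]
    tw <- max(1L, round(L * config$tailWidth))
    p <- if (minus[i]) start(genes)[i]:(start(genes)[i] + tw - 1L)
         else (end(genes)[i] - tw + 1L):end(genes)[i]
    p[!maskedV[[geneChrom[i]]][p]]
  })
  ncByChrom <- lapply(names(sl), function(ch)
    which(!codingV[[ch]] & !maskedV[[ch]]))
  names(ncByChrom) <- names(sl)

  aneu <- config$aneuploidy
  isAneu <- function(st, ch)
    !is.null(aneu) && nrow(aneu) > 0 &&
      any(aneu$strain == st & aneu$chrom == ch)

  strains <- colnames(states)
  maps <- vector("list", length(strains))
  names(maps) <- strains
  for (st in strains) {
    chromAcc <- character(0)
    posAcc <- integer(0)
    draw <- function(pool, k, chrom) {
      k <- min(k, length(pool))
      if (k > 0L) {
        posAcc <<- c(posAcc, sample(pool, k))
        chromAcc <<- c(chromAcc, rep(chrom, k))
      }
    }
    for (i in seq_along(genes)) {
      pool <- cdsPos[[i]]
      if (!length(pool)) next
      ch <- geneChrom[i]
      lam2 <- config$lambda * (1 + isAneu(st, ch))
      if (states[ids[i], st] == "NE" || isAneu(st, ch)) {
        draw(pool, rpois(1, lam2 * length(pool)), ch)
      } else {
        draw(pool, rpois(1, config$essentialLeak), ch)
        if (isTRUE(tailTolerant[ids[i]]) && length(tailPos[[i]]))
          draw(tailPos[[i]],
               rpois(1, config$lambda * length(tailPos[[i]])), ch)
      }
    }
    for (ch in names(sl)) {
      pool <- ncByChrom[[ch]]
      if (!length(pool)) next
      lam2 <- config$lambda * (1 + isAneu(st, ch))
      draw(pool, rpois(1, lam2 * length(pool)), ch)
    }
    if (!length(posAcc)) {
      maps[[st]] <- InsertionMap(st, GRanges(seqinfo = Seqinfo(
        names(sl), as.integer(sl))))
      next
    }
    strandAcc <- sample(c("+", "-"), length(posAcc), replace = TRUE)
    reads <- 1L + rgeom(length(posAcc),
                        prob = 1 / max(config$readMean, 1))
    df <- data.frame(chrom = chromAcc, pos = posAcc, strand = strandAcc,
                     reads = reads, stringsAsFactors = FALSE)
    # merge exact duplicates (same position and strand), summing reads
    key <- paste(df$chrom, df$pos, df$strand)
    if (anyDuplicated(key)) {
      reads <- tapply(df$reads, key, sum)
      df <- df[!duplicated(key), , drop = FALSE]
      df$reads <- as.integer(reads[paste(df$chrom, df$pos, df$strand)])
    }
    maps[[st]] <- InsertionMap(st, df, chromLengths = sl)
  }
  maps
}

#' Simulate a neutral biallelic SNP matrix on a tree
#'
#' Infinite-sites-like placement: each site mutates exactly once, on a
#' branch chosen with probability proportional to branch length; all tips
#' below that branch carry the derived allele. Every site is therefore
#' segregating and biallelic. A fraction \code{scatterProb} of sites are
#' tree-discordant instead: they carry two mutations (two branches drawn
#' branch-proportionally; carriers are the symmetric difference of the two
#' clades), emulating recurrent mutation and introgression-shuffled sites.
#' Two-mutation sites populate folded frequency classes that no single
#' clade size can produce — pure infinite-sites placement would leave those
#' classes empty — while keeping parsimony change counts realistic (at most
#' two). A target folded frequency spectrum (named vector
#' minority-count -> number of sites) can be requested; sites are then
#' drawn by rejection until each class quota is filled.
#'
#' @param tree rooted strain phylogeny with branch lengths.
#' @param nSites number of sites (ignored when \code{targetSpectrum} given).
#' @param seed optional RNG seed.
#' @param targetSpectrum optional named vector of folded minor-allele-count
#'   quotas.
#' @param scatterProb probability that a site is tree-discordant
#'   (default 0.1).
#' @return a \linkS4class{SNPMatrix}.
#' @export
simulateSnps <- function(tree, nSites, seed = NULL, targetSpectrum = NULL,
                         scatterProb = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  nTip <- length(tree$tip.label)
  edge <- tree$edge
  elen <- tree$edge.length
  # tip sets below each edge (by child node), via postorder accumulation
  ord <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", nTip + tree$Nnode)
  for (i in seq_len(nTip)) below[[i]] <- i
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]; ch <- ord$edge[k, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  edgeTips <- lapply(edge[, 2L], function(ch) below[[ch]])
  w <- elen / sum(elen)

  drawSite <- function() {
    v <- integer(nTip)
    if (runif(1) < scatterProb && nTip > 3L) {
      # two-mutation site; on tiny trees a segregating XOR pattern may not
      # exist, so fall back to a clade site after a few attempts
      for (try in 1:50) {
        e2 <- sample.int(nrow(edge), 2L, prob = w)
        v <- integer(nTip)
        v[edgeTips[[e2[1]]]] <- 1L
        v[edgeTips[[e2[2]]]] <- 1L - v[edgeTips[[e2[2]]]]
        k <- sum(v)
        if (k > 0L && k < nTip) return(v)
      }
      v <- integer(nTip)
    }
    e <- sample.int(nrow(edge), 1L, prob = w)
    v[edgeTips[[e]]] <- 1L
    v
  }
  calls <- NULL
  if (is.null(targetSpectrum)) {
    calls <- if (nSites > 0)
      t(vapply(seq_len(nSites), function(i) drawSite(), integer(nTip)))
      else matrix(integer(0), 0, nTip)
  } else {
    quota <- targetSpectrum
    rows <- list()
    guard <- 0L
    while (sum(quota) > 0L) {
      guard <- guard + 1L
      if (guard > 1e6) stop("cannot fill the requested frequency spectrum")
      v <- drawSite()
      cl <- as.character(min(sum(v), nTip - sum(v)))
      if (!is.na(quota[cl]) && quota[cl] > 0L) {
        rows[[length(rows) + 1L]] <- v
        quota[cl] <- quota[cl] - 1L
      }
    }
    calls <- do.call(rbind, rows)
  }
  colnames(calls) <- tree$tip.label
  nr <- nrow(calls)
  sites <- data.frame(chrom = rep("chrS", nr), pos = seq_len(nr),
                      ref = rep("A", nr), alt = rep("G", nr),
                      stringsAsFactors = FALSE)
  snpMatrix(sites, calls)
}

#' Simulate a complete synthetic SATAY dataset
#'
#' Drives the whole generator under one master seed: strain tree, genome
#' layout (genes, intergenic spacers, mask), essentiality histories with
#' gamma rate variation and coupled modules, per-strain insertion maps with
#' essential-gene depletion, 3' tolerant tails and aneuploidy, and a neutral
#' SNP matrix. The reference strain's truth states become the annotation's
#' deletion-based labels (only the reference strain has such labels, as in a
#' real study); everything else the pipeline must infer.
#'
#' @param config a [simulationConfig()].
#' @param seed master RNG seed (full determinism).
#' @return list: \code{annotation} (\linkS4class{GenomeAnnotation}),
#'   \code{tree}, \code{maps} (named list of \linkS4class{InsertionMap}),
#'   \code{snps} (\linkS4class{SNPMatrix}), \code{referenceStrain},
#'   \code{truth} (list states, changeCounts, rates, modules, tailTolerant,
#'   aneuploidy — for evaluation only, never consumed by the pipeline),
#'   \code{config}.
#' @examples
#' sim <- simulateSatayDataset(simulationConfig(nGenes = 50, nStrains = 4,
#'                                              nSnps = 100), seed = 7)
#' sim$maps[["S01"]]
#' @export
simulateSatayDataset <- function(config = simulationConfig(), seed = 1L) {
  set.seed(seed)
  tree <- .simTree(config)
  ann <- .simGenome(config)
  hist <- simulateHistory(tree, config)
  ids <- annotatedGenes(ann)$gene_id
  tailTolerant <- setNames(runif(config$nGenes) < config$tailProb, ids)
  maps <- simulateInsertions(hist$states, ann, config, tailTolerant)
  snps <- simulateSnps(tree, config$nSnps)
  # the reference strain (whose deletion-based labels train the classifier)
  # must be euploid: aneuploidy would decouple its labels from its map
  aneuStrains <- if (!is.null(config$aneuploidy)) config$aneuploidy$strain
                 else character(0)
  ref <- setdiff(tree$tip.label, aneuStrains)[1]
  genes <- annotatedGenes(ann)
  genes$annotation <- unname(ifelse(hist$states[genes$gene_id, ref] == "E",
                                    "essential", "nonessential"))
  ann <- new("GenomeAnnotation", genes = genes, mask = regionMask(ann))
  list(annotation = ann, tree = tree, maps = maps, snps = snps,
       referenceStrain = ref,
       truth = list(states = hist$states,
                    changeCounts = hist$changeCounts,
                    rates = hist$rates, modules = hist$modules,
                    tailTolerant = tailTolerant,
                    aneuploidy = config$aneuploidy),
       config = config)
}

#' Write / read a simulated dataset as plain-text files
#'
#' Serializes a dataset to the package's on-disk formats (insertion BED per
#' strain, gene GFF3 + mask BED, newick tree, SNP TSV, truth TSVs) and reads
#' it back, so file-based runs and in-memory runs are interchangeable.
#'
#' @param sim list from [simulateSatayDataset()].
#' @param dir output directory (created).
#' @return [writeDataset()]: \code{dir} invisibly; [readDataset()]: a list
#'   shaped like [simulateSatayDataset()] output (without truth).
#' @export
writeDataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (st in names(sim$maps))
    writeInsertionBed(sim$maps[[st]],
                      file.path(dir, paste0("insertions_", st, ".bed")))
  writeGenesGff(sim$annotation, file.path(dir, "genes.gff3"),
                maskOut = file.path(dir, "mask.bed"))
  writeStrainTree(sim$tree, file.path(dir, "tree.nwk"))
  writeSnpTsv(sim$snps, file.path(dir, "snps.tsv"))
  sl <- chromLengths(sim$annotation)
  write.table(data.frame(chrom = names(sl), length = as.integer(sl)),
              file.path(dir, "chrom_lengths.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth)) {
    write.table(as.data.frame(sim$truth$states),
                file.path(dir, "truth_states.tsv"),
                sep = "\t", quote = FALSE)
    write.table(data.frame(gene_id = names(sim$truth$changeCounts),
                           changes = sim$truth$changeCounts),
                file.path(dir, "truth_changes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @param referenceStrain reference strain for [readDataset()]; default the
#'   first strain found.
#' @rdname writeDataset
#' @export
readDataset <- function(dir, referenceStrain = NULL) {
  cl <- read.table(file.path(dir, "chrom_lengths.tsv"), header = TRUE,
                   sep = "\t")
  sl <- setNames(cl$length, cl$chrom)
  ann <- readGenesGff(file.path(dir, "genes.gff3"),
                      maskFile = file.path(dir, "mask.bed"),
                      chromLengths = sl)
  tree <- readStrainTree(file.path(dir, "tree.nwk"))
  beds <- list.files(dir, pattern = "^insertions_.*\\.bed$",
                     full.names = TRUE)
  strains <- sub("^insertions_(.*)\\.bed$", "\\1", basename(beds))
  maps <- lapply(seq_along(beds), function(i)
    readInsertionBed(beds[i], strains[i], chromLengths = sl))
  names(maps) <- strains
  snps <- readSnpTsv(file.path(dir, "snps.tsv"))
  list(annotation = ann, tree = tree, maps = maps, snps = snps,
       referenceStrain = if (is.null(referenceStrain)) strains[1]
                         else referenceStrain)
}
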