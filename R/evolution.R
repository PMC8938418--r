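#' Assemble the cross-strain essentiality matrix
#'
#' Combines per-strain call tables into a genes x strains matrix, forcing
#' entries on aneuploid chromosomes (automatically flagged or manually
#' listed) to undetermined: a gained chromosome makes every essential gene on
#' it insertion-tolerant, so those calls say nothing about single-copy
#' essentiality.
#'
#' @param callList named list (one element per strain) of data.frames from
#'   [classifyStrain()] (columns gene_id, prob, call); all strains must
#'   share the same gene universe.
#' @param ann a \linkS4class{GenomeAnnotation} (maps genes to chromosomes
#'   for the aneuploidy masking).
#' @param aneuploid data.frame with columns \code{strain}, \code{chrom}
#'   (e.g. rows of [aneuploidyScan()] output); may be NULL.
#' @param manualMasks data.frame of conservative manual masks with columns
#'   \code{strain}, \code{chrom} and optionally \code{start}, \code{end}
#'   (1-based closed) for arm-level events; whole chromosome when the
#'   interval columns are absent or NA.
#' @param tree optional strain phylogeny; when given, every strain must be a
#'   tip.
#' @return an \linkS4class{EssentialityMatrix}.
#' @export
buildEssentialityMatrix <- function(callList, ann, aneuploid = NULL,
                                    manualMasks = NULL, tree = NULL) {
  strains <- names(callList)
  if (is.null(strains)) stop("'callList' must be named by strain")
  if (!is.null(tree)) checkStrainTree(tree, strains)
  geneIds <- callList[[1]]$gene_id
  for (st in strains)
    if (!identical(callList[[st]]$gene_id, geneIds))
      stop("strain ", st, " has a different gene universe")
  calls <- vapply(callList, function(df) df$call, character(length(geneIds)))
  probs <- vapply(callList, function(df) df$prob, numeric(length(geneIds)))
  dimnames(calls) <- dimnames(probs) <- list(geneIds, strains)

  genes <- annotatedGenes(ann)
  geneChrom <- setNames(as.character(seqnames(genes)), genes$gene_id)
  flag <- function(strain, chrom, s = NA, e = NA) {
    if (!strain %in% strains) return(invisible(NULL))
    if (is.na(s) || is.na(e)) {
      hit <- geneIds[geneChrom[geneIds] == chrom]
    } else {
      iv <- GRanges(chrom, IRanges(s, e))
      hit <- genes$gene_id[overlapsAny(genes, iv, ignore.strand = TRUE)]
      hit <- intersect(hit, geneIds)
    }
    calls[hit, strain] <<- "U"
  }
  if (!is.null(aneuploid) && nrow(aneuploid))
    for (i in seq_len(nrow(aneuploid)))
      flag(aneuploid$strain[i], aneuploid$chrom[i])
  if (!is.null(manualMasks) && nrow(manualMasks)) {
    hasIv <- all(c("start", "end") %in% colnames(manualMasks))
    for (i in seq_len(nrow(manualMasks)))
      flag(manualMasks$strain[i], manualMasks$chrom[i],
           if (hasIv) manualMasks$start[i] else NA,
           if (hasIv) manualMasks$end[i] else NA)
  }
  new("EssentialityMatrix", calls = calls, probs = probs)
}

#' Polymorphic genes and determined-strain counts
#'
#' A gene is polymorphic when, among its determined entries (at least two
#' strains with a call), it is essential in at least one strain and
#' nonessential in at least one other.
#'
#' @param emat an \linkS4class{EssentialityMatrix} or a character call
#'   matrix with entries E/NE/U.
#' @return [polymorphicGenes()]: character vector of gene ids;
#'   [determinedCounts()]: named integer vector of determined strains per
#'   gene.
#' @export
polymorphicGenes <- function(emat) {
  calls <- if (is(emat, "EssentialityMatrix")) essCalls(emat) else emat
  nE <- rowSums(calls == "E")
  nN <- rowSums(calls == "NE")
  rownames(calls)[nE >= 1 & nN >= 1 & (nE + nN) >= 2]
}

#' @rdname polymorphicGenes
#' @export
determinedCounts <- function(emat) {
  calls <- if (is(emat, "EssentialityMatrix")) essCalls(emat) else emat
  setNames(as.integer(rowSums(calls != "U")), rownames(calls))
}

# --- two-state unit-cost Sankoff parsimony -------------------------------

# x: vector in {0,1,NA} aligned with tree$tip.label. Returns minimum number
# of state changes and tip/internal states from one minimum-cost labeling
# (ties broken toward state 0 at the root, toward the parent state below it,
# which resolves undetermined tips to their nearest determined neighborhood).
.sankoff <- function(tree, x) {
  nTip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  nNode <- nTip + tree$Nnode
  cost <- matrix(0, nrow = 2L, ncol = nNode)    # rows: state 0, state 1
  det <- !is.na(x)
  cost[1L, which(det & x == 1)] <- Inf
  cost[2L, which(det & x == 0)] <- Inf
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    c0 <- min(cost[1L, ch], cost[2L, ch] + 1)
    c1 <- min(cost[2L, ch], cost[1L, ch] + 1)
    cost[1L, p] <- cost[1L, p] + c0
    cost[2L, p] <- cost[2L, p] + c1
  }
  root <- edge[nrow(edge), 1L]
  total <- min(cost[, root])
  state <- integer(nNode)
  state[root] <- if (cost[1L, root] <= cost[2L, root]) 0L else 1L
  for (k in rev(seq_len(nrow(edge)))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    ps <- state[p]
    same <- cost[ps + 1L, ch]
    diff <- cost[2L - ps, ch] + 1
    state[ch] <- if (same <= diff) ps else 1L - ps
  }
  list(cost = total, tipStates = state[seq_len(nTip)],
       nodeStates = state[(nTip + 1L):nNode])
}

# brute-force oracle: minimize changes over all internal labelings (and all
# states of undetermined tips); exponential, only for small trees
.bruteParsimony <- function(tree, x) {
  nTip <- length(tree$tip.label)
  edge <- tree$edge
  freeTips <- which(is.na(x))
  nInt <- tree$Nnode
  best <- Inf
  intIds <- nTip + seq_len(nInt)
  for (a in seq_len(2^length(freeTips)) - 1L) {
    xt <- x
    if (length(freeTips))
      xt[freeTips] <- as.integer(intToBits(a))[seq_along(freeTips)]
    for (b in seq_len(2^nInt) - 1L) {
      st <- c(xt, as.integer(intToBits(b))[seq_len(nInt)])
      cost <- sum(st[edge[, 1L]] != st[edge[, 2L]])
      if (cost < best) best <- cost
    }
  }
  best
}

#' Impute undetermined states and count essentiality changes by parsimony
#'
#' For every gene with at least two determined strains, undetermined tips
#' are imputed by maximum parsimony and the minimum number of essentiality
#' changes along the rooted strain phylogeny is counted (two-state
#' unit-cost Sankoff dynamic programming). Imputation ties are resolved
#' toward the nonessential state at the root and toward the parent's state
#' below it. Genes with fewer than two determined strains are skipped and
#' listed.
#'
#' @param emat an \linkS4class{EssentialityMatrix} (or E/NE/U character
#'   matrix with gene rownames and strain colnames).
#' @param tree rooted strain phylogeny; tips must cover the strains.
#' @return list: \code{counts} (named integer, changes per analyzed gene),
#'   \code{imputed} (character matrix, U entries filled with the imputed
#'   E/NE), \code{skipped} (gene ids with < 2 determined strains).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' m <- rbind(g1 = c("E", "E", "NE", "NE"), g2 = c("E", "NE", "E", "NE"))
#' colnames(m) <- c("A", "B", "C", "D")
#' imputeAndCount(m, tr)$counts   # g1 = 1, g2 = 2
#' @export
imputeAndCount <- function(emat, tree) {
  calls <- if (is(emat, "EssentialityMatrix")) essCalls(emat) else emat
  checkStrainTree(tree, colnames(calls))
  ord <- match(tree$tip.label, colnames(calls))
  counts <- setNames(rep(NA_integer_, nrow(calls)), rownames(calls))
  imputed <- calls
  skipped <- character(0)
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ord]
    x <- ifelse(v == "E", 1L, ifelse(v == "NE", 0L, NA_integer_))
    if (sum(!is.na(x)) < 2L) {
      skipped <- c(skipped, rownames(calls)[i])
      next
    }
    res <- .sankoff(tree, x)
    counts[i] <- res$cost
    imp <- ifelse(res$tipStates == 1L, "E", "NE")
    imputed[i, colnames(calls)[ord]] <- imp
  }
  if (length(skipped))
    message(sprintf("[satayEvol] %d gene(s) skipped (<2 determined strains)",
                    length(skipped)))
  list(counts = counts[!is.na(counts)],
       imputed = imputed[!rownames(imputed) %in% skipped, , drop = FALSE],
       skipped = skipped)
}

#' Star-phylogeny change counts
#'
#' With every strain attached directly to the root, the minimum number of
#' state changes for a gene is simply the count of its minority state among
#' determined (or imputed) strains.
#'
#' @param states character matrix of E/NE (optionally U, which is ignored).
#' @return named integer vector of per-gene star change counts.
#' @export
starChangeCounts <- function(states) {
  nE <- rowSums(states == "E")
  nN <- rowSums(states == "NE")
  setNames(as.integer(pmin(nE, nN)), rownames(states))
}

#' Poisson overdispersion test of per-gene change counts
#'
#' Under a homogeneous rate of essentiality switching, per-gene change
#' counts are Poisson, so the variance equals the mean. The dispersion
#' statistic D = (n-1) * v / m is compared against a chi-squared
#' distribution with n-1 degrees of freedom (upper tail): large D means the
#' counts vary among genes more than a single rate allows.
#'
#' @param counts non-negative integer change counts (one per gene).
#' @param star flag recorded in the result when counts came from the
#'   star-phylogeny variant.
#' @return list: \code{mean}, \code{variance}, \code{D}, \code{df},
#'   \code{p.value} (one-tailed), \code{n}, \code{star}.
#' @examples
#' overdispersionTest(c(0, 0, 0, 4))  # D = 12, df = 3, p ~ 0.0074
#' @export
overdispersionTest <- function(counts, star = FALSE) {
  if (length(counts) < 2L) stop("need at least two genes")
  if (any(counts < 0)) stop("negative counts")
  m <- mean(counts)
  if (m == 0) stop("mean change count is zero; dispersion undefined")
  v <- var(counts)
  n <- length(counts)
  D <- (n - 1) * v / m
  list(mean = m, variance = v, D = D, df = n - 1L,
       p.value = pchisq(D, df = n - 1L, lower.tail = FALSE),
       n = n, star = star)
}

#' Gamma shape of among-gene rate variation (negative-binomial fit)
#'
#' Gene-specific switch rates drawn from a gamma distribution with shape
#' alpha turn Poisson change counts into negative-binomial ones with
#' variance m + m^2/alpha. The shape is estimated by maximum likelihood,
#' profiling out the mean (whose MLE is the sample mean); small alpha means
#' strong rate variation. When the counts are equi- or under-dispersed the
#' likelihood increases toward alpha = infinity; the estimate is then
#' reported at the cap with \code{capped = TRUE} ("no detectable
#' variation").
#'
#' @param counts non-negative integer change counts per gene.
#' @param cap upper bound for the reported shape (default 100).
#' @return list: \code{alpha}, \code{mean}, \code{logLik}, \code{capped}.
#' @export
estimateAlpha <- function(counts, cap = 100) {
  if (all(counts == 0)) stop("all counts are zero; rate not estimable")
  if (length(unique(counts)) == 1L)
    stop("all counts equal; rate variation not estimable")
  mu <- mean(counts)
  ll <- function(logA)
    sum(dnbinom(counts, size = exp(logA), mu = mu, log = TRUE))
  opt <- optimize(ll, interval = c(log(1e-4), log(cap)), maximum = TRUE)
  alpha <- exp(opt$maximum)
  capped <- alpha > cap * 0.99
  if (capped) alpha <- cap
  list(alpha = alpha, mean = mu,
       logLik = if (capped) ll(log(cap)) else opt$objective,
       capped = capped)
}

#' Frequency-matched SNP control for essentiality change counts
#'
#' Introgression distorts the strain phylogeny locally and could inflate
#' parsimony change counts. SNPs segregate under the same history, so they
#' serve as a control: for each polymorphic gene one SNP is sampled whose
#' folded minor-allele count equals the gene's minority-state count
#' (after imputation), nucleotide changes per SNP are counted with the same
#' parsimony machinery, and a paired two-tailed Wilcoxon signed-rank test
#' compares per-gene essentiality changes with their matched SNPs' changes.
#' A pooled rank-sum p-value is reported as a secondary output.
#'
#' @param snps a \linkS4class{SNPMatrix} covering the same strains.
#' @param imputedStates character E/NE matrix of the polymorphic genes
#'   (from [imputeAndCount()]).
#' @param geneCounts named change counts of the same genes.
#' @param tree rooted strain phylogeny.
#' @param nSets number of replicate control sets (default 1000).
#' @param seed optional RNG seed.
#' @return list: \code{replicates} (data.frame p_signed_rank, p_rank_sum,
#'   mean_snp_changes per replicate), \code{geneCounts},
#'   \code{geneClasses} (folded minority counts), \code{snpChangeCounts}
#'   (per SNP site, computed once).
#' @export
matchedSnpControl <- function(snps, imputedStates, geneCounts, tree,
                              nSets = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  calls <- snpCalls(snps)
  strains <- colnames(imputedStates)
  if (!all(strains %in% colnames(calls)))
    stop("SNP matrix lacks strains: ",
         paste(setdiff(strains, colnames(calls)), collapse = ", "))
  calls <- calls[, strains, drop = FALSE]
  checkStrainTree(tree, strains)
  genes <- intersect(rownames(imputedStates), names(geneCounts))
  imputedStates <- imputedStates[genes, , drop = FALSE]
  geneCounts <- geneCounts[genes]

  nE <- rowSums(imputedStates == "E")
  gClass <- pmin(nE, length(strains) - nE)

  mac <- rowSums(calls)
  sClass <- pmin(mac, length(strains) - mac)
  avail <- split(seq_len(nrow(calls)), sClass)
  missing <- setdiff(unique(gClass), as.integer(names(avail)))
  if (length(missing))
    stop("no SNPs available for minority-count class(es): ",
         paste(sort(missing), collapse = ", "))

  ord <- match(tree$tip.label, strains)
  snpChanges <- rep(NA_real_, nrow(calls))
  needed <- unique(unlist(avail[as.character(unique(gClass))]))
  for (i in needed)
    snpChanges[i] <- .sankoff(tree, calls[i, ord])$cost

  byClass <- split(seq_along(genes), gClass)
  reps <- data.frame(p_signed_rank = numeric(nSets),
                     p_rank_sum = numeric(nSets),
                     mean_snp_changes = numeric(nSets))
  for (r in seq_len(nSets)) {
    snpIdx <- integer(length(genes))
    for (cl in names(byClass)) {
      pool <- avail[[cl]]
      need <- length(byClass[[cl]])
      pick <- if (length(pool) == 1L) rep(pool, need)
              else sample(pool, need, replace = need > length(pool))
      snpIdx[byClass[[cl]]] <- pick
    }
    sc <- snpChanges[snpIdx]
    d <- geneCounts - sc
    pw <- if (all(d == 0)) 1 else
      suppressWarnings(wilcox.test(geneCounts, sc, paired = TRUE)$p.value)
    pr <- suppressWarnings(wilcox.test(geneCounts, sc)$p.value)
    reps$p_signed_rank[r] <- pw
    reps$p_rank_sum[r] <- pr
    reps$mean_snp_changes[r] <- mean(sc)
  }
  list(replicates = reps, geneCounts = geneCounts, geneClasses = gClass,
       snpChangeCounts = snpChanges)
}
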