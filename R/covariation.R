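# one-sided truncated normal draws; Robert-style exponential rejection for
# far tails, inverse CDF otherwise
.rtnormAbove <- function(m, s, lower = 0) {
  a <- (lower - m) / s
  if (a < 5) {
    u <- runif(1, pnorm(a), 1)
    u <- min(max(u, 1e-15), 1 - 1e-16)
    m + s * qnorm(u)
  } else {
    lam <- (a + sqrt(a^2 + 4)) / 2
    repeat {
      z <- a + rexp(1, lam)
      if (runif(1) <= exp(-(z - lam)^2 / 2)) return(m + s * z)
    }
  }
}

.rtnormBelow <- function(m, s, upper = 0) -.rtnormAbove(-m, s, -upper)

.mcmcDefaults <- function(mcmc) {
  def <- list(iterations = 20000L, burnin = 0.25, thin = 10L,
              proposalSd = 0.15, seed = NULL)
  def[names(mcmc)] <- mcmc
  def
}

#' Evolutionary correlation of two binary traits (threshold model)
#'
#' Felsenstein's threshold model: each gene's essentiality state in a strain
#' is the sign of a latent continuous liability that evolves as Brownian
#' motion along the phylogeny; the evolutionary correlation r of the two
#' liabilities measures how coordinately the two genes switch. The posterior
#' of r is sampled by Gibbs-within-Metropolis MCMC: tip liabilities are
#' updated one at a time from their conditional normal truncated to the
#' observed sign (essential = positive), and r is updated by a random-walk
#' Metropolis step under a uniform(-1, 1) prior.
#'
#' Strains undetermined in either gene are removed before the analysis; a
#' gene monomorphic after the removal has no information about r and raises
#' an error.
#'
#' @param x,y named E/NE/U vectors (names = strains), or 0/1 vectors where
#'   1 = essential.
#' @param tree rooted strain phylogeny with branch lengths.
#' @param mcmc list overriding the sampler defaults: \code{iterations}
#'   (20000), \code{burnin} (fraction 0.25), \code{thin} (10),
#'   \code{proposalSd} (0.15), \code{seed}.
#' @return list: \code{r} (posterior mean), \code{interval} (2.5/97.5
#'   posterior quantiles), \code{samples}, \code{acceptance}, \code{nStrains}.
#' @export
liabilityCorrelation <- function(x, y, tree, mcmc = list()) {
  opt <- .mcmcDefaults(mcmc)
  if (!is.null(opt$seed)) set.seed(opt$seed)
  toBin <- function(v) {
    nm <- names(v)
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      out <- ifelse(v == "E", 1L, ifelse(v == "NE", 0L, NA_integer_))
    } else out <- as.integer(v)
    names(out) <- nm
    out
  }
  x <- toBin(x); y <- toBin(y)
  strains <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
  if (length(strains) < 3L)
    stop("fewer than three strains determined in both genes")
  x <- x[strains]; y <- y[strains]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("a gene is monomorphic after removing undetermined strains")
  tr <- ape::keep.tip(tree, strains)
  C <- ape::vcv(tr)[strains, strains]
  C <- C / max(diag(C))
  Cinv <- solve(C)
  n <- length(strains)

  sgn <- as.integer(c(ifelse(x == 1L, 1L, -1L), ifelse(y == 1L, 1L, -1L)))
  iters <- as.integer(opt$iterations)
  keepFrom <- as.integer(ceiling(iters * opt$burnin))
  res <- .liabilityMcmcCpp(Cinv, sgn, iters, keepFrom,
                           as.integer(opt$thin), opt$proposalSd)
  samples <- res$samples
  list(r = mean(samples),
       interval = unname(quantile(samples, c(0.025, 0.975))),
       samples = samples, acceptance = res$acceptance, nStrains = n)
}

#' Pairwise liability correlations among polymorphic genes
#'
#' Runs [liabilityCorrelation()] for every unordered pair of the selected
#' genes (all polymorphic genes by default). Pairs are independent; each
#' pair gets its own RNG stream derived from \code{seed} and the gene pair,
#' so results do not depend on evaluation order. When the number of pairs
#' exceeds \code{maxPairs}, a random subset is estimated and the rest stay
#' NA (downstream clustering imputes 0 for them).
#'
#' @param emat an \linkS4class{EssentialityMatrix}.
#' @param tree rooted strain phylogeny.
#' @param genes genes to correlate; default \code{polymorphicGenes(emat)}.
#' @param mcmc sampler options, see [liabilityCorrelation()].
#' @param maxPairs cap on estimated pairs (default Inf).
#' @param seed master seed for pair subsampling and per-pair chains.
#' @return list: \code{r} (symmetric matrix, unit diagonal, NA where not
#'   estimated), \code{pairs} (data.frame gene1, gene2, r, lo, hi),
#'   \code{failures} (data.frame gene1, gene2, reason).
#' @export
correlationMatrix <- function(emat, tree, genes = NULL, mcmc = list(),
                              maxPairs = Inf, seed = NULL) {
  calls <- essCalls(emat)
  if (is.null(genes)) genes <- polymorphicGenes(emat)
  if (!length(genes)) stop("no polymorphic genes to correlate")
  genes <- intersect(rownames(calls), genes)
  ng <- length(genes)
  pairs <- which(upper.tri(matrix(0, ng, ng)), arr.ind = TRUE)
  if (!is.null(seed)) set.seed(seed)
  if (nrow(pairs) > maxPairs)
    pairs <- pairs[sample(nrow(pairs), maxPairs), , drop = FALSE]
  R <- matrix(NA_real_, ng, ng, dimnames = list(genes, genes))
  diag(R) <- 1
  out <- data.frame(gene1 = character(0), gene2 = character(0),
                    r = numeric(0), lo = numeric(0), hi = numeric(0))
  fail <- data.frame(gene1 = character(0), gene2 = character(0),
                     reason = character(0))
  baseSeed <- if (is.null(seed)) 0L else as.integer(seed)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    g1 <- genes[i]; g2 <- genes[j]
    pairSeed <- (baseSeed + 7919L * i + 104729L * j) %% .Machine$integer.max
    m <- mcmc
    m$seed <- pairSeed
    res <- tryCatch(
      liabilityCorrelation(calls[g1, ], calls[g2, ], tree, mcmc = m),
      error = function(e) e)
    if (inherits(res, "error")) {
      fail <- rbind(fail, data.frame(gene1 = g1, gene2 = g2,
                                     reason = conditionMessage(res)))
      next
    }
    R[i, j] <- R[j, i] <- res$r
    out <- rbind(out, data.frame(gene1 = g1, gene2 = g2, r = res$r,
                                 lo = res$interval[1], hi = res$interval[2]))
  }
  list(r = R, pairs = out, failures = fail)
}

#' Cluster polymorphic genes by essentiality covariation
#'
#' Complete-linkage hierarchical clustering on the distance d = 1 - r
#' (sign-preserving: concordant switching is similarity). Pairs without an
#' estimate are imputed r = 0 for clustering only. Groups are the subtrees
#' below the height cutoff; the cutoff lives on the dendrogram's native
#' height scale.
#'
#' @param corr correlation matrix (symmetric, unit diagonal, NAs allowed)
#'   or the list returned by [correlationMatrix()].
#' @param heightCutoff dendrogram height below which subtrees become groups.
#' @return list: \code{groups} (list of character vectors, largest first),
#'   \code{membership} (named integer), \code{hclust}.
#' @export
clusterGenes <- function(corr, heightCutoff) {
  R <- if (is.list(corr) && !is.null(corr$r)) corr$r else corr
  if (any(is.na(R))) {
    message(sprintf("[satayEvol] %d missing pair estimate(s) imputed as r=0",
                    sum(is.na(R[upper.tri(R)]))))
    R[is.na(R)] <- 0
    diag(R) <- 1
  }
  d <- as.dist(1 - R)
  hc <- hclust(d, method = "complete")
  if (heightCutoff >= max(hc$height))
    warning("cutoff at or above dendrogram top: one single group")
  if (heightCutoff < 0)
    warning("negative cutoff: all singletons")
  mem <- cutree(hc, h = heightCutoff)
  groups <- split(names(mem), mem)
  groups <- groups[order(lengths(groups), decreasing = TRUE)]
  names(groups) <- NULL
  list(groups = groups, membership = mem, hclust = hc)
}

#' Assign gene pairs to complex/pathway concordance groups
#'
#' Group I: both genes encode components of the same complex (or pathway);
#' Group II: both are members but only of different complexes; Group III:
#' exactly one gene is a member; Group IV: neither is. The four groups
#' partition all pairs.
#'
#' @param genes character vector of gene ids.
#' @param membership data.frame with columns \code{gene_id}, \code{group_id}
#'   (one row per membership; genes absent from the table are non-members),
#'   or a named list gene_id -> character vector of group ids.
#' @return data.frame: \code{gene1}, \code{gene2}, \code{group} (factor
#'   I/II/III/IV).
#' @export
pairGroups <- function(genes, membership) {
  if (is.data.frame(membership)) {
    membership <- split(as.character(membership$group_id),
                        as.character(membership$gene_id))
  }
  memOf <- function(g) if (is.null(membership[[g]])) character(0)
                       else membership[[g]]
  pr <- which(upper.tri(matrix(0, length(genes), length(genes))),
              arr.ind = TRUE)
  grp <- character(nrow(pr))
  for (k in seq_len(nrow(pr))) {
    m1 <- memOf(genes[pr[k, 1]]); m2 <- memOf(genes[pr[k, 2]])
    grp[k] <- if (length(m1) && length(m2)) {
      if (length(intersect(m1, m2))) "I" else "II"
    } else if (length(m1) || length(m2)) "III" else "IV"
  }
  data.frame(gene1 = genes[pr[, 1]], gene2 = genes[pr[, 2]],
             group = factor(grp, levels = c("I", "II", "III", "IV")),
             stringsAsFactors = FALSE)
}

#' Compare liability correlations across concordance groups
#'
#' Tests whether same-complex (or same-pathway) gene pairs covary in
#' essentiality more than other pairs: pairs are split into Groups I-IV by
#' [pairGroups()], and Group I's correlation distribution is compared to
#' each other group by a two-tailed Wilcoxon rank-sum test.
#'
#' @param corr correlation matrix or [correlationMatrix()] output.
#' @param membership as in [pairGroups()].
#' @param kind label recorded in the output ("complex" or "pathway").
#' @return list: \code{pairs} (pair table with r), \code{sizes},
#'   \code{medians}, \code{tests} (data.frame comparison/p.value),
#'   \code{kind}.
#' @export
groupPairsAndCompare <- function(corr, membership,
                                 kind = c("complex", "pathway")) {
  kind <- match.arg(kind)
  R <- if (is.list(corr) && !is.null(corr$r)) corr$r else corr
  genes <- rownames(R)
  tab <- pairGroups(genes, membership)
  tab$r <- R[cbind(tab$gene1, tab$gene2)]
  tab <- tab[!is.na(tab$r), , drop = FALSE]
  if (!sum(tab$group == "I"))
    stop("no same-", kind, " (Group I) pairs with estimates")
  sizes <- table(tab$group)
  meds <- tapply(tab$r, tab$group, median)
  tests <- data.frame(comparison = character(0), p.value = numeric(0))
  for (g in c("II", "III", "IV")) {
    if (!sizes[[g]]) next
    p <- suppressWarnings(
      wilcox.test(tab$r[tab$group == "I"], tab$r[tab$group == g])$p.value)
    tests <- rbind(tests, data.frame(comparison = paste0("I vs ", g),
                                     p.value = p))
  }
  list(pairs = tab, sizes = sizes, medians = meds, tests = tests,
       kind = kind)
}

#' Enrichment of polymorphism among complex/pathway members
#'
#' One-tailed chi-squared test (1 df, no continuity correction) of whether
#' member genes exhibit essentiality polymorphism more often than
#' non-member genes.
#'
#' @param polymorphic logical vector per gene.
#' @param member logical vector per gene (complex or pathway membership).
#' @return list: \code{propMember}, \code{propOther}, \code{statistic},
#'   \code{p.value} (one-tailed, direction member > other), \code{table}.
#' @export
membershipEnrichment <- function(polymorphic, member) {
  stopifnot(length(polymorphic) == length(member))
  tab <- table(member = factor(member, levels = c(TRUE, FALSE)),
               polymorphic = factor(polymorphic, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in the 2x2 table")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  pMem <- tab["TRUE", "TRUE"] / sum(tab["TRUE", ])
  pOth <- tab["FALSE", "TRUE"] / sum(tab["FALSE", ])
  pOne <- if (pMem > pOth) ct$p.value / 2 else 1 - ct$p.value / 2
  list(propMember = unname(pMem), propOther = unname(pOth),
       statistic = unname(ct$statistic), p.value = pOne, table = tab)
}
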