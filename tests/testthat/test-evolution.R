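test_that("matrix assembly masks aneuploid chromosomes and finds polymorphism", {
  ann <- genomeAnnotation(
    data.frame(chrom = c("chr1", "chr1", "chr2"), start = c(1, 2001, 1),
               end = c(1000, 3000, 1000), strand = "+",
               gene_id = c("g1", "g2", "g3"), annotation = "unknown"),
    chromLengths = c(chr1 = 5000L, chr2 = 5000L))
  mk <- function(calls) data.frame(gene_id = c("g1", "g2", "g3"),
                                   prob = c(0.99, 0.01, 0.5), call = calls,
                                   stringsAsFactors = FALSE)
  callList <- list(a = mk(c("E", "NE", "E")), b = mk(c("NE", "NE", "U")),
                   c = mk(c("E", "NE", "U")))
  emat <- buildEssentialityMatrix(callList, ann)
  expect_setequal(polymorphicGenes(emat), "g1")
  expect_equal(unname(determinedCounts(emat)), c(3L, 3L, 1L))

  # g3 has one E and rest U: one determined strain is not polymorphism
  expect_false("g3" %in% polymorphicGenes(emat))

  # aneuploid (strain b, chr1) forces its genes to U
  emat2 <- buildEssentialityMatrix(callList, ann,
    aneuploid = data.frame(strain = "b", chrom = "chr1"))
  expect_equal(unname(essCalls(emat2)[c("g1", "g2"), "b"]), c("U", "U"))
  expect_equal(unname(essCalls(emat2)["g3", "b"]), "U")  # was U anyway

  # interval-level manual mask hits only overlapping genes
  emat3 <- buildEssentialityMatrix(callList, ann,
    manualMasks = data.frame(strain = "a", chrom = "chr1",
                             start = 1, end = 1500))
  expect_equal(unname(essCalls(emat3)["g1", "a"]), "U")
  expect_equal(unname(essCalls(emat3)["g2", "a"]), "NE")

  # a strain missing from the tree is an error
  tr <- ape::read.tree(text = "((a:1,b:1):1,d:2);")
  expect_error(buildEssentialityMatrix(callList, ann, tree = tr),
               "missing from tree")
})

test_that("Sankoff counting equals brute-force enumeration on small trees", {
  sank <- satayEvol:::.sankoff
  brute <- satayEvol:::.bruteParsimony
  set.seed(42)
  for (n in 4:6) {
    tr <- ape::rtree(n)
    # exhaustive over all binary assignments, plus undetermined variants
    for (a in seq_len(2^n) - 1L) {
      x <- as.integer(intToBits(a))[seq_len(n)]
      expect_equal(sank(tr, x)$cost, brute(tr, x))
    }
    for (rep in 1:10) {
      x <- sample(c(0L, 1L, NA), n, replace = TRUE)
      if (sum(!is.na(x)) < 2L) next
      expect_equal(sank(tr, x)$cost, brute(tr, x))
    }
  }
})

test_that("change counts match hand-worked four-tip cases and impute U", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- rbind(g1 = c("E", "E", "NE", "NE"),
             g2 = c("E", "NE", "E", "NE"),
             g3 = c("NE", "NE", "NE", "NE"),
             g4 = c("E", "U", "NE", "NE"),
             g5 = c("E", "U", "U", "U"))
  colnames(m) <- c("A", "B", "C", "D")
  res <- imputeAndCount(m, tr)
  expect_equal(res$counts[c("g1", "g2", "g3", "g4")],
               c(g1 = 1L, g2 = 2L, g3 = 0L, g4 = 1L))
  expect_equal(res$skipped, "g5")
  expect_false(any(res$imputed == "U"))
  # g4 tip B is a genuine tie (cost 1 either way): resolved toward NE
  expect_equal(unname(res$imputed["g4", "B"]), "NE")
  # imputation never contradicts a determined tip
  expect_equal(res$imputed[, "A"], m[rownames(res$imputed), "A"])
})

test_that("parsimony cost is invariant to rerooting", {
  sank <- satayEvol:::.sankoff
  set.seed(13)
  tr <- ape::rtree(8)
  for (rep in 1:20) {
    x <- sample(c(0L, 1L), 8, replace = TRUE)
    base <- sank(tr, x)$cost
    for (node in 10:14) {
      re <- ape::root(tr, node = node, resolve.root = TRUE)
      ord <- match(re$tip.label, tr$tip.label)
      expect_equal(sank(re, x[ord])$cost, base)
    }
  }
})

test_that("star-phylogeny counts equal the minority-state count", {
  m <- rbind(g1 = c("E", "E", "NE", "NE", "NE"),
             g2 = c("E", "E", "E", "E", "E"),
             g3 = c("NE", "E", "NE", "E", "NE"))
  expect_equal(starChangeCounts(m), c(g1 = 2L, g2 = 0L, g3 = 2L))
})

test_that("overdispersion statistic follows its chi-squared reference", {
  od0 <- overdispersionTest(c(1, 1, 1, 1))
  expect_equal(od0$D, 0)
  expect_equal(od0$p.value, 1)

  od <- overdispersionTest(c(0, 0, 0, 4))
  expect_equal(od$mean, 1)
  expect_equal(od$variance, 4)
  expect_equal(od$D, 12)
  expect_equal(od$df, 3L)
  expect_equal(od$p.value, pchisq(12, 3, lower.tail = FALSE))
  expect_equal(od$p.value, 0.00738, tolerance = 1e-3)

  expect_error(overdispersionTest(c(0, 0, 0)), "mean change count is zero")

  # permuting gene order leaves D unchanged
  set.seed(1)
  x <- rpois(200, 0.4)
  if (mean(x) > 0)
    expect_equal(overdispersionTest(sample(x))$D, overdispersionTest(x)$D)
})

test_that("gamma-shape estimation is a genuine negative-binomial ML fit", {
  set.seed(8)
  lam <- rgamma(4000, shape = 0.3, rate = 0.3 / 0.6)
  x <- rpois(4000, lam)
  fit <- estimateAlpha(x)
  expect_false(fit$capped)
  expect_lt(abs(fit$alpha - 0.3) / 0.3, 0.3)

  # independent oracle: MASS::fitdistr size parameter
  mf <- suppressWarnings(MASS::fitdistr(x, "negative binomial"))
  expect_equal(fit$alpha, unname(mf$estimate["size"]), tolerance = 0.05)
  expect_equal(fit$mean, mean(x))

  # equidispersed counts push the shape to the cap
  expect_equal(estimateAlpha(rpois(4000, 1))$alpha, 100)
  expect_true(estimateAlpha(rpois(4000, 1))$capped)

  expect_error(estimateAlpha(rep(0L, 10)), "zero")
  expect_error(estimateAlpha(rep(2L, 10)), "equal")
})

test_that("matched SNP control enforces folded frequency classes", {
  tr <- fixtureTree()
  set.seed(91)
  # genes with known minority counts
  states <- t(vapply(1:20, function(i) simFlipTrait(tr, 1.2),
                     character(16)))
  rownames(states) <- paste0("g", 1:20)
  counts <- imputeAndCount(states, tr)$counts
  snps <- simulateSnps(tr, 400, seed = 4)

  ctl <- matchedSnpControl(snps, states, counts, tr, nSets = 5, seed = 2)
  expect_equal(nrow(ctl$replicates), 5L)
  nE <- rowSums(states == "E")
  expect_equal(unname(ctl$geneClasses), unname(pmin(nE, 16 - nE)))

  # a frequency class with no SNPs available raises a named error
  mac <- rowSums(snpCalls(snps))
  folded <- pmin(mac, 16 - mac)
  cls <- unique(ctl$geneClasses)[1]
  crippled <- snpMatrix(snpSites(snps)[folded != cls, ],
                        snpCalls(snps)[folded != cls, , drop = FALSE])
  expect_error(matchedSnpControl(crippled, states, counts, tr,
                                 nSets = 2, seed = 1),
               as.character(cls))

  # determinism under seed
  c1 <- matchedSnpControl(snps, states, counts, tr, nSets = 3, seed = 9)
  c2 <- matchedSnpControl(snps, states, counts, tr, nSets = 3, seed = 9)
  expect_equal(c1$replicates, c2$replicates)
})
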