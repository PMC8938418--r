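test_that("liability correlation recovers sign and respects symmetries", {
  tr <- fixtureTree()
  x <- setNames(rep("NE", 16), tr$tip.label)
  x[c("S03", "S07", "S11")] <- "E"
  mc <- list(iterations = 2000L, burnin = 0.25, thin = 2L, seed = 11)

  same <- liabilityCorrelation(x, x, tr, mcmc = mc)
  expect_gt(same$r, 0.8)

  flip <- setNames(ifelse(x == "E", "NE", "E"), names(x))
  opp <- liabilityCorrelation(x, flip, tr, mcmc = mc)
  expect_lt(opp$r, -0.8)

  # relabeling E<->NE on BOTH genes leaves r; flipping one flips the sign
  y <- simFlipTrait(tr, 1.5)
  r0 <- liabilityCorrelation(x, y, tr, mcmc = mc)$r
  fy <- setNames(ifelse(y == "E", "NE", "E"), names(y))
  rBoth <- liabilityCorrelation(flip, fy, tr, mcmc = mc)$r
  rOne <- liabilityCorrelation(x, fy, tr, mcmc = mc)$r
  expect_lt(abs(rBoth - r0), 0.1)
  expect_lt(abs(rOne + r0), 0.1)

  # undetermined strains are removed; monomorphic-after-removal errors
  xu <- x; xu[1:3] <- "U"
  expect_silent(liabilityCorrelation(xu, y, tr, mcmc = mc))
  mono <- setNames(c("E", rep("NE", 15)), tr$tip.label)
  monoU <- mono; monoU[which(mono == "E")] <- "U"
  expect_error(liabilityCorrelation(monoU, y, tr, mcmc = mc),
               "monomorphic")
})

test_that("posterior means agree with the reference threshold-model sampler", {
  tr <- fixtureTree()
  set.seed(3)
  x <- simFlipTrait(tr, 2)
  y <- simFlipTrait(tr, 2)
  mine <- liabilityCorrelation(x, y, tr,
    mcmc = list(iterations = 6000L, burnin = 0.25, thin = 2L, seed = 5))

  X <- cbind(g1 = ifelse(x == "E", 1, 0), g2 = ifelse(y == "E", 1, 0))
  invisible(utils::capture.output(suppressWarnings(
    tb <- phytools::threshBayes(tr, X, types = c("disc", "disc"),
                                ngen = 60000, control = list(print = FALSE),
                                plot = FALSE))))
  burn <- tb$par[tb$par$gen > 15000, "r"]
  expect_lt(abs(mine$r - mean(burn)), 0.3)
  if (abs(mean(burn)) > 0.4)
    expect_equal(sign(mine$r), sign(mean(burn)))
})

test_that("pairwise matrix is symmetric, seeded and order-independent", {
  sim <- fixtureSim(nGenes = 200, nStrains = 16, seed = 101)
  tr <- sim$tree
  states <- sim$truth$states
  poly <- names(which(apply(states, 1, function(v)
    length(unique(v)) > 1)))[1:4]
  emat <- new("EssentialityMatrix",
              calls = states[poly, , drop = FALSE],
              probs = matrix(NA_real_, length(poly), ncol(states),
                             dimnames = list(poly, colnames(states))))
  mc <- list(iterations = 800L, burnin = 0.25, thin = 4L)
  cm1 <- correlationMatrix(emat, tr, genes = poly, mcmc = mc, seed = 17)
  expect_equal(cm1$r, t(cm1$r))
  expect_equal(unname(diag(cm1$r)), rep(1, 4))
  expect_true(all(abs(cm1$r[!is.na(cm1$r)]) <= 1))
  expect_equal(nrow(cm1$pairs) + nrow(cm1$failures), 6L)

  # rerun in reversed gene order: per-pair seeds make results identical
  cm2 <- correlationMatrix(emat, tr, genes = rev(poly), mcmc = mc,
                           seed = 17)
  expect_equal(cm2$r[rownames(cm1$r), colnames(cm1$r)], cm1$r)
})

test_that("complete-linkage clustering separates correlation blocks", {
  g <- paste0("g", 1:9)
  R <- matrix(0, 9, 9, dimnames = list(g, g))
  R[1:4, 1:4] <- 0.9
  R[5:9, 5:9] <- 0.9
  diag(R) <- 1
  cl <- clusterGenes(R, heightCutoff = 0.5)
  expect_equal(sort(lengths(cl$groups), decreasing = TRUE), c(5L, 4L))
  expect_setequal(cl$groups[[1]], g[5:9])

  # identity matrix: singletons at a small cutoff
  I9 <- diag(9); dimnames(I9) <- list(g, g)
  expect_equal(lengths(clusterGenes(I9, heightCutoff = 0.05)$groups),
               rep(1L, 9))

  # cutoff at/above the top collapses everything into one group (warns)
  expect_warning(one <- clusterGenes(I9, heightCutoff = 5), "top")
  expect_equal(lengths(one$groups), 9L)

  # NA entries imputed to zero with a message
  R2 <- R; R2[1, 9] <- R2[9, 1] <- NA
  expect_message(clusterGenes(R2, 0.5), "imputed")

  # gene input order does not change the grouping
  perm <- sample(9)
  clP <- clusterGenes(R[perm, perm], heightCutoff = 0.5)
  expect_setequal(lapply(clP$groups, sort), lapply(cl$groups, sort))
})

test_that("pair grouping partitions pairs into concordance classes", {
  membership <- data.frame(gene_id = c("a", "b", "c"),
                           group_id = c("C1", "C1", "C2"))
  pg <- pairGroups(c("a", "b", "c", "d"), membership)
  expect_equal(nrow(pg), 6L)
  look <- function(x, y)
    as.character(pg$group[(pg$gene1 == x & pg$gene2 == y) |
                          (pg$gene1 == y & pg$gene2 == x)])
  expect_equal(look("a", "b"), "I")    # same complex
  expect_equal(look("a", "c"), "II")   # different complexes
  expect_equal(look("a", "d"), "III")  # one member
  expect_equal(look("c", "d"), "III")
  # partition: every pair in exactly one group
  expect_false(any(is.na(pg$group)))

  allOut <- pairGroups(c("x", "y", "z"), membership)
  expect_true(all(allOut$group == "IV"))
})

test_that("group comparisons detect a same-complex correlation shift", {
  set.seed(12)
  g <- paste0("g", 1:12)
  membership <- data.frame(gene_id = g[1:6],
                           group_id = rep(c("C1", "C2"), each = 3))
  R <- matrix(rnorm(144, 0, 0.08), 12, 12, dimnames = list(g, g))
  R <- (R + t(R)) / 2
  # same-complex pairs shifted upward
  for (cc in list(1:3, 4:6))
    for (i in cc) for (j in cc) if (i != j) R[i, j] <- R[i, j] + 0.5
  diag(R) <- 1
  out <- groupPairsAndCompare(R, membership, kind = "complex")
  expect_gt(out$medians[["I"]], max(out$medians[["III"]],
                                    out$medians[["IV"]]))
  expect_lt(out$tests$p.value[out$tests$comparison == "I vs IV"], 0.01)
  expect_equal(sum(out$sizes), genePairCount(12))

  noMem <- data.frame(gene_id = character(0), group_id = character(0))
  expect_error(groupPairsAndCompare(R, noMem), "Group I")
})

test_that("membership enrichment matches the hand-computed chi-squared", {
  # table: members 20/100 polymorphic, others 10/200
  poly <- c(rep(TRUE, 20), rep(FALSE, 80), rep(TRUE, 10), rep(FALSE, 190))
  mem <- c(rep(TRUE, 100), rep(FALSE, 200))
  res <- membershipEnrichment(poly, mem)
  # independent oracle: direct chi-squared formula on the 2x2 table
  o <- matrix(c(20, 80, 10, 190), 2, byrow = TRUE)
  E <- outer(rowSums(o), colSums(o)) / sum(o)
  chi <- sum((o - E)^2 / E)
  expect_equal(unname(res$statistic), chi)
  expect_equal(res$p.value, pchisq(chi, 1, lower.tail = FALSE) / 2)
  expect_equal(res$propMember, 0.2)
  expect_equal(res$propOther, 0.05)

  # equal proportions: one-tailed p near 0.5
  poly2 <- rep(c(TRUE, FALSE), 150)
  mem2 <- rep(c(TRUE, FALSE), each = 150)
  expect_equal(membershipEnrichment(poly2, mem2)$p.value, 0.5,
               tolerance = 0.2)

  expect_error(membershipEnrichment(rep(FALSE, 10), rep(TRUE, 10)),
               "margin")
})
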