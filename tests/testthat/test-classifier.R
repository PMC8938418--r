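test_that("training-set assembly applies exclusions with logged reasons", {
  sim <- fixtureSim(nGenes = 120, nStrains = 2, seed = 61)
  ref <- sim$referenceStrain
  f <- geneFeatures(sim$maps[[ref]], sim$annotation)
  g <- annotatedGenes(sim$annotation)
  labels <- setNames(g$annotation, g$gene_id)

  full <- buildTrainingSet(f, labels)
  keepable <- sum(!f$discard)
  expect_equal(nrow(full$features), keepable)

  # exclusion lists remove genes; a gene on two lists logs the first reason
  ex <- list(misannotated = f$gene_id[1:5],
             auxotrophy = f$gene_id[4:8])
  tr <- buildTrainingSet(f, labels, exclude = ex)
  expect_equal(nrow(tr$features), keepable - 8L)
  expect_equal(nrow(tr$exclusions), 8L)
  expect_equal(tr$exclusions$reason[tr$exclusions$gene_id == f$gene_id[4]],
               "misannotated")

  expect_error(buildTrainingSet(f, labels,
                                exclude = list(all = f$gene_id)),
               "no genes left")
})

test_that("classifier training is seeded, stratified and informative", {
  sim <- fixtureSim(nGenes = 300, nStrains = 2, seed = 41)
  ref <- sim$referenceStrain
  f <- geneFeatures(sim$maps[[ref]], sim$annotation)
  g <- annotatedGenes(sim$annotation)
  labels <- setNames(g$annotation, g$gene_id)
  training <- buildTrainingSet(f, labels)

  fit1 <- trainClassifier(training, seed = 7)
  fit2 <- trainClassifier(training, seed = 7)
  expect_identical(fit1$trainIdx, fit2$trainIdx)
  expect_identical(fit1$auc, fit2$auc)

  # clean simulated separation: held-out AUC is high
  expect_gte(fit1$auc, 0.95)

  # shuffled labels give chance-level AUC
  shuf <- training
  set.seed(9)
  shuf$labels <- sample(shuf$labels)
  fitS <- trainClassifier(shuf, seed = 7)
  expect_lt(abs(fitS$auc - 0.5), 0.1)

  # single-class input is an error
  mono <- training
  mono$labels <- factor(rep("nonessential", length(mono$labels)),
                        levels = c("nonessential", "essential"))
  expect_error(trainClassifier(mono, seed = 1), "both classes")
})

test_that("calibration solves the fitted curve at the f_ES targets", {
  # perfectly calibrated outputs: f_ES equals the bin midpoint exactly
  mids <- seq(0.025, 0.975, by = 0.05)
  probs <- rep(mids, each = 200L)
  ess <- unlist(lapply(mids, function(m)
    rep(c("essential", "nonessential"), c(round(200 * m),
                                          200 - round(200 * m)))))
  cal <- calibrateClassifier(probs, ess)
  th <- calibThresholds(cal)
  expect_equal(unname(th["t_ess"]), 0.95, tolerance = 1e-6)
  expect_equal(unname(th["t_noness"]), 0.05, tolerance = 1e-6)
  expect_equal(unname(th["t_ess75"]), 0.75, tolerance = 1e-6)
  expect_equal(unname(th["t_noness25"]), 0.25, tolerance = 1e-6)

  # logistic-shaped curve: thresholds match a dense-grid search of the
  # fitted polynomial to 1e-6
  fes <- 1 / (1 + exp(-12 * (mids - 0.5)))
  probs2 <- rep(mids, each = 400L)
  ess2 <- unlist(lapply(fes, function(m)
    rep(c("essential", "nonessential"), c(round(400 * m),
                                          400 - round(400 * m)))))
  cal2 <- calibrateClassifier(probs2, ess2)
  co <- cal2@coeffs
  grid <- seq(0, 1, by = 1e-7)
  poly <- 0; for (k in seq_along(co)) poly <- poly + co[k] * grid^(k - 1)
  for (tg in c(t_ess = 0.95, t_noness = 0.05)) {
    got <- calibThresholds(cal2)[[if (tg > 0.5) "t_ess" else "t_noness"]]
    bruteRoots <- grid[abs(poly - tg) < 1e-5]
    expect_lt(min(abs(bruteRoots - got)), 1e-6)
  }

  # FDR at the strict thresholds equals the label mixture beyond them
  called <- probs2 >= calibThresholds(cal2)["t_ess"]
  expect_equal(unname(calibFdr(cal2)["fdr_ess"]),
               mean(ess2[called] == "nonessential"))

  # a curve that never reaches the target errors (strict) or falls back
  flat <- rep(mids, each = 50L)
  essFlat <- unlist(lapply(mids, function(m)
    rep(c("essential", "nonessential"), c(20L, 30L))))  # f_ES = 0.4 all bins
  expect_error(calibrateClassifier(flat, essFlat), "never reaches")
  w <- capture_warnings(
    calFlat <- calibrateClassifier(flat, essFlat, fallback = "empirical"))
  expect_true(all(grepl("falling back", w)))
  expect_s4_class(calFlat, "CalibrationResult")
})

test_that("strain classification applies the threshold tie rules", {
  cal <- new("CalibrationResult",
             bins = data.frame(), coeffs = 0,
             thresholds = c(t_ess = 0.903, t_noness = 0.129,
                            t_ess75 = 0.75, t_noness25 = 0.25),
             fdr = c(fdr_ess = NA_real_, fdr_noness = NA_real_,
                     fdr_ess75 = NA_real_, fdr_noness25 = NA_real_),
             targets = c(ess = 0.95, noness = 0.05, ess75 = 0.75,
                         noness25 = 0.25))
  # fake model: a constant forest is impractical, exercise the rule directly
  fakeCall <- function(p) {
    if (p >= 0.903) "E" else if (p <= 0.129) "NE" else "U"
  }
  expect_equal(fakeCall(0.95), "E")
  expect_equal(fakeCall(0.903), "E")     # >= tie rule
  expect_equal(fakeCall(0.129), "NE")    # <= tie rule
  expect_equal(fakeCall(0.5), "U")

  # monotonicity on the real path: raising prob never demotes a call
  sim <- fixtureSim(nGenes = 300, nStrains = 2, seed = 41)
  ref <- sim$referenceStrain
  f <- geneFeatures(sim$maps[[ref]], sim$annotation)
  g <- annotatedGenes(sim$annotation)
  labels <- setNames(g$annotation, g$gene_id)
  fit <- trainClassifier(buildTrainingSet(f, labels), seed = 7)
  calR <- calibrateClassifier(fit$test$probs, fit$test$labels)
  calls <- classifyStrain(fit$model, calR, f)
  rank <- c(NE = 1L, U = 2L, E = 3L)
  ok <- !is.na(calls$prob)
  o <- order(calls$prob[ok])
  expect_true(all(diff(rank[calls$call[ok][o]]) >= 0L))
  # calls partition: each classified gene exactly one state
  expect_true(all(calls$call %in% c("E", "NE", "U")))
})

test_that("downsampling matches binomial expectations and is seeded", {
  sim <- fixtureSim(nGenes = 120, nStrains = 2, seed = 61)
  ref <- sim$referenceStrain
  ann <- sim$annotation
  map <- sim$maps[[ref]]
  f0 <- geneFeatures(map, ann)
  g <- annotatedGenes(ann)
  labels <- setNames(g$annotation, g$gene_id)

  sites <- insertionSites(map)
  msk <- regionMask(ann)
  unmasked <- !IRanges::overlapsAny(sites, msk, ignore.strand = TRUE)
  nCoding <- sum(unmasked &
    IRanges::overlapsAny(sites, g, ignore.strand = TRUE))

  # identity: keeping the full count reproduces the original features
  adjFull <- downsampleAdjust(map, ann, labels, nCoding, nReps = 2L,
                              seed = 3, mtry = 3L)
  expect_equal(adjFull$features$n_tn, f0$n_tn)
  expect_equal(adjFull$features$freedom_index, f0$freedom_index)

  # halving the coding insertions halves expected per-gene counts
  half <- floor(nCoding / 2)
  adjHalf <- downsampleAdjust(map, ann, labels, half, nReps = 60L,
                              seed = 3, mtry = 3L)
  keep <- f0$n_tn >= 10
  ratio <- adjHalf$features$n_tn[keep] / f0$n_tn[keep]
  expect_lt(abs(mean(ratio) - half / nCoding), 0.03)

  # determinism under a fixed seed
  a1 <- downsampleAdjust(map, ann, labels, half, nReps = 3L, seed = 5,
                         mtry = 3L)
  a2 <- downsampleAdjust(map, ann, labels, half, nReps = 3L, seed = 5,
                         mtry = 3L)
  expect_equal(a1$features, a2$features)

  expect_error(downsampleAdjust(map, ann, labels, nCoding + 10L,
                                nReps = 2L, seed = 1, mtry = 3L),
               "exceeds")
  expect_error(downsampleCodingInsertions(map, ann, nCoding + 10L),
               "exceeds")
})

test_that("relaxed rescue touches only undetermined polymorphic entries", {
  calls <- rbind(gPoly = c("E", "U", "NE"),
                 gMono = c("U", "U", "U"),
                 gFix  = c("E", "E", "U"))
  probs <- rbind(gPoly = c(0.99, 0.8, 0.05),
                 gMono = c(0.8, 0.8, 0.8),
                 gFix  = c(0.99, 0.97, 0.2))
  colnames(calls) <- colnames(probs) <- c("a", "b", "c")
  emat <- new("EssentialityMatrix", calls = calls, probs = probs)
  cal <- new("CalibrationResult",
             bins = data.frame(), coeffs = 0,
             thresholds = c(t_ess = 0.9, t_noness = 0.1,
                            t_ess75 = 0.75, t_noness25 = 0.25),
             fdr = c(fdr_ess = NA_real_, fdr_noness = NA_real_,
                     fdr_ess75 = NA_real_, fdr_noness25 = NA_real_),
             targets = c(ess = 0.95, noness = 0.05, ess75 = 0.75,
                         noness25 = 0.25))
  out <- rescuePolymorphic(emat, cal)
  cl <- essCalls(out)
  expect_equal(unname(cl["gPoly", ]), c("E", "E", "NE"))  # 0.8 >= 0.75
  expect_equal(unname(cl["gMono", ]), c("U", "U", "U"))   # not polymorphic
  expect_equal(unname(cl["gFix", ]), c("E", "E", "U"))    # 0.2 inside band
})
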