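#' @importFrom randomForest randomForest importance
#' @importFrom stats lm predict coef median quantile var sd runif rnorm
#'   rpois rgeom rbinom rexp rgamma setNames uniroot optimize pchisq
#'   dnbinom wilcox.test chisq.test hclust cutree as.dist pnorm qnorm
#'   complete.cases
NULL

# the nine classifier features, in the order used throughout
.featureCols <- c("n_tn", "tn_density", "n_reads", "read_density",
                  "longest_free", "freedom_index", "upstream_tn",
                  "neighborhood_index", "free_tenths")

# rank-based AUC (probability a random essential gene outranks a random
# nonessential one)
.auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assemble the classifier training set
#'
#' Filters the reference-strain feature table down to genes usable as
#' machine-learning truth: genes on any exclusion list are removed and
#' logged with the first matching reason, genes flagged \code{discard}
#' (effective length < 300 nt) are dropped, and only genes with a
#' deletion-based label (essential / nonessential) are kept.
#'
#' @param features data.frame from [geneFeatures()] for the reference strain.
#' @param labels named character vector (gene_id -> "essential" /
#'   "nonessential" / "unknown"), e.g. from the annotation.
#' @param exclude named list of character vectors of gene ids; names are the
#'   exclusion reasons (misannotation lists, CDS overlap with essential
#'   genes, auxotrophies, ...).
#' @return list with \code{features} (data.frame), \code{labels} (factor
#'   with levels nonessential/essential) and \code{exclusions} (data.frame
#'   gene_id, reason).
#' @export
buildTrainingSet <- function(features, labels, exclude = list()) {
  excl <- data.frame(gene_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  for (reason in names(exclude)) {
    ids <- setdiff(intersect(exclude[[reason]], features$gene_id),
                   excl$gene_id)
    if (length(ids))
      excl <- rbind(excl, data.frame(gene_id = ids, reason = reason,
                                     stringsAsFactors = FALSE))
  }
  keep <- !(features$gene_id %in% excl$gene_id) & !features$discard
  features <- features[keep, , drop = FALSE]
  lab <- labels[features$gene_id]
  use <- !is.na(lab) & lab %in% c("essential", "nonessential")
  features <- features[use, , drop = FALSE]
  lab <- factor(lab[use], levels = c("nonessential", "essential"))
  if (!nrow(features))
    stop("no genes left after exclusions")
  list(features = features, labels = lab, exclusions = excl)
}

#' Train the random-forest essentiality classifier
#'
#' Stratified 50/50 split of the labeled genes, 10-fold cross-validated
#' choice of \code{mtry} on the training half (maximizing AUC), final
#' random-forest fit, and evaluation on the held-out half. The model's
#' output for a gene is the probability that it is essential.
#'
#' @param training list from [buildTrainingSet()].
#' @param splitFraction fraction of genes used for training (default 0.5).
#' @param cvFolds folds for the internal cross-validation (default 10).
#' @param ntree trees in the forest (default 500).
#' @param mtry either NULL (choose by cross-validation over
#'   \code{mtryGrid}) or a fixed value.
#' @param mtryGrid candidate \code{mtry} values.
#' @param seed optional RNG seed; the same seed reproduces the same split
#'   and forest.
#' @return list: \code{model} (randomForest), \code{mtry},
#'   \code{importance} (named, decreasing), \code{auc} (held-out AUC),
#'   \code{test} (list features/labels/probs for calibration),
#'   \code{trainIdx}.
#' @export
trainClassifier <- function(training, splitFraction = 0.5, cvFolds = 10L,
                            ntree = 500L, mtry = NULL,
                            mtryGrid = c(2L, 3L, 5L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- training$labels
  if (nlevels(droplevels(y)) < 2L)
    stop("training set must contain both classes")
  x <- training$features[, .featureCols]
  n <- length(y)
  trainIdx <- logical(n)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    trainIdx[sample(idx, round(length(idx) * splitFraction))] <- TRUE
  }
  xt <- x[trainIdx, ]; yt <- droplevels(y[trainIdx])

  if (is.null(mtry)) {
    fold <- integer(sum(trainIdx))
    for (cl in levels(yt)) {
      idx <- which(yt == cl)
      fold[idx] <- sample(rep_len(seq_len(cvFolds), length(idx)))
    }
    cvA <- vapply(mtryGrid, function(m) {
      p <- numeric(length(yt))
      for (k in seq_len(cvFolds)) {
        tr <- fold != k
        if (nlevels(droplevels(yt[tr])) < 2L) next
        fit <- randomForest(xt[tr, ], yt[tr], ntree = ntree, mtry = m)
        p[!tr] <- predict(fit, xt[!tr, ], type = "prob")[, "essential"]
      }
      .auc(p, yt == "essential")
    }, numeric(1))
    mtry <- mtryGrid[which.max(cvA)]
  }

  model <- randomForest(xt, yt, ntree = ntree, mtry = mtry,
                        importance = TRUE)
  testX <- x[!trainIdx, ]
  testY <- y[!trainIdx]
  probs <- predict(model, testX, type = "prob")[, "essential"]
  imp <- importance(model, type = 2)[, 1]
  list(model = model, mtry = mtry,
       importance = sort(imp, decreasing = TRUE),
       auc = .auc(probs, testY == "essential"),
       test = list(features = training$features[!trainIdx, , drop = FALSE],
                   labels = testY, probs = probs),
       trainIdx = trainIdx)
}

.binEdges <- seq(0, 1, by = 0.05)

.binIndex <- function(p) pmin(pmax(floor(p / 0.05) + 1L, 1L), 20L)

.evalPoly <- function(coeffs, x) {
  out <- 0
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * x^(k - 1)
  out
}

# all roots of poly(x) = target inside [0,1], by sign-change bracketing on a
# fine grid + uniroot refinement
.polyRoots <- function(coeffs, target, tol = 1e-9) {
  g <- seq(0, 1, by = 1e-4)
  v <- .evalPoly(coeffs, g) - target
  s <- sign(v)
  roots <- g[v == 0]
  ch <- which(s[-1] * s[-length(s)] < 0)
  for (i in ch) {
    r <- uniroot(function(x) .evalPoly(coeffs, x) - target,
                 lower = g[i], upper = g[i + 1], tol = tol)
    roots <- c(roots, r$root)
  }
  sort(unique(roots))
}

#' Calibrate classifier thresholds by 20-bin polynomial regression
#'
#' Held-out classifier outputs are divided into 20 bins (0-0.05, ...,
#' 0.95-1); the fraction of annotated-essential genes per bin (f_ES) is
#' regressed on the bin midpoint with a weighted polynomial (weights = bin
#' counts, empty bins dropped). Each f_ES target is solved on the fitted
#' curve inside [0,1]; when several roots exist the one nearest the bin
#' whose empirical f_ES is closest to the target is taken. False discovery
#' rates at the resulting thresholds are computed from the held-out labels:
#' the essential-gene FDR is the fraction of annotated-nonessential genes
#' among genes at or above the essential threshold, and vice versa.
#'
#' @param probs numeric classifier outputs for held-out genes.
#' @param labels factor/character of annotated labels
#'   ("essential"/"nonessential") aligned with \code{probs}.
#' @param fTargets f_ES targets; must be named \code{ess}, \code{noness},
#'   \code{ess75}, \code{noness25} (defaults 0.95, 0.05, 0.75, 0.25).
#' @param degree polynomial degree (default 3).
#' @param fallback \code{"error"} (default) stops when the fitted curve has
#'   no root at a target; \code{"empirical"} instead takes the threshold
#'   from the empirical bin table with a warning.
#' @return a \linkS4class{CalibrationResult}.
#' @export
calibrateClassifier <- function(probs, labels,
                                fTargets = c(ess = 0.95, noness = 0.05,
                                             ess75 = 0.75, noness25 = 0.25),
                                degree = 3L,
                                fallback = c("error", "empirical")) {
  fallback <- match.arg(fallback)
  stopifnot(length(probs) == length(labels))
  ess <- as.character(labels) == "essential"
  b <- .binIndex(probs)
  nb <- tabulate(b, 20L)
  fes <- vapply(seq_len(20L), function(k)
    if (nb[k]) mean(ess[b == k]) else NA_real_, numeric(1))
  mids <- (.binEdges[-21] + .binEdges[-1]) / 2
  bins <- data.frame(lower = .binEdges[-21], upper = .binEdges[-1],
                     mid = mids, n = nb, f_es = fes)
  use <- nb > 0L
  fit <- lm(fes[use] ~ poly(mids[use], degree, raw = TRUE),
            weights = nb[use])
  coeffs <- as.numeric(coef(fit))
  coeffs[is.na(coeffs)] <- 0

  solveTarget <- function(target) {
    roots <- .polyRoots(coeffs, target)
    if (!length(roots)) {
      if (fallback == "error")
        stop(sprintf(paste0("calibration curve never reaches f_ES = %.2f ",
                            "within [0,1] (fitted range %.3f..%.3f); ",
                            "inspect the bin table"),
                     target, min(.evalPoly(coeffs, mids)),
                     max(.evalPoly(coeffs, mids))))
      warning(sprintf("no polynomial root at f_ES = %.2f; %s",
                      target, "falling back to the empirical bin edge"))
      if (target >= 0.5) {
        ok <- which(use & fes >= target)
        return(if (length(ok)) bins$lower[min(ok)] else 1)
      }
      ok <- which(use & fes <= target)
      return(if (length(ok)) bins$upper[max(ok)] else 0)
    }
    anchor <- mids[use][which.min(abs(fes[use] - target))]
    roots[which.min(abs(roots - anchor))]
  }

  th <- c(t_ess = solveTarget(fTargets[["ess"]]),
          t_noness = solveTarget(fTargets[["noness"]]),
          t_ess75 = solveTarget(fTargets[["ess75"]]),
          t_noness25 = solveTarget(fTargets[["noness25"]]))
  if (th["t_noness"] >= th["t_ess"])
    stop("calibration produced t_noness >= t_ess; curve is not usable")
  # relaxed thresholds can only widen the callable region
  th["t_ess75"] <- min(th["t_ess75"], th["t_ess"])
  th["t_noness25"] <- max(th["t_noness25"], th["t_noness"])

  fdrAt <- function(tE, tN) {
    cE <- probs >= tE; cN <- probs <= tN
    c(if (any(cE)) mean(!ess[cE]) else NA_real_,
      if (any(cN)) mean(ess[cN]) else NA_real_)
  }
  strict <- fdrAt(th["t_ess"], th["t_noness"])
  relaxed <- fdrAt(th["t_ess75"], th["t_noness25"])
  fdr <- c(fdr_ess = strict[1], fdr_noness = strict[2],
           fdr_ess75 = relaxed[1], fdr_noness25 = relaxed[2])
  new("CalibrationResult", bins = bins, coeffs = coeffs,
      thresholds = th, fdr = fdr, targets = fTargets)
}

#' Call gene essentiality for one strain
#'
#' Applies the model and strict calibrated thresholds to a strain's feature
#' table: probability >= \code{t_ess} calls E, probability <= \code{t_noness}
#' calls NE, anything strictly between is undetermined (U). Genes flagged
#' \code{discard} are not predicted and come back U with probability NA.
#'
#' @param model randomForest model (from [trainClassifier()]).
#' @param calibration a \linkS4class{CalibrationResult}.
#' @param features data.frame from [geneFeatures()].
#' @return data.frame: \code{gene_id}, \code{strain}, \code{prob},
#'   \code{call} in E/NE/U.
#' @export
classifyStrain <- function(model, calibration, features) {
  th <- calibThresholds(calibration)
  prob <- rep(NA_real_, nrow(features))
  ok <- !features$discard
  if (any(ok))
    prob[ok] <- predict(model, features[ok, .featureCols],
                        type = "prob")[, "essential"]
  call <- rep("U", nrow(features))
  call[ok & prob >= th["t_ess"]] <- "E"
  call[ok & prob <= th["t_noness"]] <- "NE"
  data.frame(gene_id = features$gene_id,
             strain = features$strain[1],
             prob = prob, call = call, stringsAsFactors = FALSE)
}

#' Downsample coding-region insertions of a map
#'
#' Uniformly subsamples (without replacement) the insertion sites that fall
#' in coding regions down to \code{target} sites, keeping all noncoding
#' sites. Used to match the reference library's depth to another strain's.
#'
#' @param map an \linkS4class{InsertionMap}.
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param target number of coding-region insertion sites to keep.
#' @return an \linkS4class{InsertionMap}.
#' @export
downsampleCodingInsertions <- function(map, ann, target) {
  sites <- insertionSites(map)
  mask <- regionMask(ann)
  unmasked <- if (length(mask))
    !overlapsAny(sites, mask, ignore.strand = TRUE) else
    rep(TRUE, length(sites))
  coding <- overlapsAny(sites, annotatedGenes(ann), ignore.strand = TRUE) &
    unmasked
  nCoding <- sum(coding)
  if (target > nCoding)
    stop(sprintf("target (%d) exceeds available coding insertions (%d)",
                 target, nCoding))
  keep <- rep(TRUE, length(sites))
  drop <- sample(which(coding), nCoding - target)
  keep[drop] <- FALSE
  InsertionMap(strainName(map), sites[keep])
}

#' Depth-matched model adjustment by downsampling
#'
#' The reference strain has the deepest coding-region insertion library;
#' strains with fewer insertions would look artificially "insertion-free".
#' For a target depth, the reference coding insertions are repeatedly
#' downsampled to that count, features are recomputed per replicate, the
#' per-gene mean features over the replicates are taken as the observed
#' features, and the model and thresholds are retrained and recalibrated on
#' those averaged features.
#'
#' @param refMap reference-strain \linkS4class{InsertionMap}.
#' @param ann a \linkS4class{GenomeAnnotation}.
#' @param labels named deletion-based labels for [buildTrainingSet()].
#' @param targetTnCount coding-insertion count of the strain to be matched;
#'   must not exceed the reference's.
#' @param nReps downsampling replicates (default 100).
#' @param exclude exclusion lists, as in [buildTrainingSet()].
#' @param seed optional RNG seed.
#' @param cache optional [featureCache()] for \code{ann}.
#' @param mtry fixed \code{mtry} (skips cross-validation; useful when the
#'   reference model already chose one).
#' @param calibArgs list of extra arguments for [calibrateClassifier()].
#' @param ... passed to [trainClassifier()].
#' @return list: \code{features} (averaged data.frame), \code{fit} (from
#'   [trainClassifier()]), \code{calibration}
#'   (\linkS4class{CalibrationResult}), \code{nReps}, \code{target}.
#' @export
downsampleAdjust <- function(refMap, ann, labels, targetTnCount,
                             nReps = 100L, exclude = list(), seed = NULL,
                             cache = NULL, mtry = NULL,
                             calibArgs = list(), ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cache)) cache <- featureCache(ann)
  eng <- .featureEngine(refMap, cache)
  coding <- eng$codingSiteIdx
  if (targetTnCount > length(coding))
    stop(sprintf("target (%d) exceeds available coding insertions (%d)",
                 targetTnCount, length(coding)))
  acc <- NULL
  for (r in seq_len(nReps)) {
    keep <- rep(TRUE, eng$nSites)
    keep[sample(coding, length(coding) - targetTnCount)] <- FALSE
    f <- eng$compute(keep)
    if (is.null(acc)) {
      acc <- f
      accMat <- as.matrix(f[, .featureCols])
    } else {
      accMat <- accMat + as.matrix(f[, .featureCols])
    }
  }
  acc[, .featureCols] <- accMat / nReps
  training <- buildTrainingSet(acc, labels, exclude = exclude)
  fit <- trainClassifier(training, mtry = mtry, ...)
  calibration <- do.call(calibrateClassifier,
                         c(list(probs = fit$test$probs,
                                labels = fit$test$labels), calibArgs))
  list(features = acc, fit = fit, calibration = calibration,
       nReps = nReps, target = targetTnCount)
}

#' Relaxed-threshold rescue of undetermined calls in polymorphic genes
#'
#' For genes already identified as polymorphic under the strict thresholds,
#' undetermined entries are re-evaluated against the relaxed thresholds
#' (f_ES = 0.75 / 0.25) so more strains get a call. Monomorphic genes are
#' never touched.
#'
#' @param emat an \linkS4class{EssentialityMatrix} (strict calls + probs).
#' @param calibrations either one \linkS4class{CalibrationResult} shared by
#'   all strains or a named list with one per strain (column).
#' @param genes genes eligible for rescue; defaults to
#'   \code{polymorphicGenes(emat)}.
#' @return the updated \linkS4class{EssentialityMatrix}.
#' @export
rescuePolymorphic <- function(emat, calibrations, genes = NULL) {
  if (is.null(genes)) genes <- polymorphicGenes(emat)
  calls <- essCalls(emat)
  probs <- essProbs(emat)
  single <- is(calibrations, "CalibrationResult")
  for (st in colnames(calls)) {
    cal <- if (single) calibrations else calibrations[[st]]
    if (is.null(cal)) next
    th <- calibThresholds(cal)
    u <- calls[, st] == "U" & rownames(calls) %in% genes &
      !is.na(probs[, st])
    calls[u & probs[, st] >= th["t_ess75"], st] <- "E"
    calls[u & probs[, st] <= th["t_noness25"], st] <- "NE"
  }
  new("EssentialityMatrix", calls = calls, probs = probs)
}
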