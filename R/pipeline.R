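#' Pipeline run configuration
#'
#' All tunable parameters of [runPipeline()] with their defaults: f_ES
#' calibration targets 0.95/0.05 (strict) and 0.75/0.25 (relaxed), 100
#' downsampling replicates, 1000 matched-SNP control sets, consensus
#' tolerance in >= 9 strains, aneuploidy density-ratio threshold 1.5, and a
#' desk-scale cap on the number of liability-correlation pairs (the full
#' pairwise matrix is cluster-scale; unestimated pairs are imputed r = 0
#' for clustering). The configuration is serialized into the run directory
#' for provenance.
#'
#' @param referenceStrain strain whose deletion-based labels train the
#'   classifier; default the dataset's.
#' @param fTargets named f_ES targets (ess, noness, ess75, noness25).
#' @param degree calibration polynomial degree.
#' @param splitFraction,cvFolds,ntree classifier options
#'   (see [trainClassifier()]).
#' @param downsampleReps downsampling replicates per strain (default 100).
#' @param ratioThreshold aneuploidy density ratio (default 1.5).
#' @param snpSets matched-SNP control replicates (default 1000).
#' @param mcmc liability-model sampler options (default 3000 iterations,
#'   25\% burn-in, thin 5).
#' @param maxPairs cap on estimated correlation pairs (default 2000).
#' @param heightCutoff complete-linkage dendrogram cutoff on d = 1 - r
#'   (default 0.8).
#' @param minStrains,minInsertions consensus segment-tolerance rule
#'   (defaults 9 strains, 1 insertion).
#' @param seed master seed; every stage derives its own stream from it.
#' @return list of class \code{satayRunConfig}.
#' @export
runConfig <- function(referenceStrain = NULL,
                      fTargets = c(ess = 0.95, noness = 0.05,
                                   ess75 = 0.75, noness25 = 0.25),
                      degree = 3L, splitFraction = 0.5, cvFolds = 10L,
                      ntree = 500L, downsampleReps = 100L,
                      ratioThreshold = 1.5, snpSets = 1000L,
                      mcmc = list(iterations = 3000L, burnin = 0.25,
                                  thin = 5L),
                      maxPairs = 2000L, heightCutoff = 0.8,
                      minStrains = 9L, minInsertions = 1L, seed = 1L) {
  cfg <- list(referenceStrain = referenceStrain, fTargets = fTargets,
              degree = degree, splitFraction = splitFraction,
              cvFolds = cvFolds, ntree = ntree,
              downsampleReps = downsampleReps,
              ratioThreshold = ratioThreshold, snpSets = snpSets,
              mcmc = mcmc, maxPairs = maxPairs,
              heightCutoff = heightCutoff, minStrains = minStrains,
              minInsertions = minInsertions, seed = as.integer(seed))
  class(cfg) <- "satayRunConfig"
  cfg
}

.writeTsv <- function(df, path, rownames = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = rownames, col.names = TRUE)
  path
}

#' Run the full essentiality-polymorphism pipeline
#'
#' Orchestrates the whole chain on one dataset: aneuploidy scan, per-strain
#' feature extraction, reference-strain training and calibration,
#' depth-matched downsampling models for shallower strains, per-strain
#' calls, cross-strain matrix with aneuploidy masking and relaxed-threshold
#' rescue of polymorphic genes, parsimony change counting, overdispersion
#' and gamma-shape rate analysis, matched-SNP introgression control,
#' pairwise liability correlations with clustering (and complex/pathway
#' concordance when a membership table is supplied), and ten-segment
#' tolerance profiling of monomorphic essential genes. Each stage writes a
#' TSV into \code{outDir}; a manifest with checksums and the serialized
#' configuration close the run. A stage failure stops the run naming the
#' stage, retaining earlier outputs.
#'
#' @param dataset list with elements \code{annotation}, \code{tree},
#'   \code{maps}, \code{snps}, \code{referenceStrain} — as returned by
#'   [simulateSatayDataset()] or [readDataset()].
#' @param outDir output directory (created).
#' @param config a [runConfig()].
#' @param membership optional data.frame (\code{gene_id}, \code{group_id})
#'   of complex or pathway memberships.
#' @param membershipKind "complex" or "pathway" (label only).
#' @param manualMasks optional data.frame of conservative manual aneuploidy
#'   masks (see [buildEssentialityMatrix()]).
#' @return (invisibly) list with every stage's in-memory result:
#'   \code{features}, \code{aneuploidy}, \code{refFit}, \code{calibrations},
#'   \code{matrix} (\linkS4class{EssentialityMatrix}), \code{polymorphic},
#'   \code{parsimony}, \code{overdispersion}, \code{overdispersionStar},
#'   \code{alpha}, \code{snpControl}, \code{correlations}, \code{clusters},
#'   \code{concordance}, \code{enrichment}, \code{segments},
#'   \code{summary}, \code{outDir}.
#' @export
runPipeline <- function(dataset, outDir, config = runConfig(),
                        membership = NULL,
                        membershipKind = c("complex", "pathway"),
                        manualMasks = NULL) {
  membershipKind <- match.arg(membershipKind)
  t0 <- Sys.time()
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[satayEvol] stage: ", name)
    tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  seedFor <- function(k) (config$seed * 1000L + k) %% .Machine$integer.max

  ann <- dataset$annotation
  tree <- dataset$tree
  maps <- dataset$maps
  strains <- names(maps)
  ref <- config$referenceStrain
  if (is.null(ref)) ref <- dataset$referenceStrain
  if (is.null(ref)) ref <- strains[1]

  stage("ingest", {
    if (!ref %in% strains) stop("reference strain not among maps: ", ref)
    checkStrainTree(tree, strains)
  })
  cache <- stage("feature-cache", featureCache(ann))

  aneu <- stage("aneuploidy-scan", {
    out <- do.call(rbind, lapply(maps, aneuploidyScan, ann = ann,
                                 ratioThreshold = config$ratioThreshold))
    .writeTsv(out, file.path(outDir, "aneuploidy.tsv"))
    out
  })

  feats <- stage("features", {
    fl <- lapply(maps, geneFeatures, ann = ann, cache = cache)
    for (st in strains)
      .writeTsv(fl[[st]], file.path(outDir,
                                    paste0("features_", st, ".tsv")))
    fl
  })

  genes <- annotatedGenes(ann)
  labels <- setNames(genes$annotation, genes$gene_id)

  refFit <- stage("train-reference", {
    training <- buildTrainingSet(feats[[ref]], labels)
    fit <- trainClassifier(training, splitFraction = config$splitFraction,
                           cvFolds = config$cvFolds, ntree = config$ntree,
                           seed = seedFor(1L))
    fit$calibration <- calibrateClassifier(fit$test$probs, fit$test$labels,
                                           fTargets = config$fTargets,
                                           degree = config$degree,
                                           fallback = "empirical")
    fit
  })

  codingCount <- function(map) {
    sites <- insertionSites(map)
    mask <- regionMask(ann)
    if (length(mask))
      sites <- sites[!overlapsAny(sites, mask, ignore.strand = TRUE)]
    sum(overlapsAny(sites, genes, ignore.strand = TRUE))
  }
  refCoding <- codingCount(maps[[ref]])

  calls <- list()
  calibrations <- list()
  stage("classify-strains", {
    for (si in seq_along(strains)) {
      st <- strains[si]
      if (st == ref) {
        model <- refFit$model
        calib <- refFit$calibration
      } else {
        target <- codingCount(maps[[st]])
        if (target < refCoding) {
          adj <- downsampleAdjust(maps[[ref]], ann, labels, target,
                                  nReps = config$downsampleReps,
                                  seed = seedFor(10L + si), cache = cache,
                                  mtry = refFit$mtry,
                                  splitFraction = config$splitFraction,
                                  ntree = config$ntree,
                                  calibArgs = list(
                                    fTargets = config$fTargets,
                                    degree = config$degree,
                                    fallback = "empirical"))
          model <- adj$fit$model
          calib <- adj$calibration
        } else {
          model <- refFit$model
          calib <- refFit$calibration
        }
      }
      calibrations[[st]] <- calib
      calls[[st]] <- classifyStrain(model, calib, feats[[st]])
    }
  })

  emat <- stage("essentiality-matrix", {
    m <- buildEssentialityMatrix(calls, ann, aneuploid = aneu,
                                 manualMasks = manualMasks, tree = tree)
    m <- rescuePolymorphic(m, calibrations)
    .writeTsv(as.data.frame(essCalls(m)),
              file.path(outDir, "essentiality_matrix.tsv"),
              rownames = TRUE)
    m
  })
  poly <- polymorphicGenes(emat)

  pars <- stage("parsimony-changes", {
    p <- imputeAndCount(emat, tree)
    .writeTsv(data.frame(gene_id = names(p$counts), changes = p$counts),
              file.path(outDir, "change_counts.tsv"))
    p
  })

  od <- stage("overdispersion", overdispersionTest(pars$counts))
  odStar <- stage("overdispersion-star",
                  overdispersionTest(starChangeCounts(pars$imputed),
                                     star = TRUE))
  alpha <- stage("gamma-shape", estimateAlpha(pars$counts))
  stage("rates-report", {
    .writeTsv(data.frame(
      statistic = c("mean_changes", "variance", "D", "df", "p",
                    "star_D", "star_p", "alpha", "alpha_capped"),
      value = c(od$mean, od$variance, od$D, od$df, od$p.value,
                odStar$D, odStar$p.value, alpha$alpha,
                as.integer(alpha$capped))),
      file.path(outDir, "rate_analysis.tsv"))
  })

  snpCtl <- stage("snp-control", {
    polyStates <- pars$imputed[intersect(rownames(pars$imputed), poly), ,
                               drop = FALSE]
    ctl <- matchedSnpControl(dataset$snps, polyStates,
                             pars$counts[rownames(polyStates)], tree,
                             nSets = config$snpSets, seed = seedFor(2L))
    .writeTsv(ctl$replicates, file.path(outDir, "snp_control.tsv"))
    ctl
  })

  corr <- stage("liability-correlations", {
    # the pair cap is applied by taking a complete block over a random gene
    # subset: complete-linkage clustering needs every within-group pair, so
    # a complete submatrix beats scattered pairs at equal budget
    maxGenes <- floor((1 + sqrt(1 + 8 * config$maxPairs)) / 2)
    corGenes <- poly
    if (length(poly) > maxGenes) {
      set.seed(seedFor(33L))
      corGenes <- sort(sample(poly, maxGenes))
      message(sprintf("[satayEvol] correlating %d of %d polymorphic genes",
                      maxGenes, length(poly)))
    }
    cm <- correlationMatrix(emat, tree, genes = corGenes,
                            mcmc = config$mcmc,
                            maxPairs = config$maxPairs,
                            seed = seedFor(3L))
    .writeTsv(cm$pairs, file.path(outDir, "correlations.tsv"))
    cm
  })

  clus <- stage("clustering", {
    cl <- clusterGenes(corr, config$heightCutoff)
    .writeTsv(data.frame(gene_id = names(cl$membership),
                         group = cl$membership),
              file.path(outDir, "gene_groups.tsv"))
    cl
  })

  conc <- NULL
  enr <- NULL
  if (!is.null(membership)) {
    conc <- stage("concordance", {
      out <- groupPairsAndCompare(corr, membership, kind = membershipKind)
      .writeTsv(out$tests, file.path(outDir, "concordance_tests.tsv"))
      out
    })
    enr <- stage("membership-enrichment", {
      det <- determinedCounts(emat) >= 2L
      gl <- rownames(essCalls(emat))[det]
      membershipEnrichment(gl %in% poly,
                           gl %in% unique(membership$gene_id))
    })
  }

  segs <- stage("segments", {
    monoEss <- names(which(
      rowSums(essCalls(emat) == "E") == determinedCounts(emat) &
        determinedCounts(emat) >= 2L &
        labels[rownames(essCalls(emat))] == "essential"))
    if (length(monoEss) < 2L) {
      list(genes = character(0))
    } else {
      profiles <- lapply(maps, segmentCounts, ann = ann, genes = monoEss,
                         cache = cache)
      cons <- consensusTolerance(profiles,
                                 minStrains = config$minStrains,
                                 minInsertions = config$minInsertions)
      .writeTsv(data.frame(gene_id = monoEss,
                           n_tolerant = cons$nTolerant),
                file.path(outDir, "segment_tolerance.tsv"))
      c(cons, list(genes = monoEss))
    }
  })

  summary <- stage("summary", {
    cl <- essCalls(emat)
    det <- determinedCounts(emat)
    s <- list(
      nGenes = nrow(cl), nStrains = ncol(cl),
      nDetermined1 = sum(det >= 1L), nComparable = sum(det >= 2L),
      nPolymorphic = length(poly),
      pctPolymorphic = polymorphismSummary(length(poly), sum(det >= 2L)),
      callRate = callRateSummary(sum(cl[, ref] != "U"),
                                 sum(cl[, ref] == "U")),
      meanChanges = od$mean, overdispersionP = od$p.value,
      alpha = alpha$alpha,
      tolerance = if (!is.null(segs$summary)) segs$summary else NULL,
      elapsedMin = as.numeric(difftime(Sys.time(), t0, units = "mins")))
    yaml::write_yaml(s, file.path(outDir, "summary.yaml"))
    s
  })

  stage("manifest", {
    yaml::write_yaml(unclass(config), file.path(outDir, "config.yaml"))
    files <- setdiff(list.files(outDir, full.names = TRUE),
                     file.path(outDir, "manifest.tsv"))
    .writeTsv(data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files))),
              file.path(outDir, "manifest.tsv"))
  })

  invisible(list(features = feats, aneuploidy = aneu, refFit = refFit,
                 calibrations = calibrations, calls = calls, matrix = emat,
                 polymorphic = poly, parsimony = pars,
                 overdispersion = od, overdispersionStar = odStar,
                 alpha = alpha, snpControl = snpCtl, correlations = corr,
                 clusters = clus, concordance = conc, enrichment = enr,
                 segments = segs, summary = summary, outDir = outDir))
}
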