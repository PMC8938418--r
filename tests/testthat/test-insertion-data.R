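test_that("reads within 2 nt on the same strand collapse to one site", {
  m <- collapseReads(data.frame(chrom = "chrI", pos = c(101, 102, 103),
                                strand = "+", reads = c(1L, 2L, 1L)),
                     strain = "s")
  s <- insertionSites(m)
  expect_length(s, 1L)
  expect_equal(start(s), 101L)
  expect_equal(s$reads, 4L)

  # gap of 3 nt separates sites
  m2 <- collapseReads(data.frame(chrom = "chrI", pos = c(101, 104),
                                 strand = "+", reads = 1L), strain = "s")
  expect_length(insertionSites(m2), 2L)

  # opposite strands never merge
  m3 <- collapseReads(data.frame(chrom = "chrI", pos = c(101, 102),
                                 strand = c("+", "-"), reads = 1L),
                      strain = "s")
  expect_length(insertionSites(m3), 2L)

  # greedy chaining: a run at spacing 2 merges end to end
  m4 <- collapseReads(data.frame(chrom = "chrI", pos = c(101, 103, 105),
                                 strand = "+", reads = 1L), strain = "s")
  expect_length(insertionSites(m4), 1L)

  expect_error(collapseReads(data.frame(chrom = "chrI", pos = -1,
                                        strand = "+", reads = 1L), "s"),
               "position")
  expect_error(collapseReads(data.frame(chrom = "chrI", pos = 5,
                                        strand = "+", reads = 0L), "s"),
               "counts")
})

test_that("collapsing is idempotent and conserves total reads", {
  set.seed(11)
  for (rep in 1:5) {
    df <- data.frame(chrom = sample(c("chrI", "chrII"), 200, TRUE),
                     pos = sample(5000L, 200, TRUE),
                     strand = sample(c("+", "-"), 200, TRUE),
                     reads = sample(10L, 200, TRUE))
    m1 <- collapseReads(df, strain = "s")
    s1 <- insertionSites(m1)
    expect_equal(sum(s1$reads), sum(df$reads))
    m2 <- collapseReads(s1, strain = "s")
    expect_equal(insertionSites(m2), s1)
  }
})

test_that("effective length subtracts masked overlap exactly", {
  g <- GenomicRanges::GRanges("chrI", IRanges::IRanges(1, 900))
  m <- GenomicRanges::GRanges("chrI", IRanges::IRanges(101, 200))
  expect_equal(as.integer(effectiveLength(g, m)), 800L)
  expect_equal(as.integer(effectiveLength(g, NULL)), 900L)

  # short gene flagged for discard
  g2 <- GenomicRanges::GRanges("chrI", IRanges::IRanges(1, 400))
  m2 <- GenomicRanges::GRanges("chrI", IRanges::IRanges(1, 150))
  e2 <- effectiveLength(g2, m2)
  expect_equal(as.integer(e2), 250L)
  expect_true(attr(e2, "discard"))

  # exact per-gene decomposition: effective + masked overlap = cds width
  set.seed(3)
  for (rep in 1:10) {
    gg <- GenomicRanges::GRanges("chrI",
      IRanges::IRanges(sample(1000, 5), width = sample(300:2000, 5)))
    mm <- GenomicRanges::reduce(GenomicRanges::GRanges("chrI",
      IRanges::IRanges(sample(3000, 8), width = sample(50:400, 8))))
    eff <- effectiveLength(gg, mm)
    for (i in seq_along(gg)) {
      ov <- sum(GenomicRanges::width(GenomicRanges::intersect(
        gg[i], mm, ignore.strand = TRUE)))
      expect_equal(GenomicRanges::width(gg)[i] - as.integer(eff)[i], ov)
    }
  }
})

test_that("aneuploidy scan flags doubled chromosomes", {
  mkMap <- function(lams, lens = rep(50000L, length(lams)), strain = "s") {
    chroms <- paste0("chr", seq_along(lams))
    df <- do.call(rbind, lapply(seq_along(lams), function(i) {
      n <- rpois(1, lams[i] * lens[i])
      data.frame(chrom = chroms[i], pos = sample(lens[i], n),
                 strand = sample(c("+", "-"), n, TRUE), reads = 1L)
    }))
    df <- df[!duplicated(df[c("chrom", "pos", "strand")]), ]
    InsertionMap(strain, df, chromLengths = setNames(lens, chroms))
  }
  mkAnn <- function(nChrom, len = 50000L)
    genomeAnnotation(
      data.frame(chrom = paste0("chr", seq_len(nChrom)), start = 1000,
                 end = 2000, strand = "+",
                 gene_id = paste0("g", seq_len(nChrom))),
      chromLengths = setNames(rep(len, nChrom),
                              paste0("chr", seq_len(nChrom))))

  set.seed(21)
  # densities (0.03, 0.031, 0.06): only the doubled chromosome flags
  m <- mkMap(c(0.03, 0.031, 0.06))
  fl <- aneuploidyScan(m, mkAnn(3))
  expect_equal(fl$chrom, "chr3")

  # uniform densities: nothing flagged (homogeneous property, 200 reps)
  falseFlags <- 0L
  for (i in 1:200) {
    fl <- aneuploidyScan(mkMap(rep(1 / 35, 3)), mkAnn(3))
    if (nrow(fl)) falseFlags <- falseFlags + 1L
  }
  expect_gte(200L - falseFlags, 198L)

  # 2x chromosome detected in >= 95% of 100 replicates
  hits <- 0L
  for (i in 1:100) {
    fl <- aneuploidyScan(mkMap(c(1 / 35, 1 / 35, 2 / 35)), mkAnn(3))
    if (identical(fl$chrom, "chr3")) hits <- hits + 1L
  }
  expect_gte(hits, 95L)

  emptyMap <- InsertionMap("s", data.frame(chrom = character(0),
                                           pos = integer(0),
                                           strand = character(0),
                                           reads = integer(0)),
                           chromLengths = c(chr1 = 1000L))
  expect_error(aneuploidyScan(emptyMap, mkAnn(1)), "zero insertions")
})

test_that("BED / GFF / newick / SNP TSV round-trips are identities", {
  tmp <- withr::local_tempdir()
  sim <- fixtureSim(nGenes = 40, nStrains = 4, seed = 5, nSnps = 50)

  bed <- file.path(tmp, "ins.bed")
  writeInsertionBed(sim$maps[[1]], bed)
  back <- readInsertionBed(bed, strainName(sim$maps[[1]]),
                           chromLengths = chromLengths(sim$annotation))
  expect_equal(start(insertionSites(back)),
               start(insertionSites(sim$maps[[1]])))
  expect_equal(insertionSites(back)$reads, insertionSites(sim$maps[[1]])$reads)

  gff <- file.path(tmp, "genes.gff3")
  mbed <- file.path(tmp, "mask.bed")
  writeGenesGff(sim$annotation, gff, maskOut = mbed)
  ann2 <- readGenesGff(gff, maskFile = mbed,
                       chromLengths = chromLengths(sim$annotation))
  g1 <- annotatedGenes(sim$annotation); g2 <- annotatedGenes(ann2)
  expect_equal(start(g2), start(g1))
  expect_equal(end(g2), end(g1))
  expect_equal(g2$gene_id, g1$gene_id)
  expect_equal(g2$annotation, g1$annotation)
  expect_equal(start(regionMask(ann2)), start(regionMask(sim$annotation)))

  nwk <- file.path(tmp, "t.nwk")
  writeStrainTree(sim$tree, nwk)
  t2 <- readStrainTree(nwk)
  expect_setequal(t2$tip.label, sim$tree$tip.label)

  # duplicated tip labels rejected
  dup <- file.path(tmp, "dup.nwk")
  writeLines("((A:1,A:1):1,B:2);", dup)
  expect_error(readStrainTree(dup), "duplicated")

  tsv <- file.path(tmp, "snps.tsv")
  writeSnpTsv(sim$snps, tsv)
  s2 <- readSnpTsv(tsv)
  expect_equal(unname(snpCalls(s2)), unname(snpCalls(sim$snps)))

  # dataset-level round trip preserves the analysis inputs
  ddir <- file.path(tmp, "ds")
  writeDataset(sim, ddir)
  back2 <- readDataset(ddir)
  expect_setequal(names(back2$maps), names(sim$maps))
  expect_equal(length(annotatedGenes(back2$annotation)),
               length(annotatedGenes(sim$annotation)))
})

test_that("container validity catches malformed objects", {
  expect_error(InsertionMap("s", data.frame(chrom = "chrI", pos = 5,
                                            strand = "+", reads = 0L)),
               "reads|counts")
  expect_error(new("EssentialityMatrix",
                   calls = matrix("X", 1, 1, dimnames = list("g", "s")),
                   probs = matrix(NA_real_, 1, 1)),
               "E, NE, U")
  m <- matrix(c(0L, 2L), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(snpMatrix(data.frame(chrom = "c", pos = 1, ref = "A",
                                    alt = "G"), m),
               "biallelic")
})
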