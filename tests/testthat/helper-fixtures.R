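# Shared fixtures, built in code and memoized across test files.

.fixtureEnv <- new.env(parent = emptyenv())

# a default-condition synthetic dataset (study conditions), cached by key
fixtureSim <- function(nGenes = 500L, nStrains = 16L, seed = 101L, ...) {
  key <- paste("sim", nGenes, nStrains, seed, sep = "_")
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- simulateSatayDataset(
      simulationConfig(nGenes = nGenes, nStrains = nStrains, ...),
      seed = seed)
  .fixtureEnv[[key]]
}

# a fixed 16-tip coalescent tree with unit total length
fixtureTree <- function(seed = 77L, n = 16L) {
  key <- paste("tree", seed, n, sep = "_")
  if (is.null(.fixtureEnv[[key]])) {
    set.seed(seed)
    tr <- ape::rcoal(n, tip.label = sprintf("S%02d", seq_len(n)))
    tr$edge.length <- tr$edge.length / sum(tr$edge.length)
    .fixtureEnv[[key]] <- tr
  }
  .fixtureEnv[[key]]
}

# one binary trait evolved by the two-state flip process (rate = expected
# events over the whole tree); resampled until polymorphic
simFlipTrait <- function(tree, rate, asChar = TRUE) {
  n <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")
  repeat {
    st <- integer(n + tree$Nnode)
    root <- ord$edge[nrow(ord$edge), 1]
    st[root] <- stats::rbinom(1, 1, 0.5)
    for (k in rev(seq_len(nrow(ord$edge)))) {
      p <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
      st[ch] <- (st[p] + stats::rpois(1, rate * ord$edge.length[k])) %% 2L
    }
    tips <- st[seq_len(n)]
    if (length(unique(tips)) > 1) break
  }
  if (asChar) setNames(ifelse(tips == 1, "E", "NE"), tree$tip.label)
  else setNames(as.integer(tips), tree$tip.label)
}

# an SNPMatrix whose sites are flip-process patterns at a given rate (for
# equal-rate null comparisons against gene states)
simFlipSnps <- function(tree, nSites, rate) {
  calls <- t(vapply(seq_len(nSites),
                    function(i) simFlipTrait(tree, rate, asChar = FALSE),
                    integer(length(tree$tip.label))))
  colnames(calls) <- tree$tip.label
  snpMatrix(data.frame(chrom = "chrS", pos = seq_len(nSites),
                       ref = "A", alt = "G"), calls)
}

# tiny hand-made annotation: one chromosome, explicit genes/mask
toyAnnotation <- function(genes, mask = NULL, chromLen = 50000L,
                          chrom = "chrI") {
  genomeAnnotation(genes, mask = mask,
                   chromLengths = setNames(chromLen, chrom))
}
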