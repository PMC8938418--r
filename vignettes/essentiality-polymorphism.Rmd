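---
title: "Methods: gene essentiality polymorphism from transposon insertion maps"
author: "satayEvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene essentiality polymorphism from transposon insertion maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Saturated transposon mutagenesis (SATAY and related Tn-seq designs) reads
out gene essentiality genome-wide: cells carrying a transposon insertion in
an essential gene die, so essential coding regions appear as insertion
deserts in the pooled sequencing of insertion junctions. When the same
assay is run across many strains of one species, genes whose essentiality
differs among strains — essentiality polymorphism — become observable at
genome scale, together with the tempo of those switches on the strain
phylogeny and their coordination across functional modules.

This package implements the full computational chain from per-strain
insertion maps to that evolutionary analysis, plus a synthetic-data
generator that reproduces the statistical structure the chain assumes, so
every stage is testable with no external downloads.

# Insertion maps and effective gene length

Aligned reads of the same orientation mapped within 2 nt are taken to come
from one transposon: `collapseReads()` chains them greedily left-to-right
(a run at positions 100, 102, 104 becomes one site at 100) because
transitive versus pairwise merging is underdetermined at this resolution;
the choice is covered by tests and read counts are conserved either way.

All densities use the *effective* gene length: CDS length minus repetitive
and unmappable positions (`effectiveLength()`). Genes with effective length
below 300 nt carry a `discard` flag and are excluded from classification.
Internally every interval is a 1-based closed `GRanges` (the Bioconductor
convention); BED input/output converts at the boundary.

Chromosome-gain aneuploidy doubles a chromosome's insertion density because
the extra copy buffers disruption of essential genes. `aneuploidyScan()`
flags chromosomes whose unmasked density is at least 1.5 times the
leave-one-out median of the strain's other chromosomes. The leave-one-out
baseline matters at small chromosome counts: with two chromosomes, a plain
median would include the doubled chromosome itself and the ratio could
never reach 1.5. Conservative manual masks (whole chromosomes or arm
intervals) are accepted alongside the automatic scan, and all affected
calls become "undetermined" rather than genuine switches.

# The nine classifier features

`geneFeatures()` computes, per gene: insertion count and density, read
count and density, the longest insertion-free stretch and its ratio to CDS
length (the freedom index), insertions within 100 nt upstream of the start
(strand-aware, both strands counted — promoter disruption is
strand-agnostic), the ratio of gene density to the density of the
surrounding 10,000 noncoding nucleotides (the neighborhood index), and the
number of insertion-free tenth-segments. Decisions the definitions leave
open, fixed here once:

* the 10,000 noncoding nt are collected walking outward, 5,000 per side,
  borrowing across sides at chromosome ends;
* a neighborhood with zero insertions gets a pseudocount density of
  0.5/window so the index stays finite and ranks empty neighborhoods
  consistently;
* the tenth-segment remainder goes to the last (3') segment; the same
  segmentation is shared with the segment-tolerance module so
  `free_tenths` always equals the number of zero-count segments there.

# Calibrated essentiality calls

A random forest (500 trees; `mtry` chosen by 10-fold cross-validation on
the training half) is trained on a stratified 50/50 split of the
deletion-annotated reference-strain genes, after removing genes on
user-supplied exclusion lists (misannotations, CDS overlaps with essential
genes, auxotrophies) — `buildTrainingSet()` logs each removal with its
first matching reason.

The forest's output is calibrated on the held-out half: outputs are cut
into 20 bins of width 0.05, the fraction of annotated-essential genes per
bin (f~ES~) is regressed on the bin midpoint with a weighted cubic
polynomial, and thresholds are the roots of f~ES~ = 0.95 and 0.05 (strict)
and 0.75/0.25 (relaxed), taking the root nearest the empirically matching
bin when several exist. Calls are E at or above the strict essential
threshold, NE at or below the nonessential one, otherwise undetermined (U).
False discovery rates at the thresholds are estimated from the held-out
labels. When the fitted curve never reaches a target the strict contract is
an error with a diagnostic; the pipeline instead requests
`fallback = "empirical"`, which takes the relevant empirical bin edge and
warns, so one degenerate strain cannot abort a multi-strain run.

Non-reference strains have shallower libraries, which deflates
insertion-based features and would inflate essential calls.
`downsampleAdjust()` therefore downsamples the reference's coding-region
insertions to each strain's observed count (100 replicates), averages the
per-gene features over replicates, and retrains/recalibrates on the
averaged features; each strain is then classified with its depth-matched
model. Adjustment applies only when the strain's count is below the
reference's.

# Polymorphism, rates, and the SNP control

`buildEssentialityMatrix()` assembles calls into a genes × strains matrix,
forcing aneuploid entries to U. A gene is polymorphic when, among at least
two determined entries, both states occur; for exactly those genes the
relaxed thresholds rescue additional U entries (`rescuePolymorphic()`).

Essentiality changes per gene are counted by two-state unit-cost Sankoff
parsimony on the rooted strain tree (`imputeAndCount()`), with undetermined
tips imputed by the same dynamic program. Ties during imputation take the
parent's state, residual root ties the nonessential (majority) state;
change counts are unaffected since all tied labelings are minimum-cost. A
star-phylogeny variant reduces to the minority-state count.

Under a single switch rate the per-gene counts would be Poisson;
`overdispersionTest()` compares D = (n−1)·variance/mean against
χ²(n−1), upper tail. Among-gene rate variation is quantified by a
negative-binomial (gamma–Poisson) maximum-likelihood fit
(`estimateAlpha()`): the mean's MLE is the sample mean, and the shape α is
profiled on a log scale with a cap at 100 reported as "no detectable
variation". Small α means strong variation.

Because introgression distorts the local phylogeny and inflates parsimony
counts, `matchedSnpControl()` compares each polymorphic gene with SNPs
whose folded minor-allele count equals the gene's minority-state count:
per replicate one matched SNP per gene is drawn, nucleotide changes are
counted with the same parsimony machinery, and a paired two-tailed Wilcoxon
signed-rank test compares the two change distributions (a pooled rank-sum
p is reported as a secondary output, since a rank-based comparison of the
two distributions could also be read as unpaired).

# Covariation under the threshold model

Coordinated essentiality switching between two genes is measured under
Felsenstein's threshold model: each gene's state in a strain is the sign of
a latent liability evolving as Brownian motion on the tree, and the
evolutionary correlation r of the pair's liabilities is the quantity of
interest. `liabilityCorrelation()` samples the posterior of r by
Gibbs-within-Metropolis MCMC — tip liabilities from their conditional
normals truncated to the observed sign, r by random walk under a
uniform(−1, 1) prior — with the sweep implemented in compiled code and
defaults of 20,000 iterations and 25% burn-in (the pipeline uses 3,000
iterations per pair, which on 16 binary tips already dominates the
posterior width; precision per pair is limited by the data, not the chain).
Strains undetermined in either gene are removed; a gene monomorphic after
removal has no information about r and errors.

Polymorphic genes are clustered by complete linkage on d = 1 − r
(sign-preserving, since concordance is the biological question), cutting
the dendrogram at a configurable height (default 0.8 on this package's
d-scale; heights from other implementations are not numerically
comparable). When the pair budget caps the computation, a complete block
over a random gene subset is estimated rather than scattered pairs:
complete linkage needs every within-group pair, so scattered estimates
with r = 0 imputation could never form a group.

Concordance with protein complexes or pathways uses the standard four
groups of gene pairs (same complex / different complexes / one member /
no member), two-tailed rank-sum comparisons of Group I against each other
group, and a one-tailed chi-squared enrichment test of polymorphism among
member genes.

# Segment tolerance inside essential genes

Each CDS is split into the same ten segments as the `free_tenths` feature.
Per strain, a gene "tolerates" insertions when some segment holds at least
two; across strains, a segment is consensus-tolerant when it has at least
one insertion in at least nine strains. Fully masked segments are
indeterminate rather than intolerant. The cohort summary reports the
fractions of monomorphic essential genes with ≥1 and ≥3 tolerant segments
and the per-segment profile, whose 3'-end excess reflects truncations late
in the coding sequence sparing most of the protein.

# The synthetic-data generator

`simulateSatayDataset()` generates the full input bundle under one master
seed. Its defaults are the study conditions and are not tuned per run:

* 16 strains on a random coalescent tree (branch lengths rescaled to sum
  to 1); 500 genes on 2 chromosomes (~1.2 Mnt), lognormal CDS lengths
  (median 1,400 nt), exponential intergenic gaps (mean 800 nt), ~10
  random masked intervals;
* insertion density λ = 1/35 per unmasked nt — the saturation the assay
  reaches; read counts 1 + geometric (mean 20);
* 20% of genes essential at the root; switch rates gamma-distributed with
  shape 0.113 (the strength of rate variation the analysis estimates on
  real data) and mean 0.17 switches per gene per tree, chosen so roughly
  10% of the independently evolving genes end up polymorphic (coupled
  modules add their own polymorphism on top, so realized fractions run
  somewhat higher);
* three coupled modules (30/12/8 genes) sharing switch-event streams with
  coupling ρ = 0.9 at rate 1.5 and a common root state, so members switch
  concordantly in the same direction — the modular covariation the
  correlation stage should detect;
* essential genes receive Poisson "leak" insertions (mean 1.5) anywhere
  plus, for the 60% of genes carrying a 3' tolerant tail (width 10% of the
  CDS, fixed per gene across strains), full-density insertions in the
  tail; together these reproduce the observed medians of a few insertions
  per essential gene versus dozens per nonessential gene;
* one chromosome-gain aneuploidy (strain S02, chr2) doubling density and
  lifting essential depletion there; the reference strain is always
  euploid, as in the real study design;
* 2,000 neutral biallelic SNPs: 90% single-mutation clade sites placed
  branch-proportionally, 10% tree-discordant "scattered" sites with a
  folded-neutral frequency, emulating introgressed or
  recombination-shuffled sites and guaranteeing that every folded
  frequency class occurs (pure clade placement can only produce classes
  equal to an existing clade size).

What the generator does *not* emulate: centromere- and nucleosome-biased
insertion preferences, sequence-level reads, within-gene essential
subdomains beyond the single 3' tail, and gene conversion. Passing tests
therefore demonstrate the statistical machinery, not robustness to those
biological nuisances.

# Problem sizes and determinism

The default end-to-end run — 16 strains × 500 genes, 100 downsampling
replicates per strain, 1,000 SNP control sets, up to 2,000 correlation
pairs at 3,000 MCMC iterations — completes in a few minutes on one CPU;
these sizes are the package's desk-scale defaults, chosen to keep the full
chain interactive. All stages derive their RNG streams from the single
`runConfig(seed=)`, and per-pair MCMC seeds are derived from the gene pair,
so results are independent of evaluation order and reruns are
byte-identical.

# Known limitations

* With 16 binary tips, each pairwise r is weakly identified; posterior
  means shrink toward zero and per-pair intervals are wide. Group-level
  contrasts (same-module versus unrelated pairs) are the reliable readout.
* The calibration polynomial is a smoother, not a monotone regression; on
  very clean data the empirical fallback can engage. A monotone (isotonic)
  alternative was deliberately not substituted to keep the published
  binning procedure.
* Parsimony counts are lower bounds on the true number of switches;
  rate-variation estimates inherit that conservatism.
* The star-phylogeny variant ignores shared ancestry entirely and is
  reported only as a robustness check.
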