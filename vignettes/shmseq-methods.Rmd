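---
title: "Models and methods behind shmseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shmseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

shmseq implements the computational core of spatial host–microbiome
sequencing (SHM-seq): an assay in which a barcoded capture array collects
both polyadenylated host transcripts and bacterial 16S rRNA V4 fragments
from a tissue section, so that microbial composition can be mapped onto
histology. This vignette explains the models the package implements, the
parameters that matter, and the choices made where the design was open.

## The capture geometry and read anatomy

The array is a 35 x 33 grid of printed spots at a 200-µm pitch (100-µm spot
diameter), of which 1,007 positions carry barcoded capture oligos. Read 1 of
a pair carries an 18-nt spatial barcode followed by a 7-nt unique molecular
identifier (UMI); read 2 is the captured 16S fragment of up to 150 nt.
`default_layout()` ships a deterministic layout: the 148 unprinted positions
are fixed as the outer border ring (132 positions) plus a 4 x 4 interior
fiducial block (16 positions), since the identity of the unprinted positions
is a printing convention rather than a property of the method. Barcodes are
generated once, deterministically, with a greedy filter enforcing pairwise
Hamming distance greater than 4 — the separation needed for demultiplexing
at up to two mismatches to be unambiguous. Real layouts load from TSV with
`load_layout()`.

## Read simulation

The capture probe, 5'-GGATTAGATACCCBDGTAGTCGAGATNB-(A20)-3', hybridizes to a
conserved flank of the 16S gene next to the V4 hypervariable region. The
20-nt poly(A) tail is the capture handle, so only the 28-nt degenerate
recognition segment is aligned. `locate_capture_site()` runs a
Smith–Waterman local alignment (match +1, mismatch −1, gap −2) of all 108
concrete expansions of the segment against a reference and keeps the best
interval (ties: highest score, then leftmost). Sites scoring below 80% of
the maximal attainable score are treated as absent and the species is
excluded from simulation, mirroring the exclusion of taxa without a usable
16S sequence.

Fragments are sampled upstream of the site: the raw length is
Normal(400, 44²) bp — the insert-size distribution characteristic of the
array chemistry — truncated below at 1 and at the available upstream span,
and the sequenced read keeps the 150 bases adjacent to the site. For
classifier training data the observed read-length distribution
Normal(143, 13²) truncated at 150 is used instead. Point mutations
(default rate 0.1%) model biological divergence from the reference;
sequencing errors (default 1% in benchmarks) are applied after shortening.
Both are uniform substitutions to a different base. Training corpora are
topped up so that every genus is seen at least 100 times.

The synthetic reference generator (`make_references()`) evolves a random
ancestral template along a balanced family→genus→species tree with a
Jukes–Cantor-style uniform substitution process (default 2% per branch).
The probe site is kept substitution-free in all species — it emulates the
conserved flank the probe targets — and genus branches receive boosted
substitution (5x) inside a variable region immediately upstream of the
site, making genera more divergent than congeneric species. This is the
simplest process that gives tunable divergence for classifier stress tests;
it does not model rRNA secondary structure, GC skew, chimeras or indels, so
passing tests demonstrate algorithmic correctness and separability behavior,
not accuracy on any real community.

## Two-stage taxonomic classification

**Stage 1: exact k-mer LCA.** `build_kmer_index()` maps every canonical
31-mer (lexicographic minimum of the k-mer and its reverse complement)
occurring in the references to the lowest common ancestor of all species
containing it. At desk scale no minimizers, spaced seeds or low-complexity
masking are needed — the contract is the LCA assignment algorithm, not any
particular tool's compression. `classify_read()` tallies the taxa hit by a
read's k-mers, scores each root-to-leaf path by the summed hits on it,
picks the best leaf (ties between leaves resolve conservatively to their
LCA), then walks up the tree while the chosen clade's k-mer support is
below `confidence` (default 0.01) times the read's k-mer count. The
genus-rank ancestor of the final node is reported; reads resolving at the
root or above genus are unclassified. Raising the confidence threshold can
only coarsen an assignment, never refine it.

**Stage 2: a convolutional/recurrent classifier.** Reads the first stage
leaves unclassified are routed to a neural network: one-hot encoding over
(A, C, G, T, N) with right-padding and masking; four parallel 1-D
convolution branches with kernel sizes 15, 17, 19 and 23 (ReLU, same
padding) to extract short motifs; concatenation; dropout 0.5; two
bidirectional LSTM layers; dropout 0.2; two dense ReLU layers; dropout 0.1
between them; and a softmax over genera. Training uses categorical
cross-entropy with Adam, an 80/20 train/test split, per-epoch shuffling,
and stops after 15 epochs or when the training loss has not decreased in 5
consecutive epochs.

The published description fixes the kernel sizes, dropout rates and layer
order but not the hidden sizes; the defaults here are 32 filters per
convolution branch, 48 recurrent units per direction per layer, and dense
widths 96 and 48. The printed total of 298,760 trainable parameters is
recorded as a calibration note only — the counts behind it are not
recoverable, and this configuration has about half as many. Convolutions
use ReLU (unstated in the source description); dropout is inactive at
prediction time. The forward and backward passes are implemented in
RcppArmadillo (`src/deepnet.cpp`); padded positions are masked in the
convolutions, carried through the LSTM state updates, and excluded from
backpropagation, which makes predictions independent of how a batch is
padded. Training is deterministic under a fixed seed and single-threaded
BLAS.

## Spatial read processing

`run_pipeline()` chains the stages in a fixed order, with exact read
accounting at each: 3' adapter trimming (suffix/prefix overlap ≥ 8 nt, ≤ 1
mismatch), a mean-quality filter (Phred ≥ 20 — the upstream pipeline's
quality rule is not restated in the source, so a simple documented mean
rule is used and exposed in the configuration), a strict length filter
(reads must be *longer than* 100 nt; a 100-nt read is removed),
demultiplexing, an optional host screen, two-stage classification, UMI
collapsing and matrix emission.

Demultiplexing retrieves candidate bank barcodes by shared 6-mers and
assigns the unique barcode within Hamming distance 2; ties are unassigned
(the referenced demultiplexer's tie behavior is unstated, and unassigned is
the conservative choice). Host removal — an alignment step in the original
protocol — is implemented as a 31-mer screen against a host k-mer set with
a 50% hit-fraction threshold, keeping the stage's contract without an
aligner dependency; a precomputed host-flag column is also accepted. UMIs
with the same barcode and genus are collapsed by connecting UMIs at Hamming
distance ≤ 1 and counting connected components (single-linkage at threshold
1), the standard directional-adjacency convention at a 7-nt UMI length.

## The hierarchical spatial model

Counts $y_{ijk}$ (taxon or gene $i$, section $j$, spot $k$) follow a
zero-inflated Poisson,
$$y_{ijk} \sim \mathrm{ZIP}(s_{jk}\lambda_{ijk},\ \theta_i),\qquad
\theta_i \sim \mathrm{Beta}(1,2),$$
with size factor $s_{jk}$ = spot total / median spot total, and a log-linear
rate
$$\log \lambda_{ijk} = B_{ijk} + \psi_{ijk} + \epsilon_{ijk}.$$

$B$ is the characteristic expression of the spot's morphological region
(MROI, one of 16 histology tags), organized hierarchically: condition-level
coefficients $\beta^{(l_1)} \sim N(0, 2^2)$ and, when a condition has
several animals, animal-level coefficients
$\beta^{(l_1,l_2)} \sim N(\beta^{(l_1)}, \sigma_{l_2}^2)$ with
$\sigma_{l_2} \sim N_{\ge 0}(0,1)$. The model is two-level when any
condition has more than one animal and one-level otherwise (the defined-flora
analysis case). $\psi$ is a conditional autoregressive (CAR) Gaussian Markov
random field over each section's 4-nearest-neighbor grid adjacency, with
precision $\tau(K - \alpha W)$, $\alpha \sim U(0,1)$,
$\tau \sim \Gamma^{-1}(1,1)$; $\epsilon$ is i.i.d. spot noise with
$\sigma_\epsilon \sim N_{\ge 0}(0, 0.3^2)$. Genes are fitted independently;
CAR parameters are not shared across genes. MROIs with no spots in a section
simply never appear in that section's design. Isolated spots (no grid
neighbors) would make the CAR precision singular, so they receive an
independent $N(0, 1/\tau)$ prior — their field value reverts toward the
prior mean.

**Inference.** Posterior sampling uses a hand-written Hamiltonian Monte
Carlo sampler with analytically derived gradients of the marginalized ZIP
likelihood (verified against numerical differentiation in the test suite).
Three reparameterizations remove the hierarchical funnels: $\epsilon =
\sigma_\epsilon u$, $\beta^{(l_1,l_2)} = \beta^{(l_1)} + \sigma_{l_2} u$,
and $\psi = \tilde\psi / \sqrt{\tau}$ with $\tilde\psi$ given the
unit-precision CAR prior. The CAR log-determinant uses the one-time
eigendecomposition of $K^{-1/2} W K^{-1/2}$, so each gradient evaluation is
linear in the number of spots plus one sparse matrix–vector product.
Warmup uses Stan-style windowed adaptation: dual-averaged step size
(target acceptance 0.8) around a diagonal metric estimated from the middle
warmup window; trajectory lengths are jittered uniformly between 10 and 24
leapfrog steps. Defaults are 4 chains of 200 iterations (100 warmup),
matching the analysis the model was designed for; split-$\hat R$ per
parameter and the divergence fraction (flagged above 10%, not fatal) are
reported in `glance()`.

On a ~320-spot, two-condition fixture drawn from the generative model, 90%
posterior intervals cover the true condition-level coefficients in over 80%
of cells (the acceptance suite recomputes this on 20 genes, about two
minutes). One caveat found while validating recovery: when the counts
matrix contains only a handful of simulated genes, computing size factors
from those same counts feeds the analyzed gene back into its own
normalizer and biases the rates. `splotch_input()` therefore accepts
precomputed size factors; with thousands of genes, as in real data, the
default self-computed factors are the standard choice.

**Testing for differences.** A contrast $\Delta_\beta = \beta_1 - \beta_2$
between two characteristic-expression cells is tested with the
Savage–Dickey density ratio $\mathrm{BF} =
p(\Delta_\beta = 0)/p(\Delta_\beta = 0 \mid \mathcal{D})$. The prior
density at zero is closed-form (difference of independent normals); the
posterior density at zero uses a normal approximation of the draws by
default — with 400 post-warmup draws, kernel-density tails are too unstable
— and a KDE option is exposed. The text's threshold "log(BF) > 0.5" is read
in base 10, consistent with how the corresponding figures are labeled, and
the DE rule is strict: flagged iff the posterior mean shift is positive and
$\log_{10}\mathrm{BF} > 0.5$. Contrasts default to condition-level
(level-1) coefficients; which level the published tables used is not
stated, so the level is an argument. A degenerate posterior (zero spread)
reports an infinite BF with a flag.

**Detection rule.** A (taxon, region) pair is called detected in the
colonized condition iff its weighted mean count in the region exceeds the
maximal weighted mean over the germ-free condition's regions for that taxon,
and the region holds more than 2% of the taxon's total count. "Weighted
mean count per region" is not defined precisely in the source; here it is
the posterior-mean rate averaged over the region's spots weighted by spot
total counts, with a uniform-weight option exposed.

## Downstream niche analysis

Spatial co-expression modules come from hierarchical clustering (average
linkage, Manhattan distance) of genes' standardized spot-expression
vectors, cut to a target number of flat clusters (28 at the published
scale). The source text is ambiguous about whether genes or the cell-to-spot
similarity matrix are clustered; clustering genes is the default and the
similarity-matrix reading is available via an argument, as is a cut-height
variant of the target-count cut. Standardization uses the sample (n−1)
standard deviation — the convention is unstated in the source — and
zero-variance genes are dropped.

Cell-type structure enters through the cell-to-spot similarity matrix
(Pearson correlation of gene-standardized profiles over common genes) and
through cluster-mean signatures scaled per gene by the maximum cluster mean.
The literal filter "average scaled expression lower than 1" would remove
almost everything after max-scaling, so the default filter removes genes
whose *pre-scaling* mean across clusters is below 1, with the literal
reading selectable. Submodules cut each module's cosine-distance average
linkage tree at 0.4 of its maximum height. Cell-type enrichment per
submodule is a two-sided Wilcoxon signed-rank test, one type versus the
mean of the rest, BH-corrected across types (submodules under 5 genes are
reported untested; the output includes the median paired difference so
direction is explicit). Gene-set enrichment is the one-tailed Fisher exact
test (hypergeometric upper tail) with BH correction and an FDR < 0.05
report threshold; sets come from GMT files.

Single-nucleus preprocessing utilities follow the conventions of the
reference atlas the signatures come from: cells with more than 800 detected
genes (strict), genes detected in at least 10 cells, cells under 30%
mitochondrial/rRNA signature, TP10K normalization, and variable-gene
selection by the largest LOESS residuals of log CV on log mean within 20
equal-frequency mean bins, combined across samples by consensus recovery.

Benchmark metrics mirror the published evaluation: pooled ("bulk-like")
accuracy; macro F1; a false-positive rate defined — since no multiclass
convention is given in the source — as misassigned classified reads over
total classified reads, so a run that classifies nothing has FPR 0; and
composition agreement (Pearson and Bray–Curtis on relative genus
abundances) over random groups of spatial spots. The fluorescence
comparison utility resamples at most three coordinates per annotated region
per sample, min-max scales within sample, pairs coordinates within
(sample, region) — matched by coordinate when both signals cover the same
spots — and averages the pooled Spearman correlation over 1,000
repetitions.

## Problem sizes and determinism

All generators are pure functions of their configuration and seed, and every
stochastic routine takes an explicit seed. The test and acceptance suites
run on synthetic communities of 3–5 genera, reads in the 5,000–20,000
range, classifier training of a few epochs (the fixtures separate well
before the 15-epoch cap), and 20-gene spatial fits on ~320 annotated spots
— sizes chosen so the whole suite completes on a single CPU in minutes
while still exercising every code path at non-trivial scale. The
paper-scale configuration (65 species from 39 genera, 500,000 training
reads, 10,924 spots) is expressible with the same functions but is not part
of the test suite.

## Known limitations

* The read simulator uses uniform substitution errors and uniform quality
  strings; no indels, chimeras, or position-dependent error profiles.
* The k-mer stage holds the index in memory as a sorted vector; it is meant
  for restricted references (tens of species), not RefSeq-scale databases.
* The negative-binomial observation variant of the count model is not
  implemented (config stub only); compositional variants are out of scope.
* The deep classifier is genus-level by design; species/strain prediction
  is out of scope.
* HMC with 400 post-warmup draws gives stable posterior means and 90%
  intervals for this model family, but tail quantiles beyond ~95% should
  not be trusted at these defaults; increase `iter`/`warmup` for those.
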