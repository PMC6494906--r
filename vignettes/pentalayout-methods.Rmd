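---
title: "Methods: multi-level organization of the GABA-A receptor subunit panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-level organization of the GABA-A receptor subunit panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentalayout)
```

## The problem

GABA-A receptors are pentameric chloride channels assembled from a pool of
19 subunit genes (six alpha, three beta, three gamma, delta, epsilon, pi,
theta, three rho). Which subunits a brain region or a single cell
transcribes constrains which receptor subtypes it can assemble, so the
*relative* transcription of the panel — not the absolute level of any one
gene — is the quantity of interest. This package provides a tested pipeline
for that analysis across three data levels: bulk regional microarray
(log2 intensities over ~111 grey-matter substructures in several subjects),
bulk RNA-Seq (linear FPKM), and single-nucleus RNA-Seq (counts per
nucleus), with a synthetic generator standing in for the public atlas
downloads.

## Containers and normalization

`ExpressionMatrix` stores genes-or-probes x samples values with an explicit
scale flag (`log2` or `linear`); all averaging is done on the stored scale
(regional microarray averages are log2 means, matching how the source atlas
reports region summaries), while every compositional quantity first passes
through `to_linear()`. `proportional_contribution()` closes each sample
over the panel: gene g's value is its percentage of the summed linear
expression of all 19 genes, so columns sum to 100 exactly. Closure makes
samples comparable across subjects and platforms, at the usual
compositional price discussed under *Limitations*.

`fold_enrichment()` compares a gene's linear-scale regional mean to its
average across regions with equal region weighting (the mean of
substructure means, not the mean over samples; the alternative weighting is
a one-line change but the equal weighting keeps the invariant that folds
average to exactly 1 per gene). Genes are then classified into three
profiles: `noise` (brain-wide mean log2 below 4 and no strong regional
enrichment), `region_specific` (brain-wide mean below 6 = 4 x 1.5 but some
region enriched at least 5-fold), and `global_high`. The log2 < 4 noise
cutoff is the only threshold inherited from the emulated study; the 1.5
band factor and the 5-fold default are artifact-defined and exposed as
arguments.

## Probe selection

Microarray panels carry several probes per gene. The selection rule is:
a single probe is kept as-is; of exactly two probes the one with the higher
mean expression wins; with three or more probes the first principal
component of the *centered, unstandardized* probe profiles is computed (no
rotation) and the probe with the largest absolute loading is chosen, ties
broken by higher mean expression and then probe id. The covariance scale is
deliberate: a probe that reports the gene's regional signal at attenuated
amplitude correlates with the faithful probe almost perfectly, so after
standardization the two have symmetric first-component loadings and the
choice between them degenerates to sampling noise. Keeping amplitude
information resolves the tie in favor of the probe with the larger signal.
`probe_consistency()` provides the complementary cross-subject check: each
probe's regional profile is correlated between every pair of subjects and
averaged; a probe tracking reproducible biology scores near 1.

## Age correction

`correct_age()` removes, per gene, a least-squares linear trend against age
(continuous mode) or one-way category means (ordinal mode, for banded-age
cohorts), returning residual + grand mean so values stay on their original
scale and remain non-negative after unlogging. Constant age yields a
warning and a pass-through rather than an error, because a single-age
subset is a legitimate (if uncorrectable) input.

## Clustering suite

Three complementary views of the same matrix:

* **Ward** (`ward_cluster`): minimum-variance agglomeration on Euclidean
  distances; merge heights are the Ward distances
  sqrt(2|A||B|/(|A|+|B|)) * ||centroid difference||, which the test suite
  pins against a brute-force enumeration oracle on all inputs of up to 7
  items.
* **Quantum clustering** (`quantum_cluster`): a Parzen wavefunction
  psi(x) = sum_i exp(-||x - x_i||^2 / 2 sigma^2) is interpreted as the
  ground state of a Schrodinger equation, giving the potential
  V(x) = E - d/2 + sum_i r_i^2 e_i / (2 sigma^2 psi); every point descends
  the analytic gradient of V and terminal positions within sigma/4 share a
  basin. Descent uses step 0.1 sigma, at most 200 iterations, convergence
  when the displacement falls below 1e-5 sigma; an uphill step is halved
  locally so the descent cannot oscillate across a narrow basin. These
  constants were chosen so the canonical two-blob benchmark (20 x SD
  separation) is stable over a full decade of sigma; they are arguments,
  not magic numbers.
* **Spectral co-clustering** (`spectral_cocluster`): bipartite biclustering
  of regions and genes — scale rows and columns by inverse square-root
  sums, take the leading singular vectors, k-means the stacked scaled
  embeddings. Real-valued input is shifted by its global minimum first,
  since the method assumes non-negative association weights.

`run_sweep()` pools quantum partitions over a sigma grid and co-clustering
partitions over a k grid (per data transform: log2 and/or proportional)
into a co-occurrence consensus: entry (i, j) is the fraction of runs in
which i and j share a cluster. Two numerical choices matter:

* Sigma grids are *relative*, as multiples of the median pairwise distance
  of the whitened embedding, and default to ten log-spaced steps over
  0.1-1.0. On a whitened embedding the median pairwise distance is set by
  the between-cluster separation, so scales at or above the median always
  return the single-cluster partition; a linear grid reaching 2 x median
  spends most of its runs on that trivial partition and drags every
  cross-group co-occurrence above the 0.5 consensus threshold. The
  informative scan lives below the median and is naturally geometric.
* `pca_whiten()` keeps the top components (default 5) and rescales each to
  unit variance. Whitening more components than the data's structural rank
  amplifies pure-noise directions to unit variance and buries the cluster
  separation — a property of whitening, not of any clustering method — so
  the consensus-recovery test on a rank-2 fixture whitens 2 components.
  On real regional data the top five components carry the large majority of
  the variance and the default is appropriate.

## Stoichiometric gating and cross-level correlation consensus

The canonical pentamer carries two alpha, two beta-position and one
odd-position subunit, predicting family sums near 40/40/20:
Sigma-alpha = alpha1..6, Sigma-beta = beta1..3 + theta,
Sigma-chi = gamma1..3 + delta + epsilon + pi; the rho genes (homomeric
receptors) are excluded and reported as Sigma-rho so the four sums
partition 100% exactly. `stoichiometric_gate()` keeps nuclei whose sums lie
inside closed windows 40±5 / 40±5 / 20±5 (closed because "±5%" reads
inclusive; the windows are arguments). `convergence_curve()` documents that
subsample means of the family sums tighten monotonically toward the
pentamer split as more nuclei are pooled.

`pairwise_correlations()` reports Pearson r with two-tailed t-based p
(df = n - 2) for every unordered pair at four observation levels:
substructures (A), bulk RNA-Seq samples (B), cell-type means (C), nuclei
within one cell type (D). `consensus_pairs()` keeps pairs significant with
the same sign in at least two analyses (raw p < 0.05 by default, with an
optional Benjamini-Hochberg flag; the emulated study reported raw p for
this table) and flags pairs that are also significant with the opposite
sign elsewhere as `both`. Within-type correlations are only attempted for
types with at least 20 gated nuclei: below that, "support" is mostly
sampling noise.

## Organizational layout and stereotypy

For one 19-gene profile, the distance between subunits x and y is
d_i(x, y) = |x - y|; over n subjects the consensus distance is
d_c(x, y) = sqrt(sum_k (x_k - y_k)^2), with no 1/n normalization — the
printed formula is implemented as-is, and the stereotypy statistic is
scale-invariant so normalization would not change it. Both give 171-entry
vectors in a fixed lexicographic pair order. Stereotypy R is the Pearson
correlation between an individual vector and a consensus vector; with a
single subject d_c reduces to d_i identically, which the suite asserts over
1,000 random profiles.

`reference_similarity()` builds the consensus from one chosen substructure
across subjects and correlates every subject x substructure individual
vector against it (whole-brain layouts use each subject's across-region
mean profile per gene; pooling all substructures into the consensus sums is
exposed as an option but not the default). `compare_to_reference()` then
runs a one-way ANOVA over structures followed by Dunnett many-to-one
contrasts against the reference. The Dunnett adjustment is computed by
simulating the null distribution of the maximum absolute many-to-one t
statistic (shared control mean, pooled chi-squared variance), which handles
unbalanced groups exactly and is itself testable: with two groups the
adjusted p converges to the ordinary pooled two-sample p, which the suite
checks. The default is 100,000 draws; the tests use 20,000-40,000 to stay
inside their time budget, at Monte-Carlo error well below the decision
threshold.

## The synthetic world

The generator encodes the study design it emulates: 6 subjects, the 111
grey-matter substructures of the packaged (synthetic) ontology, the
19-gene panel. Per gene and region, log2 expression is baseline +
log2(fold) for planted enrichments + a gene-specific regional term shared
by all subjects (`region_sd`, default 0.5 log2 units) + shared latent
factors implementing planted co-expression pairs (sign x strength x z per
pair and region) + per-subject Gaussian noise (`subject_sd`, default 0.3).
The regional term is an addition to the bare latent-factor formulation:
without it every unenriched gene is flat across regions and the probe
fixtures (shuffled-across-region variants, cross-subject consistency) and
region-clustering fixtures are degenerate. Setting `region_sd = 0`
recovers the bare formulation exactly, which the degenerate-truth test
asserts. Default baselines encode the three canonical expression profiles
(a few high-expression genes near log2 10, mid-range genes, and noise
genes near log2 3); default enrichments mirror the landmark regional
signals (a 200-fold alpha6-like cerebellar enrichment, a 31-fold
dentate-gyrus theta enrichment, 13- and 10-fold hypothalamic/amygdalar
signals).

Nuclei draw compositions from a Dirichlet (Gamma construction) around
cell-type means built on the 40/40/20 family split (within-family splits
vary deterministically across the default 76 types), with concentration
200, 10% per-gene dropout, and optional planted within-type trade-offs
applied multiplicatively before closure. What the generator does *not*
emulate: atlas normalization pipelines, batch effects, spatial
autocorrelation between neighboring substructures, and realistic
mean-variance relationships of counts. A green test therefore establishes
that the machinery recovers planted structure under honest noise — not
that the published biological values are reproduced; reproducing those
requires the real downloads, which are deliberately out of scope for the
offline build.

## Known limitations

* **Compositional closure.** Correlations of proportional contributions
  are distorted for genes that dominate the panel total: if two
  high-abundance genes rise together, closure forces their shares to
  compete and can cancel or even flip a genuine positive co-expression.
  The planted-pair recovery tests therefore plant pairs among
  moderate-contribution genes, where the planted sign survives closure;
  for dominant genes, correlations on the log2 scale are the more faithful
  readout and both inputs are supported throughout.
* **Whitening vs rank.** See the clustering section: whitening past the
  structural rank degrades separability; choose `n_components` with the
  scree in hand.
* **Consensus thresholding.** The 0.5 co-occurrence threshold splits
  connected components; with sweeps dominated by degenerate partitions it
  can chain distinct groups. The partitions are returned alongside the
  consensus precisely so this can be inspected.
* The packaged ontology is a synthetic stand-in reproducing the *shape* of
  the atlas hierarchy (111 grey-matter substructures, 22 structures, 7
  major regions, ontogenic origins, rostro-caudal ranks), not its actual
  anatomical content.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_regional(regional_truth(), seed = 1)
wb <- whole_brain_stereotypy(sim$subjects)
mean(wb$R)        # ~0.9999 at the default subject_sd = 0.3
ref <- reference_similarity(sim$subjects, "FL.FrOp", sim$ontology)
cmp <- compare_to_reference(ref, "FL", n_sim = 2e4, seed = 1)
cmp$anova
```
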