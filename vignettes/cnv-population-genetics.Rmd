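---
title: "CNV-based population genetics from array log R ratios: methods and design"
author: "cnvpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV-based population genetics from array log R ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cnvpopgen` turns probe-by-sample log R ratio (LRR) matrices from SNP
genotyping arrays into population-genetic results based on copy number
variation (CNV): multi-sample segmentation, three-state CNV genotyping,
non-redundant region calling, biallelic recoding of deletions, genetic
distances, ordination and trees, maximum-likelihood admixture, and Vst scans
for lineage-differentiated regions. A synthetic cohort generator with
recorded truth makes every stage testable without array data.

```{r, eval = FALSE}
library(cnvpopgen)
sim <- simulateCohort(SimConfig())
lrr <- gcCorrect(sim$lrr)
seg <- segmentGenome(lrr, SegConfig(seed = 1))
regions <- filterByFrequency(mergeRegions(seg))
geno <- recodeDeletions(regions)
```

# The intensity model and GC correction

LRR is a normalized log2 intensity ratio: about 0 at two copies, strongly
negative under deletion, mildly positive under duplication. Array intensities
carry long-range "waves" correlated with regional GC content. `gcCorrect`
removes them by per-sample ordinary least squares of LRR on the panel's probe
GC fraction (a loess mode handles curvature), subtracting the fit and adding
back the sample mean. For the linear mode the corrected sample is exactly
orthogonal to GC and the operation is idempotent, which the tests assert to
1e-9. A constant GC track is rejected as a degenerate design. Commercial
pipelines ship proprietary GC correction files; regression on the panel's own
GC track reproduces the stated goal — removing GC waviness — with a fully
specified, testable operation.

Missing LRR cells are imputed with the per-probe median when under 5% of a
probe's values are missing, otherwise the probe is dropped; chromosome labels
are opaque tokens filtered against a configurable autosome list (default
`"1".."29"`, the cattle autosomes, keeping the tool species-agnostic).

# Multi-sample segmentation

Chromosomes are partitioned into segments with breakpoints *shared across all
samples* (deletions common to many animals produce aligned steps; shared
breakpoints are what allows a segment to be genotyped across the cohort).
`bestSplit` finds the split maximizing the reduction in pooled
within-segment sum of squared deviations,

$$ T(k) \;=\; \mathrm{SSE}(\text{block}) - \mathrm{SSE}(\text{left}_k) -
\mathrm{SSE}(\text{right}_k), $$

summed over samples, with ties broken toward the smallest index. Whether a
split is real is decided by a permutation test: probe order is shuffled
*identically across samples* — preserving the per-probe cross-sample
covariance, so only positional contiguity is destroyed — and
$p = (1 + \#\{\text{perm max } T \ge T_{obs}\}) / (1 + n_{perm})$. Splits
with $p \le 0.01$ under 1,000 permutations (both configurable in
`SegConfig`) are accepted and recursion continues on both halves; every
segment keeps at least `min_probes` (default 3) probes.

One refinement matters in practice. When a single block contains **two** CNV
loci, the best *single* split can be unimpressive (both halves retain high
within-variance) even though splits inside each half are overwhelming; a
pure accept/stop rule then abandons both loci. The recursion therefore uses a
one-level lookahead: a rejected split is still emitted when either half's own
best split tests significant, after which normal recursion re-finds the
interior breakpoints. On pure noise this costs at most two extra tests per
rejected block, so the expected false-breakpoint rate stays near
$3\,p_{threshold}$; the suite measures it at about 2% over 200 noise-only
chromosomes against a 5% bound.

Numerical notes: statistics are computed from per-sample cumulative sums
(exact, no subtraction of large squares per probe), clipped at zero;
a constant block reports statistic 0 and no split; the permutation stream is
seeded per chromosome so segmentations are reproducible; during recursion the
permutation loop stops early once significance is impossible, which leaves
accepted p-values exact and merely shortens rejections.

# Three-state genotyping and CNV regions

Per-sample segment means are genotyped by the symmetric threshold rule: mean
$\le -0.3$ is a loss, $\ge +0.3$ a gain, else neutral (`CallConfig`,
boundary inclusive — a convention the caller must fix; inclusivity is chosen
and documented). Segments with any non-neutral sample become candidates;
candidates on one chromosome whose probe-index spans overlap or touch are
unioned into non-redundant regions. Within a merged region a sample's state
comes from the constituent segment with the largest absolute mean, and the
region's type is `loss`/`gain` when all non-neutral sample states agree,
otherwise `mixed`. Regions with carrier frequency strictly above 1% are
retained and re-identified `CNV1..CNVn` by descending frequency (ties by
chromosome and start). Internally coordinates are 1-based inclusive base
pairs of the first/last probe; BED export converts to 0-based half-open.

Deletion regions are recoded as biallelic markers: a loss is `"12"` (the
deletion event), anything else `"22"`, with a 0/1 dosage view. This mirrors
the practice of treating high-confidence deletions as biallelic markers so
that the mature SNP toolbox applies. Heterozygous deletions are *not* called
separately: real LRR histograms of common deletions typically show two peaks
(near 0 and near −1) and no reliable universal heterozygote threshold, so a
single loss state is used. The generator nevertheless simulates
Hardy-Weinberg heterozygotes (mean −0.5), which the ±0.3 rule folds into the
loss call — the decision's consequences are therefore measurable in the
tests rather than hidden.

A boundary case worth knowing: with the generator's default duplication mean
(+0.3) equal to the calling threshold, a duplication carrier's segment mean
falls on the decision boundary and is genotyped essentially at chance. This
reproduces a real property of array CNV calling — duplications are
substantially harder to genotype than deletions — and it is why the package's
accuracy claims, like every downstream analysis, are stated for deletion
CNVs.

# Population structure on deletion markers

**Relatedness.** With the one-state coding only two identity-by-state
classes are observable per marker (codes match or differ), so the classical
three-equation moment estimator of IBD sharing collapses: `piHat` estimates
$P(\mathrm{IBD}=0)$ as the observed mismatch count over its expectation
under independence, $\sum_l 2 f_l (1-f_l)$, assigns the residual to
$P(\mathrm{IBD}=2)$ (the middle state is not identifiable from binary
markers) and reports $\hat\pi = P_1/2 + P_2$, clamped to $[0,1]$. Duplicates
score near 1, independent pairs near 0; close relatives are attenuated but
remain far above the 0.4 removal threshold. `relatednessFilter` removes, from
the worst pair, the member with the larger mean sharing, deterministically.

**Distance.** `ibsDistance` implements
$D = 1 - (\mathrm{IBS2} + 0.5\,\mathrm{IBS1})/N$; with codes limited to
`{"12","22"}` any mismatching pair still shares the `"2"` allele, so IBS0
cannot occur and $D \le 0.5$ by construction. $D$ is a dissimilarity, not a
guaranteed metric; the suite asserts bounds, symmetry and the zero diagonal
rather than the triangle inequality.

**Ordination and trees.** `classicalMDS` is Torgerson scaling (double-center
$-D^2/2$, top eigenpairs, coordinates scaled by $\sqrt{\lambda}$) with each
coordinate's sign fixed so its largest-magnitude loading is positive —
eigenvector signs are otherwise arbitrary and would break reproducibility.
Fewer positive eigenvalues than requested dimensions yield fewer coordinates
with a warning. `njTree` performs Saitou-Nei neighbor joining (negative
branch estimates clamped at zero and counted); on additive distances it
reproduces all path lengths exactly, which the suite checks to 1e-9 on
random trees. `hierCluster` clusters mean-LRR profiles with Euclidean
distance and average linkage (exposed via `linkage=`; dendrogram defaults
differ between tools and no single choice is canonical).

**Admixture.** `admixtureFit` maximizes the standard admixture likelihood

$$ \ell(Q, F) = \sum_{i,l} x_{il} \log \textstyle\sum_k q_{ik} f_{kl}
  \;+\; (c - x_{il}) \log \sum_k q_{ik} (1 - f_{kl}) $$

by expectation-maximization, with $Q$ rows on the simplex and $F \in [0,1]$.
Each deletion marker contributes a single allele draw ($c = 1$), matching
the one-state coding; $c = 2$ serves standard biallelic data. EM is run from
several seeded starts and the best final likelihood wins; the trace is
non-decreasing every iteration (asserted on every fit in the test suite;
probabilities are clamped at 1e-12 inside logarithms only). A Bayesian MCMC
treatment with correlated allele frequencies would model uncertainty more
fully; maximum likelihood with restarts was chosen because it is
deterministic per seed, fast at desk scale, and directly testable — with
three moderately diverged groups, 200 markers and ten admixed individuals it
recovers ancestry proportions with mean absolute error well under 0.08 after
label alignment.

# Vst differentiation scans

For a region and two groups, with per-individual region mean LRRs,

$$ V_{ST} = \frac{V_T - V_S}{V_T}, $$

where $V_T$ is the variance of the pooled values and $V_S$ the size-weighted
mean of the within-group variances. Population variances (denominator $n$)
are the default: by the law of total variance this guarantees
$V_{ST} \in [0,1]$, with 0 meaning no differentiation and 1 complete
fixation of different intensity classes. An `unbiased = TRUE` switch uses
$(n-1)$ variances, which can go slightly negative and is reported unclamped.
$V_T = 0$ regions are degenerate: $V_{ST} = 0$ with a flag, never counted as
differentiated. $V_{ST}$ is computed on the continuous region means, not on
the discretized states, and is invariant to shifting or rescaling the
intensities. In pairwise comparisons $V_S$ is averaged within the two
compared groups (a breed-level alternative is available via `by = "breed"`);
flags use strict thresholds $> 0.4$ and $> 0.6$, and
`uniqueDifferentiated` takes the set union of flagged region ids across
comparisons.

Gene annotation reports every (region, gene) pair overlapping by at least
1 bp under half-open boundary semantics: a region ending exactly where a
gene starts does not overlap. BED input is 0-based half-open, GFF3 1-based
inclusive; both are normalized on import. `geneOverlapContrast` summarizes
gene-overlapping versus gene-free regions (count, mean, SEM of length and
carrier frequency) and runs Welch two-sample t-tests;
`welchTestSummary` exposes the same test computed from class summaries
(mean, SEM, N) alone.

# The synthetic cohort: what it emulates, and what it does not

`SimConfig` defaults define the package's standard study conditions, a
desk-scale analogue of a multi-breed bovine array cohort:

| parameter | default | meaning |
|---|---|---|
| groups / breeds / animals | 3 × 2 × 8 (+6 hybrids) | three ancestral lineages, breeds nested within them, admixed individuals between them |
| panel | 5 chromosomes × 400 probes, 2 kb spacing | uniform probe grid with a smooth sinusoidal GC track |
| CNV loci | 20, spanning 10–30 probes, 70% losses | multi-probe events placed non-overlapping with a 5-probe buffer |
| differentiated loci | 10 deletion loci at frequencies (0.9, 0.05) | group 1 versus the rest; the targets of the Vst scan |
| drift | Balding-Nichols F = 0.15 (group), 0.05 (breed) | hierarchical allele-frequency divergence |
| intensity | means (0, −0.5, −1.2, +0.3) for 2/1/0/3 copies; noise sd 0.1; GC wave amplitude 0.2 | per-probe Gaussian noise around copy-state means |

Genotypes are Hardy-Weinberg draws at breed allele frequencies; hybrids draw
at frequencies mixed by a flat-Dirichlet ancestry (admixture proportions of
real hybrid breeds are rarely quantified, and the flat composition exercises
the whole simplex). Duplication loci are collapsed to carrier/non-carrier.
Everything is deterministic given the seed, and the truth set (locus spans,
per-sample copy states, breed frequencies, ancestry) is returned alongside
the data.

The generator deliberately omits: B-allele frequencies (the pipeline is
LRR-only), linkage disequilibrium between loci, probe-density variation,
batch effects beyond the single GC wave, and genotyping error other than
Gaussian intensity noise. Passing tests therefore demonstrate correctness of
the algorithms under a clean generative model — not calibration against real
array chemistry, where per-state LRR distributions are wider, asymmetric and
platform-dependent.

Problem sizes used by the test-suite and the acceptance script (the standard
cohort, a 200-marker admixture cohort, 200 noise-only chromosomes of 100
probes) were chosen as the smallest instances at which every statistical
property under test is comfortably away from its sampling noise.

# Known limitations

* Duplications are detected but genotyped only as carrier/non-carrier, and at
  the default simulation settings sit on the calling boundary (see above);
  they are excluded from marker-based analyses by design.
* `piHat` underestimates intermediate relatedness (parent-offspring) because
  binary markers cannot separate IBD 1 from IBD 2; it is a removal screen,
  not a kinship estimator.
* The Vst scan tests differentiation, not selection: drift, bottlenecks and
  founder effects produce high values without selection, so flagged regions
  are candidates only.
* Greedy recursive splitting is not guaranteed to be the global minimal-SSE
  partition for arbitrary inputs; the oracle tests cover the
  piecewise-constant regime the method is designed for, plus
  single-breakpoint instances where the exhaustive and greedy answers
  coincide by construction.
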