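---
title: "Coexpression modules, differential coexpression, and regulomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression modules, differential coexpression, and regulomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulomix)
```

## The scientific problem

Drug-resistant structural epilepsies (temporal lobe epilepsy with
hippocampal sclerosis, focal cortical dysplasias, tuberous sclerosis
complex) are studied as separate pathologies, yet their resected brain
tissue may share transcriptional programs. regulomix implements a
network-level comparison of such multi-cohort bulk RNA-seq studies: it
discovers gene coexpression modules independently in each patient cohort,
asks whether each module's internal correlation differs between disease and
control tissue (differential coexpression), annotates modules with pathway
and cell-type gene sets, predicts upstream regulators from a signed
regulatory knowledge base, and finally clusters modules *across* cohorts
into "regulomes" — shared regulatory programs — classified by how they
behave in disease versus control tissue.

Because the real study's data are a controlled-access clinical resource,
the package ships a synthetic-data generator that plants every kind of
structure the pipeline is supposed to find. All validation in the test
suite and in `scripts/acceptance.R` is against this planted ground truth or
against exact combinatorial oracles.

## Preprocessing

Counts pass three standard steps:

* **Detection filter.** A gene is kept if at least 20% of samples show at
  least 6 counts *within every cohort*. The source conventions for this
  rule disagree on "every cohort" versus "any cohort"; the stricter
  per-every-cohort reading is the default and a `scope = "any"` flag
  switches to the laxer one.
* **TMM scaling.** The trimmed mean of M-values is implemented from its
  published definition (reference sample = upper-quartile fraction closest
  to the mean; two-sided trims of 0.30 on M and 0.05 on A; inverse
  approximate binomial variances as weights; factors rescaled to product
  one). The test suite cross-checks it against the independent edgeR
  implementation.
* **log2-CPM.** `log2((count + 0.5) / (lib * factor + 1) * 1e6)`, the
  transform used by voom (cross-checked against limma).

Before network construction, genes must show a raw median absolute
deviation of at least 0.25 (no 1.4826 consistency constant; the threshold
is inclusive).

## Module discovery

Per cohort (disease samples only; cohorts with 20 or fewer disease samples
are refused):

1. Spearman dissimilarity `1 - rho` over all gene pairs.
2. Signed soft-thresholded adjacency `A = ((1 + rho)/2)^6`, with `1 - A`
   as the clustering distance. The signed form keeps anti-correlated genes
   apart; an `signed = FALSE` flag provides the unsigned `|rho|^6`
   alternative.
3. Ward (`ward.D2`) clustering, scanning K = 1...200. For each K the
   fraction of variance explained, `R2(K) = 1 - WSS/TSS`, is computed on a
   classical-MDS embedding of the distance (positive-eigenvalue axes,
   truncated at 50 dimensions — the structure relevant to cluster sums of
   squares lives in the leading axes). K is selected at the largest
   absolute discrete second difference of the curve — the inflection point.
4. Leave-one-out stability: the whole dissimilarity-to-K pass is re-run
   once per sample; the co-clustering fraction of every gene pair forms a
   similarity matrix S. By default K is re-selected in every iteration
   (`k_policy = "fixed"` reuses one K).
5. Junk removal: per iteration, the cluster with the lowest mean
   within-cluster adjacency is the "junk" cluster, *provided* it is less
   cohesive than the matrix-wide mean adjacency (the cohesion floor, on by
   default, protects data in which every cluster is tight). Genes sitting
   in the junk cluster in at least 50% of iterations (inclusive) are
   removed.
6. Consensus modules: Ward on `1 - S` over the remaining genes, K by the
   same inflection rule.
7. Over/under splitting: each module's eigengene (first principal
   component of the gene-standardised disease submatrix, sign fixed to
   correlate non-negatively with the module mean profile) partitions member
   genes by the sign of their correlation with it; each part is suffixed
   `o` or `u` by the sign of its mean disease-minus-control expression.

### Why the R2 curve is not smoothed by default

An earlier design called for a 5-point running-mean smoothing of the R2
curve before taking second differences. On planted data the elbow of the
curve is a single-K spike in the second difference; any averaging both
dilutes the spike and drags the argmax one K early (planted K = 5 was
reported as 4, costing two planted modules to the junk cluster). The
default is therefore `smooth_window = 1` (no smoothing); the window remains
configurable for noisy curves. The smoother that is available uses edge
replication, because a window that shrinks at the boundary fabricates
curvature at `k_min`.

### What the junk rule can and cannot do

The junk module is defined operationally (the method's source never defines
it): lowest mean intramodular adjacency per iteration, with the cohesion
floor. When one planted module is much weaker than the scanned structure
(e.g. two small anti-correlated halves next to a dominant module), the
inflection rule may select a K at which the weak structure shares a cluster
with the background and is junked with it. The discovery benchmark
(`benchmark_module_recovery`) plants four modules of comparable strength
and recovers them essentially perfectly; weaker, subordinate structure is
genuinely at risk — a property of the method, not of this implementation.

## Differential coexpression and conservation

The module statistic is the **median pairwise squared Spearman
correlation** (a Pearson flag exists). Differential coexpression compares
disease and control arms: `delta = median R2(disease) - median R2(control)`,
with a two-sided permutation null obtained by relabelling samples
(arm sizes preserved; default 10,000 permutations) and the +1-smoothed
empirical p-value `(1 + #{|delta*| >= |delta|}) / (n_perm + 1)`, which can
never be exactly zero. Permutation streams are seeded per module
(`derive_seed(global_seed, module_id)`), so results do not depend on
execution order or parallel scheduling.

**Conservation** of a module in another cohort cannot permute a two-arm
label (there is only one arm), so the null redraws random gene sets of the
same size from the target cohort's expressed genes; the one-sided empirical
p asks whether the module's coexpression exceeds what arbitrary gene sets
achieve there. At least half the module's genes must be measurable in the
target cohort.

**Eigengene-phenotype association** is ordinary least squares of the
eigengene on a covariate with a two-sided t-test on its slope; when the
covariate is disease duration and age is available, age is added as an
adjustment covariate automatically, since duration is confounded with age.

## Enrichment and upstream regulators

Enrichment is the upper-tail hypergeometric test with all expressed genes
as the universe, computed in log space, with Benjamini-Hochberg correction
applied within each collection across *all* (query, set) tests performed.
Query genes missing from the universe are dropped with a warning rather
than erroring, because public gene-set collections routinely contain
unmeasured genes.

The regulator-prediction stage reasons over a two-layer signed knowledge
base: transcription factors and miRNAs carry direct signed edges onto
genes; cell-membrane receptor proteins (CMPs) act on genes through
canonical two-layer paths CMP -> TF -> gene whose sign is the product of
the edge signs ("unspecified" anywhere makes the path unspecified;
conflicting defined paths to the same gene are "ambiguous"). Each regulator
with at least 3 expressed targets is tested for overlap with each module by
the same hypergeometric kernel (a CMP's overlap set counts all composed
targets regardless of sign), with BH correction across all regulator-module
tests. A direction ("activates"/"inhibits") is called when the majority
sign covers at least 60% of the signed overlapping edges — the source
reports single-direction calls without stating its dominance rule, so 60%
is this package's declared operationalisation (configurable). Duplicate
curated edges with conflicting signs collapse to "unspecified" with a
warning rather than silently picking a side. miRNA regulators are exempt
from the regulator-expression requirement because miRNAs are not measured
in a poly-A mRNA assay.

## Regulomes

All modules from all cohorts are compared by the inclusion index
`|x ∩ y| / min(|x|, |y|)`, clustered by Ward on `1 - inclusion`, with the
number of clusters maximising the mean silhouette width over
K = 2...min(n-1, 40). The cap of 40 comfortably exceeds the plausible
number of shared programs at this scale. If every pair of modules is
disjoint the silhouette is undefined and each module becomes its own
regulome, with a warning.

A regulome's **intersect genes** are those occurring in at least one member
module of every cohort represented in it (union for single-cohort
regulomes). Classification applies four rules in a declared precedence
order (the source describes the classes verbally; the precedence and
thresholds here are this package's operationalisation, all configurable):

1. **pathology_specific** — members from a single cohort (or maximal
   inclusion with other-cohort modules below 0.3) and at least one member
   differentially coexpressed;
2. **activated** — at least one member differentially coexpressed and no
   member's coexpression conserved in control tissue;
3. **enhanced** — at least one member differentially coexpressed with
   positive delta and at least one member conserved in control tissue;
4. **constitutive** — everything else.

## Sample-level structure

`sample_dendrogram()` builds a Ward tree on the top principal components
(cumulative variance >= 80%, configurable). `dapc()` performs PCA reduction
followed by linear discriminant analysis with equal priors per cohort —
cohort sizes reflect sampling, not prevalence — returning posterior
memberships and the prior-versus-assigned reassignment matrix.
`optimize_a_score()` chooses the PC count by the a-score: observed
reassignment proportion minus its mean over random relabelings (10 by
default), which penalises the overfitting that inflates apparent
discrimination as PCs accumulate.

## The synthetic-data generator

Each planted module is driven by one latent Gaussian factor per arm. A
member gene's latent value is `sgn * a * f + sqrt(1 - a^2) * e` (sign -1
for "under" genes), exponentiated into a lognormal mean, scaled
compositionally so each sample's expected total equals its lognormal
library size, and observed through a negative binomial (dispersion 0.05 by
default — a typical bulk RNA-seq value; library mean 2e6 at desk scale).
"Under" genes additionally have their baseline halved in disease samples,
"over" genes doubled (fold change 2), so the o/u labelling has a planted
truth.

The loading `a` is calibrated numerically (one `uniroot` solve per module
and arm) against a closed-form map from loading to expected count-scale
Spearman correlation with three attenuation terms: the Gaussian
Pearson-to-Spearman conversion `(6/pi) asin(rho/2)`, the observation-noise
variance `1/depth + dispersion` of the negative binomial on the log scale,
and the compositional weight of the module in the library (normalising by
the library total subtracts the fraction of the module factor that the
total carries). The generator's own tests confirm realised median pairwise
Spearman r2 within 0.1 of the target in each arm at 100 samples, and the
calibration is strictly monotone in the target.

Background genes are independent, with a smaller latent standard deviation
(0.4 versus 1.0 for module genes) and a large aggregate library mass, so
that each module stays a small fraction of the transcriptome as in real
data; this is what keeps compositional normalisation from eroding planted
correlations. What the generator deliberately does **not** emulate: batch
effects, isoform structure, gene-length bias, sample outliers, and
correlated background programs. Passing the planted-recovery benchmarks
therefore demonstrates correctness of the machinery under the stated model,
not robustness to every artefact of real tissue data.

Decoy regulators and decoy gene sets are drawn on a seed stream offset from
the cohort generator's by fixed namespace keys, so adding decoys never
perturbs the expression draw.

## Problem sizes and levels used in validation

The validation suite and `scripts/acceptance.R` use these study sizes,
chosen as the smallest designs at which each stage's behaviour is
cleanly measurable:

* module recovery: 4 modules (25-50 genes, r2 = 0.7), 200 background
  genes, 30 + 30 samples, 20 runs; success is adjusted Rand >= 0.8
  against the planted partition;
* differential coexpression: 200 random null modules spread over 10
  independently generated studies (modules drawn from one study share
  samples and genes, so their outcomes are correlated and a single-study
  rejection rate estimates the level with high variance) and 50 planted
  replicates (delta = 0.5), 500 permutations at alpha = 0.05;
* regulator recovery: one planted TF against 50 decoys, 100 knowledge-base
  replicates;
* regulome classification: one regulome per class across two 40 + 40
  cohorts, 300 permutations per test, 50 replicates. The class rules are
  applied at alpha = 0.005 in this benchmark: the joint four-label decision
  consults roughly seven member-level tests, and a Bonferroni-style
  per-test tightening of 0.05 keeps the family-wise error of the joint
  decision low. The classification default elsewhere remains 0.05.
* the regulome benchmark evaluates classification on the planted module
  memberships rather than re-running discovery, so classification error is
  not confounded with discovery error; discovery has its own benchmark.

## Numerical and degenerate-input conventions

* Ties in Spearman ranks use average ranks; Ward merges are deterministic
  given input order, and the final partitions are invariant to gene and
  sample order (tested).
* A constant gene is an error naming the gene wherever correlation is
  undefined; genes constant only within a leave-one-out subset are excluded
  from the stability matrix with a warning.
* Empirical p-values are +1-smoothed and can reach at most
  `1/(n_perm + 1)`.
* An R2(K) curve with no curvature (e.g. all-identical objects) falls back
  to `k_min` with a warning; an all-disjoint module set falls back to one
  regulome per module with a warning.
* Eigengene sign is fixed against the module mean profile; negating the
  stored loadings does not change returned scores.

## Known limitations

* The inflection rule inherits the scale-selection behaviour of second
  differences: structure much weaker than the dominant modules can be
  absorbed into the junk cluster (see above).
* The conservation null (random gene sets) answers "is this module more
  coexpressed than arbitrary genes there", which is weaker than a matched
  two-arm permutation; with a single target arm no two-arm null exists.
* CMP significance pools all paths through all TFs; per-path resolution is
  out of scope.
* The pipeline starts at a gene-level count matrix; read-level processing,
  outlier-sample removal and batch correction are upstream concerns.
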