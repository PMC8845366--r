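---
title: "Functional epigenetic module discovery with cell-type deconvolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{femnet methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femnet)
```

# The problem

In bulk tissue, disease-associated changes in DNA methylation (DNAm) are
confounded twice over: genuine per-cell epigenetic changes are diluted and
distorted by shifts in cell-type composition, and single-locus tests pay a
heavy multiple-testing price across hundreds of thousands of CpGs. femnet
addresses both at once. It searches for *functional epigenetic modules*
(FEMs): connected subgraphs of a protein--protein-interaction (PPI) network
in which promoter DNAm and gene expression change together, in opposite
directions, between cases and normals -- the canonical signature of
epigenetic gene silencing (promoter hypermethylation with underexpression)
or derepression. Cell-type composition is estimated from the methylome
itself by reference-based deconvolution and enters every differential model
as a covariate, so that module statistics reflect within-cell-type change
rather than shifting tissue make-up.

# The model, step by step

## Promoter summarization

Probe-level beta values (in $[0,1]$) are summarized per gene with a strict
region-class precedence: the mean over TSS200 probes if any exist, else the
mean over first-exon probes, else the mean over TSS1500 probes
(`summarizePromoters()`). These regions are where DNAm is most reliably
anti-correlated with expression, which is exactly the pattern the module
statistic rewards. The class used and the probe count are recorded per gene.

## Cell-type deconvolution

A DNAm reference matrix is built from purified profiles by one-vs-rest
moderated-t comparisons (limma), keeping CpGs with BH FDR $< 0.05$ and an
absolute difference in mean beta above a per-comparison threshold (default
0.9; real references relax individual comparisons slightly, e.g. to 0.875,
which the `deltaThresh` argument supports per cell type). Fractions are then
estimated per sample by robust partial correlations: a Huber robust
regression (tuning constant 1.345, with intercept) of the sample's betas on
the reference profiles, with negative coefficients truncated to zero and
the rest renormalized to sum to one (`estimateFractionsRPC()`). Betas are
used on their natural scale, following the reference-based deconvolution
literature. The packaged `syntheticReference()` is a synthetic stand-in
built from `simulatePureProfiles()`; it exists to exercise the layer
end-to-end and is not meant for real methylomes.

## Differential statistics

`moderatedT()` fits, per gene, value ~ group + covariates by least squares
and shrinks residual variances with the empirical-Bayes inverse-gamma model
of limma; cell-type fractions enter as covariates. Because fractions sum to
one, the final fraction column is dropped (absorbed by the intercept) --
the paperwork of an identifiable parameterization, not a modeling choice
with consequences. With a per-gene copy-number covariate the models are
refit gene by gene and the same shrinkage is applied; `cnvRobustness()`
summarizes how much the group statistics move. Cell-type *specific*
differential methylation (`cellTypeSpecificDMG()`) uses the
fraction-by-disease interaction model: value ~ all fractions + all
fraction-by-case terms, without a global intercept (the fraction main
effects span it); the interaction coefficient for cell type $k$ estimates
the disease effect inside that cell type, tested with moderated t and BH
FDR per cell type.

## The integrated statistic and the spin-glass search

Per gene, with $t_{DM}$ and $t_{DE}$ the differential methylation and
expression statistics,
$$t^{(I)} = \left\{H(t_{DM})\,H(-t_{DE}) + H(-t_{DM})\,H(t_{DE})\right\}\,
  |t_{DM} - t_{DE}|,$$
where $H$ is the Heaviside step with $H(0) = 0$: the statistic is positive
only for strictly anti-correlated change. Edges carry the mean of their
endpoints' statistics, $w_{gh} = 0.5\,(t^{(I)}_g + t^{(I)}_h)$. A module
$M$ is scored by the spin-glass Hamiltonian restricted to its unordered
member pairs,
$$\mathcal H(M) = -\sum_{g<h \in M}\left(w_{gh} - \gamma\, p_{gh}\right),
  \qquad p_{gh} = \frac{w_{g\cdot} w_{h\cdot}}{2W},$$
with $w_{g\cdot}$ the weighted degree, $W$ the total edge weight and
$p_{gh}$ the configuration-model null expectation (the standard
normalization of the "null probability" in weighted spin-glass community
detection). Non-edges inside the module contribute only the null penalty.
If $W = 0$ every energy is defined to be zero and nothing grows.

Modules are grown greedily from seed genes (the top `nSeeds = 100` genes by
$t^{(I)}$): at each step the adjacent gene giving the largest energy
decrease is added; growth stops when no addition decreases the energy. Ties
are broken lexicographically by gene id, so results are bit-reproducible.
The recorded energy sequence is strictly decreasing, and the incremental
update used during growth agrees with full recomputation to $10^{-10}$
(tested). Modules outside the size range $[10, 100]$ are discarded
($\gamma = 0.5$ typically lands grown modules in this range on PPI-scale
networks). Significance is assessed by a Monte-Carlo randomization: the
node statistics are permuted over the network (topology fixed), edge
weights re-derived, and the module's size-normalized modularity
($-\mathcal H(M)/|M|$, our ranking statistic; the size normalization makes
modules of different sizes comparable) recomputed on the fixed membership,
with $p = (1 + \#\{\text{runs} \ge \text{observed}\})/(1 + \text{runs})$
over 1000 runs. Overlapping survivors (Jaccard $> 0.5$) are deduplicated
keeping the lower-energy module, and members are flagged DM / DR / DM&DR /
anti-correlated at a configurable gene-level FDR (default 0.05).

Two properties of the greedy grower are worth knowing. First, a neighbour
whose weighted degree is concentrated in its edges into the module is
always absorbed when $\gamma \le$ its concentration ratio -- so grown
modules typically include a thin ring of adjacent genes around a true
community, and singleton results occur only for seeds whose incident edges
all carry zero weight. Second, growth is additions-only (no removals or
swaps), matching the deterministic growth the method prescribes; the
exhaustive-enumeration oracle in the test suite confirms the greedy energy
never beats the true optimum and attains it on strongly planted instances.

## FEM-scores in independent cohorts

For validation cohorts, each gene significant in discovery is z-scored
against the cohort's own normal samples, $z_{gs} = (x_{gs} -
\mu_{gN})/(\sigma_{gN} + \gamma_0)$, and the module score is the signed
average $\mathrm{score}_{ms} = |m|^{-1} \sum_{g \in m}
\mathrm{Sign}(t_g)\, z_{gs}$ with discovery signs. We use the population SD
(divisor $n$): with as few as 5--6 normals the choice visibly changes
scores, and the population form is the maximum-likelihood scale for the
reference group. The offset $\gamma_0$ (default 0) guards against
spuriously small normal SDs when normals are few; `calibrateOffset()`
chooses it by root finding so that the genome-wide SD of DNAm z-scores
equals that of the RNA z-scores (to $10^{-6}$; clamped at zero with a
warning when the target exceeds what is achievable). Cohorts with both
modalities use the joint score $|m|^{-1}\sum_g |z^{(M)}_{gs} -
z^{(R)}_{gs}|$ over the anti-correlated discovery genes: opposite-direction
deregulation drives the two z-scores apart, so the score is nonnegative and
zero only when the modalities agree exactly. Single-cell expression is
scored the same way after restricting the signature to genes with nonzero
variance across the scored cells; modules with fewer than 5 variable genes
are declared unscoreable, a cutoff taken from the observed behaviour of
dropout-heavy Smart-Seq2 data. Surrogate-tissue (saliva-like) cohorts reuse
the signed score with healthy controls as the normal reference and ordered
stage labels. Group separation is tested with a one-tailed Wilcoxon
rank-sum test (exact below a combined $n$ of 25 without ties; otherwise the
normal approximation with continuity and tie correction) and summarized by
AUC $= U/(n_1 n_2)$; `scoreWithCovariateAdjustment()` refits score ~ group
+ epithelial fraction to check that separation is not composition-driven.

# The synthetic benchmark

`simulationConfig()` fixes the study conditions for the generator family;
the defaults are the package's benchmark and are not tuned per run.

* **Network** (`simulateNetwork()`): a preferential-attachment backbone of
  1000 genes (attachment 10, mean degree about 20, comparable to curated
  PPI resources), with three planted modules of 35 genes each. Planted
  modules are *insulated cliques*: internal density 1, original external
  edges rewired into the background (degree-preserving) and a single
  boundary edge retained per module. This is the strong regime of a
  planted-partition benchmark.

  Why so strong? With $\gamma = 0.5$ and the within-module Hamiltonian, a
  grown module stops absorbing background genes only once its share of the
  network's weighted degree makes the null penalty exceed typical boundary
  edge weights. Three equal 35-cliques carrying the planted signal sit
  comfortably above that resolution; smaller or sparsely connected planted
  modules (e.g. 15 genes at density 0.9 with several boundary edges) fall
  below it and the grower over-absorbs -- a genuine resolution limit of the
  seeded spin-glass at this $\gamma$, which users should expect on real
  networks too, where modules are not cliques and recovery is accordingly
  noisier. The generator exposes all of these dials
  (`plantedSizes`, `internalDensity`, `boundaryEdges`, `attachment`) so the
  regime can be weakened deliberately.

* **Cohort** (`simulateCohort()`): 50 cases and 50 controls. True fractions
  are Dirichlet(6, 2, 2) over epithelial/fibroblast/immune (epithelial-
  dominated, as in tumors). Per gene and cell type a baseline promoter beta
  is drawn (planted genes start hypomethylated, 0.1--0.3, so the planted
  gain fits in range); cases shift planted genes by $\Delta\beta = 0.3$ in
  the *epithelial component only*, and their expression by $-1$ log unit
  (anti-correlated). The observed gene beta is the fraction-weighted
  mixture with logit-normal noise (SD 0.2 on the logit scale, roughly 0.05
  in beta units mid-range; the logit construction keeps betas strictly
  inside $(0,1)$). Gene values are exploded to 2 TSS200 + 1 first-exon + 1
  TSS1500 probes with logit jitter (SD 0.02); TSS1500 probes sit at a
  shifted baseline so the summarization precedence is actually exercised.
  The planted marker CpGs are included as measured rows, so the cohort can
  be deconvolved from its own array. Expression is baseline + effect +
  Gaussian noise (SD 1). An optional CNV covariate can be independent of or
  confounded with the group.

* **Purified profiles** (`simulatePureProfiles()`): 5 samples per cell
  type; 50 markers per type, half hypermethylated (0.975 vs 0.025), half
  hypomethylated, planted difference about 0.95; 350 shared non-marker
  CpGs; logit noise SD 0.15. The hyper/hypo mix matters: an all-hyper
  design makes the reference columns sum to a constant and the RPC design
  collinear with its intercept.

* **Saliva-like cohort** (`simulateSalivaCohort()`): stages N/NDBE/HGD/C
  with 65/33/14/51 samples; the mean epithelial fraction rises
  0.25 to 0.45 across stages and the designated module shifts by 0.1 per
  stage step in the epithelial component only.

* **Single cells** (`simulateScrna()`): 4 patients, 147 BE-like and 112
  normal cells each, signature shift 1 log unit, Gaussian noise, negative
  values clipped at zero, Bernoulli dropout 0.6 by default.

What the generator does *not* emulate: probe-level QC artifacts, batch and
platform effects, correlated noise between modalities, realistic PPI motif
structure, immune-subtype heterogeneity, or count-based single-cell noise
(dropout is plain Bernoulli on log values). Passing the benchmark therefore
demonstrates correctness of the machinery and recoverability under the
stated conditions -- not performance on real cohorts.

# Numerical choices and degenerate inputs

* Ties in greedy growth and seeding: lexicographic gene id; improvement
  threshold $10^{-12}$ (strict decrease required).
* $H(0) = 0$: genes with a zero statistic never contribute to $t^{(I)}$.
* $W = 0$ (all-null statistics): all energies zero; no growth.
* Monte-Carlo p uses the add-one form, so its floor is $1/(1+\text{runs})$.
* Constant genes in differential models: $t = 0$, $p = 1$, with a warning;
  zero residual df is an error. Variance shrinkage falls back to ordinary
  t (with a warning) when fewer than 10 genes are available.
* RPC: all-zero truncated coefficients are an error ("sample not
  representable"); below 90% reference-CpG coverage a warning, below 50%
  an error.
* Offset calibration brackets the root by doubling and solves to
  $10^{-6}$; an unattainable target clamps to zero with a warning.
* All randomness flows from explicit integer seeds; the generator derives
  stable per-stage child seeds so adding one simulated artifact never
  perturbs another.

# Problem sizes used in the shipped checks

The test-suite and the acceptance script run the discovery pipeline on the
default 1000-gene fixture (about 10 s), the exhaustive Hamiltonian oracle
on 100 graphs of at most 12 nodes, null calibration on 3000 genes, 100
replicates of the cell-type-specific model, and the scoring suites on the
cohort sizes above. These sizes give stable pass/fail behaviour across
seeds while keeping a full run near half a minute; they are the package's
chosen benchmark scale, and every threshold asserted in the tests was fixed
before the suite was frozen.

# Known limitations

* The spin-glass resolution limit at $\gamma = 0.5$ discussed above: weakly
  connected or small true modules are over-grown rather than isolated.
* Greedy growth is additions-only; a removal/swap pass could tighten module
  boundaries but is deliberately out of scope to match the deterministic
  growth procedure.
* The Monte-Carlo test evaluates a module's membership as given; for
  modules *grown on the same statistics* the test is anti-conservative
  under the global null (selection bias). In the full pipeline this is
  mitigated by the size filter, which discards the degenerate giant
  modules that greedy growth produces on null data; users applying
  `mcSignificance()` to hand-picked gene sets are unaffected.
* Reference-based deconvolution inherits the reference's scope: cell types
  missing from the reference are apportioned to the closest available
  profiles.
* The packaged reference is synthetic, for pipeline exercise only.
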