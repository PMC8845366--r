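# femnet

Functional epigenetic module (FEM) discovery with cell-type deconvolution,
for epigenomics researchers analysing matched DNA methylation and gene
expression from heterogeneous bulk tissue.

Instead of testing CpGs one at a time, femnet searches a protein–protein
interaction network for connected gene modules in which promoter DNA
methylation and expression change *in opposite directions* between cases
and normals — the signature of epigenetic silencing or derepression — while
adjusting every differential statistic for cell-type composition estimated
from the methylome itself. Discovered modules can then be scored as
per-sample activation signatures in independent bulk, single-cell and
surrogate-tissue (saliva-like) cohorts.

## The statistic at the core

Per gene, with moderated t-statistics of differential methylation and
expression,

    t_int = { H(t_DM) H(-t_DE) + H(-t_DM) H(t_DE) } * |t_DM - t_DE|,  H(0) = 0

so `t_int > 0` only for anti-correlated change. Each network edge is
weighted `w_gh = 0.5 (t_int_g + t_int_h)`, and a candidate module `M` is
scored by the spin-glass Hamiltonian over its member pairs

    H(M) = - sum_{g<h in M} ( w_gh - gamma * p_gh ),   p_gh = wdeg_g wdeg_h / (2W)

with `gamma = 0.5` by default. Modules are grown greedily from the
top-ranked seed genes, filtered to 10–100 genes, tested by a 1000-run
Monte-Carlo randomization of the statistics over the fixed topology, and
deduplicated. Supporting layers: promoter summarization with strict
TSS200 → 1stExon → TSS1500 precedence; reference-based cell-fraction
estimation by Huber robust regression (RPC); limma-moderated differential
statistics with fractions as covariates; a fraction-by-disease interaction
model for cell-type-specific differential methylation; and z-score-based
FEM-scores (signed-average, joint |z_M − z_R|, and a single-cell variant
with a variable-gene gate).

## Worked example

Everything below is synthetic, generated with known ground truth (three
planted anti-correlated 35-gene modules in a 1000-gene network, 50 cases
vs 50 controls, epithelial/fibroblast/immune mixtures):

```r
library(femnet)

cfg <- simulationConfig(rngSeed = 7)
net <- simulateNetwork(cfg)
coh <- simulateCohort(net$network, net$truth, cfg)

pm <- summarizePromoters(coh$beta, coh$annotation)
#> PromoterMethylation: 1000 genes x 100 samples
#>   region classes used: TSS200=1000

pure <- simulatePureProfiles(cfg)
ref  <- buildReferenceMatrix(pure$beta, pure$labels)
fr   <- estimateFractionsRPC(coh$beta, ref)
round(head(fr, 3), 3)
#>        Epi   Fib    IC
#> s001 0.842 0.079 0.079
#> s002 0.517 0.381 0.102
#> s003 0.637 0.228 0.135

gs <- computeGeneStats(pm, coh$expr, coh$sampleSheet, fr, net$network)
#> GeneStats over 1000 genes; 110 DM and 111 DE at FDR<0.05; 564 with positive t_int

wnet <- weightNetwork(net$network, gs)
mods <- inferModules(wnet, gs, SpinGlassConfig(rngSeed = 7))
mods
#> FemModuleSet of 3 modules
#>   g0143 (n=38, mod=335, p=0.000999)
#>   g0180 (n=36, mod=349, p=0.000999)
#>   g0896 (n=36, mod=346, p=0.000999)
```

The three reported modules are the three planted ones (Jaccard 0.97, 0.92,
0.97 against the ground truth); each is significant at the Monte-Carlo
floor 1/1001. Scoring the first module's methylation signature in an
independent synthetic validation cohort separates cases from normals
perfectly:

```r
sigs <- moduleSignatures(mods, gs, "meth")
val  <- simulateCohort(net$network, net$truth, simulationConfig(rngSeed = 99))
pmV  <- summarizePromoters(val$beta, val$annotation)
grp  <- setNames(val$sampleSheet$group, val$sampleSheet$sample_id)
z    <- zscoreVsNormals(betaValues(pmV), names(grp)[grp == "normal"])
sc   <- femScoreSigned(z, sigs[[1]], moduleId = names(sigs)[1], groups = grp)
unlist(evaluateScores(sc, "case"))
#>    wilcoxonP          auc           n1           n2
#> 3.533036e-18 1.000000e+00 5.000000e+01 5.000000e+01
```

`runFemPipeline()` orchestrates the same stages (simulate → summarize →
deconvolve → diffstats → modules → score → evaluate) from a YAML/JSON
config with per-stage provenance records, and `femReport()` tabulates
per-module flag counts and evaluation metrics. The methods vignette
(`vignettes/femnet-methods.Rmd`) documents the model, the synthetic
benchmark's design and its limitations.

A note on upstream QC: the package expects preprocessed beta matrices
(detection-P filtering, removal of cross-reactive/SNP probes, imputation
and type-2 bias correction are assumed done upstream, as in standard
450k/EPIC pipelines); readers validate completeness and range only.

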