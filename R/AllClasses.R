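#' @import methods
NULL

# region classes accepted for promoter summarization, in precedence order
REGION_CLASSES <- c("TSS200", "FirstExon", "TSS1500")

#' Promoter-level DNA methylation with summarization provenance
#'
#' Gene-by-sample matrix of mean promoter beta values, together with a record
#' of which Illumina region class (TSS200, then FirstExon, then TSS1500) was
#' used for each gene and how many probes contributed.
#'
#' @slot beta numeric matrix, genes x samples, values in [0,1].
#' @slot provenance data.frame with columns \code{gene}, \code{region_class},
#'   \code{n_probes}, one row per gene, aligned to \code{rownames(beta)}.
#' @exportClass PromoterMethylation
setClass("PromoterMethylation",
  representation(beta = "matrix", provenance = "data.frame"))

setValidity("PromoterMethylation", function(object) {
  b <- object@beta
  if (any(!is.finite(b))) return("beta contains non-finite values")
  if (any(b < 0 | b > 1)) return("beta values must lie in [0,1]")
  if (!identical(rownames(b), object@provenance$gene))
    return("provenance rows must align with beta rownames")
  if (!all(object@provenance$region_class %in% REGION_CLASSES))
    return("unknown region class in provenance")
  TRUE
})

#' Per-gene differential statistics aligned to a gene network
#'
#' Holds the differential-methylation and differential-expression moderated
#' t-statistics for every gene of the analysis universe, their p-values and
#' BH-adjusted FDR, and the nonnegative integrated statistic that rewards
#' anti-correlated methylation/expression change.
#'
#' @slot stats data.frame with columns \code{gene}, \code{t_dm}, \code{p_dm},
#'   \code{fdr_dm}, \code{t_de}, \code{p_de}, \code{fdr_de}, \code{t_int}.
#' @exportClass GeneStats
setClass("GeneStats", representation(stats = "data.frame"))

setValidity("GeneStats", function(object) {
  s <- object@stats
  need <- c("gene", "t_dm", "p_dm", "fdr_dm", "t_de", "p_de", "fdr_de", "t_int")
  if (!all(need %in% names(s))) return("missing required stat columns")
  if (anyDuplicated(s$gene)) return("duplicate gene ids")
  if (any(s$t_int < 0)) return("integrated statistic must be nonnegative")
  bad <- sign(s$t_dm) == sign(s$t_de) & s$t_int != 0
  if (any(bad)) return("t_int must be 0 when t_dm and t_de agree in sign")
  TRUE
})

#' Edge-weighted gene network for spin-glass module search
#'
#' An undirected simple graph whose edges carry the average of the incident
#' genes' integrated statistics. Weighted degrees and the total edge weight
#' are cached, together with adjacency indices used by the greedy grower.
#'
#' @slot nodes character vector of gene ids.
#' @slot edges integer matrix (m x 2) of node indices, first column < second.
#' @slot weights numeric vector of edge weights, \code{0.5*(tInt[g]+tInt[h])}.
#' @slot tInt numeric per-node integrated statistic.
#' @slot wdeg numeric per-node weighted degree.
#' @slot deg integer per-node degree.
#' @slot totalWeight numeric, sum of all edge weights.
#' @slot adj list of integer vectors: neighbours of each node.
#' @slot adjEdges list of integer vectors: incident edge indices per node.
#' @exportClass WeightedNetwork
setClass("WeightedNetwork",
  representation(nodes = "character", edges = "matrix", weights = "numeric",
                 tInt = "numeric", wdeg = "numeric", deg = "integer",
                 totalWeight = "numeric", adj = "list", adjEdges = "list"))

setValidity("WeightedNetwork", function(object) {
  n <- length(object@nodes)
  m <- nrow(object@edges)
  if (length(object@weights) != m) return("one weight per edge required")
  if (length(object@tInt) != n || length(object@wdeg) != n)
    return("per-node slots must match node count")
  if (m > 0) {
    w <- 0.5 * (object@tInt[object@edges[, 1]] + object@tInt[object@edges[, 2]])
    if (max(abs(w - object@weights)) > 1e-8)
      return("edge weights inconsistent with node statistics")
  }
  TRUE
})

#' Configuration of the seeded spin-glass module search
#'
#' @slot gamma positive resolution parameter of the Hamiltonian (default 0.5).
#' @slot nSeeds number of top-ranked seed genes to grow from.
#' @slot sizeMin,sizeMax retained module size range.
#' @slot mcRuns Monte-Carlo randomization runs for module significance.
#' @slot alpha significance level on the Monte-Carlo p-value.
#' @slot rngSeed integer seed governing all randomization.
#' @exportClass SpinGlassConfig
setClass("SpinGlassConfig",
  representation(gamma = "numeric", nSeeds = "integer", sizeMin = "integer",
                 sizeMax = "integer", mcRuns = "integer", alpha = "numeric",
                 rngSeed = "integer"))

setValidity("SpinGlassConfig", function(object) {
  if (object@gamma <= 0) return("gamma must be positive")
  if (object@sizeMin > object@sizeMax) return("sizeMin must be <= sizeMax")
  if (object@mcRuns < 100L) return("mcRuns must be at least 100")
  if (object@alpha <= 0 || object@alpha > 1) return("alpha must be in (0,1]")
  TRUE
})

#' Constructor for \linkS4class{SpinGlassConfig}
#'
#' @param gamma spin-glass resolution parameter; 0.5 typically yields modules
#'   of 10-100 genes on PPI-scale networks.
#' @param nSeeds number of seed genes (top-ranked by integrated statistic).
#' @param sizeMin,sizeMax size range of retained modules.
#' @param mcRuns Monte-Carlo runs for the randomization test.
#' @param alpha retained modules must have Monte-Carlo p below this level.
#' @param rngSeed integer seed for the Monte-Carlo randomization.
#' @return A \linkS4class{SpinGlassConfig} object.
#' @export
SpinGlassConfig <- function(gamma = 0.5, nSeeds = 100L, sizeMin = 10L,
                            sizeMax = 100L, mcRuns = 1000L, alpha = 0.05,
                            rngSeed = 1L) {
  new("SpinGlassConfig", gamma = gamma, nSeeds = as.integer(nSeeds),
      sizeMin = as.integer(sizeMin), sizeMax = as.integer(sizeMax),
      mcRuns = as.integer(mcRuns), alpha = alpha,
      rngSeed = as.integer(rngSeed))
}

#' A functional epigenetic module
#'
#' A connected gene set grown from a seed gene by greedy minimization of the
#' spin-glass Hamiltonian, with its final energy, size-normalized modularity,
#' Monte-Carlo p-value and per-member differential flags.
#'
#' @slot seed seed gene id.
#' @slot members character vector of member gene ids (includes the seed).
#' @slot energy final Hamiltonian energy (lower is better).
#' @slot modularity size-normalized negative energy, \code{-energy/|members|}.
#' @slot mcP Monte-Carlo p-value (NA until computed).
#' @slot energyTrace energy after each accepted growth step.
#' @slot flags data.frame of per-member flags \code{dm}, \code{dr},
#'   \code{dmdr}, \code{anticorrelated} (empty until annotated).
#' @exportClass FemModule
setClass("FemModule",
  representation(seed = "character", members = "character", energy = "numeric",
                 modularity = "numeric", mcP = "numeric",
                 energyTrace = "numeric", flags = "data.frame"))

setValidity("FemModule", function(object) {
  if (!(object@seed %in% object@members)) return("seed must be a member")
  if (anyDuplicated(object@members)) return("duplicate members")
  TRUE
})

#' A collection of functional epigenetic modules
#'
#' @slot modules list of \linkS4class{FemModule} objects.
#' @exportClass FemModuleSet
setClass("FemModuleSet", representation(modules = "list"))

setValidity("FemModuleSet", function(object) {
  if (!all(vapply(object@modules, is, logical(1), "FemModule")))
    return("all elements must be FemModule objects")
  TRUE
})

#' DNA methylation reference matrix for cell-type deconvolution
#'
#' Marker-CpG by cell-type matrix of mean beta values in purified profiles,
#' with a per-CpG record of which one-vs-rest comparison selected it.
#'
#' @slot ref numeric matrix, marker CpGs x cell types, values in [0,1].
#' @slot selectedBy character vector naming, per CpG, the cell-type
#'   comparison(s) that selected it (comma separated when several).
#' @exportClass ReferenceMatrix
setClass("ReferenceMatrix",
  representation(ref = "matrix", selectedBy = "character"))

setValidity("ReferenceMatrix", function(object) {
  if (any(object@ref < 0 | object@ref > 1)) return("beta values must be in [0,1]")
  if (length(object@selectedBy) != nrow(object@ref))
    return("one provenance entry per CpG required")
  if (anyDuplicated(rownames(object@ref))) return("duplicate CpG ids")
  TRUE
})

## show methods -------------------------------------------------------------

setMethod("show", "PromoterMethylation", function(object) {
  cat("PromoterMethylation:", nrow(object@beta), "genes x",
      ncol(object@beta), "samples\n")
  cat("  region classes used:",
      paste(sprintf("%s=%d", names(table(object@provenance$region_class)),
                    table(object@provenance$region_class)), collapse = ", "),
      "\n")
})

setMethod("show", "GeneStats", function(object) {
  s <- object@stats
  cat("GeneStats over", nrow(s), "genes;",
      sum(s$fdr_dm < 0.05), "DM and", sum(s$fdr_de < 0.05),
      "DE at FDR<0.05;", sum(s$t_int > 0), "with positive t_int\n")
})

setMethod("show", "WeightedNetwork", function(object) {
  cat("WeightedNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges, total weight",
      format(object@totalWeight, digits = 6), "\n")
})

setMethod("show", "FemModule", function(object) {
  cat("FemModule seeded at", object@seed, ":", length(object@members),
      "genes, modularity", format(object@modularity, digits = 4))
  if (!is.na(object@mcP)) cat(", MC p =", format(object@mcP, digits = 3))
  cat("\n")
})

setMethod("show", "FemModuleSet", function(object) {
  cat("FemModuleSet of", length(object@modules), "modules\n")
  for (m in object@modules)
    cat(sprintf("  %s (n=%d, mod=%.3g, p=%.3g)\n", m@seed, length(m@members),
                m@modularity, m@mcP))
})

setMethod("show", "ReferenceMatrix", function(object) {
  cat("ReferenceMatrix:", nrow(object@ref), "marker CpGs x",
      ncol(object@ref), "cell types (",
      paste(colnames(object@ref), collapse = ", "), ")\n")
})

setMethod("show", "SpinGlassConfig", function(object) {
  cat(sprintf(
    "SpinGlassConfig: gamma=%g, nSeeds=%d, size [%d,%d], mcRuns=%d, alpha=%g, seed=%d\n",
    object@gamma, object@nSeeds, object@sizeMin, object@sizeMax,
    object@mcRuns, object@alpha, object@rngSeed))
})
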