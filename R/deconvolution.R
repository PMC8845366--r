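#' Build a DNAm reference matrix from purified cell-type profiles
#'
#' For each cell type a one-vs-rest moderated-t comparison (that cell type's
#' purified samples against all others pooled) is performed with \pkg{limma};
#' CpGs with BH FDR below \code{fdrThresh} and an absolute difference in mean
#' beta above the comparison's delta threshold are selected as markers. The
#' union of markers over all comparisons defines the reference matrix, whose
#' entries are the within-cell-type mean betas; each CpG records which
#' comparison(s) selected it.
#'
#' @param pure probe x sample beta matrix of purified profiles.
#' @param labels cell-type label per sample (length = ncol(pure)).
#' @param fdrThresh BH FDR threshold (default 0.05).
#' @param deltaThresh minimum absolute difference in mean beta; either a
#'   single value (default 0.9) or a named vector with one entry per cell
#'   type, allowing a relaxed threshold for individual comparisons.
#' @return a \linkS4class{ReferenceMatrix}.
#' @export
buildReferenceMatrix <- function(pure, labels, fdrThresh = 0.05,
                                 deltaThresh = 0.9) {
  checkNumericMatrix(pure, "purified beta matrix")
  labels <- as.character(labels)
  if (length(labels) != ncol(pure))
    stopf("need one cell-type label per purified sample")
  types <- sort(unique(labels))
  if (length(types) < 3) stopf("need at least three cell types")
  if (any(table(labels) < 2)) stopf("need >=2 samples per cell type")
  if (length(deltaThresh) == 1)
    deltaThresh <- stats::setNames(rep(deltaThresh, length(types)), types)
  if (!all(types %in% names(deltaThresh)))
    stopf("deltaThresh must name every cell type")

  selected <- list()
  for (ct in types) {
    isCt <- labels == ct
    design <- cbind(Intercept = 1, ct = as.numeric(isCt))
    fit <- limma::eBayes(limma::lmFit(pure, design))
    fdr <- stats::p.adjust(fit$p.value[, "ct"], "BH")
    delta <- rowMeans(pure[, isCt, drop = FALSE]) -
      rowMeans(pure[, !isCt, drop = FALSE])
    hit <- fdr < fdrThresh & abs(delta) > deltaThresh[ct]
    if (!any(hit))
      stopf("comparison '%s vs rest' selected no CpGs (FDR < %g, |delta| > %g)",
            ct, fdrThresh, deltaThresh[ct])
    selected[[ct]] <- rownames(pure)[hit]
  }
  cpgs <- sort(unique(unlist(selected)))
  ref <- vapply(types, function(ct)
    rowMeans(pure[cpgs, labels == ct, drop = FALSE]), numeric(length(cpgs)))
  rownames(ref) <- cpgs
  selBy <- vapply(cpgs, function(cg)
    paste(types[vapply(types, function(ct) cg %in% selected[[ct]],
                       logical(1))], collapse = ","), character(1))
  new("ReferenceMatrix", ref = ref, selectedBy = unname(selBy))
}

#' Estimate cell-type fractions by robust partial correlations
#'
#' Per sample, the beta values over the reference CpGs are regressed onto the
#' reference cell-type profiles by robust linear regression (Huber loss,
#' tuning constant 1.345, with intercept); negative coefficients are
#' truncated to zero and the remainder renormalized to sum to one. Beta
#' values are used on their natural [0,1] scale.
#'
#' @param beta probe x sample beta matrix of the mixtures to deconvolve.
#' @param reference a \linkS4class{ReferenceMatrix} (or plain CpG x cell-type
#'   matrix).
#' @return samples x cell-types matrix of fractions (rows sum to 1).
#' @export
estimateFractionsRPC <- function(beta, reference) {
  ref <- if (is(reference, "ReferenceMatrix")) referenceProfiles(reference)
         else reference
  checkNumericMatrix(beta, "beta matrix")
  common <- intersect(rownames(ref), rownames(beta))
  cover <- length(common) / nrow(ref)
  if (cover < 0.5)
    stopf("only %.0f%% of reference CpGs present in the data (need >=50%%)",
          100 * cover)
  if (cover < 0.9)
    warnf("only %.0f%% of reference CpGs present in the data", 100 * cover)
  R <- ref[common, , drop = FALSE]
  B <- beta[common, , drop = FALSE]
  out <- matrix(NA_real_, ncol(B), ncol(R),
                dimnames = list(colnames(B), colnames(R)))
  for (s in seq_len(ncol(B))) {
    fit <- suppressWarnings(
      MASS::rlm(B[, s] ~ R, psi = MASS::psi.huber, k = 1.345, maxit = 100))
    co <- pmax(fit$coefficients[-1], 0)
    if (sum(co) <= 0)
      stopf("sample '%s' is not representable by the reference", colnames(B)[s])
    out[s, ] <- co / sum(co)
  }
  out
}
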