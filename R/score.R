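#' Module signatures from discovery statistics
#'
#' Derives, per module, the signed gene signature used for validation
#' scoring: for the chosen modality, the genes that were significantly
#' differential in the discovery cohort together with the sign (+1/-1) of
#' their discovery t-statistic. For \code{modality = "joint"} the signature
#' is restricted to genes that are significant in both modalities with
#' anti-correlated directions.
#'
#' @param modules a \linkS4class{FemModuleSet} with annotated flags.
#' @param stats the discovery \linkS4class{GeneStats}.
#' @param modality one of "meth", "expr", "joint".
#' @param sigThresh discovery FDR threshold (must match the annotation one).
#' @return named list (by module seed) of data.frames with columns
#'   \code{gene} and \code{sign} (for "joint": \code{sign_meth},
#'   \code{sign_expr}).
#' @export
moduleSignatures <- function(modules, stats, modality = c("meth", "expr", "joint"),
                             sigThresh = 0.05) {
  modality <- match.arg(modality)
  s <- statTable(stats)
  out <- list()
  for (m in as.list(modules)) {
    i <- match(moduleMembers(m), s$gene)
    ok <- !is.na(i)
    dm <- ok & s$fdr_dm[i] < sigThresh
    de <- ok & s$fdr_de[i] < sigThresh
    sig <- switch(modality,
      meth = {
        g <- moduleMembers(m)[dm]
        data.frame(gene = g, sign = sign(s$t_dm[match(g, s$gene)]))
      },
      expr = {
        g <- moduleMembers(m)[de]
        data.frame(gene = g, sign = sign(s$t_de[match(g, s$gene)]))
      },
      joint = {
        anti <- dm & de & sign(s$t_dm[i]) == -sign(s$t_de[i]) & s$t_dm[i] != 0
        g <- moduleMembers(m)[anti]
        data.frame(gene = g,
                   sign_meth = sign(s$t_dm[match(g, s$gene)]),
                   sign_expr = sign(s$t_de[match(g, s$gene)]))
      })
    out[[moduleSeed(m)]] <- sig
  }
  out
}

#' z-score a matrix against its normal samples
#'
#' Standardizes each gene using the mean and standard deviation estimated
#' over the normal/healthy samples of the cohort:
#' \eqn{z_{gs} = (x_{gs} - \mu_{gN}) / (\sigma_{gN} + \mathrm{offset})}.
#' The population form of the standard deviation (divisor \eqn{n}) is used,
#' which matters with the small normal counts typical of validation cohorts.
#' Genes whose denominator is zero are dropped with a warning.
#'
#' @param mat gene x sample matrix (betas or log expression).
#' @param normalIds sample ids forming the normal reference (>= 2).
#' @param offset nonnegative constant added to the normal standard
#'   deviation; see \code{\link{calibrateOffset}}.
#' @return z-score matrix over the same samples (possibly fewer genes).
#' @export
zscoreVsNormals <- function(mat, normalIds, offset = 0) {
  checkNumericMatrix(mat, "matrix")
  normalIds <- intersect(normalIds, colnames(mat))
  if (length(normalIds) < 2) stopf("need >=2 normal samples for z-scoring")
  if (offset < 0) stopf("offset must be nonnegative")
  N <- mat[, normalIds, drop = FALSE]
  mu <- rowMeans(N)
  sdev <- sqrt(rowMeans((N - mu)^2))  # population SD
  denom <- sdev + offset
  drop <- denom == 0
  if (any(drop)) {
    warnf("%d gene(s) with zero SD over normals dropped", sum(drop))
    mat <- mat[!drop, , drop = FALSE]
    mu <- mu[!drop]; denom <- denom[!drop]
  }
  (mat - mu) / denom
}

#' Signed-average FEM-score
#'
#' Scores module activation per sample as the average of the sample's gene
#' z-scores, each multiplied by the discovery sign of the gene:
#' \eqn{\mathrm{score}_{ms} = |m|^{-1} \sum_{g \in m} \mathrm{Sign}(t_g) z_{gs}},
#' over the signature genes present in the z-matrix. A high score means the
#' sample deviates from the normal state in the direction seen in discovery.
#'
#' @param z z-score matrix from \code{\link{zscoreVsNormals}}.
#' @param signature data.frame with columns \code{gene}, \code{sign} (one
#'   element of \code{\link{moduleSignatures}}).
#' @param moduleId module identifier carried into the result.
#' @param groups optional named group label per sample.
#' @return data.frame: sample_id, module_id, score, n_genes_used, group.
#' @export
femScoreSigned <- function(z, signature, moduleId = "module", groups = NULL) {
  g <- intersect(signature$gene, rownames(z))
  if (length(g) == 0) {
    warnf("module %s: no signature gene present; skipped", moduleId)
    return(NULL)
  }
  sg <- signature$sign[match(g, signature$gene)]
  sc <- colSums(z[g, , drop = FALSE] * sg) / length(g)
  data.frame(sample_id = colnames(z), module_id = moduleId, score = sc,
             n_genes_used = length(g),
             group = if (is.null(groups)) NA_character_ else
               as.character(groups[colnames(z)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Calibrate the DNAm z-score variance offset
#'
#' With few normal samples the per-gene DNAm standard deviations are noisy
#' and can be spuriously small, inflating z-scores. A constant offset
#' \eqn{\gamma \ge 0} added to every gene's normal SD is calibrated by
#' bisection so that the genome-wide standard deviation of the DNAm z-scores
#' equals that of the RNA z-scores. If the DNAm z SD is already at or below
#' the target at \eqn{\gamma = 0}, the offset is clamped to 0 with a warning.
#'
#' @param meth gene x sample DNAm matrix (genome-wide, not module-restricted).
#' @param normalIds normal sample ids for the DNAm cohort.
#' @param rnaZ genome-wide RNA z-score matrix defining the target SD.
#' @param tol convergence tolerance on the SD match (default 1e-6).
#' @return list with \code{gammaOffset}, \code{achievedSD}, \code{targetSD}.
#' @export
calibrateOffset <- function(meth, normalIds, rnaZ, tol = 1e-6) {
  target <- stats::sd(as.numeric(rnaZ))
  if (!is.finite(target)) stopf("non-finite target SD")
  sdAt <- function(g) stats::sd(as.numeric(
    suppressWarnings(zscoreVsNormals(meth, normalIds, offset = g))))
  s0 <- sdAt(0)
  if (!is.finite(s0)) stopf("non-finite DNAm z-score SD")
  if (s0 <= target) {
    if (s0 < target)
      warnf("DNAm z SD at offset 0 (%.4g) already below target (%.4g); offset clamped to 0",
            s0, target)
    return(list(gammaOffset = 0, achievedSD = s0, targetSD = target))
  }
  hi <- 1
  while (sdAt(hi) > target) hi <- hi * 2
  root <- stats::uniroot(function(g) sdAt(g) - target, c(0, hi),
                         tol = tol / 10)$root
  list(gammaOffset = root, achievedSD = sdAt(root), targetSD = target)
}

#' Joint DNAm + RNA FEM-score
#'
#' For cohorts with matched methylation and expression, module activation is
#' scored as the mean absolute difference of the two modalities' z-scores
#' over the module's anti-correlated signature genes:
#' \eqn{\mathrm{score}_{ms} = |m|^{-1}\sum_{g\in m} |z^{(M)}_{gs} - z^{(R)}_{gs}|}.
#' Because the signature genes move in opposite directions in the two
#' modalities, coordinated deregulation drives the two z-scores apart and
#' the score up; the score is nonnegative and zero only when the modalities
#' agree exactly.
#'
#' @param zMeth,zRna z-score matrices sharing samples (columns).
#' @param signature data.frame with column \code{gene} (the anti-correlated
#'   discovery genes, e.g. from \code{moduleSignatures(..., "joint")}).
#' @param moduleId module identifier.
#' @param groups optional named group label per sample.
#' @return data.frame as in \code{\link{femScoreSigned}}.
#' @export
femScoreJoint <- function(zMeth, zRna, signature, moduleId = "module",
                          groups = NULL) {
  samples <- intersect(colnames(zMeth), colnames(zRna))
  if (length(samples) == 0) stopf("no common samples between modalities")
  g <- intersect(signature$gene, intersect(rownames(zMeth), rownames(zRna)))
  if (length(g) == 0) {
    warnf("module %s: no signature gene present in both modalities; skipped",
          moduleId)
    return(NULL)
  }
  d <- abs(zMeth[g, samples, drop = FALSE] - zRna[g, samples, drop = FALSE])
  sc <- colMeans(d)
  data.frame(sample_id = samples, module_id = moduleId, score = sc,
             n_genes_used = length(g),
             group = if (is.null(groups)) NA_character_ else
               as.character(groups[samples]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' FEM-score in single-cell expression data
#'
#' Scores a module in log-normalized single-cell expression. Dropout makes
#' many signature genes uninformative, so the signature is first restricted
#' to genes with nonzero variance across the scored cells; modules with
#' fewer than \code{minVarGenes} variable signature genes are declared
#' unscoreable. Scoring then proceeds as z-scoring against the normal cells
#' followed by the signed-average FEM-score.
#'
#' @param logexpr gene x cell matrix of log-normalized counts.
#' @param signature data.frame with \code{gene}, \code{sign}.
#' @param normalCells cell ids forming the normal reference (>= 2).
#' @param moduleId module identifier.
#' @param minVarGenes minimum number of variable signature genes (default 5).
#' @param groups optional named group label per cell.
#' @return data.frame of scores, or \code{NULL} when unscoreable.
#' @export
femScoreScrna <- function(logexpr, signature, normalCells,
                          moduleId = "module", minVarGenes = 5,
                          groups = NULL) {
  checkNumericMatrix(logexpr, "log expression matrix")
  if (length(intersect(normalCells, colnames(logexpr))) < 2)
    stopf("need >=2 normal cells")
  g <- intersect(signature$gene, rownames(logexpr))
  v <- apply(logexpr[g, , drop = FALSE], 1, stats::var)
  variable <- g[v > 0]
  if (length(variable) < minVarGenes) {
    message(sprintf(
      "module %s unscoreable: %d variable signature gene(s) < %d required",
      moduleId, length(variable), minVarGenes))
    return(NULL)
  }
  z <- zscoreVsNormals(logexpr[variable, , drop = FALSE], normalCells)
  femScoreSigned(z, signature[signature$gene %in% variable, , drop = FALSE],
                 moduleId = moduleId, groups = groups)
}

#' Evaluate FEM-scores between two groups
#'
#' One-tailed Wilcoxon rank-sum test of the alternative that the positive
#' group has larger scores (exact below a combined n of 25 when there are no
#' ties, otherwise the normal approximation with continuity and tie
#' correction), and the area under the ROC curve computed from the
#' Mann-Whitney U statistic, \eqn{AUC = U/(n_1 n_2)} (ties credited 1/2).
#'
#' @param scores data.frame with columns \code{score} and \code{group}.
#' @param positiveGroup label of the group expected to score higher.
#' @return list with \code{wilcoxonP}, \code{auc}, \code{n1}, \code{n2}.
#' @export
evaluateScores <- function(scores, positiveGroup) {
  x <- scores$score[scores$group == positiveGroup]
  y <- scores$score[scores$group != positiveGroup]
  if (length(x) == 0 || length(y) == 0)
    stopf("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) < 25 && !ties
  wt <- stats::wilcox.test(x, y, alternative = "greater", exact = exact,
                           correct = TRUE)
  list(wilcoxonP = wt$p.value,
       auc = unname(wt$statistic) / (length(x) * length(y)),
       n1 = length(x), n2 = length(y))
}

#' Group test on FEM-scores adjusted for a covariate
#'
#' Linear model of the score on the group indicator plus a per-sample
#' covariate (typically the estimated epithelial fraction), reporting the
#' group coefficient's t-statistic and two-sided p-value. Used to check that
#' a score difference is not explained by cell-type composition alone.
#'
#' @param scores data.frame with \code{score}, \code{group} and
#'   \code{sample_id}.
#' @param covariate named numeric vector (by sample id) or numeric vector
#'   aligned to the rows of \code{scores}.
#' @param positiveGroup label coded 1 in the group indicator.
#' @return list with \code{t}, \code{p}, \code{coefficient}.
#' @export
scoreWithCovariateAdjustment <- function(scores, covariate, positiveGroup) {
  cv <- if (!is.null(names(covariate))) covariate[scores$sample_id]
        else covariate
  if (anyNA(cv)) stopf("covariate missing for some samples")
  grp <- as.numeric(scores$group == positiveGroup)
  if (stats::var(cv) == 0) {
    warnf("constant covariate: test reduces to the unadjusted comparison")
    fit <- stats::lm(scores$score ~ grp)
  } else {
    fit <- stats::lm(scores$score ~ grp + cv)
  }
  su <- summary(fit)$coefficients
  list(t = su["grp", "t value"], p = su["grp", "Pr(>|t|)"],
       coefficient = su["grp", "Estimate"])
}
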