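#' Cell-fraction-adjusted moderated t-statistics
#'
#' Fits, per gene, a linear model of the measured value (promoter beta or
#' log-expression) on a two-group contrast plus covariates, and moderates the
#' residual variances by the empirical-Bayes inverse-gamma shrinkage of
#' \pkg{limma}. Cell-type fractions enter as covariates so that the group
#' contrast is not driven by shifts in cell-type composition; because the
#' fractions sum to one, the last fraction column is omitted from the design
#' (absorbed by the intercept).
#'
#' With a per-gene CNV covariate the model is refit gene by gene (the design
#' differs per gene) and the residual variances are then shrunk with
#' \code{limma::squeezeVar}, giving the same moderated-t construction.
#'
#' @param mat numeric matrix, genes x samples (betas or log expression).
#' @param sampleSheet data.frame with \code{sample_id} and \code{group}
#'   covering the matrix columns.
#' @param fractions optional samples x cell-types matrix of fractions in
#'   [0,1]; rownames must cover the matrix columns. The last column is
#'   dropped from the design.
#' @param cnv optional genes x samples matrix of per-gene copy-number values,
#'   aligned to \code{mat}.
#' @param caseLabel group label treated as the case; default "case", or the
#'   non-"normal" label when exactly two labels are present.
#' @param shrink logical; \code{FALSE} disables empirical-Bayes shrinkage and
#'   returns ordinary least-squares t-statistics.
#' @return data.frame with columns gene, t, p, fdr, direction (sign of t).
#' @export
moderatedT <- function(mat, sampleSheet, fractions = NULL, cnv = NULL,
                       caseLabel = NULL, shrink = TRUE) {
  checkNumericMatrix(mat, "data matrix")
  sheet <- sampleSheet[match(colnames(mat), sampleSheet$sample_id), ]
  if (anyNA(sheet$sample_id))
    stopf("sample sheet does not cover all matrix columns")
  grp <- as.character(sheet$group)
  labs <- unique(grp)
  if (length(labs) != 2) stopf("exactly two group labels required, got: %s",
                               paste(labs, collapse = ", "))
  if (is.null(caseLabel))
    caseLabel <- if ("normal" %in% labs) setdiff(labs, "normal") else
      if ("case" %in% labs) "case" else sort(labs)[2]
  if (!caseLabel %in% labs) stopf("case label '%s' not present", caseLabel)
  case <- as.numeric(grp == caseLabel)
  if (min(table(case)) < 2) stopf("need >=2 samples per group")

  design <- cbind(Intercept = 1, case = case)
  if (!is.null(fractions)) {
    fr <- as.matrix(fractions)
    if (!all(colnames(mat) %in% rownames(fr)))
      stopf("fractions must cover all samples")
    fr <- fr[colnames(mat), , drop = FALSE]
    # sum-to-one: drop the final cell type, absorbed by the intercept
    design <- cbind(design, fr[, -ncol(fr), drop = FALSE])
  }
  if (qr(design)$rank < ncol(design))
    stopf("design matrix is rank-deficient (collinear covariates)")
  dfRes <- ncol(mat) - ncol(design) - if (is.null(cnv)) 0 else 1
  if (dfRes <= 0) stopf("zero residual degrees of freedom")

  if (is.null(cnv)) {
    fit <- limma::lmFit(mat, design)
    out <- moderatedFromFit(fit$coefficients[, "case"],
                            fit$stdev.unscaled[, "case"],
                            fit$sigma, fit$df.residual, shrink)
  } else {
    checkNumericMatrix(cnv, "cnv matrix")
    if (!identical(dim(cnv), dim(mat)))
      stopf("cnv matrix must be aligned to the data matrix")
    ng <- nrow(mat)
    b <- se <- sg <- dfr <- numeric(ng)
    for (i in seq_len(ng)) {
      X <- cbind(design, cnv = cnv[i, ])
      if (qr(X)$rank < ncol(X)) X <- design  # degenerate cnv (e.g. constant 0)
      f <- stats::lm.fit(X, mat[i, ])
      ci <- which(colnames(X) == "case")
      XtXinv <- chol2inv(chol(crossprod(X)))
      b[i] <- f$coefficients[ci]
      se[i] <- sqrt(XtXinv[ci, ci])
      dfr[i] <- f$df.residual
      sg[i] <- sqrt(sum(f$residuals^2) / f$df.residual)
    }
    out <- moderatedFromFit(b, se, sg, dfr, shrink)
  }
  rownames(out) <- NULL
  data.frame(gene = rownames(mat), out, stringsAsFactors = FALSE)
}

# shared moderated/ordinary t construction from per-gene OLS summaries
moderatedFromFit <- function(coef, seUnscaled, sigma, dfRes, shrink) {
  constant <- sigma < 1e-10 & abs(coef) < 1e-10
  if (shrink && sum(sigma > 0) >= 10) {
    sv <- tryCatch(limma::squeezeVar(sigma^2, dfRes), error = function(e) NULL)
  } else sv <- NULL
  if (is.null(sv)) {
    if (shrink) warnf("variance shrinkage unavailable; using ordinary t")
    tt <- coef / (seUnscaled * sigma)
    dfTot <- dfRes
  } else {
    tt <- coef / (seUnscaled * sqrt(sv$var.post))
    dfTot <- dfRes + sv$df.prior
  }
  if (any(constant)) {
    warnf("%d constant gene(s): t set to 0, p to 1", sum(constant))
    tt[constant] <- 0
  }
  tt[!is.finite(tt)] <- 0
  p <- 2 * stats::pt(-abs(tt), df = pmin(dfTot, 1e6))
  p[constant] <- 1
  data.frame(t = tt, p = p, fdr = stats::p.adjust(p, "BH"),
             direction = sign(tt))
}

#' Aligned differential statistics over a gene network
#'
#' Computes cell-fraction-adjusted moderated t-statistics of differential
#' methylation (case vs normal promoter betas) and differential expression
#' for every gene of the analysis universe, defined as the intersection of
#' the network's nodes with the genes measured in both modalities. The two
#' modalities may cover different sample sets. Genes missing from either
#' modality are dropped with a reported count. The per-gene integrated
#' statistic (see \code{\link{integratedStatistic}}) is attached.
#'
#' @param meth \linkS4class{PromoterMethylation} or gene x sample beta matrix.
#' @param expr gene x sample log-expression matrix.
#' @param sampleSheet sample sheet covering all methylation and expression
#'   samples.
#' @param fractions samples x cell-types fraction matrix (rownames = sample
#'   ids); used as covariates for any modality whose samples are covered.
#' @param network igraph gene network.
#' @param fdrThresh FDR level used downstream for DM/DE flags (stored only).
#' @return a \linkS4class{GeneStats} object.
#' @export
computeGeneStats <- function(meth, expr, sampleSheet, fractions = NULL,
                             network, fdrThresh = 0.05) {
  if (is(meth, "PromoterMethylation")) meth <- betaValues(meth)
  nodes <- igraph::V(network)$name
  universe <- sort(intersect(nodes, intersect(rownames(meth), rownames(expr))))
  if (length(universe) == 0) stopf("no overlap between network and data genes")
  nDropped <- length(intersect(rownames(meth), nodes)) +
    length(intersect(rownames(expr), nodes)) - 2 * length(universe)
  if (nDropped > 0)
    message(sprintf("gene stats: dropped %d network gene(s) missing a modality",
                    nDropped))
  if (length(universe) < 0.5 * length(nodes))
    warnf("less than 50%% of network genes are covered by both modalities")

  frFor <- function(m) {
    if (is.null(fractions)) return(NULL)
    if (all(colnames(m) %in% rownames(fractions))) fractions else NULL
  }
  dm <- moderatedT(meth[universe, , drop = FALSE], sampleSheet, frFor(meth))
  de <- moderatedT(expr[universe, , drop = FALSE], sampleSheet, frFor(expr))
  tab <- data.frame(gene = universe,
                    t_dm = dm$t, p_dm = dm$p, fdr_dm = dm$fdr,
                    t_de = de$t, p_de = de$p, fdr_de = de$fdr,
                    t_int = integratedStatistic(dm$t, de$t),
                    stringsAsFactors = FALSE)
  new("GeneStats", stats = tab)
}

#' Compare differential statistics with and without CNV adjustment
#'
#' Pairs the unadjusted and CNV-adjusted t-statistics over a gene set and
#' summarizes their agreement, to assess whether module-level differential
#' methylation/expression is robust to copy-number state.
#'
#' @param statsUnadj,statsCnvAdj data.frames from \code{\link{moderatedT}}
#'   (the latter fit with a per-gene CNV covariate), over the same genes.
#' @param genes optional gene subset (e.g. module members); default all.
#' @return list with the paired table, Pearson \code{correlation} of t, and
#'   \code{signConcordance} (fraction of genes with equal t sign).
#' @export
cnvRobustness <- function(statsUnadj, statsCnvAdj, genes = NULL) {
  if (is.null(genes)) genes <- statsUnadj$gene
  a <- statsUnadj[match(genes, statsUnadj$gene), ]
  b <- statsCnvAdj[match(genes, statsCnvAdj$gene), ]
  if (anyNA(a$gene) || anyNA(b$gene))
    stopf("both tables must cover the requested genes")
  tab <- data.frame(gene = genes, t_unadj = a$t, t_cnv_adj = b$t,
                    stringsAsFactors = FALSE)
  list(table = tab,
       correlation = stats::cor(a$t, b$t),
       signConcordance = mean(sign(a$t) == sign(b$t)))
}

#' Cell-type specific differentially methylated genes
#'
#' Detects in which cell type a disease-associated methylation change occurs,
#' using the fraction-by-disease interaction model: for each gene the
#' promoter beta is regressed on all cell-type fractions and on each
#' fraction's interaction with the case indicator, without a global intercept
#' (the fractions sum to one, so their main effects span the intercept). The
#' interaction coefficient for cell type k estimates the within-cell-type
#' disease effect; its moderated t and BH FDR (per cell type, over genes)
#' give the cts-DMG calls.
#'
#' @param meth \linkS4class{PromoterMethylation} or gene x sample beta matrix.
#' @param sampleSheet sample sheet with sample_id and group.
#' @param fractions samples x cell-types matrix; each row must sum to 1
#'   within 1e-6.
#' @param fdrThresh per-cell-type FDR threshold for the significance flags.
#' @param caseLabel see \code{\link{moderatedT}}.
#' @return data.frame with, per gene and cell type k, columns
#'   \code{est_k}, \code{t_k}, \code{p_k}, \code{fdr_k}, \code{sig_k}.
#' @export
cellTypeSpecificDMG <- function(meth, sampleSheet, fractions,
                                fdrThresh = 0.05, caseLabel = NULL) {
  if (is(meth, "PromoterMethylation")) meth <- betaValues(meth)
  checkNumericMatrix(meth, "methylation matrix")
  fr <- as.matrix(fractions)
  if (!all(colnames(meth) %in% rownames(fr)))
    stopf("fractions must cover all samples")
  fr <- fr[colnames(meth), , drop = FALSE]
  if (any(abs(rowSums(fr) - 1) > 1e-6))
    stopf("cell-type fractions must sum to 1 per sample")
  k <- ncol(fr)
  if (k < 2) stopf("need fractions for at least two cell types")

  sheet <- sampleSheet[match(colnames(meth), sampleSheet$sample_id), ]
  grp <- as.character(sheet$group)
  labs <- unique(grp)
  if (length(labs) != 2) stopf("exactly two group labels required")
  if (is.null(caseLabel))
    caseLabel <- if ("normal" %in% labs) setdiff(labs, "normal") else
      if ("case" %in% labs) "case" else sort(labs)[2]
  case <- as.numeric(grp == caseLabel)

  X <- cbind(fr, fr * case)
  colnames(X) <- c(colnames(fr), paste0(colnames(fr), ".case"))
  if (qr(X)$rank < ncol(X))
    stopf("interaction design is rank-deficient; cell-type fractions must vary across samples")

  fit <- limma::lmFit(meth, X)
  fit <- limma::eBayes(fit)
  out <- data.frame(gene = rownames(meth), stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    cn <- paste0(colnames(fr)[j], ".case")
    tj <- fit$t[, cn]
    pj <- fit$p.value[, cn]
    fj <- stats::p.adjust(pj, "BH")
    out[[paste0("est_", colnames(fr)[j])]] <- fit$coefficients[, cn]
    out[[paste0("t_", colnames(fr)[j])]] <- tj
    out[[paste0("p_", colnames(fr)[j])]] <- pj
    out[[paste0("fdr_", colnames(fr)[j])]] <- fj
    out[[paste0("sig_", colnames(fr)[j])]] <- fj < fdrThresh
  }
  rownames(out) <- NULL
  out
}
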