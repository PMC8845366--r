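makeToyCohort <- function(nGenes = 10, nPer = 4, seed = 11) {
  set.seed(seed)
  n <- 2 * nPer
  mat <- matrix(rnorm(nGenes * n, 5, 1), nGenes,
                dimnames = list(paste0("g", seq_len(nGenes)),
                                paste0("s", seq_len(n))))
  sheet <- data.frame(sample_id = colnames(mat),
                      group = rep(c("case", "normal"), each = nPer))
  epi <- runif(n, 0.3, 0.7)
  split <- runif(n, 0.2, 0.8)
  fr <- cbind(Epi = epi, Fib = (1 - epi) * split, IC = (1 - epi) * (1 - split))
  rownames(fr) <- colnames(mat)
  list(mat = mat, sheet = sheet, fr = fr)
}

test_that("unshrunk moderated t equals the per-gene OLS oracle", {
  toy <- makeToyCohort()
  out <- moderatedT(toy$mat, toy$sheet, toy$fr, shrink = FALSE)
  case <- as.numeric(toy$sheet$group == "case")
  for (i in seq_len(nrow(toy$mat))) {
    oracle <- olsTOracle(toy$mat[i, ], case, toy$fr[, 1:2])
    expect_equal(out$t[i], unname(oracle["t value"]), tolerance = 1e-8)
    expect_equal(out$p[i], unname(oracle["Pr(>|t|)"]), tolerance = 1e-8)
  }
})

test_that("constant genes give t = 0, p = 1 with a warning", {
  toy <- makeToyCohort()
  toy$mat[3, ] <- 2.5
  expect_warning(out <- moderatedT(toy$mat, toy$sheet, shrink = FALSE),
                 "constant")
  expect_equal(out$t[3], 0)
  expect_equal(out$p[3], 1)
})

test_that("swapping group labels negates t and preserves p", {
  toy <- makeToyCohort()
  a <- moderatedT(toy$mat, toy$sheet, toy$fr, caseLabel = "case")
  b <- moderatedT(toy$mat, toy$sheet, toy$fr, caseLabel = "normal")
  expect_equal(a$t, -b$t, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("moderated t is invariant to affine rescaling of covariates", {
  toy <- makeToyCohort()
  a <- moderatedT(toy$mat, toy$sheet, toy$fr)
  fr2 <- toy$fr
  fr2[, 1] <- 10 * fr2[, 1] - 3
  fr2[, 2] <- -2 * fr2[, 2] + 0.5
  b <- moderatedT(toy$mat, toy$sheet, fr2)
  expect_equal(a$t, b$t, tolerance = 1e-8)
})

test_that("BH FDR is at least the raw p-value and direction matches sign", {
  toy <- makeToyCohort(nGenes = 50)
  out <- moderatedT(toy$mat, toy$sheet)
  expect_true(all(out$fdr >= out$p - 1e-12))
  expect_equal(out$direction, sign(out$t))
})

test_that("degenerate designs are rejected", {
  toy <- makeToyCohort(nPer = 2)
  # 4 samples, intercept + group + 2 fraction covariates -> zero residual df
  expect_error(moderatedT(toy$mat, toy$sheet, toy$fr), "residual degrees")
  one <- toy$mat[, 1:3]
  sheet <- data.frame(sample_id = colnames(one),
                      group = c("case", "normal", "normal"))
  expect_error(moderatedT(one, sheet), ">=2 samples per group")
})

test_that("an all-zero CNV covariate reproduces the unadjusted statistics", {
  toy <- makeToyCohort(nGenes = 12, nPer = 6)
  unadj <- moderatedT(toy$mat, toy$sheet, toy$fr)
  cnv0 <- matrix(0, nrow(toy$mat), ncol(toy$mat),
                 dimnames = dimnames(toy$mat))
  adj <- moderatedT(toy$mat, toy$sheet, toy$fr, cnv = cnv0)
  expect_equal(adj$t, unadj$t, tolerance = 1e-8)
  rob <- cnvRobustness(unadj, adj)
  expect_equal(rob$signConcordance, 1)
  expect_equal(rob$correlation, 1, tolerance = 1e-8)
})

test_that("CNV adjustment attenuates effects only under confounding", {
  set.seed(21)
  nPer <- 25; n <- 2 * nPer; nGenes <- 40
  case <- rep(c(1, 0), each = nPer)
  sheet <- data.frame(sample_id = paste0("s", 1:n),
                      group = rep(c("case", "normal"), each = nPer))
  base <- matrix(rnorm(nGenes * n, 0, 0.5), nGenes)
  eff <- outer(rep(1, nGenes), case)
  # independent CNV: adjustment leaves planted signs intact
  cnvI <- matrix(rnorm(nGenes * n, 0, 0.5), nGenes)
  matI <- base + eff + 0.8 * cnvI
  dimnames(matI) <- list(paste0("g", 1:nGenes), sheet$sample_id)
  dimnames(cnvI) <- dimnames(matI)
  unadjI <- moderatedT(matI, sheet)
  adjI <- moderatedT(matI, sheet, cnv = cnvI)
  robI <- cnvRobustness(unadjI, adjI)
  expect_equal(robI$signConcordance, 1)
  # CNV fully confounded with the group: adjusted |t| collapses
  cnvC <- outer(rep(1, nGenes), case) + matrix(rnorm(nGenes * n, 0, 0.05),
                                               nGenes)
  matC <- base + 0.0 * eff + 1.5 * cnvC   # effect flows through CNV only
  dimnames(matC) <- dimnames(matI); dimnames(cnvC) <- dimnames(matI)
  unadjC <- moderatedT(matC, sheet)
  adjC <- moderatedT(matC, sheet, cnv = cnvC)
  expect_lt(mean(abs(adjC$t)), mean(abs(unadjC$t)) / 2)
})

test_that("computeGeneStats aligns modalities on the network universe", {
  set.seed(5)
  genes <- paste0("G", 1:5)
  g <- igraph::graph_from_edgelist(
    cbind(genes[1:4], genes[2:5]), directed = FALSE)
  n <- 12
  meth <- matrix(runif(5 * n, 0.2, 0.8), 5,
                 dimnames = list(genes, paste0("s", 1:n)))
  expr <- matrix(rnorm(5 * n, 5), 5, dimnames = dimnames(meth))
  sheet <- data.frame(sample_id = colnames(meth),
                      group = rep(c("case", "normal"), each = n / 2))
  gs <- suppressWarnings(computeGeneStats(meth, expr, sheet, network = g))
  expect_setequal(geneIds(gs), genes)
  st <- statTable(gs)
  expect_equal(st$t_int, integratedStatistic(st$t_dm, st$t_de))

  # one gene missing from expression: dropped with a message
  expect_message(
    gs4 <- suppressWarnings(
      computeGeneStats(meth, expr[-3, ], sheet, network = g)),
    "dropped 1")
  expect_equal(length(geneIds(gs4)), 4L)

  expect_error(
    suppressWarnings(computeGeneStats(meth[0, , drop = FALSE], expr, sheet,
                                      network = g)),
    "no overlap")
})

test_that("cell-type specific calls recover an epithelial-only effect", {
  set.seed(33)
  nPer <- 50; n <- 2 * nPer; nGenes <- 60
  case <- rep(c(1, 0), each = nPer)
  sheet <- data.frame(sample_id = paste0("s", 1:n),
                      group = rep(c("case", "normal"), each = nPer))
  fr <- femnet:::rdirichlet(n, c(5, 3, 2))
  colnames(fr) <- c("Epi", "Fib", "IC"); rownames(fr) <- sheet$sample_id
  baseC <- matrix(runif(nGenes * 3, 0.2, 0.6), nGenes)  # gene x celltype
  mix <- baseC %*% t(fr)
  mix[1, ] <- mix[1, ] + 0.3 * fr[, "Epi"] * case  # epithelial-only shift
  mat <- pmin(pmax(mix + matrix(rnorm(nGenes * n, 0, 0.03), nGenes), 0), 1)
  dimnames(mat) <- list(paste0("g", 1:nGenes), sheet$sample_id)
  res <- cellTypeSpecificDMG(mat, sheet, fr)
  expect_true(res$sig_Epi[1])
  expect_false(res$sig_Fib[1])
  expect_false(res$sig_IC[1])

  # constant fractions make the interaction design rank-deficient
  frC <- matrix(rep(c(0.5, 0.3, 0.2), each = n), n,
                dimnames = list(sheet$sample_id, c("Epi", "Fib", "IC")))
  expect_error(cellTypeSpecificDMG(mat, sheet, frC), "rank-deficient")

  # fractions must sum to one
  frBad <- fr; frBad[1, 1] <- frBad[1, 1] + 0.1
  expect_error(cellTypeSpecificDMG(mat, sheet, frBad), "sum to 1")
})
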