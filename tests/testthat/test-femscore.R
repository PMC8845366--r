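test_that("z-scoring against normals has the stated normal-reference moments", {
  set.seed(2)
  m <- matrix(rnorm(5 * 10, 5, 2), 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  normals <- paste0("s", 1:6)
  z <- zscoreVsNormals(m, normals)
  expect_equal(unname(rowMeans(z[, normals])), rep(0, 5), tolerance = 1e-12)
  popSD <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(unname(apply(z[, normals], 1, popSD)), rep(1, 5),
               tolerance = 1e-12)
  # a value at mu + 2 sigma scores exactly 2
  mu <- rowMeans(m[, normals]); sd <- apply(m[, normals], 1, popSD)
  m2 <- cbind(m, new = mu + 2 * sd)
  expect_equal(unname(zscoreVsNormals(m2, normals)[, "new"]), rep(2, 5),
               tolerance = 1e-12)
  # zero-SD genes are dropped with a warning
  m3 <- m; m3[2, normals] <- 0.5
  expect_warning(z3 <- zscoreVsNormals(m3, normals), "zero SD")
  expect_false("g2" %in% rownames(z3))
  expect_error(zscoreVsNormals(m, normals[1]), ">=2 normal")
})

test_that("signed FEM-score matches hand evaluation and is linear in z", {
  z <- matrix(c(2, -1), 2, dimnames = list(c("g1", "g2"), "s1"))
  sig <- data.frame(gene = c("g1", "g2"), sign = c(1, -1))
  sc <- femScoreSigned(z, sig, "m1")
  expect_equal(sc$score, 1.5)       # (2 + 1)/2
  expect_equal(sc$n_genes_used, 2L)
  expect_equal(femScoreSigned(2 * z, sig)$score, 3)   # linearity
  z0 <- z * 0
  expect_equal(femScoreSigned(z0, sig)$score, 0)
  # genes absent from z are skipped; none present means NULL with a warning
  expect_warning(res <- femScoreSigned(z, data.frame(gene = "gX", sign = 1)),
                 "no signature gene")
  expect_null(res)
})

test_that("scores are invariant to per-gene affine transforms of the input", {
  set.seed(6)
  m <- matrix(rnorm(4 * 12, 10, 3), 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:12)))
  normals <- paste0("s", 1:5)
  sig <- data.frame(gene = paste0("g", 1:4), sign = c(1, -1, 1, -1))
  a <- femScoreSigned(zscoreVsNormals(m, normals), sig)
  m2 <- m * 7 - 3   # same affine transform per gene
  b <- femScoreSigned(zscoreVsNormals(m2, normals), sig)
  expect_equal(a$score, b$score, tolerance = 1e-10)
})

test_that("offset calibration matches the target SD by bisection", {
  set.seed(13)
  # normals are tight per gene, the rest of the cohort spreads widely, so
  # the DNAm z SD at zero offset is well above the RNA target
  meth <- cbind(matrix(rep(runif(200, 0.45, 0.55), 5), 200) +
                  matrix(rnorm(200 * 5, 0, 0.01), 200),
                matrix(runif(200 * 15, 0.1, 0.9), 200))
  dimnames(meth) <- list(paste0("g", 1:200), paste0("s", 1:20))
  normals <- paste0("s", 1:5)
  rnaZ <- zscoreVsNormals(
    matrix(rnorm(200 * 20, 5, 1), 200, dimnames = dimnames(meth)), normals)
  # target equal to the achieved SD at zero offset: gamma = 0
  z0 <- zscoreVsNormals(meth, normals)
  cal0 <- calibrateOffset(meth, normals, z0)
  expect_equal(cal0$gammaOffset, 0)
  # DNAm z SD well above target: the calibrated offset matches to 1e-6
  cal <- calibrateOffset(meth, normals, rnaZ)
  expect_gt(cal$gammaOffset, 0)
  expect_lt(abs(cal$achievedSD - cal$targetSD), 1e-6)
  # unattainable target (above SD at gamma = 0): clamped with a warning
  bigZ <- z0 * 10
  expect_warning(calC <- calibrateOffset(meth, normals, bigZ), "clamped")
  expect_equal(calC$gammaOffset, 0)
})

test_that("joint FEM-score matches hand evaluation and is nonnegative", {
  zM <- matrix(c(1, -2), 2, dimnames = list(c("g1", "g2"), "s1"))
  zR <- matrix(c(-1, 1), 2, dimnames = list(c("g1", "g2"), "s1"))
  sig <- data.frame(gene = c("g1", "g2"))
  sc <- femScoreJoint(zM, zR, sig)
  expect_equal(sc$score, 2.5)   # (|1-(-1)| + |-2-1|)/2
  expect_equal(femScoreJoint(zM, zM, sig)$score, 0)
  set.seed(3)
  zA <- matrix(rnorm(20), 4, dimnames = list(paste0("g", 1:4),
                                             paste0("s", 1:5)))
  zB <- matrix(rnorm(20), 4, dimnames = dimnames(zA))
  sc2 <- femScoreJoint(zA, zB, data.frame(gene = paste0("g", 1:4)))
  expect_true(all(sc2$score >= 0))
  zOther <- zA; colnames(zOther) <- paste0("t", 1:5)
  expect_error(femScoreJoint(zA, zOther, sig), "no common samples")
})

test_that("single-cell scoring enforces the variable-gene gate", {
  set.seed(10)
  genes <- paste0("g", 1:10)
  cells <- paste0("c", 1:30)
  m <- matrix(rexp(300), 10, dimnames = list(genes, cells))
  sig <- data.frame(gene = genes[1:6], sign = rep(1, 6))
  # three variable signature genes only: unscoreable at the default gate
  m2 <- m; m2[sig$gene[4:6], ] <- 0
  expect_message(
    res <- femScoreScrna(m2[sig$gene, ], sig, normalCells = cells[1:10]),
    "unscoreable")
  expect_null(res)
  # all cells identical: every gene has zero variance
  mC <- matrix(1, 10, 30, dimnames = list(genes, cells))
  expect_message(resC <- femScoreScrna(mC, sig, normalCells = cells[1:10]),
                 "unscoreable")
  expect_null(resC)
  # enough variable genes: scores come back for every cell
  res2 <- femScoreScrna(m, sig, normalCells = cells[1:10])
  expect_equal(nrow(res2), 30L)
  expect_error(femScoreScrna(m, sig, normalCells = cells[1]), ">=2 normal")
})

test_that("evaluation reproduces the exhaustive pair-counting AUC", {
  sc <- data.frame(score = c(3, 4, 5, 1, 2, 3),
                   group = rep(c("case", "normal"), each = 3))
  ev <- evaluateScores(sc, "case")
  # oracle: count concordant pairs with half-credit ties
  cases <- sc$score[sc$group == "case"]; ctrl <- sc$score[sc$group == "normal"]
  u <- sum(outer(cases, ctrl, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(ev$auc, u / 9)
  expect_equal(ev$auc, 8.5 / 9, tolerance = 1e-12)
  # perfect separation
  sep <- data.frame(score = c(5:9, 1:4),
                    group = rep(c("case", "normal"), c(5, 4)))
  expect_equal(evaluateScores(sep, "case")$auc, 1)
  expect_lt(evaluateScores(sep, "case")$wilcoxonP, 0.05)
  # identical distributions at large n: AUC near 1/2, p near 1/2
  set.seed(15)
  nullSc <- data.frame(score = rnorm(400),
                       group = rep(c("case", "normal"), each = 200))
  evN <- evaluateScores(nullSc, "case")
  expect_gt(evN$auc, 0.45); expect_lt(evN$auc, 0.55)
  expect_gt(evN$wilcoxonP, 0.05)
  expect_error(evaluateScores(nullSc[nullSc$group == "case", ], "case"),
               "non-empty")
})

test_that("covariate adjustment behaves under orthogonal and confounded designs", {
  set.seed(19)
  n <- 60
  grp <- rep(c("case", "normal"), each = n / 2)
  covOrth <- rnorm(n)
  score <- 1 * (grp == "case") + rnorm(n, 0, 0.5)
  sc <- data.frame(sample_id = paste0("s", 1:n), score = score, group = grp)
  unadj <- scoreWithCovariateAdjustment(sc, covOrth, "case")
  plain <- summary(lm(score ~ I(grp == "case")))$coefficients[2, "t value"]
  expect_lt(abs(unadj$t - plain) / plain, 0.15)
  # score fully explained by the covariate
  covConf <- as.numeric(grp == "case") + rnorm(n, 0, 0.01)
  scConf <- sc; scConf$score <- 2 * covConf + rnorm(n, 0, 0.01)
  adj <- scoreWithCovariateAdjustment(scConf, covConf, "case")
  expect_lt(abs(adj$t), 2)
  # constant covariate: warning, reduces to unadjusted test
  expect_warning(
    red <- scoreWithCovariateAdjustment(sc, rep(1, n), "case"),
    "constant covariate")
  expect_equal(red$t, plain, tolerance = 1e-10)
})

test_that("module signatures carry discovery signs per modality", {
  genes <- c("a", "b", "c", "d")
  st <- makeStats(genes, tdm = c(3, -2, 4, 1), tde = c(-3, 2, 4, -2))
  st$fdr_dm <- c(0.001, 0.001, 0.001, 0.2)   # d not DM-significant
  gs <- new("GeneStats", stats = st)
  mod <- new("FemModule", seed = "a", members = genes, energy = -1,
             modularity = 1, mcP = 0.01, energyTrace = numeric(0),
             flags = data.frame())
  mods <- new("FemModuleSet", modules = list(mod))
  sigM <- moduleSignatures(mods, gs, "meth")[["a"]]
  expect_setequal(sigM$gene, c("a", "b", "c"))
  expect_equal(sigM$sign[sigM$gene == "b"], -1)
  sigJ <- moduleSignatures(mods, gs, "joint")[["a"]]
  # only anti-correlated significant genes: c is concordant, d not DM
  expect_setequal(sigJ$gene, c("a", "b"))
})
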