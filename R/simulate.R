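#' Configuration for the synthetic-data generator
#'
#' Bundles every parameter of the synthetic benchmark with defaults chosen
#' to emulate the statistical structure of a bulk esophageal case/control
#' study: a scale-free PPI-like network with planted, internally dense and
#' weakly bounded modules of anti-correlated promoter methylation /
#' expression deregulation; case and control cohorts whose observed betas
#' are epithelial/fibroblast/immune mixtures with Dirichlet fractions and
#' logit-normal noise; purified reference profiles with planted marker CpGs;
#' a staged saliva-like cohort whose epithelial fraction rises with stage;
#' and dropout-laden single-cell log expression.
#'
#' @param rngSeed integer master seed; each generator derives a stable child
#'   seed from it, so generated pieces are independent and reproducible.
#' @param nGenes network size (>= 50).
#' @param attachment preferential-attachment edges per node.
#' @param plantedSizes sizes of the planted modules.
#' @param internalDensity internal edge density of planted modules.
#' @param boundaryEdges edges connecting each planted module to the rest of
#'   the network.
#' @param deltaBeta case beta shift in the epithelial component of planted
#'   genes.
#' @param logFC case log-expression shift of planted genes (opposite sign to
#'   the methylation change when \code{antiCorrelated}).
#' @param antiCorrelated logical; plant anti-correlated effects.
#' @param nCases,nControls cohort group sizes.
#' @param cellTypes cell-type names (epithelial first).
#' @param dirichletAlpha Dirichlet concentration of the true fractions.
#' @param logitNoiseSD bulk beta noise SD on the logit scale.
#' @param exprNoiseSD expression noise SD (log scale).
#' @param probesPerGene named counts of TSS200/FirstExon/TSS1500 probes.
#' @param probeJitterSD per-probe jitter SD on the logit scale.
#' @param purePerType purified samples per cell type.
#' @param markersPerType planted marker CpGs per cell type.
#' @param nNonMarkerCpGs shared non-marker CpGs in purified profiles.
#' @param pureNoiseSD purified-profile noise SD (logit scale).
#' @param dropout single-cell dropout rate in [0,1).
#' @param nPatients simulated patients for the single-cell data.
#' @param cellsPerPatient named counts of BE and normal cells per patient.
#' @param scShift single-cell signature shift (log scale).
#' @param scNoiseSD single-cell expression noise SD.
#' @param salivaStageSizes named sample counts for stages N/NDBE/HGD/C.
#' @param salivaEpiTrend mean epithelial fraction per stage.
#' @param salivaDeltaPerStage epithelial-component beta shift per stage step
#'   for the designated module.
#' @return a validated list of class \code{femSimConfig}.
#' @export
simulationConfig <- function(rngSeed = 1L,
                             nGenes = 1000L,
                             attachment = 10L,
                             plantedSizes = c(35L, 35L, 35L),
                             internalDensity = 1,
                             boundaryEdges = 1L,
                             deltaBeta = 0.3,
                             logFC = -1,
                             antiCorrelated = TRUE,
                             nCases = 50L, nControls = 50L,
                             cellTypes = c("Epi", "Fib", "IC"),
                             dirichletAlpha = c(6, 2, 2),
                             logitNoiseSD = 0.2,
                             exprNoiseSD = 1,
                             probesPerGene = c(TSS200 = 2L, FirstExon = 1L,
                                               TSS1500 = 1L),
                             probeJitterSD = 0.02,
                             purePerType = 5L,
                             markersPerType = 50L,
                             nNonMarkerCpGs = 350L,
                             pureNoiseSD = 0.15,
                             dropout = 0.6,
                             nPatients = 4L,
                             cellsPerPatient = c(BE = 147L, normal = 112L),
                             scShift = 1,
                             scNoiseSD = 1,
                             salivaStageSizes = c(N = 65L, NDBE = 33L,
                                                  HGD = 14L, C = 51L),
                             salivaEpiTrend = c(0.25, 0.32, 0.38, 0.45),
                             salivaDeltaPerStage = 0.1) {
  cfg <- as.list(environment())
  if (cfg$nGenes < 50) stopf("nGenes must be >= 50")
  if (any(cfg$plantedSizes > cfg$nGenes))
    stopf("planted module size exceeds the network size")
  if (sum(cfg$plantedSizes) > cfg$nGenes / 2)
    stopf("planted modules may cover at most half the network")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stopf("dropout must be in [0,1)")
  if (cfg$internalDensity <= 0 || cfg$internalDensity > 1)
    stopf("internalDensity must be in (0,1]")
  if (length(cfg$dirichletAlpha) != length(cfg$cellTypes))
    stopf("dirichletAlpha must match cellTypes")
  if (cfg$deltaBeta < 0 || cfg$deltaBeta > 0.5)
    stopf("deltaBeta must be in [0, 0.5]")
  class(cfg) <- "femSimConfig"
  cfg
}

geneNames <- function(n) sprintf("g%04d", seq_len(n))

# deterministic planted marker profiles: per cell type, half the markers are
# hypermethylated in that type (beta 0.975 vs 0.025 elsewhere) and half
# hypomethylated (0.025 vs 0.975), as in real DNAm references; the mix keeps
# the reference columns linearly independent of the intercept
plantedMarkerProfiles <- function(cfg) {
  types <- cfg$cellTypes
  k <- length(types)
  nM <- cfg$markersPerType
  if (nM == 0)
    return(matrix(numeric(0), 0, k, dimnames = list(NULL, types)))
  names <- unlist(lapply(types, function(ct) sprintf("cg_%s_%03d", ct,
                                                     seq_len(nM))))
  prof <- matrix(NA_real_, k * nM, k, dimnames = list(names, types))
  for (j in seq_len(k)) {
    rows <- (j - 1) * nM + seq_len(nM)
    hyper <- rows[seq_len(ceiling(nM / 2))]
    hypo <- setdiff(rows, hyper)
    prof[hyper, ] <- 0.025; prof[hyper, j] <- 0.975
    prof[hypo, ] <- 0.975; prof[hypo, j] <- 0.025
  }
  prof
}

#' Simulate a PPI-like network with planted modules
#'
#' Generates an undirected scale-free backbone by preferential attachment,
#' then plants the configured modules as internally dense connected
#' subgraphs that touch the rest of the network through a small number of
#' boundary edges (a planted-partition-style construction: module members
#' have their original external edges rewired into the background so that
#' communities are insulated, as pathway modules are). Degrees of background
#' nodes are preserved by the rewiring.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return list with \code{network} (igraph, named nodes) and \code{truth}
#'   (planted module memberships and per-module effect signs).
#' @export
simulateNetwork <- function(cfg = simulationConfig()) {
  withSeed(childSeed(cfg$rngSeed, "network"), {
    n <- cfg$nGenes
    g <- igraph::sample_pa(n, power = 1, m = cfg$attachment,
                           directed = FALSE)
    igraph::V(g)$name <- geneNames(n)
    # choose disjoint member sets, avoiding the highest-degree hubs so that
    # module insulation is attainable
    deg <- igraph::degree(g)
    pool <- order(deg)[seq_len(floor(0.8 * n))]
    pool <- sample(pool)
    modules <- list()
    used <- integer(0)
    for (s in cfg$plantedSizes) {
      mem <- setdiff(pool, used)[seq_len(s)]
      used <- c(used, mem)
      modules[[length(modules) + 1]] <- mem
    }
    el <- igraph::as_edgelist(g, names = FALSE)
    inMod <- integer(n); for (k in seq_along(modules)) inMod[modules[[k]]] <- k
    crossing <- inMod[el[, 1]] != inMod[el[, 2]] &
      (inMod[el[, 1]] > 0 | inMod[el[, 2]] > 0)
    internalOld <- inMod[el[, 1]] > 0 & inMod[el[, 1]] == inMod[el[, 2]]
    keep <- el[!crossing & !internalOld, , drop = FALSE]
    # rewire the severed external stubs among background nodes
    bg <- which(inMod == 0)
    newEdges <- list()
    for (r in which(crossing)) {
      v <- if (inMod[el[r, 1]] == 0) el[r, 1] else el[r, 2]
      if (inMod[v] > 0) next  # module-module crossing: drop entirely
      w <- sample(setdiff(bg, v), 1)
      newEdges[[length(newEdges) + 1]] <- c(v, w)
    }
    # dense internal structure: a spanning path plus random extra edges
    for (k in seq_along(modules)) {
      mem <- modules[[k]]
      s <- length(mem)
      target <- max(s - 1, round(cfg$internalDensity * s * (s - 1) / 2))
      path <- cbind(mem[-s], mem[-1])
      allPairs <- t(utils::combn(mem, 2))
      pathKey <- paste(pmin(path[, 1], path[, 2]), pmax(path[, 1], path[, 2]))
      pairKey <- paste(pmin(allPairs[, 1], allPairs[, 2]),
                       pmax(allPairs[, 1], allPairs[, 2]))
      extra <- allPairs[!pairKey %in% pathKey, , drop = FALSE]
      nExtra <- min(target - (s - 1), nrow(extra))
      if (nExtra > 0)
        extra <- extra[sample.int(nrow(extra), nExtra), , drop = FALSE]
      else extra <- extra[0, , drop = FALSE]
      newEdges[[length(newEdges) + 1]] <- rbind(path, extra)
      # boundary edges into the background
      bnd <- cbind(sample(mem, cfg$boundaryEdges, replace = TRUE),
                   sample(bg, cfg$boundaryEdges))
      newEdges[[length(newEdges) + 1]] <- bnd
    }
    el2 <- rbind(keep, do.call(rbind, newEdges))
    g2 <- igraph::graph_from_edgelist(el2, directed = FALSE)
    g2 <- igraph::add_vertices(g2, n - igraph::vcount(g2))
    g2 <- igraph::simplify(g2)
    igraph::V(g2)$name <- geneNames(n)
    truth <- list(
      modules = lapply(modules, function(m) sort(geneNames(n)[m])),
      dnamSign = rep(sign(cfg$deltaBeta), length(modules)),
      exprSign = rep(sign(cfg$logFC), length(modules)))
    list(network = g2, truth = truth)
  })
}

#' Simulate a mixed-cell-type case/control cohort
#'
#' Per sample, true epithelial/fibroblast/immune fractions are drawn from a
#' Dirichlet distribution. Per gene and cell type a baseline promoter beta
#' is drawn; in cases, planted-module genes receive the configured beta
#' shift in the epithelial component only, and their expression is shifted
#' in the opposite direction (anti-correlation). The observed gene beta is
#' the fraction-weighted mixture with logit-normal noise, exploded to
#' TSS200/FirstExon/TSS1500 probes with probe-level jitter (TSS1500 probes
#' sit at a shifted baseline so that the summarization precedence matters).
#' Expression is baseline plus case effect plus Gaussian noise.
#'
#' @param network igraph network from \code{\link{simulateNetwork}}.
#' @param truth ground-truth list from \code{\link{simulateNetwork}}.
#' @param cfg a \code{\link{simulationConfig}}.
#' @param cnv one of "none", "independent", "confounded": optional per-gene
#'   copy-number covariate, independent of or confounded with the group.
#' @return list with \code{beta} (probe matrix), \code{annotation},
#'   \code{expr}, \code{sampleSheet}, \code{fractions} (true), and
#'   \code{cnv}; plus \code{geneBeta}, the noise-free per-gene observed
#'   mixture, for oracles.
#' @export
simulateCohort <- function(network, truth, cfg = simulationConfig(),
                           cnv = c("none", "independent", "confounded")) {
  cnv <- match.arg(cnv)
  withSeed(childSeed(cfg$rngSeed, "cohort"), {
    genes <- sort(igraph::V(network)$name)
    n <- length(genes)
    planted <- unique(unlist(truth$modules))
    isPlanted <- genes %in% planted
    nS <- cfg$nCases + cfg$nControls
    samples <- sprintf("s%03d", seq_len(nS))
    group <- c(rep("case", cfg$nCases), rep("normal", cfg$nControls))
    fr <- rdirichlet(nS, cfg$dirichletAlpha)
    dimnames(fr) <- list(samples, cfg$cellTypes)

    base <- ifelse(isPlanted, stats::runif(n, 0.1, 0.3),
                   stats::runif(n, 0.1, 0.9))
    ctOff <- matrix(stats::rnorm(n * length(cfg$cellTypes), 0, 0.5), n)
    mgc <- expit(logit(base) + ctOff)  # gene x cell-type baseline betas

    mix <- mgc %*% t(fr)
    if (cfg$deltaBeta != 0) {
      epiCase <- clampBeta(mgc[, 1] + cfg$deltaBeta)
      shift <- (epiCase - mgc[, 1]) * isPlanted
      mix <- mix + outer(shift, fr[, 1] * (group == "case"))
    }
    geneBeta <- expit(logit(clampBeta(mix)) +
                      matrix(stats::rnorm(n * nS, 0, cfg$logitNoiseSD), n))
    dimnames(geneBeta) <- list(genes, samples)

    ppg <- cfg$probesPerGene
    ann <- do.call(rbind, lapply(names(ppg), function(cl)
      if (ppg[[cl]] > 0)
        data.frame(probe_id = as.vector(outer(genes, seq_len(ppg[[cl]]),
                     function(g, k) sprintf("%s_%s_%d", g, cl, k))),
                   gene = rep(genes, ppg[[cl]]),
                   region_class = cl, stringsAsFactors = FALSE)))
    shift1500 <- ifelse(ann$region_class == "TSS1500", 0.5, 0)
    probeBeta <- expit(logit(geneBeta[ann$gene, , drop = FALSE]) + shift1500 +
                       matrix(stats::rnorm(nrow(ann) * nS, 0,
                                           cfg$probeJitterSD), nrow(ann)))
    rownames(probeBeta) <- ann$probe_id
    # marker CpGs (same planted markers as simulatePureProfiles) are part of
    # the measured array, so the cohort can be deconvolved end-to-end
    if (cfg$markersPerType > 0) {
      mkProfile <- plantedMarkerProfiles(cfg)
      mkNames <- rownames(mkProfile)
      mkBeta <- expit(logit(clampBeta(mkProfile %*% t(fr))) +
                      matrix(stats::rnorm(length(mkNames) * nS, 0,
                                          cfg$logitNoiseSD), length(mkNames)))
      probeBeta <- rbind(probeBeta, mkBeta)
    }

    exprBase <- stats::rnorm(n, 6, 1)
    eff <- cfg$logFC * isPlanted
    if (!cfg$antiCorrelated) eff <- abs(eff) * sign(cfg$deltaBeta)
    expr <- outer(exprBase, rep(1, nS)) +
      outer(eff, as.numeric(group == "case")) +
      matrix(stats::rnorm(n * nS, 0, cfg$exprNoiseSD), n)
    dimnames(expr) <- list(genes, samples)

    cnvMat <- NULL
    if (cnv != "none") {
      cnvMat <- matrix(stats::rnorm(n * nS, 0, 0.2), n,
                       dimnames = list(genes, samples))
      if (cnv == "confounded")
        cnvMat <- cnvMat + outer(0.5 * isPlanted,
                                 as.numeric(group == "case"))
    }
    list(beta = probeBeta, annotation = ann, expr = expr,
         sampleSheet = data.frame(sample_id = samples, group = group,
                                  stringsAsFactors = FALSE),
         fractions = fr, cnv = cnvMat, geneBeta = geneBeta, truth = truth)
  })
}

#' Simulate purified cell-type DNAm profiles with planted markers
#'
#' Each cell type receives \code{markersPerType} marker CpGs, half
#' hypermethylated in that cell type (beta ~ 0.975 against ~ 0.025
#' elsewhere) and half hypomethylated, giving planted mean differences of
#' about 0.95 in either direction, as in real DNAm references; non-marker
#' CpGs share a common baseline across cell types. Logit-normal noise is
#' added per sample.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return list with \code{beta} (CpG x sample), \code{labels} (cell type
#'   per sample) and \code{markers} (named list of planted marker CpGs).
#' @export
simulatePureProfiles <- function(cfg = simulationConfig()) {
  withSeed(childSeed(cfg$rngSeed, "pure"), {
    types <- cfg$cellTypes
    k <- length(types)
    prof <- plantedMarkerProfiles(cfg)
    markers <- lapply(types, function(ct)
      rownames(prof)[grepl(sprintf("^cg_%s_", ct), rownames(prof))])
    names(markers) <- types
    nonmark <- sprintf("cg_shared_%04d", seq_len(cfg$nNonMarkerCpGs))
    cpgs <- c(rownames(prof), nonmark)
    baseline <- matrix(rep(stats::runif(length(cpgs), 0.2, 0.8), k),
                       ncol = k, dimnames = list(cpgs, types))
    baseline[rownames(prof), ] <- prof
    labels <- rep(types, each = cfg$purePerType)
    samples <- sprintf("p_%s_%d", labels, sequence(rep(cfg$purePerType, k)))
    b <- expit(logit(baseline[, match(labels, types), drop = FALSE]) +
               matrix(stats::rnorm(length(cpgs) * length(labels), 0,
                                   cfg$pureNoiseSD), length(cpgs)))
    dimnames(b) <- list(cpgs, samples)
    list(beta = b, labels = stats::setNames(labels, samples),
         markers = markers)
  })
}

#' Simulate a staged saliva-like DNAm cohort
#'
#' Emulates a surrogate-tissue cohort across disease stages N, NDBE, HGD and
#' C: the mean epithelial fraction increases with stage per the configured
#' trend, and the designated module's promoter betas shift with stage in the
#' epithelial component only. Observed probe-level betas are mixtures with
#' logit-normal noise, exploded to probes as in \code{\link{simulateCohort}}.
#'
#' @param network,truth from \code{\link{simulateNetwork}}.
#' @param cfg a \code{\link{simulationConfig}}.
#' @param moduleIndex which planted module carries the stage effect.
#' @return list with \code{beta}, \code{annotation}, \code{sampleSheet}
#'   (group = stage), \code{fractions} (true), \code{geneBeta}.
#' @export
simulateSalivaCohort <- function(network, truth, cfg = simulationConfig(),
                                 moduleIndex = 1) {
  withSeed(childSeed(cfg$rngSeed, "saliva"), {
    genes <- sort(igraph::V(network)$name)
    n <- length(genes)
    stages <- names(cfg$salivaStageSizes)
    sizes <- cfg$salivaStageSizes
    stage <- rep(stages, sizes)
    nS <- length(stage)
    samples <- sprintf("sal%03d", seq_len(nS))
    stageIdx <- match(stage, stages) - 1

    conc <- 30
    epiMean <- cfg$salivaEpiTrend[stageIdx + 1]
    fEpi <- stats::rbeta(nS, epiMean * conc, (1 - epiMean) * conc)
    restSplit <- rdirichlet(nS, c(1, 9))  # fibroblast negligible in saliva
    fr <- cbind(fEpi, (1 - fEpi) * restSplit)
    dimnames(fr) <- list(samples, cfg$cellTypes)

    modGenes <- truth$modules[[moduleIndex]]
    isMod <- genes %in% modGenes
    base <- ifelse(isMod, stats::runif(n, 0.1, 0.3), stats::runif(n, 0.1, 0.9))
    ctOff <- matrix(stats::rnorm(n * length(cfg$cellTypes), 0, 0.5), n)
    mgc <- expit(logit(base) + ctOff)

    mix <- mgc %*% t(fr)
    if (cfg$salivaDeltaPerStage != 0) {
      for (j in which(stageIdx > 0)) {
        epiShift <- clampBeta(mgc[, 1] +
                              cfg$salivaDeltaPerStage * stageIdx[j]) - mgc[, 1]
        mix[, j] <- mix[, j] + epiShift * isMod * fr[j, 1]
      }
    }
    geneBeta <- expit(logit(clampBeta(mix)) +
                      matrix(stats::rnorm(n * nS, 0, cfg$logitNoiseSD), n))
    dimnames(geneBeta) <- list(genes, samples)

    ppg <- cfg$probesPerGene
    ann <- do.call(rbind, lapply(names(ppg), function(cl)
      if (ppg[[cl]] > 0)
        data.frame(probe_id = as.vector(outer(genes, seq_len(ppg[[cl]]),
                     function(g, k) sprintf("%s_%s_%d", g, cl, k))),
                   gene = rep(genes, ppg[[cl]]),
                   region_class = cl, stringsAsFactors = FALSE)))
    shift1500 <- ifelse(ann$region_class == "TSS1500", 0.5, 0)
    probeBeta <- expit(logit(geneBeta[ann$gene, , drop = FALSE]) + shift1500 +
                       matrix(stats::rnorm(nrow(ann) * nS, 0,
                                           cfg$probeJitterSD), nrow(ann)))
    rownames(probeBeta) <- ann$probe_id
    if (cfg$markersPerType > 0) {
      mkProfile <- plantedMarkerProfiles(cfg)
      mkBeta <- expit(logit(clampBeta(mkProfile %*% t(fr))) +
                      matrix(stats::rnorm(nrow(mkProfile) * nS, 0,
                                          cfg$logitNoiseSD), nrow(mkProfile)))
      probeBeta <- rbind(probeBeta, mkBeta)
    }

    list(beta = probeBeta, annotation = ann,
         sampleSheet = data.frame(sample_id = samples, group = stage,
                                  stringsAsFactors = FALSE),
         fractions = fr, geneBeta = geneBeta,
         moduleGenes = sort(modGenes))
  })
}

#' Simulate dropout-laden single-cell log expression
#'
#' Cells from several patients and two tissues (BE-like and normal
#' squamous); BE cells shift the designated signature genes by the
#' configured amount, Gaussian noise is added, negative log values are
#' clipped at zero, and Bernoulli dropout zeroes entries at the configured
#' rate.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @param signatureGenes genes carrying the BE shift.
#' @param signatureSigns +1/-1 per signature gene (direction of the BE
#'   shift); default all +1.
#' @param genes full gene universe; defaults to the package's synthetic gene
#'   names of size \code{cfg$nGenes}.
#' @return list with \code{logexpr} (gene x cell), \code{cells} data.frame
#'   (cell_id, patient, tissue).
#' @export
simulateScrna <- function(cfg = simulationConfig(), signatureGenes,
                          signatureSigns = NULL, genes = NULL) {
  withSeed(childSeed(cfg$rngSeed, "scrna"), {
    if (is.null(genes)) genes <- geneNames(cfg$nGenes)
    if (is.null(signatureSigns))
      signatureSigns <- rep(1, length(signatureGenes))
    nG <- length(genes)
    per <- cfg$cellsPerPatient
    cells <- do.call(rbind, lapply(seq_len(cfg$nPatients), function(p)
      data.frame(patient = sprintf("P%d", p),
                 tissue = rep(names(per), per), stringsAsFactors = FALSE)))
    cells$cell_id <- sprintf("c%05d", seq_len(nrow(cells)))
    nC <- nrow(cells)
    base <- stats::runif(nG, 0.5, 3)
    m <- outer(base, rep(1, nC))
    isBE <- cells$tissue == "BE"
    i <- match(signatureGenes, genes)
    ok <- !is.na(i)
    m[i[ok], isBE] <- m[i[ok], isBE] + cfg$scShift * signatureSigns[ok]
    m <- m + matrix(stats::rnorm(nG * nC, 0, cfg$scNoiseSD), nG)
    m <- pmax(m, 0)
    if (cfg$dropout > 0)
      m[matrix(stats::runif(nG * nC) < cfg$dropout, nG)] <- 0
    dimnames(m) <- list(genes, cells$cell_id)
    list(logexpr = m, cells = cells[, c("cell_id", "patient", "tissue")])
  })
}
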