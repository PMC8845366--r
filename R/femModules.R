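#' Integrated differential methylation/expression statistic
#'
#' The per-gene integrated statistic rewards anti-correlated change:
#' \deqn{t^{(I)} = \{H(t_{DM})H(-t_{DE}) + H(-t_{DM})H(t_{DE})\}\,|t_{DM}-t_{DE}|}
#' where \eqn{H} is the Heaviside step with \eqn{H(0)=0}, so the statistic is
#' positive only when the methylation and expression t-statistics have
#' strictly opposite signs (promoter hypermethylation with underexpression,
#' or hypomethylation with overexpression), and is zero otherwise.
#'
#' @param tDM,tDE numeric vectors of differential methylation / expression
#'   t-statistics (recycled to common length).
#' @return nonnegative numeric vector.
#' @examples
#' integratedStatistic(2, -3)   # 5
#' integratedStatistic(2, 3)    # 0
#' @export
integratedStatistic <- function(tDM, tDE) {
  if (any(!is.finite(tDM)) || any(!is.finite(tDE)))
    stopf("integrated statistic requires finite inputs")
  opposite <- (tDM > 0 & tDE < 0) | (tDM < 0 & tDE > 0)
  as.numeric(opposite) * abs(tDM - tDE)
}

#' Weight a gene network by integrated statistics
#'
#' Assigns each edge the average of its two genes' integrated statistics,
#' \eqn{w_{gh} = 0.5 (t_g^{(I)} + t_h^{(I)})}, and caches per-node weighted
#' degrees and the total edge weight. Network genes absent from the
#' statistics table receive \eqn{t^{(I)} = 0}, with a reported count.
#'
#' @param network igraph undirected simple graph with gene names.
#' @param stats a \linkS4class{GeneStats} object (or a named numeric vector
#'   of integrated statistics).
#' @return a \linkS4class{WeightedNetwork}.
#' @export
weightNetwork <- function(network, stats) {
  tv <- if (is(stats, "GeneStats")) tInt(stats) else stats
  nodes <- sort(igraph::V(network)$name)
  n <- length(nodes)
  t <- tv[nodes]
  nMissing <- sum(is.na(t))
  if (nMissing > 0) {
    message(sprintf("weightNetwork: %d network gene(s) without statistics get t_int = 0",
                    nMissing))
    t[is.na(t)] <- 0
  }
  names(t) <- nodes
  el <- igraph::as_edgelist(network)
  e1 <- match(el[, 1], nodes); e2 <- match(el[, 2], nodes)
  swap <- e1 > e2
  tmp <- e1[swap]; e1[swap] <- e2[swap]; e2[swap] <- tmp
  edges <- cbind(e1, e2)
  w <- 0.5 * (t[e1] + t[e2])
  names(w) <- NULL
  deg <- tabulate(c(e1, e2), nbins = n)
  wdeg <- numeric(n)
  agg <- rowsum(c(w, w), c(e1, e2))
  wdeg[as.integer(rownames(agg))] <- agg[, 1]
  adj <- vector("list", n); adjEdges <- vector("list", n)
  ord <- split(seq_along(e1), e1)
  ord2 <- split(seq_along(e2), e2)
  for (i in seq_len(n)) {
    ei <- c(ord[[as.character(i)]], ord2[[as.character(i)]])
    if (is.null(ei)) ei <- integer(0)
    adjEdges[[i]] <- ei
    adj[[i]] <- ifelse(edges[ei, 1] == i, edges[ei, 2], edges[ei, 1])
  }
  new("WeightedNetwork", nodes = nodes, edges = edges, weights = as.numeric(w),
      tInt = as.numeric(t), wdeg = wdeg, deg = as.integer(deg),
      totalWeight = sum(w), adj = adj, adjEdges = adjEdges)
}

# energy of a member set given summaries: internal weight sw, sum of weighted
# degrees sd, sum of squared weighted degrees sd2
energyFromSummaries <- function(sw, sd, sd2, gamma, W) {
  if (W <= 0) return(sw * 0)  # all-null statistics: every energy is 0
  -(sw - gamma * (sd^2 - sd2) / (4 * W))
}

#' Spin-glass Hamiltonian energy of a gene set
#'
#' The module energy is \eqn{-\sum_{g<h \in M} (w_{gh} - \gamma p_{gh})} over
#' unordered member pairs, where \eqn{w_{gh}} is the edge weight (0 for
#' non-edges) and \eqn{p_{gh} = w_{g\cdot} w_{h\cdot} / (2W)} is the
#' configuration-model null expectation from the weighted degrees
#' \eqn{w_{g\cdot}} and total weight \eqn{W}. Lower energy means the module
#' is heavier than expected under the null. When \eqn{W = 0} all energies
#' are defined to be 0.
#'
#' @param members character vector of member genes (or integer node indices).
#' @param wnet a \linkS4class{WeightedNetwork}.
#' @param gamma resolution parameter.
#' @return scalar energy.
#' @export
moduleEnergy <- function(members, wnet, gamma = 0.5) {
  idx <- resolveMembers(members, wnet)
  inM <- logical(length(wnet@nodes)); inM[idx] <- TRUE
  e <- wnet@edges
  internal <- inM[e[, 1]] & inM[e[, 2]]
  sw <- sum(wnet@weights[internal])
  sd <- sum(wnet@wdeg[idx]); sd2 <- sum(wnet@wdeg[idx]^2)
  energyFromSummaries(sw, sd, sd2, gamma, wnet@totalWeight)
}

resolveMembers <- function(members, wnet) {
  if (is.character(members)) {
    idx <- match(members, wnet@nodes)
    if (anyNA(idx))
      stopf("member(s) not in network: %s",
            paste(utils::head(members[is.na(idx)], 5), collapse = ", "))
    idx
  } else as.integer(members)
}

#' Grow a module from a seed gene by greedy energy minimization
#'
#' Starting from the singleton seed, repeatedly evaluates every gene adjacent
#' to the current module and adds the one yielding the largest decrease of
#' the Hamiltonian energy; growth stops when no neighbouring gene decreases
#' the energy (or when \code{maxSize} is reached). Ties are broken by
#' lexicographic gene id, making growth fully deterministic. The energy after
#' each accepted step is recorded and is strictly decreasing.
#'
#' @param seed seed gene id.
#' @param wnet a \linkS4class{WeightedNetwork}.
#' @param config a \linkS4class{SpinGlassConfig} (only \code{gamma} is used).
#' @param maxSize optional hard cap on module size; growth that is still
#'   improving at the cap is cut off there (used by
#'   \code{\link{inferModules}}, whose size filter discards such modules
#'   anyway).
#' @return a \linkS4class{FemModule} (Monte-Carlo p not yet computed).
#' @export
growModule <- function(seed, wnet, config = SpinGlassConfig(), maxSize = Inf) {
  sIdx <- resolveMembers(seed, wnet)
  gamma <- config@gamma
  n <- length(wnet@nodes)
  W <- wnet@totalWeight
  inM <- logical(n)
  wToM <- numeric(n)     # sum of edge weights from each node into the module
  isCand <- logical(n)
  members <- integer(0)
  sd <- 0
  energy <- 0
  trace <- numeric(0)

  addNode <- function(v) {
    inM[v] <<- TRUE
    members <<- c(members, v)
    sd <<- sd + wnet@wdeg[v]
    nb <- wnet@adj[[v]]
    ew <- wnet@weights[wnet@adjEdges[[v]]]
    keep <- !inM[nb]
    wToM[nb[keep]] <<- wToM[nb[keep]] + ew[keep]
    isCand[nb[keep]] <<- TRUE
    isCand[v] <<- FALSE
  }
  addNode(sIdx)

  if (W > 0) {
    while (length(members) < maxSize) {
      cand <- which(isCand)
      if (length(cand) == 0) break
      gains <- wToM[cand] - gamma * wnet@wdeg[cand] * sd / (2 * W)
      best <- max(gains)
      if (best <= 1e-12) break
      pick <- cand[which(gains >= best - 1e-12)[1]]  # lexicographic tie-break
      energy <- energy - (wToM[pick] - gamma * wnet@wdeg[pick] * sd / (2 * W))
      addNode(pick)
      trace <- c(trace, energy)
    }
  }
  memberNames <- wnet@nodes[members]  # in addition order, seed first
  new("FemModule", seed = wnet@nodes[sIdx], members = memberNames,
      energy = energy, modularity = -energy / length(members),
      mcP = NA_real_, energyTrace = trace,
      flags = data.frame())
}

# run code under a temporary RNG state seeded with `seed`
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Monte-Carlo significance of a module
#'
#' Keeps the network topology and the module membership fixed, permutes the
#' node-level integrated statistics uniformly over all nodes, re-derives the
#' edge weights and weighted degrees, and recomputes the module's
#' size-normalized modularity for each run. The p-value is
#' \eqn{(1 + \#\{\mathrm{runs\ with\ modularity} \ge \mathrm{observed}\}) /
#' (1 + \mathrm{runs})}.
#'
#' @param module a \linkS4class{FemModule}.
#' @param wnet the \linkS4class{WeightedNetwork} the module was grown on.
#' @param config a \linkS4class{SpinGlassConfig}; \code{mcRuns} and
#'   \code{rngSeed} govern the randomization.
#' @return the Monte-Carlo p-value.
#' @export
mcSignificance <- function(module, wnet, config = SpinGlassConfig()) {
  idx <- resolveMembers(moduleMembers(module), wnet)
  m <- length(idx)
  if (m == 0) stopf("empty module")
  n <- length(wnet@nodes)
  gamma <- config@gamma
  e <- wnet@edges
  inM <- logical(n); inM[idx] <- TRUE
  internal <- inM[e[, 1]] & inM[e[, 2]]
  indeg <- tabulate(c(e[internal, 1], e[internal, 2]), nbins = n)[idx]
  # sparse member-row adjacency for fast weighted-degree recomputation
  nb <- wnet@adj[idx]
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(m), lengths(nb)),
    j = unlist(nb),
    x = 1, dims = c(m, n), index1 = TRUE)
  obs <- -moduleEnergy(idx, wnet, gamma) / m

  degM <- wnet@deg[idx]
  modNull <- withSeed(config@rngSeed, {
    out <- numeric(config@mcRuns)
    chunk <- 250L
    done <- 0L
    while (done < config@mcRuns) {
      nr <- min(chunk, config@mcRuns - done)
      P <- vapply(seq_len(nr), function(r) wnet@tInt[sample.int(n)],
                  numeric(n))
      TM <- P[idx, , drop = FALSE]
      wdegM <- 0.5 * (degM * TM + as.matrix(A %*% P))
      sw <- 0.5 * colSums(indeg * TM)
      sdv <- colSums(wdegM); sd2 <- colSums(wdegM^2)
      Wv <- 0.5 * as.numeric(wnet@deg %*% P)
      en <- -(sw - gamma * (sdv^2 - sd2) / (4 * Wv))
      en[Wv <= 0] <- 0
      out[done + seq_len(nr)] <- -en / m
      done <- done + nr
    }
    out
  })
  (1 + sum(modNull >= obs - 1e-12)) / (1 + config@mcRuns)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

annotateModule <- function(module, stats, sigThresh = 0.05) {
  s <- statTable(stats)
  i <- match(moduleMembers(module), s$gene)
  dm <- !is.na(i) & s$fdr_dm[i] < sigThresh
  dr <- !is.na(i) & s$fdr_de[i] < sigThresh
  dmdr <- dm & dr
  anti <- dmdr & !is.na(i) & sign(s$t_dm[i]) == -sign(s$t_de[i]) &
    s$t_dm[i] != 0
  module@flags <- data.frame(gene = moduleMembers(module), dm = dm, dr = dr,
                             dmdr = dmdr, anticorrelated = anti,
                             stringsAsFactors = FALSE)
  module
}

#' Infer functional epigenetic modules
#'
#' The full seeded spin-glass search: the top \code{nSeeds} genes by
#' integrated statistic are used as seeds; a module is grown greedily from
#' each; modules outside the configured size range are discarded; the
#' Monte-Carlo randomization test is applied to the survivors and only
#' modules with \code{mcP < alpha} are kept; overlapping modules (Jaccard
#' index > 0.5) are deduplicated keeping the lower-energy one; finally,
#' members are annotated as significantly differentially methylated (DM),
#' differentially expressed (DR), both (DM&DR), and anti-correlated (DM&DR
#' with opposite t signs).
#'
#' @param wnet a \linkS4class{WeightedNetwork}.
#' @param stats the \linkS4class{GeneStats} used to weight the network.
#' @param config a \linkS4class{SpinGlassConfig}.
#' @param sigThresh gene-level BH FDR threshold for the DM/DR member flags.
#' @return a \linkS4class{FemModuleSet}.
#' @export
inferModules <- function(wnet, stats, config = SpinGlassConfig(),
                         sigThresh = 0.05) {
  t <- wnet@tInt
  ord <- order(-t, wnet@nodes)
  seeds <- wnet@nodes[ord[seq_len(min(config@nSeeds, length(t)))]]
  grown <- lapply(seeds, growModule, wnet = wnet, config = config,
                  maxSize = config@sizeMax + 1L)
  sizes <- vapply(grown, function(m) length(moduleMembers(m)), integer(1))
  grown <- grown[sizes >= config@sizeMin & sizes <= config@sizeMax]
  if (length(grown) == 0) {
    message("inferModules: no module in the configured size range")
    return(new("FemModuleSet", modules = list()))
  }
  for (i in seq_along(grown))
    grown[[i]]@mcP <- mcSignificance(grown[[i]], wnet, config)
  grown <- grown[vapply(grown, mcPValue, numeric(1)) < config@alpha]
  if (length(grown) == 0) {
    message("inferModules: no module passed the Monte-Carlo test")
    return(new("FemModuleSet", modules = list()))
  }
  # deduplicate: visit by increasing energy, keep a module only if it does
  # not overlap (Jaccard > 0.5) an already kept one
  ordE <- order(vapply(grown, moduleEnergyValue, numeric(1)),
                vapply(grown, moduleSeed, character(1)))
  kept <- list()
  for (i in ordE) {
    mi <- grown[[i]]
    dup <- any(vapply(kept, function(k)
      jaccard(moduleMembers(k), moduleMembers(mi)) > 0.5, logical(1)))
    if (!dup) kept[[length(kept) + 1]] <- mi
  }
  kept <- lapply(kept, annotateModule, stats = stats, sigThresh = sigThresh)
  new("FemModuleSet", modules = kept)
}
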