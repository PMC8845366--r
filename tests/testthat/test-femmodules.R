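test_that("integrated statistic matches hand evaluation and conventions", {
  expect_equal(integratedStatistic(2, -3), 5)
  expect_equal(integratedStatistic(-1, 2.5), 3.5)
  expect_equal(integratedStatistic(2, 3), 0)    # concordant signs
  expect_equal(integratedStatistic(0, 5), 0)    # H(0) = 0 convention
  expect_equal(integratedStatistic(-4, 0), 0)
  expect_error(integratedStatistic(NA, 1), "finite")
  expect_error(integratedStatistic(1, Inf), "finite")
})

test_that("integrated statistic is symmetric under a global sign flip", {
  set.seed(1)
  a <- rnorm(200); b <- rnorm(200)
  expect_equal(integratedStatistic(a, b), integratedStatistic(-a, -b))
  expect_true(all(integratedStatistic(a, b) >= 0))
})

test_that("network weighting averages the incident statistics", {
  tInt <- c(A = 4, B = 6, C = 0, D = 2)
  wn <- makeWeightedNet(tInt, rbind(c("A", "B"), c("B", "C"), c("C", "D"),
                                    c("A", "C")))
  e <- wn@edges; w <- wn@weights
  key <- paste(wn@nodes[e[, 1]], wn@nodes[e[, 2]])
  expect_equal(w[key == "A B"], 5)
  expect_equal(w[key == "B C"], 3)
  expect_equal(w[key == "C D"], 1)
  expect_equal(wn@totalWeight, 5 + 3 + 1 + 2)  # hand-summed
  # missing statistics become zero with a message
  g <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("B", "E")),
                                   directed = FALSE)
  expect_message(wn2 <- weightNetwork(g, c(A = 4, B = 6)), "1 network gene")
  expect_equal(wn2@tInt[wn2@nodes == "E"], 0)
  # all-null statistics: every weight zero
  wn0 <- makeWeightedNet(c(A = 0, B = 0), rbind(c("A", "B")))
  expect_equal(wn0@totalWeight, 0)
})

test_that("module energy matches hand evaluation and the pairwise oracle", {
  # singleton: no pairs
  wn <- makeWeightedNet(c(A = 1, B = 3), rbind(c("A", "B")))
  expect_equal(moduleEnergy("A", wn), 0)
  # constructed two-node case: w_AB = 2 and p_AB = 0.1 via a heavy far pair
  tInt <- c(A = 2, B = 2, C = 18, D = 18)
  edges <- rbind(c("A", "B"), c("C", "D"))
  wn2 <- makeWeightedNet(tInt, edges)
  expect_equal(moduleEnergy(c("A", "B"), wn2, gamma = 0.5), -(2 - 0.05))
  # null term dominates for a module with no internal edges
  expect_gt(moduleEnergy(c("A", "C"), wn2, gamma = 5), 0)
  expect_error(moduleEnergy(c("A", "Z"), wn2), "not in network")
  # random graphs against the independent pairwise oracle
  set.seed(7)
  for (rep in 1:10) {
    inst <- randomSmallInstance(n = 9)
    wn3 <- makeWeightedNet(inst$tInt, inst$edges)
    mem <- sample(names(inst$tInt), 4)
    expect_equal(moduleEnergy(mem, wn3, 0.5),
                 energyOracle(mem, inst$tInt, inst$edges, 0.5),
                 tolerance = 1e-10)
  }
})

test_that("greedy growth absorbs a strong star and stalls on a dominated seed", {
  # star with strongly weighted spokes, tiny gamma: whole star absorbed
  spokes <- sprintf("S%d", 1:5)
  tInt <- c(H = 10, setNames(rep(8, 5), spokes))
  wn <- makeWeightedNet(tInt, cbind("H", spokes))
  m <- growModule("H", wn, SpinGlassConfig(gamma = 0.1))
  expect_setequal(moduleMembers(m), c("H", spokes))
  expect_equal(moduleSeed(m), "H")
  # a seed whose incident edges carry zero weight (both endpoints have a
  # zero integrated statistic) has no improving move: the null penalty is
  # the only term and the module stays a singleton
  tInt2 <- c(A = 0, B = 0, C = 10, D = 10)
  edges2 <- rbind(c("A", "B"), c("B", "C"), c("C", "D"))
  wn2 <- makeWeightedNet(tInt2, edges2)
  m2 <- growModule("A", wn2, SpinGlassConfig(gamma = 0.5))
  expect_equal(moduleMembers(m2), "A")
  # isolated seed
  wn3 <- makeWeightedNet(c(A = 1, B = 2, C = 3), rbind(c("B", "C")))
  expect_equal(moduleMembers(growModule("A", wn3)), "A")
})

test_that("recorded energies decrease strictly and match full recomputation", {
  set.seed(12)
  for (rep in 1:15) {
    inst <- randomSmallInstance(n = 12, p = 0.4)
    wn <- makeWeightedNet(inst$tInt, inst$edges)
    m <- growModule(inst$seed, wn)
    tr <- m@energyTrace
    if (length(tr) >= 2) expect_true(all(diff(tr) < 0))
    # incremental energies equal full recomputation at every prefix
    mem <- moduleMembers(m)  # in addition order
    for (k in seq_along(tr)) {
      expect_equal(tr[k], moduleEnergy(mem[seq_len(k + 1)], wn, 0.5),
                   tolerance = 1e-10)
    }
  }
})

test_that("greedy energy respects the exhaustive connected-subset oracle", {
  set.seed(99)
  nStrong <- 0; nStrongEqual <- 0
  for (rep in 1:40) {
    strong <- rep %% 2 == 0
    inst <- randomSmallInstance(n = 10, strong = strong)
    wn <- makeWeightedNet(inst$tInt, inst$edges)
    m <- growModule(inst$seed, wn)
    gE <- moduleEnergyValue(m)
    nodes <- wn@nodes
    adj <- wn@adj
    seedIdx <- which(nodes == inst$seed)
    subsets <- connectedSubsetsWithSeed(adj, seedIdx)
    minE <- min(vapply(subsets, function(s) moduleEnergy(s, wn, 0.5),
                       numeric(1)))
    expect_gte(gE, minE - 1e-10)
    if (strong) {
      nStrong <- nStrong + 1
      if (abs(gE - minE) < 1e-10) nStrongEqual <- nStrongEqual + 1
    }
  }
  # on the strong planted instances the greedy optimum is the global one
  expect_equal(nStrongEqual, nStrong)
})

test_that("Monte-Carlo significance is deterministic, calibrated and powered", {
  # permutation-invariant statistics give p = 1
  nodes <- sprintf("n%02d", 1:12)
  el <- t(combn(nodes, 2)); el <- el[seq(1, nrow(el), by = 3), ]
  wnFlat <- makeWeightedNet(setNames(rep(2, 12), nodes), el)
  mFlat <- growModule("n01", wnFlat)
  cfg <- SpinGlassConfig(mcRuns = 199, rngSeed = 5)
  expect_equal(mcSignificance(mFlat, wnFlat, cfg), 1)
  # determinism under a fixed seed
  set.seed(4)
  inst <- randomSmallInstance(n = 12, p = 0.5)
  wn <- makeWeightedNet(inst$tInt, inst$edges)
  m <- growModule(inst$seed, wn)
  p1 <- mcSignificance(m, wn, cfg)
  p2 <- mcSignificance(m, wn, cfg)
  expect_identical(p1, p2)
  # planted concentration of the largest statistics: p at the floor
  strong <- randomSmallInstance(n = 12, strong = TRUE)
  wnS <- makeWeightedNet(strong$tInt, strong$edges)
  mS <- growModule(strong$seed, wnS)
  cfgBig <- SpinGlassConfig(mcRuns = 1000, rngSeed = 5)
  expect_lte(mcSignificance(mS, wnS, cfgBig), 0.01)
})

test_that("mc p-values are roughly uniform for random modules under the null", {
  set.seed(61)
  cfg <- simulationConfig(rngSeed = 61, nGenes = 300L,
                          plantedSizes = c(20L, 20L),
                          deltaBeta = 0, logFC = 0)
  net <- simulateNetwork(cfg)
  tNull <- setNames(abs(rnorm(300)), sort(igraph::V(net$network)$name))
  wn <- weightNetwork(net$network, tNull)
  sg <- SpinGlassConfig(mcRuns = 200, rngSeed = 61)
  ps <- vapply(1:120, function(i) {
    start <- sample(wn@nodes, 1)
    nb <- igraph::neighborhood(net$network, order = 2,
                               nodes = start)[[1]]$name
    mem <- unique(c(start, sample(nb, min(7, length(nb)))))
    mod <- new("FemModule", seed = start, members = mem, energy = 0,
               modularity = 0, mcP = NA_real_, energyTrace = numeric(0),
               flags = data.frame())
    mcSignificance(mod, wn, SpinGlassConfig(mcRuns = 200,
                                            rngSeed = 61 + i))
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("module inference applies size filter, dedup and annotation", {
  # strong isolated clique of 6 in a weak background: two member seeds
  # collapse to one module after deduplication; sizeMin above the clique
  # size rejects it
  set.seed(8)
  clique <- sprintf("c%d", 1:6)
  bg <- sprintf("b%02d", 1:20)
  elC <- t(combn(clique, 2))
  elB <- t(combn(bg, 2)); elB <- elB[runif(nrow(elB)) < 0.25, ]
  edges <- rbind(elC, elB, c("c1", "b01"))
  tInt <- c(setNames(runif(6, 8, 10), clique), setNames(runif(20, 0, 0.5), bg))
  tdm <- tInt / 2; tde <- -tInt / 2
  stats <- new("GeneStats", stats = makeStats(names(tInt), tdm, tde))
  wn <- weightNetwork(igraph::graph_from_edgelist(edges, directed = FALSE),
                      stats)
  cfg <- SpinGlassConfig(nSeeds = 4, sizeMin = 3, sizeMax = 15,
                         mcRuns = 299, rngSeed = 2)
  mods <- inferModules(wn, stats, cfg)
  expect_equal(length(mods), 1L)
  expect_true(all(clique %in% moduleMembers(mods[[1]])))
  fl <- memberFlags(mods[[1]])
  expect_true(all(fl$anticorrelated[fl$gene %in% clique]))
  expect_true(all(fl$dmdr == (fl$dm & fl$dr)))
  # a size filter above the module size rejects it
  cfgBig <- SpinGlassConfig(nSeeds = 4, sizeMin = 10, sizeMax = 15,
                            mcRuns = 299, rngSeed = 2)
  expect_message(none <- inferModules(wn, stats, cfgBig), "no module")
  expect_equal(length(none), 0L)
})
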