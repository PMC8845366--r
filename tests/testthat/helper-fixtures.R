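# shared fixture builders and independent oracles, all constructed in code

# write a small matrix to a temp TSV and return the path
writeTempMatrix <- function(m, idColumn = "probe_id", sep = "\t",
                            ext = ".tsv") {
  path <- tempfile(fileext = ext)
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- idColumn
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# weighted network from an explicit node-statistic vector and edge list
makeWeightedNet <- function(tInt, edges) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  missing <- setdiff(names(tInt), igraph::V(g)$name)
  if (length(missing) > 0) g <- igraph::add_vertices(g, length(missing),
                                                     name = missing)
  weightNetwork(g, tInt)
}

# independent oracle: module energy by direct evaluation of the formula,
# pairwise, without any of the package's cached summaries
energyOracle <- function(members, tInt, edges, gamma = 0.5) {
  nodes <- sort(unique(c(edges[, 1], edges[, 2], names(tInt))))
  t <- setNames(rep(0, length(nodes)), nodes)
  t[names(tInt)] <- tInt
  w <- 0.5 * (t[edges[, 1]] + t[edges[, 2]])
  W <- sum(w)
  if (W <= 0) return(0)
  wdeg <- setNames(rep(0, length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    wdeg[edges[i, 1]] <- wdeg[edges[i, 1]] + w[i]
    wdeg[edges[i, 2]] <- wdeg[edges[i, 2]] + w[i]
  }
  ew <- function(a, b) {
    hit <- (edges[, 1] == a & edges[, 2] == b) |
           (edges[, 1] == b & edges[, 2] == a)
    if (any(hit)) sum(w[hit]) else 0
  }
  e <- 0
  if (length(members) >= 2) {
    pairs <- combn(members, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      e <- e - (ew(a, b) - gamma * wdeg[a] * wdeg[b] / (2 * W))
    }
  }
  unname(e)
}

# enumerate all connected node subsets that contain `seed` (indices into the
# adjacency list), up to the full graph; standard recursive expansion
connectedSubsetsWithSeed <- function(adj, seed) {
  n <- length(adj)
  out <- list()
  recurse <- function(members, frontier, banned) {
    out[[length(out) + 1]] <<- members
    cand <- setdiff(frontier, banned)
    while (length(cand) > 0) {
      v <- cand[1]
      newFrontier <- union(frontier, setdiff(adj[[v]], c(members, v)))
      recurse(c(members, v), setdiff(newFrontier, v), banned)
      banned <- c(banned, v)
      cand <- cand[-1]
    }
  }
  recurse(seed, setdiff(adj[[seed]], seed), integer(0))
  out
}

# random small weighted-graph instance for the exhaustive-oracle tests
randomSmallInstance <- function(n = 10, p = 0.35, strong = FALSE) {
  nodes <- sprintf("n%02d", seq_len(n))
  repeat {
    el <- t(combn(nodes, 2))
    el <- el[runif(nrow(el)) < p, , drop = FALSE]
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (igraph::vcount(g) == n && igraph::is_connected(g)) break
    g <- igraph::add_vertices(g, n - igraph::vcount(g),
                              name = setdiff(nodes, igraph::V(g)$name))
    if (igraph::is_connected(g)) break
  }
  if (strong) {
    # strong planted instance: an isolated 5-clique with large statistics,
    # a separate random background component with weak statistics
    clique <- sprintf("c%02d", 1:5)
    elC <- t(combn(clique, 2))
    bg <- sprintf("b%02d", seq_len(n - 5))
    elB <- t(combn(bg, 2))
    elB <- elB[runif(nrow(elB)) < 0.5, , drop = FALSE]
    el <- rbind(elC, elB)
    tInt <- c(setNames(runif(5, 5, 10), clique),
              setNames(runif(n - 5, 0, 1), bg))
    seed <- clique[1]
  } else {
    el <- igraph::as_edgelist(g)
    tInt <- setNames(runif(n, 0, 3) * rbinom(n, 1, 0.7), nodes)
    seed <- nodes[1]
  }
  list(edges = el, tInt = tInt, seed = seed)
}

# ordinary least-squares t oracle for one gene: direct lm fit
olsTOracle <- function(y, case, covariates = NULL) {
  df <- data.frame(y = y, case = case)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- lm(y ~ ., data = df)
  summary(fit)$coefficients["case", c("t value", "Pr(>|t|)")]
}

# Jaccard index between two gene sets
jaccardSets <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small discovery fixture shared by scoring tests: stats table with known
# signs and significance
makeStats <- function(genes, tdm, tde, sig = TRUE) {
  fdr <- ifelse(sig, 0.001, 0.5)
  data.frame(gene = genes, t_dm = tdm, p_dm = 0.001, fdr_dm = fdr,
             t_de = tde, p_de = 0.001, fdr_de = fdr,
             t_int = integratedStatistic(tdm, tde),
             stringsAsFactors = FALSE)
}
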