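#' Read a probe-level beta-value matrix
#'
#' Reads a TSV/CSV matrix of DNA methylation beta values (probes as rows,
#' samples as columns; first column holds probe ids). Values are validated to
#' lie in [0,1]; duplicate probe ids and missing values are rejected, since
#' imputation is assumed to have happened upstream.
#'
#' @param path path to a TSV/CSV file, optionally gzip-compressed.
#' @param sep field separator; guessed from the extension when NULL
#'   (".csv"/".csv.gz" means comma, otherwise tab).
#' @return numeric matrix of betas with probe rownames and sample colnames.
#' @export
readBetaMatrix <- function(path, sep = NULL) {
  m <- readNamedMatrix(path, sep)
  if (anyDuplicated(rownames(m))) {
    d <- unique(rownames(m)[duplicated(rownames(m))])
    stopf("duplicated probe ids: %s", paste(utils::head(d, 5), collapse = ", "))
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stopf("missing beta value at probe %s, sample %s; impute upstream",
          rownames(m)[idx[1]], colnames(m)[idx[2]])
  }
  bad <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("beta value out of [0,1] at probe %s, sample %s (value %g)",
          rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], m[bad[1, , drop = FALSE]])
  }
  m
}

#' Read a gene-level log-expression matrix
#'
#' @inheritParams readBetaMatrix
#' @return numeric matrix (genes x samples); all values must be finite.
#' @export
readExprMatrix <- function(path, sep = NULL) {
  m <- readNamedMatrix(path, sep)
  if (any(!is.finite(m))) stopf("expression matrix contains non-finite values")
  if (anyDuplicated(rownames(m)))
    stopf("duplicated gene ids in expression matrix")
  m
}

readNamedMatrix <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  con <- openInput(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("matrix file needs an id column plus >=1 sample")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a named matrix as TSV
#'
#' @param m matrix with row and column names.
#' @param path output path; gzip-compressed when it ends in ".gz".
#' @param idColumn name of the first (id) column.
#' @export
writeMatrixTSV <- function(m, path, idColumn = "id") {
  checkNumericMatrix(m, "matrix")
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idColumn
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an Illumina-manifest-like probe annotation
#'
#' Expects columns \code{probe_id}, \code{gene}, \code{region_class} (and
#' optionally \code{chrom}). A probe may map to several genes via separate
#' rows. Region classes are normalized to TSS200 / FirstExon / TSS1500
#' ("1stExon" is accepted as a synonym for FirstExon).
#'
#' @param path CSV/TSV path (gzip ok).
#' @param sep field separator, guessed from extension when NULL.
#' @return data.frame with columns probe_id, gene, region_class.
#' @export
readProbeAnnotation <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  con <- openInput(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("probe_id", "gene", "region_class")
  if (!all(need %in% names(df)))
    stopf("annotation must have columns: %s", paste(need, collapse = ", "))
  df$region_class[df$region_class == "1stExon"] <- "FirstExon"
  bad <- setdiff(unique(df$region_class), REGION_CLASSES)
  if (length(bad) > 0)
    stopf("unknown region class(es): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(df[, c("probe_id", "gene")]))
    stopf("duplicate probe/gene annotation rows")
  df[, intersect(c("probe_id", "gene", "region_class", "chrom"), names(df))]
}

#' Read a sample sheet
#'
#' Expects columns \code{sample_id} and \code{group}; \code{stage} is
#' optional. Group labels are free strings (typically "normal"/"case" or
#' ordered stages N/NDBE/HGD/C).
#'
#' @inheritParams readProbeAnnotation
#' @return data.frame with sample_id, group and optional stage.
#' @export
readSampleSheet <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  con <- openInput(path)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stopf("sample sheet must have columns sample_id and group")
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample ids")
  if (anyNA(df$group)) stopf("every sample needs a group label")
  df
}

#' Read an undirected gene network from an edge list
#'
#' Accepts a two-column edge list (gene, gene), or the three-column SIF
#' dialect (gene, interaction, gene) whose middle column is ignored.
#' Self-loops are dropped and duplicate edges collapsed, with a message
#' reporting the counts.
#'
#' @param path edge-list path (gzip ok); whitespace- or tab-separated.
#' @param header logical, does the file carry a header line?
#' @return an \pkg{igraph} undirected simple graph.
#' @export
readNetwork <- function(path, header = FALSE) {
  con <- openInput(path)
  on.exit(close(con))
  df <- tryCatch(
    utils::read.table(con, header = header, stringsAsFactors = FALSE),
    error = function(e) data.frame())
  if (nrow(df) == 0) {
    warnf("empty network file: returning a graph with no nodes")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  if (ncol(df) < 2) stopf("network file needs at least two columns")
  sif <- grepl("\\.sif(\\.gz)?$", path) && ncol(df) >= 3
  el <- if (sif) cbind(as.character(df[[1]]), as.character(df[[3]]))
        else cbind(as.character(df[[1]]), as.character(df[[2]]))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  nSelf <- sum(igraph::which_loop(g))
  nDup <- sum(igraph::which_multiple(g))
  g <- igraph::simplify(g)
  if (nSelf + nDup > 0)
    message(sprintf("network: dropped %d self-loop(s), collapsed %d duplicate edge(s)",
                    nSelf, nDup))
  g
}

#' Write a gene network as a two-column edge list
#'
#' @param g igraph undirected graph.
#' @param path output path.
#' @export
writeNetwork <- function(g, path) {
  el <- igraph::as_edgelist(g)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summarize probe-level methylation to gene promoters
#'
#' For each gene, the promoter methylation is the arithmetic mean of its
#' TSS200 probes present in the matrix. Genes with no TSS200 probe fall back
#' to FirstExon probes, and failing that to TSS1500 probes; the class used is
#' recorded per gene. The precedence is strict: a TSS1500 probe never
#' contributes when a higher-precedence probe exists. Genes with no annotated
#' probe in the matrix are omitted. Probes annotated to several genes
#' contribute to each of them independently.
#'
#' @param beta probe-level beta matrix (probes x samples), as from
#'   \code{\link{readBetaMatrix}}.
#' @param annotation probe annotation data.frame with columns probe_id, gene,
#'   region_class, as from \code{\link{readProbeAnnotation}}.
#' @return a \linkS4class{PromoterMethylation} object.
#' @export
summarizePromoters <- function(beta, annotation) {
  checkNumericMatrix(beta, "beta matrix")
  ann <- annotation[annotation$probe_id %in% rownames(beta), , drop = FALSE]
  if (nrow(ann) == 0)
    stopf("annotation covers no probe of the matrix")
  ann$region_class <- factor(ann$region_class, levels = REGION_CLASSES)
  genes <- sort(unique(ann$gene))
  byGene <- split(ann, ann$gene)
  rows <- vector("list", length(genes))
  prov <- data.frame(gene = genes, region_class = NA_character_,
                     n_probes = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    a <- byGene[[genes[i]]]
    cls <- REGION_CLASSES[min(as.integer(a$region_class))]
    probes <- a$probe_id[a$region_class == cls]
    rows[[i]] <- colMeans(beta[probes, , drop = FALSE])
    prov$region_class[i] <- cls
    prov$n_probes[i] <- length(probes)
  }
  b <- do.call(rbind, rows)
  rownames(b) <- genes
  colnames(b) <- colnames(beta)
  new("PromoterMethylation", beta = b, provenance = prov)
}

#' Write modules as TSV and GMT
#'
#' @param modules a \linkS4class{FemModuleSet}.
#' @param tsvPath path for the long-format TSV (module_id, seed, gene, flags).
#' @param gmtPath optional path for a GMT file (one line per module).
#' @return invisibly, the TSV path.
#' @export
writeModules <- function(modules, tsvPath, gmtPath = NULL) {
  rows <- lapply(as.list(modules), function(m) {
    f <- memberFlags(m)
    if (nrow(f) == 0)
      f <- data.frame(gene = moduleMembers(m), dm = NA, dr = NA,
                      dmdr = NA, anticorrelated = NA)
    data.frame(module_id = moduleSeed(m), seed = moduleSeed(m),
               gene = f$gene, dm = f$dm, dr = f$dr, dmdr = f$dmdr,
               anticorrelated = f$anticorrelated,
               modularity = moduleModularity(m), mc_p = mcPValue(m),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gmtPath)) {
    lines <- vapply(as.list(modules), function(m)
      paste(c(moduleSeed(m), "femnet", moduleMembers(m)), collapse = "\t"),
      character(1))
    writeLines(lines, gmtPath)
  }
  invisible(tsvPath)
}

#' Write a reference matrix as CSV
#'
#' @param ref a \linkS4class{ReferenceMatrix}.
#' @param path output CSV path.
#' @export
writeReferenceMatrix <- function(ref, path) {
  df <- data.frame(cpg_id = rownames(referenceProfiles(ref)),
                   referenceProfiles(ref),
                   selected_by = ref@selectedBy,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference matrix written by \code{\link{writeReferenceMatrix}}
#'
#' @param path CSV path.
#' @return a \linkS4class{ReferenceMatrix}.
#' @export
readReferenceMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                          stringsAsFactors = FALSE)
  sel <- if ("selected_by" %in% names(df)) df$selected_by else
    rep(NA_character_, nrow(df))
  keep <- setdiff(names(df), c("cpg_id", "selected_by"))
  m <- as.matrix(df[, keep, drop = FALSE])
  rownames(m) <- df$cpg_id
  new("ReferenceMatrix", ref = m, selectedBy = as.character(sel))
}
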