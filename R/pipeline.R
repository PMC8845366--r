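# FNV-1a hash of a string, used for config provenance stamping
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

PIPELINE_STAGES <- c("simulate", "summarize", "deconvolve", "diffstats",
                     "modules", "score", "evaluate")

CONFIG_KEYS <- c("seed", "simulation", "spinglass", "thresholds",
                 "deconvolution", "score", "inputs")

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML/JSON file) with the
#' sections \code{seed}, \code{simulation} (arguments to
#' \code{\link{simulationConfig}}), \code{spinglass} (arguments to
#' \code{\link{SpinGlassConfig}}), \code{thresholds}, \code{deconvolution},
#' \code{score} and \code{inputs} (paths, for runs on real data). Unknown
#' keys are rejected with a field-level message.
#'
#' @param config named list or path to a YAML/JSON file.
#' @return the validated configuration list.
#' @export
validateRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a config file path")
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown) > 0)
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  simKnown <- names(formals(simulationConfig))
  bad <- setdiff(names(config$simulation), simKnown)
  if (length(bad) > 0)
    stopf("unknown simulation key(s): %s", paste(bad, collapse = ", "))
  sgKnown <- names(formals(SpinGlassConfig))
  bad <- setdiff(names(config$spinglass), sgKnown)
  if (length(bad) > 0)
    stopf("unknown spinglass key(s): %s", paste(bad, collapse = ", "))
  config
}

stageProvenance <- function(outDir, stage, config) {
  file.path(outDir, sprintf("provenance_%s.json", stage))
}

stageUpToDate <- function(outDir, stage, hash, artifacts) {
  pf <- stageProvenance(outDir, stage)
  if (!file.exists(pf)) return(FALSE)
  prov <- tryCatch(jsonlite::read_json(pf), error = function(e) NULL)
  if (is.null(prov) || !identical(prov$config_hash, hash)) return(FALSE)
  all(file.exists(file.path(outDir, artifacts)))
}

writeProvenance <- function(outDir, stage, hash, seed) {
  jsonlite::write_json(
    list(stage = stage, config_hash = hash, seed = seed,
         package_version = as.character(utils::packageVersion("femnet")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    stageProvenance(outDir, stage), auto_unbox = TRUE, pretty = TRUE)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages \code{simulate} (synthetic fixture generation),
#' \code{summarize} (probe-to-promoter summarization), \code{deconvolve}
#' (reference construction and fraction estimation), \code{diffstats}
#' (cell-fraction-adjusted differential statistics), \code{modules}
#' (spin-glass module inference), \code{score} (FEM-scores) and
#' \code{evaluate} (Wilcoxon/AUC evaluation). Each stage writes its
#' artifacts plus a JSON provenance record (config hash, seed, package
#' version) into \code{outDir} and is skipped on rerun when its provenance
#' matches and its artifacts exist, unless \code{force}.
#'
#' @param config run configuration (list or YAML/JSON path); see
#'   \code{\link{validateRunConfig}}.
#' @param stages ordered subset of the stage names above.
#' @param outDir output directory (created if needed).
#' @param force rerun stages even when up to date.
#' @return invisibly, a character vector of the stages actually run.
#' @export
runFemPipeline <- function(config = list(), stages = PIPELINE_STAGES,
                           outDir = "femnet_results", force = FALSE) {
  config <- validateRunConfig(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- fnv1a(paste(deparse(config), collapse = ""))
  seed <- as.integer(config$seed)
  ran <- character(0)
  p <- function(...) file.path(outDir, ...)

  needInput <- function(key, stage) {
    f <- p(key)
    if (file.exists(f)) return(f)
    alt <- config$inputs[[sub("\\..*$", "", key)]]
    if (!is.null(alt) && file.exists(alt)) return(alt)
    stopf("stage '%s' requires input '%s' (not found in '%s' or config$inputs)",
          stage, key, outDir)
  }

  simCfg <- do.call(simulationConfig,
                    c(list(rngSeed = seed), config$simulation))
  sgCfg <- do.call(SpinGlassConfig,
                   c(list(rngSeed = seed), config$spinglass))
  sigThresh <- config$thresholds$sigThresh %||% 0.05

  if ("simulate" %in% stages) {
    arts <- c("network.tsv", "beta.tsv", "annotation.csv", "expr.tsv",
              "sample_sheet.tsv", "fractions_true.tsv", "pure_beta.tsv",
              "pure_labels.tsv", "ground_truth.json")
    if (force || !stageUpToDate(outDir, "simulate", hash, arts)) {
      net <- simulateNetwork(simCfg)
      coh <- simulateCohort(net$network, net$truth, simCfg)
      pure <- simulatePureProfiles(simCfg)
      writeNetwork(net$network, p("network.tsv"))
      writeMatrixTSV(coh$beta, p("beta.tsv"), "probe_id")
      utils::write.table(coh$annotation, p("annotation.csv"), sep = ",",
                         quote = FALSE, row.names = FALSE)
      writeMatrixTSV(coh$expr, p("expr.tsv"), "gene")
      utils::write.table(coh$sampleSheet, p("sample_sheet.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeMatrixTSV(coh$fractions, p("fractions_true.tsv"), "sample_id")
      writeMatrixTSV(pure$beta, p("pure_beta.tsv"), "cpg_id")
      utils::write.table(
        data.frame(sample_id = names(pure$labels), cell_type = pure$labels),
        p("pure_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(modules = net$truth$modules, markers = pure$markers),
        p("ground_truth.json"), auto_unbox = FALSE, pretty = TRUE)
      writeProvenance(outDir, "simulate", hash, seed)
      ran <- c(ran, "simulate")
    }
  }

  if ("summarize" %in% stages) {
    arts <- c("gene_beta.tsv", "summarization_provenance.tsv")
    if (force || !stageUpToDate(outDir, "summarize", hash, arts)) {
      beta <- readBetaMatrix(needInput("beta.tsv", "summarize"))
      ann <- readProbeAnnotation(needInput("annotation.csv", "summarize"))
      pm <- summarizePromoters(beta, ann)
      writeMatrixTSV(betaValues(pm), p("gene_beta.tsv"), "gene")
      utils::write.table(provenance(pm), p("summarization_provenance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeProvenance(outDir, "summarize", hash, seed)
      ran <- c(ran, "summarize")
    }
  }

  if ("deconvolve" %in% stages) {
    arts <- c("reference_matrix.csv", "fractions_estimated.tsv")
    if (force || !stageUpToDate(outDir, "deconvolve", hash, arts)) {
      pure <- readBetaMatrix(needInput("pure_beta.tsv", "deconvolve"))
      lab <- utils::read.table(needInput("pure_labels.tsv", "deconvolve"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      ref <- buildReferenceMatrix(
        pure, stats::setNames(lab$cell_type, lab$sample_id)[colnames(pure)],
        fdrThresh = config$deconvolution$fdrThresh %||% 0.05,
        deltaThresh = config$deconvolution$deltaThresh %||% 0.9)
      writeReferenceMatrix(ref, p("reference_matrix.csv"))
      beta <- readBetaMatrix(needInput("beta.tsv", "deconvolve"))
      frEst <- estimateFractionsRPC(beta, ref)
      writeMatrixTSV(frEst, p("fractions_estimated.tsv"), "sample_id")
      writeProvenance(outDir, "deconvolve", hash, seed)
      ran <- c(ran, "deconvolve")
    }
  }

  if ("diffstats" %in% stages) {
    arts <- "gene_stats.tsv"
    if (force || !stageUpToDate(outDir, "diffstats", hash, arts)) {
      gb <- readNamedMatrix(needInput("gene_beta.tsv", "diffstats"))
      ex <- readExprMatrix(needInput("expr.tsv", "diffstats"))
      sheet <- readSampleSheet(needInput("sample_sheet.tsv", "diffstats"))
      fr <- readNamedMatrix(needInput("fractions_estimated.tsv", "diffstats"))
      net <- readNetwork(needInput("network.tsv", "diffstats"))
      gs <- computeGeneStats(gb, ex, sheet, fr, net)
      utils::write.table(statTable(gs), p("gene_stats.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeProvenance(outDir, "diffstats", hash, seed)
      ran <- c(ran, "diffstats")
    }
  }

  if ("modules" %in% stages) {
    arts <- c("modules.tsv", "modules.gmt")
    if (force || !stageUpToDate(outDir, "modules", hash, arts)) {
      st <- utils::read.table(needInput("gene_stats.tsv", "modules"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      gs <- new("GeneStats", stats = st)
      net <- readNetwork(needInput("network.tsv", "modules"))
      wnet <- weightNetwork(net, gs)
      mods <- inferModules(wnet, gs, sgCfg, sigThresh = sigThresh)
      writeModules(mods, p("modules.tsv"), p("modules.gmt"))
      writeProvenance(outDir, "modules", hash, seed)
      ran <- c(ran, "modules")
    }
  }

  if ("score" %in% stages) {
    arts <- "scores.tsv"
    if (force || !stageUpToDate(outDir, "score", hash, arts)) {
      st <- utils::read.table(needInput("gene_stats.tsv", "score"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      gs <- new("GeneStats", stats = st)
      modTab <- utils::read.table(needInput("modules.tsv", "score"),
                                  header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
      gb <- readNamedMatrix(needInput("gene_beta.tsv", "score"))
      sheet <- readSampleSheet(needInput("sample_sheet.tsv", "score"))
      groups <- stats::setNames(sheet$group, sheet$sample_id)
      normals <- sheet$sample_id[sheet$group == "normal"]
      s <- statTable(gs)
      rows <- list()
      for (mid in unique(modTab$module_id)) {
        mg <- modTab$gene[modTab$module_id == mid]
        dmg <- mg[!is.na(match(mg, s$gene)) &
                    s$fdr_dm[match(mg, s$gene)] < sigThresh]
        if (length(dmg) == 0) next
        sig <- data.frame(gene = dmg, sign = sign(s$t_dm[match(dmg, s$gene)]))
        z <- suppressWarnings(zscoreVsNormals(gb, normals))
        rows[[mid]] <- femScoreSigned(z, sig, moduleId = mid, groups = groups)
      }
      if (length(rows) == 0) stopf("no scoreable modules")
      utils::write.table(do.call(rbind, rows), p("scores.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      writeProvenance(outDir, "score", hash, seed)
      ran <- c(ran, "score")
    }
  }

  if ("evaluate" %in% stages) {
    arts <- "evaluation.json"
    if (force || !stageUpToDate(outDir, "evaluate", hash, arts)) {
      sc <- utils::read.table(needInput("scores.tsv", "evaluate"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      pos <- config$score$positiveGroup %||% "case"
      ev <- lapply(split(sc, sc$module_id), evaluateScores,
                   positiveGroup = pos)
      jsonlite::write_json(ev, p("evaluation.json"), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      writeProvenance(outDir, "evaluate", hash, seed)
      ran <- c(ran, "evaluate")
    }
  }
  invisible(ran)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summary report over pipeline results
#'
#' A pure function of the results directory: tabulates per-module member
#' counts by flag (DM, DR, DM&DR, anti-correlated) and, when present, the
#' per-module Wilcoxon/AUC evaluation, writing both TSV and JSON.
#'
#' @param resultsDir directory written by \code{\link{runFemPipeline}}.
#' @param outPrefix path prefix for \code{report.tsv}/\code{report.json}
#'   (default inside \code{resultsDir}).
#' @return invisibly, the report data.frame.
#' @export
femReport <- function(resultsDir, outPrefix = file.path(resultsDir, "report")) {
  mf <- file.path(resultsDir, "modules.tsv")
  if (!file.exists(mf)) stopf("no modules.tsv under '%s'", resultsDir)
  modTab <- utils::read.table(mf, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  if (nrow(modTab) == 0) {
    rep <- data.frame(module_id = character(0))
  } else {
    sp <- split(modTab, modTab$module_id)
    rep <- do.call(rbind, lapply(names(sp), function(mid) {
      m <- sp[[mid]]
      data.frame(module_id = mid, seed = m$seed[1], n_genes = nrow(m),
                 n_dm = sum(m$dm), n_dr = sum(m$dr), n_dmdr = sum(m$dmdr),
                 n_anticorrelated = sum(m$anticorrelated),
                 modularity = m$modularity[1], mc_p = m$mc_p[1],
                 stringsAsFactors = FALSE)
    }))
  }
  ef <- file.path(resultsDir, "evaluation.json")
  if (file.exists(ef) && nrow(rep) > 0) {
    ev <- jsonlite::read_json(ef, simplifyVector = TRUE)
    rep$wilcoxon_p <- vapply(rep$module_id, function(m)
      if (m %in% names(ev)) ev[[m]]$wilcoxonP else NA_real_, numeric(1))
    rep$auc <- vapply(rep$module_id, function(m)
      if (m %in% names(ev)) ev[[m]]$auc else NA_real_, numeric(1))
  }
  rep <- rep[order(rep$module_id), , drop = FALSE]
  rownames(rep) <- NULL
  utils::write.table(rep, paste0(outPrefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(rep, paste0(outPrefix, ".json"), pretty = TRUE,
                       digits = NA)
  invisible(rep)
}
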