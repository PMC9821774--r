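#' Pipeline configuration constructor
#'
#' All defaults follow the printed construction thresholds: fold change
#' >= 2 with p < 0.05 (circRNA, miRNA) or FDR < 0.05 (mRNA) for the DE
#' gates, Spearman < -0.7 for miRNA-target pairs, Pearson > 0.9 for
#' circRNA-mRNA pairs, and hypergeometric p < 0.05 for the shared-sponge
#' test; every comparison is strict.
#'
#' @param sccThreshold,pccThreshold,spongeAlpha,fcThreshold,deAlpha,mrnaFdr
#'   decision thresholds (see [PipelineConfig-class]).
#' @param pseudocount fold-change pseudocount.
#' @param universeMode `"de"`, `"interactions"` or `"profiled"`.
#' @param correlationPooling `"pooled"` or `"within"`.
#' @param adjustSponge BH-adjust sponge p-values before gating.
#' @param seed integer seed.
#' @param outputDir output directory; `""` disables file output.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(sccThreshold = -0.7, pccThreshold = 0.9,
                           spongeAlpha = 0.05, fcThreshold = 2,
                           deAlpha = 0.05, mrnaFdr = 0.05,
                           pseudocount = 1,
                           universeMode = "de",
                           correlationPooling = "pooled",
                           adjustSponge = FALSE,
                           seed = 1L, outputDir = "") {
  new("PipelineConfig",
      sccThreshold = as.numeric(sccThreshold),
      pccThreshold = as.numeric(pccThreshold),
      spongeAlpha = as.numeric(spongeAlpha),
      fcThreshold = as.numeric(fcThreshold),
      deAlpha = as.numeric(deAlpha), mrnaFdr = as.numeric(mrnaFdr),
      pseudocount = as.numeric(pseudocount),
      universeMode = universeMode, correlationPooling = correlationPooling,
      adjustSponge = adjustSponge, seed = as.integer(seed),
      outputDir = outputDir)
}

.configSnapshot <- function(config) {
  nm <- slotNames("PipelineConfig")
  setNames(lapply(nm, function(s) slot(config, s)), nm)
}

#' Serialize / load a pipeline configuration
#'
#' JSON round-trip reproducing every threshold bit-exactly (numbers are
#' written at full precision).
#'
#' @param config a [PipelineConfig-class].
#' @param path JSON path.
#' @return `readPipelineConfig()` returns a [PipelineConfig-class].
#' @export
writePipelineConfig <- function(config, path) {
  # 17 significant digits: lossless double round-trip
  jsonlite::write_json(.configSnapshot(config), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- slotNames("PipelineConfig")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, x)
}

#' Run the end-to-end ceRNA inference pipeline
#'
#' Executes, per tissue: class-specific DE calling (exact conditional NB
#' test at a per-class common dispersion), Spearman filtering of predicted
#' miRNA-target pairs among DE features, Pearson filtering of
#' common-miRNA circRNA-mRNA candidates, the hypergeometric shared-sponge
#' test, and tripartite network assembly with a structural audit. Inputs
#' are either in-memory objects (`counts` + `interactions` + `design`), a
#' simulation configuration (`simConfig`; the study is generated first), or
#' file paths (`inputs`).
#'
#' @param config a [PipelineConfig-class].
#' @param counts named list of [RNACountSet-class] per RNA class.
#' @param interactions interaction data.frame.
#' @param design a [StudyDesign-class].
#' @param simConfig a [SimulationConfig-class]; when given (and `counts` is
#'   `NULL`), [simulateCounts()] and [generateInteractions()] supply the
#'   inputs.
#' @param inputs named list of file paths: `circRNA`, `miRNA`, `mRNA`,
#'   `metadata`, `interactions`.
#' @return a list with `networks` (one [CeRNANetwork-class] per tissue),
#'   `deTables`, `pairs`, `candidates`, `sponge`, `truth` (when simulated)
#'   and `manifest` (config snapshot, input checksums, per-stage row
#'   counts, warnings).
#' @export
runPipeline <- function(config = pipelineConfig(), counts = NULL,
                        interactions = NULL, design = NULL,
                        simConfig = NULL, inputs = NULL) {
  validObject(config)
  warnings <- character()
  checksums <- NULL
  truth <- NULL

  if (is.null(counts) && !is.null(simConfig)) {
    if (is.null(design)) design <- generateDesign(seed = config@seed)
    sim <- simulateCounts(design, simConfig)
    counts <- sim$counts
    truth <- sim$truth
    interactions <- generateInteractions(truth, simConfig)
  } else if (is.null(counts) && !is.null(inputs)) {
    meta <- readSampleMetadata(inputs$metadata)
    counts <- lapply(setNames(VALID_RNA_CLASSES, VALID_RNA_CLASSES),
                     function(cl)
                       readExpressionTSV(inputs[[cl]], cl, meta))
    interactions <- readInteractionsTSV(inputs$interactions)
    files <- unlist(inputs[c(VALID_RNA_CLASSES, "metadata", "interactions")])
    checksums <- as.list(tools::md5sum(files))
    if (is.null(design)) {
      conds <- unique(meta$condition)
      design <- generateDesign(unique(meta$tissue), conds,
                               max(meta$replicate), config@seed)
    }
  }
  if (is.null(counts) || is.null(interactions))
    stop("stage input: provide counts+interactions, simConfig, or inputs")

  outDir <- config@outputDir
  if (nzchar(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  tissues <- design@tissues
  networks <- list(); deTabs <- list(); pairTabs <- list()
  candTabs <- list(); spongeTabs <- list(); stages <- list()

  for (ts in tissues) {
    mats <- lapply(counts, function(x)
      assay(tissueSubset(x, ts), "counts"))
    condLev <- S4Vectors::metadata(counts[[1]])$conditionLevels
    cd <- colData(tissueSubset(counts[[1]], ts))
    cond <- factor(cd$condition, levels = condLev)

    de <- lapply(setNames(VALID_RNA_CLASSES, VALID_RNA_CLASSES),
                 function(cl)
                   callDE(mats[[cl]], condition = cond, rnaClass = cl,
                          pseudocount = config@pseudocount,
                          fcThreshold = config@fcThreshold,
                          deAlpha = config@deAlpha,
                          mrnaFdr = config@mrnaFdr))
    expr <- lapply(mats, normalizeCPM)
    groups <- if (config@correlationPooling == "within")
      lapply(levels(cond), function(l) which(cond == l)) else NULL

    retained <- withCallingHandlers(
      filterMirnaTargetPairs(de, interactions, expr,
                             sccThreshold = config@sccThreshold,
                             conditionGroups = groups),
      warning = function(w) {
        warnings <<- c(warnings, paste0(ts, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    cand <- filterCernaPairs(de, retained, expr,
                             pccThreshold = config@pccThreshold,
                             conditionGroups = groups)
    universe <- switch(config@universeMode,
      de = length(unique(interactions$mirna_id[
        interactions$mirna_id %in% .sigFeatures(de$miRNA)])),
      interactions = length(unique(interactions$mirna_id)),
      profiled = nrow(mats$miRNA))
    sponge <- if (nrow(cand))
      spongeTest(cand, retained, universe, alpha = config@spongeAlpha,
                 adjust = config@adjustSponge)
    else {
      s <- data.frame(circ_id = character(), mrna_id = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), pvalue = numeric(), pcc = numeric(),
                      shared_mirnas = character(), stringsAsFactors = FALSE)
      attr(s, "tested") <- 0L
      s
    }
    net <- buildNetwork(retained, sponge, tissue = ts, deTables = de)
    viol <- auditNetwork(net, pccThreshold = config@pccThreshold,
                         alpha = config@spongeAlpha)
    if (viol > 0)
      stop("stage network [", ts, "]: structural audit failed: ",
           paste(attr(viol, "details"), collapse = "; "))

    networks[[ts]] <- net
    deTabs[[ts]] <- de
    pairTabs[[ts]] <- retained
    candTabs[[ts]] <- cand
    spongeTabs[[ts]] <- sponge
    stages[[ts]] <- list(
      features = vapply(mats, nrow, integer(1)),
      de_significant = vapply(de, function(d) sum(d$significant),
                              integer(1)),
      interactions_in = nrow(interactions),
      mirna_pairs_retained = nrow(retained),
      cerna_candidates = nrow(cand),
      sponge_tested = attr(sponge, "tested"),
      sponge_retained = nrow(sponge),
      mirna_universe = universe,
      audit_violations = as.integer(viol))

    if (nzchar(outDir)) {
      for (cl in VALID_RNA_CLASSES)
        writeDETable(de[[cl]], file.path(outDir,
          sprintf("de_%s_%s.tsv", ts, cl)), rnaClass = cl, tissue = ts)
      writePairsTSV(retained, file.path(outDir,
        sprintf("pairs_mirna_%s.tsv", ts)))
      writePairsTSV(cand, file.path(outDir,
        sprintf("pairs_cerna_%s.tsv", ts)))
      utils::write.table(sponge, file.path(outDir,
        sprintf("sponge_%s.tsv", ts)), sep = "\t", quote = FALSE,
        row.names = FALSE)
      writeNetworkTSV(net, file.path(outDir,
        sprintf("network_edges_%s.tsv", ts)),
        file.path(outDir, sprintf("network_nodes_%s.tsv", ts)))
      if (nrow(net@nodes))
        writeGraphML(net, file.path(outDir, sprintf("network_%s.graphml",
                                                    ts)))
      jsonlite::write_json(networkSummary(net),
        file.path(outDir, sprintf("summary_%s.json", ts)),
        auto_unbox = TRUE)
    }
  }

  manifest <- list(
    config = .configSnapshot(config),
    input_checksums = checksums,
    version = as.character(utils::packageVersion("ceRNAsponge")),
    stages = stages,
    warnings = warnings)
  if (nzchar(outDir)) {
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE)
    if (!is.null(truth))
      writeGroundTruthJSON(truth, file.path(outDir, "ground_truth.json"))
  }
  list(networks = networks, deTables = deTabs, pairs = pairTabs,
       candidates = candTabs, sponge = spongeTabs, truth = truth,
       manifest = manifest, design = design)
}
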