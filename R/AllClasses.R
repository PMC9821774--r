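#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @import SummarizedExperiment
NULL

VALID_RNA_CLASSES <- c("circRNA", "miRNA", "mRNA")
VALID_TARGET_TYPES <- c("circRNA", "mRNA")

#' Two-condition multi-tissue study design
#'
#' Describes a factorial sampling layout: a set of tissues, exactly two
#' conditions (control first, e.g. non-heat-stress "NHS" before heat-stress
#' "HS"), and a fixed number of biological replicates per tissue and
#' condition. Sample identifiers follow the `<condition>_<tissue-initial><replicate>`
#' convention (e.g. `NHS_H1`).
#'
#' @slot tissues character vector of tissue labels.
#' @slot conditions character vector of exactly two distinct condition labels,
#'   control first.
#' @slot replicates integer, biological replicates per tissue x condition
#'   (at least 2).
#' @slot seed integer seed recorded with the design.
#' @export
setClass("StudyDesign",
  representation(
    tissues = "character",
    conditions = "character",
    replicates = "integer",
    seed = "integer"
  )
)

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@tissues) < 1L || anyDuplicated(object@tissues))
    msg <- c(msg, "tissues must be a non-empty set of distinct labels")
  if (length(object@conditions) != 2L ||
      object@conditions[1] == object@conditions[2])
    msg <- c(msg, "conditions must be exactly two distinct labels")
  if (length(object@replicates) != 1L || is.na(object@replicates) ||
      object@replicates < 2L)
    msg <- c(msg, "invalid design: replicates per condition must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Synthetic count-simulation configuration
#'
#' Parameters of the negative-binomial generator: feature counts per RNA
#' class, a log-normal distribution of baseline means, a single class-level
#' dispersion (variance = mu + dispersion * mu^2, i.e. `size = 1/dispersion`
#' in [stats::rnbinom()]), the fraction and magnitude of planted differential
#' expression, the number and coupling strength of planted ceRNA triads, and
#' the density of decoy miRNA-target interactions.
#'
#' @slot nCirc,nMirna,nMrna integer feature counts per class.
#' @slot baselineMeanlog,baselineSdlog log-scale location/spread of baseline
#'   means.
#' @slot dispersion positive NB dispersion (1/size).
#' @slot deFraction fraction of features per class carrying a planted
#'   condition effect.
#' @slot deLog2FC planted absolute log2 fold change.
#' @slot nTriads number of planted circRNA-miRNA-mRNA triads.
#' @slot couplingStrength in (0,1]; scales the shared latent factor that
#'   couples triad members within a tissue.
#' @slot latentScale natural-log amplitude multiplying the latent factor at
#'   coupling 1.
#' @slot interactionDensity decoy edge sampling probability among non-planted
#'   miRNA x target combinations.
#' @slot libSizeJitter samples' depth factors are drawn uniformly in
#'   `1 +/- libSizeJitter`.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(
    nCirc = "integer", nMirna = "integer", nMrna = "integer",
    baselineMeanlog = "numeric", baselineSdlog = "numeric",
    dispersion = "numeric",
    deFraction = "numeric", deLog2FC = "numeric",
    nTriads = "integer", couplingStrength = "numeric",
    latentScale = "numeric",
    interactionDensity = "numeric",
    libSizeJitter = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (any(c(object@nCirc, object@nMirna, object@nMrna) < 1L))
    msg <- c(msg, "feature counts must be positive")
  if (object@dispersion <= 0)
    msg <- c(msg, "dispersion must be > 0")
  if (object@deFraction < 0 || object@deFraction > 1)
    msg <- c(msg, "deFraction must lie in [0,1]")
  if (object@interactionDensity < 0 || object@interactionDensity > 1)
    msg <- c(msg, "interactionDensity must lie in [0,1]")
  if (object@couplingStrength <= 0 || object@couplingStrength > 1)
    msg <- c(msg, "couplingStrength must lie in (0,1]")
  if (object@nTriads < 0L)
    msg <- c(msg, "nTriads must be nonnegative")
  if (object@nTriads > min(object@nCirc, object@nMirna, object@nMrna))
    msg <- c(msg, "nTriads exceeds the smallest class feature count")
  if (object@deLog2FC <= 0)
    msg <- c(msg, "deLog2FC must be positive")
  if (object@libSizeJitter < 0 || object@libSizeJitter >= 1)
    msg <- c(msg, "libSizeJitter must lie in [0,1)")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated study
#'
#' Ledger of planted effects: which features carry a condition effect (and in
#' which direction), which circRNA-miRNA-mRNA triads were planted, and which
#' interaction rows carry true regulation. Every planted triad's circRNA and
#' mRNA appear in `plantedDE`, and its two miRNA-target edges appear in
#' `plantedInteractions`.
#'
#' @slot plantedDE data.frame with columns `class`, `feature_id`, `direction`.
#' @slot plantedTriads data.frame with columns `circ_id`, `mirna_id`,
#'   `mrna_id`.
#' @slot plantedInteractions data.frame with columns `mirna_id`, `target_id`,
#'   `target_type`.
#' @export
setClass("GroundTruth",
  representation(
    plantedDE = "data.frame",
    plantedTriads = "data.frame",
    plantedInteractions = "data.frame"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  de <- object@plantedDE
  tr <- object@plantedTriads
  pi <- object@plantedInteractions
  if (!all(c("class", "feature_id", "direction") %in% names(de)))
    msg <- c(msg, "plantedDE must have columns class, feature_id, direction")
  if (!all(c("circ_id", "mirna_id", "mrna_id") %in% names(tr)))
    msg <- c(msg, "plantedTriads must have columns circ_id, mirna_id, mrna_id")
  if (!all(c("mirna_id", "target_id", "target_type") %in% names(pi)))
    msg <- c(msg,
      "plantedInteractions must have columns mirna_id, target_id, target_type")
  if (!length(msg) && nrow(tr)) {
    circ_de <- de$feature_id[de$class == "circRNA"]
    mrna_de <- de$feature_id[de$class == "mRNA"]
    if (!all(tr$circ_id %in% circ_de) || !all(tr$mrna_id %in% mrna_de))
      msg <- c(msg, "every planted triad's circRNA and mRNA must be in plantedDE")
    key <- paste(pi$mirna_id, pi$target_id, pi$target_type)
    need <- c(paste(tr$mirna_id, tr$circ_id, "circRNA"),
              paste(tr$mirna_id, tr$mrna_id, "mRNA"))
    if (!all(need %in% key))
      msg <- c(msg, "every planted triad edge must be in plantedInteractions")
  }
  if (length(msg)) msg else TRUE
})

#' Count matrix for one RNA class across tissues
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a nonnegative
#' integer `counts` assay for a single RNA class, with per-sample `tissue`,
#' `condition` and `replicate` columns in `colData`. Subset by tissue with
#' [tissueSubset()].
#'
#' @slot rnaClass one of `"circRNA"`, `"miRNA"`, `"mRNA"`.
#' @export
setClass("RNACountSet",
  contains = "SummarizedExperiment",
  representation(rnaClass = "character")
)

setValidity("RNACountSet", function(object) {
  msg <- character()
  if (length(object@rnaClass) != 1L ||
      !object@rnaClass %in% VALID_RNA_CLASSES)
    msg <- c(msg, sprintf("rnaClass must be one of %s",
                          paste(VALID_RNA_CLASSES, collapse = ", ")))
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (any(m < 0) || any(m != round(m)))
      msg <- c(msg, "counts must be nonnegative integers")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      msg <- c(msg, "feature IDs must be present and unique")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
      msg <- c(msg, "sample IDs must be present and unique")
  }
  cd <- colData(object)
  if (!all(c("tissue", "condition", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must have tissue, condition, replicate")
  if (length(msg)) msg else TRUE
})

#' Typed tripartite ceRNA network
#'
#' Nodes are circRNAs, miRNAs and mRNAs (with a differential-expression
#' direction attribute); edges are typed `circ_mirna`, `mirna_mrna`
#' (negative Spearman pairs) or `circ_mrna` (positive Pearson pairs with a
#' significant shared-sponge test). The tripartite typing is enforced:
#' no edge connects two nodes of the same class, and every `circ_mrna` edge
#' carries its shared-miRNA witnesses.
#'
#' @slot nodes data.frame with columns `id`, `type`, `direction`.
#' @slot edges data.frame with columns `from`, `to`, `edge_type`,
#'   `coefficient`, `pvalue`, `shared_mirnas`.
#' @slot tissue tissue label.
#' @export
setClass("CeRNANetwork",
  representation(
    nodes = "data.frame",
    edges = "data.frame",
    tissue = "character"
  )
)

.edgeEndpointTypes <- list(
  circ_mirna = c("circRNA", "miRNA"),
  mirna_mrna = c("miRNA", "mRNA"),
  circ_mrna  = c("circRNA", "mRNA")
)

setValidity("CeRNANetwork", function(object) {
  msg <- character()
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("id", "type", "direction") %in% names(nd)))
    msg <- c(msg, "nodes must have columns id, type, direction")
  if (!all(c("from", "to", "edge_type", "coefficient", "pvalue",
             "shared_mirnas") %in% names(ed)))
    msg <- c(msg, paste("edges must have columns from, to, edge_type,",
                        "coefficient, pvalue, shared_mirnas"))
  if (length(msg)) return(msg)
  if (anyDuplicated(nd$id))
    msg <- c(msg, "duplicate node IDs")
  if (nrow(nd) && !all(nd$type %in% VALID_RNA_CLASSES))
    msg <- c(msg, "node types must be circRNA/miRNA/mRNA")
  if (nrow(ed)) {
    if (!all(ed$from %in% nd$id) || !all(ed$to %in% nd$id))
      msg <- c(msg, "dangling edge reference")
    else {
      type_of <- setNames(nd$type, nd$id)
      for (et in unique(ed$edge_type)) {
        want <- .edgeEndpointTypes[[et]]
        if (is.null(want)) {
          msg <- c(msg, sprintf("unknown edge type '%s'", et))
          next
        }
        sel <- ed$edge_type == et
        if (!all(type_of[ed$from[sel]] == want[1]) ||
            !all(type_of[ed$to[sel]] == want[2]))
          msg <- c(msg, sprintf("edge type '%s' violates tripartite typing", et))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' Thresholds and switches of the end-to-end ceRNA inference run. All
#' decision thresholds are strict inequalities: a pair sitting exactly at a
#' threshold is excluded.
#'
#' @slot sccThreshold Spearman cutoff for miRNA-target pairs (keep if
#'   SCC < threshold; default -0.7).
#' @slot pccThreshold Pearson cutoff for circRNA-mRNA pairs (keep if
#'   PCC > threshold; default 0.9).
#' @slot spongeAlpha hypergeometric sponge-test cutoff (keep if p < alpha;
#'   default 0.05).
#' @slot fcThreshold fold-change gate (significant needs |log2FC| >=
#'   log2(fcThreshold); default 2).
#' @slot deAlpha p-value gate for circRNA and miRNA classes (default 0.05).
#' @slot mrnaFdr FDR gate for the mRNA class (default 0.05).
#' @slot pseudocount added to mean CPM before the fold-change log (default 1).
#' @slot universeMode miRNA universe for the sponge test: `"de"` (distinct
#'   DE miRNAs in the interaction table; default), `"interactions"` (all
#'   interaction-table miRNAs) or `"profiled"` (all quantified miRNAs).
#' @slot correlationPooling `"pooled"` (correlations across all samples of a
#'   tissue; default) or `"within"` (per condition, conservative combination).
#' @slot adjustSponge apply BH to sponge p-values before gating (default
#'   FALSE).
#' @slot seed integer seed.
#' @slot outputDir output directory ("" = do not write files).
#' @export
setClass("PipelineConfig",
  representation(
    sccThreshold = "numeric", pccThreshold = "numeric",
    spongeAlpha = "numeric", fcThreshold = "numeric",
    deAlpha = "numeric", mrnaFdr = "numeric",
    pseudocount = "numeric",
    universeMode = "character",
    correlationPooling = "character",
    adjustSponge = "logical",
    seed = "integer",
    outputDir = "character"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@sccThreshold < -1 || object@sccThreshold > 1)
    msg <- c(msg, "sccThreshold must lie in [-1,1]")
  if (object@pccThreshold < -1 || object@pccThreshold > 1)
    msg <- c(msg, "pccThreshold must lie in [-1,1]")
  for (nm in c("spongeAlpha", "deAlpha", "mrnaFdr")) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0,1]", nm))
  }
  if (object@fcThreshold < 1)
    msg <- c(msg, "fcThreshold must be >= 1")
  if (object@pseudocount < 0)
    msg <- c(msg, "pseudocount must be >= 0")
  if (!object@universeMode %in% c("de", "interactions", "profiled"))
    msg <- c(msg, "universeMode must be de/interactions/profiled")
  if (!object@correlationPooling %in% c("pooled", "within"))
    msg <- c(msg, "correlationPooling must be pooled/within")
  if (length(msg)) msg else TRUE
})
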