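#' Simulation configuration constructor
#'
#' Defaults describe a desk-scale fixture: 300 circRNAs, 100 miRNAs and 500
#' mRNAs per tissue, log-normal baseline means (meanlog 6, i.e. several
#' hundred counts for a typical feature), a single NB dispersion of 0.1,
#' 10% of features per class carrying a planted |log2FC| = 2.5 condition
#' effect split symmetrically across conditions, 10 planted ceRNA triads
#' coupled at strength 0.9 through a bounded mean-centred latent factor,
#' and decoy miRNA-target edges at density 0.05.
#'
#' @param nCirc,nMirna,nMrna features per RNA class.
#' @param baselineMeanlog,baselineSdlog log-normal baseline-mean parameters.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param deFraction fraction of features per class with a planted effect.
#' @param deLog2FC planted absolute log2 fold change (HS over NHS).
#' @param nTriads planted circRNA-miRNA-mRNA triads.
#' @param couplingStrength latent-factor coupling in (0,1].
#' @param latentScale natural-log amplitude of the latent factor at
#'   coupling 1.
#' @param interactionDensity decoy interaction sampling probability.
#' @param libSizeJitter per-sample depth factors drawn in 1 +/- jitter.
#' @param seed RNG seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nCirc = 300L, nMirna = 100L, nMrna = 500L,
                             baselineMeanlog = 6, baselineSdlog = 1,
                             dispersion = 0.1,
                             deFraction = 0.1, deLog2FC = 2.5,
                             nTriads = 10L, couplingStrength = 0.9,
                             latentScale = 1.5,
                             interactionDensity = 0.05,
                             libSizeJitter = 0.2,
                             seed = 1L) {
  new("SimulationConfig",
      nCirc = as.integer(nCirc), nMirna = as.integer(nMirna),
      nMrna = as.integer(nMrna),
      baselineMeanlog = baselineMeanlog, baselineSdlog = baselineSdlog,
      dispersion = dispersion,
      deFraction = deFraction, deLog2FC = deLog2FC,
      nTriads = as.integer(nTriads), couplingStrength = couplingStrength,
      latentScale = latentScale,
      interactionDensity = interactionDensity,
      libSizeJitter = libSizeJitter,
      seed = as.integer(seed))
}

#' Deterministic synthetic feature identifiers
#'
#' Identifier style follows field conventions: `novel_circ_NNNNNN` for
#' circRNAs, `bta-miR-sim-NNNN` for miRNAs and `ENSBTAG`-style IDs for
#' mRNAs. The `sim` infix marks miRNA IDs as synthetic.
#'
#' @param config a [SimulationConfig-class].
#' @param rnaClass one of `"circRNA"`, `"miRNA"`, `"mRNA"`.
#' @return character vector of feature IDs.
#' @export
featureIds <- function(config, rnaClass = VALID_RNA_CLASSES) {
  rnaClass <- match.arg(rnaClass)
  switch(rnaClass,
    circRNA = sprintf("novel_circ_%06d", seq_len(config@nCirc)),
    miRNA   = sprintf("bta-miR-sim-%04d", seq_len(config@nMirna)),
    mRNA    = sprintf("ENSBTAG%011d", seq_len(config@nMrna)))
}

#' Construct an RNACountSet
#'
#' @param counts nonnegative integer matrix, features x samples.
#' @param sampleData data.frame with columns `sample_id`, `tissue`,
#'   `condition`, `replicate` matching the columns of `counts`.
#' @param rnaClass RNA class of the features.
#' @return an [RNACountSet-class].
#' @export
RNACountSet <- function(counts, sampleData, rnaClass) {
  idx <- match(colnames(counts), sampleData$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  cd <- S4Vectors::DataFrame(sampleData[idx, c("tissue", "condition",
                                               "replicate")],
                             row.names = colnames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  # remember the condition order (control first) independent of sample order
  S4Vectors::metadata(se)$conditionLevels <- unique(sampleData$condition)
  new("RNACountSet", se, rnaClass = rnaClass)
}

#' @rdname rnaClass
#' @export
setMethod("rnaClass", "RNACountSet", function(x) x@rnaClass)

#' @rdname tissueSubset
#' @export
setMethod("tissueSubset", "RNACountSet", function(x, tissue) {
  sel <- colData(x)$tissue == tissue
  if (!any(sel)) stop("tissue not present: ", tissue)
  x[, sel]
})

setMethod("show", "RNACountSet", function(object) {
  cat("RNACountSet (", object@rnaClass, "): ", nrow(object), " features x ",
      ncol(object), " samples; tissues: ",
      paste(unique(colData(object)$tissue), collapse = ", "), "\n", sep = "")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@plantedDE), "planted DE features,",
      nrow(object@plantedTriads), "planted triads,",
      nrow(object@plantedInteractions), "planted interactions\n")
})

#' Simulate multi-tissue two-condition NB counts with planted structure
#'
#' For each tissue, counts are drawn negative-binomially around log-normal
#' baseline means with per-sample library-size factors. Planted DE features
#' have a mean ratio of `2^deLog2FC` between conditions, applied as
#' `+deLog2FC/2` in one condition and `-deLog2FC/2` in the other with
#' balanced up/down directions, so library composition stays comparable
#' between conditions. Each planted triad shares, within each tissue, a
#' per-sample latent factor (uniform, variance 1, bounded — no single
#' sample can dominate a group mean) added on the log-mean scale with
#' positive sign for the circRNA and mRNA and negative sign for the miRNA,
#' scaled by `couplingStrength * latentScale` and mean-centred on the count
#' scale; the triad's circRNA and mRNA additionally carry opposite-sign
#' condition effects to its miRNA. Non-planted features are
#' condition-independent.
#'
#' @param design a [StudyDesign-class].
#' @param config a [SimulationConfig-class].
#' @return a list with elements `counts` (named list of one
#'   [RNACountSet-class] per RNA class, spanning all tissues), `truth`
#'   (a [GroundTruth-class]) and `design`.
#' @examples
#' sim <- simulateCounts(generateDesign(), simulationConfig(nTriads = 2L))
#' sim$truth
#' @export
simulateCounts <- function(design, config) {
  validObject(design); validObject(config)
  set.seed(config@seed)
  info <- sampleInfo(design)
  classes <- VALID_RNA_CLASSES
  ids <- lapply(setNames(classes, classes), featureIds, config = config)
  nfeat <- vapply(ids, length, integer(1))

  # baseline means shared across tissues
  mu0 <- lapply(ids, function(f)
    setNames(stats::rlnorm(length(f), config@baselineMeanlog,
                           config@baselineSdlog), f))

  # planted triads: distinct features per class
  tri <- data.frame(circ_id = character(), mirna_id = character(),
                    mrna_id = character(), stringsAsFactors = FALSE)
  if (config@nTriads > 0L) {
    tri <- data.frame(
      circ_id  = sample(ids$circRNA, config@nTriads),
      mirna_id = sample(ids$miRNA, config@nTriads),
      mrna_id  = sample(ids$mRNA, config@nTriads),
      stringsAsFactors = FALSE)
  }
  # balanced up/down signs keep library composition comparable between
  # conditions (CPM fold changes would otherwise be biased)
  triSign <- if (config@nTriads > 0L)
    rep_len(c(1, -1), config@nTriads) else numeric()

  # planted DE: triad members first (circ/mRNA follow the triad sign, the
  # miRNA opposes it), then extra random features up to deFraction per class
  de <- list()
  triadMembers <- list(circRNA = tri$circ_id, miRNA = tri$mirna_id,
                       mRNA = tri$mrna_id)
  triadDir <- list(circRNA = triSign, miRNA = -triSign, mRNA = triSign)
  for (cl in classes) {
    dir <- setNames(rep(0, nfeat[[cl]]), ids[[cl]])
    dir[triadMembers[[cl]]] <- triadDir[[cl]]
    target <- round(config@deFraction * nfeat[[cl]])
    extra <- target - length(triadMembers[[cl]])
    if (extra > 0L) {
      pool <- setdiff(ids[[cl]], triadMembers[[cl]])
      pick <- sample(pool, extra)
      dir[pick] <- rep_len(c(1, -1), extra)
    }
    de[[cl]] <- dir
  }
  plantedDE <- do.call(rbind, lapply(classes, function(cl) {
    dd <- de[[cl]][de[[cl]] != 0]
    if (!length(dd))
      return(data.frame(class = character(), feature_id = character(),
                        direction = character(), stringsAsFactors = FALSE))
    data.frame(class = cl, feature_id = names(dd),
               direction = ifelse(dd > 0, "up", "down"),
               stringsAsFactors = FALSE)
  }))
  rownames(plantedDE) <- NULL

  plantedInteractions <- if (nrow(tri)) {
    unique(rbind(
      data.frame(mirna_id = tri$mirna_id, target_id = tri$circ_id,
                 target_type = "circRNA", stringsAsFactors = FALSE),
      data.frame(mirna_id = tri$mirna_id, target_id = tri$mrna_id,
                 target_type = "mRNA", stringsAsFactors = FALSE)))
  } else {
    data.frame(mirna_id = character(), target_id = character(),
               target_type = character(), stringsAsFactors = FALSE)
  }
  rownames(plantedInteractions) <- NULL

  truth <- new("GroundTruth", plantedDE = plantedDE, plantedTriads = tri,
               plantedInteractions = plantedInteractions)

  amp <- config@couplingStrength * config@latentScale
  lfcNat <- config@deLog2FC * log(2)
  counts <- lapply(setNames(classes, classes), function(cl)
    matrix(0L, nfeat[[cl]], nrow(info),
           dimnames = list(ids[[cl]], info$sample_id)))

  for (ts in design@tissues) {
    sel <- which(info$tissue == ts)
    ns <- length(sel)
    libf <- stats::runif(ns, 1 - config@libSizeJitter,
                         1 + config@libSizeJitter)
    isHS <- info$condition[sel] == design@conditions[2]
    # bounded variance-1 latent factor: monotone coupling without the
    # heavy multiplicative tail a Gaussian would put on group means
    latent <- if (config@nTriads > 0L)
      matrix(stats::runif(config@nTriads * ns, -sqrt(3), sqrt(3)),
             config@nTriads, ns)
    else matrix(0, 0, ns)
    for (cl in classes) {
      lm <- matrix(log(mu0[[cl]]), nfeat[[cl]], ns) +
        matrix(log(libf), nfeat[[cl]], ns, byrow = TRUE)
      dd <- de[[cl]]
      hit <- which(dd != 0)
      if (length(hit)) {
        # fold change split symmetrically across conditions: the mean ratio
        # stays 2^deLog2FC while library totals stay balanced
        lm[hit, isHS] <- lm[hit, isHS] + dd[hit] * lfcNat / 2
        lm[hit, !isHS] <- lm[hit, !isHS] - dd[hit] * lfcNat / 2
      }
      if (config@nTriads > 0L) {
        memb <- match(triadMembers[[cl]], ids[[cl]])
        sgn <- if (cl == "miRNA") -1 else 1
        b <- amp * sqrt(3)
        # centre the multiplicative latent: E[exp(amp * U)] = sinh(b)/b
        lm[memb, ] <- lm[memb, ] + sgn * amp * latent - log(sinh(b) / b)
      }
      y <- stats::rnbinom(length(lm), mu = exp(lm),
                          size = 1 / config@dispersion)
      counts[[cl]][, sel] <- matrix(as.integer(y), nfeat[[cl]], ns)
    }
  }

  sets <- lapply(setNames(classes, classes), function(cl)
    RNACountSet(counts[[cl]], info, cl))
  list(counts = sets, truth = truth, design = design)
}

#' Generate a miRNA-target interaction table
#'
#' Returns all planted miRNA-target interactions plus decoy edges sampled
#' independently with probability `interactionDensity` among all non-planted
#' miRNA x target combinations (targets are all circRNAs and mRNAs of the
#' configured feature space). Rows are unique under
#' (mirna_id, target_id, target_type).
#'
#' @param truth a [GroundTruth-class] from [simulateCounts()].
#' @param config the [SimulationConfig-class] used for the simulation.
#' @return data.frame with columns `mirna_id`, `target_id`, `target_type`.
#' @export
generateInteractions <- function(truth, config) {
  validObject(truth); validObject(config)
  set.seed(config@seed + 1000L)
  mir <- featureIds(config, "miRNA")
  targets <- rbind(
    data.frame(target_id = featureIds(config, "circRNA"),
               target_type = "circRNA", stringsAsFactors = FALSE),
    data.frame(target_id = featureIds(config, "mRNA"),
               target_type = "mRNA", stringsAsFactors = FALSE))
  planted <- truth@plantedInteractions
  out <- planted
  if (config@interactionDensity > 0) {
    all <- expand.grid(mirna_id = mir, ti = seq_len(nrow(targets)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    decoys <- data.frame(mirna_id = all$mirna_id,
                         target_id = targets$target_id[all$ti],
                         target_type = targets$target_type[all$ti],
                         stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(decoys)) < config@interactionDensity
    decoys <- decoys[keep, , drop = FALSE]
    out <- rbind(planted, decoys)
  }
  out <- out[!duplicated(paste(out$mirna_id, out$target_id,
                               out$target_type)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
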