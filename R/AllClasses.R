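#' @import methods
#' @importFrom stats cor pt pchisq qchisq rnorm rexp runif rbinom rf df
#'   optim p.adjust hclust as.dist dist sd var chisq.test fisher.test
#'   wilcox.test kruskal.test cor.test setNames quantile complete.cases
#' @importFrom utils read.delim write.table packageVersion head
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

GROUP_LEVELS <- c("recurrence", "nonrecurrence", "healthy")

#' Simulation configuration for the synthetic cohort
#'
#' Holds every knob of the synthetic-data generators: cohort sizes,
#' planted differential expression, planted co-expression modules
#' (per-group within-module correlations), expression noise, and the
#' proportional-hazards survival model tied to marker expression.
#'
#' @slot nGenes total number of genes.
#' @slot nRecurrence,nNonRecurrence,nHealthy group sizes (samples).
#' @slot nDEUp,nDEDown numbers of genes mean-shifted up/down in the
#'   recurrence group.
#' @slot deEffect standardized mean shift (in units of \code{noiseSD}).
#' @slot moduleSpecs list of module specifications, each a list with
#'   elements \code{size}, \code{nHubs}, \code{corGroup1} (within-module
#'   correlation among recurrence samples) and \code{corGroup2} (among
#'   non-recurrence samples).
#' @slot noiseSD expression-scale standard deviation of gene noise.
#' @slot baselineHazard baseline event rate, events per month.
#' @slot logHRPerMarker log hazard ratio per unit (centered) marker
#'   expression.
#' @slot censorTimeMax administrative censoring time, months (>= 36 so
#'   that censored patients can satisfy the non-recurrence rule).
#' @slot markerGenes genes whose expression drives the hazard; empty
#'   means "use the default planted markers".
#' @slot seed integer seed; all generators derive their streams from it.
#' @export
setClass("SimulationConfig", representation(
  nGenes = "integer",
  nRecurrence = "integer",
  nNonRecurrence = "integer",
  nHealthy = "integer",
  nDEUp = "integer",
  nDEDown = "integer",
  deEffect = "numeric",
  moduleSpecs = "list",
  noiseSD = "numeric",
  baselineHazard = "numeric",
  logHRPerMarker = "numeric",
  censorTimeMax = "numeric",
  markerGenes = "character",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (object@nRecurrence < 1L || object@nNonRecurrence < 1L)
    msg <- c(msg, "nRecurrence and nNonRecurrence must be positive")
  if (object@nHealthy < 0L) msg <- c(msg, "nHealthy must be >= 0")
  if (object@nDEUp < 0L || object@nDEDown < 0L)
    msg <- c(msg, "nDEUp and nDEDown must be >= 0")
  if (object@deEffect < 0) msg <- c(msg, "deEffect must be >= 0")
  if (object@noiseSD <= 0) msg <- c(msg, "noiseSD must be > 0")
  if (object@baselineHazard <= 0) msg <- c(msg, "baselineHazard must be > 0")
  if (object@censorTimeMax < 36)
    msg <- c(msg, "censorTimeMax must be >= 36 months (non-recurrence rule)")
  modSizes <- vapply(object@moduleSpecs, function(m) as.integer(m$size), 1L)
  for (m in object@moduleSpecs) {
    if (!all(c("size", "nHubs", "corGroup1", "corGroup2") %in% names(m))) {
      msg <- c(msg, "each module spec needs size, nHubs, corGroup1, corGroup2")
      next
    }
    if (m$nHubs < 0 || m$nHubs > m$size)
      msg <- c(msg, "module nHubs must be in [0, size]")
    if (abs(m$corGroup1) > 1 || abs(m$corGroup2) > 1)
      msg <- c(msg, "module correlations must lie in [-1, 1]")
  }
  # DE genes and module genes occupy disjoint index blocks
  if (object@nDEUp + object@nDEDown + sum(modSizes) > object@nGenes)
    msg <- c(msg, "nDEUp + nDEDown + module sizes exceed nGenes")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults emulate the validation-cohort design the package targets:
#' 80 patients (35 recurrence, 45 non-recurrence), a 2000-gene matrix with
#' 300 planted differentially expressed genes (standardized shift 2), and
#' one 30-gene module co-expressed at r = 0.9 among recurrence samples only,
#' its genes also shifted up (module specs may carry a \code{shift} of
#' "up", "down" or "none"; candidate hub genes are typically
#' differentially expressed as well, and the network stage runs on the
#' DEG set). Survival follows an exponential proportional-hazards model with
#' HR = 3 per unit marker expression and administrative censoring at 60
#' months.
#'
#' @param nGenes,nRecurrence,nNonRecurrence,nHealthy cohort dimensions.
#' @param nDEUp,nDEDown,deEffect planted differential expression.
#' @param moduleSpecs planted co-expression modules; see
#'   \linkS4class{SimulationConfig}.
#' @param noiseSD,baselineHazard,logHRPerMarker,censorTimeMax,markerGenes,seed
#'   see \linkS4class{SimulationConfig}.
#' @return a validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nGenes = 200, nDEUp = 10, nDEDown = 10)
#' @export
simulationConfig <- function(nGenes = 2000L,
                             nRecurrence = 35L,
                             nNonRecurrence = 45L,
                             nHealthy = 0L,
                             nDEUp = 150L,
                             nDEDown = 150L,
                             deEffect = 2,
                             moduleSpecs = list(
                               # differential module: recurrence-specific
                               # co-expression; its hubs are the markers
                               list(size = 30L, nHubs = 3L,
                                    corGroup1 = 0.9, corGroup2 = 0.0,
                                    shift = "up"),
                               # shared module: co-expressed in both groups,
                               # background for the DiffK normalization
                               list(size = 30L, nHubs = 3L,
                                    corGroup1 = 0.7, corGroup2 = 0.7,
                                    shift = "down")),
                             noiseSD = 1,
                             baselineHazard = 0.03,
                             logHRPerMarker = log(3),
                             censorTimeMax = 60,
                             markerGenes = character(0),
                             seed = 1L) {
  new("SimulationConfig",
      nGenes = as.integer(nGenes),
      nRecurrence = as.integer(nRecurrence),
      nNonRecurrence = as.integer(nNonRecurrence),
      nHealthy = as.integer(nHealthy),
      nDEUp = as.integer(nDEUp),
      nDEDown = as.integer(nDEDown),
      deEffect = as.numeric(deEffect),
      moduleSpecs = moduleSpecs,
      noiseSD = as.numeric(noiseSD),
      baselineHazard = as.numeric(baselineHazard),
      logHRPerMarker = as.numeric(logHRPerMarker),
      censorTimeMax = as.numeric(censorTimeMax),
      markerGenes = as.character(markerGenes),
      seed = as.integer(seed))
}

#' Group-labelled expression container
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one
#' \code{"exprs"} assay (log-scale expression, genes x samples) and a
#' \code{group} column in \code{colData} with levels
#' recurrence / nonrecurrence / healthy. Planted-truth records from the
#' simulator live in \code{metadata(x)$truth}.
#'
#' @export
setClass("RecurrenceExperiment", contains = "SummarizedExperiment")

setValidity("RecurrenceExperiment", function(object) {
  msg <- character(0)
  if (!"exprs" %in% assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    v <- assay(object, "exprs")
    if (!is.numeric(v)) msg <- c(msg, "'exprs' must be numeric")
    else if (any(!is.finite(v))) msg <- c(msg, "'exprs' contains missing/non-finite values")
  }
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  else {
    g <- object$group
    if (!all(as.character(g) %in% GROUP_LEVELS))
      msg <- c(msg, sprintf("group labels must be one of: %s",
                            paste(GROUP_LEVELS, collapse = ", ")))
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique gene identifiers (rownames) are required")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "unique sample identifiers (colnames) are required")
  if (length(msg)) msg else TRUE
})

#' Construct a RecurrenceExperiment
#'
#' @param values numeric genes x samples matrix of log-scale expression,
#'   with gene identifiers as rownames and sample identifiers as colnames.
#' @param group per-sample labels (character or factor) in
#'   \{recurrence, nonrecurrence, healthy\}.
#' @param truth optional planted-structure record (a list), stored in
#'   \code{metadata()}.
#' @return a \linkS4class{RecurrenceExperiment}.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' re <- recurrenceExperiment(m, c(rep("recurrence", 2), rep("nonrecurrence", 3)))
#' @export
recurrenceExperiment <- function(values, group, truth = list()) {
  group <- factor(as.character(group), levels = GROUP_LEVELS)
  if (anyNA(group))
    stop("unknown group label; expected one of: ",
         paste(GROUP_LEVELS, collapse = ", "))
  se <- SummarizedExperiment(assays = list(exprs = values),
                             colData = DataFrame(group = group,
                                                 row.names = colnames(values)))
  obj <- new("RecurrenceExperiment", se)
  metadata(obj)$truth <- truth
  validObject(obj)
  obj
}

#' @describeIn recurrenceExperiment the expression matrix.
#' @param x a \linkS4class{RecurrenceExperiment}.
#' @export
exprValues <- function(x) assay(x, "exprs")

#' @describeIn recurrenceExperiment per-sample group factor.
#' @export
sampleGroups <- function(x) x$group

#' @describeIn recurrenceExperiment planted-truth record (list; empty if the
#'   data were not simulated).
#' @export
plantedTruth <- function(x) metadata(x)$truth

setMethod("show", "RecurrenceExperiment", function(object) {
  cat("RecurrenceExperiment:", nrow(object), "genes x", ncol(object),
      "samples\n")
  print(table(droplevels(sampleGroups(object))))
  tr <- plantedTruth(object)
  if (length(tr))
    cat("planted truth:", length(tr$deUp), "up,", length(tr$deDown),
        "down,", length(tr$hubs), "module hubs\n")
  invisible(NULL)
})

#' Random-variance-model variance prior
#'
#' Parameters of the inverse-gamma prior on gene variances fitted across
#' all genes: the precision 1/sigma^2 is Gamma(shape = a, scale = b), so
#' that a*b*s^2 follows an F(d, 2a) distribution for residual variances
#' s^2 with d degrees of freedom. The moderated t-test gains 2a degrees
#' of freedom from the prior.
#'
#' @slot a shape parameter (> 0).
#' @slot b scale parameter (> 0).
#' @slot nGenesFit number of genes used in the fit.
#' @slot residDf residual degrees of freedom per gene (n1 + n2 - 2).
#' @slot logLik maximized log-likelihood.
#' @export
setClass("RVMPrior", representation(
  a = "numeric", b = "numeric", nGenesFit = "integer",
  residDf = "numeric", logLik = "numeric"))

setValidity("RVMPrior", function(object) {
  if (object@a <= 0 || object@b <= 0) "a and b must be > 0" else TRUE
})

setMethod("show", "RVMPrior", function(object) {
  cat(sprintf(
    "RVMPrior: a = %.4g, b = %.4g (fit on %d genes, residual df = %g)\n",
    object@a, object@b, object@nGenesFit, object@residDf))
  cat(sprintf("  moderated df = residual df + 2a = %.3f\n",
              object@residDf + 2 * object@a))
  invisible(NULL)
})

#' Per-group co-expression network
#'
#' A simple undirected graph over genes. Edges carry the Pearson
#' correlation r and its p-value; isolated genes are kept as nodes with
#' degree zero.
#'
#' @slot nodes gene identifiers.
#' @slot edges data.frame with columns geneA, geneB, r, p (unordered
#'   pairs, no self-edges, no duplicates).
#' @slot groupLabel which sample group the network was built from.
#' @export
setClass("CoexpressionNetwork", representation(
  nodes = "character", edges = "data.frame", groupLabel = "character"))

setValidity("CoexpressionNetwork", function(object) {
  msg <- character(0)
  e <- object@edges
  need <- c("geneA", "geneB", "r", "p")
  if (!all(need %in% colnames(e)))
    return("edges must have columns geneA, geneB, r, p")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate nodes")
  if (nrow(e)) {
    if (any(e$geneA == e$geneB)) msg <- c(msg, "self-edges are not allowed")
    if (!all(c(e$geneA, e$geneB) %in% object@nodes))
      msg <- c(msg, "edges reference unknown nodes")
    if (any(abs(e$r) > 1 + 1e-12)) msg <- c(msg, "|r| must be <= 1")
    key <- paste(pmin(e$geneA, e$geneB), pmax(e$geneA, e$geneB))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn buildNetwork node identifiers of a network.
#' @export
networkNodes <- function(net) net@nodes

#' @describeIn buildNetwork edge table (geneA, geneB, r, p) of a network.
#' @export
networkEdges <- function(net) net@edges

#' @describeIn buildNetwork group label the network was built from.
#' @export
networkGroup <- function(net) net@groupLabel

setMethod("show", "CoexpressionNetwork", function(object) {
  cat(sprintf("CoexpressionNetwork [%s]: %d nodes, %d edges\n",
              object@groupLabel, length(object@nodes), nrow(object@edges)))
  invisible(NULL)
})

#' Pipeline configuration
#'
#' Exactly one input source must be given: either \code{simulation} (a
#' \linkS4class{SimulationConfig}) or \code{inputPaths} (a named list with
#' elements expression, groups, clinical, gmt pointing to files on disk).
#'
#' @slot inputPaths named list of input file paths (possibly empty).
#' @slot simulation a SimulationConfig, or NULL.
#' @slot pMax,qMax differential-expression gates (p < pMax and
#'   BH FDR < qMax).
#' @slot corPMax,corMinAbsR co-expression edge criteria: correlation
#'   p < corPMax and |r| >= corMinAbsR.
#' @slot nPerm permutations for the DiffK empirical null (0 disables).
#' @slot nMarkers how many top-DiffK genes to carry into survival
#'   validation.
#' @slot seed integer seed for the run.
#' @export
setClass("PipelineConfig", representation(
  inputPaths = "list", simulation = "ANY",
  pMax = "numeric", qMax = "numeric",
  corPMax = "numeric", corMinAbsR = "numeric",
  nPerm = "integer", nMarkers = "integer", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character(0)
  hasPaths <- length(object@inputPaths) > 0
  hasSim <- !is.null(object@simulation)
  if (hasPaths == hasSim)
    msg <- c(msg, "exactly one of inputPaths / simulation must be given")
  if (hasPaths &&
      !all(c("expression", "groups", "clinical", "gmt") %in%
           names(object@inputPaths)))
    msg <- c(msg, "inputPaths needs expression, groups, clinical, gmt")
  if (hasSim && !is(object@simulation, "SimulationConfig"))
    msg <- c(msg, "simulation must be a SimulationConfig")
  for (nm in c("pMax", "qMax", "corPMax")) {
    v <- slot(object, nm)
    if (v <= 0 || v > 1) msg <- c(msg, paste(nm, "must be in (0, 1]"))
  }
  if (object@corMinAbsR < 0 || object@corMinAbsR > 1)
    msg <- c(msg, "corMinAbsR must be in [0, 1]")
  if (object@nPerm < 0L) msg <- c(msg, "nPerm must be >= 0")
  if (object@nMarkers < 1L) msg <- c(msg, "nMarkers must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param simulation a \linkS4class{SimulationConfig} (synthetic run), or
#'   NULL when reading files.
#' @param inputPaths named list of file paths (expression, groups,
#'   clinical, gmt) for a file-based run.
#' @param pMax,qMax,corPMax,corMinAbsR,nPerm,nMarkers,seed see
#'   \linkS4class{PipelineConfig}.
#' @return a validated \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(simulation = NULL, inputPaths = list(),
                           pMax = 0.05, qMax = 0.10,
                           corPMax = 0.05, corMinAbsR = 0.7,
                           nPerm = 0L, nMarkers = 3L, seed = 1L) {
  new("PipelineConfig", inputPaths = inputPaths, simulation = simulation,
      pMax = pMax, qMax = qMax, corPMax = corPMax, corMinAbsR = corMinAbsR,
      nPerm = as.integer(nPerm), nMarkers = as.integer(nMarkers),
      seed = as.integer(seed))
}
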