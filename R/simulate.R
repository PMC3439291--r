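#' Simulate a group-labelled expression matrix
#'
#' Draws a Gaussian log-scale expression matrix with (i) planted
#' differentially expressed genes, mean-shifted by +/- deEffect * noiseSD
#' in the recurrence group; (ii) planted co-expression modules realized
#' through one latent factor per module and group, with per-group
#' loadings chosen so member-member correlation equals the configured
#' value (hubs get a higher loading and hence correlate more strongly
#' with every member); (iii) independent noise elsewhere. Healthy
#' samples, when present, share the non-recurrence correlation structure
#' and carry no mean shift.
#'
#' Gene identifiers are allocated in blocks: DE-up genes first, then
#' DE-down, then module genes, then pure noise. The planted structure is
#' recorded in \code{plantedTruth()}: elements \code{deUp}, \code{deDown},
#' \code{modules} (list of member/hub id vectors), \code{hubs}, and
#' \code{markers} (the genes whose expression drives the survival
#' simulator; defaults to the first three DE-up genes, falling back to
#' module hubs).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed integer seed (defaults to \code{config@seed}).
#' @return a \linkS4class{RecurrenceExperiment}.
#' @examples
#' x <- simulateExpression(simulationConfig(nGenes = 100, nDEUp = 5,
#'                                          nDEDown = 5, moduleSpecs = list()))
#' @export
simulateExpression <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(seed)
  nRec <- config@nRecurrence
  nNon <- config@nNonRecurrence
  nHea <- config@nHealthy
  nS <- nRec + nNon + nHea
  nG <- config@nGenes
  group <- rep(GROUP_LEVELS, times = c(nRec, nNon, nHea))
  sampleIds <- c(sprintf("R%03d", seq_len(nRec)),
                 sprintf("N%03d", seq_len(nNon)),
                 if (nHea) sprintf("H%03d", seq_len(nHea)))
  geneIds <- sprintf("G%05d", seq_len(nG))

  baseline <- rnorm(nG, mean = 8, sd = 1.5)
  vals <- matrix(rnorm(nG * nS, 0, config@noiseSD), nrow = nG, ncol = nS,
                 dimnames = list(geneIds, sampleIds))

  # planted mean shifts, recurrence group only
  idxUp <- seq_len(config@nDEUp)
  idxDown <- config@nDEUp + seq_len(config@nDEDown)
  recCols <- which(group == "recurrence")
  shift <- config@deEffect * config@noiseSD
  if (length(idxUp)) vals[idxUp, recCols] <- vals[idxUp, recCols] + shift
  if (length(idxDown)) vals[idxDown, recCols] <- vals[idxDown, recCols] - shift

  # planted modules: x = loading * factor + sqrt(1 - loading^2) * noise,
  # all on the noiseSD scale, so member-member correlation = corGroup
  modules <- list()
  extraUp <- integer(0); extraDown <- integer(0)
  offset <- config@nDEUp + config@nDEDown
  colSets <- list(which(group == "recurrence"),
                  which(group %in% c("nonrecurrence", "healthy")))
  for (m in config@moduleSpecs) {
    size <- as.integer(m$size)
    nHubs <- as.integer(m$nHubs)
    idx <- offset + seq_len(size)
    offset <- offset + size
    modShift <- if (is.null(m$shift)) "none" else m$shift
    loadings <- function(rho) {
      if (rho <= 0) return(rep(0, size))
      a <- rep(sqrt(rho), size)
      # hubs load more strongly and so correlate most with the module
      if (nHubs > 0) a[seq_len(nHubs)] <- sqrt(sqrt(rho))
      a
    }
    rhos <- c(m$corGroup1, m$corGroup2)
    for (gi in 1:2) {
      cols <- colSets[[gi]]
      if (!length(cols)) next
      a <- loadings(rhos[gi])
      f <- rnorm(length(cols))
      vals[idx, cols] <- config@noiseSD * (a %o% f) +
        sqrt(1 - a^2) * vals[idx, cols]
    }
    # modules may carry a mean shift as well (shift = "up"/"down"/"none"):
    # differentially co-expressed candidate genes are typically also
    # differentially expressed, and the network stage runs on the DEG set.
    # Applied after the factor structure so the full shift survives.
    if (modShift == "up") {
      vals[idx, recCols] <- vals[idx, recCols] + shift
      extraUp <- c(extraUp, idx)
    } else if (modShift == "down") {
      vals[idx, recCols] <- vals[idx, recCols] - shift
      extraDown <- c(extraDown, idx)
    }
    modules[[length(modules) + 1L]] <-
      list(genes = geneIds[idx],
           hubs = geneIds[idx[seq_len(nHubs)]],
           corGroup1 = m$corGroup1, corGroup2 = m$corGroup2)
  }

  vals <- vals + baseline

  hubs <- unlist(lapply(modules, `[[`, "hubs"), use.names = FALSE)
  markers <- config@markerGenes
  if (!length(markers)) {
    markers <- if (length(hubs)) head(hubs, 3L)
    else if (config@nDEUp > 0) geneIds[idxUp][seq_len(min(3L, config@nDEUp))]
    else geneIds[1L]
  }
  if (!all(markers %in% geneIds))
    stop("markerGenes not present in the simulated gene set: ",
         paste(setdiff(markers, geneIds), collapse = ", "))

  truth <- list(deUp = geneIds[c(idxUp, extraUp)],
                deDown = geneIds[c(idxDown, extraDown)],
                modules = modules, hubs = hubs, markers = markers)
  recurrenceExperiment(vals, group, truth = truth)
}

#' Simulate a clinical table with proportional-hazards survival
#'
#' For every patient sample (recurrence and non-recurrence groups;
#' healthy subjects have no follow-up) a recurrence time is drawn from an
#' exponential proportional-hazards model with rate
#' \code{baselineHazard * exp(logHRPerMarker * (m - mean(m)))}, where m is
#' the mean expression of the marker genes in that patient, followed by
#' administrative censoring at \code{censorTimeMax}. Patients are then
#' assigned to outcome groups by the two-cutoff rule: an event within 12
#' months defines the recurrence group and event-free follow-up of at
#' least 36 months the non-recurrence group; patients falling between the
#' cutoffs match neither definition and are excluded (their count is
#' recorded in \code{attr(x, "nExcluded")}).
#'
#' Clinical covariates (age, sex, AFP class, tumor number, cirrhosis,
#' differentiation) are drawn independently of outcome from frequencies
#' typical of an early-stage HBV-related hepatocellular carcinoma cohort.
#'
#' @param expr a \linkS4class{RecurrenceExperiment} containing the marker
#'   genes.
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed integer seed (defaults to \code{config@seed + 1}).
#' @param dropExcluded drop between-cutoff patients (default TRUE, the
#'   two-group design)? With FALSE they are kept with \code{group = NA},
#'   which is what unbiased survival-model validation should use.
#' @return a data.frame with columns patient_id, time_months, event,
#'   group (outcome group by the cutoff rule), expr_group (the label
#'   carried by the expression sample), the covariates, and one
#'   \code{marker_<gene>} column per marker gene. Attributes:
#'   \code{nExcluded}, \code{markers}.
#' @export
simulateClinical <- function(expr, config, seed = config@seed + 1L,
                             dropExcluded = TRUE) {
  stopifnot(is(expr, "RecurrenceExperiment"), is(config, "SimulationConfig"))
  set.seed(seed)
  markers <- config@markerGenes
  if (!length(markers)) markers <- plantedTruth(expr)$markers
  if (!length(markers)) stop("no marker genes available")
  if (!all(markers %in% rownames(expr)))
    stop("marker genes absent from expression matrix: ",
         paste(setdiff(markers, rownames(expr)), collapse = ", "))

  patient <- sampleGroups(expr) %in% c("recurrence", "nonrecurrence")
  ids <- colnames(expr)[patient]
  n <- length(ids)
  mv <- exprValues(expr)[markers, ids, drop = FALSE]
  m <- colMeans(mv)
  lp <- config@logHRPerMarker * (m - mean(m))
  tLat <- rexp(n, rate = config@baselineHazard * exp(lp))
  event <- as.integer(tLat < config@censorTimeMax)
  time <- pmin(tLat, config@censorTimeMax)

  outcome <- rep(NA_character_, n)
  outcome[event == 1L & time <= 12] <- "recurrence"
  outcome[event == 0L & time >= 36] <- "nonrecurrence"
  nExcluded <- sum(is.na(outcome))
  if (nExcluded == n)
    stop("all simulated patients fall between the 12/36-month cutoffs; ",
         "adjust baselineHazard or censorTimeMax")

  covar <- data.frame(
    age = round(rnorm(n, 50, 8)),
    sex = sample(c("male", "female"), n, TRUE, prob = c(0.87, 0.13)),
    afp_class = sample(c("<=400", ">400"), n, TRUE, prob = c(0.55, 0.45)),
    tumor_number = sample(c("solitary", "multiple"), n, TRUE,
                          prob = c(0.59, 0.41)),
    cirrhosis = sample(c("yes", "no"), n, TRUE, prob = c(0.65, 0.35)),
    differentiation = sample(c("I-II", "III-IV"), n, TRUE,
                             prob = c(0.54, 0.46)),
    stringsAsFactors = FALSE)

  clin <- data.frame(patient_id = ids, time_months = time, event = event,
                     group = outcome,
                     expr_group = as.character(sampleGroups(expr)[patient]),
                     covar, stringsAsFactors = FALSE)
  mvt <- t(mv)
  colnames(mvt) <- paste0("marker_", markers)
  clin <- cbind(clin, as.data.frame(mvt))
  rownames(clin) <- NULL
  if (dropExcluded) clin <- clin[!is.na(clin$group), , drop = FALSE]
  rownames(clin) <- NULL
  attr(clin, "nExcluded") <- nExcluded
  attr(clin, "markers") <- markers
  clin
}

#' Simulate a gene-set annotation collection
#'
#' Emits (i) a positive-control term per planted DE direction,
#' concentrated on the planted genes; (ii) size-matched random terms as
#' negative controls; and (iii) random terms of varied sizes. The
#' universe is the full simulated gene set.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param expr the matching \linkS4class{RecurrenceExperiment}.
#' @param seed integer seed (defaults to \code{config@seed + 2}).
#' @param nRandomTerms number of varied-size random terms.
#' @param nMatchedControls number of size-matched negative-control terms
#'   per positive control.
#' @param posFraction fraction of the planted DE set included in each
#'   positive-control term.
#' @return an annotation collection; see \code{\link{annotationCollection}}.
#' @export
simulateAnnotations <- function(config, expr, seed = config@seed + 2L,
                                nRandomTerms = 30L, nMatchedControls = 5L,
                                posFraction = 0.8) {
  stopifnot(is(expr, "RecurrenceExperiment"))
  set.seed(seed)
  universe <- rownames(expr)
  truth <- plantedTruth(expr)
  terms <- list()
  desc <- character(0)
  addTerm <- function(id, about, members) {
    terms[[id]] <<- members
    desc[id] <<- about
  }
  for (dir in c("up", "down")) {
    planted <- truth[[if (dir == "up") "deUp" else "deDown"]]
    if (!length(planted)) next
    sz <- max(2L, round(posFraction * length(planted)))
    pos <- sample(planted, sz)
    addTerm(paste0("POSCTRL_", toupper(dir)),
            paste("positive control:", dir, "planted genes"), pos)
    for (i in seq_len(nMatchedControls))
      addTerm(sprintf("CTRL_%s_%02d", toupper(dir), i),
              "size-matched random control", sample(universe, sz))
  }
  sizes <- pmin(length(universe),
                pmax(5L, round(exp(runif(nRandomTerms, log(10), log(200))))))
  for (i in seq_len(nRandomTerms))
    addTerm(sprintf("RAND_%03d", i), "random term", sample(universe, sizes[i]))
  annotationCollection(terms, termDesc = desc, universe = universe)
}

#' Construct an annotation collection
#'
#' The in-memory form of a GMT file: a named list of member-gene vectors
#' with a term-description attribute and a gene universe attribute.
#' Every member must belong to the universe; empty terms are not allowed.
#'
#' @param terms named list of character vectors (term id -> members).
#' @param termDesc named character vector of term descriptions (missing
#'   entries default to the term id).
#' @param universe all annotatable genes.
#' @return a named list of class \code{"AnnotationCollection"} with
#'   attributes \code{termDesc} and \code{universe}.
#' @export
annotationCollection <- function(terms, termDesc = NULL, universe) {
  if (!length(terms) || is.null(names(terms)) || any(names(terms) == ""))
    stop("terms must be a non-empty named list")
  if (anyDuplicated(names(terms))) stop("duplicate term ids")
  terms <- lapply(terms, function(m) unique(as.character(m)))
  if (any(vapply(terms, length, 1L) == 0L)) stop("empty terms are not allowed")
  bad <- setdiff(unique(unlist(terms)), universe)
  if (length(bad))
    stop("term members absent from the universe: ",
         paste(head(bad, 5), collapse = ", "))
  d <- setNames(names(terms), names(terms))
  if (!is.null(termDesc)) d[names(termDesc)] <- termDesc
  structure(terms, termDesc = d[names(terms)],
            universe = unique(as.character(universe)),
            class = "AnnotationCollection")
}

#' @describeIn annotationCollection the gene universe of a collection.
#' @param x an AnnotationCollection.
#' @export
annotationUniverse <- function(x) attr(x, "universe")
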