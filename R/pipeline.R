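#' Read and validate the pipeline's input files
#'
#' Reads the expression matrix + group labels, the clinical CSV, and the
#' GMT annotation file named in \code{inputPaths}, and cross-validates
#' sample identifiers: every clinical patient must be a column of the
#' expression matrix (mismatches are reported by name). GMT members
#' absent from the expression matrix are dropped; terms left empty are
#' removed.
#'
#' @param config a \linkS4class{PipelineConfig} with \code{inputPaths}.
#' @return list with elements expr (\linkS4class{RecurrenceExperiment}),
#'   clinical (data.frame), annotations (annotation collection).
#' @export
readInputs <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  paths <- config@inputPaths
  if (!length(paths)) stop("config carries no input paths (simulation run?)")
  for (p in unlist(paths))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  expr <- readExpressionTSV(paths$expression, paths$groups)
  clinical <- readClinicalCSV(paths$clinical)
  unknown <- setdiff(clinical$patient_id, colnames(expr))
  if (length(unknown))
    stop("clinical patient id(s) absent from the expression matrix: ",
         paste(unknown, collapse = ", "))
  ann <- readGMT(paths$gmt)
  terms <- lapply(unclass(ann), intersect, rownames(expr))
  terms <- terms[vapply(terms, length, 1L) > 0L]
  if (!length(terms))
    stop(paths$gmt, ": no annotation term overlaps the expression genes")
  annotations <- annotationCollection(
    terms, termDesc = attr(ann, "termDesc")[names(terms)],
    universe = rownames(expr))
  list(expr = expr, clinical = clinical, annotations = annotations)
}

.configFingerprint <- function(config) {
  txt <- paste(vapply(slotNames(config), function(s)
    paste(deparse(slot(config, s)), collapse = ""), ""), collapse = ";")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

.emptyMetrics <- function() {
  data.frame(gene_id = character(0), k1 = integer(0), k2 = integer(0),
             K1 = numeric(0), K2 = numeric(0), diffK = numeric(0),
             rank = integer(0), rankAbs = integer(0),
             core1 = integer(0), core2 = integer(0))
}

#' Run the full discovery-and-validation pipeline
#'
#' Executes, in order: differential expression (random-variance-model
#' moderated t-test, BH FDR, gate p < pMax and FDR < qMax, hierarchical
#' clustering of the DEG set), category enrichment of the up- and
#' down-regulated sets, per-group co-expression networks over the DEG
#' genes with k-core decomposition and DiffK ranking (network 1 =
#' recurrence), and survival validation of the top-DiffK markers
#' (ROC-derived Youden cutoff, dichotomization, contingency test,
#' Kaplan-Meier + log-rank, univariate and multivariate Cox). With a
#' simulation config the inputs are generated; otherwise they are read
#' from \code{inputPaths}. Identical config + seed yields an identical
#' report (up to the timestamp in the provenance block).
#'
#' An empty DEG set or an edgeless network does not abort the run: the
#' affected stages are skipped, their outputs left empty, and the
#' condition flagged in the report.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param outDir optional output directory; when given, all stage tables,
#'   the JSON report and a checksum manifest are written there (see
#'   \code{\link{writeOutputs}}).
#' @return list of class \code{"RunReport"}; element \code{report} is
#'   the machine-readable summary, the remaining elements hold full
#'   stage results.
#' @export
runPipeline <- function(config, outDir = NULL) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir) || file.access(outDir, 2) != 0)
      stop("output directory is not writable: ", outDir)
  }

  simulated <- !is.null(config@simulation)
  if (simulated) {
    sim <- config@simulation
    expr <- simulateExpression(sim)
    clinical <- simulateClinical(expr, sim)
    annotations <- simulateAnnotations(sim, expr)
  } else {
    inp <- readInputs(config)
    expr <- inp$expr; clinical <- inp$clinical; annotations <- inp$annotations
  }

  ## --- differential expression ---------------------------------------
  prior <- fitRVMPrior(expr)
  deTable <- rvmTTest(expr, prior)
  degs <- selectDEGs(deTable, pMax = config@pMax, qMax = config@qMax)
  degGenes <- c(degs$up, degs$down)
  flags <- character(0)
  clustering <- NULL
  if (length(degGenes) >= 2L) {
    patientCols <- as.character(sampleGroups(expr)) %in%
      c("recurrence", "nonrecurrence")
    clustering <- clusterExpression(exprValues(expr)[, patientCols,
                                                     drop = FALSE],
                                    genes = degGenes)
  } else flags <- c(flags, "empty or singleton DEG set")

  ## --- enrichment -----------------------------------------------------
  universe <- annotationUniverse(annotations)
  enrich <- rbind(
    if (length(degs$up)) enrichDEGs(degs$up, annotations, direction = "up"),
    if (length(degs$down)) enrichDEGs(degs$down, annotations,
                                      direction = "down"))
  if (is.null(enrich)) {
    enrich <- suppressWarnings(enrichDEGs(character(0), annotations))
    flags <- c(flags, "enrichment skipped: no DEGs")
  }

  ## --- co-expression networks and DiffK -------------------------------
  groups <- c("recurrence", "nonrecurrence")
  nets <- list(); cores <- list()
  metrics <- .emptyMetrics()
  if (length(degGenes) >= 2L) {
    for (g in groups) {
      corr <- correlationMatrix(expr, g, genes = degGenes)
      edges <- suppressWarnings(
        significantPairs(corr, pMax = config@corPMax,
                         minAbsR = config@corMinAbsR))
      nets[[g]] <- buildNetwork(edges, degGenes, groupLabel = g)
      cores[[g]] <- kcoreDecompose(nets[[g]])
    }
    if (max(connectivity(nets[[1]])) == 0 ||
        max(connectivity(nets[[2]])) == 0) {
      flags <- c(flags, "a network has maximum degree 0; DiffK skipped")
    } else {
      metrics <- diffK(nets[[groups[1]]], nets[[groups[2]]])
      metrics$core1 <- cores[[groups[1]]]$core[metrics$gene_id]
      metrics$core2 <- cores[[groups[2]]]$core[metrics$gene_id]
      if (config@nPerm > 0L) {
        pm <- permutationDiffK(expr, genes = degGenes, groups = groups,
                               nPerm = config@nPerm, pMax = config@corPMax,
                               minAbsR = config@corMinAbsR,
                               seed = config@seed + 17L)
        metrics$permP <- pm$permP[match(metrics$gene_id, pm$gene_id)]
      }
    }
  } else flags <- c(flags, "network stage skipped: no DEGs")

  ## --- survival validation of top-DiffK markers -----------------------
  markers <- head(metrics$gene_id, config@nMarkers)
  validation <- list()
  if (length(markers) && nrow(clinical)) {
    keep <- clinical$patient_id %in% colnames(expr) &
      clinical$group %in% groups
    clin <- clinical[keep, , drop = FALSE]
    recurrent <- as.integer(clin$group == "recurrence")
    for (mk in markers) {
      v <- exprValues(expr)[mk, clin$patient_id]
      res <- list(marker = mk)
      ok <- tryCatch({
        roc <- rocCutoff(v, recurrent, markerId = mk)
        di <- dichotomize(v, roc$cutoff, outcome = clin$group)
        res$auc <- roc$auc; res$cutoff <- roc$cutoff
        res$sensitivity <- roc$sensitivity
        res$specificity <- roc$specificity
        res$pctHigh <- as.list(di$pctHigh)
        res$table <- di$table
        if (!di$degenerate) {
          ct <- contingencyTest(unclass(di$table))
          res$pChi2 <- ct$pChi2; res$pFisher <- ct$pFisher
          hl <- factor(ifelse(di$high, "high", "low"),
                       levels = c("low", "high"))
          res$km <- kmEstimate(clin$time_months, clin$event, hl)
          lr <- logrankTest(clin$time_months, clin$event, hl)
          res$logrankStat <- lr$statistic; res$logrankP <- lr$p
          cdat <- data.frame(time_months = clin$time_months,
                             event = clin$event, expression = hl)
          cx <- coxFit(cdat, "expression")
          res$coxHR <- cx$terms$HR[1]
          res$coxCI <- c(cx$terms$ciLow[1], cx$terms$ciHigh[1])
          res$coxP <- cx$terms$p[1]
        } else res$flag <- "degenerate dichotomy"
        TRUE
      }, error = function(e) {
        res$flag <<- conditionMessage(e)
        FALSE
      })
      validation[[mk]] <- res
    }
    ## multivariate model: marker indicators + AFP class (when present)
    mvCov <- character(0)
    cdat <- data.frame(time_months = clin$time_months, event = clin$event)
    for (mk in markers) {
      v <- exprValues(expr)[mk, clin$patient_id]
      cut <- validation[[mk]]$cutoff
      if (is.null(cut)) next
      col <- paste0(mk, "_high")
      cdat[[col]] <- factor(ifelse(v > cut, "high", "low"),
                            levels = c("low", "high"))
      if (nlevels(droplevels(cdat[[col]])) == 2L) mvCov <- c(mvCov, col)
    }
    if ("afp_class" %in% colnames(clin) &&
        length(unique(clin$afp_class)) == 2L) {
      cdat$afp_class <- clin$afp_class
      mvCov <- c(mvCov, "afp_class")
    }
    if (length(mvCov) >= 2L) {
      mv <- tryCatch(coxFit(cdat, mvCov), error = function(e) NULL)
      if (!is.null(mv)) validation$multivariate <- mv$terms
    }
  } else if (length(markers) == 0L)
    flags <- c(flags, "survival validation skipped: no ranked markers")

  ## --- machine-readable report ----------------------------------------
  topEnrich <- function(dir, k = 10) {
    e <- enrich[enrich$direction == dir, , drop = FALSE]
    head(e[, c("term_id", "nf", "Nf", "Re", "pFisher", "q", "LgP")], k)
  }
  report <- list(
    degCounts = as.list(degs$counts),
    thresholds = list(pMax = config@pMax, qMax = config@qMax,
                      corPMax = config@corPMax,
                      corMinAbsR = config@corMinAbsR,
                      nPerm = config@nPerm, nMarkers = config@nMarkers),
    topEnrichedUp = topEnrich("up"),
    topEnrichedDown = topEnrich("down"),
    topDiffK = head(metrics, 20),
    markerValidation = lapply(validation[markers[markers %in%
                                                   names(validation)]],
      function(r) r[setdiff(names(r), c("km", "table"))]),
    multivariateCox = validation$multivariate,
    nClinicalExcluded = if (is.null(attr(clinical, "nExcluded")))
      NA_integer_ else attr(clinical, "nExcluded"),
    flags = flags,
    provenance = list(package = "RecurNet",
                      version = as.character(packageVersion("RecurNet")),
                      seed = config@seed,
                      configHash = .configFingerprint(config),
                      simulated = simulated,
                      timestamp = format(Sys.time(), tz = "UTC")))

  out <- structure(list(report = report, expr = expr, clinical = clinical,
                        annotations = annotations, prior = prior,
                        deTable = deTable, degs = degs,
                        clustering = clustering, enrichment = enrich,
                        networks = nets, cores = cores, metrics = metrics,
                        validation = validation, config = config),
                   class = "RunReport")
  if (!is.null(outDir)) out$manifest <- writeOutputs(out, outDir)
  out
}

#' @export
print.RunReport <- function(x, ...) {
  r <- x$report
  cat("RecurNet run:", r$degCounts$up, "up /", r$degCounts$down,
      "down DEGs\n")
  if (nrow(r$topDiffK))
    cat("top DiffK genes:",
        paste(head(r$topDiffK$gene_id, 5), collapse = ", "), "\n")
  if (length(r$flags)) cat("flags:", paste(r$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Persist all stage outputs of a run
#'
#' Writes the DE table, enrichment table, per-group edge lists, the
#' node-metrics table (k1, k2, K1, K2, DiffK, ranks, core numbers),
#' per-marker Kaplan-Meier step tables, the clinical table, the JSON
#' report, and a \code{manifest.json} listing every file with its MD5
#' checksum. Empty stages produce headers-only files so the output set
#' is always complete.
#'
#' @param run a \code{"RunReport"} from \code{\link{runPipeline}}.
#' @param outDir output directory (created if needed).
#' @return data.frame (file, md5), invisibly also written as
#'   \code{manifest.json}.
#' @export
writeOutputs <- function(run, outDir) {
  stopifnot(inherits(run, "RunReport"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wtsv <- function(d, name) {
    f <- file.path(outDir, name)
    write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, f)
  }
  de <- run$deTable[, c("gene_id", "logRatio", "tStat", "df", "p", "q",
                        "direction")]
  wtsv(de, "de_table.tsv")
  wtsv(run$enrichment, "enrichment.tsv")
  for (g in c("recurrence", "nonrecurrence")) {
    f <- file.path(outDir, paste0("edges_", g, ".tsv"))
    if (!is.null(run$networks[[g]])) writeEdgeList(run$networks[[g]], f)
    else writeLines("gene_a\tgene_b\tr\tp\tgroup", f)
    files <- c(files, f)
  }
  wtsv(run$metrics, "node_metrics.tsv")
  for (mk in names(run$validation)) {
    km <- run$validation[[mk]]$km
    if (is.null(km)) next
    wtsv(km$curves, paste0("km_", mk, ".tsv"))
  }
  f <- file.path(outDir, "clinical.csv")
  writeClinicalCSV(run$clinical, f)
  files <- c(files, f)
  f <- file.path(outDir, "report.json")
  jsonlite::write_json(run$report, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, dataframe = "rows")
  files <- c(files, f)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
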