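#' Read and write the pipeline's plain-text formats
#'
#' Expression travels as tab-separated text with gene identifiers in the
#' first column (header \code{gene_id}) and sample identifiers in the
#' header row; group labels as a two-column sample/group TSV; the
#' clinical table as CSV with a header; gene sets as standard GMT
#' (term id, description, then tab-separated members).
#'
#' @param x object to write (see each function).
#' @param file,groupFile file paths.
#' @return the written file path (writers, invisibly) or the parsed
#'   object (readers).
#' @name recurnet-io
NULL

#' @describeIn recurnet-io write expression + group labels of a
#'   \linkS4class{RecurrenceExperiment} to \code{file} / \code{groupFile}.
#' @export
writeExpressionTSV <- function(x, file, groupFile) {
  stopifnot(is(x, "RecurrenceExperiment"))
  tab <- data.frame(gene_id = rownames(x), exprValues(x),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  grp <- data.frame(sample_id = colnames(x),
                    group = as.character(sampleGroups(x)))
  write.table(grp, groupFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(file, groupFile))
}

#' @describeIn recurnet-io read expression + group labels back into a
#'   \linkS4class{RecurrenceExperiment}; malformed numeric cells are
#'   reported with their line and column.
#' @export
readExpressionTSV <- function(file, groupFile) {
  raw <- read.delim(file, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (!ncol(raw) || colnames(raw)[1] != "gene_id")
    stop(sprintf("%s: first column must be 'gene_id'", file))
  genes <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat),
                                dimnames = dimnames(mat)))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "%s: non-numeric value '%s' at line %d, column '%s'",
      file, mat[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L,
      colnames(mat)[bad[1, 2]]))
  if (anyNA(num))
    stop(sprintf("%s: missing values are not allowed", file))
  rownames(num) <- genes
  grp <- read.delim(groupFile, header = TRUE, sep = "\t",
                    colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(grp)))
    stop(sprintf("%s: expected columns sample_id, group", groupFile))
  missing <- setdiff(colnames(num), grp$sample_id)
  if (length(missing))
    stop(sprintf("%s: no group label for sample(s): %s", groupFile,
                 paste(missing, collapse = ", ")))
  labels <- grp$group[match(colnames(num), grp$sample_id)]
  recurrenceExperiment(num, labels)
}

#' @describeIn recurnet-io write a clinical table (data.frame) as CSV.
#' @export
writeClinicalCSV <- function(x, file) {
  utils::write.csv(x, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @describeIn recurnet-io read a clinical CSV; requires columns
#'   patient_id, time_months, event, group and validates their contents.
#' @export
readClinicalCSV <- function(file) {
  clin <- utils::read.csv(file, header = TRUE, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_months", "event", "group")
  miss <- setdiff(need, colnames(clin))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", file,
                 paste(miss, collapse = ", ")))
  if (!is.numeric(clin$time_months) || any(clin$time_months <= 0))
    stop(sprintf("%s: time_months must be positive numbers", file))
  if (!all(clin$event %in% c(0L, 1L)))
    stop(sprintf("%s: event must be 0 or 1", file))
  clin
}

#' @describeIn recurnet-io write an annotation collection as GMT.
#' @export
writeGMT <- function(x, file) {
  stopifnot(inherits(x, "AnnotationCollection"))
  desc <- attr(x, "termDesc")
  lines <- vapply(names(x), function(id)
    paste(c(id, desc[[id]], x[[id]]), collapse = "\t"), "")
  writeLines(lines, file)
  invisible(file)
}

#' @describeIn recurnet-io read a GMT file; the universe defaults to the
#'   union of all members unless \code{universe} is supplied.
#' @param universe optional gene universe for \code{readGMT}.
#' @export
readGMT <- function(file, universe = NULL) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop(sprintf("%s: line %d has fewer than 3 tab-separated fields",
                 file, short[1]))
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- setNames(vapply(fields, `[[`, "", 2L), ids)
  terms <- setNames(lapply(fields, function(f) f[-(1:2)]), ids)
  if (is.null(universe)) universe <- unique(unlist(terms))
  annotationCollection(terms, termDesc = desc, universe = universe)
}

#' @describeIn recurnet-io write a network's edge list as TSV
#'   (gene_a, gene_b, r, p, group).
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @export
writeEdgeList <- function(net, file) {
  stopifnot(is(net, "CoexpressionNetwork"))
  e <- networkEdges(net)
  out <- data.frame(gene_a = e$geneA, gene_b = e$geneB, r = e$r, p = e$p,
                    group = rep(networkGroup(net), nrow(e)))
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @describeIn recurnet-io read an edge-list TSV back into a
#'   \linkS4class{CoexpressionNetwork}; \code{nodes} restores isolated
#'   genes lost by the edge-list representation.
#' @param nodes node universe for \code{readEdgeList}.
#' @export
readEdgeList <- function(file, nodes = NULL) {
  e <- read.delim(file, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "r", "p")
  if (!all(need %in% colnames(e)))
    stop(sprintf("%s: expected columns %s", file, paste(need, collapse = ", ")))
  grp <- if (nrow(e)) unique(e$group) else "unknown"
  if (length(grp) != 1L)
    stop(sprintf("%s: edge list mixes groups", file))
  edges <- data.frame(geneA = e$gene_a, geneB = e$gene_b, r = e$r, p = e$p,
                      stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- unique(c(edges$geneA, edges$geneB))
  buildNetwork(edges, nodes, groupLabel = grp)
}
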