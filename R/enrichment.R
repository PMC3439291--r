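#' Enrichment ratio of a gene category
#'
#' Re = (nf/n) / (Nf/N): the rate of a category within the
#' differentially expressed target set relative to its rate in the gene
#' universe. A value of 1 means the category occurs at the background
#' rate; values above 1 mean over-representation.
#'
#' @param nf DEG-set genes in the category.
#' @param n DEG-set genes annotated to any category.
#' @param Nf universe genes in the category.
#' @param N universe genes annotated to any category.
#' @return the enrichment ratio (>= 0). By convention Nf = 0 with
#'   nf = 0 returns 0; Nf = 0 with nf > 0 is an impossible input and
#'   errors.
#' @examples
#' enrichmentRatio(10, 100, 50, 1000)  # 2.0
#' @export
enrichmentRatio <- function(nf, n, Nf, N) {
  stopifnot(length(nf) == 1, length(n) == 1, length(Nf) == 1, length(N) == 1)
  if (n <= 0 || N <= 0) stop("n and N must be positive")
  if (nf < 0 || Nf < 0) stop("counts must be non-negative")
  if (nf > n || Nf > N) stop("nf <= n and Nf <= N are required")
  if (Nf == 0) {
    if (nf > 0) stop("impossible input: nf > 0 with Nf = 0")
    return(0)
  }
  (nf / n) / (Nf / N)
}

#' Fisher and chi-square tests for a gene category
#'
#' Forms the 2x2 table [nf, n - nf; Nf - nf, N - n - Nf + nf]
#' (DEG vs non-DEG x in-category vs not) and returns the two-sided
#' Fisher exact p (point-probability rule: the sum of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table) and the Pearson chi-square p without continuity
#' correction.
#'
#' @inheritParams enrichmentRatio
#' @return list with elements pFisher, pChi2, chi2Stat, table.
#' @export
categoryTest <- function(nf, n, Nf, N) {
  tab <- matrix(c(nf, Nf - nf, n - nf, N - n - Nf + nf),
                nrow = 2, byrow = FALSE,
                dimnames = list(c("deg", "other"), c("inCat", "notCat")))
  if (any(tab < 0)) stop("negative derived cell; check nf <= Nf, n <= N")
  pFisher <- min(1, fisher.test(tab)$p.value)  # guard fp overshoot of 1
  cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(pFisher = pFisher, pChi2 = unname(cs$p.value),
       chi2Stat = unname(cs$statistic), table = tab)
}

#' Score gene categories for over-representation in a DEG set
#'
#' Every annotation term is scored against one direction of the DEG set.
#' Following the convention that keeps the two rates comparable, n is
#' the number of DEG-set genes annotated to at least one term and N the
#' number of universe genes annotated to at least one term; nf and Nf
#' are the term's overlap with each. Results carry the enrichment ratio
#' Re, the two-sided Fisher and chi-square p-values, BH FDR across terms
#' (within the direction), and LgP = log10(pFisher).
#'
#' @param degSet character vector of DEG gene ids (one direction).
#' @param annotations an annotation collection
#'   (\code{\link{annotationCollection}} / \code{\link{readGMT}}).
#' @param universe gene universe (defaults to the collection's).
#' @param direction label recorded in the result ("up"/"down").
#' @return data.frame sorted by pFisher with columns term_id, term_name,
#'   direction, nf, n, Nf, N, Re, pFisher, pChi2, q, LgP.
#' @export
enrichDEGs <- function(degSet, annotations, universe = NULL,
                       direction = "up") {
  stopifnot(inherits(annotations, "AnnotationCollection"))
  if (is.null(universe)) universe <- annotationUniverse(annotations)
  if (!length(degSet)) {
    warning("empty DEG set; returning no enrichment results")
    return(data.frame(term_id = character(0), term_name = character(0),
                      direction = character(0), nf = integer(0),
                      n = integer(0), Nf = integer(0), N = integer(0),
                      Re = numeric(0), pFisher = numeric(0),
                      pChi2 = numeric(0), q = numeric(0), LgP = numeric(0)))
  }
  bad <- setdiff(degSet, universe)
  if (length(bad))
    stop("DEG genes absent from the universe: ",
         paste(head(bad, 5), collapse = ", "))
  annotated <- unique(unlist(annotations, use.names = FALSE))
  annotated <- intersect(annotated, universe)
  degAnn <- intersect(degSet, annotated)
  n <- length(degAnn)
  N <- length(annotated)
  if (N == 0L) stop("no annotated genes in the universe")
  desc <- attr(annotations, "termDesc")
  rows <- lapply(names(annotations), function(id) {
    members <- intersect(annotations[[id]], annotated)
    Nf <- length(members)
    nf <- length(intersect(members, degAnn))
    re <- if (Nf == 0) 0 else enrichmentRatio(nf, max(n, 1L), Nf, N)
    ct <- categoryTest(nf, max(n, 1L), Nf, N)
    data.frame(term_id = id, term_name = unname(desc[[id]]),
               direction = direction, nf = nf, n = n, Nf = Nf, N = N,
               Re = re, pFisher = ct$pFisher, pChi2 = ct$pChi2,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bhFDR(res$pFisher)
  res$LgP <- log10(res$pFisher)
  res <- res[order(res$pFisher, -res$Re, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
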