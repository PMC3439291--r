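## Random-variance-model moderated t-test for two-group designs.
##
## The precision 1/sigma_g^2 of each gene is modelled as Gamma(a, scale b),
## which makes a*b*s_g^2 an F(d, 2a) variate for the residual variance s_g^2
## on d = n1 + n2 - 2 degrees of freedom. (a, b) are fitted across all genes
## by maximum likelihood of that F model; the moderated variance is the
## inverse posterior-mean precision (d*s^2 + 2/b) / (d + 2a) and the
## moderated t-statistic gains 2a degrees of freedom: df = d + 2a. With
## three samples per group this raises df well above the ordinary 4, which
## is what makes the test usable at such sample sizes.

.groupMatrices <- function(x, groups) {
  stopifnot(is(x, "RecurrenceExperiment"), length(groups) == 2L)
  g <- as.character(sampleGroups(x))
  m1 <- exprValues(x)[, g == groups[1], drop = FALSE]
  m2 <- exprValues(x)[, g == groups[2], drop = FALSE]
  if (ncol(m1) < 2L || ncol(m2) < 2L)
    stop("each group needs at least 2 samples; got ",
         ncol(m1), " and ", ncol(m2))
  list(m1 = m1, m2 = m2)
}

.pooledVariance <- function(m1, m2) {
  n1 <- ncol(m1); n2 <- ncol(m2)
  v1 <- apply(m1, 1, var)
  v2 <- apply(m2, 1, var)
  ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
}

#' Fit the random-variance-model prior
#'
#' Maximum-likelihood fit of the inverse-gamma variance prior (a, b)
#' across all genes, from the per-gene pooled residual variances of a
#' two-group comparison. Under the model, a*b*s^2 ~ F(d, 2a) with
#' d = n1 + n2 - 2.
#'
#' Genes with exactly zero residual variance carry no likelihood
#' information under the continuous model and are dropped from the fit
#' (an error is raised if all variances are zero). When the variances
#' are (near-)identical the likelihood pushes a to its upper
#' optimization bound of 1e8 -- the complete-shrinkage regime.
#'
#' @param x a \linkS4class{RecurrenceExperiment}.
#' @param groups the two group labels compared (first minus second).
#' @return an \linkS4class{RVMPrior}.
#' @examples
#' x <- simulateExpression(simulationConfig(nGenes = 200, nRecurrence = 3,
#'   nNonRecurrence = 3, nDEUp = 0, nDEDown = 0, moduleSpecs = list()))
#' fitRVMPrior(x)
#' @export
fitRVMPrior <- function(x, groups = c("recurrence", "nonrecurrence")) {
  mm <- .groupMatrices(x, groups)
  if (nrow(x) < 10L) stop("at least 10 genes are required to fit the prior")
  d <- ncol(mm$m1) + ncol(mm$m2) - 2
  s2 <- .pooledVariance(mm$m1, mm$m2)
  if (all(s2 <= .Machine$double.eps))
    stop("all gene-wise variances are zero; cannot fit the variance prior")
  s2 <- s2[s2 > 0]
  negll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(df(a * b * s2, df1 = d, df2 = 2 * a, log = TRUE) + log(a * b))
  }
  start <- c(log(2), log(1 / mean(s2)))
  fit <- optim(start, negll, method = "L-BFGS-B",
               lower = c(log(1e-3), log(1e-10)),
               upper = c(log(1e8), log(1e10)),
               control = list(maxit = 500))
  new("RVMPrior", a = exp(fit$par[1]), b = exp(fit$par[2]),
      nGenesFit = length(s2), residDf = d, logLik = -fit$value)
}

#' Moderated t-test with a random-variance prior
#'
#' Per gene, the moderated variance is
#' \code{s2Tilde = (d * s2 + 2/b) / (d + 2a)} and
#' \code{t = (mean1 - mean2) / sqrt(s2Tilde * (1/n1 + 1/n2))}, with a
#' two-sided p-value from a t distribution on \code{d + 2a} degrees of
#' freedom. BH-adjusted FDR values are included.
#'
#' @param x a \linkS4class{RecurrenceExperiment}.
#' @param prior an \linkS4class{RVMPrior} fitted on the same data/groups.
#' @param groups the two group labels compared (first minus second).
#' @return data.frame with one row per gene: gene_id, meanGroup1,
#'   meanGroup2, logRatio, s2, s2Tilde, tStat, df, p, q, direction.
#' @export
rvmTTest <- function(x, prior, groups = c("recurrence", "nonrecurrence")) {
  stopifnot(is(prior, "RVMPrior"))
  mm <- .groupMatrices(x, groups)
  n1 <- ncol(mm$m1); n2 <- ncol(mm$m2)
  d <- n1 + n2 - 2
  if (d != prior@residDf)
    stop("prior was fitted on a design with residual df ", prior@residDf,
         ", data have ", d)
  mu1 <- rowMeans(mm$m1)
  mu2 <- rowMeans(mm$m2)
  s2 <- .pooledVariance(mm$m1, mm$m2)
  a <- prior@a; b <- prior@b
  s2Tilde <- (d * s2 + 2 / b) / (d + 2 * a)
  dfMod <- d + 2 * a
  tStat <- (mu1 - mu2) / sqrt(s2Tilde * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tStat), df = dfMod)
  res <- data.frame(
    gene_id = rownames(x),
    meanGroup1 = mu1, meanGroup2 = mu2, logRatio = mu1 - mu2,
    s2 = s2, s2Tilde = s2Tilde, tStat = tStat, df = dfMod, p = p,
    q = bhFDR(p),
    direction = ifelse(mu1 - mu2 >= 0, "up", "down"),
    stringsAsFactors = FALSE)
  rownames(res) <- res$gene_id
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; a validating wrapper around
#' \code{\link[stats]{p.adjust}(method = "BH")}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values (q-values), same order as the input.
#' @export
bhFDR <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' Retains genes with p < pMax and BH FDR < qMax (the discovery gates of
#' the analysis: p below 0.05 and FDR below 10 percent by default) and
#' partitions them by the sign of the log-ratio. An optional absolute
#' log-ratio filter is available but off by default.
#'
#' @param results data.frame from \code{\link{rvmTTest}}.
#' @param pMax,qMax significance gates.
#' @param minAbsLogRatio optional fold-change gate on |logRatio|
#'   (0 = disabled).
#' @return list of class \code{"DEGSelection"}: \code{up} and \code{down}
#'   gene-id vectors, \code{table} (the retained rows), \code{counts},
#'   and the thresholds used.
#' @export
selectDEGs <- function(results, pMax = 0.05, qMax = 0.10,
                       minAbsLogRatio = 0) {
  if (!nrow(results)) stop("empty results")
  keep <- results$p < pMax & results$q < qMax &
    abs(results$logRatio) >= minAbsLogRatio
  tab <- results[keep, , drop = FALSE]
  up <- tab$gene_id[tab$logRatio >= 0]
  down <- tab$gene_id[tab$logRatio < 0]
  structure(list(up = up, down = down, table = tab,
                 counts = c(up = length(up), down = length(down),
                            total = length(up) + length(down)),
                 pMax = pMax, qMax = qMax,
                 minAbsLogRatio = minAbsLogRatio),
            class = "DEGSelection")
}

#' @export
print.DEGSelection <- function(x, ...) {
  cat(sprintf("DEG selection (p < %g, FDR < %g): %d up, %d down\n",
              x$pMax, x$qMax, x$counts["up"], x$counts["down"]))
  invisible(x)
}

#' Agglomerative clustering of genes and samples
#'
#' Unsupervised hierarchical clustering of an expression matrix (for
#' heatmap display of a DEG set): genes and samples are clustered
#' separately and their dendrograms and leaf orders returned.
#' Correlation distance (1 - r) with average linkage is the default;
#' Euclidean distance and other \code{\link[stats]{hclust}} linkages are
#' available. For the sample-side correlation distance, gene profiles
#' are first centered (the heatmap row-scaling convention): without
#' centering, between-sample correlations are dominated by the shared
#' gene-baseline profile and a pure group mean-shift is invisible.
#' Pairs involving a constant profile have no defined correlation;
#' their correlation is taken as zero (distance 1), so constant rows
#' cluster apart rather than failing.
#'
#' @param x a \linkS4class{RecurrenceExperiment} or numeric matrix.
#' @param genes optional gene subset (e.g. the DEG set).
#' @param distance "correlation" (1 - Pearson r) or "euclidean".
#' @param linkage an hclust agglomeration method.
#' @return list with geneOrder, sampleOrder (leaf orders), geneTree,
#'   sampleTree (hclust objects).
#' @export
clusterExpression <- function(x, genes = NULL,
                              distance = c("correlation", "euclidean"),
                              linkage = "average") {
  distance <- match.arg(distance)
  mat <- if (is(x, "RecurrenceExperiment")) exprValues(x) else as.matrix(x)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(mat))
    if (length(miss)) stop("unknown genes: ", paste(head(miss, 5),
                                                    collapse = ", "))
    mat <- mat[genes, , drop = FALSE]
  }
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("need at least 2 genes and 2 samples")
  distFun <- function(m) {
    if (distance == "euclidean") return(dist(m))
    r <- suppressWarnings(cor(t(m)))
    r[!is.finite(r)] <- 0  # constant profiles: correlation taken as 0
    as.dist(1 - r)
  }
  geneTree <- hclust(distFun(mat), method = linkage)
  sampleMat <- if (distance == "correlation") t(mat - rowMeans(mat))
               else t(mat)
  sampleTree <- hclust(distFun(sampleMat), method = linkage)
  list(geneOrder = rownames(mat)[geneTree$order],
       sampleOrder = colnames(mat)[sampleTree$order],
       geneTree = geneTree, sampleTree = sampleTree,
       distance = distance, linkage = linkage)
}
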