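#' Pairwise Pearson correlations within one sample group
#'
#' Computes the Pearson correlation for every unordered gene pair using
#' the samples of one group, with a p-value from the t-transform
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#' Constant genes have no defined correlation and are flagged; their
#' pairs carry NA.
#'
#' @param x a \linkS4class{RecurrenceExperiment}.
#' @param group which sample group to use.
#' @param genes optional gene subset.
#' @return list of class \code{"CorrelationResult"}: r and p matrices,
#'   sample size n, logical \code{constant} flags, and the group label.
#' @export
correlationMatrix <- function(x, group, genes = NULL) {
  stopifnot(is(x, "RecurrenceExperiment"))
  mat <- exprValues(x)[, as.character(sampleGroups(x)) == group,
                       drop = FALSE]
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  n <- ncol(mat)
  if (n < 3L)
    stop("correlation p-values need at least 3 samples; group '",
         group, "' has ", n)
  if (nrow(mat) < 2L) stop("need at least 2 genes")
  constant <- apply(mat, 1, function(v) var(v) == 0)
  r <- suppressWarnings(cor(t(mat)))
  r[constant, ] <- NA
  r[, constant] <- NA
  rc <- pmin(pmax(r, -1), 1)
  tt <- abs(rc) * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * pt(tt, df = n - 2, lower.tail = FALSE)
  p[abs(rc) >= 1] <- 0
  diag(p) <- 0
  structure(list(r = r, p = p, n = n, constant = constant, group = group),
            class = "CorrelationResult")
}

#' Select significant correlation pairs
#'
#' Retains unordered pairs with correlation p < pMax and |r| >= minAbsR.
#' At tiny sample sizes a pure p gate is vacuous, so a magnitude gate is
#' applied as well; both criteria are recorded on the result.
#'
#' @param corr a \code{"CorrelationResult"} from
#'   \code{\link{correlationMatrix}}.
#' @param pMax correlation p-value gate.
#' @param minAbsR minimum |r| gate.
#' @return data.frame (geneA, geneB, r, p) with attributes pMax,
#'   minAbsR; a warning is issued when no pair passes.
#' @export
significantPairs <- function(corr, pMax = 0.05, minAbsR = 0.7) {
  stopifnot(inherits(corr, "CorrelationResult"))
  r <- corr$r; p <- corr$p
  keep <- upper.tri(r) & !is.na(r) & p < pMax & abs(r) >= minAbsR
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(geneA = rownames(r)[idx[, 1]],
                      geneB = colnames(r)[idx[, 2]],
                      r = r[idx], p = p[idx], stringsAsFactors = FALSE)
  if (!nrow(edges))
    warning("no significant correlation pairs at p < ", pMax,
            ", |r| >= ", minAbsR)
  edges <- edges[order(edges$geneA, edges$geneB), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "pMax") <- pMax
  attr(edges, "minAbsR") <- minAbsR
  edges
}

#' Build a co-expression network from an edge list
#'
#' @param edges data.frame with columns geneA, geneB, r, p.
#' @param nodes node universe; isolated genes are kept with degree 0.
#' @param groupLabel label of the sample group the edges came from.
#' @return a \linkS4class{CoexpressionNetwork}. Duplicate unordered
#'   pairs with conflicting r are an error; exact duplicates are
#'   collapsed.
#' @export
buildNetwork <- function(edges, nodes, groupLabel = "unknown") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(edges))
    edges <- data.frame(geneA = character(0), geneB = character(0),
                        r = numeric(0), p = numeric(0))
  a <- pmin(edges$geneA, edges$geneB)
  b <- pmax(edges$geneA, edges$geneB)
  edges$geneA <- a; edges$geneB <- b
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    sameR <- tapply(edges$r, key, function(v) diff(range(v)) < 1e-12)
    if (!all(sameR))
      stop("duplicate edge(s) with conflicting r: ",
           paste(head(gsub("\r", "-", names(sameR)[!sameR]), 3),
                 collapse = ", "))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(edges) <- NULL
  new("CoexpressionNetwork", nodes = as.character(nodes),
      edges = edges[, c("geneA", "geneB", "r", "p")],
      groupLabel = groupLabel)
}

#' Whole-network connectivity (degree centrality)
#'
#' k(i) = number of edges incident to gene i, the connectivity measure
#' used to compare networks.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @return named integer vector over all nodes (isolated nodes have 0).
#' @export
connectivity <- function(net) {
  stopifnot(is(net, "CoexpressionNetwork"))
  k <- setNames(integer(length(net@nodes)), net@nodes)
  e <- net@edges
  if (nrow(e)) {
    t1 <- table(e$geneA); t2 <- table(e$geneB)
    k[names(t1)] <- k[names(t1)] + as.integer(t1)
    k[names(t2)] <- k[names(t2)] + as.integer(t2)
  }
  k
}

.degreeOn <- function(nodes, edges) {
  k <- setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    t1 <- table(edges$geneA); t2 <- table(edges$geneB)
    k[names(t1)] <- k[names(t1)] + as.integer(t1)
    k[names(t2)] <- k[names(t2)] + as.integer(t2)
  }
  k
}

#' k-core decomposition
#'
#' Iterative pruning: for increasing k, nodes of degree < k are removed
#' (repeatedly, since removals lower the degrees of neighbours) until
#' the remaining subgraph has minimum degree >= k. The core number of a
#' node is the largest k at which it survives; the maximum core is the
#' subgraph of nodes attaining the largest core number, the densest
#' module of the network.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @return list with \code{core} (named integer vector of core numbers)
#'   and \code{maxCore} (a \linkS4class{CoexpressionNetwork} restricted
#'   to the maximum core).
#' @examples
#' edges <- data.frame(geneA = c("a", "b", "a", "c"),
#'                     geneB = c("b", "c", "c", "d"),
#'                     r = 1, p = 0)
#' kcoreDecompose(buildNetwork(edges, letters[1:4]))$core
#' @export
kcoreDecompose <- function(net) {
  stopifnot(is(net, "CoexpressionNetwork"))
  core <- setNames(integer(length(net@nodes)), net@nodes)
  curNodes <- net@nodes
  curEdges <- net@edges
  k <- 1L
  while (length(curNodes)) {
    repeat {
      deg <- .degreeOn(curNodes, curEdges)
      drop <- curNodes[deg < k]
      if (!length(drop)) break
      core[drop] <- k - 1L
      curNodes <- setdiff(curNodes, drop)
      curEdges <- curEdges[curEdges$geneA %in% curNodes &
                             curEdges$geneB %in% curNodes, , drop = FALSE]
    }
    if (length(curNodes)) {
      core[curNodes] <- k  # provisional; raised if they survive k + 1
      k <- k + 1L
    }
  }
  maxK <- if (length(core)) max(core) else 0L
  inMax <- names(core)[core == maxK]
  e <- net@edges
  e <- e[e$geneA %in% inMax & e$geneB %in% inMax, , drop = FALSE]
  list(core = core,
       maxCore = buildNetwork(e, inMax, groupLabel = net@groupLabel))
}

#' Differential connectivity (DiffK) between two networks
#'
#' For each gene i over the union of the two node sets, the degrees
#' k1(i), k2(i) are normalized by the maximum degree of their network,
#' K1(i) = k1(i)/max(k1) and K2(i) = k2(i)/max(k2), and the differential
#' connectivity is DiffK(i) = K1(i) - K2(i), in [-1, 1]. Genes are
#' ranked by descending signed DiffK (the importance ranking: network 1
#' is conventionally the recurrence group, so hubs specific to it rank
#' first); a ranking by |DiffK| is reported alongside. Ties break by
#' descending k1, then gene id.
#'
#' @param net1,net2 \linkS4class{CoexpressionNetwork}s (genes missing
#'   from one network get degree 0 there).
#' @param allowEmpty with the default FALSE, a network whose maximum
#'   degree is 0 cannot be normalized and raises an error; TRUE instead
#'   sets its K to 0 for all genes (used inside permutation nulls).
#' @return data.frame: gene_id, k1, k2, K1, K2, diffK, rank, rankAbs,
#'   ordered by rank.
#' @export
diffK <- function(net1, net2, allowEmpty = FALSE) {
  stopifnot(is(net1, "CoexpressionNetwork"), is(net2, "CoexpressionNetwork"))
  genes <- sort(union(net1@nodes, net2@nodes))
  k1 <- setNames(integer(length(genes)), genes)
  k2 <- k1
  c1 <- connectivity(net1); c2 <- connectivity(net2)
  k1[names(c1)] <- c1
  k2[names(c2)] <- c2
  norm <- function(k, label) {
    mx <- max(k)
    if (mx == 0) {
      if (!allowEmpty)
        stop("network '", label, "' has maximum degree 0; ",
             "connectivity cannot be normalized")
      return(k * 0)
    }
    k / mx
  }
  K1 <- norm(k1, net1@groupLabel)
  K2 <- norm(k2, net2@groupLabel)
  dk <- K1 - K2
  ord <- order(-dk, -k1, genes)
  res <- data.frame(gene_id = genes, k1 = as.integer(k1),
                    k2 = as.integer(k2), K1 = K1, K2 = K2, diffK = dk,
                    stringsAsFactors = FALSE)
  res$rank <- NA_integer_
  res$rank[ord] <- seq_along(ord)
  ordAbs <- order(-abs(dk), -pmax(k1, k2), genes)
  res$rankAbs <- NA_integer_
  res$rankAbs[ordAbs] <- seq_along(ordAbs)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

.diffKOnLabels <- function(mat, labels, groups, pMax, minAbsR) {
  # full per-group pipeline on a plain matrix + label vector
  perGroup <- function(g) {
    sub <- mat[, labels == g, drop = FALSE]
    n <- ncol(sub)
    constant <- apply(sub, 1, function(v) var(v) == 0)
    r <- suppressWarnings(cor(t(sub)))
    r[constant, ] <- NA; r[, constant] <- NA
    rc <- pmin(pmax(r, -1), 1)
    tt <- abs(rc) * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
    p <- 2 * pt(tt, df = n - 2, lower.tail = FALSE)
    p[abs(rc) >= 1] <- 0
    keep <- upper.tri(r) & !is.na(r) & p < pMax & abs(r) >= minAbsR
    idx <- which(keep, arr.ind = TRUE)
    buildNetwork(data.frame(geneA = rownames(r)[idx[, 1]],
                            geneB = colnames(r)[idx[, 2]],
                            r = r[idx], p = p[idx],
                            stringsAsFactors = FALSE),
                 rownames(mat), groupLabel = g)
  }
  diffK(perGroup(groups[1]), perGroup(groups[2]), allowEmpty = TRUE)
}

#' Permutation significance for DiffK
#'
#' The analysis provides no analytic null for DiffK, so one is built by
#' permuting the group labels of the samples and re-running the whole
#' per-group network pipeline (correlations, edge selection, degree
#' normalization) with the same thresholds. The empirical p-value per
#' gene uses the add-one rule
#' p = (1 + #\{perm |diffK*| >= |diffK|\}) / (nPerm + 1), so p is never 0.
#'
#' @param x a \linkS4class{RecurrenceExperiment}.
#' @param genes optional gene subset.
#' @param groups the two groups compared.
#' @param nPerm number of permutations (>= 100 recommended; fewer give a
#'   coarse p granularity and trigger a warning).
#' @param pMax,minAbsR edge criteria, as in
#'   \code{\link{significantPairs}}.
#' @param seed integer seed for the permutation stream.
#' @return data.frame from \code{\link{diffK}} with an extra
#'   \code{permP} column.
#' @export
permutationDiffK <- function(x, genes = NULL,
                             groups = c("recurrence", "nonrecurrence"),
                             nPerm = 100L, pMax = 0.05, minAbsR = 0.7,
                             seed = 1L) {
  stopifnot(is(x, "RecurrenceExperiment"))
  if (nPerm < 100L)
    warning("nPerm < 100 gives empirical p-values with granularity ",
            "coarser than 0.01")
  labels <- as.character(sampleGroups(x))
  keepS <- labels %in% groups
  mat <- exprValues(x)[, keepS, drop = FALSE]
  labels <- labels[keepS]
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  obs <- .diffKOnLabels(mat, labels, groups, pMax, minAbsR)
  obsAbs <- setNames(abs(obs$diffK), obs$gene_id)
  exceed <- setNames(integer(length(obsAbs)), names(obsAbs))
  set.seed(seed)
  for (i in seq_len(nPerm)) {
    permLabels <- sample(labels)
    pd <- .diffKOnLabels(mat, permLabels, groups, pMax, minAbsR)
    permAbs <- setNames(abs(pd$diffK), pd$gene_id)[names(obsAbs)]
    exceed <- exceed + as.integer(permAbs >= obsAbs - 1e-12)
  }
  obs$permP <- (1 + exceed[obs$gene_id]) / (nPerm + 1)
  obs
}
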