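# Independent oracles used to cross-check package computations.
# These deliberately share no code with the implementation.

# Two-sided Fisher exact p by brute-force enumeration of all tables with
# the observed margins, summing the probabilities of tables no more
# likely than the observed one (standard point-probability rule; ties in
# probability are recognized up to a 1e-7 relative tolerance).
oracleFisher2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  logp <- lchoose(c1, xs) + lchoose(N - c1, r1 - xs) - lchoose(N, r1)
  probs <- exp(logp)
  pObs <- probs[xs == a]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Core numbers by independent per-k survival: for each k, prune the full
# graph from scratch; a node's core number is the largest k it survives.
oracleCoreNumbers <- function(nodes, edgeA, edgeB) {
  degOf <- function(nds) {
    keep <- edgeA %in% nds & edgeB %in% nds
    k <- setNames(integer(length(nds)), nds)
    t1 <- table(edgeA[keep]); t2 <- table(edgeB[keep])
    k[names(t1)] <- k[names(t1)] + as.integer(t1)
    k[names(t2)] <- k[names(t2)] + as.integer(t2)
    k
  }
  core <- setNames(integer(length(nodes)), nodes)
  k <- 1L
  repeat {
    surv <- nodes
    repeat {
      d <- degOf(surv)
      bad <- surv[d < k]
      if (!length(bad)) break
      surv <- setdiff(surv, bad)
    }
    if (!length(surv)) break
    core[surv] <- k
    k <- k + 1L
  }
  core
}

# Benjamini-Hochberg step-up written from the definition.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  q
}

# Naive agglomerative clustering: returns the sequence of merges
# (each a sorted pair of cluster member sets) for a distance matrix.
oracleAgglomerate <- function(d, method = c("single", "average")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dd <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      val <- if (method == "single") min(dd) else mean(dd)
      if (val < bestD) { bestD <- val; best <- c(j, i) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  merges
}

# Random simple graph as an edge data.frame on given node names.
randomGraphEdges <- function(nodes, pEdge) {
  n <- length(nodes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < pEdge
  a <- nodes[pairs[keep, 1]]
  data.frame(geneA = a, geneB = nodes[pairs[keep, 2]],
             r = rep(1, length(a)), p = rep(0, length(a)),
             stringsAsFactors = FALSE)
}

# Small helper: a tiny labelled expression object from a plain matrix.
makeExperiment <- function(values, group) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  recurrenceExperiment(values, group)
}

# Members (leaf indices) of the cluster created at a given hclust merge step.
cutreeMembers <- function(h, step) {
  expand <- function(i) {
    if (i < 0) return(-i)
    c(expand(h$merge[i, 1]), expand(h$merge[i, 2]))
  }
  expand(step)
}
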