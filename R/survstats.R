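#' ROC analysis and Youden-optimal cutoff for a marker
#'
#' Builds the empirical ROC curve of a continuous marker against a
#' binary outcome, classifying "high" as value > threshold over every
#' observed threshold. The AUC is computed by the trapezoid rule and the
#' reported cutoff maximizes Youden's J = sensitivity + specificity - 1;
#' ties go to the lowest threshold.
#'
#' @param values per-patient marker levels.
#' @param labels recurrence indicator (logical or 0/1); both classes
#'   must be present.
#' @param markerId optional identifier carried through to the result.
#' @return list of class \code{"CutoffResult"}: markerId, auc, cutoff,
#'   sensitivity, specificity, and the full \code{curve} data.frame
#'   (threshold, sensitivity, specificity, youdenJ).
#' @examples
#' rocCutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
rocCutoff <- function(values, labels, markerId = NA_character_) {
  labels <- as.integer(labels)
  stopifnot(length(values) == length(labels), all(labels %in% 0:1))
  if (!any(labels == 1) || !any(labels == 0))
    stop("both outcome classes must be present")
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  thr <- sort(unique(values))
  sens <- vapply(thr, function(t) mean(pos > t), 1)
  spec <- vapply(thr, function(t) mean(neg <= t), 1)
  # trapezoid AUC over (1 - specificity, sensitivity), closed at (0,0),(1,1);
  # thresholds ascend, so fpr/tpr descend from (1,1) to (0,0)
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
               (tpr[-length(tpr)] + tpr[-1]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # ties -> lowest threshold
  structure(list(markerId = markerId, auc = auc, cutoff = thr[best],
                 sensitivity = sens[best], specificity = spec[best],
                 curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec, youdenJ = j)),
            class = "CutoffResult")
}

#' @export
print.CutoffResult <- function(x, ...) {
  cat(sprintf(
    "ROC cutoff%s: AUC = %.3f, cutoff = %g (sens %.3f, spec %.3f)\n",
    if (is.na(x$markerId)) "" else paste0(" [", x$markerId, "]"),
    x$auc, x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' Dichotomize a marker at a cutoff
#'
#' "High" is defined strictly as value > cutoff (the convention the 2x2
#' counts depend on). When an outcome vector is supplied, the 2x2
#' high/low by outcome table and the percentage of high-expression
#' patients within each outcome class are also returned.
#'
#' @param values marker levels.
#' @param cutoff finite threshold.
#' @param outcome optional outcome labels (factor/character/0-1).
#' @return list of class \code{"DichotomyResult"}: \code{high} (logical
#'   vector), and with an outcome also \code{table} (2x2 counts,
#'   high/low x outcome) and \code{pctHigh} (percent high per outcome
#'   class). Degenerate splits (all high or all low) are flagged via
#'   \code{degenerate}.
#' @export
dichotomize <- function(values, cutoff, outcome = NULL) {
  stopifnot(is.finite(cutoff))
  high <- values > cutoff
  out <- list(high = high, cutoff = cutoff,
              degenerate = all(high) || !any(high))
  if (!is.null(outcome)) {
    stopifnot(length(outcome) == length(values))
    lev <- factor(ifelse(high, "high", "low"), levels = c("high", "low"))
    tab <- table(expression = lev, outcome = outcome)
    out$table <- tab
    out$pctHigh <- 100 * tab["high", ] / colSums(tab)
  }
  structure(out, class = "DichotomyResult")
}

#' Contingency-table tests
#'
#' Pearson chi-square without continuity correction for an r x c table
#' of counts; for 2x2 tables the two-sided Fisher exact p-value
#' (point-probability rule) is reported as well.
#'
#' @param tab matrix of non-negative integer counts, at least 2x2, with
#'   no zero row/column margin.
#' @return list: chi2Stat, df, pChi2, and pFisher (NA unless 2x2).
#' @examples
#' contingencyTest(matrix(c(14, 21, 33, 12), 2))  # chi-square ~ 9.026
#' @export
contingencyTest <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row/column margin")
  cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
  pF <- if (all(dim(tab) == 2L)) min(1, fisher.test(tab)$p.value)
        else NA_real_
  list(chi2Stat = unname(cs$statistic), df = unname(cs$parameter),
       pChi2 = unname(cs$p.value), pFisher = pF)
}

#' Nonparametric group comparison
#'
#' Mann-Whitney U (two groups; exact enumeration when both groups have
#' at most 8 untied observations) or Kruskal-Wallis (three or more
#' groups), for comparing marker levels between outcome groups.
#'
#' @param values numeric observations.
#' @param groups group labels (>= 2 observations per group).
#' @return list: method, statistic, p.
#' @export
groupCompare <- function(values, groups) {
  groups <- factor(groups)
  if (any(table(groups) < 2L)) stop("each group needs >= 2 observations")
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (nlevels(groups) == 2L) {
    v1 <- values[groups == levels(groups)[1]]
    v2 <- values[groups == levels(groups)[2]]
    exact <- length(v1) <= 8 && length(v2) <= 8 &&
      !anyDuplicated(c(v1, v2))
    wt <- suppressWarnings(wilcox.test(v1, v2, exact = exact,
                                       correct = !exact))
    list(method = "mann-whitney", statistic = unname(wt$statistic),
         p = wt$p.value)
  } else {
    kt <- kruskal.test(values, groups)
    list(method = "kruskal-wallis", statistic = unname(kt$statistic),
         p = kt$p.value)
  }
}

#' Kaplan-Meier recurrence-free survival curves
#'
#' Product-limit estimates per group, with at-risk accounting; censored
#' patients leave the risk set after their time.
#'
#' @param time positive follow-up times (months).
#' @param event 1 = event (recurrence), 0 = censored.
#' @param group group labels (a single group is fine).
#' @return list of class \code{"KMResult"}: \code{curves}, a data.frame
#'   (group, time, nRisk, nEvent, nCensor, surv), and \code{fit}, the
#'   underlying \code{\link[survival]{survfit}} object.
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 0, 1), rep("a", 3))
#' @export
kmEstimate <- function(time, event, group = rep("all", length(time))) {
  stopifnot(all(time > 0), all(event %in% 0:1))
  d <- data.frame(time = time, event = event, group = factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(d$group)[1], length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, nRisk = sm$n.risk,
                       nEvent = sm$n.event, nCensor = sm$n.censor,
                       surv = sm$surv, stringsAsFactors = FALSE)
  structure(list(curves = curves, fit = fit), class = "KMResult")
}

#' Log-rank test between survival curves
#'
#' Standard observed-minus-expected log-rank chi-square (1 df for two
#' groups).
#'
#' @inheritParams kmEstimate
#' @return list: statistic, df, p.
#' @export
logrankTest <- function(time, event, group) {
  stopifnot(all(time > 0), all(event %in% 0:1))
  if (sum(event) < 1L) stop("log-rank test needs at least one event")
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  d <- data.frame(time = time, event = event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards model
#'
#' Partial-likelihood fit (Breslow tie handling by default, Efron
#' available) with per-covariate hazard ratios, Wald 95 percent
#' confidence intervals and p-values, mirroring a univariate or
#' multivariate prognostic-factor analysis. Monotone likelihood
#' (perfect separation) is detected and reported through the
#' \code{separation} flag.
#'
#' @param data data.frame containing the time, event, and covariate
#'   columns.
#' @param covariates covariate column names entering the linear
#'   predictor.
#' @param timeCol,eventCol column names for follow-up time and event
#'   indicator.
#' @param ties "breslow" (default) or "efron".
#' @return list of class \code{"CoxResult"}: \code{terms}, a data.frame
#'   (term, coef, HR, ciLow, ciHigh, p), \code{separation},
#'   \code{fit} (the \code{\link[survival]{coxph}} object).
#' @export
coxFit <- function(data, covariates, timeCol = "time_months",
                   eventCol = "event", ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  miss <- setdiff(c(timeCol, eventCol, covariates), colnames(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (sum(data[[eventCol]]) < 1) stop("no events in the data")
  for (cv in covariates)
    if (length(unique(data[[cv]])) < 2L)
      stop("covariate '", cv, "' is constant")
  fml <- stats::as.formula(paste0(
    "survival::Surv(", timeCol, ", ", eventCol, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sf <- summary(fit)
  co <- sf$coefficients
  ci <- sf$conf.int
  separation <- any(grepl("infinite", warn)) || any(abs(co[, "coef"]) > 15)
  if (separation)
    warning("monotone partial likelihood (perfect separation) detected; ",
            "coefficient estimates are unreliable")
  terms <- data.frame(term = rownames(co), coef = co[, "coef"],
                      HR = ci[, "exp(coef)"],
                      ciLow = ci[, "lower .95"], ciHigh = ci[, "upper .95"],
                      p = co[, "Pr(>|z|)"], stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  structure(list(terms = terms, separation = separation, ties = ties,
                 fit = fit), class = "CoxResult")
}

#' @export
print.CoxResult <- function(x, ...) {
  cat("Cox proportional hazards (", x$ties, " ties)\n", sep = "")
  t <- x$terms
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %s: HR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
                t$term[i], t$HR[i], t$ciLow[i], t$ciHigh[i], t$p[i]))
  if (x$separation) cat("  WARNING: perfect separation detected\n")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with tie handling and the t-approximation p-value.
#'
#' @param x,y paired observations (n >= 3); constant vectors are an
#'   error.
#' @return list: rho, p, n.
#' @export
spearmanCorr <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (var(x) == 0 || var(y) == 0)
    stop("rank correlation is undefined for a constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Immunohistochemistry quantification indices
#'
#' Pure arithmetic of the slide-quantification conventions: the mean
#' integral optical density AIOD = positive area x OD / total area, and
#' the labeling index LI = 1000 x positive cells / cells counted
#' (positives per 1000 hepatocytes).
#'
#' @param positiveArea,totalArea stained and total areas (same units),
#'   positiveArea <= totalArea.
#' @param od optical density (dimensionless).
#' @param positiveCells,cellsCounted cell counts.
#' @return list of class \code{"IHCQuantRecord"} with all inputs plus
#'   \code{aiod} and \code{li}.
#' @examples
#' ihcIndices(50, 100, 0.8, 250, 1000)  # aiod 0.4, li 250
#' @export
ihcIndices <- function(positiveArea, totalArea, od,
                       positiveCells = NA_real_, cellsCounted = NA_real_) {
  if (totalArea <= 0) stop("totalArea must be positive")
  if (positiveArea < 0 || positiveArea > totalArea)
    stop("positiveArea must lie in [0, totalArea]")
  li <- if (is.na(positiveCells) || is.na(cellsCounted)) NA_real_ else {
    if (cellsCounted <= 0) stop("cellsCounted must be positive")
    if (positiveCells < 0 || positiveCells > cellsCounted)
      stop("positiveCells must lie in [0, cellsCounted]")
    1000 * positiveCells / cellsCounted
  }
  structure(list(positiveArea = positiveArea, totalArea = totalArea,
                 od = od, positiveCells = positiveCells,
                 cellsCounted = cellsCounted,
                 aiod = positiveArea * od / totalArea, li = li),
            class = "IHCQuantRecord")
}
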