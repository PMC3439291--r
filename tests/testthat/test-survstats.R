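test_that("ROC analysis finds separating cutoffs and calibrated AUC", {
  # perfect separation
  r <- rocCutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_gte(r$cutoff, 2); expect_lt(r$cutoff, 3)
  # labels independent of values: AUC near 1/2
  set.seed(14)
  r0 <- rocCutoff(rnorm(200), rbinom(200, 1, 0.5))
  expect_lt(abs(r0$auc - 0.5), 0.1)
  expect_error(rocCutoff(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("AUC equals the Mann-Whitney identity on tie-free data", {
  set.seed(15)
  for (i in 1:10) {
    v <- rnorm(40)
    lab <- rbinom(40, 1, 0.5)
    if (!any(lab == 1) || !any(lab == 0)) next
    u <- sum(outer(v[lab == 1], v[lab == 0], ">"))
    expect_equal(rocCutoff(v, lab)$auc,
                 u / (sum(lab == 1) * sum(lab == 0)))
  }
})

test_that("dichotomization reproduces the published marker percentages", {
  # reconstruct the printed 2x2 marker tables as raw values + cutoff 0:
  # cyclin B1: 28/35 recurrence high, 15/45 non-recurrence high
  markerTable <- function(highRec, nRec, highNon, nNon) {
    values <- c(rep(1, highRec), rep(-1, nRec - highRec),
                rep(1, highNon), rep(-1, nNon - highNon))
    outcome <- c(rep("recurrence", nRec), rep("nonrecurrence", nNon))
    dichotomize(values, 0, outcome)
  }
  cyc <- markerTable(28, 35, 15, 45)
  expect_equal(unname(cyc$pctHigh["recurrence"]), 80)
  sec <- markerTable(23, 35, 8, 45)
  expect_equal(round(unname(sec$pctHigh["recurrence"]), 1), 65.7)
  bir <- markerTable(19, 35, 11, 45)
  expect_equal(unname(bir$pctHigh["recurrence"]), 100 * 19 / 35)
  # degenerate splits are flagged; cutoff -Inf is rejected as non-finite
  d <- dichotomize(c(1, 2, 3), 10)
  expect_true(d$degenerate)
  expect_true(all(dichotomize(c(1, 2, 3), -1e9)$high))
  expect_error(dichotomize(1:3, -Inf), "is.finite")
})

test_that("contingency tests match the closed form and the oracle", {
  ct <- contingencyTest(matrix(c(14, 21, 33, 12), 2))
  expect_equal(ct$chi2Stat, 9.026, tolerance = 1e-3)
  # proportional rows carry no association
  ct0 <- contingencyTest(matrix(c(10, 5, 20, 10), 2))
  expect_equal(ct0$chi2Stat, 0)
  expect_equal(ct0$pChi2, 1)
  expect_equal(ct0$pFisher, 1)
  # Fisher equals exhaustive hypergeometric enumeration, all totals <= 40
  set.seed(16)
  for (i in 1:150) {
    N <- sample(4:40, 1)
    a <- sample(0:N, 1); b <- sample(0:(N - a), 1)
    c <- sample(0:(N - a - b), 1); d <- N - a - b - c
    tab <- matrix(c(a, c, b, d), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(contingencyTest(tab)$pFisher, oracleFisher2x2(a, b, c, d),
                 tolerance = 1e-12)
  }
  expect_error(contingencyTest(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(contingencyTest(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("rank-based group comparisons cover exact and tied cases", {
  # (1,2,3) vs (10,11,12): U = 0, exact two-sided p = 2/20
  gc <- groupCompare(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(gc$method, "mann-whitney")
  expect_equal(gc$p, 0.1)
  # identical distributions: p in the null region
  gc0 <- groupCompare(c(5, 6, 7, 5, 6, 7), rep(c("a", "b"), each = 3))
  expect_gt(gc0$p, 0.99)
  # three identical groups: Kruskal-Wallis statistic ~ 0
  gk <- groupCompare(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(gk$method, "kruskal-wallis")
  expect_lt(gk$statistic, 1e-10)
  expect_error(groupCompare(1:3, c("a", "a", "b")), ">= 2 observations")
})

test_that("Kaplan-Meier estimates match hand product-limit values", {
  km <- kmEstimate(c(1, 2), c(1, 1))
  expect_equal(km$curves$surv, c(0.5, 0))
  km2 <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  s <- setNames(km2$curves$surv, km2$curves$time)
  expect_equal(unname(s["1"]), 2 / 3)
  expect_equal(unname(s["3"]), 0)  # 2/3 * (1 - 1/1)
  # all censored: survival stays at 1
  km3 <- kmEstimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km3$curves$surv == 1))
  # curves are non-increasing step functions starting at 1
  set.seed(17)
  km4 <- kmEstimate(rexp(50, 0.1), rbinom(50, 1, 0.7),
                    rep(c("x", "y"), 25))
  for (g in c("x", "y")) {
    sg <- km4$curves$surv[km4$curves$group == g]
    expect_true(all(diff(sg) <= 1e-12))
    expect_lte(sg[1], 1)
  }
  # with no censoring KM equals the empirical survival function
  tt <- c(2, 4, 4, 7, 9)
  km5 <- kmEstimate(tt, rep(1, 5))
  emp <- vapply(km5$curves$time, function(t0) mean(tt > t0), 1)
  expect_equal(km5$curves$surv, emp)
})

test_that("log-rank test honours its symmetries and detects effects", {
  tm <- c(1, 3, 5, 7, 2, 4, 6, 8); ev <- rep(1, 8)
  g <- rep(c("a", "b"), each = 4)
  # identical groups built from the same data: statistic 0
  lr0 <- logrankTest(rep(tm[1:4], 2), rep(1, 8), g)
  expect_lt(lr0$statistic, 1e-10)
  expect_gt(lr0$p, 0.999)
  # invariance under label swap
  lr1 <- logrankTest(tm, ev, g)
  lr2 <- logrankTest(tm, ev, rev(g))
  expect_equal(lr1$statistic, lr2$statistic)
  expect_error(logrankTest(tm, rep(0, 8), g), "at least one event")
  # strong planted hazard ratio: highly significant in most replicates
  set.seed(18)
  hits <- vapply(1:40, function(i) {
    grp <- rep(0:1, each = 100)
    t0 <- rexp(200, rate = 0.05 * 5^grp)
    ev0 <- as.integer(t0 < 60); t0 <- pmin(t0, 60)
    logrankTest(t0, ev0, grp)$p < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("log-rank equals the Cox score test for a binary covariate", {
  set.seed(19)
  d <- data.frame(time_months = rexp(80, 0.1),
                  event = rbinom(80, 1, 0.8),
                  grp = rep(c(0, 1), 40))
  lr <- logrankTest(d$time_months, d$event, d$grp)
  sc <- survival::coxph(survival::Surv(time_months, event) ~ grp,
                        data = d)$score
  expect_equal(lr$statistic, unname(sc), tolerance = 1e-6)
})

test_that("Cox fit recovers planted effects and flags separation", {
  set.seed(20)
  n <- 500
  xv <- rnorm(n)
  t0 <- rexp(n, rate = 0.05 * exp(log(3) * xv))
  d <- data.frame(time_months = pmin(t0, 60),
                  event = as.integer(t0 < 60), x = xv)
  fit <- coxFit(d, "x")
  expect_lt(abs(fit$terms$HR[1] - 3) / 3, 0.15)
  expect_true(fit$terms$ciLow[1] < 3 && fit$terms$ciHigh[1] > 1)
  expect_false(fit$separation)
  # two subjects, perfectly separated covariate: diagnostic fires
  d2 <- data.frame(time_months = c(1, 2), event = c(1, 1), x = c(1, 0))
  expect_warning(fit2 <- coxFit(d2, "x"), "separation")
  expect_true(fit2$separation)
  expect_error(coxFit(data.frame(time_months = 1:3, event = c(1, 0, 1),
                                 x = rep(1, 3)), "x"), "constant")
  expect_error(coxFit(data.frame(time_months = 1:3, event = rep(0, 3),
                                 x = 1:3), "x"), "no events")
})

test_that("Cox confidence intervals attain near-nominal coverage", {
  set.seed(24)
  hits <- vapply(1:300, function(i) {
    n <- 200
    xv <- rnorm(n)
    t0 <- rexp(n, rate = 0.05 * exp(log(2) * xv))
    d <- data.frame(time_months = pmin(t0, 60),
                    event = as.integer(t0 < 60), x = xv)
    ft <- coxFit(d, "x")$terms
    ft$ciLow[1] <= 2 && 2 <= ft$ciHigh[1]
  }, TRUE)
  expect_gt(mean(hits), 0.91)
  expect_lt(mean(hits), 0.99)
})

test_that("Spearman correlation handles monotone and null inputs", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearmanCorr(x, x)$rho, 1)
  expect_equal(spearmanCorr(x, -x)$rho, -1)
  expect_error(spearmanCorr(x, rep(1, 6)), "constant")
  expect_error(spearmanCorr(1:2, 1:2), "at least 3")
  set.seed(25)
  far <- vapply(1:200, function(i)
    abs(spearmanCorr(rnorm(100), rnorm(100))$rho) >= 0.3, TRUE)
  expect_lte(mean(far), 0.01)
})

test_that("IHC indices follow their defining formulas", {
  r <- ihcIndices(50, 100, 0.8, 250, 1000)
  expect_equal(r$aiod, 0.4)
  expect_equal(r$li, 250)
  expect_equal(ihcIndices(0, 100, 0.8)$aiod, 0)
  expect_error(ihcIndices(120, 100, 0.8), "positiveArea")
  expect_error(ihcIndices(10, 0, 0.8), "totalArea")
})
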