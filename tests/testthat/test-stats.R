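test_that("percent change uses the absolute-baseline denominator", {
  expect_equal(percentChange(10, 5), -50)
  expect_equal(percentChange(-2, -3), -50)  # decrease of a negative value
  expect_true(is.na(percentChange(0, 5)))
  expect_equal(percentChange(c(10, -2, 0), c(5, -3, 5)),
               c(-50, -50, NA))
})

test_that("pathologic response labels follow the necrosis thresholds", {
  lab <- classifyPathologicResponse(c(0, 0.50, 0.51, 0.90, 0.905, 0.95, 1))
  expect_equal(as.character(lab),
               c("nonresponder", "nonresponder", "responder", "responder",
                 "near_complete_responder", "near_complete_responder",
                 "near_complete_responder"))
  expect_equal(isResponder(lab),
               c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_error(classifyPathologicResponse(1.2), "\\[0, 1\\]")
  expect_error(classifyPathologicResponse(-0.1), "\\[0, 1\\]")
})

test_that("Mann-Whitney exact path matches enumeration and wilcox.test", {
  # canonical worked case: fully separated triples
  r <- mannWhitneyTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")

  # identical groups -> p = 1
  expect_equal(mannWhitneyTest(c(3, 3, 3), c(3, 3, 3))$p, 1)

  # random tie-free cases agree with the enumeration oracle and wilcox.test
  set.seed(21)
  for (i in 1:15) {
    m <- sample(2:7, 1); n <- sample(2:7, 1)
    x <- sample(seq(1, 100), m); y <- sample(seq(101, 200), n)[sample(n)]
    pool <- sample(c(x, y)); x <- pool[1:m]; y <- pool[-(1:m)]
    r <- mannWhitneyTest(x, y)
    expect_equal(r$method, "exact")
    expect_equal(r$p, mwEnumOracle(x, y))
    expect_equal(r$p, stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }

  # tied cases agree with the enumeration oracle
  for (i in 1:10) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    x <- sample(1:4, m, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    r <- mannWhitneyTest(x, y)
    expect_equal(r$method, "exact-enumeration")
    expect_equal(r$p, mwEnumOracle(x, y))
  }
})

test_that("Mann-Whitney large-sample path is a calibrated approximation", {
  set.seed(31)
  # above the switch the normal approximation is used
  x <- rnorm(20); y <- rnorm(25)
  expect_equal(mannWhitneyTest(x, y)$method, "normal-approximation")
  # approximate p tracks wilcox.test's corrected normal p
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(mannWhitneyTest(x, y)$p, ref, tolerance = 1e-10)
  # null p-values are roughly uniform: mean near 0.5
  ps <- replicate(200, mannWhitneyTest(rnorm(15), rnorm(18))$p)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("compareGroupsContinuous splits by a two-level factor", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- c("a", "a", "a", "b", "b", "b")
  expect_equal(compareGroupsContinuous(v, g)$p, 0.1)
  expect_error(compareGroupsContinuous(v, rep("a", 6)), "two")
})

test_that("Fisher exact test matches hypergeometric enumeration", {
  expect_equal(compareGroupsCategorical(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  # proportional rows -> independence exactly
  expect_equal(compareGroupsCategorical(matrix(c(4, 2, 6, 3), 2)), 1)
  set.seed(41)
  for (i in 1:25) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(compareGroupsCategorical(tab), fisherEnumOracle(tab),
                 tolerance = 1e-12)
  }
  expect_error(compareGroupsCategorical(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_error(compareGroupsCategorical(matrix(c(1.5, 1, 1, 1), 2)),
               "integer")
})

test_that("univariate screen keeps variables below the threshold", {
  set.seed(51)
  resp <- rep(c(TRUE, FALSE), each = 8)
  pct <- data.frame(
    separating = ifelse(resp, rnorm(16, -50, 5), rnorm(16, 20, 5)),
    flat = rep(1, 16),          # constant: ties everywhere, p = 1
    noise = rnorm(16)
  )
  scr <- univariateScreen(pct, resp)
  expect_true("separating" %in% scr$screened)
  expect_false("flat" %in% scr$screened)
  expect_equal(scr$p[["flat"]], 1)
  # threshold is a strict inequality on p
  pNoise <- scr$p[["noise"]]
  expect_true("noise" %in%
                univariateScreen(pct, resp, threshold = pNoise + 1e-9)$screened)
  expect_false("noise" %in%
                 univariateScreen(pct, resp, threshold = pNoise)$screened)
  expect_error(univariateScreen(pct, c(TRUE, rep(FALSE, 15))), ">= 2")
})

test_that("backward elimination removes noise and keeps signal", {
  set.seed(61)
  n <- 80
  x1 <- rnorm(n, 0, 15)  # informative, per-unit log-OR 0.12
  x2 <- rnorm(n, 0, 15)  # pure noise
  y <- runif(n) < plogis(0.12 * x1)
  df <- data.frame(y = y, x1 = x1, x2 = x2, x3 = rep(2, n))
  res <- fitLogisticBackward(df, "y", c("x1", "x2", "x3"))
  expect_true("x1" %in% res$retained)
  expect_true("x3" %in% res$removed)       # constant: zero LR contribution
  expect_false(res$separation)
  m <- res$model[res$model$variable == "x1", ]
  expect_gt(m$or, 1)                       # sign consistency
  expect_true(m$ci_lo <= m$or && m$or <= m$ci_hi)
  expect_error(fitLogisticBackward(df, "y", character(0)), "empty")
  df2 <- df; df2$y <- TRUE
  expect_error(fitLogisticBackward(df2, "y", "x1"), "both classes")
})

test_that("complete separation is flagged, not hidden", {
  df <- data.frame(y = rep(c(FALSE, TRUE), each = 10),
                   x = c(rnorm(10, -10), rnorm(10, 10)))
  res <- fitLogisticBackward(df, "y", "x")
  expect_true(res$separation)
  expect_true("x" %in% res$retained)
})

test_that("elimination respects the LR threshold and ignores input order", {
  set.seed(71)
  for (i in 1:10) {
    n <- 40
    df <- data.frame(y = rep(c(TRUE, FALSE), each = n / 2),
                     a = rnorm(n), b = rnorm(n), c = rnorm(n))
    df$a <- df$a + ifelse(df$y, 1.2, 0)
    r1 <- fitLogisticBackward(df, "y", c("a", "b", "c"))
    r2 <- fitLogisticBackward(df, "y", c("c", "b", "a"))
    expect_identical(r1$retained, r2$retained)
    expect_identical(r1$model, r2$model)
    # every removed variable had deletion-LR p >= 0.10 at its removal step,
    # re-derived here with independent glm fits
    vars <- sort(c("a", "b", "c"))
    for (v in r1$removed) {
      fullF <- as.formula(paste("y ~", paste(vars, collapse = "+")))
      red <- setdiff(vars, v)
      redF <- if (length(red)) as.formula(paste("y ~", paste(red, collapse = "+")))
              else y ~ 1
      dd <- glm(redF, df, family = binomial())$deviance -
        glm(fullF, df, family = binomial())$deviance
      expect_gte(pchisq(max(0, dd), 1, lower.tail = FALSE), 0.10)
      vars <- red
    }
    # and every retained variable's deletion p is < 0.10
    for (v in r1$retained) {
      vars <- r1$retained
      fullF <- as.formula(paste("y ~", paste(vars, collapse = "+")))
      red <- setdiff(vars, v)
      redF <- if (length(red)) as.formula(paste("y ~", paste(red, collapse = "+")))
              else y ~ 1
      dd <- glm(redF, df, family = binomial())$deviance -
        glm(fullF, df, family = binomial())$deviance
      expect_lt(pchisq(max(0, dd), 1, lower.tail = FALSE), 0.10)
    }
  }
})

test_that("ROC analysis reproduces known AUCs and Youden cutoffs", {
  # perfect separation, lower score = response
  r <- rocAnalysis(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                   direction = "lower")
  expect_equal(r$auc, 1.0)
  expect_gt(r$cutoff, 2); expect_lt(r$cutoff, 3)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_match(r$rule, "less than")

  # all scores tied across classes: every pair contributes 0.5
  r2 <- rocAnalysis(rep(5, 8), rep(c(TRUE, FALSE), 4), direction = "lower")
  expect_equal(r2$auc, 0.5)

  # permuted labels, large n: AUC near 0.5
  set.seed(81)
  r3 <- rocAnalysis(rnorm(600), sample(rep(c(TRUE, FALSE), 300)),
                    direction = "lower")
  expect_lt(abs(r3$auc - 0.5), 0.07)

  # brute-force concordance oracle, both directions, with ties
  for (i in 1:20) {
    sc <- sample(1:6, 25, replace = TRUE)
    lab <- sample(c(TRUE, FALSE), 25, replace = TRUE)
    if (!any(lab) || all(lab)) next
    dir <- sample(c("lower", "higher"), 1)
    expect_equal(rocAnalysis(sc, lab, dir)$auc,
                 aucBruteOracle(sc, lab, dir))
  }
  expect_error(rocAnalysis(1:5, rep(TRUE, 5)), "both classes")
})

test_that("ROC cross-checks against pROC on a nontrivial instance", {
  skip_if_not_installed("pROC")
  set.seed(91)
  sc <- c(rnorm(30, 1), rnorm(40, 0))
  lab <- rep(c(TRUE, FALSE), c(30, 40))
  mine <- rocAnalysis(sc, lab, direction = "higher")
  ref <- pROC::roc(response = lab, predictor = sc, direction = "<",
                   quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
  best <- pROC::coords(ref, "best", best.method = "youden",
                       transpose = FALSE)
  expect_equal(mine$cutoff, best$threshold)
})
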