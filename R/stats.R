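#' Percent change of a feature between paired scans
#'
#' 100 * (post - pre) / |pre|. The denominator is the absolute baseline so
#' that a decrease is reported as negative even when the baseline is
#' negative — the natural sign language for skewness, whose baselines are
#' typically negative in solid tumors. A zero baseline leaves the change
#' undefined (`NA`). Vectorized.
#'
#' @param pre,post baseline and follow-up values.
#' @return Percent change (%); `NA` where `pre == 0`.
#' @examples
#' percentChange(10, 5)    # -50
#' percentChange(-2, -3)   # -50: a decrease of a negative quantity
#' @export
percentChange <- function(pre, post) {
  out <- 100 * (post - pre) / abs(pre)
  out[pre == 0] <- NA_real_
  out
}

#' Classify pathologic response from necrosis fraction
#'
#' Tumor regression in the resected specimen is scored from the necrosis
#' proportion: 0-50% necrosis is no response; more than 50% is a pathologic
#' response; more than 90% a near-complete pathologic response.
#' Near-complete responders are a subset of responders in all two-group
#' analyses ([isResponder()]).
#'
#' @param necrosisFraction proportion(s) in `[0, 1]`.
#' @return Factor with levels `nonresponder`, `responder`,
#'   `near_complete_responder`.
#' @examples
#' classifyPathologicResponse(c(0.50, 0.51, 0.95))
#' @export
classifyPathologicResponse <- function(necrosisFraction) {
  f <- as.double(necrosisFraction)
  if (any(!is.finite(f)) || any(f < 0 | f > 1))
    stop("necrosis fraction must lie in [0, 1]")
  lab <- ifelse(f > 0.90, "near_complete_responder",
                ifelse(f > 0.50, "responder", "nonresponder"))
  factor(lab, levels = c("nonresponder", "responder",
                         "near_complete_responder"))
}

#' Collapse response labels to the two-group responder indicator
#'
#' @param label output of [classifyPathologicResponse()].
#' @return Logical: TRUE for responders (including near-complete).
#' @export
isResponder <- function(label) {
  label %in% c("responder", "near_complete_responder")
}

#' Mann-Whitney U test (exact or tie-corrected normal approximation)
#'
#' Two-sided Mann-Whitney test of two independent groups. When both groups
#' have at most `exactMax` observations the exact null distribution is used:
#' the closed-form count distribution of U when there are no ties, or full
#' enumeration of all group assignments when ties are present (skipped, with
#' the approximate path taken, if the enumeration exceeds ~3e6 tables). The
#' two-sided p is the null probability of a U at least as far from mn/2 as
#' observed. Otherwise a normal approximation with tie correction and
#' continuity correction is used. The statistic and which path was used are
#' returned.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param exactMax exact-path group-size switch (default 12).
#' @return list: `p`, `U` (statistic for `x`), `method` ("exact",
#'   "exact-enumeration" or "normal-approximation").
#' @export
mannWhitneyTest <- function(x, y, exactMax = 12L) {
  x <- as.double(x); y <- as.double(y)
  m <- length(x); n <- length(y)
  if (m < 1L || n < 1L) stop("both groups must be non-empty")
  N <- m + n
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (m <= exactMax && n <= exactMax) {
    if (!ties) {
      # exact count distribution of U
      uLo <- min(U, m * n - U)
      p <- 2 * sum(dwilcox(0:uLo, m, n))
      return(list(p = min(1, p), U = U, method = "exact"))
    }
    if (choose(N, m) <= 3e6) {
      # permutation null over the observed (tied) ranks
      dev <- abs(2 * U - m * n)
      idx <- combn(N, m)
      u2 <- 2 * (colSums(matrix(r[idx], nrow = m)) - m * (m + 1) / 2) - m * n
      p <- mean(abs(u2) >= dev - 1e-9)
      return(list(p = p, U = U, method = "exact-enumeration"))
    }
  }
  # normal approximation with tie correction and continuity correction
  tt <- table(c(x, y))
  tieAdj <- sum(tt^3 - tt) / (N * (N - 1))
  sigma2 <- m * n / 12 * ((N + 1) - tieAdj)
  dev <- abs(U - m * n / 2)
  z <- max(0, dev - 0.5) / sqrt(sigma2)
  list(p = min(1, 2 * pnorm(-z)), U = U, method = "normal-approximation")
}

#' Compare a continuous variable between two groups
#'
#' Spec'd comparison for continuous per-patient quantities (e.g. percent
#' changes by responder status): two-sided Mann-Whitney via
#' [mannWhitneyTest()].
#'
#' @param values numeric vector.
#' @param groups logical or two-level factor splitting `values`.
#' @param exactMax exact-path switch (default 12).
#' @return list as in [mannWhitneyTest()].
#' @export
compareGroupsContinuous <- function(values, groups, exactMax = 12L) {
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2L)
    stop("groups must split values into exactly two non-empty groups")
  g <- droplevels(g)
  mannWhitneyTest(values[g == levels(g)[1]], values[g == levels(g)[2]],
                  exactMax = exactMax)
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided Fisher exact p: the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that
#' of the observed table (as computed by `stats::fisher.test`).
#'
#' @param counts 2x2 matrix of nonnegative integer counts; every margin
#'   must be positive.
#' @return The two-sided p-value.
#' @examples
#' compareGroupsCategorical(matrix(c(2, 0, 0, 2), 2))  # 1/3
#' @export
compareGroupsCategorical <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L)) stop("counts must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("every margin must be positive")
  fisher.test(counts)$p.value
}

#' Univariate screen of percent-change variables
#'
#' Computes the Mann-Whitney p between responders and nonresponders for each
#' variable and keeps those with p below the screening threshold (default
#' 0.50) as candidates for the multivariable logistic model. Requires at
#' least two patients per class. Patients with an undefined (NA) value are
#' dropped variable-wise; a variable left with an empty class is excluded
#' with p = NA.
#'
#' @param pct data.frame of percent-change variables (rows = patients).
#' @param responder logical vector, TRUE for responders.
#' @param threshold screening threshold on p (default 0.50).
#' @param exactMax exact Mann-Whitney switch (default 12).
#' @return list: `p` (named vector), `screened` (character vector of
#'   variables with p < threshold).
#' @export
univariateScreen <- function(pct, responder, threshold = 0.50,
                             exactMax = 12L) {
  responder <- as.logical(responder)
  if (sum(responder) < 2L || sum(!responder) < 2L)
    stop("need >= 2 responders and >= 2 nonresponders")
  p <- vapply(names(pct), function(v) {
    x <- pct[[v]]
    ok <- !is.na(x)
    if (sum(ok & responder) < 1L || sum(ok & !responder) < 1L)
      return(NA_real_)
    mannWhitneyTest(x[ok & responder], x[ok & !responder],
                    exactMax = exactMax)$p
  }, numeric(1))
  list(p = p, screened = names(p)[!is.na(p) & p < threshold])
}

# deviance-based LR p for deleting `v` from the model on `vars`
.deletionP <- function(df, yvar, vars, v) {
  fullF <- as.formula(paste(yvar, "~", paste(vars, collapse = " + ")))
  redVars <- setdiff(vars, v)
  redF <- if (length(redVars) == 0) as.formula(paste(yvar, "~ 1")) else
    as.formula(paste(yvar, "~", paste(redVars, collapse = " + ")))
  full <- suppressWarnings(glm(fullF, data = df, family = binomial()))
  red <- suppressWarnings(glm(redF, data = df, family = binomial()))
  stat <- max(0, red$deviance - full$deviance)
  dfree <- max(1L, full$rank - red$rank)
  if (full$rank == red$rank) return(1)  # aliased/constant: no LR contribution
  stats::pchisq(stat, df = dfree, lower.tail = FALSE)
}

#' Backward-stepwise logistic regression with likelihood-ratio removal
#'
#' Fits a binary logistic regression of responder status on the screened
#' percent-change variables, all entered simultaneously, then iteratively
#' removes the variable whose deletion likelihood-ratio p is largest and at
#' least `removal` (default 0.10) until every remaining variable's deletion
#' p falls below the threshold. Reports, per retained variable, the odds
#' ratio per unit percent change with Wald 95% CI and Wald p. Complete or
#' quasi-complete separation is detected (fitted probabilities numerically 0
#' or 1) and flagged; estimates are still reported but marked unreliable.
#' Ties in deletion p are broken alphabetically so the result never depends
#' on input order.
#'
#' @param df data.frame holding the outcome and covariates.
#' @param yvar name of the logical/0-1 outcome column (TRUE = responder).
#' @param variables candidate covariate names (non-empty).
#' @param removal LR removal probability threshold (default 0.10).
#' @return list: `model` (data.frame variable/or/ci_lo/ci_hi/p, zero rows if
#'   everything was removed), `retained`, `removed` (in removal order),
#'   `separation` (logical), `fit` (the final `glm`, or NULL if empty).
#' @export
fitLogisticBackward <- function(df, yvar, variables, removal = 0.10) {
  if (length(variables) == 0L) stop("empty candidate variable set")
  y <- df[[yvar]]
  if (length(unique(y[!is.na(y)])) != 2L)
    stop("outcome must contain both classes")
  keep <- complete.cases(df[, c(yvar, variables), drop = FALSE])
  df <- df[keep, , drop = FALSE]
  vars <- sort(variables)
  removed <- character(0)
  repeat {
    if (length(vars) == 0L) break
    pDel <- vapply(vars, function(v) .deletionP(df, yvar, vars, v),
                   numeric(1))
    worst <- vars[which.max(pDel)]  # ties: first in alphabetical order
    if (pDel[[worst]] >= removal) {
      vars <- setdiff(vars, worst)
      removed <- c(removed, worst)
    } else break
  }
  separation <- FALSE
  if (length(vars) == 0L) {
    return(list(model = data.frame(variable = character(0), or = numeric(0),
                                   ci_lo = numeric(0), ci_hi = numeric(0),
                                   p = numeric(0)),
                retained = character(0), removed = removed,
                separation = FALSE, fit = NULL))
  }
  f <- as.formula(paste(yvar, "~", paste(vars, collapse = " + ")))
  fit <- withCallingHandlers(
    glm(f, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- fit$fitted.values
  if (any(mu < 1e-8 | mu > 1 - 1e-8)) separation <- TRUE
  cf <- coef(fit)[vars]
  se <- sqrt(diag(vcov(fit)))[vars]
  z <- cf / se
  model <- data.frame(variable = vars, or = exp(cf),
                      ci_lo = exp(cf - 1.959964 * se),
                      ci_hi = exp(cf + 1.959964 * se),
                      p = 2 * pnorm(-abs(z)), row.names = NULL)
  list(model = model, retained = vars, removed = removed,
       separation = separation, fit = fit)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Empirical ROC of a continuous score against responder status. The AUC is
#' the pairwise concordance probability with ties counted one half. The
#' operating cutoff maximizes Youden's J = sensitivity + specificity - 1
#' over midpoints between adjacent observed scores; ties in J are broken
#' toward higher sensitivity. With `direction = "lower"` the rule is
#' "score < cutoff predicts response" (the natural direction for features
#' that decrease under response); `"auto"` picks the direction giving
#' AUC >= 0.5 from the group medians.
#'
#' @param scores numeric score per patient (e.g. a percent change or a model
#'   linear predictor).
#' @param responder logical, TRUE = responder; both classes required.
#' @param direction "auto" (default), "lower" or "higher".
#' @return list: `auc`, `cutoff`, `direction`, `sensitivity` and
#'   `specificity` (both %), `J`, and `rule` (human-readable cutoff rule).
#' @export
rocAnalysis <- function(scores, responder, direction = c("auto", "lower",
                                                         "higher")) {
  direction <- match.arg(direction)
  responder <- as.logical(responder)
  ok <- !is.na(scores) & !is.na(responder)
  scores <- scores[ok]; responder <- responder[ok]
  nr <- sum(responder); nn <- sum(!responder)
  if (nr == 0L || nn == 0L) stop("both classes must be present")
  if (direction == "auto") {
    direction <- if (median(scores[responder]) <= median(scores[!responder]))
      "lower" else "higher"
  }
  s <- if (direction == "lower") -scores else scores
  # AUC: P(score_responder "more response-like" than score_nonresponder)
  r <- rank(s)
  auc <- (sum(r[responder]) - nr * (nr + 1) / 2) / (nr * nn)
  # candidate cutoffs: midpoints between adjacent unique raw scores + ends
  u <- sort(unique(scores))
  cand <- if (length(u) == 1L) u else
    c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  best <- NULL
  for (cc in cand) {
    pred <- if (direction == "lower") scores < cc else scores > cc
    sens <- sum(pred & responder) / nr
    spec <- sum(!pred & !responder) / nn
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 && sens > best$sens + 1e-12)) {
      best <- list(J = J, sens = sens, spec = spec, cutoff = cc)
    }
  }
  list(auc = auc, cutoff = best$cutoff, direction = direction,
       sensitivity = 100 * best$sens, specificity = 100 * best$spec,
       J = best$J,
       rule = sprintf("%s %.4g predicts response",
                      if (direction == "lower") "less than" else
                        "greater than", best$cutoff))
}
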