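#' Fold modulation by touch
#'
#' `exp(beta_touch)` of a touch-only fit: the multiplicative fold change of
#' the firing rate during touch relative to baseline (a coefficient of 1 is
#' an e-fold increase; `log2` of the ratio of -1 is a twofold decrease).
#'
#' @param fit a touch-only [GLMFit-class] (or a bare `beta_touch` value).
#' @return fold ratio (> 0).
#' @export
touchModulation <- function(fit) {
  if (is(fit, "GLMFit")) {
    stopifnot(fit@variant == "touch_only")
    fit <- coef(fit)[["touch"]]
  }
  exp(fit)
}

#' Fold modulation during female- and male-partner touch
#'
#' From a touch+sex fit: `female = exp(beta_touch)` and
#' `male = exp(beta_touch + beta_sex)` (sex coded 0 = female, 1 = male).
#'
#' @param fit a touch+sex [GLMFit-class], or a length-2 numeric
#'   `c(betaTouch, betaSex)`.
#' @return named numeric `c(female = ..., male = ...)`.
#' @export
sexModulations <- function(fit) {
  if (is(fit, "GLMFit")) {
    stopifnot(fit@variant == "touch_sex")
    bt <- coef(fit)[["touch"]]
    bs <- coef(fit)[["sex"]]
  } else {
    bt <- fit[1]
    bs <- fit[2]
  }
  c(female = exp(bt), male = exp(bt + bs))
}

#' Bias-versus-potentiation population model
#'
#' Mixed-effects regression of the male-partner modulation on the
#' female-partner modulation, subject sex, and their interaction, with a
#' per-subject random intercept:
#' `male ~ 1 + female + subjectSex + female:subjectSex + (1 | subject)`.
#' Fitting is on the log2 fold-change scale by default (symmetric for
#' increases and decreases; the ratio scale is selectable). Records with a
#' more than 32-fold change on either axis (|log2| > 5) are removed before
#' fitting. Potentiation is indicated by a slope whose 95% CI excludes 1;
#' bias by an intercept CI excluding 0.
#'
#' @param records data.frame with columns `femaleMod`, `maleMod` (fold
#'   ratios) or `femaleLog2`, `maleLog2`, plus `subjectId`, `subjectSex`.
#' @param scale `"log2"` (default) or `"ratio"`.
#' @param foldLimit exclusion threshold in log2 units (default 5).
#' @return list with `terms` (data.frame: estimate, 2.5%, 97.5%, p per fixed
#'   effect), `potentiation`, `bias` (logical CI calls), `nUsed`,
#'   `nRemoved`, `model` (`"mixed"` or `"fixed"`), and `fit`.
#' @export
fitPopulationModel <- function(records, scale = c("log2", "ratio"), foldLimit = 5) {
  scale <- match.arg(scale)
  if (!all(c("femaleLog2", "maleLog2") %in% names(records))) {
    records$femaleLog2 <- log2(records$femaleMod)
    records$maleLog2 <- log2(records$maleMod)
  }
  ok <- abs(records$femaleLog2) <= foldLimit & abs(records$maleLog2) <= foldLimit
  d <- records[ok, , drop = FALSE]
  if (scale == "log2") {
    d$x <- d$femaleLog2
    d$y <- d$maleLog2
  } else {
    d$x <- 2^d$femaleLog2
    d$y <- 2^d$maleLog2
  }
  d$sexM <- as.numeric(d$subjectSex == "M")
  d$subject <- factor(d$subjectId)
  singleSubject <- nlevels(d$subject) < 2L
  if (singleSubject) {
    warning("single subject: random intercept unidentifiable, fixed-effects fit used")
    fit <- stats::lm(y ~ x * sexM, data = d)
    s <- stats::coef(summary(fit))
    ci <- stats::confint(fit)
  } else {
    fit <- suppressMessages(lmerTest::lmer(y ~ x * sexM + (1 | subject), data = d))
    s <- stats::coef(summary(fit))
    ci <- suppressMessages(stats::confint(fit, method = "Wald"))
    ci <- ci[rownames(s), , drop = FALSE]
  }
  terms <- data.frame(
    term = c("intercept", "femaleMod", "subjectSex", "femaleMod:subjectSex"),
    estimate = s[, "Estimate"],
    lo = ci[, 1], hi = ci[, 2],
    p = s[, grep("^Pr", colnames(s))[1]],
    row.names = NULL
  )
  slopeRow <- terms[terms$term == "femaleMod", ]
  intRow <- terms[terms$term == "intercept", ]
  list(
    terms = terms,
    potentiation = slopeRow$lo > 1 || slopeRow$hi < 1,
    bias = intRow$lo > 0 || intRow$hi < 0,
    nUsed = nrow(d), nRemoved = sum(!ok),
    model = if (singleSubject) "fixed" else "mixed", fit = fit
  )
}

#' Contingency analysis of unit labels across areas
#'
#' Chi-square test of independence plus standardized Pearson residuals
#' `r_ij = (O - E) / sqrt(E (1 - p_row)(1 - p_col))`; cells with |r| > 1.96
#' (two-sided normal 5%) are flagged as driving the dependence.
#'
#' @param tab contingency table (matrix or table), e.g. label counts by area.
#' @return list with `p`, `statistic`, `expected`, `residuals`
#'   (standardized), `flagged` (logical matrix).
#' @export
contingencyAnalysis <- function(tab) {
  tab <- as.table(as.matrix(tab))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(
    p = ct$p.value, statistic = unname(ct$statistic),
    expected = ct$expected, residuals = ct$stdres,
    flagged = abs(ct$stdres) > stats::qnorm(0.975)
  )
}

#' Kendall rank correlation between female- and male-partner modulations
#'
#' Tie-adjusted Kendall's tau (ties are rare on continuous modulations but
#' possible after filtering).
#'
#' @param femaleMod,maleMod numeric vectors.
#' @return list with `tau` and `p`.
#' @export
rankCorrelation <- function(femaleMod, maleMod) {
  ct <- suppressWarnings(
    stats::cor.test(femaleMod, maleMod, method = "kendall")
  )
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Direction of population modulation, optionally split by subject sex
#'
#' Convenience wrapper around standard location tests: is the median touch
#' coefficient of a set of units shifted from zero (Wilcoxon signed-rank or
#' t test), and do male- and female-subject units differ?
#'
#' @param beta numeric vector of touch coefficients.
#' @param subjectSex optional parallel `"F"`/`"M"` vector.
#' @param normal use t tests instead of rank tests.
#' @return list with `median`, `p` and, when `subjectSex` is given,
#'   `pBetweenSexes`.
#' @export
modulationDirectionTest <- function(beta, subjectSex = NULL, normal = FALSE) {
  test1 <- function(x) {
    if (normal) stats::t.test(x)$p.value else
      suppressWarnings(stats::wilcox.test(x, exact = FALSE))$p.value
  }
  out <- list(median = stats::median(beta), p = test1(beta))
  if (!is.null(subjectSex)) {
    f <- beta[subjectSex == "F"]
    m <- beta[subjectSex == "M"]
    out$pBetweenSexes <- if (normal) {
      stats::t.test(f, m, var.equal = FALSE)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(f, m, exact = FALSE))$p.value
    }
  }
  out
}
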