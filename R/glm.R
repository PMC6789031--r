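#' Build the point-process predictor matrix for one unit
#'
#' Bins the unit's spikes on the 1-ms grid, trims baseline bins more than
#' `margin` seconds from any touch episode, and assembles the design:
#' constant, eleven spike-history terms (five 1-ms lags, six 25-ms windows
#' spanning the previous 155 ms), `nRec - 1` recording indicators, the touch
#' indicator, and optionally the partner-sex indicator (0 = female,
#' 1 = male, active during touch episodes; a recording-constant sex column
#' would be collinear with the recording indicators when each block hosts
#' one partner). History features are computed on the original timeline, so
#' spikes inside trimmed spans still feed the history of retained bins; only
#' likelihood rows for trimmed bins are dropped.
#'
#' @param session a [Session-class].
#' @param unit unit id.
#' @param includeSex include the partner-sex column (the touch+sex variant).
#' @param margin baseline-trimming margin in seconds (default 5).
#' @param binWidth bin width (s), default 1 ms.
#' @return a [PredictorMatrix-class].
#' @export
buildPredictorMatrix <- function(session, unit, includeSex = TRUE,
                                 margin = 5, binWidth = 1e-3) {
  stopifnot(is(session, "Session"))
  nRec <- nrow(blocks(session))
  if (nRec < 1L) stop("session has no recording blocks")
  bst <- binSpikes(spikeTimes(session, unit), sessionEnd(session), binWidth)
  bst <- trimBaseline(bst, episodes(session), margin)
  counts <- binCounts(bst)
  nBins <- length(counts)
  H <- cpp_history_matrix(counts)
  ind <- binIndicators(blocks(session), episodes(session), nBins, binWidth)
  kept <- which(keptMask(bst))
  ncols <- 1L + 11L + (nRec - 1L) + 1L + as.integer(includeSex)
  X <- matrix(0, nrow = length(kept), ncol = ncols)
  cn <- c(
    "const", paste0("h", 1:11),
    if (nRec > 1L) paste0("rec", 2:nRec), "touch",
    if (includeSex) "sex"
  )
  colnames(X) <- cn
  X[, "const"] <- 1
  X[, 2:12] <- H[kept, ]
  if (nRec > 1L) {
    for (b in 2:nRec) X[, paste0("rec", b)] <- as.numeric(ind$rec[kept] == b)
  }
  X[, "touch"] <- ind$touch[kept]
  if (includeSex) X[, "sex"] <- ind$sex[kept]
  new("PredictorMatrix",
    X = X, y = counts[kept], keptBins = kept,
    binWidth = binWidth, includeSex = includeSex, nRec = as.integer(nRec)
  )
}

#' Poisson point-process log likelihood
#'
#' Full log likelihood in nats at coefficient vector `beta`, including the
#' `sum(y) log(Delta) - sum(log y!)` constants, so absolute values are
#' comparable across model variants.
#'
#' @param beta coefficient vector (length `ncol(X)`).
#' @param pm a [PredictorMatrix-class].
#' @return log likelihood (nats).
#' @export
ppLogLik <- function(beta, pm) {
  stopifnot(is(pm, "PredictorMatrix"), length(beta) == ncol(pm@X))
  cpp_pp_loglik(pm@X, as.numeric(pm@y), log(pm@binWidth), as.numeric(beta))
}

# shared default initializer: log mean rate for the constant, zero elsewhere
betaStart <- function(pm) {
  rate <- sum(pm@y) / (length(pm@y) * pm@binWidth)
  b <- numeric(ncol(pm@X))
  b[1] <- log(max(rate, 1e-3))
  b
}

#' Fit the point-process GLM by Newton maximum likelihood
#'
#' Newton iterations with step-halving on the concave Poisson log-link
#' likelihood; convergence when the maximum absolute score falls below
#' `tol * (1 + total spike count)`. Non-convergence (including complete
#' separation, where a predictor perfectly silences the unit) is flagged on
#' the returned fit rather than raised.
#'
#' @param pm a [PredictorMatrix-class] (or a [Session-class] together with
#'   `unit`).
#' @param unit unit id when a session is supplied.
#' @param includeSex model variant when building from a session.
#' @param betaInit optional start values.
#' @param maxIter,tol Newton controls.
#' @param ... passed to [buildPredictorMatrix()].
#' @return a [GLMFit-class].
#' @export
fitUnitModel <- function(pm, unit = NULL, includeSex = TRUE, betaInit = NULL,
                         maxIter = 50L, tol = 1e-9, ...) {
  if (is(pm, "Session")) {
    pm <- buildPredictorMatrix(pm, unit, includeSex = includeSex, ...)
  }
  stopifnot(is(pm, "PredictorMatrix"))
  if (is.null(betaInit)) betaInit <- betaStart(pm)
  r <- cpp_pp_fit(pm@X, as.numeric(pm@y), log(pm@binWidth), betaInit, maxIter, tol)
  beta <- r$beta
  names(beta) <- colnames(pm@X)
  fit <- new("GLMFit",
    beta = beta, logLik = r$logLik, converged = r$converged,
    variant = if (pm@includeSex) "touch_sex" else "touch_only",
    nIter = as.integer(r$iter), gradNorm = r$gradNorm
  )
  if (!r$converged) {
    warning("point-process fit did not converge; excluded downstream")
  }
  fit
}

#' Circular-permutation test for touch modulation
#'
#' Fits the touch-only model, then refits it against predictor matrices in
#' which the touch column has been circularly shifted along the retained-bin
#' axis (uniform shifts of at least `minShift` seconds, so shuffled touch
#' epochs keep their durations and autocorrelation while decoupling from the
#' spikes). The p value is the plus-one permutation estimate
#' `p = (1 + #\{LL_shuffled >= LL_observed\}) / (n + 1)`.
#'
#' @param session a [Session-class].
#' @param unit unit id.
#' @param nShuffles number of circular shifts (default 100).
#' @param seed optional RNG seed for the shifts.
#' @param minShift minimum shift in seconds (default 1).
#' @param margin,binWidth passed to [buildPredictorMatrix()].
#' @return list with `p`, `llObserved`, `llShuffled`, `fit`
#'   (the touch-only [GLMFit-class]).
#' @export
shuffleTouchTest <- function(session, unit, nShuffles = 100L, seed = NULL,
                             minShift = 1, margin = 5, binWidth = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  pm <- buildPredictorMatrix(session, unit,
    includeSex = FALSE,
    margin = margin, binWidth = binWidth
  )
  fit <- fitUnitModel(pm)
  n <- nrow(pm@X)
  lo <- max(1L, as.integer(round(minShift / binWidth)))
  if (n <= 2L * lo) stop("retained span too short for the minimum circular shift")
  shifts <- sample(seq.int(lo, n - lo), nShuffles, replace = TRUE)
  lls <- cpp_shuffle_shift_ll(
    pm@X, as.numeric(pm@y), log(binWidth),
    which(colnames(pm@X) == "touch") - 1L, shifts, coef(fit)
  )
  exceed <- sum(is.na(lls) | lls >= logLik(fit) - 1e-6)
  list(
    p = (1 + exceed) / (nShuffles + 1), llObserved = logLik(fit),
    llShuffled = lls, fit = fit
  )
}

# per-bin index into the session's partner table for touch bins (NA outside
# episodes); relabeling a partner changes exactly the touch bins of that
# partner's episodes
binPartnerIndex <- function(episodes, nBins, binWidth, partners) {
  centers <- (seq_len(nBins) - 0.5) * binWidth
  idx <- rep(NA_integer_, nBins)
  pOf <- match(episodes$partnerId, partners$id)
  for (i in seq_len(nrow(episodes))) {
    idx[centers >= episodes$onset[i] & centers < episodes$offset[i]] <- pOf[i]
  }
  idx
}

# Draw distinct label assignments over partners: permutations of the
# observed label multiset, excluding the observed assignment (it enters the
# estimator through the plus-one term), WITHOUT replacement, capped at the
# combinatorial maximum. Sampling distinct assignments keeps the plus-one
# estimator valid when the assignment space is small: re-drawing the same few
# assignments with replacement would fabricate precision the design cannot
# support, and the estimator then badly over-rejects under the null.
drawSexAssignments <- function(labels, nShuffles) {
  n <- length(labels)
  nM <- sum(labels == "M")
  total <- choose(n, nM)
  if (total <= 10000) {
    combs <- utils::combn(n, nM)
    out <- apply(combs, 2, function(ix) {
      l <- rep("F", n)
      l[ix] <- "M"
      l
    })
    out <- out[, colSums(out == labels) < n, drop = FALSE] # drop identity
    if (ncol(out) > nShuffles) {
      out <- out[, sample(ncol(out), nShuffles), drop = FALSE]
    }
  } else {
    draws <- replicate(2L * nShuffles, sample(labels))
    keys <- apply(draws, 2, paste, collapse = "")
    keep <- !duplicated(keys) & keys != paste(labels, collapse = "")
    out <- draws[, keep, drop = FALSE]
    out <- out[, seq_len(min(ncol(out), nShuffles)), drop = FALSE]
  }
  out
}

#' Partner-label shuffle test for sex-touch modulation
#'
#' Fits the touch+sex model, then refits it with the partner animals'
#' male/female labels permuted at the partner level (every episode of a
#' partner keeps a single label). Distinct non-identity assignments are
#' drawn without replacement, capped at the combinatorial maximum (with few
#' partners all assignments are enumerated, making the test exact); the
#' p value is the plus-one permutation estimate over the `m` assignments
#' used, `(1 + #\{LL_shuffled >= LL_observed\}) / (m + 1)`. With only two
#' partners per sex the p value therefore saturates at 1/6.
#'
#' @inheritParams shuffleTouchTest
#' @return list with `p`, `llObserved`, `llShuffled`, `fit` (the touch+sex
#'   [GLMFit-class]). When all partners share one sex the test is undefined
#'   and `p = 1` is returned with a warning.
#' @export
shuffleSexTest <- function(session, unit, nShuffles = 100L, seed = NULL,
                           margin = 5, binWidth = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  pm <- buildPredictorMatrix(session, unit,
    includeSex = TRUE,
    margin = margin, binWidth = binWidth
  )
  fit <- fitUnitModel(pm)
  ep <- episodes(session)
  partners <- unique(ep[, c("partnerId", "partnerSex")])
  names(partners) <- c("id", "sex")
  if (length(unique(partners$sex)) < 2L) {
    warning("all partners share one sex; sex shuffle undefined, p set to 1")
    return(list(p = 1, llObserved = logLik(fit), llShuffled = numeric(0), fit = fit))
  }
  nBins <- as.integer(ceiling(sessionEnd(session) / binWidth - 1e-9))
  pIdx <- binPartnerIndex(ep, nBins, binWidth, partners)[pm@keptBins]
  assign <- drawSexAssignments(partners$sex, nShuffles)
  m <- ncol(assign)
  newCols <- matrix(0, nrow = length(pIdx), ncol = m)
  inTouch <- !is.na(pIdx)
  for (s in seq_len(m)) {
    newCols[inTouch, s] <- as.numeric(assign[pIdx[inTouch], s] == "M")
  }
  lls <- cpp_shuffle_col_ll(
    pm@X, as.numeric(pm@y), log(binWidth),
    which(colnames(pm@X) == "sex") - 1L, newCols, coef(fit)
  )
  exceed <- sum(is.na(lls) | lls >= logLik(fit) - 1e-6)
  list(
    p = (1 + exceed) / (length(lls) + 1), llObserved = logLik(fit),
    llShuffled = lls, fit = fit, nAssignments = length(lls)
  )
}

#' Classify a unit from its shuffle p values
#'
#' `sex_touch` whenever `pSex < alpha`; `touch` when `pSex >= alpha` and
#' `pTouch < alpha`; otherwise `nonsignificant`.
#'
#' @param pTouch,pSex shuffle p values.
#' @param alpha significance level (default 0.05).
#' @return character label.
#' @export
classifyUnit <- function(pTouch, pSex, alpha = 0.05) {
  if (pSex < alpha) {
    "sex_touch"
  } else if (pTouch < alpha) {
    "touch"
  } else {
    "nonsignificant"
  }
}

#' Run both shuffle tests and classify one unit
#'
#' @inheritParams shuffleTouchTest
#' @param nTouchShuffles,nSexShuffles shuffle counts (default 100 each).
#' @param alpha significance level.
#' @return list with `pTouch`, `pSex`, `label`, and the two underlying fits.
#' @export
classifySessionUnit <- function(session, unit, nTouchShuffles = 100L,
                                nSexShuffles = 100L, seed = NULL, alpha = 0.05,
                                margin = 5, binWidth = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  tt <- shuffleTouchTest(session, unit, nTouchShuffles,
    margin = margin, binWidth = binWidth
  )
  st <- shuffleSexTest(session, unit, nSexShuffles,
    margin = margin, binWidth = binWidth
  )
  list(
    pTouch = tt$p, pSex = st$p, label = classifyUnit(tt$p, st$p, alpha),
    touchFit = tt$fit, sexFit = st$fit
  )
}

#' Model-predicted PSTH, split by partner sex
#'
#' Forward-simulates the fitted model over the session's episode structure
#' (the history terms make the model generative, not just descriptive),
#' then averages simulated activity aligned to touch onsets, separately for
#' female- and male-partner episodes, with the same alpha-kernel smoothing
#' as the empirical PSTH.
#'
#' @param fit a [GLMFit-class] (touch-only or touch+sex).
#' @param session the [Session-class] providing the episode structure.
#' @param nSim number of simulated session replicates to average.
#' @param window,tau as in [psth()].
#' @return list with elements `F` and `M` (each a [psth()]-style list with
#'   `time` and `mean`), averaged across simulations.
#' @export
modelPsth <- function(fit, session, nSim = 10L, window = c(-2.5, 1), tau = 0.075) {
  stopifnot(is(fit, "GLMFit"))
  b <- coef(fit)
  nRec <- nrow(blocks(session))
  tb <- unitTrueBeta(
    beta0 = b[["const"]], h = unname(b[paste0("h", 1:11)]),
    betaRec = if (nRec > 1L) unname(b[paste0("rec", 2:nRec)]) else NULL,
    betaTouch = b[["touch"]],
    betaSex = if ("sex" %in% names(b)) b[["sex"]] else 0
  )
  ep <- episodes(session)
  acc <- list(F = NULL, M = NULL)
  for (k in seq_len(nSim)) {
    st <- spikeTimesFromCounts(
      generateSpikeTrain(blocks(session), ep, tb, warn = FALSE)
    )
    for (sx in c("F", "M")) {
      ons <- ep$onset[ep$partnerSex == sx]
      if (!length(ons)) next
      p <- suppressWarnings(psth(st, ons, window = window, tau = tau))
      acc[[sx]] <- if (is.null(acc[[sx]])) p$mean else acc[[sx]] + p$mean
    }
  }
  grid <- seq(window[1], window[2], by = 1e-3)
  out <- list()
  for (sx in c("F", "M")) {
    if (!is.null(acc[[sx]])) {
      out[[sx]] <- list(time = grid, mean = acc[[sx]] / nSim)
    }
  }
  out
}
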