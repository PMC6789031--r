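#' Information per spike over a stimulus-category set
#'
#' `I = (1 / lambda) * sum_i lambda_i * log2(lambda_i / lambda) * p_i`,
#' where `lambda_i` is the firing rate during the i-th stimulus category,
#' `p_i` its occupancy probability and `lambda = sum_i p_i lambda_i` the
#' overall mean rate. The `0 * log 0` limit is taken as 0.
#'
#' @param rates category firing rates (1/s), non-negative.
#' @param probs occupancy probabilities, summing to 1.
#' @return information in bits per spike (non-negative).
#' @export
infoPerSpike <- function(rates, probs) {
  stopifnot(length(rates) == length(probs), all(rates >= 0), all(probs >= 0))
  if (abs(sum(probs) - 1) > 1e-8) stop("occupancy probabilities must sum to 1")
  lambda <- sum(rates * probs)
  if (lambda <= 0) stop("mean rate is zero; information per spike undefined")
  terms <- ifelse(rates > 0, rates * log2(rates / lambda) * probs, 0)
  sum(terms) / lambda
}

# Kept-bin stimulus categories for one unit.
# stimuli = "partner": baseline plus one category per partner animal's touch
# episodes; "sex": baseline, touch-with-female, touch-with-male.
categoryBins <- function(session, unit, stimuli = c("partner", "sex"),
                         margin = 5, binWidth = 1e-3,
                         partnerSex = NULL) {
  stimuli <- match.arg(stimuli)
  bst <- binSpikes(spikeTimes(session, unit), sessionEnd(session), binWidth)
  bst <- trimBaseline(bst, episodes(session), margin)
  kept <- which(keptMask(bst))
  ep <- episodes(session)
  if (!is.null(partnerSex)) { # relabeled partners (sex-shuffled information)
    ep$partnerSex <- partnerSex[match(
      ep$partnerId,
      unique(ep$partnerId)
    )]
  }
  nBins <- length(binCounts(bst))
  centers <- (seq_len(nBins) - 0.5) * binWidth
  cat <- integer(nBins) # 0 = baseline
  if (stimuli == "partner") {
    ids <- unique(ep$partnerId)
    levels <- c("baseline", ids)
    for (i in seq_len(nrow(ep))) {
      cat[centers >= ep$onset[i] & centers < ep$offset[i]] <-
        match(ep$partnerId[i], ids)
    }
  } else {
    levels <- c("baseline", "touch_F", "touch_M")
    for (i in seq_len(nrow(ep))) {
      cat[centers >= ep$onset[i] & centers < ep$offset[i]] <-
        if (ep$partnerSex[i] == "F") 1L else 2L
    }
  }
  list(
    y = binCounts(bst)[kept], cat = cat[kept], levels = levels,
    binWidth = binWidth
  )
}

#' Information per spike of one unit over touch-stimulus categories
#'
#' Rates are estimated as total spikes over total occupancy time per
#' category; occupancy probabilities are the retained-bin fractions.
#'
#' @param session a [Session-class].
#' @param unit unit id.
#' @param stimuli `"partner"` (baseline + each partner's episodes) or
#'   `"sex"` (baseline, touch with female, touch with male).
#' @param margin,binWidth see [buildPredictorMatrix()].
#' @return list with `infoPerSpike` (bits/spike), `rates`, `probs`, `levels`.
#' @export
unitInfo <- function(session, unit, stimuli = "partner", margin = 5,
                     binWidth = 1e-3) {
  cb <- categoryBins(session, unit, stimuli, margin, binWidth)
  nCat <- length(cb$levels)
  occ <- tabulate(cb$cat + 1L, nbins = nCat)
  spk <- vapply(seq_len(nCat) - 1L, function(k) sum(cb$y[cb$cat == k]), numeric(1))
  use <- occ > 0L
  rates <- spk[use] / (occ[use] * cb$binWidth)
  probs <- occ[use] / sum(occ)
  list(
    infoPerSpike = infoPerSpike(rates, probs), rates = rates, probs = probs,
    levels = cb$levels[use]
  )
}

#' Circular-shift significance test for information per spike
#'
#' The stimulus-category timeline is circularly shifted along the retained
#' bins (occupancies are invariant; only the spike/category alignment
#' changes) and the information per spike recomputed per shift. The p value
#' is the upper-tail plus-one permutation estimate.
#'
#' @inheritParams unitInfo
#' @param nShuffles number of shifts (default 200).
#' @param seed optional RNG seed.
#' @param minShift minimum shift (s), default 1.
#' @return list with `p`, `observed` (bits/spike), `shuffled`.
#' @export
infoShuffleTest <- function(session, unit, stimuli = "partner",
                            nShuffles = 200L, seed = NULL, minShift = 1,
                            margin = 5, binWidth = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  cb <- categoryBins(session, unit, stimuli, margin, binWidth)
  n <- length(cb$y)
  nCat <- length(cb$levels)
  occ <- tabulate(cb$cat + 1L, nbins = nCat)
  probs <- occ / sum(occ)
  lo <- max(1L, as.integer(round(minShift / binWidth)))
  if (n <= 2L * lo) stop("retained span too short for the minimum circular shift")
  obs <- unitInfo(session, unit, stimuli, margin, binWidth)$infoPerSpike
  shifts <- sample(seq.int(lo, n - lo), nShuffles, replace = TRUE)
  spk <- cpp_category_spikes_shifted(cb$y, cb$cat, nCat, shifts)
  shuffled <- vapply(seq_len(nShuffles), function(s) {
    use <- occ > 0L
    rates <- spk[s, use] / (occ[use] * cb$binWidth)
    infoPerSpike(rates, probs[use] / sum(probs[use]))
  }, numeric(1))
  list(
    p = (1 + sum(shuffled >= obs - 1e-12)) / (nShuffles + 1),
    observed = obs, shuffled = shuffled
  )
}

#' Real-minus-shuffled information over baseline / male-touch / female-touch
#'
#' Computes the information per spike over the three situations (baseline,
#' touch with male partners, touch with female partners), then recomputes it
#' under partner-level sex-label permutations (the same partner-level
#' machinery as [shuffleSexTest()]); distinct non-identity assignments are
#' enumerated and capped at `maxShuffles`. Positive differences mean the
#' true sex labels are more informative than relabelings.
#'
#' @inheritParams unitInfo
#' @param maxShuffles cap on the number of distinct assignments used.
#' @return data.frame with one row per shuffle: `deltaI` (bits/spike),
#'   `real`, `shuffled`.
#' @export
sexShuffledDeltaInfo <- function(session, unit, maxShuffles = 20L,
                                 margin = 5, binWidth = 1e-3) {
  ep <- episodes(session)
  ids <- unique(ep$partnerId)
  labels <- ep$partnerSex[match(ids, ep$partnerId)]
  nM <- sum(labels == "M")
  if (nM == 0L || nM == length(labels)) {
    stop("sex-shuffled information requires partners of both sexes")
  }
  real <- unitInfo(session, unit, "sex", margin, binWidth)$infoPerSpike
  combs <- utils::combn(length(labels), nM)
  assigns <- apply(combs, 2, function(ix) {
    l <- rep("F", length(labels))
    l[ix] <- "M"
    l
  })
  keep <- colSums(assigns == labels) < length(labels) # drop identity
  assigns <- assigns[, keep, drop = FALSE]
  if (ncol(assigns) > maxShuffles) {
    assigns <- assigns[, sample(ncol(assigns), maxShuffles), drop = FALSE]
  }
  shuffled <- vapply(seq_len(ncol(assigns)), function(s) {
    cb <- categoryBins(session, unit, "sex", margin, binWidth,
      partnerSex = assigns[, s]
    )
    nCat <- length(cb$levels)
    occ <- tabulate(cb$cat + 1L, nbins = nCat)
    spk <- vapply(seq_len(nCat) - 1L, function(k) sum(cb$y[cb$cat == k]), numeric(1))
    use <- occ > 0L
    infoPerSpike(spk[use] / (occ[use] * cb$binWidth), occ[use] / sum(occ))
  }, numeric(1))
  data.frame(deltaI = real - shuffled, real = real, shuffled = shuffled)
}

#' Mixed-effects test of the mean information difference
#'
#' Fits `deltaI ~ 1 + (1 | unit)`: the repeated shuffles per unit are
#' dependent, so the unit enters as a random intercept. With a single
#' observation per unit the model degenerates to a paired one-sample t test,
#' which is then used directly.
#'
#' @param deltaI numeric vector of real-minus-shuffled information values.
#' @param unit parallel vector of unit ids.
#' @return list with `intercept` (estimated mean difference, bits/spike),
#'   `p` (two-sided), and `model` (`"mixed"` or `"t.test"`).
#' @export
deltaInfoTest <- function(deltaI, unit) {
  stopifnot(length(deltaI) == length(unit))
  if (length(unique(unit)) < 2L) stop("at least two units required")
  if (stats::sd(deltaI) == 0) { # degenerate data: no dispersion to test against
    return(list(
      intercept = mean(deltaI), p = if (mean(deltaI) == 0) 1 else 0,
      model = "degenerate"
    ))
  }
  perUnit <- table(unit)
  if (max(perUnit) == 1L) {
    tt <- stats::t.test(deltaI)
    return(list(
      intercept = unname(tt$estimate), p = tt$p.value,
      model = "t.test"
    ))
  }
  d <- data.frame(deltaI = deltaI, unit = factor(unit))
  fit <- suppressMessages(lmerTest::lmer(deltaI ~ 1 + (1 | unit), data = d))
  s <- stats::coef(summary(fit))
  list(
    intercept = s[1, "Estimate"], p = s[1, "Pr(>|t|)"], model = "mixed",
    fit = fit
  )
}
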