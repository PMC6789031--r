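#' Solve log-normal parameters from a median and interquartile range
#'
#' The behavioral timing generator assumes log-normal durations and
#' inter-touch intervals (heavy-tailed, spanning orders of magnitude on a
#' log axis). Given a median `m` and quartiles `(q25, q75)`, the log-scale
#' parameters are `meanlog = log(m)` and
#' `sdlog = (log(q75) - log(q25)) / (2 * 0.6745)`.
#'
#' @param m median (s).
#' @param q25,q75 quartiles (s).
#' @return list with `meanlog` and `sdlog`.
#' @export
lognormalFromQuantiles <- function(m, q25, q75) {
  stopifnot(m > 0, q25 > 0, q75 > q25)
  list(meanlog = log(m), sdlog = (log(q75) - log(q25)) / (2 * stats::qnorm(0.75)))
}

#' Default behavioral-timing calibration
#'
#' Touch durations: median 1.33 s, IQR 0.77--2.53 s. Inter-touch intervals:
#' median 4.68 s, IQR 1.24--23.78 s. Both modeled as log-normal.
#'
#' @return list with `duration` and `interval`, each a `meanlog`/`sdlog` pair.
#' @export
episodeTimingParams <- function() {
  list(
    duration = lognormalFromQuantiles(1.33, 0.77, 2.53),
    interval = lognormalFromQuantiles(4.68, 1.24, 23.78)
  )
}

#' Draw touch durations / inter-touch intervals from the calibrated law
#'
#' Uses the current RNG state (`set.seed()` upstream fixes the draw).
#'
#' @param n number of draws.
#' @param params timing calibration, default [episodeTimingParams()].
#' @return numeric vector of seconds.
#' @export
sampleTouchDurations <- function(n, params = episodeTimingParams()) {
  stats::rlnorm(n, params$duration$meanlog, params$duration$sdlog)
}

#' @rdname sampleTouchDurations
#' @export
sampleInterTouchIntervals <- function(n, params = episodeTimingParams()) {
  stats::rlnorm(n, params$interval$meanlog, params$interval$sdlog)
}

#' Generate touch episodes tiled into recording blocks
#'
#' Episodes are laid down block by block: draw an interval, then a duration,
#' append the episode if it fits before the block end, repeat. One partner is
#' presented per block (the alternating-partner design); partners cycle
#' through the supplied list.
#'
#' @param nBlocks number of recording blocks.
#' @param blockLength block length in seconds (scalar or per-block vector).
#' @param partners data.frame with `id` and `sex` (`"F"`/`"M"`), cycled over
#'   blocks. Default: two female and two male partners.
#' @param params timing calibration, see [episodeTimingParams()].
#' @param gap gap between consecutive blocks (s), default 0.
#' @return list with `blocks` and `episodes` data.frames (Session layout).
#' @export
generateEpisodes <- function(nBlocks = 6, blockLength = 720,
                             partners = data.frame(
                               id = c("f1", "m1", "f2", "m2"),
                               sex = c("F", "M", "F", "M")
                             ),
                             params = episodeTimingParams(), gap = 0) {
  blockLength <- rep_len(blockLength, nBlocks)
  starts <- cumsum(c(0, (blockLength + gap)[-nBlocks]))
  blocks <- data.frame(
    blockIndex = seq_len(nBlocks), start = starts,
    end = starts + blockLength
  )
  pidx <- rep_len(seq_len(nrow(partners)), nBlocks)
  eps <- vector("list", nBlocks)
  for (b in seq_len(nBlocks)) {
    t <- blocks$start[b]
    on <- off <- numeric(0)
    repeat {
      t <- t + sampleInterTouchIntervals(1L, params)
      d <- sampleTouchDurations(1L, params)
      if (t + d >= blocks$end[b]) break
      on <- c(on, t)
      off <- c(off, t + d)
      t <- t + d
    }
    if (length(on)) {
      eps[[b]] <- data.frame(
        onset = on, offset = off,
        partnerId = partners$id[pidx[b]], partnerSex = partners$sex[pidx[b]],
        blockIndex = b, stringsAsFactors = FALSE
      )
    }
  }
  keep <- !vapply(eps, is.null, logical(1))
  episodes <- if (any(keep)) {
    do.call(rbind, eps[keep])
  } else {
    data.frame(
      onset = numeric(0), offset = numeric(0), partnerId = character(0),
      partnerSex = character(0), blockIndex = integer(0)
    )
  }
  list(blocks = blocks, episodes = episodes)
}

#' Default generative coefficients for a synthetic unit
#'
#' Baseline 5 spikes/s; the five 1-ms history terms impose a relative
#' refractory profile; the six 25-ms history terms are zero; no recording
#' drift.
#'
#' @param beta0 log baseline rate (rate in 1/s).
#' @param h 11 spike-history coefficients.
#' @param betaRec per-recording offsets (length `nBlocks - 1`).
#' @param betaTouch,betaSex touch and partner-sex coefficients.
#' @return named list in the layout the simulator and fitter share.
#' @export
unitTrueBeta <- function(beta0 = log(5), h = c(-4, -2, -1, -0.5, -0.2, rep(0, 6)),
                         betaRec = NULL, betaTouch = 0, betaSex = 0) {
  stopifnot(length(h) == 11L)
  list(beta0 = beta0, h = h, betaRec = betaRec, betaTouch = betaTouch, betaSex = betaSex)
}

# Shared per-bin covariate encoder: the forward simulator and the GLM
# predictor builder both use this, so the generative and inference encodings
# cannot drift apart.
# The sex indicator is gated by touch (1 only inside episodes with a male
# partner): a sex column constant over a whole recording block would be
# exactly collinear with the per-recording indicators, and the touch-gated
# form is the one under which male touch modulation = exp(betaTouch + betaSex)
# against a baseline of exp(beta0).
# Returns touch (0/1), sex (0/1), rec (1-based block index) per bin.
binIndicators <- function(blocks, episodes, nBins, binWidth = 1e-3) {
  centers <- (seq_len(nBins) - 0.5) * binWidth
  rec <- findInterval(centers, blocks$start)
  rec[rec < 1L] <- 1L
  rec[rec > nrow(blocks)] <- nrow(blocks)
  touch <- numeric(nBins)
  sex <- numeric(nBins)
  if (!is.null(episodes) && nrow(episodes)) {
    for (i in seq_len(nrow(episodes))) {
      inEp <- centers >= episodes$onset[i] & centers < episodes$offset[i]
      touch[inEp] <- 1
      if (episodes$partnerSex[i] == "M") sex[inEp] <- 1
    }
  }
  list(touch = touch, sex = sex, rec = as.integer(rec))
}

#' Forward-simulate a spike train from the generative point-process model
#'
#' Bin-by-bin simulation: each 1-ms bin's count is Poisson with mean
#' `Delta * exp(row . beta)`, where the row encodes the spike history emitted
#' so far, the recording indicator, the touch indicator and the partner-sex
#' indicator, exactly as the inference-side predictor matrix defines them.
#'
#' @param blocks,episodes Session-layout data.frames (see
#'   [generateEpisodes()]).
#' @param trueBeta coefficient list from [unitTrueBeta()].
#' @param binWidth bin width (s), default 1 ms.
#' @param warn warn when the per-bin mean exceeds 1 in a nontrivial fraction
#'   of bins (model leaving the sparse-spiking regime).
#' @return a [BinnedSpikeTrain-class] (all bins retained).
#' @export
generateSpikeTrain <- function(blocks, episodes, trueBeta = unitTrueBeta(),
                               binWidth = 1e-3, warn = TRUE) {
  nBins <- as.integer(ceiling(max(blocks$end) / binWidth - 1e-9))
  ind <- binIndicators(blocks, episodes, nBins, binWidth)
  nRec <- nrow(blocks)
  betaRec <- trueBeta$betaRec
  if (is.null(betaRec)) betaRec <- rep(0, nRec - 1L)
  sim <- cpp_simulate_glm_train(
    ind$touch, ind$sex, ind$rec, nRec,
    trueBeta$beta0, trueBeta$h, betaRec,
    trueBeta$betaTouch, trueBeta$betaSex, binWidth
  )
  if (warn && sim$denseBins > 0.001 * nBins) {
    warning(sprintf(
      "per-bin mean exceeded 1 in %d bins; model is leaving the sparse-spiking regime",
      sim$denseBins
    ))
  }
  new("BinnedSpikeTrain",
    counts = sim$counts, binWidth = binWidth,
    keptMask = rep(TRUE, nBins)
  )
}

# Spike times from binned counts: y spikes in a bin are placed evenly inside
# it (deterministic; adequate at 1-ms resolution).
spikeTimesFromCounts <- function(bst) {
  counts <- binCounts(bst)
  idx <- which(counts > 0L)
  if (!length(idx)) {
    return(numeric(0))
  }
  unlist(lapply(idx, function(i) {
    k <- counts[i]
    (i - 1L + (seq_len(k) - 0.5) / k) * binWidth(bst)
  }), use.names = FALSE)
}

#' Generate a full synthetic session
#'
#' Behavioral timing from the calibrated generator, spike trains from the
#' generative point-process model.
#'
#' @param units named list of coefficient lists ([unitTrueBeta()]), one per
#'   unit.
#' @param nBlocks,blockLength,partners,params passed to [generateEpisodes()].
#' @param subjectId,subjectSex,area session metadata.
#' @return a [Session-class]; the generating coefficients are attached as
#'   attribute `trueBeta`.
#' @export
generateSession <- function(units = list(u1 = unitTrueBeta()),
                            nBlocks = 6, blockLength = 720,
                            partners = data.frame(
                              id = c("f1", "m1", "f2", "m2"),
                              sex = c("F", "M", "F", "M")
                            ),
                            params = episodeTimingParams(),
                            subjectId = "synth", subjectSex = "F", area = "S1") {
  beh <- generateEpisodes(nBlocks, blockLength, partners, params)
  trains <- lapply(units, function(tb) {
    spikeTimesFromCounts(generateSpikeTrain(beh$blocks, beh$episodes, tb))
  })
  s <- Session(
    subjectId = subjectId, subjectSex = subjectSex, area = area,
    blocks = beh$blocks, episodes = beh$episodes, units = trains
  )
  attr(s, "trueBeta") <- units
  s
}

#' Generate a population modulation table with known structure
#'
#' Emulates the population geometries of the bias/potentiation analysis on
#' the log2 fold-change scale: per neuron, the female-partner modulation is
#' drawn from a centred distribution and the male-partner modulation is
#' `bias + slope * female + sexEffect * subjectSex + interaction * female *
#' subjectSex + subject intercept + noise`.
#'
#' @param nPerSubject neurons per subject.
#' @param subjects data.frame with `id` and `sex`.
#' @param bias intercept (log2 fold-change units).
#' @param slope slope on the female modulation (1 = diagonal).
#' @param sexEffect additive subject-sex effect.
#' @param interaction female-modulation-by-subject-sex interaction.
#' @param subjectSd sd of the per-subject random intercept.
#' @param noiseSd residual sd.
#' @param femaleSd sd of the female modulation distribution.
#' @param area area label stamped on the records.
#' @return data.frame of modulation records (`femaleMod`/`maleMod` are fold
#'   ratios; `femaleLog2`/`maleLog2` the log2 values used for fitting), with
#'   the generating parameters in attribute `truth`.
#' @export
generatePopulation <- function(nPerSubject = 25,
                               subjects = data.frame(
                                 id = paste0("s", 1:6),
                                 sex = rep(c("F", "M"), 3)
                               ),
                               bias = 0, slope = 1, sexEffect = 0,
                               interaction = 0, subjectSd = 0.1,
                               noiseSd = 0.3, femaleSd = 1, area = "S1") {
  recs <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    u <- stats::rnorm(1, 0, subjectSd)
    f <- stats::rnorm(nPerSubject, 0, femaleSd)
    sx <- as.numeric(subjects$sex[i] == "M")
    m <- bias + slope * f + sexEffect * sx + interaction * f * sx + u +
      stats::rnorm(nPerSubject, 0, noiseSd)
    recs[[i]] <- data.frame(
      unitId = sprintf("%s_u%02d", subjects$id[i], seq_len(nPerSubject)),
      area = area, subjectId = subjects$id[i], subjectSex = subjects$sex[i],
      femaleLog2 = f, maleLog2 = m,
      femaleMod = 2^f, maleMod = 2^m, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs)
  attr(out, "truth") <- list(
    bias = bias, slope = slope, sexEffect = sexEffect,
    interaction = interaction, subjectSd = subjectSd, noiseSd = noiseSd
  )
  out
}

#' Generate labeled waveform-feature clusters
#'
#' Two Gaussian clusters in (spike width, post-positivity) space with stored
#' class labels, for exercising the spike-shape classifier.
#'
#' @param n per-class counts, length 2 (`putative_I`, `putative_E`).
#' @param means 2 x 2 matrix, rows = class, columns = (width ms,
#'   post-positivity).
#' @param sds 2 x 2 matrix of per-class, per-feature standard deviations.
#' @return data.frame with `widthHalfMax`, `postPositivity`, `class`.
#' @export
generateWaveformFeatures <- function(n = c(40, 120),
                                     means = rbind(c(0.17, 0.05), c(0.38, 0.35)),
                                     sds = rbind(c(0.03, 0.05), c(0.05, 0.08))) {
  cls <- c("putative_I", "putative_E")
  out <- do.call(rbind, lapply(1:2, function(k) {
    if (n[k] == 0L) {
      return(NULL)
    }
    data.frame(
      widthHalfMax = stats::rnorm(n[k], means[k, 1], sds[k, 1]),
      postPositivity = stats::rnorm(n[k], means[k, 2], sds[k, 2]),
      class = cls[k], stringsAsFactors = FALSE
    )
  }))
  out$widthHalfMax <- pmax(out$widthHalfMax, 1e-3)
  out
}
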