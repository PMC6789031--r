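POPULATIONS <- c("L23e", "L23i", "L4e", "L4i", "L5e", "L5i", "L6e", "L6i", "Thal")
POP_INHIBITORY <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)

#' Default configuration of the layered LIF microcircuit
#'
#' Eight cortical populations (excitatory and inhibitory pairs in layers
#' 2/3, 4, 5 and 6; 77,169 neurons at full scale) plus a thalamic input
#' population of 902 neurons, with pairwise connection probabilities,
#' layer-specific background drive, and the standard LIF constants
#' (tau_m = 10 ms, C_m = 250 pF, V_r = -65 mV, V_th = -50 mV,
#' tau_ref = 2 ms, tau_syn = 0.5 ms). Excitatory synaptic weights are
#' Normal(87.8, 8.8) pA (doubled for L4e to L2/3e), inhibitory weights are
#' -4 times the excitatory draw; delays are Normal(1.5, 0.75) ms from
#' excitatory and Normal(0.8, 0.4) ms from inhibitory sources, truncated
#' below at one 0.1-ms integration step.
#'
#' The printed L5e-to-L2/3i connection probability is typographically
#' ambiguous; the value consistent with the upstream microcircuit model
#' (0.0755) is the default and can be overridden.
#'
#' @param scale population-size scale factor in (0, 1]; in-degrees are
#'   preserved under scaling (expected synapses per target neuron held
#'   fixed) so single-neuron input statistics are approximately invariant.
#' @param l5eToL23i connection probability for the ambiguous cell.
#' @param bgScale multiplier on the background currents (0 silences the
#'   network's intrinsic drive).
#' @return a [NetworkConfig-class].
#' @export
microcircuitConfig <- function(scale = 0.1, l5eToL23i = 0.0755, bgScale = 1) {
  N <- c(20683, 5834, 21915, 5479, 4850, 1065, 14395, 2948, 902)
  names(N) <- POPULATIONS
  pConn <- rbind(
    L23e = c(0.101, 0.169, 0.044, 0.082, 0.032, 0.0, 0.008, 0.0, 0.0),
    L23i = c(0.135, 0.137, 0.032, 0.052, l5eToL23i, 0.0, 0.004, 0.0, 0.0),
    L4e  = c(0.008, 0.006, 0.050, 0.135, 0.007, 0.0003, 0.045, 0.0, 0.0983),
    L4i  = c(0.069, 0.003, 0.079, 0.160, 0.003, 0.0, 0.106, 0.0, 0.0619),
    L5e  = c(0.100, 0.062, 0.051, 0.006, 0.083, 0.373, 0.020, 0.0, 0.0),
    L5i  = c(0.055, 0.027, 0.026, 0.002, 0.060, 0.316, 0.009, 0.0, 0.0),
    L6e  = c(0.016, 0.007, 0.021, 0.017, 0.057, 0.020, 0.040, 0.225, 0.0512),
    L6i  = c(0.036, 0.001, 0.003, 0.001, 0.028, 0.008, 0.066, 0.144, 0.0196)
  )
  colnames(pConn) <- POPULATIONS
  bg <- bgScale * c(1600, 1500, 2100, 1900, 2000, 1900, 2900, 2100)
  names(bg) <- POPULATIONS[1:8]
  neuron <- list(
    tauM = 10, Cm = 250, Vr = -65, Vth = -50, tauRef = 2, tauSyn = 0.5, # ms/pF/mV
    wMean = 87.8, wSd = 8.8, inhFactor = -4, l4eToL23eFactor = 2,
    delayE = c(1.5, 0.75), delayI = c(0.8, 0.4), # ms
    bgUnit = 0.3512, # pA per unit of b
    dt = 0.1, # ms
    initV = c(-58, 10) # mV
  )
  new("NetworkConfig", N = N, pConn = pConn, bg = bg, neuron = neuron, scale = scale)
}

#' Synapse count between two populations
#'
#' `K = log(1 - p) / log(1 - 1 / (N_pre * N_post))`: the expected number of
#' synapses that realizes connection probability `p` when synapses are
#' assigned by drawing (pre, post) pairs uniformly with replacement.
#'
#' @param p connection probability in [0, 1).
#' @param nPre,nPost population sizes.
#' @return real-valued synapse count (rounded at instantiation).
#' @export
synapseCount <- function(p, nPre, nPost) {
  stopifnot(nPre * nPost >= 1)
  if (any(p >= 1)) stop("p = 1 has no finite synapse count under this scheme")
  if (any(p < 0)) stop("p must be non-negative")
  ifelse(p == 0, 0, log(1 - p) / log(1 - 1 / (nPre * nPost)))
}

#' Full-scale synapse table and total
#'
#' Evaluates the synapse-count formula for every (source, target) pair at
#' full scale, thalamic projections included.
#'
#' @param config a [NetworkConfig-class].
#' @return `synapseTable`: data.frame with `source`, `target`, `p`, `K`;
#'   `totalSynapses`: their sum.
#' @export
synapseTable <- function(config = microcircuitConfig()) {
  out <- expand.grid(
    target = POPULATIONS[1:8], source = POPULATIONS,
    stringsAsFactors = FALSE
  )[, c(2, 1)]
  out$p <- mapply(function(s, t) config@pConn[t, s], out$source, out$target)
  out$K <- mapply(
    function(s, t, p) synapseCount(p, config@N[s], config@N[t]),
    out$source, out$target, out$p
  )
  out
}

#' @rdname synapseTable
#' @export
totalSynapses <- function(config = microcircuitConfig()) {
  sum(synapseTable(config)$K)
}

#' Instantiate the microcircuit
#'
#' Draws every synapse (pre and post sampled uniformly with replacement, so
#' multapses and autapses are permitted), with per-synapse weights and
#' delays from the configured normal distributions. At scale < 1 the
#' per-pair synapse count is `K * scale` (in-degree preservation).
#'
#' @param config a [NetworkConfig-class].
#' @param seed integer seed for the connectivity stream.
#' @return an opaque network handle (list with the external pointer, the
#'   configuration and the scaled population sizes).
#' @export
buildNetwork <- function(config = microcircuitConfig(), seed = 1L) {
  sizes <- scaledCounts(config)
  tab <- synapseTable(config)
  tab <- tab[tab$p > 0, ]
  nrn <- config@neuron
  kScaled <- round(tab$K * sizes[tab$target] / config@N[tab$target])
  srcIdx <- match(tab$source, POPULATIONS) - 1L
  tgtIdx <- match(tab$target, POPULATIONS) - 1L
  srcInh <- c(POP_INHIBITORY, FALSE)[srcIdx + 1L]
  wMu <- ifelse(tab$source == "L4e" & tab$target == "L23e",
    nrn$wMean * nrn$l4eToL23eFactor, nrn$wMean
  )
  wSign <- ifelse(srcInh, nrn$inhFactor, 1)
  dMu <- ifelse(srcInh, nrn$delayI[1], nrn$delayE[1]) / nrn$dt
  dSd <- ifelse(srcInh, nrn$delayI[2], nrn$delayE[2]) / nrn$dt
  ptr <- cpp_build_network(
    as.integer(sizes), POP_INHIBITORY, srcIdx, tgtIdx,
    as.numeric(kScaled), wMu, rep(nrn$wSd, nrow(tab)), wSign, dMu, dSd,
    as.integer(seed)
  )
  structure(
    list(ptr = ptr, config = config, sizes = sizes),
    class = "MicrocircuitNetwork"
  )
}

#' @export
print.MicrocircuitNetwork <- function(x, ...) {
  s <- cpp_network_summary(x$ptr)
  cat(sprintf(
    "MicrocircuitNetwork: %d cortical + %d thalamic neurons, %.3g synapses (scale %.3g)\n",
    s$nNeurons, s$nThal, s$nSynapses, x$config@scale
  ))
  invisible(x)
}

#' Specification of a touch/neuromodulation experiment
#'
#' Each trial is 1000 ms baseline, 700 ms touch (thalamic rate stepped from
#' 0 to 30 Hz), 300 ms post. Modulated and non-modulated trials alternate.
#' During the touch window of modulated trials, the reset/leak potential of
#' all inhibitory populations is raised by `vrShift` mV (0, +0.5 or +1.0 in
#' the modulation grid) and the membrane time constant of all excitatory
#' populations is multiplied by `rmFactor` (1.0, 1.1 or 1.2), emulating an
#' oxytocin-like rise in inhibitory drive and in excitatory input
#' resistance, respectively.
#'
#' @param vrShift inhibitory reset-potential shift during touch (mV).
#' @param rmFactor excitatory membrane-resistance factor during touch.
#' @param nTrials total trials, alternating non-modulated/modulated.
#' @param thalRate thalamic touch rate (Hz), default 30.
#' @return list of experiment parameters (times in ms).
#' @export
modulationExperiment <- function(vrShift = 0, rmFactor = 1, nTrials = 40L,
                                 thalRate = 30) {
  list(
    vrShift = vrShift, rmFactor = rmFactor, nTrials = as.integer(nTrials),
    trialLen = 2000, touchOn = 1000, touchOff = 1700, baseFrom = 300,
    thalRate = thalRate
  )
}

#' Simulate a touch/neuromodulation experiment
#'
#' Runs the interleaved trial schedule with exact exponential integration at
#' 0.1-ms steps and counts each neuron's spikes in the 700-ms windows before
#' and after touch onset. A random sample of neurons (default 2000) across
#' all cortical populations is retained.
#'
#' @param network a [buildNetwork()] handle.
#' @param experiment a [modulationExperiment()].
#' @param seed seed for thalamic spiking and initial conditions.
#' @param sampleSize neurons to sample (capped at the network size).
#' @param sampleSeed separate seed for the neuron sample.
#' @param rateCeiling abort threshold, average population rate in Hz.
#' @return a [TrialResult-class].
#' @export
simulateExperiment <- function(network, experiment = modulationExperiment(),
                               seed = 1L, sampleSize = 2000L,
                               sampleSeed = seed + 1L, rateCeiling = 200) {
  stopifnot(inherits(network, "MicrocircuitNetwork"))
  cfg <- network$config
  nrn <- cfg@neuron
  res <- cpp_simulate_circuit(
    network$ptr,
    bgCurrent = cfg@bg * nrn$bgUnit,
    dt = nrn$dt, tauM = nrn$tauM, Cm = nrn$Cm, Vr = nrn$Vr, Vth = nrn$Vth,
    tauRef = nrn$tauRef, tauSyn = nrn$tauSyn,
    initMu = nrn$initV[1], initSd = nrn$initV[2],
    nTrials = experiment$nTrials, trialLen = experiment$trialLen,
    touchOn = experiment$touchOn, touchOff = experiment$touchOff,
    baseFrom = experiment$baseFrom,
    thalRate = experiment$thalRate / 1000, # spikes per ms
    vrShiftInh = experiment$vrShift, rmFactorExc = experiment$rmFactor,
    rateCeiling = rateCeiling, seed = as.integer(seed)
  )
  nCortical <- nrow(res$countsBase)
  set.seed(sampleSeed)
  samp <- sort(sample.int(nCortical, min(sampleSize, nCortical)))
  pops <- POPULATIONS[res$popOf[samp]]
  new("TrialResult",
    countsBase = res$countsBase[samp, , drop = FALSE],
    countsTouch = res$countsTouch[samp, , drop = FALSE],
    condition = rep_len(c("nonmod", "mod"), experiment$nTrials),
    population = pops,
    inhibitory = POP_INHIBITORY[match(pops, POPULATIONS[1:8])],
    neuronId = as.integer(samp),
    window = (experiment$touchOff - experiment$touchOn) / 1000
  )
}

#' Per-neuron touch coefficients from a simulated experiment
#'
#' `beta_touch = log(r_touch / r_base)` per neuron and condition, with rates
#' pooled over that condition's trials. Neurons with fewer than 3 spikes
#' across trials, or with any zero-count window (undefined log), are
#' flagged excluded.
#'
#' @param tr a [TrialResult-class].
#' @return data.frame with `neuronId`, `population`, `inhibitory`,
#'   `betaNonmod`, `betaMod`, `excluded`.
#' @export
touchBetas <- function(tr) {
  stopifnot(is(tr, "TrialResult"))
  conds <- c("nonmod", "mod")
  sums <- lapply(conds, function(cc) {
    sel <- tr@condition == cc
    list(
      base = rowSums(tr@countsBase[, sel, drop = FALSE]),
      touch = rowSums(tr@countsTouch[, sel, drop = FALSE]),
      time = sum(sel) * tr@window
    )
  })
  names(sums) <- conds
  total <- sums$nonmod$base + sums$nonmod$touch + sums$mod$base + sums$mod$touch
  zeroWindow <- sums$nonmod$base == 0 | sums$nonmod$touch == 0 |
    sums$mod$base == 0 | sums$mod$touch == 0
  beta <- function(cc) {
    log((sums[[cc]]$touch / sums[[cc]]$time) / (sums[[cc]]$base / sums[[cc]]$time))
  }
  data.frame(
    neuronId = tr@neuronId, population = tr@population,
    inhibitory = tr@inhibitory,
    betaNonmod = beta("nonmod"), betaMod = beta("mod"),
    excluded = total < 3 | zeroWindow
  )
}

#' Select the population response model by BIC
#'
#' Three least-squares models of the modulated response against the
#' non-modulated response: a bias model (slope fixed at 1, free intercept),
#' a potentiation model (intercept fixed at 0, free slope), and a full model
#' (both free). `BIC = n log(RSS / n) + k log(n)` with k the number of free
#' mean parameters; the lowest BIC wins.
#'
#' @param betaNonmod,betaMod per-neuron touch coefficients (excluded neurons
#'   already removed), or a [touchBetas()] data.frame as the first argument.
#' @return list with `models` (data.frame: model, k, rss, bic, intercept,
#'   slope), `selected`, `intercept`, `slope` (of the selected model).
#' @export
responseModelSelection <- function(betaNonmod, betaMod = NULL) {
  if (is.data.frame(betaNonmod)) {
    d <- betaNonmod[!betaNonmod$excluded, ]
    betaMod <- d$betaMod
    betaNonmod <- d$betaNonmod
  }
  ok <- is.finite(betaNonmod) & is.finite(betaMod)
  x <- betaNonmod[ok]
  y <- betaMod[ok]
  n <- length(x)
  if (n < 10L) stop("fewer than 10 usable neurons for response-model selection")
  fits <- list(
    bias = {
      b <- mean(y - x)
      list(k = 1L, rss = sum((y - x - b)^2), intercept = b, slope = 1)
    },
    potentiation = {
      a <- sum(x * y) / sum(x * x)
      list(k = 1L, rss = sum((y - a * x)^2), intercept = 0, slope = a)
    },
    full = {
      f <- stats::lm.fit(cbind(1, x), y)
      list(
        k = 2L, rss = sum(f$residuals^2),
        intercept = f$coefficients[1], slope = f$coefficients[2]
      )
    }
  )
  models <- data.frame(
    model = names(fits),
    k = vapply(fits, `[[`, integer(1), "k"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    intercept = vapply(fits, `[[`, numeric(1), "intercept"),
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    row.names = NULL
  )
  models$bic <- n * log(models$rss / n) + models$k * log(n)
  sel <- models$model[which.min(models$bic)]
  list(
    models = models, selected = sel,
    intercept = models$intercept[models$model == sel],
    slope = models$slope[models$model == sel], n = n
  )
}

#' Trial-permutation test of the modulated-vs-non-modulated difference
#'
#' Under a null modulation the two interleaved trial sets are exchangeable:
#' the mean per-neuron difference in touch coefficients is compared with its
#' distribution under random reassignments of trials to conditions.
#'
#' @param tr a [TrialResult-class].
#' @param nPerm permutations (default 200).
#' @param seed optional RNG seed.
#' @return list with `p` (two-sided), `observed`, `permuted`.
#' @export
conditionPermutationTest <- function(tr, nPerm = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is(tr, "TrialResult"))
  nTrials <- length(tr@condition)
  nMod <- sum(tr@condition == "mod")
  stat <- function(isMod) {
    tm <- sum(isMod) * tr@window
    tn <- sum(!isMod) * tr@window
    bM <- rowSums(tr@countsBase[, isMod, drop = FALSE])
    tM <- rowSums(tr@countsTouch[, isMod, drop = FALSE])
    bN <- rowSums(tr@countsBase[, !isMod, drop = FALSE])
    tN <- rowSums(tr@countsTouch[, !isMod, drop = FALSE])
    ok <- bM > 0 & tM > 0 & bN > 0 & tN > 0 & (bM + tM + bN + tN) >= 3
    mean(log(tM[ok] / bM[ok]) - log(tN[ok] / bN[ok]))
  }
  obs <- stat(tr@condition == "mod")
  perm <- vapply(seq_len(nPerm), function(i) {
    stat(seq_len(nTrials) %in% sample.int(nTrials, nMod))
  }, numeric(1))
  list(
    p = (1 + sum(abs(perm) >= abs(obs))) / (nPerm + 1),
    observed = obs, permuted = perm
  )
}

#' Compare simulated excitatory and inhibitory touch responses
#'
#' Summary of touch coefficients per class (ground-truth E/I labels are
#' available in simulation), for comparison with spike-shape-classified
#' recordings.
#'
#' @param tr a [TrialResult-class] or a [touchBetas()] data.frame.
#' @return data.frame with per-class n and median/IQR of the non-modulated
#'   and modulated touch coefficients.
#' @export
eiResponseComparison <- function(tr) {
  b <- if (is(tr, "TrialResult")) touchBetas(tr) else tr
  b <- b[!b$excluded, ]
  do.call(rbind, lapply(c(FALSE, TRUE), function(inh) {
    d <- b[b$inhibitory == inh, ]
    data.frame(
      class = if (inh) "inhibitory" else "excitatory", n = nrow(d),
      medianBetaNonmod = stats::median(d$betaNonmod),
      medianBetaMod = stats::median(d$betaMod),
      iqrBetaNonmod = stats::IQR(d$betaNonmod)
    )
  }))
}

#' Single-neuron membrane trace under constant current
#'
#' Exposes the network's exact integrator for one neuron with no synaptic
#' input and no threshold, for validation against the closed-form membrane
#' solution.
#'
#' @param V0 initial potential (mV).
#' @param Iext constant current (pA).
#' @param duration duration (ms).
#' @param config a [NetworkConfig-class] providing the constants.
#' @return data.frame with `time` (ms) and `V` (mV).
#' @export
membraneTrace <- function(V0, Iext, duration, config = microcircuitConfig()) {
  nrn <- config@neuron
  n <- round(duration / nrn$dt)
  v <- cpp_lif_single(V0, Iext, n, nrn$dt, nrn$tauM, nrn$Cm, nrn$Vr)
  data.frame(time = seq(0, duration, by = nrn$dt), V = v)
}
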