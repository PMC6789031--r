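#' @import methods
NULL

SEX_LEVELS <- c("F", "M")
AREA_LEVELS <- c("S1", "VMC", "ACC", "PrL", "A1")

#' Session: spike trains, touch episodes and recording blocks
#'
#' A `Session` holds everything recorded from one subject in one sitting:
#' per-unit spike times (seconds, sorted), the table of social facial touch
#' episodes (onset/offset in seconds plus partner identity and sex), and the
#' recording-block structure (consecutive blocks, typically each with one
#' interaction partner).
#'
#' @slot subjectId character scalar.
#' @slot subjectSex `"F"` or `"M"`.
#' @slot area cortical area label, one of S1, VMC, ACC, PrL, A1.
#' @slot blocks data.frame with columns `blockIndex`, `start`, `end` (s).
#' @slot episodes data.frame with columns `onset`, `offset` (s), `partnerId`,
#'   `partnerSex` (`"F"`/`"M"`), `blockIndex`.
#' @slot units named list of numeric vectors of sorted spike times (s).
#'
#' @exportClass Session
setClass("Session",
  representation(
    subjectId = "character",
    subjectSex = "character",
    area = "character",
    blocks = "data.frame",
    episodes = "data.frame",
    units = "list"
  )
)

validSession <- function(object) {
  msgs <- character()
  b <- object@blocks
  e <- object@episodes
  if (!all(c("blockIndex", "start", "end") %in% names(b))) {
    msgs <- c(msgs, "blocks must have columns blockIndex, start, end")
  }
  if (!all(c("onset", "offset", "partnerId", "partnerSex", "blockIndex") %in% names(e))) {
    msgs <- c(msgs, "episodes must have columns onset, offset, partnerId, partnerSex, blockIndex")
  }
  if (length(msgs)) return(msgs)
  if (!(object@subjectSex %in% SEX_LEVELS)) {
    msgs <- c(msgs, sprintf("unknown subject sex code '%s'", object@subjectSex))
  }
  if (!(object@area %in% AREA_LEVELS)) {
    msgs <- c(msgs, sprintf("unknown area '%s'", object@area))
  }
  if (nrow(b)) {
    if (is.unsorted(b$start)) msgs <- c(msgs, "blocks must be sorted by start")
    if (any(b$end <= b$start)) msgs <- c(msgs, "block end must exceed block start")
    if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)] - 1e-9)) {
      msgs <- c(msgs, "blocks must be non-overlapping")
    }
  }
  if (nrow(e)) {
    if (any(e$offset <= e$onset)) {
      msgs <- c(msgs, "episode offset must exceed onset")
    }
    if (is.unsorted(e$onset)) msgs <- c(msgs, "episodes must be sorted by onset")
    if (nrow(e) > 1L && any(e$onset[-1L] < e$offset[-nrow(e)] - 1e-9)) {
      msgs <- c(msgs, "episodes must be non-overlapping")
    }
    if (!all(e$partnerSex %in% SEX_LEVELS)) {
      msgs <- c(msgs, "unknown partner sex code in episodes")
    }
    # every episode inside exactly one block
    if (nrow(b)) {
      inBlock <- vapply(seq_len(nrow(e)), function(i) {
        hit <- which(e$onset[i] >= b$start - 1e-9 & e$offset[i] <= b$end + 1e-9)
        length(hit) == 1L && hit == e$blockIndex[i]
      }, logical(1))
      if (!all(inBlock)) {
        msgs <- c(msgs, "each episode must lie inside exactly one block (its blockIndex)")
      }
    }
  }
  send <- if (nrow(b)) max(b$end) else 0
  for (u in names(object@units)) {
    st <- object@units[[u]]
    if (length(st)) {
      if (is.unsorted(st)) msgs <- c(msgs, sprintf("spike times of unit '%s' must be sorted", u))
      if (min(st) < 0 || max(st) > send + 1e-9) {
        msgs <- c(msgs, sprintf("spike times of unit '%s' outside [0, session end]", u))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("Session", validSession)

#' Binned spike train on a 1-ms grid
#'
#' Half-open bins `[t, t + binWidth)`, zero-based in time: a spike at time
#' `t` falls in bin `floor(t / binWidth) + 1` (R indexing). `keptMask` marks
#' bins retained after baseline trimming; all likelihood computations run on
#' the retained bins only.
#'
#' @slot counts integer vector of per-bin spike counts.
#' @slot binWidth numeric, bin width in seconds (default 0.001).
#' @slot keptMask logical vector parallel to `counts`.
#'
#' @exportClass BinnedSpikeTrain
setClass("BinnedSpikeTrain",
  representation(counts = "integer", binWidth = "numeric", keptMask = "logical")
)

setValidity("BinnedSpikeTrain", function(object) {
  msgs <- character()
  if (length(object@binWidth) != 1L || object@binWidth <= 0) {
    msgs <- c(msgs, "binWidth must be a positive scalar")
  }
  if (any(object@counts < 0L)) msgs <- c(msgs, "counts must be non-negative")
  if (length(object@keptMask) != length(object@counts)) {
    msgs <- c(msgs, "keptMask must be parallel to counts")
  }
  if (length(msgs)) msgs else TRUE
})

#' Predictor matrix of the point-process GLM
#'
#' Rows are the retained 1-ms bins of one unit; columns are the constant,
#' eleven spike-history terms (five 1-ms bins covering the previous 0--5 ms
#' and six 25-ms bins covering 5--155 ms), `nRec - 1` recording indicators,
#' the touch indicator, and (optionally) the partner-sex indicator
#' (0 = female, 1 = male).
#'
#' @slot X numeric matrix with named columns.
#' @slot y integer response (spike counts of the retained bins).
#' @slot keptBins integer, original bin index of each row.
#' @slot binWidth numeric, seconds.
#' @slot includeSex logical.
#' @slot nRec integer, number of recording blocks.
#'
#' @exportClass PredictorMatrix
setClass("PredictorMatrix",
  representation(
    X = "matrix", y = "integer", keptBins = "integer",
    binWidth = "numeric", includeSex = "logical", nRec = "integer"
  )
)

setValidity("PredictorMatrix", function(object) {
  msgs <- character()
  if (nrow(object@X) != length(object@y)) msgs <- c(msgs, "nrow(X) must equal length(y)")
  if (nrow(object@X) != length(object@keptBins)) msgs <- c(msgs, "keptBins must index rows of X")
  expected <- 1L + 11L + (object@nRec - 1L) + 1L + as.integer(object@includeSex)
  if (ncol(object@X) != expected) {
    msgs <- c(msgs, sprintf("expected %d columns, found %d", expected, ncol(object@X)))
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted point-process GLM
#'
#' @slot beta named numeric coefficient vector.
#' @slot logLik numeric, full Poisson log likelihood in nats (including the
#'   `sum(y) * log(Delta) - sum(log y!)` constants, so values are comparable
#'   across model variants).
#' @slot converged logical.
#' @slot variant `"touch_only"` or `"touch_sex"`.
#' @slot nIter integer, Newton iterations used.
#' @slot gradNorm numeric, max absolute gradient at the optimum.
#'
#' @exportClass GLMFit
setClass("GLMFit",
  representation(
    beta = "numeric", logLik = "numeric", converged = "logical",
    variant = "character", nIter = "integer", gradNorm = "numeric"
  )
)

#' Layered LIF microcircuit configuration
#'
#' Population sizes, connection probabilities, background drive and neuron
#' constants of the eight-population cortical microcircuit plus its thalamic
#' input population. `scale` in (0, 1] shrinks population sizes; expected
#' synapse counts per target neuron (in-degrees) are preserved under scaling
#' so single-neuron input statistics stay approximately invariant.
#'
#' @slot N named numeric, neuron counts per population (8 cortical + Thal)
#'   at full scale.
#' @slot pConn 8 x 9 matrix of connection probabilities, rows = target
#'   population, columns = source population (including Thal).
#' @slot bg named numeric, background scaling factor b per cortical
#'   population; the background current is `b * 0.3512` pA.
#' @slot neuron list of neuron/synapse constants (tauM, Cm, Vr, Vth, tauRef,
#'   tauSyn in SI-style units noted in the constructor; weight and delay
#'   distribution parameters).
#' @slot scale numeric in (0, 1].
#'
#' @exportClass NetworkConfig
setClass("NetworkConfig",
  representation(
    N = "numeric", pConn = "matrix", bg = "numeric",
    neuron = "list", scale = "numeric"
  )
)

setValidity("NetworkConfig", function(object) {
  msgs <- character()
  if (length(object@N) != 9L) msgs <- c(msgs, "N must have 9 populations (8 cortical + Thal)")
  if (!all(dim(object@pConn) == c(8L, 9L))) msgs <- c(msgs, "pConn must be 8 x 9 (target x source)")
  if (any(object@pConn < 0 | object@pConn > 1)) msgs <- c(msgs, "pConn entries must lie in [0, 1]")
  if (length(object@scale) != 1L || object@scale <= 0 || object@scale > 1) {
    msgs <- c(msgs, "scale must lie in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of a simulated touch/neuromodulation experiment
#'
#' Per-sampled-neuron spike counts in the 700-ms windows before and after
#' simulated touch onset, per trial, with the trial condition schedule
#' (non-modulated and modulated trials interleaved).
#'
#' @slot countsBase integer matrix, sampled neurons x trials (pre-onset window).
#' @slot countsTouch integer matrix, sampled neurons x trials (post-onset window).
#' @slot condition character per trial, `"nonmod"` or `"mod"`.
#' @slot population character per sampled neuron.
#' @slot inhibitory logical per sampled neuron.
#' @slot neuronId integer, global index of each sampled neuron.
#' @slot window numeric, counting-window length in seconds (0.7).
#'
#' @exportClass TrialResult
setClass("TrialResult",
  representation(
    countsBase = "matrix", countsTouch = "matrix", condition = "character",
    population = "character", inhibitory = "logical", neuronId = "integer",
    window = "numeric"
  )
)

setValidity("TrialResult", function(object) {
  msgs <- character()
  if (!all(dim(object@countsBase) == dim(object@countsTouch))) {
    msgs <- c(msgs, "count matrices must have identical dimensions")
  }
  if (ncol(object@countsBase) != length(object@condition)) {
    msgs <- c(msgs, "one condition label per trial required")
  }
  if (nrow(object@countsBase) != length(object@population)) {
    msgs <- c(msgs, "one population label per sampled neuron required")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Session", function(object) {
  cat(sprintf(
    "Session: subject %s (%s), area %s\n  %d block(s) spanning %.1f s, %d touch episode(s), %d unit(s)\n",
    object@subjectId, object@subjectSex, object@area,
    nrow(object@blocks), sessionEnd(object), nrow(object@episodes),
    length(object@units)
  ))
  px <- unique(object@episodes[, c("partnerId", "partnerSex")])
  if (nrow(px)) {
    cat(sprintf(
      "  partners: %d female, %d male\n",
      sum(px$partnerSex == "F"), sum(px$partnerSex == "M")
    ))
  }
})

setMethod("show", "BinnedSpikeTrain", function(object) {
  cat(sprintf(
    "BinnedSpikeTrain: %d bins of %.3g ms, %d spikes, %d bins retained\n",
    length(object@counts), object@binWidth * 1e3, sum(object@counts),
    sum(object@keptMask)
  ))
})

setMethod("show", "GLMFit", function(object) {
  cat(sprintf(
    "GLMFit (%s): logLik %.2f nats, %sconverged in %d iterations\n",
    object@variant, object@logLik, if (object@converged) "" else "NOT ",
    object@nIter
  ))
  print(round(object@beta, 4))
})

setMethod("show", "NetworkConfig", function(object) {
  cat(sprintf(
    "NetworkConfig: %d cortical neurons (+%d thalamic) at scale %.3g\n",
    sum(scaledCounts(object)[1:8]), scaledCounts(object)[9], object@scale
  ))
})

setMethod("show", "TrialResult", function(object) {
  cat(sprintf(
    "TrialResult: %d sampled neurons, %d trials (%d non-modulated, %d modulated)\n",
    nrow(object@countsBase), ncol(object@countsBase),
    sum(object@condition == "nonmod"), sum(object@condition == "mod")
  ))
})
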