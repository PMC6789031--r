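#' Construct a Session
#'
#' Validates and assembles a session from its parts. Episodes are assigned a
#' `blockIndex` automatically when the column is absent (each episode must
#' then fall inside exactly one block).
#'
#' @param subjectId character scalar.
#' @param subjectSex `"F"` or `"M"`.
#' @param area one of `"S1"`, `"VMC"`, `"ACC"`, `"PrL"`, `"A1"`.
#' @param blocks data.frame with `blockIndex`, `start`, `end` (seconds).
#' @param episodes data.frame with `onset`, `offset`, `partnerId`,
#'   `partnerSex` and optionally `blockIndex`.
#' @param units named list of sorted numeric spike-time vectors (seconds).
#' @return a [Session-class].
#' @export
Session <- function(subjectId, subjectSex, area, blocks, episodes, units = list()) {
  blocks <- as.data.frame(blocks)
  episodes <- as.data.frame(episodes)
  blocks$blockIndex <- as.integer(blocks$blockIndex)
  if (nrow(episodes) && !"blockIndex" %in% names(episodes)) {
    episodes$blockIndex <- vapply(seq_len(nrow(episodes)), function(i) {
      hit <- which(episodes$onset[i] >= blocks$start - 1e-9 &
        episodes$offset[i] <= blocks$end + 1e-9)
      if (length(hit) != 1L) {
        stop(sprintf(
          "episode %d [%.3f, %.3f] does not lie inside exactly one block",
          i, episodes$onset[i], episodes$offset[i]
        ))
      }
      blocks$blockIndex[hit]
    }, integer(1))
  }
  if (nrow(episodes)) {
    episodes$partnerId <- as.character(episodes$partnerId)
    episodes$partnerSex <- as.character(episodes$partnerSex)
    episodes$blockIndex <- as.integer(episodes$blockIndex)
  }
  units <- lapply(units, as.numeric)
  s <- new("Session",
    subjectId = as.character(subjectId), subjectSex = as.character(subjectSex),
    area = as.character(area), blocks = blocks, episodes = episodes,
    units = units
  )
  px <- unique(episodes[, c("partnerId", "partnerSex")])
  if (nrow(px) && (sum(px$partnerSex == "F") < 2L || sum(px$partnerSex == "M") < 2L)) {
    warning("fewer than 2 partners of each sex; partner-sex shuffling will be weak or undefined")
  }
  s
}

#' Read / write a session bundle
#'
#' A session is stored as a directory holding `session.json` (subject,
#' area, blocks), `episodes.csv` (columns `onset_s`, `offset_s`,
#' `partner_id`, `partner_sex`, `block_index`) and one `unit_<id>.csv`
#' spike-time file per unit. Validation errors are raised, never silently
#' repaired.
#'
#' @param path directory of the bundle.
#' @return `readSession` returns a [Session-class]; `writeSession` returns
#'   `path` invisibly.
#' @export
readSession <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "session.json"), simplifyVector = TRUE)
  ep <- utils::read.csv(file.path(path, "episodes.csv"), stringsAsFactors = FALSE)
  need <- c("onset_s", "offset_s", "partner_id", "partner_sex")
  if (!all(need %in% names(ep))) {
    stop("episodes.csv must have columns onset_s, offset_s, partner_id, partner_sex")
  }
  episodes <- data.frame(
    onset = ep$onset_s, offset = ep$offset_s,
    partnerId = as.character(ep$partner_id), partnerSex = as.character(ep$partner_sex),
    stringsAsFactors = FALSE
  )
  if ("block_index" %in% names(ep)) episodes$blockIndex <- as.integer(ep$block_index)
  ufiles <- sort(list.files(path, pattern = "^unit_.*\\.csv$", full.names = TRUE))
  units <- lapply(ufiles, function(f) utils::read.csv(f)$spike_time_s)
  names(units) <- sub("^unit_(.*)\\.csv$", "\\1", basename(ufiles))
  Session(
    subjectId = meta$subject_id, subjectSex = meta$subject_sex, area = meta$area,
    blocks = data.frame(
      blockIndex = as.integer(meta$blocks$block_index),
      start = meta$blocks$start_s, end = meta$blocks$end_s
    ),
    episodes = episodes, units = units
  )
}

#' @param session a [Session-class].
#' @rdname readSession
#' @export
writeSession <- function(session, path) {
  stopifnot(is(session, "Session"))
  validObject(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  b <- blocks(session)
  meta <- list(
    subject_id = session@subjectId, subject_sex = session@subjectSex,
    area = session@area,
    blocks = data.frame(block_index = b$blockIndex, start_s = b$start, end_s = b$end)
  )
  jsonlite::write_json(meta, file.path(path, "session.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  e <- episodes(session)
  utils::write.csv(
    data.frame(
      onset_s = e$onset, offset_s = e$offset, partner_id = e$partnerId,
      partner_sex = e$partnerSex, block_index = e$blockIndex
    ),
    file.path(path, "episodes.csv"),
    row.names = FALSE
  )
  for (u in unitIds(session)) {
    utils::write.csv(data.frame(spike_time_s = spikeTimes(session, u)),
      file.path(path, sprintf("unit_%s.csv", u)),
      row.names = FALSE
    )
  }
  invisible(path)
}

#' Behavioral timing summaries of touch episodes
#'
#' Durations are `offset - onset`; inter-touch intervals run from each
#' offset to the next onset. Returns medians and interquartile ranges in
#' seconds; with fewer than two episodes the interval summary is empty.
#'
#' @param episodes data.frame with `onset` and `offset` columns (seconds),
#'   sorted by onset, or a [Session-class].
#' @return list with elements `durations` and `intervals`, each a list
#'   holding `values`, `median`, `iqr` (length-2 numeric, 25% and 75%).
#' @export
touchStatistics <- function(episodes) {
  if (is(episodes, "Session")) episodes <- episodes(episodes)
  summarise <- function(v) {
    if (!length(v)) {
      return(list(values = numeric(0), median = NA_real_, iqr = c(NA_real_, NA_real_)))
    }
    list(
      values = v, median = stats::median(v),
      iqr = unname(stats::quantile(v, c(0.25, 0.75)))
    )
  }
  dur <- episodes$offset - episodes$onset
  itv <- if (nrow(episodes) > 1L) {
    episodes$onset[-1L] - episodes$offset[-nrow(episodes)]
  } else {
    numeric(0)
  }
  list(durations = summarise(dur), intervals = summarise(itv))
}

#' Bin spike times on the 1-ms grid
#'
#' Half-open bins: a spike at time `t` increments bin `floor(t / binWidth)`.
#' The total count is conserved for any input within `[0, sessionEnd)`.
#'
#' @param spikeTimes sorted numeric spike times (s).
#' @param sessionEnd session end time (s); the grid covers `[0, sessionEnd)`.
#' @param binWidth bin width in seconds (default 1 ms).
#' @return a [BinnedSpikeTrain-class] with all bins initially retained.
#' @export
binSpikes <- function(spikeTimes, sessionEnd, binWidth = 1e-3) {
  if (length(spikeTimes) && min(spikeTimes) < 0) stop("negative spike times are not allowed")
  nBins <- as.integer(ceiling(sessionEnd / binWidth - 1e-9))
  if (length(spikeTimes) && max(spikeTimes) >= nBins * binWidth) {
    stop("spike times must lie within [0, sessionEnd)")
  }
  idx <- pmin(as.integer(floor(spikeTimes / binWidth)) + 1L, nBins)
  counts <- integer(nBins)
  if (length(idx)) {
    tab <- tabulate(idx, nbins = nBins)
    counts <- as.integer(tab)
  }
  new("BinnedSpikeTrain",
    counts = counts, binWidth = binWidth,
    keptMask = rep(TRUE, nBins)
  )
}

#' Trim baseline bins far from any social interaction
#'
#' Marks as retained only bins whose center lies within `margin` seconds of
#' the nearest touch-episode boundary (bins inside an episode are always
#' retained). The removed bins are excluded from all likelihoods downstream;
#' their spike counts still feed the spike-history predictors, since those
#' spikes were emitted.
#'
#' @param bst a [BinnedSpikeTrain-class].
#' @param episodes data.frame with `onset`/`offset` columns, sorted.
#' @param margin seconds (default 5); `Inf` keeps every bin.
#' @return the train with an updated `keptMask`.
#' @export
trimBaseline <- function(bst, episodes, margin = 5) {
  stopifnot(is(bst, "BinnedSpikeTrain"))
  if (is(episodes, "Session")) episodes <- episodes(episodes)
  n <- length(binCounts(bst))
  if (!nrow(episodes)) {
    bst@keptMask <- rep(is.infinite(margin), n)
    return(bst)
  }
  if (is.infinite(margin)) {
    bst@keptMask <- rep(TRUE, n)
    return(bst)
  }
  centers <- (seq_len(n) - 0.5) * binWidth(bst)
  kept <- rep(FALSE, n)
  for (i in seq_len(nrow(episodes))) {
    lo <- episodes$onset[i] - margin
    hi <- episodes$offset[i] + margin
    kept[centers >= lo & centers <= hi] <- TRUE
  }
  bst@keptMask <- kept
  bst
}

#' Causal alpha (PSP-shaped) smoothing kernel
#'
#' `f(x) = (x / tau) * exp(1 - x / tau)` for `x >= 0`, zero for `x < 0`.
#' The peak value is 1, reached at `x = tau`.
#'
#' @param x numeric, seconds.
#' @param tau kernel time constant in seconds (default 0.075).
#' @export
alphaKernel <- function(x, tau = 0.075) {
  ifelse(x < 0, 0, (x / tau) * exp(1 - x / tau))
}

#' Peri-stimulus time histogram with alpha-kernel smoothing
#'
#' Aligns a unit's spikes to episode onsets, smooths each trial with the
#' causal alpha kernel (normalized to unit integral so traces are in
#' spikes/s) and averages across episodes; the shaded-variability
#' convention is the s.e.m. across episodes. A paired Wilcoxon signed-rank
#' test compares the mean rate per episode in the baseline window with the
#' post-onset window.
#'
#' @param spikeTimes numeric spike times (s) or a [Session-class] together
#'   with `unit`.
#' @param onsets episode onset times (s). Taken from the session when a
#'   session is supplied.
#' @param unit unit id when `spikeTimes` is a session.
#' @param window alignment window in seconds, default `c(-2.5, 1)`.
#' @param tau alpha-kernel time constant (s), default 0.075.
#' @param baselineWindow window for the rate comparison, default
#'   `c(-2.5, 0)` (a `c(-2, 0)` convention is selectable).
#' @param postWindow post-onset window, default `c(0, 0.5)`.
#' @param dt evaluation grid step (s).
#' @return list with `time`, `mean` (spikes/s), `sem`, per-trial matrix
#'   `trials`, and `test` (the Wilcoxon result, or `NULL` with a warning
#'   when fewer than two onsets are available).
#' @export
psth <- function(spikeTimes, onsets = NULL, unit = NULL, window = c(-2.5, 1),
                 tau = 0.075, baselineWindow = c(-2.5, 0), postWindow = c(0, 0.5),
                 dt = 1e-3) {
  if (is(spikeTimes, "Session")) {
    session <- spikeTimes
    if (is.null(unit)) stop("supply a unit id with a session")
    spikeTimes <- spikeTimes(session, unit)
    if (is.null(onsets)) onsets <- episodes(session)$onset
  }
  grid <- seq(window[1], window[2], by = dt)
  norm <- 1 / (exp(1) * tau) # unit-integral normalization of the alpha kernel
  trials <- matrix(0, nrow = length(onsets), ncol = length(grid))
  for (i in seq_along(onsets)) {
    rel <- spikeTimes - onsets[i]
    rel <- rel[rel >= window[1] - 8 * tau & rel <= window[2]]
    if (length(rel)) {
      for (s in rel) trials[i, ] <- trials[i, ] + alphaKernel(grid - s, tau) * norm
    }
  }
  test <- NULL
  if (length(onsets) >= 2L) {
    rateIn <- function(w) {
      vapply(onsets, function(o) {
        sum(spikeTimes >= o + w[1] & spikeTimes < o + w[2]) / diff(w)
      }, numeric(1))
    }
    base <- rateIn(baselineWindow)
    post <- rateIn(postWindow)
    test <- suppressWarnings(stats::wilcox.test(post, base, paired = TRUE, exact = FALSE))
  } else {
    warning("fewer than 2 onsets; baseline-vs-post test skipped")
  }
  list(
    time = grid,
    mean = colMeans(trials),
    sem = apply(trials, 2, stats::sd) / sqrt(max(1L, nrow(trials))),
    trials = trials,
    test = test
  )
}
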