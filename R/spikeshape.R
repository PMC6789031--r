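#' Extract spike-shape features from a mean waveform
#'
#' The average spike is oversampled at twice the sampling rate with
#' cubic-spline interpolation; the two features are the spike width at half
#' of the peak amplitude and the "post-positivity": the integral of the
#' waveform between 0.375 and 0.75 ms after the spike peak, normalized by
#' the peak voltage. Both are invariant to uniform amplitude scaling.
#'
#' @param waveform numeric vector of voltage samples (spike peak positive).
#' @param samplingRate samples per second.
#' @return list with `widthHalfMax` (ms) and `postPositivity`
#'   (dimensionless).
#' @export
extractFeatures <- function(waveform, samplingRate) {
  n <- length(waveform)
  t <- (seq_len(n) - 1L) / samplingRate # seconds
  sp <- stats::spline(t, waveform, n = 2L * n)
  ti <- sp$x
  vi <- sp$y
  ip <- which.max(vi)
  peak <- vi[ip]
  if (peak <= 0) stop("waveform has no positive peak")
  tPeak <- ti[ip]
  if (tPeak + 0.75e-3 > ti[length(ti)] + 1e-12) {
    stop("post-peak window (0.375-0.75 ms) exceeds the waveform")
  }
  half <- peak / 2
  # width at half maximum: linear interpolation of the crossings flanking
  # the peak on the oversampled trace
  crossLeft <- NA_real_
  for (i in seq(ip, 2L)) {
    if (vi[i - 1] < half && vi[i] >= half) {
      f <- (half - vi[i - 1]) / (vi[i] - vi[i - 1])
      crossLeft <- ti[i - 1] + f * (ti[i] - ti[i - 1])
      break
    }
  }
  crossRight <- NA_real_
  for (i in seq(ip, length(vi) - 1L)) {
    if (vi[i] >= half && vi[i + 1] < half) {
      f <- (vi[i] - half) / (vi[i] - vi[i + 1])
      crossRight <- ti[i] + f * (ti[i + 1] - ti[i])
      break
    }
  }
  if (is.na(crossLeft) || is.na(crossRight)) {
    stop("waveform does not fall below half maximum on both sides of the peak")
  }
  # trapezoid integral over [tPeak + 0.375 ms, tPeak + 0.75 ms], on a dense
  # grid interpolated from the oversampled trace
  lim <- tPeak + c(0.375e-3, 0.75e-3)
  grid <- seq(lim[1], lim[2], length.out = 201L)
  vg <- stats::spline(t, waveform, xout = grid)$y
  integral <- sum((vg[-1] + vg[-length(vg)]) / 2 * diff(grid))
  list(
    widthHalfMax = (crossRight - crossLeft) * 1e3,
    postPositivity = integral / peak * 1e3 # per-ms normalization keeps O(1)
  )
}

#' Feature table for a set of mean waveforms
#'
#' @param waveforms matrix, one unit per row, common sample grid.
#' @param samplingRate samples per second.
#' @return data.frame with `widthHalfMax` (ms) and `postPositivity`.
#' @export
extractFeaturesMatrix <- function(waveforms, samplingRate) {
  out <- t(apply(waveforms, 1, function(w) {
    f <- extractFeatures(w, samplingRate)
    c(f$widthHalfMax, f$postPositivity)
  }))
  data.frame(widthHalfMax = out[, 1], postPositivity = out[, 2])
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance feature; cannot standardize")
  (x - mean(x)) / s
}

# two-component full-covariance EM with additive diagonal regularization
gmm2 <- function(Z, regularization = 0.1, maxIter = 200L, tol = 1e-8) {
  n <- nrow(Z)
  km <- stats::kmeans(Z, centers = 2L, nstart = 5L)
  r <- cbind(as.numeric(km$cluster == 1L), as.numeric(km$cluster == 2L))
  r <- pmax(r, 0.05)
  r <- r / rowSums(r)
  logdens <- function(Z, mu, S) {
    ch <- chol(S)
    d <- forwardsolve(t(ch), t(Z) - mu)
    -colSums(d^2) / 2 - sum(log(diag(ch))) - log(2 * pi)
  }
  ll0 <- -Inf
  for (it in seq_len(maxIter)) {
    pi_k <- colMeans(r)
    mu <- lapply(1:2, function(k) colSums(Z * r[, k]) / sum(r[, k]))
    S <- lapply(1:2, function(k) {
      d <- sweep(Z, 2, mu[[k]])
      (t(d * r[, k]) %*% d) / sum(r[, k]) + diag(regularization, 2)
    })
    lg <- vapply(1:2, function(k) log(pi_k[k]) + logdens(Z, mu[[k]], S[[k]]),
      numeric(n)
    )
    m <- pmax(lg[, 1], lg[, 2])
    ll <- sum(m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m)))
    r <- exp(lg - m)
    r <- r / rowSums(r)
    if (is.finite(ll0) && abs(ll - ll0) < tol * abs(ll0)) break
    ll0 <- ll
  }
  list(resp = r, mu = mu, S = S, pi = pi_k, logLik = ll)
}

#' Classify units into putative E/I classes by a two-component GMM
#'
#' Features are z-scored per dimension, a two-component full-covariance
#' Gaussian mixture is fitted by EM (k-means initialization, additive 0.1
#' diagonal covariance regularization on the standardized scale), and units
#' are assigned by posterior responsibility. The thin-spiked component
#' (smaller mean width) is labeled `putative_I`. A degenerate mixture (an
#' effectively empty component) triggers the single-Gaussian fallback cut.
#'
#' @param features data.frame with `widthHalfMax` and `postPositivity`.
#' @param regularization additive diagonal covariance term (default 0.1).
#' @param seed optional RNG seed (k-means initialization).
#' @return the input with columns `class` (`putative_I`/`putative_E`) and
#'   `posterior` (responsibility of the assigned class); the fallback, if
#'   triggered, is noted in attribute `method`.
#' @export
classifyWaveforms <- function(features, regularization = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Z <- cbind(zscore(features$widthHalfMax), zscore(features$postPositivity))
  fit <- tryCatch(gmm2(Z, regularization), error = function(e) NULL)
  degenerate <- is.null(fit) ||
    min(colSums(fit$resp > 0.5)) == 0L || min(fit$pi) < 1e-3
  if (degenerate) {
    out <- classifyFallbackCut(features)
    attr(out, "method") <- "fallback_cut"
    return(out)
  }
  hard <- max.col(fit$resp)
  meanWidth <- vapply(1:2, function(k) {
    stats::weighted.mean(features$widthHalfMax, fit$resp[, k])
  }, numeric(1))
  thin <- which.min(meanWidth)
  features$class <- ifelse(hard == thin, "putative_I", "putative_E")
  features$posterior <- fit$resp[cbind(seq_len(nrow(Z)), hard)]
  attr(features, "method") <- "gmm"
  features
}

#' Single-Gaussian fallback cut
#'
#' When the feature cloud is not bimodal, a single 2-d Gaussian is fitted
#' and the distribution is cut through its mean along the shortest axis:
#' units are split by the sign of their projection onto the principal axis
#' with the largest variance. The thin-spiked side is labeled `putative_I`.
#'
#' @param features data.frame with `widthHalfMax` and `postPositivity`.
#' @return the input with a `class` column; attribute `method` set to
#'   `"fallback_cut"`.
#' @export
classifyFallbackCut <- function(features) {
  Z <- cbind(zscore(features$widthHalfMax), zscore(features$postPositivity))
  S <- stats::cov(Z)
  if (!all(is.finite(S)) || sum(diag(S)) == 0) stop("zero covariance; cut undefined")
  eg <- eigen(S, symmetric = TRUE)
  if (abs(eg$values[1] - eg$values[2]) < 1e-8 * sum(abs(eg$values))) {
    warning("near-isotropic feature cloud; axis choice degenerate, first principal direction used")
  }
  proj <- sweep(Z, 2, colMeans(Z)) %*% eg$vectors[, 1]
  side <- proj[, 1] > 0
  wA <- mean(features$widthHalfMax[side])
  wB <- mean(features$widthHalfMax[!side])
  features$class <- ifelse(side == (wA < wB), "putative_I", "putative_E")
  attr(features, "method") <- "fallback_cut"
  features
}
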