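test_that("log-normal calibration solves the printed quantiles", {
  p <- lognormalFromQuantiles(1.33, 0.77, 2.53)
  expect_equal(p$meanlog, log(1.33))
  expect_equal(p$sdlog, (log(2.53) - log(0.77)) / (2 * qnorm(0.75)))
  # population quartiles of the solved law reproduce the inputs approximately
  expect_equal(qlnorm(0.5, p$meanlog, p$sdlog), 1.33, tolerance = 1e-12)
  # degenerate law: zero spread collapses to the median
  d0 <- list(duration = list(meanlog = log(1.33), sdlog = 0), interval = list(meanlog = log(4.68), sdlog = 0))
  expect_equal(sampleTouchDurations(5, d0), rep(1.33, 5))
})

test_that("episode generator tiles valid episodes into blocks", {
  set.seed(3)
  g <- generateEpisodes(nBlocks = 4, blockLength = 400)
  ep <- g$episodes
  expect_true(all(ep$offset > ep$onset))
  expect_false(is.unsorted(ep$onset))
  expect_true(all(ep$onset[-1] >= ep$offset[-nrow(ep)]))
  for (i in seq_len(nrow(ep))) {
    b <- g$blocks[ep$blockIndex[i], ]
    expect_true(ep$onset[i] >= b$start && ep$offset[i] <= b$end)
  }
  # one partner per block
  perBlock <- tapply(ep$partnerId, ep$blockIndex, function(x) length(unique(x)))
  expect_true(all(perBlock == 1L))
  # durations follow the calibrated law (generous Monte-Carlo tolerance)
  set.seed(4)
  g2 <- generateEpisodes(nBlocks = 3, blockLength = 2000)
  durs <- g2$episodes$offset - g2$episodes$onset
  expect_gt(length(durs), 50)
  expect_lt(abs(median(durs) - 1.33), 0.35)
})

test_that("forward simulator reproduces homogeneous and e-fold rates", {
  blocks <- data.frame(blockIndex = 1L, start = 0, end = 200)
  ep <- data.frame(
    onset = seq(5, 190, by = 10), offset = seq(7, 192, by = 10),
    partnerId = "a", partnerSex = "F", blockIndex = 1L
  )
  tb0 <- unitTrueBeta(beta0 = log(5), h = rep(0, 11), betaTouch = 0)
  set.seed(1)
  bst <- generateSpikeTrain(blocks, ep, tb0)
  expect_equal(sum(binCounts(bst)) / 200, 5, tolerance = 0.1)
  # betaTouch = 1: rate inside touch is e-fold the baseline rate
  tb1 <- unitTrueBeta(beta0 = log(5), h = rep(0, 11), betaTouch = 1)
  set.seed(2)
  rates <- replicate(5, {
    b1 <- generateSpikeTrain(blocks, ep, tb1)
    centers <- (seq_along(binCounts(b1)) - 0.5) * 1e-3
    inT <- rep(FALSE, length(centers))
    for (i in seq_len(nrow(ep))) inT[centers >= ep$onset[i] & centers < ep$offset[i]] <- TRUE
    c(sum(binCounts(b1)[inT]) / sum(inT), sum(binCounts(b1)[!inT]) / sum(!inT))
  })
  ratio <- mean(rates[1, ]) / mean(rates[2, ])
  expect_equal(ratio, exp(1), tolerance = 0.1)
})

test_that("refractory history suppresses short ISIs, matching a thinning sampler", {
  blocks <- data.frame(blockIndex = 1L, start = 0, end = 60)
  ep <- data.frame(
    onset = 20, offset = 22, partnerId = "a", partnerSex = "F",
    blockIndex = 1L
  )
  tb <- unitTrueBeta(beta0 = log(20), h = c(-6, -6, -3, -1, -0.5, rep(0, 6)))
  set.seed(5)
  bst <- generateSpikeTrain(blocks, ep, tb)
  st <- which(binCounts(bst) > 0)
  isi <- diff(st) # ms
  expect_gt(length(isi), 200)
  pShort <- mean(isi <= 2)
  # independent oracle: direct Bernoulli/thinning sampler written in R,
  # sharing nothing with the C++ path
  set.seed(5)
  n <- 60000L
  y <- integer(n)
  for (i in seq_len(n)) {
    eta <- log(20)
    for (k in 1:5) if (i - k >= 1) eta <- eta + tb$h[k] * y[i - k]
    # window history terms are zero in tb, so only the 1-ms lags matter here
    y[i] <- rpois(1, 1e-3 * exp(eta))
  }
  ys <- which(y > 0)
  pRef <- mean(diff(ys) <= 2)
  # both samplers show a refractory dip relative to a homogeneous train
  lambdaHz <- sum(binCounts(bst)) / 60
  pHomog <- 1 - exp(-lambdaHz * 2e-3) # P(next spike within 2 ms) if Poisson
  expect_lt(pShort, pHomog / 3)
  expect_lt(abs(pShort - pRef), 0.02)
})

test_that("generators are bit-reproducible under a fixed seed", {
  set.seed(99)
  s1 <- suppressWarnings(generateSession(nBlocks = 2, blockLength = 30))
  set.seed(99)
  s2 <- suppressWarnings(generateSession(nBlocks = 2, blockLength = 30))
  expect_identical(episodes(s1), episodes(s2))
  expect_identical(spikeTimes(s1, "u1"), spikeTimes(s2, "u1"))
  set.seed(7)
  w1 <- generateWaveformFeatures()
  set.seed(7)
  w2 <- generateWaveformFeatures()
  expect_identical(w1, w2)
})

test_that("population generator produces the requested geometry", {
  set.seed(11)
  diag0 <- generatePopulation(bias = 0, slope = 1, subjectSd = 0, noiseSd = 0)
  expect_equal(diag0$maleLog2, diag0$femaleLog2, tolerance = 1e-12)
  set.seed(12)
  pot <- generatePopulation(nPerSubject = 100, slope = 0.6, noiseSd = 0.1, subjectSd = 0)
  fit <- lm(maleLog2 ~ femaleLog2, data = pot)
  expect_equal(unname(coef(fit)[2]), 0.6, tolerance = 0.05)
  expect_identical(attr(pot, "truth")$slope, 0.6)
})

test_that("waveform-feature generator covers its boundary cases", {
  set.seed(13)
  single <- generateWaveformFeatures(n = c(0, 50))
  expect_equal(unique(single$class), "putative_E")
  expect_equal(nrow(single), 50)
  both <- generateWaveformFeatures(n = c(30, 60))
  expect_equal(table(both$class)[["putative_I"]], 30)
  expect_true(all(both$widthHalfMax > 0))
})
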