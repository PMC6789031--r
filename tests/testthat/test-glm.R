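test_that("predictor matrix has the 5+6 history layout and correct width", {
  set.seed(21)
  s <- suppressWarnings(generateSession(
    nBlocks = 4, blockLength = 10,
    partners = fourPartners, params = denseTiming()
  ))
  pm <- buildPredictorMatrix(s, "u1", includeSex = TRUE)
  expect_equal(ncol(designMatrix(pm)), 17) # 1 + 11 + 3 + 1 + 1
  expect_equal(
    colnames(designMatrix(pm)),
    c("const", paste0("h", 1:11), paste0("rec", 2:4), "touch", "sex")
  )
  pmT <- buildPredictorMatrix(s, "u1", includeSex = FALSE)
  expect_equal(ncol(designMatrix(pmT)), 16)
  # total count conserved between rows and the retained spike train
  expect_equal(sum(response(pm)), sum(response(pmT)))
})

test_that("history columns equal brute-force windowed counts", {
  # a unit with spikes at known lags plus a random train
  set.seed(22)
  s <- suppressWarnings(generateSession(
    units = list(u1 = unitTrueBeta(beta0 = log(20), h = rep(0, 11))),
    nBlocks = 2, blockLength = 12, partners = fourPartners,
    params = denseTiming()
  ))
  pm <- buildPredictorMatrix(s, "u1", includeSex = FALSE, margin = Inf)
  X <- designMatrix(pm)
  counts <- binCounts(binSpikes(spikeTimes(s, "u1"), sessionEnd(s)))
  lagWindows <- c(lapply(1:5, function(k) c(k, k)), lapply(0:5, function(w) c(6 + 25 * w, 30 + 25 * w)))
  rows <- sample(nrow(X), 200)
  for (r in rows) {
    i <- pm@keptBins[r]
    for (k in 1:11) {
      win <- lagWindows[[k]]
      lo <- i - win[2]
      hi <- i - win[1]
      expected <- if (hi >= 1) sum(counts[max(1, lo):hi]) else 0
      expect_identical(unname(X[r, k + 1]), as.numeric(expected))
    }
  }
  # an isolated spike k bins back shows up in h_k alone (of the 1-ms lags)
  j <- which(counts == 1)[1] + 4L
  r4 <- which(pm@keptBins == j)
  if (length(r4) && sum(counts[(j - 5):(j - 1)]) == 1) {
    expect_equal(unname(X[r4, paste0("h", 1:5)]), c(0, 0, 0, 1, 0))
  }
})

test_that("log likelihood matches the closed form and per-bin Poisson pmf", {
  # silent unit, beta = [log 1000, 0...]: lambda * Delta = 1, LL = -nKept
  s <- tinySession()
  s@units$silent <- numeric(0)
  pm <- buildPredictorMatrix(s, "silent", includeSex = FALSE)
  beta0 <- c(log(1000), rep(0, ncol(designMatrix(pm)) - 1))
  expect_equal(ppLogLik(beta0, pm), -nrow(designMatrix(pm)), tolerance = 1e-9)
  # random coefficients against independent dpois() summation
  set.seed(23)
  s2 <- suppressWarnings(generateSession(
    nBlocks = 2, blockLength = 10,
    partners = fourPartners, params = denseTiming()
  ))
  pm2 <- buildPredictorMatrix(s2, "u1", includeSex = TRUE)
  for (i in 1:5) {
    beta <- rnorm(ncol(designMatrix(pm2)), 0, 0.3)
    beta[1] <- log(5) + rnorm(1, 0, 0.2)
    oracle <- sum(dpois(
      response(pm2),
      exp(designMatrix(pm2) %*% beta) * 1e-3, log = TRUE
    ))
    expect_equal(ppLogLik(beta, pm2), oracle, tolerance = 1e-9 * abs(oracle))
  }
  # incremental identity: one extra spike in a bin changes LL by
  # log(lambda * Delta) - log(y + 1)
  r <- 50L
  pm3 <- pm2
  pm3@y[r] <- pm3@y[r] + 1L
  beta <- c(log(5), rep(0, ncol(designMatrix(pm2)) - 1))
  lam <- exp(designMatrix(pm2)[r, , drop = FALSE] %*% beta) * 1e-3
  expect_equal(
    ppLogLik(beta, pm3) - ppLogLik(beta, pm2),
    drop(log(lam)) - log(pm2@y[r] + 1),
    tolerance = 1e-9
  )
})

test_that("Newton fit matches independent IRLS and recovers a constant rate", {
  set.seed(24)
  s <- suppressWarnings(generateSession(
    units = list(u1 = unitTrueBeta(
      beta0 = log(12), h = c(-1, -0.5, -0.2, -0.1, 0, rep(0, 6)),
      betaTouch = 0.4, betaSex = 0.2
    )),
    nBlocks = 4, blockLength = 15, partners = fourPartners,
    params = denseTiming()
  ))
  pm <- buildPredictorMatrix(s, "u1")
  fit <- fitUnitModel(pm)
  expect_true(converged(fit))
  g <- glm.fit(designMatrix(pm), response(pm),
    family = poisson(),
    offset = rep(log(1e-3), nrow(designMatrix(pm))),
    control = list(epsilon = 1e-12, maxit = 50)
  )
  expect_lt(max(abs(coef(fit) - g$coefficients)), 1e-6)
  expect_equal(logLik(fit), ppLogLik(coef(fit), pm), tolerance = 1e-10)
  # homogeneous unit: constant coefficient recovers log rate
  set.seed(25)
  sh <- suppressWarnings(generateSession(
    units = list(u1 = unitTrueBeta(beta0 = log(8), h = rep(0, 11))),
    nBlocks = 2, blockLength = 40, partners = fourPartners,
    params = denseTiming()
  ))
  fh <- fitUnitModel(sh, "u1", includeSex = FALSE)
  expect_equal(coef(fh)[["const"]], log(8), tolerance = 0.15)
})

test_that("MLE dominates the generator's coefficients and nesting holds", {
  for (seed in 26:28) {
    set.seed(seed)
    tb <- unitTrueBeta(betaTouch = 0.3, betaSex = 0.2)
    s <- suppressWarnings(generateSession(
      units = list(u1 = tb), nBlocks = 4,
      blockLength = 12, partners = fourPartners, params = denseTiming()
    ))
    pm <- buildPredictorMatrix(s, "u1")
    fit <- fitUnitModel(pm)
    trueBeta <- c(tb$beta0, tb$h, rep(0, 3), tb$betaTouch, tb$betaSex)
    expect_gte(logLik(fit), ppLogLik(trueBeta, pm) - 1e-8)
    fitT <- fitUnitModel(s, "u1", includeSex = FALSE)
    expect_lte(logLik(fitT), logLik(fit) + 1e-6) # nested models
  }
})

test_that("classification rules follow the two p-value criteria", {
  expect_equal(classifyUnit(0.6, 0.03), "sex_touch") # sex criterion alone suffices
  expect_equal(classifyUnit(0.03, 0.5), "touch")
  expect_equal(classifyUnit(0.5, 0.5), "nonsignificant")
  expect_equal(classifyUnit(0.03, 0.03), "sex_touch")
  expect_equal(classifyUnit(0.6, 0.03, alpha = 0.01), "nonsignificant")
})

test_that("touch shuffle has power for strong touch responses", {
  hits <- 0L
  for (seed in 31:33) {
    set.seed(seed)
    s <- suppressWarnings(generateSession(
      units = list(u1 = unitTrueBeta(betaTouch = 0.8)),
      nBlocks = 4, blockLength = 20, partners = fourPartners,
      params = denseTiming()
    ))
    if (shuffleTouchTest(s, "u1", 100)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 2)
})

test_that("sex shuffle enumerates assignments, saturates with 2+2 partners", {
  set.seed(34)
  s <- suppressWarnings(generateSession(
    units = list(u1 = unitTrueBeta(betaTouch = 0.5, betaSex = 1.2)),
    nBlocks = 4, blockLength = 20, partners = fourPartners,
    params = denseTiming()
  ))
  r <- shuffleSexTest(s, "u1", 100)
  expect_equal(r$nAssignments, 5) # C(4,2) - identity
  expect_gte(r$p, 1 / 6)
  # with 4+4 partners a strong effect is detectable
  hits <- 0L
  for (seed in 35:37) {
    set.seed(seed)
    repeat {
      s8 <- suppressWarnings(generateSession(
        units = list(u1 = unitTrueBeta(betaTouch = 0.4, betaSex = 0.9)),
        nBlocks = 8, blockLength = 12, partners = eightPartners,
        params = denseTiming()
      ))
      if (length(unique(episodes(s8)$partnerId)) == 8L) break
    }
    if (shuffleSexTest(s8, "u1", 100)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 2)
  # single-sex partner set: undefined, p = 1 with a warning
  oneSex <- data.frame(id = c("f1", "f2"), sex = c("F", "F"))
  set.seed(38)
  s1 <- suppressWarnings(generateSession(
    nBlocks = 2, blockLength = 20,
    partners = oneSex, params = denseTiming()
  ))
  expect_warning(r1 <- shuffleSexTest(s1, "u1", 50), "one sex")
  expect_equal(r1$p, 1)
})

test_that("model-predicted PSTH reflects the fitted modulation", {
  set.seed(39)
  s <- suppressWarnings(generateSession(
    units = list(u1 = unitTrueBeta(beta0 = log(10), h = rep(0, 11), betaTouch = 0.2, betaSex = 0.8)),
    nBlocks = 8, blockLength = 15, partners = fourPartners,
    params = denseTiming()
  ))
  fit <- fitUnitModel(s, "u1")
  mp <- modelPsth(fit, s, nSim = 8)
  expect_named(mp, c("F", "M"))
  inTouch <- mp$F$time > 0.05 & mp$F$time < 0.45
  ratio <- mean(mp$M$mean[inTouch]) / mean(mp$F$mean[inTouch])
  expect_gt(ratio, 1) # male-partner touch drives the higher predicted rate
  # smoothing and episode-duration mixing dilute the pure exp(betaSex) ratio
  expect_lt(abs(log(ratio) - coef(fit)[["sex"]]), 0.45)
})
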