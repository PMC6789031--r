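test_that("fold-modulation formulas follow the log-link coefficients", {
  expect_equal(touchModulation(1), exp(1))
  expect_equal(touchModulation(0), 1)
  expect_equal(touchModulation(-log(2)), 0.5) # log2(ratio) = -1: twofold decrease
  m <- sexModulations(c(0.3, 0.2))
  expect_equal(unname(m["female"]), exp(0.3))
  expect_equal(unname(m["male"]), exp(0.5))
  m0 <- sexModulations(c(0.4, 0))
  expect_equal(unname(m0["female"]), unname(m0["male"]))
})

test_that("fold modulation matches empirical rate ratios of a synthetic unit", {
  set.seed(51)
  s <- suppressWarnings(generateSession(
    units = list(u1 = unitTrueBeta(beta0 = log(8), h = rep(0, 11), betaTouch = 0.4)),
    nBlocks = 6, blockLength = 20, partners = fourPartners,
    params = denseTiming()
  ))
  fit <- fitUnitModel(s, "u1", includeSex = FALSE)
  # empirical in-touch / out-of-touch rate ratio over retained bins
  bst <- trimBaseline(binSpikes(spikeTimes(s, "u1"), sessionEnd(s)), episodes(s))
  centers <- (seq_along(binCounts(bst)) - 0.5) * 1e-3
  inT <- rep(FALSE, length(centers))
  ep <- episodes(s)
  for (i in seq_len(nrow(ep))) inT[centers >= ep$onset[i] & centers < ep$offset[i]] <- TRUE
  kept <- keptMask(bst)
  ratio <- (sum(binCounts(bst)[kept & inT]) / sum(kept & inT)) /
    (sum(binCounts(bst)[kept & !inT]) / sum(kept & !inT))
  expect_equal(touchModulation(fit), ratio, tolerance = 0.1)
})

test_that("population model separates diagonal, bias and potentiation regimes", {
  set.seed(52)
  diag <- generatePopulation(nPerSubject = 40, bias = 0, slope = 1, noiseSd = 0.2)
  fd <- fitPopulationModel(diag)
  expect_false(fd$potentiation)
  expect_false(fd$bias)
  expect_equal(fd$model, "mixed")
  set.seed(53)
  pot <- generatePopulation(nPerSubject = 40, bias = 0, slope = 0.6, noiseSd = 0.2)
  fp <- fitPopulationModel(pot)
  expect_true(fp$potentiation)
  expect_false(fp$bias)
  expect_equal(fp$terms$estimate[fp$terms$term == "femaleMod"], 0.6, tolerance = 0.12)
  set.seed(54)
  bias <- generatePopulation(nPerSubject = 40, bias = 0.5, slope = 1, noiseSd = 0.2)
  fb <- fitPopulationModel(bias)
  expect_true(fb$bias)
  expect_false(fb$potentiation)
  set.seed(55)
  inter <- generatePopulation(
    nPerSubject = 60, bias = 0, slope = 0.8,
    interaction = -0.4, noiseSd = 0.2
  )
  fi <- fitPopulationModel(inter)
  iRow <- fi$terms[fi$terms$term == "femaleMod:subjectSex", ]
  expect_lt(iRow$hi, 0) # interaction sign recovered
})

test_that("population model applies the 32-fold filter and subject fallback", {
  set.seed(56)
  recs <- generatePopulation(nPerSubject = 30, noiseSd = 0.2)
  recs$femaleLog2[1] <- 7 # >32-fold: must be excluded
  recs$maleLog2[2] <- -6
  f <- fitPopulationModel(recs)
  expect_equal(f$nRemoved, 2)
  expect_equal(f$nUsed, nrow(recs) - 2)
  one <- recs[recs$subjectId == "s1", ]
  expect_warning(f1 <- fitPopulationModel(one), "single subject")
  expect_equal(f1$model, "fixed")
})

test_that("contingency analysis reproduces hand-computed chi-square pieces", {
  # perfectly proportional table: independence, all residuals zero
  tabP <- outer(c(10, 20, 30), c(2, 3)) / 5
  rP <- contingencyAnalysis(tabP)
  expect_equal(rP$p, 1)
  expect_equal(max(abs(rP$residuals)), 0, tolerance = 1e-10)
  # 2x2 table against the standard formulas computed by hand
  tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  r <- contingencyAnalysis(tab)
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - E)^2 / E)
  expect_equal(r$statistic, chi2, tolerance = 1e-12)
  expect_equal(r$p, pchisq(chi2, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  stdres <- (tab - E) / sqrt(E * outer(1 - rowSums(tab) / n, 1 - colSums(tab) / n))
  expect_equal(unclass(r$residuals), stdres, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(r$flagged, abs(stdres) > qnorm(0.975), ignore_attr = TRUE)
  # raw O - E margins vanish on random tables
  set.seed(57)
  for (i in 1:5) {
    t2 <- matrix(rpois(12, 20) + 1, 3, 4)
    r2 <- contingencyAnalysis(t2)
    d <- t2 - r2$expected
    expect_lt(max(abs(rowSums(d))), 1e-9)
    expect_lt(max(abs(colSums(d))), 1e-9)
  }
})

test_that("Kendall correlation matches a brute-force pair count", {
  f <- c(0.2, 0.5, 0.9, 1.4, 2.0)
  expect_equal(rankCorrelation(f, 2 * f + 1)$tau, 1)
  set.seed(58)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  y[3] <- y[7] # introduce a tie
  got <- rankCorrelation(x, y)$tau
  # O(n^2) concordant/discordant enumeration with tie adjustment (tau-b)
  C <- D <- tx <- ty <- 0
  n <- length(x)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[i] - x[j])
      sy <- sign(y[i] - y[j])
      if (sx == 0 && sy == 0) {
      } else if (sx == 0) {
        tx <- tx + 1
      } else if (sy == 0) {
        ty <- ty + 1
      } else if (sx == sy) {
        C <- C + 1
      } else {
        D <- D + 1
      }
    }
  }
  tauB <- (C - D) / sqrt((C + D + tx) * (C + D + ty))
  expect_equal(got, tauB, tolerance = 1e-12)
  # independent pairs: tau near zero
  set.seed(59)
  r0 <- rankCorrelation(rnorm(400), rnorm(400))
  expect_lt(abs(r0$tau), 0.1)
})

test_that("direction test summarizes signed population modulation", {
  set.seed(60)
  beta <- rnorm(60, 0.3, 0.2)
  sexes <- rep(c("F", "M"), 30)
  r <- modulationDirectionTest(beta, sexes)
  expect_lt(r$p, 0.01)
  expect_gt(r$pBetweenSexes, 0.01)
  expect_equal(r$median, median(beta))
})
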