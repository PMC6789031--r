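test_that("synapse-count formula matches its closed form and boundaries", {
  expect_equal(synapseCount(0, 100, 100), 0)
  expect_error(synapseCount(1, 10, 10), "p = 1")
  expect_error(synapseCount(-0.1, 10, 10), "non-negative")
  # printed thalamus-to-L4e pair
  expect_equal(synapseCount(0.0983, 902, 21915), 2.045e6, tolerance = 0.005)
  # large-N consistency: -ln(1-p) * Npre * Npost / K -> 1
  cfg <- microcircuitConfig()
  tab <- synapseTable(cfg)
  tab <- tab[tab$p > 0, ]
  ratio <- -log(1 - tab$p) * cfg@N[tab$source] * cfg@N[tab$target] / tab$K
  expect_lt(max(abs(ratio - 1)), 1e-4)
})

test_that("synapse count realizes the target connection probability", {
  # Monte-Carlo oracle: draw K (pre, post) pairs with replacement and
  # measure the fraction of connected ordered pairs
  nPre <- 40L
  nPost <- 50L
  p <- 0.2
  K <- round(synapseCount(p, nPre, nPost))
  set.seed(61)
  props <- replicate(20, {
    pre <- sample.int(nPre, K, replace = TRUE)
    post <- sample.int(nPost, K, replace = TRUE)
    length(unique((pre - 1L) * nPost + post)) / (nPre * nPost)
  })
  expect_equal(mean(props), p, tolerance = 0.01)
})

test_that("full-scale bookkeeping: 77,169 neurons and ~0.3e9 synapses", {
  cfg1 <- microcircuitConfig(scale = 1)
  expect_identical(sum(scaledCounts(cfg1)[1:8]), 77169L)
  tot <- totalSynapses(cfg1)
  expect_equal(signif(tot / 1e9, 1), 0.3)
})

test_that("instantiated networks match the requested statistics", {
  cfg <- microcircuitConfig(scale = 0.05)
  net <- buildNetwork(cfg, seed = 3)
  s <- soctouch:::cpp_network_summary(net$ptr)
  expect_equal(s$nNeurons, sum(scaledCounts(cfg)[1:8]))
  expect_equal(s$nSynapses, round(totalSynapses(cfg) * 0.05), tolerance = 0.01)
  # positive (excitatory-source) weights are a mixture of Normal(87.8, 8.8)
  # draws and the doubled L4e-to-L2/3e draws: check against the mixture
  tab <- synapseTable(cfg)
  tab <- tab[tab$p > 0, ]
  srcInh <- substr(tab$source, nchar(tab$source), nchar(tab$source)) == "i"
  kSc <- round(tab$K * scaledCounts(cfg)[tab$target] / cfg@N[tab$target])
  kExc <- sum(kSc[!srcInh])
  kDouble <- sum(kSc[!srcInh & tab$source == "L4e" & tab$target == "L23e"])
  pD <- kDouble / kExc
  mixMean <- (1 - pD) * 87.8 + pD * 175.6
  mixVar <- (1 - pD) * (87.8^2 + 8.8^2) + pD * (175.6^2 + 17.6^2) - mixMean^2
  expect_equal(s$excWeightMean, mixMean, tolerance = 0.005)
  expect_equal(s$excWeightSd, sqrt(mixVar), tolerance = 0.05)
  # realized per-pair synapse count equals the deterministic K
  sizes <- as.integer(scaledCounts(cfg))
  kWant <- unname(round(synapseCount(cfg@pConn["L4e", "Thal"], cfg@N["Thal"], cfg@N["L4e"]) *
    sizes[3] / cfg@N["L4e"]))
  kGot <- soctouch:::cpp_pair_synapse_count(net$ptr, 8L, 2L, sizes)
  expect_equal(kGot, kWant)
})

test_that("membrane integrator matches the analytic solution to 1e-9", {
  cfg <- microcircuitConfig()
  nrn <- cfg@neuron
  V0 <- -58
  Iext <- 300
  tr <- membraneTrace(V0, Iext, duration = 50, config = cfg)
  vInf <- nrn$Vr + Iext * nrn$tauM / nrn$Cm
  analytic <- vInf + (V0 - vInf) * exp(-tr$time / nrn$tauM)
  expect_lt(max(abs(tr$V - analytic) / abs(analytic)), 1e-9)
})

test_that("undriven network is silent and touch drives the thalamorecipient layer", {
  cfg0 <- microcircuitConfig(scale = 0.02, bgScale = 0)
  net0 <- buildNetwork(cfg0, seed = 4)
  ex0 <- modulationExperiment(nTrials = 2L, thalRate = 0)
  tr0 <- simulateExperiment(net0, ex0, seed = 5, sampleSize = 500)
  expect_equal(sum(tr0@countsBase) + sum(tr0@countsTouch), 0)
  # with background and thalamic input, touch raises L4e above its baseline
  cfg <- microcircuitConfig(scale = 0.04)
  net <- buildNetwork(cfg, seed = 6)
  tr <- simulateExperiment(net, modulationExperiment(nTrials = 6L),
    seed = 7, sampleSize = 2000
  )
  l4e <- tr@population == "L4e"
  expect_gt(mean(tr@countsTouch[l4e, ]), mean(tr@countsBase[l4e, ]))
  # class-wise partition bookkeeping
  b <- touchBetas(tr)
  comp <- eiResponseComparison(tr)
  expect_equal(sum(comp$n), sum(!b$excluded))
})

test_that("response-model selection discriminates synthetic geometries", {
  set.seed(62)
  x <- rnorm(500, 0.4, 0.6)
  potY <- 0.6 * x + rnorm(500, 0, 0.05)
  selPot <- responseModelSelection(x, potY)
  expect_equal(selPot$selected, "potentiation")
  expect_lt(selPot$slope, 1)
  biasY <- x + 0.3 + rnorm(500, 0, 0.05)
  selBias <- responseModelSelection(x, biasY)
  expect_equal(selBias$selected, "bias")
  expect_gt(selBias$intercept, 0)
  nullY <- x + rnorm(500, 0, 0.05)
  selNull <- responseModelSelection(x, nullY)
  expect_lt(abs(selNull$slope - 1), 0.05)
  expect_lt(abs(selNull$intercept), 0.05)
  fullY <- 0.5 * x + 0.3 + rnorm(500, 0, 0.05)
  expect_equal(responseModelSelection(x, fullY)$selected, "full")
  expect_error(responseModelSelection(x[1:5], potY[1:5]), "10 usable")
})

test_that("inhibitory depolarization potentiates responses; null trials are exchangeable", {
  cfg <- microcircuitConfig(scale = 0.05)
  net <- buildNetwork(cfg, seed = 11)
  trNull <- simulateExperiment(net, modulationExperiment(0, 1, nTrials = 20L), seed = 12)
  trPot <- simulateExperiment(net, modulationExperiment(1, 1, nTrials = 20L), seed = 12)
  # exchangeability under null modulation
  expect_gt(conditionPermutationTest(trNull, nPerm = 200, seed = 13)$p, 0.01)
  # the regression slope of modulated on non-modulated responses drops well
  # below the attenuation level set by the null configuration
  selNull <- responseModelSelection(touchBetas(trNull))
  selPot <- responseModelSelection(touchBetas(trPot))
  expect_lt(selPot$models$slope[selPot$models$model == "full"],
    selNull$models$slope[selNull$models$model == "full"] - 0.1)
})
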