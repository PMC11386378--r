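test_that("occupancy index matches the closed form and is order-invariant", {
  fr <- makeSampleFrame() # 16 + 9x3, 10 groups
  m <- matrix(0L, 3, 43, dimnames = list(c("all", "one", "none2"),
                                         fr$sample_id))
  m["all", ] <- 5L
  m["one", fr$group == "C3"] <- 2L # all 3 samples of one group
  m["none2", 1] <- 1L
  rk <- occupancyIndex(m, fr)
  expect_equal(rk$taxon[1], "all")
  expect_equal(rk$index[rk$taxon == "all"], 1)
  expect_equal(rk$index[rk$taxon == "one"],
               0.5 * (3 / 43) + 0.5 * (1 / 10), tolerance = 1e-12)
  expect_equal(rk$index[rk$taxon == "one"], 0.0849, tolerance = 1e-3)

  set.seed(2)
  perm <- sample(43)
  rk2 <- occupancyIndex(m[, perm], fr[perm, ])
  expect_equal(rk2, rk)

  # occ_all is invariant to duplicating an existing sample's counts
  m3 <- cbind(m, dup = m[, 1])
  pres <- rowMeans(m3 > 0)
  expect_equal(unname(pres["all"]), 1)
})

test_that("contribution curve: completeness, monotonicity, hand example", {
  ge <- simulateExperiment(smallConfig(50, 45), seed = 3)
  fr <- as.data.frame(SummarizedExperiment::colData(ge))
  rk <- occupancyIndex(counts(ge), fr)
  curve <- bcContributionCurve(rk, counts(ge))
  expect_equal(unname(curve[length(curve)]), 100, tolerance = 1e-9)
  expect_true(all(diff(curve) >= -1e-12))

  # two identical samples, 3 taxa: top taxon's share is its min fraction
  m <- matrix(c(6L, 3L, 1L, 6L, 3L, 1L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  curve2 <- bcContributionCurve(c("a", "b", "c"), m)
  expect_equal(unname(curve2), c(60, 90, 100), tolerance = 1e-9)
})

test_that("core selection implements the last-2%-decrease rule", {
  curve <- c(50, 80, 95, 96, 96.5)
  expect_equal(selectCore(curve, paste0("t", 1:5)), paste0("t", 1:3))
  steep <- c(30, 60, 90, 100)
  expect_equal(selectCore(steep, paste0("t", 1:4)), paste0("t", 1:4))
  expect_error(selectCore(curve, paste0("t", 1:5), threshold = 0),
               "positive")
})

test_that("planted omnipresent taxa are recovered as the core", {
  # 10 abundant omnipresent taxa among 290 sparse low-abundance ones
  cfg <- simConfig(nTaxa = 300, nGenera = 120, baseMu = -2.5,
                   depthMean = 2000, nResilient = 0, nSusceptible = 0,
                   nStable = 0, nSpecialist = 0, nNeutral = 0, nCore = 10,
                   coreMu = 3)
  ge <- simulateExperiment(cfg, seed = 8)
  tr <- plantedTruth(ge)
  planted <- rownames(ge)[tr$label == "core"]
  res <- coreNeutralAnalysis(ge)
  expect_lte(length(setdiff(coreTaxa(res), planted)), 2)
  expect_gte(length(intersect(coreTaxa(res), planted)), 8)
})

test_that("Sloan fit recovers the generative migration rate", {
  p <- metacommunity(300, sigma = 2, seed = 13)
  depth <- 2e4
  mTrue <- 0.005
  cm <- simulateNeutralCommunity(p, mTrue, nSamples = 50, depth = depth,
                                 seed = 14)
  fit <- fitNeutralModel(cm)
  mHat <- migrationEstimate(fit) / mean(colSums(cm))
  expect_lt(abs(mHat - mTrue) / mTrue, 0.2)
  expect_gte(fitR2(fit), 0.85)

  # limit: abundant taxa are predicted omnipresent
  tab <- neutralTable(fit)
  expect_true(all(tab$predicted[tab$p > 0.05] > 0.999))
})

test_that("neutrality classes partition taxa and detect planted selection", {
  p <- metacommunity(200, sigma = 2, seed = 15)
  cm <- simulateNeutralCommunity(p, 0.01, nSamples = 40, depth = 1e4,
                                 seed = 16)
  fit <- fitNeutralModel(cm)
  cls <- classifyNeutrality(fit)
  expect_equal(length(cls), nrow(neutralTable(fit)))
  expect_true(all(cls %in% c("above", "neutral", "below")))

  inside <- neutralTable(fit)
  mid <- inside$taxon[inside$occupancy >= inside$lower &
                        inside$occupancy <= inside$upper][1]
  expect_equal(as.character(classifyNeutrality(fit, mid)), "neutral")
  expect_error(classifyNeutrality(fit, "no_such_taxon"), "absent")

  # boost occupancy of rare taxa above the neutral expectation
  hits <- 0
  for (s in 1:5) {
    cm2 <- simulateNeutralCommunity(p, 0.01, nSamples = 40, depth = 1e4,
                                    seed = 20 + s)
    sel <- names(sort(p[rowMeans(cm2 > 0) < 0.5], decreasing = TRUE))[1:5]
    cm2[sel, ][cm2[sel, ] == 0] <- 1L
    cls2 <- classifyNeutrality(fitNeutralModel(cm2), sel)
    hits <- hits + mean(cls2 == "above")
  }
  expect_gte(hits / 5, 0.8)
})
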