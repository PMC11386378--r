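test_that("null-effect taxon gets near-zero coefficients", {
  fr <- makeSampleFrame()
  depth <- 1e5
  # counts exactly proportional across samples: no condition signal
  p <- c(t1 = 0.3, t2 = 0.5, t3 = 0.2)
  m <- matrix(rep(round(p * depth), 43), 3, 43,
              dimnames = list(names(p), fr$sample_id))
  storage.mode(m) <- "integer"
  mod <- fitResponseModel(m, fr)
  expect_true(all(abs(responseCoefficients(mod)) < 0.05))
})

test_that("planted condition effects are recovered from the simulator", {
  ge <- simulateExperiment(simConfig(), seed = 7)
  tr <- plantedTruth(ge)
  tax <- taxonomyTable(ge)
  mod <- fitResponseModel(ge, top = 100, seed = 1)
  B <- responseCoefficients(mod)
  resG <- intersect(tax$genus[tr$label == "resilient"], rownames(B))
  expect_gt(length(resG), 5)
  expect_true(all(B[resG, ] > 0))
  expect_true(mean(B[resG, ]) > 0.7 && mean(B[resG, ]) < 1.3)
  susG <- intersect(tax$genus[tr$label == "susceptible"], rownames(B))
  expect_true(mean(B[susG, ]) > -1.3 && mean(B[susG, ]) < -0.7)
})

test_that("classification follows the sign rule with CI filtering", {
  B <- rbind(up = rep(0.5, 9), down = rep(-0.5, 9),
             mix = c(rep(0.5, 8), -0.1))
  SE <- matrix(0.1, 3, 9, dimnames = dimnames(B))
  colnames(B) <- colnames(SE) <- paste0("C", 1:9)
  mod <- methods::new("ResponseModel", taxa = rownames(B),
                      intercepts = setNames(rep(0, 3), rownames(B)),
                      coefficients = B, se = SE,
                      dispersion = setNames(rep(10, 3), rownames(B)),
                      converged = rep(TRUE, 3), rank = 0L,
                      loadings = matrix(0, 3, 0), scores = matrix(0, 9, 0),
                      conditions = paste0("C", 1:9))
  cl <- classifyResponse(mod)
  expect_equal(as.character(cl), c("resilient", "susceptible", "mixed"))

  # wide intervals demote sign-consistent rows under CI filtering
  mod@se <- matrix(2, 3, 9, dimnames = dimnames(B))
  clCI <- classifyResponse(mod, requireCI = TRUE)
  expect_true(all(clCI == "mixed"))

  # NA coefficients label the taxon mixed with a warning
  mod@coefficients[1, 1] <- NA
  expect_warning(clNA <- classifyResponse(mod), "NA")
  expect_equal(as.character(clNA[1]), "mixed")
})

test_that("coefficients are invariant to sample order and depth scaling", {
  ge <- simulateExperiment(smallConfig(), seed = 9)
  fr <- as.data.frame(SummarizedExperiment::colData(ge))
  m <- counts(ge)[topTaxa(counts(ge), 15), ]
  mod1 <- fitResponseModel(m, fr, family = "poisson",
                           sampleTotals = colSums(counts(ge)))
  set.seed(2)
  perm <- sample(ncol(m))
  mod2 <- fitResponseModel(m[, perm], fr[perm, ], family = "poisson",
                           sampleTotals = colSums(counts(ge))[perm])
  expect_equal(responseCoefficients(mod2), responseCoefficients(mod1),
               tolerance = 1e-6)

  # doubling one sample's counts is absorbed by the offset (Poisson limit)
  m3 <- m
  m3[, 1] <- m3[, 1] * 2L
  tot <- colSums(counts(ge)); tot[1] <- tot[1] * 2
  mod3 <- fitResponseModel(m3, fr, family = "poisson", sampleTotals = tot)
  # absorbed by the offset up to the GLM's depth weighting of samples
  expect_equal(responseCoefficients(mod3), responseCoefficients(mod1),
               tolerance = 0.02)
})

test_that("latent factors at rank 2 leave coefficients essentially unchanged", {
  # data simulated without latent structure: rank 0 and rank 2 agree
  cfg <- simConfig(nTaxa = 40, nGenera = 40, nResilient = 2,
                   nSusceptible = 2, nStable = 5, nCore = 2, nSpecialist = 0,
                   nNeutral = 5)
  ge <- simulateExperiment(cfg, seed = 11)
  fr <- as.data.frame(SummarizedExperiment::colData(ge))
  m <- counts(ge)[topTaxa(counts(ge), 20), ]
  mod0 <- fitResponseModel(m, fr, rank = 0)
  mod2 <- fitResponseModel(m, fr, rank = 2, maxIter = 5, seed = 3)
  rmse <- sqrt(mean((responseCoefficients(mod0) -
                       responseCoefficients(mod2))^2, na.rm = TRUE))
  expect_lt(rmse, 0.1)
  expect_equal(ncol(mod2@scores), 2)
})

test_that("all-zero taxa yield NA coefficients with a warning", {
  fr <- makeSampleFrame()
  set.seed(1)
  m <- matrix(rpois(3 * 43, 40), 3, 43,
              dimnames = list(c("a", "b", "zero"), fr$sample_id))
  m["zero", ] <- 0L
  expect_warning(mod <- fitResponseModel(m, fr), "all-zero")
  expect_true(all(is.na(responseCoefficients(mod)["zero", ])))
})
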