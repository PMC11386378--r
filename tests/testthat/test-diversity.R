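test_that("chao1 and shannon match their closed forms", {
  col <- c(rep(1L, 4), rep(2L, 2), rep(5L, 4)) # S=10, F1=4, F2=2
  expect_equal(chao1(col), 12)
  expect_equal(chao1(c(5L, 5L, 5L)), 3) # no singletons
  expect_equal(chao1(c(1L, 1L, 1L, 9L)), 4 + 3) # F1=3, F2=0

  expect_equal(shannonIndex(rep(1L, 8)), log(8))
  expect_equal(shannonIndex(c(0L, 7L, 0L)), 0)
  expect_equal(shannonIndex(c(1L, 1L, 2L)),
               -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)))
  expect_error(shannonIndex(c(0L, 0L)), "zero total")

  # cross-check against the vegan implementations on random data
  set.seed(8)
  m <- matrix(rpois(40 * 6, 3), 40, 6,
              dimnames = list(paste0("t", 1:40), paste0("s", 1:6)))
  est <- vegan::estimateR(t(m))
  expect_equal(unname(apply(m, 2, chao1)), unname(est["S.chao1", ]),
               tolerance = 1e-8)
  expect_equal(unname(apply(m, 2, shannonIndex)),
               unname(vegan::diversity(t(m), "shannon")), tolerance = 1e-10)
})

test_that("rarefaction subsamples without replacement at exact depth", {
  m <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(rarefyCounts(m, 5, seed = 1)[, 1]), c(5, 0))
  m2 <- tinyCounts()
  expect_identical(rarefyCounts(m2, depth = min(colSums(m2)), seed = 1) |>
                     colSums() |> unname(), rep(min(colSums(m2)), 2))
  expect_error(rarefyCounts(m2, 0), "positive")
  expect_warning(rarefyCounts(m2, 8), "dropping")

  # hypergeometric expectation: mean over seeded rarefactions ~ depth * p
  col <- matrix(c(60L, 30L, 10L), 3, 1, dimnames = list(c("a", "b", "c"), "s"))
  draws <- sapply(1:200, function(s) rarefyCounts(col, 50, seed = s)[, 1])
  expm <- 50 * c(0.6, 0.3, 0.1)
  se <- sqrt(50 * c(0.6, 0.3, 0.1) * c(0.4, 0.7, 0.9) / 200) # binomial bound
  expect_true(all(abs(rowMeans(draws) - expm) < 3 * se + 0.3))
})

test_that("Bray-Curtis matches hand examples and vegan", {
  r <- cbind(s1 = c(0.2, 0.8), s2 = c(0.5, 0.5))
  rownames(r) <- c("a", "b")
  d <- brayCurtis(r)
  expect_equal(d["s1", "s2"], 0.3)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))
  dis <- cbind(s1 = c(1, 0), s2 = c(0, 1))
  rownames(dis) <- c("a", "b")
  expect_equal(brayCurtis(dis)["s1", "s2"], 1)
  set.seed(2)
  r2 <- randomRelMatrix(20, 8, seed = 2)
  expect_true(all(brayCurtis(r2) >= 0 & brayCurtis(r2) <= 1))
})

test_that("PCoA reproduces linear geometry and symmetries", {
  # points on a line: the first axis reconstructs pairwise distances
  x <- c(0, 1, 3, 7)
  d <- as.matrix(dist(x))
  fit <- pcoaOrdination(d)
  rec <- as.matrix(dist(fit$points[, 1]))
  expect_equal(rec, d, tolerance = 1e-8)

  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  fit3 <- pcoaOrdination(d3)
  eig <- fit3$eigenvalues
  expect_equal(eig[1], eig[2], tolerance = 1e-10)

  # duplicated sample lands on identical coordinates
  r <- randomRelMatrix(15, 5, seed = 3)
  r <- cbind(r, dup = r[, 1])
  fit4 <- pcoaOrdination(brayCurtis(r))
  expect_equal(fit4$points[1, ], fit4$points[ncol(r), ], tolerance = 1e-8)

  expect_error(pcoaOrdination(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA: invariance, minimum p on separated blocks, seeding", {
  set.seed(4)
  r <- cbind(randomRelMatrix(20, 8, seed = 5), randomRelMatrix(20, 8, seed = 6))
  r[1:10, 1:8] <- 0
  r[11:20, 9:16] <- 0
  r <- sweep(r, 2, colSums(r), "/")
  colnames(r) <- paste0("s", 1:16)
  g <- rep(c("A", "B"), each = 8)
  d <- brayCurtis(r)
  res <- permanovaTest(d, g, nPerm = 999, seed = 1)
  # disjoint blocks sit at the permutation floor (rarely one tied relabelling)
  expect_lte(res$p, 0.002)

  # permuting sample order leaves the statistic unchanged
  perm <- sample(16)
  res2 <- permanovaTest(d[perm, perm], g[perm], nPerm = 99, seed = 1)
  expect_equal(res2$F, res$F, tolerance = 1e-10)

  res3a <- permanovaTest(d, g, nPerm = 99, seed = 7)
  res3b <- permanovaTest(d, g, nPerm = 99, seed = 7)
  expect_identical(res3a$p, res3b$p)
  expect_error(permanovaTest(d[1:3, 1:3], c("A", "B", "C")), "singleton")
})

test_that("group tests star convention and degenerate cases", {
  expect_equal(pStars(c(0.2, 0.04, 0.004, 0.0004)), c("", "*", "**", "***"))
  set.seed(5)
  v <- c(rnorm(6), rnorm(6, 3))
  g <- rep(c("A", "B"), each = 6)
  res <- groupDiversityTest(v, g)
  expect_lt(res$anova_p, 0.01)
  expect_equal(nrow(res$pairwise), 1)
  same <- rep(c(1, 1, 2, 2), 2)
  gg <- rep(c("A", "B"), each = 4)
  res2 <- groupDiversityTest(rep(1, 8), gg)
  expect_equal(res2$pairwise$p, 1) # identical groups, zero noise
  expect_error(groupDiversityTest(1:3, c("A", "A", "B")), "at least 2")
})
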