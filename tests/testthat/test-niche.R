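test_that("niche breadth hits its exact bounds", {
  fr <- makeSampleFrame()
  m <- matrix(0, 3, 43, dimnames = list(c("uniformG", "oneState", "twoState"),
                                        fr$sample_id))
  # equal mean abundance in every state
  m["uniformG", ] <- 0.1
  # present in exactly one of the ten states
  m["oneState", fr$group == "C4"] <- 0.2
  # equal shares in exactly two states
  m["twoState", fr$group %in% c("C1", "C2")] <- 0.3
  nb <- nicheBreadth(m, fr)
  expect_equal(nb$B_N[nb$taxon == "uniformG"], 1, tolerance = 1e-12)
  expect_equal(nb$B_N[nb$taxon == "oneState"], 0.1, tolerance = 1e-12)
  expect_equal(nb$B_N[nb$taxon == "twoState"], 0.2, tolerance = 1e-12)
  expect_equal(nb$R[1], 10)

  # bounds hold on random data
  r <- randomRelMatrix(30, 43, seed = 4)
  colnames(r) <- fr$sample_id
  nb2 <- nicheBreadth(r, fr)
  expect_true(all(nb2$B_N >= 1 / 10 - 1e-12 & nb2$B_N <= 1 + 1e-12))

  m0 <- rbind(m, absent = 0)
  expect_warning(nb3 <- nicheBreadth(m0, fr), "absent")
  expect_true(is.na(nb3$B_N[nb3$taxon == "absent"]))
})

test_that("an all-zero extra state changes R and B_N but not B", {
  fr <- data.frame(sample_id = paste0("s", 1:6),
                   group = rep(c("A", "B", "C"), each = 2))
  m <- matrix(c(1, 1, 1, 1, 0, 0), 1, 6,
              dimnames = list("g", fr$sample_id))
  nbAB <- nicheBreadth(m[, 1:4, drop = FALSE], fr[1:4, ])
  nbABC <- nicheBreadth(m, fr)
  expect_equal(nbAB$B, nbABC$B)
  expect_equal(nbAB$B_N, nbAB$B / 2)
  expect_equal(nbABC$B_N, nbABC$B / 3)
})

test_that("permutation null is seeded and calibrated on null data", {
  fr <- makeSampleFrame()
  r <- randomRelMatrix(5, 43, seed = 6)
  colnames(r) <- fr$sample_id
  a <- nicheNullTest(r, fr, nPerm = 199, seed = 3)
  b <- nicheNullTest(r, fr, nPerm = 199, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$p_specialist > 0 & a$p_specialist <= 1))

  # reduced-scale null calibration of the specialist tail
  rej <- 0
  for (s in 1:200) {
    set.seed(5000 + s)
    r1 <- matrix(exp(rnorm(2 * 43)), 2, 43,
                 dimnames = list(c("g1", "g2"), fr$sample_id))
    r1 <- sweep(r1, 2, colSums(r1), "/")
    nt <- nicheNullTest(r1, fr, nPerm = 99, seed = s)
    rej <- rej + (nt$p_specialist[1] <= 0.05)
  }
  expect_gt(rej / 200, 0.01)
  expect_lt(rej / 200, 0.12)
})

test_that("classification combines thresholds with adjusted significance", {
  profiles <- data.frame(
    taxon = paste0("g", 1:30),
    B_N = c(0.547, seq(0.62, 0.95, length.out = 28), 0.99),
    p_adj_specialist = c(0.028, rep(0.5, 29)),
    p_adj_generalist = c(rep(0.5, 29), 0.2))
  cls <- classifyNiche(profiles)
  expect_equal(as.character(cls$class[1]), "specialist")
  expect_equal(cls$stars[1], "*")
  # high breadth without significance stays unclassified
  expect_equal(as.character(cls$class[30]), "neither")
  expect_true(attr(cls, "lower_threshold") > 0.547)

  # planted generalists in synthetic data are recovered
  fr <- makeSampleFrame()
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    bg <- matrix(exp(rnorm(38 * 43, 0, 2)), 38, 43)
    bg <- sweep(bg, 2, colSums(bg), "/")
    # generalists hold a fluctuating share whose group means balance
    # exactly on the relative-abundance scale (a perfectly even niche)
    shares <- matrix(0, 2, 43)
    for (i in 1:2) {
      v <- exp(rnorm(43, 0, 0.8))
      for (g in levels(fr$group)) {
        sel <- fr$group == g
        v[sel] <- v[sel] / mean(v[sel])
      }
      shares[i, ] <- 0.05 * v
    }
    r <- rbind(shares, sweep(bg, 2, 1 - colSums(shares), "*"))
    dimnames(r) <- list(sprintf("g%02d", 1:40), fr$sample_id)
    nt <- nicheNullTest(r, fr, nPerm = 499, seed = 50 + s)
    cls2 <- classifyNiche(nt)
    hits <- hits + mean(cls2$class[1:2] == "generalist")
  }
  expect_gte(hits / 5, 0.9)
})

test_that("Levins overlap realises its exact asymmetry", {
  fr <- data.frame(sample_id = paste0("s", 1:4),
                   group = rep(c("A", "B"), each = 2))
  m <- rbind(both = c(1, 1, 1, 1) / 4,
             onlyA = c(2, 2, 0, 0) / 4)
  colnames(m) <- fr$sample_id
  LO <- levinsOverlap(m, fr)
  expect_equal(LO["both", "onlyA"], 0.5 / 1.0) # covers half of onlyA's states
  expect_equal(LO["onlyA", "both"], 0.5 / 0.5) # fully covers shared states
  expect_equal(diag(LO), c(both = 1, onlyA = 1))

  ident <- rbind(g1 = m["both", ], g2 = m["both", ])
  LOi <- levinsOverlap(ident, fr)
  expect_true(all(LOi == 1))

  disj <- rbind(g1 = c(1, 1, 0, 0), g2 = c(0, 0, 1, 1))
  colnames(disj) <- fr$sample_id
  LOd <- levinsOverlap(disj, fr)
  expect_equal(LOd["g1", "g2"], 0)
  expect_equal(LOd["g2", "g1"], 0)

  withZero <- rbind(g1 = c(1, 1, 1, 1), gz = c(0, 0, 0, 0))
  colnames(withZero) <- fr$sample_id
  LOz <- levinsOverlap(withZero, fr)
  expect_true(all(is.na(LOz["gz", ])))
})
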