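# shared fixture builders (all programmatic, nothing on disk)

tinyCounts <- function() {
  matrix(c(5L, 3L, 0L, 7L), nrow = 2,
         dimnames = list(c("taxA", "taxB"), c("s1", "s2")))
}

# closed (columns sum to 1) random relative-abundance matrix
randomRelMatrix <- function(nTaxa, nSamples, seed = 1, sigma = 1) {
  set.seed(seed)
  r <- matrix(exp(rnorm(nTaxa * nSamples, 0, sigma)), nTaxa, nSamples,
              dimnames = list(sprintf("g%03d", seq_len(nTaxa)),
                              sprintf("s%03d", seq_len(nSamples))))
  sweep(r, 2, colSums(r), "/")
}

# relative-abundance matrix with a planted constant-sum ensemble occupying
# `fraction` of every sample; members fluctuate, their total does not
plantedStableMatrix <- function(nMembers, nBackground, nSamples,
                                fraction = 0.5, seed = 1) {
  set.seed(seed)
  pw <- matrix(rgamma(nMembers * nSamples, 2), nMembers)
  pw <- sweep(pw, 2, colSums(pw), "/") * fraction
  bw <- matrix(rgamma(nBackground * nSamples, 2), nBackground)
  bw <- sweep(bw, 2, colSums(bw), "/") * (1 - fraction)
  r <- rbind(pw, bw)
  dimnames(r) <- list(sprintf("g%03d", seq_len(nMembers + nBackground)),
                      sprintf("s%03d", seq_len(nSamples)))
  r
}

# a simConfig with planted sets scaled down for small test communities
smallConfig <- function(nTaxa = 60, nGenera = 50, ...) {
  simConfig(nTaxa = nTaxa, nGenera = nGenera, nResilient = 2,
            nSusceptible = 2, nStable = 4, nCore = 2, nSpecialist = 1,
            nNeutral = 4, ...)
}

# metacommunity abundance vector for neutral simulations
metacommunity <- function(nTaxa = 300, sigma = 2, seed = 1) {
  set.seed(seed)
  p <- exp(rnorm(nTaxa, 0, sigma))
  p <- p / sum(p)
  names(p) <- sprintf("ASV_%04d", seq_len(nTaxa))
  p
}
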