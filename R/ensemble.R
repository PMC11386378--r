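# stable-ensemble search: find a genus subset whose summed relative
# abundance is maximally stable (minimum CV) across all samples, by a
# genetic algorithm over binary membership vectors (plus an exhaustive
# oracle for small pools)

#' Coefficient of variation of an ensemble's summed abundance
#'
#' For subset S, `t_j = sum_{g in S} r_gj` per sample j; returns
#' `sd(t) / mean(t)` with the sample (n-1) standard deviation.
#'
#' @param subset character vector of member genera (non-empty, present in
#'   `r`).
#' @param r relative-abundance matrix (genera x samples).
#' @return the CV (0 for the full community, whose totals are closed to 1).
#' @export
ensembleCV <- function(subset, r) {
  if (length(subset) == 0) stop("empty ensemble")
  missing <- setdiff(subset, rownames(r))
  if (length(missing))
    stop("members absent from matrix: ", paste(missing, collapse = ", "))
  t_j <- colSums(r[subset, , drop = FALSE])
  mu <- mean(t_j)
  if (mu == 0) stop("ensemble has zero mean abundance")
  sd(t_j) / mu
}

# vectorised fitness of a population of membership vectors (rows)
.popCV <- function(P, r) {
  totals <- P %*% r # pop x samples
  mu <- rowMeans(totals)
  n <- ncol(totals)
  sdev <- sqrt(pmax(0, (rowSums(totals^2) - n * mu^2) / (n - 1)))
  ifelse(mu > 0, sdev / mu, Inf)
}

# enforce the size cap: drop uniformly random excess members (a
# deterministic drop rule makes low-abundance optima unreachable once the
# population converges); revive one random member if a vector went empty
.repair <- function(P, maxSize) {
  sizes <- rowSums(P)
  for (i in which(sizes > maxSize)) {
    on <- which(P[i, ] == 1)
    drop <- sample(on, sizes[i] - maxSize) # length(on) >= 2 here
    P[i, drop] <- 0
  }
  empty <- which(rowSums(P) == 0)
  if (length(empty))
    P[cbind(empty, sample.int(ncol(P), length(empty), replace = TRUE))] <- 1
  P
}

#' Genetic-algorithm search for a stable ensemble
#'
#' Searches binary genus-membership vectors for the subset (of at most
#' `maxSize` members) minimising [ensembleCV()]. The algorithm uses a
#' population of `popSize` vectors, tournament selection (k = 3), uniform
#' crossover (p = 0.5), per-gene mutation at rate `1/n_genera`, elitism of
#' 5, and a repair step enforcing the size cap by dropping random excess
#' members (seeded). The initial population contains every
#' singleton, so the best single genus is always reachable. Search stops
#' after `stall` generations without improvement or `maxGenerations`
#' generations.
#'
#' @param x relative-abundance matrix (genera x samples, >= 2 samples) or a
#'   [GranuleExperiment-class] (collapsed to genus and total-sum scaled).
#' @param maxSize ensemble size cap (clamped to the number of genera with a
#'   warning).
#' @param popSize,maxGenerations,stall,elitism GA controls.
#' @param seed integer seed; same seed, same result.
#' @param ... unused.
#' @return an [EnsembleSolution-class] with the member set, its CV and the
#'   best-so-far CV per generation (non-increasing by elitism).
#' @rdname searchStableEnsemble
#' @export
setMethod("searchStableEnsemble", "matrix",
          function(x, maxSize = 20, popSize = 200, maxGenerations = 1000,
                   stall = 50, elitism = 5, seed = 1, ...) {
  if (ncol(x) < 2) stop("need at least 2 samples")
  stopifnot(maxSize >= 1)
  n <- nrow(x)
  if (maxSize > n) {
    warning("maxSize clamped to the number of genera (", n, ")")
    maxSize <- n
  }
  set.seed(seed)

  # initial population: all singletons, then random vectors
  P <- matrix(0, popSize, n)
  sing <- seq_len(min(n, popSize))
  P[cbind(sing, sing)] <- 1
  if (popSize > n) {
    pOn <- min(0.5, maxSize / n)
    P[(n + 1):popSize, ] <- matrix(
      as.numeric(runif((popSize - n) * n) < pOn), popSize - n, n)
  }
  P <- .repair(P, maxSize)

  fit <- .popCV(P, x)
  bestCV <- min(fit)
  bestVec <- P[which.min(fit), ]
  traj <- numeric(0)
  sinceImprove <- 0L
  gen <- 0L
  while (gen < maxGenerations && sinceImprove < stall) {
    gen <- gen + 1L
    ord <- order(fit)
    elite <- P[ord[seq_len(elitism)], , drop = FALSE]
    nChild <- popSize - elitism
    # tournament selection, k = 3
    pick <- function(k) {
      idx <- matrix(sample.int(popSize, 3 * k, replace = TRUE), k, 3)
      idx[cbind(seq_len(k), max.col(-matrix(fit[idx], k, 3)))]
    }
    pa <- pick(nChild)
    pb <- pick(nChild)
    mask <- matrix(runif(nChild * n) < 0.5, nChild, n)
    child <- P[pa, , drop = FALSE]
    child[mask] <- P[pb, , drop = FALSE][mask]
    flip <- matrix(runif(nChild * n) < 1 / n, nChild, n)
    child[flip] <- 1 - child[flip]
    child <- .repair(child, maxSize)
    P <- rbind(elite, child)
    fit <- .popCV(P, x)
    gBest <- min(fit)
    if (gBest < bestCV - 1e-15) {
      bestCV <- gBest
      bestVec <- P[which.min(fit), ]
      sinceImprove <- 0L
    } else sinceImprove <- sinceImprove + 1L
    traj <- c(traj, bestCV)
  }
  methods::new("EnsembleSolution",
               members = rownames(x)[bestVec == 1], cv = bestCV,
               trajectory = traj, generations = gen,
               converged = sinceImprove >= stall, seed = as.integer(seed),
               method = "ga")
})

#' @rdname searchStableEnsemble
#' @export
setMethod("searchStableEnsemble", "GranuleExperiment", function(x, ...) {
  m <- collapseToGenus(counts(x), taxonomyTable(x))
  searchStableEnsemble(toRelative(m), ...)
})

#' Exhaustive stable-ensemble search
#'
#' Enumerates every non-empty subset of at most `maxSize` genera and returns
#' the global CV minimum; intended as an oracle for validating the genetic
#' algorithm on small pools.
#'
#' @param r relative-abundance matrix (genera x samples).
#' @param maxSize ensemble size cap.
#' @param budget maximum number of subsets to enumerate (default 2e6).
#' @return an [EnsembleSolution-class] with `method = "exhaustive"`.
#' @export
exhaustiveStableEnsemble <- function(r, maxSize, budget = 2e6) {
  n <- nrow(r)
  maxSize <- min(maxSize, n)
  total <- sum(choose(n, seq_len(maxSize)))
  if (total > budget)
    stop("enumeration budget exceeded (", format(total, big.mark = ","),
         " subsets); use searchStableEnsemble()")
  bestCV <- Inf
  bestSet <- NULL
  for (k in seq_len(maxSize)) {
    sets <- combn(n, k)
    for (c in seq_len(ncol(sets))) {
      idx <- sets[, c]
      t_j <- colSums(r[idx, , drop = FALSE])
      mu <- mean(t_j)
      if (mu == 0) next
      cv <- sd(t_j) / mu
      if (cv < bestCV) {
        bestCV <- cv
        bestSet <- idx
      }
    }
  }
  methods::new("EnsembleSolution", members = rownames(r)[bestSet],
               cv = bestCV, trajectory = numeric(0), generations = 0L,
               converged = TRUE, seed = NA_integer_, method = "exhaustive")
}
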