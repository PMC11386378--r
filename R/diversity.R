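# alpha diversity, Bray-Curtis beta diversity, PCoA and PERMANOVA
#
# The ecological primitives are delegated to vegan (rrarefy, vegdist,
# adonis2) behind the interfaces used by the rest of the pipeline.

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' reads (vegan's `rrarefy`), seeded. Samples whose total is below the
#' requested depth are dropped with a warning.
#'
#' @param m count matrix (taxa x samples).
#' @param depth target depth; default (`NULL`) is the minimum sample total.
#' @param seed integer seed.
#' @return rarefied integer count matrix.
#' @export
rarefyCounts <- function(m, depth = NULL, seed = 1) {
  .checkCountMatrix(m)
  cs <- colSums(m)
  if (is.null(depth)) depth <- min(cs)
  if (depth <= 0) stop("rarefaction depth must be positive")
  drop <- cs < depth
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(colnames(m)[drop], collapse = ", "))
    m <- m[, !drop, drop = FALSE]
  }
  set.seed(seed)
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(m), sample = depth)),
    # silence vegan's small-count heuristic; inputs are validated above
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  out
}

#' Chao1 richness estimator
#'
#' Bias-corrected Chao1: `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` with F1 the
#' number of singletons and F2 the number of doubletons.
#'
#' @param col non-negative integer counts of one sample.
#' @return estimated richness (>= observed richness).
#' @examples
#' chao1(c(rep(1, 4), rep(2, 2), rep(5, 4)))  # 12
#' @export
chao1 <- function(col) {
  if (any(col < 0) || any(col != floor(col))) stop("counts must be integers")
  sObs <- sum(col > 0)
  f1 <- sum(col == 1)
  f2 <- sum(col == 2)
  sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon entropy
#'
#' `H = -sum p ln p` over the non-zero proportions of a sample (natural
#' log: nats).
#'
#' @param col non-negative counts of one sample with a positive total.
#' @param base logarithm base (default `exp(1)`).
#' @return entropy, >= 0.
#' @export
shannonIndex <- function(col, base = exp(1)) {
  if (sum(col) <= 0) stop("sample has zero total count")
  p <- col[col > 0] / sum(col)
  -sum(p * log(p, base = base))
}

#' Per-sample alpha diversity table
#'
#' @param m count matrix (optionally rarefied first, see [rarefyCounts()]).
#' @return data.frame with `sample`, `observed`, `singletons`, `doubletons`,
#'   `chao1`, `shannon`.
#' @export
alphaDiversity <- function(m) {
  .checkCountMatrix(m)
  data.frame(
    sample = colnames(m),
    observed = colSums(m > 0),
    singletons = colSums(m == 1),
    doubletons = colSums(m == 2),
    chao1 = apply(m, 2, chao1),
    shannon = apply(m, 2, shannonIndex),
    row.names = NULL)
}

#' Group comparison of a diversity metric
#'
#' One-way ANOVA across groups followed by pairwise Welch t-tests with
#' Benjamini-Hochberg adjustment; pairwise stars use the conventional
#' thresholds (see [pStars()]).
#'
#' @param values per-sample metric.
#' @param groups group labels (>= 2 groups with >= 2 samples each).
#' @return list with `anova_p`, the omnibus F-test p-value, and `pairwise`,
#'   a data.frame of group pairs with raw/adjusted p and stars.
#' @export
groupDiversityTest <- function(values, groups) {
  groups <- .checkGroups(groups, values)
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need at least 2 groups with at least 2 samples each")
  fit <- aov(values ~ groups)
  anova_p <- summary(fit)[[1]]$`Pr(>F)`[1]
  pairs <- combn(levels(groups), 2)
  pw <- apply(pairs, 2, function(pr) {
    a <- values[groups == pr[1]]
    b <- values[groups == pr[2]]
    if (var(a) == 0 && var(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else t.test(a, b)$p.value
  })
  adj <- p.adjust(pw, method = "BH")
  list(anova_p = anova_p,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             p = pw, p_adj = adj, stars = pStars(adj)))
}

#' Bray-Curtis distance matrix
#'
#' `d(j, k) = 1 - sum_i min(r_ij, r_ik)` for relative-abundance columns
#' summing to 1 (computed via vegan's `vegdist`).
#'
#' @param r relative-abundance matrix (taxa x samples, columns sum to 1).
#' @return symmetric distance matrix with zero diagonal, entries in [0, 1].
#' @export
brayCurtis <- function(r) {
  if (any(abs(colSums(r) - 1) > 1e-6))
    stop("columns must sum to 1; use toRelative() first")
  as.matrix(vegan::vegdist(t(r), method = "bray"))
}

#' Principal coordinates analysis
#'
#' Gower-centred eigendecomposition of the squared distances; coordinates
#' are scaled by the square root of their eigenvalue. Axes with
#' non-positive eigenvalues are reported but dropped from the coordinates.
#'
#' @param d symmetric distance matrix.
#' @return list with `points` (samples x retained axes), `eigenvalues`
#'   (all), and `negative`, the number of negative eigenvalues.
#' @export
pcoaOrdination <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  fit <- stats::cmdscale(stats::as.dist(d), k = nrow(d) - 1, eig = TRUE)
  eig <- fit$eig
  keep <- which(eig[seq_len(ncol(fit$points))] > 1e-10)
  list(points = fit$points[, keep, drop = FALSE], eigenvalues = eig,
       negative = sum(eig < -1e-10))
}

#' Permutation PERMANOVA
#'
#' Pseudo-F from the among/within partition of a distance matrix (vegan's
#' `adonis2`) with a seeded label permutation test:
#' `p = (#(F_perm >= F_obs) + 1) / (nPerm + 1)`, so 999 permutations give a
#' floor of exactly 0.001.
#'
#' @param d distance matrix.
#' @param groups group labels.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer seed.
#' @return list with `F`, `p` and `nPerm`.
#' @export
permanovaTest <- function(d, groups, nPerm = 999, seed = 1) {
  if (nPerm < 99) stop("use at least 99 permutations")
  d <- as.matrix(d)
  groups <- .checkGroups(groups, seq_len(ncol(d)))
  sizes <- table(groups)
  if (all(sizes == 1)) stop("all groups are singletons")
  if (any(sizes == 1))
    warning("group(s) with a single sample: ",
            paste(names(sizes)[sizes == 1], collapse = ", "))
  set.seed(seed)
  df <- data.frame(group = groups)
  fit <- vegan::adonis2(stats::as.dist(d) ~ group, data = df,
                        permutations = nPerm)
  list(F = fit$F[1], p = fit$`Pr(>F)`[1], nPerm = nPerm)
}
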