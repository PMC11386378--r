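# Levins niche breadth, permutation null, specialist/generalist calls and
# asymmetric Levins overlap
#
# The condition states are the ten design groups (ORIGINAL + C1..C9): a
# genus confined to a single state has B_N = 1/10, the floor observed for
# strict specialists.

# per-genus condition shares: mean relative abundance per group state,
# normalised to sum to 1 across states
.conditionShares <- function(r, groups) {
  glev <- levels(groups)
  means <- matrix(vapply(glev, function(g)
    rowMeans(r[, groups == g, drop = FALSE]), numeric(nrow(r))),
    nrow = nrow(r), dimnames = list(rownames(r), glev))
  tot <- rowSums(means)
  list(q = means / tot, total = tot)
}

#' Levins niche breadth
#'
#' For each genus, `q_j` is the share of its total mean relative abundance
#' falling in condition state j; `B = 1 / sum_j q_j^2` and the normalised
#' breadth `B_N = B / R` with R the number of states. `B_N = 1` marks a
#' broad, non-discriminatory niche (generalist); `B_N -> 1/R` a narrow one
#' (specialist).
#'
#' @param x relative-abundance matrix (genera x samples) or a
#'   [GranuleExperiment-class] (collapsed to genus and total-sum scaled
#'   first).
#' @param frame sample frame with a `group` column; every state must have
#'   at least one sample (matrix method).
#' @param ... unused.
#' @return data.frame (`taxon`, `B`, `B_N`, `R`); genera absent everywhere
#'   get NA with a warning.
#' @rdname nicheBreadth
#' @export
setMethod("nicheBreadth", "matrix", function(x, frame, ...) {
  groups <- .checkGroups(frame$group, colnames(x))
  R <- nlevels(groups)
  cs <- .conditionShares(x, groups)
  B <- 1 / rowSums(cs$q^2)
  empty <- cs$total == 0
  if (any(empty)) {
    warning("genera absent from all samples: ",
            paste(rownames(x)[empty], collapse = ", "))
    B[empty] <- NA_real_
  }
  data.frame(taxon = rownames(x), B = B, B_N = B / R, R = R,
             row.names = NULL)
})

#' @rdname nicheBreadth
#' @export
setMethod("nicheBreadth", "GranuleExperiment", function(x, ...) {
  m <- collapseToGenus(counts(x), taxonomyTable(x))
  nicheBreadth(toRelative(m),
               as.data.frame(SummarizedExperiment::colData(x)))
})

#' Permutation null test for niche breadth
#'
#' Shuffles the sample-to-condition assignment (preserving each genus's
#' abundance multiset), recomputes `B_N` for every genus, and reports
#' one-sided permutation p-values for both tails:
#' specialist tail `p = (#(B_N_null <= B_N_obs) + 1) / (nPerm + 1)`,
#' generalist tail analogously with `>=`. Benjamini-Hochberg adjustment is
#' applied across genera within each tail.
#'
#' @param r relative-abundance matrix (genera x samples).
#' @param frame sample frame with `group`.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer seed.
#' @return data.frame (`taxon`, `B_N`, `p_specialist`, `p_adj_specialist`,
#'   `p_generalist`, `p_adj_generalist`).
#' @export
nicheNullTest <- function(r, frame, nPerm = 999, seed = 1) {
  if (nPerm < 99) stop("use at least 99 permutations")
  groups <- .checkGroups(frame$group, colnames(r))
  obs <- nicheBreadth(r, frame)$B_N
  set.seed(seed)
  leS <- integer(nrow(r))
  geG <- integer(nrow(r))
  for (b in seq_len(nPerm)) {
    perm <- groups[sample.int(length(groups))]
    cs <- .conditionShares(r, perm)
    bn <- 1 / rowSums(cs$q^2) / nlevels(groups)
    leS <- leS + as.integer(!is.na(bn) & bn <= obs)
    geG <- geG + as.integer(!is.na(bn) & bn >= obs)
  }
  pS <- (leS + 1) / (nPerm + 1)
  pG <- (geG + 1) / (nPerm + 1)
  pS[is.na(obs)] <- NA
  pG[is.na(obs)] <- NA
  data.frame(taxon = rownames(r), B_N = obs,
             p_specialist = pS, p_adj_specialist = p.adjust(pS, "BH"),
             p_generalist = pG, p_adj_generalist = p.adjust(pG, "BH"),
             row.names = NULL)
}

#' Classify genera as specialists or generalists
#'
#' Thresholds are the empirical 5th and 95th percentiles of `B_N` across
#' all recovered genera: a genus is a `specialist` when its `B_N` is below
#' the lower threshold and its adjusted specialist-tail p-value is below
#' `alpha`; a `generalist` when above the upper threshold with a
#' significant generalist tail; otherwise `neither`.
#'
#' @param profiles data.frame from [nicheNullTest()].
#' @param lowerQ,upperQ threshold quantiles (defaults 0.05 / 0.95).
#' @param alpha significance level on the adjusted p-values.
#' @return `profiles` with added columns `class` and `stars` (from the
#'   specialist/generalist tail actually used), plus the thresholds as
#'   attributes `lower_threshold` / `upper_threshold`.
#' @export
classifyNiche <- function(profiles, lowerQ = 0.05, upperQ = 0.95,
                          alpha = 0.05) {
  bn <- profiles$B_N
  if (sum(!is.na(bn)) < 20)
    warning("fewer than 20 genera; B_N quantile thresholds are unstable")
  lo <- quantile(bn, lowerQ, na.rm = TRUE, names = FALSE)
  hi <- quantile(bn, upperQ, na.rm = TRUE, names = FALSE)
  cls <- rep("neither", nrow(profiles))
  cls[!is.na(bn) & bn < lo & profiles$p_adj_specialist < alpha] <- "specialist"
  cls[!is.na(bn) & bn > hi & profiles$p_adj_generalist < alpha] <- "generalist"
  profiles$class <- factor(cls, levels = c("specialist", "generalist",
                                           "neither"))
  profiles$stars <- ifelse(cls == "generalist",
                           pStars(profiles$p_adj_generalist),
                           pStars(profiles$p_adj_specialist))
  attr(profiles, "lower_threshold") <- lo
  attr(profiles, "upper_threshold") <- hi
  profiles
}

#' Asymmetric Levins niche overlap
#'
#' `LO_{1,2} = sum_j q_1j * q_2j / sum_j q_2j^2` over the condition-share
#' vectors: `LO_{1,2} = 1` means genus 1 fully covers the states where
#' genus 2 occurs. The matrix is not symmetric; the diagonal is exactly 1.
#'
#' @param r relative-abundance matrix (genera x samples).
#' @param frame sample frame with `group`.
#' @param genera genera to compare (default: all rows of `r`).
#' @return `length(genera)` square matrix of LO values (rows = first
#'   index); genera with all-zero shares give NA rows/columns.
#' @export
levinsOverlap <- function(r, frame, genera = rownames(r)) {
  groups <- .checkGroups(frame$group, colnames(r))
  miss <- setdiff(genera, rownames(r))
  if (length(miss)) stop("unknown genera: ", paste(miss, collapse = ", "))
  cs <- .conditionShares(r[genera, , drop = FALSE], groups)
  q <- cs$q
  q[cs$total == 0, ] <- NA
  num <- q %*% t(q)
  den <- rowSums(q^2)
  LO <- sweep(num, 2, den, "/")
  diag(LO) <- ifelse(is.na(den), NA, 1)
  dimnames(LO) <- list(genera, genera)
  LO
}
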