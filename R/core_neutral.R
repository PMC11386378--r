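# abundance-occupancy core ranking with a Bray-Curtis contribution stopping
# rule, and Sloan neutral-model classification of assembly
#
# "Compartments" are the condition groups of the design: the occupancy index
# mixes overall occupancy with mean within-group (replicate-consistency)
# occupancy in equal halves.

#' Occupancy / replicate-consistency ranking
#'
#' `index_i = 0.5 * occ_all(i) + 0.5 * mean_g occ_g(i)` where `occ_all` is
#' the fraction of all samples in which taxon i is detected and `occ_g` the
#' fraction of replicates within group g. Ranking is descending by index
#' with ties broken by total abundance, then lexicographically by id.
#'
#' @param x count matrix (taxa x samples) or [GranuleExperiment-class].
#' @param frame sample frame with a `group` column (matrix method).
#' @param ... unused.
#' @return data.frame (`taxon`, `index`, `occ_all`, `occ_group`, `rank`)
#'   ordered by rank.
#' @rdname occupancyIndex
#' @export
setMethod("occupancyIndex", "matrix", function(x, frame, ...) {
  .checkCountMatrix(x)
  groups <- .checkGroups(frame$group, colnames(x))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  pres <- x > 0
  occAll <- rowMeans(pres)
  occG <- vapply(levels(groups), function(g)
    rowMeans(pres[, groups == g, drop = FALSE]), numeric(nrow(x)))
  occGroup <- rowMeans(occG)
  idx <- 0.5 * occAll + 0.5 * occGroup
  tot <- rowSums(x)
  ord <- order(-idx, -tot, rownames(x))
  out <- data.frame(taxon = rownames(x)[ord], index = idx[ord],
                    occ_all = occAll[ord], occ_group = occGroup[ord],
                    row.names = NULL)
  out$rank <- seq_len(nrow(out))
  out
})

#' @rdname occupancyIndex
#' @export
setMethod("occupancyIndex", "GranuleExperiment", function(x, ...)
  occupancyIndex(counts(x),
                 as.data.frame(SummarizedExperiment::colData(x))))

#' Cumulative Bray-Curtis contribution curve
#'
#' For the top-r ranked taxa K and each sample pair (j, k), the share of
#' Bray-Curtis similarity carried by K is
#' `sum_{i in K} 2 min(r_ij, r_ik) / (sum_i r_ij + sum_i r_ik)`; the curve
#' value at rank r is the mean over pairs of `share / total similarity`,
#' in percent. Non-decreasing in r and exactly 100 at the last rank.
#'
#' @param ranking data.frame from [occupancyIndex()] (or a character vector
#'   of taxon ids in rank order) covering every taxon of `m`.
#' @param m count matrix.
#' @return numeric vector, percent contribution at ranks 1..n.
#' @export
bcContributionCurve <- function(ranking, m) {
  taxa <- if (is.data.frame(ranking)) ranking$taxon else ranking
  if (!setequal(taxa, rownames(m)))
    stop("ranking must cover exactly the taxa of the matrix")
  r <- toRelative(m)[taxa, , drop = FALSE]
  pairs <- combn(ncol(r), 2)
  # columns sum to 1, so the pair denominator is 2 and the similarity share
  # of a set is simply the summed per-taxon minima
  V <- vapply(seq_len(ncol(pairs)), function(c)
    pmin(r[, pairs[1, c]], r[, pairs[2, c]]), numeric(nrow(r)))
  S <- colSums(V)
  zero <- S == 0
  if (any(zero)) {
    warning(sum(zero), " sample pair(s) with zero similarity skipped")
    V <- V[, !zero, drop = FALSE]
    S <- S[!zero]
  }
  cum <- apply(V, 2, cumsum)
  100 * rowMeans(sweep(cum, 2, S, "/"))
}

#' Select the core set from a contribution curve
#'
#' Implements the "last 2% decrease" rule: the core is the smallest top-r*
#' prefix of the ranking such that every subsequent marginal gain in
#' explained Bray-Curtis similarity is below `threshold` percentage points
#' (adding further taxa offers diminishing returns).
#'
#' @param curve non-decreasing percent-contribution curve
#'   ([bcContributionCurve()]).
#' @param ranking the ranking behind the curve (data.frame or id vector).
#' @param threshold marginal-gain threshold in percentage points (default
#'   2).
#' @return character vector: the core taxa (top-r* of the ranking).
#' @export
selectCore <- function(curve, ranking, threshold = 2) {
  if (threshold <= 0) stop("threshold must be positive")
  taxa <- if (is.data.frame(ranking)) ranking$taxon else ranking
  stopifnot(length(taxa) == length(curve))
  gains <- diff(curve)
  big <- which(gains >= threshold)
  rStar <- if (length(big) == 0) 1L else max(big) + 1L
  taxa[seq_len(rStar)]
}

#' Fit the Sloan neutral community model
#'
#' Predicted occupancy of taxon i at migration-depth product Nm is
#' `1 - pbeta(d, Nm * p_i, Nm * (1 - p_i))` with p_i the mean relative
#' abundance and d the detection limit. Nm is fitted by least squares on
#' occupancy via bounded scalar minimisation (on log Nm); the 95% band is a
#' Wilson interval around the predicted occupancy at n = number of samples.
#'
#' @param x count matrix (taxa x samples) or [GranuleExperiment-class].
#' @param detectionLimit detection limit d; default `1 / mean(sample
#'   depth)`.
#' @param ... unused.
#' @return a [NeutralFit-class].
#' @rdname fitNeutralModel
#' @export
setMethod("fitNeutralModel", "matrix",
          function(x, detectionLimit = NULL, ...) {
  .checkCountMatrix(x)
  if (is.null(detectionLimit)) detectionLimit <- 1 / mean(colSums(x))
  if (detectionLimit <= 0) stop("detection limit must be positive")
  d <- detectionLimit
  n <- ncol(x)
  p <- rowMeans(toRelative(x))
  occ <- rowMeans(x > 0)
  keep <- p > 0
  nPartial <- sum(occ[keep] > 0 & occ[keep] < 1)
  if (nPartial < 10)
    warning("only ", nPartial,
            " taxa with intermediate occupancy; fit may be unstable")
  pk <- p[keep]; ok <- occ[keep]
  predict <- function(Nm) 1 - pbeta(d, Nm * pk, Nm * (1 - pk))
  sse <- function(lNm) sum((ok - predict(exp(lNm)))^2)
  bounds <- log(c(1e-3, 1e9))
  opt <- optimize(sse, bounds)
  if (min(abs(opt$minimum - bounds)) < 1e-6)
    warning("Nm optimiser at its bound")
  Nm <- exp(opt$minimum)
  pred <- predict(Nm)
  ci <- .wilson(pred, n)
  R2 <- 1 - opt$objective / sum((ok - mean(ok))^2)
  tab <- data.frame(taxon = rownames(x)[keep], p = pk, occupancy = ok,
                    predicted = pred, lower = ci[, "lower"],
                    upper = ci[, "upper"], row.names = NULL)
  methods::new("NeutralFit", table = tab, Nm = Nm, detectionLimit = d,
               R2 = R2, nSamples = as.integer(n))
})

#' @rdname fitNeutralModel
#' @export
setMethod("fitNeutralModel", "GranuleExperiment", function(x, ...)
  fitNeutralModel(counts(x), ...))

#' Classify assembly of taxa against the neutral expectation
#'
#' `above` (observed occupancy above the upper 95% bound: selected by the
#' environment), `below` (under the lower bound: dispersal limited) or
#' `neutral`.
#'
#' @param fit a [NeutralFit-class].
#' @param subset taxa to classify (default: all fitted taxa; the core set
#'   in the granule analysis).
#' @return named factor with levels `above`, `neutral`, `below`.
#' @export
classifyNeutrality <- function(fit, subset = NULL) {
  stopifnot(methods::is(fit, "NeutralFit"))
  tab <- fit@table
  if (is.null(subset)) subset <- tab$taxon
  miss <- setdiff(subset, tab$taxon)
  if (length(miss))
    stop("taxa absent from fit: ", paste(miss, collapse = ", "))
  tab <- tab[match(subset, tab$taxon), ]
  cls <- ifelse(tab$occupancy > tab$upper, "above",
                ifelse(tab$occupancy < tab$lower, "below", "neutral"))
  factor(setNames(cls, subset), levels = c("above", "neutral", "below"))
}

#' Full core-microbiome + neutral-assembly analysis
#'
#' Chains [occupancyIndex()], [bcContributionCurve()], [selectCore()],
#' [fitNeutralModel()] and [classifyNeutrality()] (classification restricted
#' to the core set).
#'
#' @param x a [GranuleExperiment-class] or count matrix.
#' @param frame sample frame (matrix input only).
#' @param threshold marginal-gain threshold of [selectCore()].
#' @param detectionLimit see [fitNeutralModel()].
#' @return a [CoreNeutralResult-class].
#' @export
coreNeutralAnalysis <- function(x, frame = NULL, threshold = 2,
                                detectionLimit = NULL) {
  if (methods::is(x, "GranuleExperiment")) {
    frame <- as.data.frame(SummarizedExperiment::colData(x))
    x <- counts(x)
  }
  rk <- occupancyIndex(x, frame)
  curve <- bcContributionCurve(rk, x)
  core <- selectCore(curve, rk, threshold)
  fit <- fitNeutralModel(x, detectionLimit = detectionLimit)
  cls <- classifyNeutrality(fit, intersect(core, fit@table$taxon))
  methods::new("CoreNeutralResult", ranking = rk, curve = curve,
               core = core, fit = fit, classes = cls)
}
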