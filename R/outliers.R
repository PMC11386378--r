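# CLR-based within-group replicate-consistency screening
#
# Replicate granules are declared one homogeneous community when no sample
# contributes more than median + 2 IQR of the per-sample share of the
# group's total variance on the CLR scale.

#' Centred log-ratio transform
#'
#' Per sample j: `x_ij = ln((c_ij + pseudocount) / g_j)` with `g_j` the
#' geometric mean of `(c_ij + pseudocount)` over taxa, so every column sums
#' to zero.
#'
#' @param x count matrix (taxa x samples) or [GranuleExperiment-class].
#' @param pseudocount positive offset added to every count before taking
#'   logs (default 0.5: simple symmetric zero handling).
#' @return real matrix of the same shape; columns sum to 0.
#' @examples
#' m <- matrix(c(9L, 0L), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' clrTransform(m, pseudocount = 1)
#' @rdname clrTransform
#' @export
setMethod("clrTransform", "matrix", function(x, pseudocount = 0.5, ...) {
  .checkCountMatrix(x)
  if (pseudocount <= 0) stop("pseudocount must be positive")
  lx <- log(x + pseudocount)
  out <- sweep(lx, 2, colMeans(lx))
  attr(out, "pseudocount") <- pseudocount
  out
})

#' @rdname clrTransform
#' @export
setMethod("clrTransform", "GranuleExperiment",
          function(x, pseudocount = 0.5, ...)
            clrTransform(counts(x), pseudocount))

#' Per-sample contributions to group variance
#'
#' For CLR-transformed data, each sample's sum of squared deviations from
#' the per-taxon mean, as a fraction of the group total:
#' `SS_j = sum_i (x_ij - mean_i)^2`, `contribution_j = SS_j / sum_k SS_k`.
#'
#' @param x CLR matrix (taxa x samples) with at least two samples.
#' @return named numeric vector of fractions summing to 1.
#' @export
varianceContributions <- function(x) {
  if (!is.matrix(x) || ncol(x) < 2)
    stop("need a matrix with at least 2 samples")
  ss <- colSums((x - rowMeans(x))^2)
  tot <- sum(ss)
  if (tot == 0) stop("no variance in group")
  ss / tot
}

#' Flag outlying replicates
#'
#' Applies the outlier rule to per-sample variance contributions: the cutoff
#' is `median + 2 * IQR` of the contributions (linear-interpolation
#' quantiles) and samples strictly above it are flagged.
#'
#' @param contributions named fractions from [varianceContributions()];
#'   at least 4 samples so the IQR is meaningful.
#' @param pseudocount recorded in the report for provenance.
#' @return an [OutlierReport-class].
#' @export
detectOutliers <- function(contributions, pseudocount = 0.5) {
  if (length(contributions) < 4)
    stop("need at least 4 samples for the median + 2 IQR rule")
  med <- median(contributions)
  iqr <- IQR(contributions) # type = 7, linear interpolation
  cutoff <- med + 2 * iqr
  flagged <- names(contributions)[contributions > cutoff]
  methods::new("OutlierReport", contributions = contributions, median = med,
               iqr = iqr, cutoff = cutoff,
               flagged = if (is.null(flagged)) character() else flagged,
               pseudocount = pseudocount)
}

#' Replicate-consistency screen for one sample group
#'
#' Convenience wrapper chaining [clrTransform()], [varianceContributions()]
#' and [detectOutliers()] for the samples of one group (by default the
#' untreated `ORIGINAL` replicates).
#'
#' @param x a [GranuleExperiment-class] or count matrix.
#' @param group group label to screen (ignored for plain matrices, which are
#'   screened as given).
#' @param pseudocount CLR pseudocount.
#' @param ... unused.
#' @return an [OutlierReport-class].
#' @rdname screenReplicates
#' @export
setMethod("screenReplicates", "GranuleExperiment",
          function(x, group = "ORIGINAL", pseudocount = 0.5, ...) {
  keep <- sampleGroups(x) == group
  if (!any(keep)) stop("no samples in group ", group)
  screenReplicates(counts(x)[, keep, drop = FALSE], pseudocount = pseudocount)
})

#' @rdname screenReplicates
#' @export
setMethod("screenReplicates", "matrix",
          function(x, pseudocount = 0.5, ...) {
  detectOutliers(varianceContributions(clrTransform(x, pseudocount)),
                 pseudocount = pseudocount)
})
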