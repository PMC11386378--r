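#' GranuleExperiment: container for a single-granule community experiment
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with the conventions
#' used throughout this package: a single `counts` assay of non-negative
#' taxon-by-sample counts, sample annotation (`colData`) holding the
#' incubation design (`group`, `replicate`, `pH`, `temperature_C`,
#' `substrate`, `cobalt`) and taxon annotation (`rowData`) holding the
#' taxonomic lineage and, for simulated data, the planted ground-truth
#' labels.
#'
#' @slot .. no additional slots; the class fixes invariants on the inherited
#'   ones via its validity method.
#' @seealso [GranuleExperiment()] for construction, [simulateExperiment()]
#'   for simulated instances.
#' @export
setClass("GranuleExperiment", contains = "SummarizedExperiment")

setValidity("GranuleExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(m)) msg <- c(msg, "counts contain NA")
    if (any(m < 0)) msg <- c(msg, "counts contain negative entries")
    if (any(colSums(m) == 0)) msg <- c(msg, "some samples have zero total count")
  }
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate taxon ids")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate sample ids")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  if (length(msg)) msg else TRUE
})

#' Report from CLR replicate-consistency screening
#'
#' Per-sample proportional contributions to within-group variance on the CLR
#' scale, the median + 2 IQR outlier cutoff, and the flagged samples.
#'
#' @slot contributions named numeric, fractions summing to 1.
#' @slot median,iqr,cutoff numeric scalars; `cutoff = median + 2 * iqr`.
#' @slot flagged character, sample ids strictly above the cutoff.
#' @slot pseudocount numeric, pseudocount used for the CLR transform.
#' @export
setClass("OutlierReport",
  representation(contributions = "numeric", median = "numeric",
                 iqr = "numeric", cutoff = "numeric",
                 flagged = "character", pseudocount = "numeric"))

setValidity("OutlierReport", function(object) {
  msg <- character()
  co <- object@contributions
  if (any(co < 0)) msg <- c(msg, "negative contributions")
  if (abs(sum(co) - 1) > 1e-8) msg <- c(msg, "contributions must sum to 1")
  if (!setequal(object@flagged, names(co)[co > object@cutoff]))
    msg <- c(msg, "flagged set inconsistent with cutoff")
  if (length(msg)) msg else TRUE
})

#' Per-taxon condition-response model
#'
#' Negative-binomial regression coefficients of taxon counts against the
#' incubation conditions (natural-log scale, untreated reference), with Wald
#' standard errors, per-taxon dispersion and optional latent-factor terms.
#'
#' @slot taxa character, modelled taxa.
#' @slot intercepts named numeric.
#' @slot coefficients,se taxa x condition matrices.
#' @slot dispersion per-taxon NB size parameter (theta).
#' @slot converged per-taxon convergence flag.
#' @slot rank latent-factor rank used (0 = plain NB regression).
#' @slot loadings,scores latent-factor loadings (taxa x rank) and per-sample
#'   scores (samples x rank); zero-column matrices when `rank = 0`.
#' @slot conditions character, condition (non-reference) group labels.
#' @export
setClass("ResponseModel",
  representation(taxa = "character", intercepts = "numeric",
                 coefficients = "matrix", se = "matrix",
                 dispersion = "numeric", converged = "logical",
                 rank = "integer", loadings = "matrix", scores = "matrix",
                 conditions = "character"))

setValidity("ResponseModel", function(object) {
  msg <- character()
  if (ncol(object@coefficients) != length(object@conditions))
    msg <- c(msg, "coefficient columns must match conditions")
  if (!identical(dim(object@coefficients), dim(object@se)))
    msg <- c(msg, "coefficients and standard errors differ in shape")
  if (length(msg)) msg else TRUE
})

#' Stable-ensemble search result
#'
#' A genus subset whose summed relative abundance has minimal coefficient of
#' variation (CV) across samples, plus the fitness trajectory of the search.
#'
#' @slot members character, the genus set.
#' @slot cv CV of the summed relative abundance of the members.
#' @slot trajectory best CV after each generation (non-increasing).
#' @slot generations number of generations run.
#' @slot converged TRUE if the search stalled before the generation cap.
#' @slot seed integer seed used (NA for exhaustive search).
#' @slot method "ga" or "exhaustive".
#' @export
setClass("EnsembleSolution",
  representation(members = "character", cv = "numeric",
                 trajectory = "numeric", generations = "integer",
                 converged = "logical", seed = "integer", method = "character"))

setValidity("EnsembleSolution", function(object) {
  msg <- character()
  if (object@cv < 0) msg <- c(msg, "CV must be non-negative")
  if (length(object@trajectory) &&
      any(diff(object@trajectory) > 1e-12))
    msg <- c(msg, "fitness trajectory must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Sloan neutral-model fit
#'
#' Least-squares fit of the neutral expectation of taxon occupancy from mean
#' relative abundance, with a Wilson 95% band and per-taxon classification
#' input.
#'
#' @slot table data.frame with columns `taxon`, `p` (mean relative
#'   abundance), `occupancy`, `predicted`, `lower`, `upper`.
#' @slot Nm fitted migration-depth product.
#' @slot detectionLimit detection limit d used.
#' @slot R2 coefficient of determination of the occupancy fit.
#' @slot nSamples number of samples behind the occupancies.
#' @export
setClass("NeutralFit",
  representation(table = "data.frame", Nm = "numeric",
                 detectionLimit = "numeric", R2 = "numeric",
                 nSamples = "integer"))

setValidity("NeutralFit", function(object) {
  if (object@Nm <= 0) "Nm must be positive" else TRUE
})

#' Combined core-microbiome and neutral-assembly result
#'
#' @slot ranking data.frame of per-taxon occupancy index and rank.
#' @slot curve cumulative percent contribution to Bray-Curtis similarity at
#'   each rank.
#' @slot core character, the selected core taxa.
#' @slot fit the [NeutralFit-class] used for assembly classification.
#' @slot classes factor (`above`/`neutral`/`below`) over the core taxa.
#' @export
setClass("CoreNeutralResult",
  representation(ranking = "data.frame", curve = "numeric",
                 core = "character", fit = "NeutralFit", classes = "factor"))
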