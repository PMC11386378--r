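#' Construct a GranuleExperiment
#'
#' Bundles a taxon-by-sample count matrix, the sample frame describing the
#' incubation design, and (optionally) a taxonomy table into a validated
#' [GranuleExperiment-class] object.
#'
#' @param counts non-negative numeric matrix, taxa in rows, samples in
#'   columns, with unique dimnames.
#' @param sampleData data.frame keyed by `sample_id` (or with rownames equal
#'   to the sample ids) containing at least a `group` column; typically the
#'   frame produced by [makeSampleFrame()].
#' @param taxonomy optional data.frame as returned by [readTaxonomyTable()];
#'   matched to the taxa by its `taxon_id` column.
#' @param truth optional data.frame of planted ground-truth labels (one row
#'   per taxon) as produced by [simulateExperiment()].
#' @return a `GranuleExperiment`.
#' @examples
#' m <- matrix(c(5L, 3L, 0L, 7L), 2, dimnames = list(c("t1", "t2"), c("a", "b")))
#' sf <- data.frame(sample_id = c("a", "b"), group = "ORIGINAL",
#'                  replicate = 1:2)
#' GranuleExperiment(m, sf)
#' @export
GranuleExperiment <- function(counts, sampleData, taxonomy = NULL,
                              truth = NULL) {
  .checkCountMatrix(counts)
  if (!is.null(sampleData$sample_id)) {
    rownames(sampleData) <- sampleData$sample_id
  }
  sampleData <- sampleData[colnames(counts), , drop = FALSE]
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(taxonomy)) {
    idx <- match(rownames(counts), taxonomy$taxon_id)
    if (anyNA(idx))
      stop("taxa missing from taxonomy: ",
           paste(head(rownames(counts)[is.na(idx)], 5), collapse = ", "))
    rd <- cbind(rd, DataFrame(taxonomy[idx, setdiff(colnames(taxonomy),
                                                    "taxon_id"),
                                       drop = FALSE]))
  }
  if (!is.null(truth)) {
    rd <- cbind(rd, DataFrame(truth))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(sampleData),
    rowData = rd)
  methods::new("GranuleExperiment", se)
}

#' @describeIn GranuleExperiment count matrix accessor.
#' @param object,x a `GranuleExperiment`.
#' @export
setMethod("counts", "GranuleExperiment", function(object)
  SummarizedExperiment::assay(object, "counts"))

#' Sample group labels
#'
#' @param x a [GranuleExperiment-class].
#' @return factor of group labels (e.g. `ORIGINAL`, `C1` ... `C9`), one per
#'   sample.
#' @export
sampleGroups <- function(x) {
  stopifnot(methods::is(x, "GranuleExperiment"))
  droplevels(as.factor(SummarizedExperiment::colData(x)$group))
}

#' Taxonomy annotation of a GranuleExperiment
#'
#' @param x a [GranuleExperiment-class].
#' @return data.frame of the taxon annotation columns (lineage ranks), or an
#'   empty data.frame when none were supplied.
#' @export
taxonomyTable <- function(x) {
  stopifnot(methods::is(x, "GranuleExperiment"))
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  keep <- intersect(c("domain", "phylum", "class", "order", "family",
                      "genus"), colnames(rd))
  cbind(data.frame(taxon_id = rownames(x)), rd[, keep, drop = FALSE])
}

#' Planted ground truth of a simulated experiment
#'
#' @param x a [GranuleExperiment-class] produced by [simulateExperiment()].
#' @return data.frame with at least a `label` column, or NULL for real data.
#' @export
plantedTruth <- function(x) {
  stopifnot(methods::is(x, "GranuleExperiment"))
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  if (!"label" %in% colnames(rd)) return(NULL)
  keep <- grep("^(label|delta_|specialist_|true_)", colnames(rd), value = TRUE)
  cbind(data.frame(taxon_id = rownames(x)), rd[, keep, drop = FALSE])
}

setMethod("show", "GranuleExperiment", function(object) {
  cat("GranuleExperiment:", nrow(object), "taxa x", ncol(object), "samples\n")
  g <- table(sampleGroups(object))
  cat("groups:", paste(names(g), g, sep = "=", collapse = " "), "\n")
  if (!is.null(plantedTruth(object)))
    cat("planted truth:",
        paste(names(table(plantedTruth(object)$label)), collapse = ", "), "\n")
})

setMethod("show", "OutlierReport", function(object) {
  cat("OutlierReport:", length(object@contributions), "samples; cutoff",
      signif(object@cutoff, 4), "\n")
  if (length(object@flagged))
    cat("flagged:", paste(object@flagged, collapse = ", "), "\n")
  else cat("no outliers flagged\n")
})

setMethod("show", "ResponseModel", function(object) {
  cat("ResponseModel:", length(object@taxa), "taxa x",
      length(object@conditions), "conditions (rank", object@rank, ")\n")
  cat("converged:", sum(object@converged), "/", length(object@taxa), "\n")
})

setMethod("show", "EnsembleSolution", function(object) {
  cat("EnsembleSolution (", object@method, "): ", length(object@members),
      " members, CV = ", signif(object@cv, 4), "\n", sep = "")
})

setMethod("show", "NeutralFit", function(object) {
  cat("NeutralFit: Nm =", signif(object@Nm, 5), ", R2 =",
      signif(object@R2, 4), ", d =", signif(object@detectionLimit, 3),
      ",", nrow(object@table), "taxa\n")
})

setMethod("show", "CoreNeutralResult", function(object) {
  cat("CoreNeutralResult:", length(object@core), "core taxa of",
      nrow(object@ranking), "\n")
  print(table(object@classes))
})

#' Accessors for result objects
#'
#' Small extractor functions so downstream code does not reach into slots.
#'
#' @param x a result object of this package.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
ensembleMembers <- function(x) x@members

#' @rdname accessors
#' @export
ensembleCv <- function(x) x@cv

#' @rdname accessors
#' @export
fitnessTrajectory <- function(x) x@trajectory

#' @rdname accessors
#' @export
responseCoefficients <- function(x) x@coefficients

#' @rdname accessors
#' @export
responseSE <- function(x) x@se

#' @rdname accessors
#' @export
outlierSamples <- function(x) x@flagged

#' @rdname accessors
#' @export
varianceContributionValues <- function(x) x@contributions

#' @rdname accessors
#' @export
neutralTable <- function(x) x@table

#' @rdname accessors
#' @export
migrationEstimate <- function(x) x@Nm

#' @rdname accessors
#' @export
fitR2 <- function(x) x@R2

#' @rdname accessors
#' @export
coreTaxa <- function(x) x@core

#' @rdname accessors
#' @export
coreRanking <- function(x) x@ranking

#' @rdname accessors
#' @export
contributionCurve <- function(x) x@curve

#' @rdname accessors
#' @export
assemblyClasses <- function(x) x@classes
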