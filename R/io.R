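# table io, genus collation, normalisation and the shared condition design
#
# All tables are tab-separated UTF-8 with a header line; the first column of
# a count table is the literal "taxon_id". One fixed dialect, no
# autodetection.

#' The micro-batch-reactor condition design
#'
#' The ten sample groups of the single-granule experiment: untreated
#' `ORIGINAL` granules plus nine incubation conditions spanning a plate
#' baseline, pH, temperature, substrate and cobalt-deprivation effects.
#'
#' @return data.frame with columns `group`, `pH`, `temperature_C`,
#'   `substrate`, `cobalt`; the `ORIGINAL` row carries NA incubation
#'   parameters.
#' @examples
#' conditionDesign()
#' @export
conditionDesign <- function() {
  data.frame(
    group = c("ORIGINAL", paste0("C", 1:9)),
    pH = c(NA, 7, 4, 10, 7, 7, 7, 7, 7, 7),
    temperature_C = c(NA, 37, 37, 37, 23, 37, 37, 37, 37, 37),
    substrate = c(NA, "VFA_MIX", "VFA_MIX", "VFA_MIX", "VFA_MIX",
                  "CELLULOSE", "GLUCOSE", "ACETATE", "ACETATE", "VFA_MIX"),
    cobalt = c(NA, rep("supplied", 7), "deprived", "deprived"),
    stringsAsFactors = FALSE)
}

.groupLevels <- function() c("ORIGINAL", paste0("C", 1:9))

#' Build the default sample frame
#'
#' Lays out the sample-to-group design of the experiment: `nOriginal`
#' untreated replicate granules plus `nReplicates` granules under each of the
#' nine incubation conditions (43 samples under the defaults), with the
#' incubation parameters filled in from [conditionDesign()].
#'
#' @param nOriginal number of untreated replicate samples.
#' @param nReplicates replicates per incubation condition.
#' @return data.frame with columns `sample_id`, `group`, `replicate`, `pH`,
#'   `temperature_C`, `substrate`, `cobalt`.
#' @examples
#' nrow(makeSampleFrame())  # 43
#' @export
makeSampleFrame <- function(nOriginal = 16, nReplicates = 3) {
  stopifnot(nOriginal >= 1, nReplicates >= 1)
  des <- conditionDesign()
  rows <- lapply(seq_len(nrow(des)), function(i) {
    n <- if (des$group[i] == "ORIGINAL") nOriginal else nReplicates
    data.frame(
      sample_id = sprintf("%s_r%02d", des$group[i], seq_len(n)),
      group = des$group[i], replicate = seq_len(n),
      pH = des$pH[i], temperature_C = des$temperature_C[i],
      substrate = des$substrate[i], cobalt = des$cobalt[i],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = .groupLevels())
  rownames(out) <- out$sample_id
  out
}

#' Validate a sample frame against the condition design
#'
#' Checks that every condition group carries exactly the incubation
#' parameters of [conditionDesign()] and that `ORIGINAL` samples carry none.
#'
#' @param frame a sample frame data.frame.
#' @return the frame, invisibly; errors describe the first violation.
#' @export
validateSampleFrame <- function(frame) {
  need <- c("sample_id", "group", "replicate")
  if (!all(need %in% colnames(frame)))
    stop("sample frame must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(frame$sample_id)) stop("duplicate sample ids")
  bad <- setdiff(unique(as.character(frame$group)), .groupLevels())
  if (length(bad)) stop("unknown groups: ", paste(bad, collapse = ", "))
  des <- conditionDesign()
  par_cols <- intersect(c("pH", "temperature_C", "substrate", "cobalt"),
                        colnames(frame))
  for (g in setdiff(unique(as.character(frame$group)), "ORIGINAL")) {
    for (p in par_cols) {
      want <- des[des$group == g, p]
      got <- unique(frame[frame$group == g, p])
      if (!all(got == want))
        stop("group ", g, " carries ", p, " = ", paste(got, collapse = "/"),
             " but the design requires ", want)
    }
  }
  if ("pH" %in% par_cols && any(!is.na(frame$pH[frame$group == "ORIGINAL"])))
    stop("ORIGINAL samples must not carry incubation parameters")
  invisible(frame)
}

#' Read a taxon-by-sample count table
#'
#' @param path TSV file whose header starts with `taxon_id` followed by the
#'   sample ids; cells are non-negative integers.
#' @return integer matrix, taxa in rows (named), samples in columns, column
#'   order as in the file.
#' @export
readCountTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (colnames(df)[1] != "taxon_id")
    stop("first column of a count table must be 'taxon_id', got '",
         colnames(df)[1], "'")
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate taxon ids in ", path)
  if (anyDuplicated(colnames(df)[-1])) stop("duplicate sample ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-integer or negative count '", m[bad[1, 1], bad[1, 2]],
         "' at taxon '", ids[bad[1, 1]], "', sample '",
         colnames(m)[bad[1, 2]], "'")
  }
  storage.mode(num) <- "integer"
  dimnames(num) <- list(ids, colnames(m))
  num
}

#' Write a count table
#'
#' Inverse of [readCountTable()]; round-trips losslessly.
#'
#' @param m taxon-by-sample matrix.
#' @param path output TSV path.
#' @export
writeCountTable <- function(m, path) {
  .checkCountMatrix(m)
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy lineage table
#'
#' @param path TSV with columns `taxon_id`, `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus`; empty or NA genus cells denote unassigned
#'   taxa (pooled as "unknowns" by [collapseToGenus()]).
#' @return data.frame.
#' @export
readTaxonomyTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (!"taxon_id" %in% colnames(df)) stop("taxonomy table needs 'taxon_id'")
  if (!"genus" %in% colnames(df)) stop("taxonomy table needs 'genus'")
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon ids in ", path)
  df
}

#' @rdname readTaxonomyTable
#' @param tax taxonomy data.frame.
#' @export
writeTaxonomyTable <- function(tax, path) {
  write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `group`, `replicate`, `pH`,
#'   `temperature_C`, `substrate`, `cobalt`.
#' @return data.frame with `group` as a factor over the design levels.
#' @export
readSampleFrame <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validateSampleFrame(df)
  df$group <- factor(df$group, levels = .groupLevels())
  rownames(df) <- df$sample_id
  df
}

#' @rdname readSampleFrame
#' @param frame sample frame data.frame.
#' @export
writeSampleFrame <- function(frame, path) {
  write.table(frame, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a GranuleExperiment from its three tables
#'
#' @param countPath,taxonomyPath,metadataPath TSV paths; `taxonomyPath` may
#'   be NULL.
#' @return a [GranuleExperiment-class].
#' @export
readGranuleExperiment <- function(countPath, metadataPath,
                                  taxonomyPath = NULL) {
  m <- readCountTable(countPath)
  frame <- readSampleFrame(metadataPath)
  tax <- if (is.null(taxonomyPath)) NULL else readTaxonomyTable(taxonomyPath)
  GranuleExperiment(m, frame, taxonomy = tax)
}

#' Collate taxa to genus level
#'
#' Sums the counts of all taxa sharing a genus label into one row per genus;
#' taxa without a genus assignment are pooled into a single `"unknowns"` row.
#' Per-sample totals are conserved exactly (integer arithmetic).
#'
#' @param x count matrix (taxa x samples) or [GranuleExperiment-class].
#' @param taxonomy data.frame with `taxon_id` and `genus` columns covering
#'   every taxon of `x`.
#' @return genus-by-sample matrix (rows in lexicographic genus order), or a
#'   genus-level `GranuleExperiment`.
#' @rdname collapseToGenus
#' @export
setMethod("collapseToGenus", "matrix", function(x, taxonomy, ...) {
  .checkCountMatrix(x)
  idx <- match(rownames(x), taxonomy$taxon_id)
  if (anyNA(idx))
    stop("taxa missing from taxonomy: ",
         paste(rownames(x)[is.na(idx)], collapse = ", "))
  genus <- taxonomy$genus[idx]
  genus[is.na(genus) | genus == ""] <- "unknowns"
  rowsum(x, group = genus)
})

#' @rdname collapseToGenus
#' @export
setMethod("collapseToGenus", "GranuleExperiment", function(x, taxonomy, ...) {
  if (missing(taxonomy)) taxonomy <- taxonomyTable(x)
  m <- collapseToGenus(counts(x), taxonomy)
  GranuleExperiment(m, as.data.frame(SummarizedExperiment::colData(x)))
})

#' Total-sum scaling to relative abundances
#'
#' @param x count matrix or [GranuleExperiment-class]; every sample must have
#'   a positive total.
#' @return matrix of the same shape whose columns sum to 1.
#' @rdname toRelative
#' @export
setMethod("toRelative", "matrix", function(x, ...) {
  .checkCountMatrix(x, "abundance matrix")
  cs <- colSums(x)
  if (any(cs == 0))
    stop("zero-sum sample(s): ",
         paste(colnames(x)[cs == 0], collapse = ", "))
  sweep(x, 2, cs, "/")
})

#' @rdname toRelative
#' @export
setMethod("toRelative", "GranuleExperiment", function(x, ...)
  toRelative(counts(x)))

#' Most abundant taxa
#'
#' Ranks taxa by relative abundance summed over samples (total-sum scaled per
#' sample first, so deep samples do not dominate), descending; ties broken
#' lexicographically by taxon id.
#'
#' @param x count matrix or [GranuleExperiment-class].
#' @param n number of taxa to return (clamped to the number available).
#' @return character vector of taxon ids, most abundant first.
#' @rdname topTaxa
#' @export
setMethod("topTaxa", "matrix", function(x, n, ...) {
  stopifnot(n >= 1)
  tot <- rowSums(toRelative(x))
  ord <- order(-tot, rownames(x))
  rownames(x)[ord][seq_len(min(n, nrow(x)))]
})

#' @rdname topTaxa
#' @export
setMethod("topTaxa", "GranuleExperiment", function(x, n, ...)
  topTaxa(counts(x), n))
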