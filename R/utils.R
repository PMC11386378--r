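# internal helpers shared across modules

# derive a per-stage child seed from a single user seed; kept well below
# .Machine$integer.max so set.seed() always accepts it
.childSeed <- function(seed, offset) {
  (abs(as.integer(seed)) %% 1000000L) * 1000L + as.integer(offset)
}

.checkCountMatrix <- function(m, what = "count matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix (taxa x samples)")
  if (anyNA(m)) stop(what, " contains missing values")
  if (any(m < 0)) stop(what, " contains negative entries")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate taxon ids in ", what)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", what)
  invisible(m)
}

.checkGroups <- function(groups, samples) {
  groups <- as.factor(groups)
  if (length(groups) != length(samples))
    stop("group vector length does not match number of samples")
  droplevels(groups)
}

# Wilson score interval for a proportion
.wilson <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  cbind(lower = pmax(0, ctr - hw), upper = pmin(1, ctr + hw))
}

#' Significance stars for p-values
#'
#' Maps p-values to the conventional star labels: `***` for p < 0.001, `**`
#' for p < 0.01, `*` for p < 0.05 and `""` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of the same length.
#' @examples
#' pStars(c(0.2, 0.04, 0.004, 0.0004))
#' @export
pStars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 0.001) "***" else if (x < 0.01) "**" else if (x < 0.05) "*" else ""
  }, character(1))
}
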