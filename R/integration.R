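# cross-analysis membership matrix and VFA consumption summaries

#' Cross-analysis membership matrix
#'
#' Combines the taxon sets returned by the individual analyses into one
#' boolean matrix (taxa x categories). Rows are the union of all sets,
#' sorted by the number of categories a taxon appears in (descending), then
#' lexicographically.
#'
#' @param top25,resilient,susceptible,stable,core,specialist character
#'   vectors of taxa over a common genus namespace (any may be empty).
#' @return logical matrix with columns `Top25`, `Resilient`, `Susceptible`,
#'   `Stable`, `Core`, `Specialist`. A taxon in both the resilient and the
#'   susceptible set is an error (the sign rule forbids it).
#' @export
buildMembershipMatrix <- function(top25 = character(),
                                  resilient = character(),
                                  susceptible = character(),
                                  stable = character(),
                                  core = character(),
                                  specialist = character()) {
  both <- intersect(resilient, susceptible)
  if (length(both))
    stop("taxa cannot be both resilient and susceptible: ",
         paste(both, collapse = ", "))
  sets <- list(Top25 = top25, Resilient = resilient,
               Susceptible = susceptible, Stable = stable, Core = core,
               Specialist = specialist)
  taxa <- sort(unique(unlist(sets)))
  M <- vapply(sets, function(s) taxa %in% s, logical(length(taxa)))
  if (length(taxa) == 0)
    return(matrix(logical(0), 0, length(sets),
                  dimnames = list(NULL, names(sets))))
  M <- matrix(M, nrow = length(taxa), dimnames = list(taxa, names(sets)))
  M[order(-rowSums(M), rownames(M)), , drop = FALSE]
}

#' Fraction of a compound consumed over an incubation cycle
#'
#' `(C_first - C_last) / C_first` from the first and last observed time
#' points; negative values indicate net production.
#'
#' @param series data.frame with `time_h` and `concentration_mg_l` columns
#'   (as from [simulateVfaSeries()]), or a numeric concentration vector in
#'   time order.
#' @return consumed fraction (<= 1); NA with a warning when the initial
#'   concentration is zero.
#' @export
vfaConsumption <- function(series) {
  conc <- if (is.data.frame(series)) {
    if (nrow(series) < 2) stop("need at least 2 time points")
    series$concentration_mg_l[order(series$time_h)]
  } else {
    if (length(series) < 2) stop("need at least 2 time points")
    as.numeric(series)
  }
  c0 <- conc[1]
  if (c0 == 0) {
    warning("initial concentration is zero")
    return(NA_real_)
  }
  (c0 - conc[length(conc)]) / c0
}

#' Permutation test for a difference in consumption fractions
#'
#' Two-sided seeded permutation test on the difference of group means:
#' `p = (#(|diff_perm| >= |diff_obs|) + 1) / (nPerm + 1)`.
#'
#' @param groupA,groupB numeric vectors (>= 2 replicates each).
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return list with `diff` (mean A - mean B) and `p`.
#' @export
compareConsumption <- function(groupA, groupB, nPerm = 9999, seed = 1) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("need at least 2 replicates per group")
  pooled <- c(groupA, groupB)
  nA <- length(groupA)
  obs <- mean(groupA) - mean(groupB)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(nPerm)) {
    idx <- sample.int(length(pooled), nA)
    d <- mean(pooled[idx]) - mean(pooled[-idx])
    if (abs(d) >= abs(obs) - 1e-15) hits <- hits + 1L
  }
  list(diff = obs, p = (hits + 1) / (nPerm + 1))
}
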