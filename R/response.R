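# per-taxon condition-response modelling
#
# Counts of each (genus-level) taxon are regressed on the incubation
# condition with the untreated ORIGINAL group as reference:
#   log mu_ij = log s_i + alpha_j + beta_{j, c(i)} [+ u_i' lambda_j]
# with s_i the sample total as offset and a negative-binomial error.
# Latent sample scores u_i (rank d >= 0) are an optional variance-absorbing
# refinement fitted by alternating conditional maximisation; the
# resilient/susceptible calls use only the signs of beta.

.fitTaxon <- function(y, df, family) {
  if (family == "poisson") {
    fit <- tryCatch(suppressWarnings(
      stats::glm(y ~ . - offs + offset(offs), data = cbind(y = y, df),
                 family = stats::poisson())), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(fit = fit, theta = Inf, converged = fit$converged)
  } else {
    fit <- tryCatch(suppressWarnings(
      MASS::glm.nb(y ~ . - offs + offset(offs), data = cbind(y = y, df))),
      error = function(e) NULL)
    if (is.null(fit)) {
      # fall back to Poisson and flag non-convergence of the NB fit
      fit <- tryCatch(suppressWarnings(
        stats::glm(y ~ . - offs + offset(offs), data = cbind(y = y, df),
                   family = stats::poisson())), error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      return(list(fit = fit, theta = Inf, converged = FALSE))
    }
    list(fit = fit, theta = max(fit$theta, 1e-8), converged = fit$converged)
  }
}

#' Fit the condition-response model
#'
#' One negative-binomial regression per taxon of counts on the condition
#' groups (reference `ORIGINAL`), with the log sample total as offset so
#' coefficients are log fold changes of relative abundance. With
#' `rank > 0`, latent per-sample scores and per-taxon loadings are added and
#' estimated by alternating conditional maximisation (taxon-wise GLM given
#' scores, score update given loadings) until the penalised log-likelihood
#' changes by less than `tol`.
#'
#' @param x count matrix (taxa x samples, typically the top-100 genera) or a
#'   [GranuleExperiment-class].
#' @param frame sample frame (matrix method only); needs a `group` column
#'   with an `ORIGINAL` level of >= 2 samples.
#' @param rank number of latent factors (default 0; the classification uses
#'   only coefficient signs, latent terms are a refinement).
#' @param sampleTotals per-sample totals used for the offset; defaults to
#'   the column sums of `x`. Pass the totals of the full table when `x` is a
#'   subset of taxa.
#' @param family `"nb"` (default) or `"poisson"` (infinite-dispersion
#'   limit).
#' @param tol,maxIter convergence tolerance and iteration cap of the
#'   alternating maximisation (`rank > 0` only).
#' @param seed seed for the latent-score initialisation.
#' @param ... unused.
#' @return a [ResponseModel-class]. Taxa with all-zero counts get NA
#'   coefficients with a warning; taxa whose NB fit fails fall back to
#'   Poisson and are flagged unconverged.
#' @rdname fitResponseModel
#' @export
setMethod("fitResponseModel", "matrix",
          function(x, frame, rank = 0, sampleTotals = NULL, family = "nb",
                   tol = 1e-6, maxIter = 500, seed = 1, ...) {
  .checkCountMatrix(x)
  family <- match.arg(family, c("nb", "poisson"))
  groups <- .checkGroups(frame$group, colnames(x))
  if (!"ORIGINAL" %in% levels(groups) || sum(groups == "ORIGINAL") < 2)
    stop("need an ORIGINAL reference group with at least 2 samples")
  groups <- stats::relevel(groups, "ORIGINAL")
  conds <- levels(groups)[-1]
  if (is.null(sampleTotals)) sampleTotals <- colSums(x)
  offs <- log(sampleTotals)
  rank <- as.integer(rank)
  nTax <- nrow(x); nSamp <- ncol(x)

  set.seed(seed)
  U <- if (rank > 0)
    matrix(rnorm(nSamp * rank, 0, 0.1), nSamp, rank) else
    matrix(0, nSamp, 0)

  runPass <- function(U) {
    df <- data.frame(g = groups, offs = offs)
    if (rank > 0) {
      colnames(U) <- paste0("lv", seq_len(rank))
      df <- cbind(df, as.data.frame(U))
    }
    fits <- vector("list", nTax)
    for (i in seq_len(nTax)) {
      if (all(x[i, ] == 0)) next
      fits[[i]] <- .fitTaxon(x[i, ], df, family)
    }
    fits
  }

  extract <- function(fits) {
    coefNames <- paste0("g", conds)
    B <- SE <- matrix(NA_real_, nTax, length(conds),
                      dimnames = list(rownames(x), conds))
    A <- TH <- setNames(rep(NA_real_, nTax), rownames(x))
    CV <- setNames(rep(FALSE, nTax), rownames(x))
    L <- matrix(0, nTax, rank, dimnames = list(rownames(x), NULL))
    for (i in seq_len(nTax)) {
      f <- fits[[i]]
      if (is.null(f)) next
      cf <- coef(f$fit)
      sm <- summary(f$fit)$coefficients
      A[i] <- cf["(Intercept)"]
      B[i, ] <- cf[coefNames]
      SE[i, ] <- sm[coefNames, "Std. Error"]
      TH[i] <- f$theta
      CV[i] <- isTRUE(f$converged)
      if (rank > 0) L[i, ] <- cf[paste0("lv", seq_len(rank))]
    }
    list(B = B, SE = SE, A = A, TH = TH, CV = CV, L = L)
  }

  fits <- runPass(U)
  est <- extract(fits)

  if (rank > 0) {
    ok <- which(!is.na(est$A))
    ll <- -Inf
    for (iter in seq_len(maxIter)) {
      # score update: per-sample Newton-free optimisation with a standard
      # normal penalty keeping the scores identifiable
      for (i in seq_len(nSamp)) {
        gi <- match(as.character(groups[i]), conds)
        base <- est$A[ok] + if (is.na(gi)) 0 else est$B[ok, gi]
        obj <- function(u) {
          mu <- exp(offs[i] + base + est$L[ok, , drop = FALSE] %*% u)
          -sum(dnbinom(x[ok, i], size = est$TH[ok], mu = mu, log = TRUE)) +
            sum(u^2) / 2
        }
        U[i, ] <- optim(U[i, ], obj, method = "BFGS")$par
      }
      U <- scale(U, center = TRUE, scale = FALSE) # centre for identifiability
      fits <- runPass(U)
      est <- extract(fits)
      llNew <- sum(vapply(seq_len(nTax), function(i) {
        f <- fits[[i]]
        if (is.null(f)) 0 else as.numeric(stats::logLik(f$fit))
      }, numeric(1))) - sum(U^2) / 2
      if (abs(llNew - ll) < tol) break
      ll <- llNew
    }
  }

  zeroTax <- rownames(x)[vapply(seq_len(nTax),
                                function(i) all(x[i, ] == 0), logical(1))]
  if (length(zeroTax))
    warning("all-zero taxa get NA coefficients: ",
            paste(zeroTax, collapse = ", "))

  methods::new("ResponseModel", taxa = rownames(x), intercepts = est$A,
               coefficients = est$B, se = est$SE, dispersion = est$TH,
               converged = est$CV, rank = rank, loadings = est$L,
               scores = U, conditions = conds)
})

#' @rdname fitResponseModel
#' @param top number of most abundant genera to model (GranuleExperiment
#'   method; the experiment is collapsed to genus level first when taxonomy
#'   is present).
#' @export
setMethod("fitResponseModel", "GranuleExperiment",
          function(x, top = 100, rank = 0, ...) {
  tax <- taxonomyTable(x)
  m <- if ("genus" %in% colnames(tax)) collapseToGenus(counts(x), tax)
       else counts(x)
  sel <- topTaxa(m, top)
  fitResponseModel(m[sel, , drop = FALSE],
                   frame = as.data.frame(SummarizedExperiment::colData(x)),
                   rank = rank, sampleTotals = colSums(m), ...)
})

#' Classify taxa as resilient, susceptible or mixed
#'
#' A taxon is `resilient` when its coefficient is positive for every
#' condition and `susceptible` when negative for every condition; anything
#' else (including taxa with NA coefficients) is `mixed`. With
#' `requireCI = TRUE` a condition only counts as positive/negative when its
#' 95% Wald interval excludes zero.
#'
#' @param model a [ResponseModel-class].
#' @param requireCI require the 95% Wald interval to exclude 0 per
#'   condition.
#' @param level confidence level of the Wald intervals.
#' @return named factor with levels `resilient`, `susceptible`, `mixed`.
#' @export
classifyResponse <- function(model, requireCI = FALSE, level = 0.95) {
  stopifnot(methods::is(model, "ResponseModel"))
  B <- model@coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- B - z * model@se
  hi <- B + z * model@se
  lab <- apply(seq_len(nrow(B)) |> as.matrix(), 1, function(i) {
    b <- B[i, ]
    if (anyNA(b)) return("mixed")
    if (requireCI) {
      if (all(lo[i, ] > 0)) "resilient"
      else if (all(hi[i, ] < 0)) "susceptible"
      else "mixed"
    } else {
      if (all(b > 0)) "resilient"
      else if (all(b < 0)) "susceptible"
      else "mixed"
    }
  })
  if (anyNA(B))
    warning("taxa with NA coefficients were labelled 'mixed'")
  factor(setNames(lab, model@taxa),
         levels = c("resilient", "susceptible", "mixed"))
}
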