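# synthetic single-granule communities with planted ground truth
#
# The generator reproduces the design of the incubation experiment (16
# untreated replicate granules + 9 conditions x 3 replicates = 43 samples)
# and plants taxa with known behaviour for every downstream analysis:
# resilient / susceptible responders, a compensating stable ensemble,
# omnipresent core taxa, a neutral block and condition specialists.

# one Dirichlet-multinomial draw: composition ~ Dirichlet(alpha), counts ~
# Multinomial(depth, composition)
.rdirmultinom <- function(alpha, depth) {
  x <- rgamma(length(alpha), shape = alpha)
  s <- sum(x)
  if (s == 0) { # numerically degenerate alphas: fall back to the mean
    x <- alpha
    s <- sum(x)
  }
  rmultinom(1, depth, x / s)[, 1]
}

#' Configuration of the community simulator
#'
#' Collects every tunable of [simulateExperiment()] with the defaults that
#' emulate the single-granule study design: 300 ASVs in ~120 genera, 16
#' untreated replicates plus 9 conditions x 3 replicates, Dirichlet-
#' multinomial counts at a mean depth of 2e4 reads, and planted taxa for each
#' downstream analysis.
#'
#' Planted sets are pairwise disjoint and each planted ASV carries its own
#' genus so genus collation preserves the planted signal. Effects are
#' natural-log fold changes applied to the expected composition before
#' softmax renormalisation:
#' * resilient taxa: `+effectSize` in all nine conditions;
#' * susceptible taxa: `-effectSize` in all nine conditions;
#' * stable-ensemble members: per-condition effects drawn with
#'   `stableEffectSd` and recentred so the members' summed expected
#'   abundance is preserved in every condition;
#' * core taxa: no effects, elevated base abundance (`coreMu`) so occupancy
#'   is 1 everywhere;
#' * specialists: abundance restricted to `specialistK` groups (which may
#'   include `ORIGINAL`) via `specialistSuppress` elsewhere;
#' * neutral block: no condition effects at all;
#' * background: small per-condition effects with sd `backgroundEffectSd`.
#'
#' @param nTaxa,nGenera total ASVs and target number of genera.
#' @param nOriginal,nReplicates design sizes (see [makeSampleFrame()]).
#' @param depthMean,depthCv sequencing depth is drawn per sample from a
#'   Gamma distribution with this mean and coefficient of variation, then
#'   rounded.
#' @param baseMu,baseSigma lognormal parameters of background base
#'   abundances (natural-log scale).
#' @param plantedMu,plantedSigma base-abundance parameters of planted taxa
#'   (kept abundant so they survive genus-level top-N filters).
#' @param coreMu base-abundance mean of the core taxa.
#' @param theta Dirichlet concentration of the compositional noise
#'   (`alpha = theta * expected composition`); larger is less noisy.
#' @param effectSize planted log-fold effect magnitude for
#'   resilient/susceptible taxa.
#' @param backgroundEffectSd,stableEffectSd effect spreads (see above).
#' @param nResilient,nSusceptible,nStable,nCore,nSpecialist,nNeutral planted
#'   set sizes.
#' @param specialistK number of condition groups a specialist occupies.
#' @param specialistSuppress log-fold suppression of specialists outside
#'   their groups.
#' @param unknownFraction fraction of background ASVs left without a genus
#'   assignment (collated as "unknowns").
#' @return a classed list of settings for [simulateExperiment()].
#' @export
simConfig <- function(nTaxa = 300, nGenera = 120, nOriginal = 16,
                      nReplicates = 3, depthMean = 2e4, depthCv = 0.1,
                      baseMu = 0, baseSigma = 1.5, plantedMu = 2,
                      plantedSigma = 0.5, coreMu = 3.5, theta = 1500,
                      effectSize = 1, backgroundEffectSd = 0.3,
                      stableEffectSd = 0.5, nResilient = 8,
                      nSusceptible = 10, nStable = 20, nCore = 10,
                      nSpecialist = 5, nNeutral = 40, specialistK = 1,
                      specialistSuppress = -6, unknownFraction = 0.05) {
  cfg <- as.list(environment())
  nPlanted <- nResilient + nSusceptible + nStable + nCore + nSpecialist +
    nNeutral
  if (nPlanted > nTaxa)
    stop("planted sets exceed the number of taxa (", nPlanted, " > ",
         nTaxa, "); planted sets must be disjoint")
  if (nGenera < nResilient + nSusceptible + nStable + nCore + nSpecialist + 1)
    stop("too few genera to give each planted taxon its own genus")
  stopifnot(theta > 0, depthMean > 0, depthCv > 0, effectSize >= 0,
            specialistK >= 1, specialistK <= 10,
            unknownFraction >= 0, unknownFraction < 1)
  class(cfg) <- "simConfig"
  cfg
}

#' Simulate a single-granule incubation experiment
#'
#' Draws a taxon-by-sample count table under the study design with planted
#' ground truth (see [simConfig()]). Expected per-sample compositions are
#' `softmax(base log-abundance + condition effect)`; counts are Dirichlet-
#' multinomial with concentration `theta` at a per-sample Gamma-distributed
#' depth. The same seed always yields byte-identical output.
#'
#' @param cfg a [simConfig()].
#' @param seed integer seed; fanned out to fixed per-stage child seeds.
#' @return a [GranuleExperiment-class] whose `rowData` carries the planted
#'   truth (`label`, per-condition `delta_*` effects) and whose taxonomy
#'   maps planted taxa to their own genera; the configuration and `theta`
#'   are stored in `metadata()`.
#' @examples
#' ge <- simulateExperiment(simConfig(nTaxa = 60, nGenera = 50), seed = 1)
#' table(plantedTruth(ge)$label)
#' @export
simulateExperiment <- function(cfg = simConfig(), seed = 1) {
  stopifnot(inherits(cfg, "simConfig"))
  frame <- makeSampleFrame(cfg$nOriginal, cfg$nReplicates)
  groups <- frame$group
  nSamp <- nrow(frame)
  glev <- .groupLevels()

  taxa <- sprintf("ASV_%04d", seq_len(cfg$nTaxa))

  # --- planted assignment (deterministic layout, seeded values) ----------
  set.seed(.childSeed(seed, 1L))
  lab <- rep("background", cfg$nTaxa)
  cursor <- 0L
  take <- function(n) {
    idx <- cursor + seq_len(n)
    cursor <<- cursor + n
    idx
  }
  idxRes <- take(cfg$nResilient);    lab[idxRes] <- "resilient"
  idxSus <- take(cfg$nSusceptible);  lab[idxSus] <- "susceptible"
  idxStb <- take(cfg$nStable);       lab[idxStb] <- "stable_member"
  idxCor <- take(cfg$nCore);         lab[idxCor] <- "core"
  idxSpc <- take(cfg$nSpecialist);   lab[idxSpc] <- "specialist"
  idxNeu <- take(cfg$nNeutral);      lab[idxNeu] <- "neutral"

  base <- rnorm(cfg$nTaxa, cfg$baseMu, cfg$baseSigma)
  planted <- c(idxRes, idxSus, idxStb, idxSpc)
  base[planted] <- rnorm(length(planted), cfg$plantedMu, cfg$plantedSigma)
  base[idxCor] <- rnorm(length(idxCor), cfg$coreMu, cfg$plantedSigma)

  # effect matrix over the 10 groups; ORIGINAL column non-zero only for
  # specialists (their niche may or may not include the untreated state)
  set.seed(.childSeed(seed, 2L))
  E <- matrix(0, cfg$nTaxa, length(glev), dimnames = list(taxa, glev))
  bg <- lab == "background"
  E[bg, -1] <- rnorm(sum(bg) * 9, 0, cfg$backgroundEffectSd)
  E[idxRes, -1] <- cfg$effectSize
  E[idxSus, -1] <- -cfg$effectSize
  spcGroups <- vector("list", length(idxSpc))
  for (k in seq_along(idxSpc)) {
    gs <- sample(glev, cfg$specialistK)
    spcGroups[[k]] <- gs
    E[idxSpc[k], ] <- cfg$specialistSuppress
    E[idxSpc[k], gs] <- 0
  }
  # stable ensemble: per condition, member effects are drawn and then
  # shifted so the subset's summed expected RELATIVE abundance equals its
  # untreated value exactly — individual members fluctuate, the ensemble
  # total is preserved (the property the ensemble search must detect)
  w <- exp(base)
  wStb <- w[idxStb]
  t0 <- sum(wStb * exp(E[idxStb, 1])) / sum(w * exp(E[, 1]))
  for (g in 2:length(glev)) {
    z <- rnorm(length(idxStb), 0, cfg$stableEffectSd)
    A <- sum(wStb * exp(z))
    B <- sum((w * exp(E[, g]))[-idxStb])
    E[idxStb, g] <- z + log(t0 * B / ((1 - t0) * A))
  }

  # --- counts -------------------------------------------------------------
  set.seed(.childSeed(seed, 3L))
  shape <- 1 / cfg$depthCv^2
  depths <- pmax(1, round(rgamma(nSamp, shape = shape,
                                 scale = cfg$depthMean / shape)))
  m <- matrix(0L, cfg$nTaxa, nSamp, dimnames = list(taxa, frame$sample_id))
  for (j in seq_len(nSamp)) {
    lp <- base + E[, as.character(groups[j])]
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    m[, j] <- .rdirmultinom(cfg$theta * p, depths[j])
  }

  # --- taxonomy: planted taxa keep private genera -------------------------
  set.seed(.childSeed(seed, 4L))
  genus <- character(cfg$nTaxa)
  own <- c(idxRes, idxSus, idxStb, idxCor, idxSpc)
  genus[own] <- sprintf("genus_%03d", seq_along(own))
  rest <- setdiff(seq_len(cfg$nTaxa), own)
  nPool <- max(1, cfg$nGenera - length(own))
  genus[rest] <- sprintf("genus_%03d",
                         length(own) + sample.int(nPool, length(rest),
                                                  replace = TRUE))
  nUnk <- round(cfg$unknownFraction * length(rest))
  if (nUnk > 0) genus[sample(rest, nUnk)] <- NA_character_
  tax <- data.frame(taxon_id = taxa,
                    domain = "Unclassified", phylum = "Unclassified",
                    class = "Unclassified", order = "Unclassified",
                    family = "Unclassified", genus = genus,
                    stringsAsFactors = FALSE)

  truth <- data.frame(label = lab, stringsAsFactors = FALSE)
  deltas <- E[, -1, drop = FALSE]
  colnames(deltas) <- paste0("delta_", glev[-1])
  truth <- cbind(truth, as.data.frame(deltas))
  truth$specialist_groups <- ""
  truth$specialist_groups[idxSpc] <-
    vapply(spcGroups, paste, character(1), collapse = ";")

  ge <- GranuleExperiment(m, frame, taxonomy = tax, truth = truth)
  metadata(ge)$simConfig <- cfg
  metadata(ge)$seed <- seed
  metadata(ge)$theta <- cfg$theta
  ge
}

#' Simulate a neutrally assembled community
#'
#' Realises the sampling assumptions of the Sloan neutral model: for each
#' sample the local composition is drawn from `Dirichlet(N * m * p)` (N =
#' depth, m = migration probability, p = metacommunity relative abundances)
#' and counts are multinomial at the given depth.
#'
#' @param p metacommunity relative abundances (summing to 1).
#' @param m migration probability in (0, 1].
#' @param nSamples number of local communities to draw.
#' @param depth sequencing depth per sample.
#' @param seed integer seed.
#' @return taxon-by-sample integer count matrix.
#' @examples
#' p <- c(a = 0.5, b = 0.3, c = 0.2)
#' simulateNeutralCommunity(p, m = 0.5, nSamples = 4, depth = 100, seed = 1)
#' @export
simulateNeutralCommunity <- function(p, m, nSamples, depth, seed = 1) {
  if (abs(sum(p) - 1) > 1e-6) stop("p must sum to 1")
  if (!(m > 0 && m <= 1)) stop("m must be in (0, 1]")
  stopifnot(nSamples >= 1, depth >= 1)
  set.seed(seed)
  alpha <- depth * m * p
  out <- vapply(seq_len(nSamples), function(j) .rdirmultinom(alpha, depth),
                integer(length(p)))
  rownames(out) <- if (is.null(names(p)))
    sprintf("ASV_%04d", seq_along(p)) else names(p)
  colnames(out) <- sprintf("S%03d", seq_len(nSamples))
  out
}

#' Simulate a volatile fatty acid concentration series
#'
#' A linearly decaying concentration over the twelve sampling hours of a
#' 48-h batch incubation (0, 4, 8, 12, 20, 24, 28, 32, 36, 40, 42, 48 h),
#' ending at `initial * (1 - consumptionFraction)`, plus seeded Gaussian
#' noise (clamped at zero).
#'
#' @param initial initial concentration (mg/L).
#' @param consumptionFraction fraction consumed over the cycle, in `[0, 1]`.
#' @param noiseSd Gaussian noise standard deviation (mg/L).
#' @param acid acid name.
#' @param replicate replicate id.
#' @param seed integer seed.
#' @return data.frame with columns `acid`, `replicate`, `time_h`,
#'   `concentration_mg_l`.
#' @export
simulateVfaSeries <- function(initial, consumptionFraction, noiseSd = 0,
                              acid = "acetic", replicate = 1L, seed = 1) {
  if (initial < 0) stop("initial concentration must be non-negative")
  if (consumptionFraction < 0 || consumptionFraction > 1)
    stop("consumptionFraction must be in [0, 1]")
  tp <- c(0, 4, 8, 12, 20, 24, 28, 32, 36, 40, 42, 48)
  conc <- initial * (1 - consumptionFraction * tp / max(tp))
  if (noiseSd > 0) {
    set.seed(seed)
    conc <- pmax(0, conc + rnorm(length(tp), 0, noiseSd))
  }
  data.frame(acid = acid, replicate = replicate, time_h = tp,
             concentration_mg_l = conc, stringsAsFactors = FALSE)
}
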