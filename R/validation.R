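#' Random k-fold site partition
#'
#' Partitions sites into k folds of near-equal size (sizes differ by at most
#' one), deterministically under the seed.
#'
#' @param siteIds character or integer vector of site identifiers.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return an integer fold assignment named by site.
#' @export
makeFolds <- function(siteIds, k, seed = 1L) {
  .stopIfNot(k >= 2, "at least two folds required")
  .stopIfNot(k <= length(siteIds), "more folds than sites")
  set.seed(seed)
  folds <- rep(seq_len(k), length.out = length(siteIds))
  setNames(folds[sample.int(length(siteIds))], siteIds)
}

#' K-fold baseline and conditional cross-validation
#'
#' For every fold the model is refitted on the training sites and the
#' held-out sites are predicted.  In \emph{baseline} mode the entire response
#' vector of a test site is treated as unknown and predicted marginally from
#' the environment alone.  In \emph{conditional} mode the test site's
#' abundance information -- both hurdle components, presence-absence and
#' (where the species is present) abundance conditional on presence -- is
#' conditioned on, and the trait columns are predicted through the shared
#' latent factors.  Predicted/observed pairs are returned for observed trait
#' cells only, on the log (model) scale.
#'
#' Species left with zero presences in a training fold are skipped for that
#' fold with a warning.
#'
#' @param design a \linkS4class{JstdmDesign}.
#' @param priors a \linkS4class{JstdmPriors} object.
#' @param k number of folds (ignored when \code{folds} is given).
#' @param folds optional precomputed fold assignment from [makeFolds()].
#' @param mode \code{"both"} (default; shares the per-fold refits),
#'   \code{"baseline"} or \code{"conditional"}.
#' @param chains,iterations,burnin,thin reduced MCMC settings for the fold
#'   refits; override for full-length runs.
#' @param nSweeps,nDiscard inner Gibbs length for conditional prediction.
#' @param seed master seed (folds and per-fold fits derive from it).
#' @return a data.frame with columns \code{mode}, \code{fold}, \code{site},
#'   \code{species}, \code{trait}, \code{predicted}, \code{observed} (log
#'   scale), with the settings attached as attributes.
#' @export
crossValidate <- function(design, priors = jstdmPriors(), k = 10L, folds = NULL,
                          mode = c("both", "baseline", "conditional"),
                          chains = 4L, iterations = 4000L, burnin = 2000L,
                          thin = 20L, nSweeps = 50L, nDiscard = 20L,
                          seed = 1L) {
  mode <- match.arg(mode)
  modes <- if (mode == "both") c("baseline", "conditional") else mode
  sites <- rownames(design@Y)
  if (is.null(folds)) folds <- makeFolds(sites, k, seed = seed)
  .stopIfNot(identical(sort(names(folds)), sort(sites)),
             "fold assignment does not cover the design sites")
  rtAll <- unique(columnUnits(design@mre)$rtype)
  traitTypes <- setdiff(rtAll, c("PA", "ABUC"))
  .stopIfNot(length(traitTypes) > 0, "no trait response types to cross-validate")
  condTypes <- intersect(c("PA", "ABUC"), rtAll)

  out <- list()
  for (f in sort(unique(folds))) {
    testSites <- names(folds)[folds == f]
    trainSites <- setdiff(sites, testSites)

    # the training design is rebuilt from the training sites alone (response
    # and covariate scalings, derived species-level traits) so no information
    # about the held-out sites reaches the fold's model
    trainMre <- design@mre[, trainSites]
    paVals <- responseValues(trainMre)[, columnUnits(trainMre)$rtype == "PA",
                                       drop = FALSE]
    absent <- speciesNames(trainMre)[colSums(paVals) == 0]
    if (length(absent)) {
      warning(sprintf("fold %d: species with no training presences skipped: %s",
                      f, paste(absent, collapse = ", ")))
      trainMre <- filterByPrevalence(trainMre, 1L)
    }
    speciesTraitsArg <- switch(design@traitProvenance,
      none = NULL,
      derived = "derived",
      {
        tr <- design@traitRaw[speciesNames(trainMre), , drop = FALSE]
        attr(tr, "provenance") <- "supplied"
        tr
      })
    trainDesign <- jstdmDesign(
      trainMre,
      covariates = if (ncol(design@covariates))
        design@covariates[trainSites, , drop = FALSE] else NULL,
      speciesTraits = speciesTraitsArg,
      scaleCovariates = length(design@xScale) > 0)
    cu <- columnUnits(trainDesign@mre)
    traitCols <- which(cu$rtype %in% traitTypes)

    fit <- runMCMC(trainDesign, priors, chains = chains,
                   iterations = iterations, burnin = burnin, thin = thin,
                   seed = seed + 1000L * f)

    Xtest <- if (ncol(design@covariates))
      .buildXnew(trainDesign, newdata = design@covariates[testSites, , drop = FALSE])
    else matrix(1, length(testSites), 1,
                dimnames = list(testSites, "(Intercept)"))

    # observed log-scale values of the full design (truth for the test sites)
    keepCols <- rownames(cu)
    vals <- responseValues(design@mre)[testSites, keepCols, drop = FALSE]
    obs <- observedMask(design@mre)[testSites, keepCols, drop = FALSE]

    preds <- list()
    if ("baseline" %in% modes)
      preds$baseline <- predictMarginal(fit, Xnew = Xtest,
                                        seed = seed + 1000L * f + 1L,
                                        backTransform = "log")$mean
    if ("conditional" %in% modes) {
      C <- matrix(NA_real_, length(testSites), ncol(trainDesign@Y),
                  dimnames = list(testSites, colnames(trainDesign@Y)))
      condCols <- which(cu$rtype %in% condTypes)
      C[, condCols] <- ifelse(obs[, condCols, drop = FALSE],
                              vals[, condCols, drop = FALSE], NA_real_)
      preds$conditional <- predictConditional(
        fit, Xnew = Xtest, condition = C, conditionScale = "log",
        nSweeps = nSweeps, nDiscard = nDiscard,
        seed = seed + 1000L * f + 2L, backTransform = "log")$mean
    }

    for (md in names(preds)) {
      pm <- preds[[md]]
      for (cIdx in traitCols) {
        sp <- cu$species[cIdx]
        if (sp %in% absent) next
        rows <- which(obs[, cIdx])
        if (!length(rows)) next
        out[[length(out) + 1L]] <- data.frame(
          mode = md, fold = f, site = testSites[rows],
          species = sp, trait = cu$rtype[cIdx],
          predicted = pm[rows, cIdx], observed = vals[rows, cIdx],
          row.names = NULL)
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "settings") <- list(k = length(unique(folds)), chains = chains,
                                iterations = iterations, burnin = burnin,
                                thin = thin, seed = seed, modes = modes)
  res
}

#' Predictive correlation per species-trait combination
#'
#' Pearson correlation between predicted and observed values on the log
#' (model) scale, computed separately for each species-trait combination
#' (and cross-validation mode, when present).  The sign is preserved -- the
#' correlation is not squared -- so negative values flag predictions worse
#' than random.  Combinations with fewer than three pairs or zero-variance
#' predictions are reported as missing, not zero.
#'
#' @param cvResult a data.frame from [crossValidate()] (or any table with
#'   \code{species}, \code{trait}, \code{predicted}, \code{observed} and
#'   optionally \code{mode}).
#' @return a data.frame with columns \code{mode} (if present),
#'   \code{species}, \code{trait}, \code{n}, \code{correlation}.
#' @export
predictiveCorrelation <- function(cvResult) {
  byCols <- intersect(c("mode", "species", "trait"), colnames(cvResult))
  groups <- split(cvResult, cvResult[byCols], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    r <- if (nrow(g) < 3L || sd(g$predicted) == 0 || sd(g$observed) == 0)
      NA_real_ else cor(g$predicted, g$observed)
    cbind(g[1L, byCols, drop = FALSE],
          data.frame(n = nrow(g), correlation = r))
  }))
  rownames(out) <- NULL
  out
}

#' Improvement of conditional over baseline cross-validation
#'
#' Per trait: the share of species for which the conditional predictive
#' correlation exceeds the baseline one, and the shares with a difference of
#' at least \code{threshold} in either direction.  Species with an undefined
#' correlation in either mode are excluded.
#'
#' @param corrBaseline,corrConditional correlation tables from
#'   [predictiveCorrelation()] (single mode each), or a single table with a
#'   \code{mode} column passed as \code{corrBaseline}.
#' @param threshold minimum difference counted as a material change
#'   (default 0.2).
#' @return a data.frame with one row per trait: \code{n},
#'   \code{propImproved}, \code{propLargeGain}, \code{propLargeLoss}.
#' @export
improvementSummary <- function(corrBaseline, corrConditional = NULL,
                               threshold = 0.2) {
  if (is.null(corrConditional)) {
    .stopIfNot("mode" %in% colnames(corrBaseline),
               "supply two tables or one table with a 'mode' column")
    corrConditional <- corrBaseline[corrBaseline$mode == "conditional", ]
    corrBaseline <- corrBaseline[corrBaseline$mode == "baseline", ]
  }
  m <- merge(corrBaseline, corrConditional, by = c("species", "trait"),
             suffixes = c(".base", ".cond"))
  m <- m[!is.na(m$correlation.base) & !is.na(m$correlation.cond), ]
  do.call(rbind, lapply(split(m, m$trait), function(g) {
    d <- g$correlation.cond - g$correlation.base
    data.frame(trait = g$trait[1L], n = nrow(g),
               propImproved = mean(d > 0),
               propLargeGain = mean(d >= threshold),
               propLargeLoss = mean(d <= -threshold))
  }))
}
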