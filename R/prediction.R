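#' Extended linear predictor
#'
#' \code{L = X Beta + H Lambda}: the sites x column-units linear predictor
#' combining measured environmental predictors and latent factors.
#'
#' @param draw a posterior draw (a list with \code{Beta} and \code{Lambda}).
#' @param Xnew sites x covariates design matrix on the fitted scaling.
#' @param Hnew sites x factors matrix of factor scores.
#' @export
linearPredictor <- function(draw, Xnew, Hnew) {
  .stopIfNot(ncol(Xnew) == nrow(draw$Beta), "Xnew width does not match Beta")
  .stopIfNot(ncol(Hnew) == nrow(draw$Lambda), "Hnew width does not match Lambda")
  Xnew %*% draw$Beta + Hnew %*% draw$Lambda
}

# map a model-scale linear predictor to the response scale
.responseScale <- function(L, design, sigma2, isProbit, backTransform) {
  out <- L
  if (any(isProbit)) out[, isProbit] <- pnorm(L[, isProbit, drop = FALSE])
  ln <- which(!isProbit)
  if (length(ln)) {
    ys <- design@yScale[ln]; yc <- design@yCenter[ln]
    logv <- sweep(sweep(L[, ln, drop = FALSE], 2, ys, "*"), 2, yc, "+")
    out[, ln] <- switch(backTransform,
      log = logv,
      median = exp(logv),
      mean = exp(sweep(logv, 2, (ys * sqrt(sigma2[ln]))^2 / 2, "+")))
  }
  out
}

.buildXnew <- function(design, newdata = NULL, Xnew = NULL) {
  if (!is.null(Xnew)) {
    .stopIfNot(ncol(Xnew) == ncol(design@X), "Xnew width does not match the design")
    return(Xnew)
  }
  if (is.null(newdata)) return(design@X)
  newdata <- as.data.frame(newdata)
  covNames <- colnames(design@X)[-1]
  .stopIfNot(all(covNames %in% colnames(newdata)),
             "newdata must contain covariates: %s", paste(covNames, collapse = ", "))
  C <- as.matrix(newdata[, covNames, drop = FALSE])
  if (length(design@xScale))
    C <- sweep(sweep(C, 2, design@xCenter), 2, design@xScale, "/")
  cbind("(Intercept)" = 1, C)
}

# convert user conditioning values to the model scale
.conditionToModelScale <- function(C, design, conditionScale) {
  cu <- columnUnits(design@mre)
  isProbit <- cu$family == "bernoulli_probit"
  out <- C
  for (c in seq_len(ncol(C))) {
    v <- C[, c]
    set <- !is.na(v)
    if (!any(set)) next
    if (isProbit[c]) {
      .stopIfNot(all(v[set] %in% c(0, 1)), "conditioned PA values must be 0 or 1")
    } else if (conditionScale != "model") {
      lv <- if (conditionScale == "natural") {
        .stopIfNot(all(v[set] > 0), "conditioned log-normal values must be positive")
        log(v[set])
      } else v[set]
      out[set, c] <- (lv - design@yCenter[c]) / design@yScale[c]
    }
  }
  out
}

# normalise the condition argument to a sitesNew x p matrix with NA = unset
.conditionMatrix <- function(condition, design, nNew, conditionScale) {
  p <- ncol(design@Y)
  un <- colnames(design@Y)
  C <- matrix(NA_real_, nNew, p, dimnames = list(NULL, un))
  if (is.null(condition)) return(C)
  if (is.null(dim(condition))) {
    .stopIfNot(!is.null(names(condition)), "conditioning values must be named by column unit")
    condition <- matrix(rep(unlist(condition), each = nNew), nNew,
                        dimnames = list(NULL, names(condition)))
  }
  condition <- as.matrix(condition)
  .stopIfNot(nrow(condition) == nNew, "condition rows must match prediction sites")
  unknown <- setdiff(colnames(condition), un)
  .stopIfNot(length(unknown) == 0, "unknown column units: %s", paste(unknown, collapse = ", "))
  C[, colnames(condition)] <- condition
  .conditionToModelScale(C, design, conditionScale)
}

# Core predictive engine.  For every posterior draw it produces a
# sites x column-units response-scale prediction and hands it to onDraw.
# Marginal mode samples fresh factor scores from their standard-normal prior.
# Conditional mode runs a short inner Gibbs over the new sites' factor scores
# and the probit latents of conditioned PA cells, then reports predictions
# averaged over the post-discard inner sweeps (meanMat) plus the final-sweep
# draw (endMat).
.predictDraws <- function(fit, Xnew, C = NULL, nSweeps = 50L, nDiscard = 20L,
                          seed = NULL, backTransform = "median",
                          onDraw = function(i, meanMat, endMat) NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- fit@design
  cu <- columnUnits(design@mre)
  isProbit <- cu$family == "bernoulli_probit"
  n <- nrow(Xnew)
  nf <- fit@priors@nFactors
  conditional <- !is.null(C) && any(!is.na(C))
  if (conditional) {
    condMask <- !is.na(C)
    .stopIfNot(!all(condMask), "every column unit is conditioned: nothing to predict")
    pat <- apply(condMask, 1, paste, collapse = "")
    patGroups <- split(seq_len(n), pat)
    # conditioned probit cells as linear indices into the sites x units grid
    probCells <- which(condMask & matrix(isProbit, n, length(isProbit), byrow = TRUE))
    probSite <- ((probCells - 1L) %% n) + 1L
    probCol <- ((probCells - 1L) %/% n) + 1L
    yProb <- C[probCells]
    Z0 <- C
    Z0[!condMask] <- 0
    total <- nDiscard + nSweeps
  }
  p <- length(isProbit)
  for (i in seq_along(fit@draws)) {
    d <- fit@draws[[i]]
    Fm <- Xnew %*% d$Beta
    if (!conditional) {
      Hnew <- matrix(rnorm(n * nf), n, nf)
      L <- Fm + Hnew %*% d$Lambda
      M <- .responseScale(L, design, d$sigma2, isProbit, backTransform)
      onDraw(i, M, M)
    } else {
      # per-site factor-score posterior precision is fixed within a draw:
      # precompute its inverse and Cholesky per conditioning pattern, then
      # run every site through the inner sweeps simultaneously
      LamT <- t(d$Lambda)                   # p x nf
      Wt <- condMask * rep(1 / d$sigma2, each = n)
      PinvArr <- matrix(0, n, nf * nf)
      UArr <- matrix(0, n, nf * nf)
      for (g in patGroups) {
        J <- which(condMask[g[1], ])
        lamJ <- d$Lambda[, J, drop = FALSE]
        P <- diag(nf) + lamJ %*% (t(lamJ) / d$sigma2[J])
        Pi <- solve(P)
        U <- chol(Pi)                       # rows of E %*% U have covariance Pi
        PinvArr[g, ] <- rep(as.vector(Pi), each = length(g))
        UArr[g, ] <- rep(as.vector(U), each = length(g))
      }
      H <- matrix(0, n, nf)
      Z <- Z0
      acc <- matrix(0, n, p)
      for (sw in seq_len(total)) {
        if (length(probCells)) {
          mu <- Fm[probCells] +
            rowSums(H[probSite, , drop = FALSE] * LamT[probCol, , drop = FALSE])
          Z[probCells] <- .rtruncProbit(mu, yProb)
        }
        Bm <- ((Z - Fm) * Wt) %*% LamT      # n x nf score-posterior location
        eps <- matrix(rnorm(n * nf), n, nf)
        Hn <- matrix(0, n, nf)
        for (a in seq_len(nf)) {
          v <- 0
          for (b in seq_len(nf))
            v <- v + PinvArr[, (b - 1L) * nf + a] * Bm[, b] +
              eps[, b] * UArr[, (a - 1L) * nf + b]
          Hn[, a] <- v
        }
        H <- Hn
        if (sw > nDiscard)
          acc <- acc + .responseScale(Fm + H %*% d$Lambda, design, d$sigma2,
                                      isProbit, backTransform)
      }
      onDraw(i, acc / nSweeps,
             .responseScale(Fm + H %*% d$Lambda, design, d$sigma2,
                            isProbit, backTransform))
    }
  }
  invisible(NULL)
}

.newPrediction <- function(mean, draws, design, backTransform) {
  structure(list(mean = mean, draws = draws,
                 columnUnits = as.data.frame(columnUnits(design@mre)),
                 backTransform = backTransform),
            class = "jstdmPrediction")
}

#' @export
print.jstdmPrediction <- function(x, ...) {
  cat(sprintf("jstdmPrediction: %d sites x %d column units (%s scale)%s\n",
              nrow(x$mean), ncol(x$mean), x$backTransform,
              if (is.null(x$draws)) "" else sprintf("; %d draws kept", dim(x$draws)[1])))
  invisible(x)
}

#' Marginal posterior prediction
#'
#' For every posterior draw, fresh factor scores are sampled from their
#' standard-normal prior, the extended linear predictor is formed, and
#' presence-absence columns are mapped through the probit link while
#' log-normal columns are back-transformed (predictive median
#' \code{exp(log-value)} by default, predictive mean or raw log scale by
#' request).  Predictions are averaged over draws.
#'
#' @param fit a \linkS4class{JstdmFit}.
#' @param newdata sites x covariates data.frame on the original covariate
#'   scale (the recorded scaling is applied); default: the fitted sites.
#' @param Xnew alternatively, a ready design matrix on the fitted scaling.
#' @param seed seed for the predictive factor draws.
#' @param backTransform \code{"median"}, \code{"mean"} or \code{"log"}.
#' @param keepDraws keep the per-draw prediction array.
#' @return a \code{jstdmPrediction}: list with \code{mean}
#'   (sites x column-units) and optionally \code{draws}.
#' @export
predictMarginal <- function(fit, newdata = NULL, Xnew = NULL, seed = NULL,
                            backTransform = c("median", "mean", "log"),
                            keepDraws = FALSE) {
  backTransform <- match.arg(backTransform)
  Xnew <- .buildXnew(fit@design, newdata, Xnew)
  n <- nrow(Xnew); p <- ncol(fit@design@Y); nd <- length(fit@draws)
  acc <- matrix(0, n, p, dimnames = list(rownames(Xnew), colnames(fit@design@Y)))
  drawArr <- if (keepDraws) array(NA_real_, c(nd, n, p)) else NULL
  .predictDraws(fit, Xnew, NULL, seed = seed, backTransform = backTransform,
                onDraw = function(i, M, E) {
                  acc <<- acc + M
                  if (keepDraws) drawArr[i, , ] <<- E
                })
  .newPrediction(acc / nd, drawArr, fit@design, backTransform)
}

#' Conditional posterior prediction
#'
#' Predicts unobserved column units for new sites while conditioning on
#' observed values of other column units at the same sites -- the engine
#' behind conditional cross-validation and focal-species scenario
#' simulation.  For every posterior draw a short inner Gibbs sampler
#' alternates between the new sites' factor scores and the probit latents of
#' conditioned presence-absence cells; predictions are averaged over the
#' post-discard inner sweeps, which marginalises the factor scores over
#' their conditional distribution.  Conditioning on nothing is an error; use
#' [predictMarginal()].
#'
#' @inheritParams predictMarginal
#' @param condition a named vector (one value per conditioned column unit,
#'   recycled across sites) or a sites x units matrix with \code{NA} for
#'   unset cells.  Presence-absence values must be 0/1; log-normal values
#'   are interpreted on the scale given by \code{conditionScale}.
#' @param conditionScale \code{"natural"} (default), \code{"log"} or
#'   \code{"model"} (already centred/scaled).
#' @param nSweeps,nDiscard inner Gibbs length per posterior draw.
#' @return a \code{jstdmPrediction}; conditioned columns are predicted like
#'   any other (their predictions simply track the conditioning).
#' @export
predictConditional <- function(fit, newdata = NULL, Xnew = NULL, condition,
                               nSweeps = 50L, nDiscard = 20L, seed = NULL,
                               backTransform = c("median", "mean", "log"),
                               conditionScale = c("natural", "log", "model"),
                               keepDraws = FALSE) {
  backTransform <- match.arg(backTransform)
  conditionScale <- match.arg(conditionScale)
  Xnew <- .buildXnew(fit@design, newdata, Xnew)
  n <- nrow(Xnew); p <- ncol(fit@design@Y); nd <- length(fit@draws)
  C <- .conditionMatrix(condition, fit@design, n, conditionScale)
  .stopIfNot(any(!is.na(C)), "no conditioning values supplied; use predictMarginal()")
  acc <- matrix(0, n, p, dimnames = list(rownames(Xnew), colnames(fit@design@Y)))
  drawArr <- if (keepDraws) array(NA_real_, c(nd, n, p)) else NULL
  .predictDraws(fit, Xnew, C, nSweeps = nSweeps, nDiscard = nDiscard,
                seed = seed, backTransform = backTransform,
                onDraw = function(i, M, E) {
                  acc <<- acc + M
                  if (keepDraws) drawArr[i, , ] <<- E
                })
  .newPrediction(acc / nd, drawArr, fit@design, backTransform)
}

#' Scenario specification
#'
#' A conditioning specification for focal-species scenario simulation: fixed
#' covariate values (on the original scale, or \code{"low"}/\code{"high"}
#' for dataset quantiles) and/or fixed focal-species column-unit values;
#' unset entries are marginalised.
#'
#' @param covariates named list mapping covariate names to a numeric value
#'   or \code{"low"}/\code{"high"} (10\%/90\% quantiles of the reference
#'   sites).
#' @param condition named list mapping column-unit names
#'   (\code{"RTYPE:species"}) to fixed values on the natural scale
#'   (presence-absence in 0/1).
#' @param focal focal species excluded from community summaries; defaults to
#'   the species named in \code{condition}.
#' @export
jstdmScenario <- function(covariates = list(), condition = list(), focal = NULL) {
  structure(list(covariates = covariates, condition = condition, focal = focal),
            class = "jstdmScenario")
}

#' Scenario prediction and expected richness
#'
#' Builds the prediction design from the reference sites with the scenario's
#' covariate overrides, applies conditional (or, with an empty conditioning
#' set, marginal) prediction, and summarises the occurrence probabilities of
#' all non-focal species together with expected species richness -- the sum
#' of species-specific occurrence probabilities, averaged over reference
#' sites, with a posterior interval over draws.
#'
#' @param fit a \linkS4class{JstdmFit}.
#' @param scenario a [jstdmScenario()].
#' @param referenceSites site names/indices supplying the covariate
#'   distribution (default: all fitted sites).
#' @param seed,nSweeps,nDiscard passed to the predictive engine.
#' @param level width of the richness posterior interval.
#' @return a list with \code{probabilities} (posterior-mean occurrence
#'   probabilities, sites x non-focal species), \code{richness} (mean, lower,
#'   upper), \code{richnessDraws} and \code{siteRichness}.
#' @export
scenarioPredict <- function(fit, scenario, referenceSites = NULL, seed = NULL,
                            nSweeps = 50L, nDiscard = 20L, level = 0.95) {
  design <- fit@design
  if (is.null(referenceSites)) referenceSites <- rownames(design@Y)
  cov <- design@covariates[referenceSites, , drop = FALSE]
  for (nm in names(scenario$covariates)) {
    .stopIfNot(nm %in% colnames(cov), "unknown covariate '%s' in scenario", nm)
    v <- scenario$covariates[[nm]]
    if (identical(v, "low")) v <- quantile(cov[[nm]], 0.10)
    else if (identical(v, "high")) v <- quantile(cov[[nm]], 0.90)
    .stopIfNot(is.numeric(v), "covariate value must be numeric or 'low'/'high'")
    cov[[nm]] <- v
  }
  Xnew <- .buildXnew(design, newdata = if (ncol(cov)) cov else NULL)
  n <- nrow(Xnew)
  un <- colnames(design@Y)
  if (length(scenario$condition)) {
    unknown <- setdiff(names(scenario$condition), un)
    .stopIfNot(length(unknown) == 0, "scenario conditions unknown column units: %s",
               paste(unknown, collapse = ", "))
  }
  focal <- scenario$focal
  if (is.null(focal) && length(scenario$condition))
    focal <- unique(sub("^[^:]+:", "", names(scenario$condition)))
  cu <- columnUnits(design@mre)
  paCols <- which(cu$rtype == "PA" & !(cu$species %in% focal))
  .stopIfNot(length(paCols) > 0, "no non-focal species to summarise")

  nd <- length(fit@draws)
  probAcc <- matrix(0, n, length(paCols),
                    dimnames = list(referenceSites, cu$species[paCols]))
  richDraws <- numeric(nd)
  siteRich <- matrix(0, n, 1)
  onDraw <- function(i, M, E) {
    pm <- M[, paCols, drop = FALSE]
    probAcc <<- probAcc + pm
    sr <- rowSums(pm)
    siteRich <<- siteRich + sr
    richDraws[i] <<- mean(sr)
  }
  if (length(scenario$condition)) {
    C <- .conditionMatrix(unlist(scenario$condition), design, n, "natural")
    .predictDraws(fit, Xnew, C, nSweeps = nSweeps, nDiscard = nDiscard,
                  seed = seed, backTransform = "median", onDraw = onDraw)
  } else {
    .predictDraws(fit, Xnew, NULL, seed = seed, backTransform = "median",
                  onDraw = onDraw)
  }
  alpha <- (1 - level) / 2
  list(probabilities = probAcc / nd,
       richness = c(mean = mean(richDraws),
                    lower = unname(quantile(richDraws, alpha)),
                    upper = unname(quantile(richDraws, 1 - alpha))),
       richnessDraws = richDraws,
       siteRichness = drop(siteRich) / nd)
}

#' Expected species richness from occurrence probabilities
#'
#' Per posterior draw, expected richness is the sum of species-specific
#' occurrence probabilities; the posterior mean and interval over draws are
#' reported (per site when a draws x sites x species array is supplied).
#'
#' @param probDraws a draws x species matrix or draws x sites x species
#'   array of occurrence probabilities in [0, 1].
#' @param level interval width.
#' @export
expectedRichness <- function(probDraws, level = 0.95) {
  .stopIfNot(all(probDraws >= 0 & probDraws <= 1, na.rm = TRUE),
             "occurrence probabilities must lie in [0, 1]")
  alpha <- (1 - level) / 2
  if (length(dim(probDraws)) == 3L) {
    rich <- apply(probDraws, c(1, 2), sum)        # draws x sites
    data.frame(site = seq_len(ncol(rich)),
               mean = colMeans(rich),
               lower = apply(rich, 2, quantile, alpha),
               upper = apply(rich, 2, quantile, 1 - alpha))
  } else {
    rich <- rowSums(as.matrix(probDraws))
    c(mean = mean(rich),
      lower = unname(quantile(rich, alpha)),
      upper = unname(quantile(rich, 1 - alpha)))
  }
}
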