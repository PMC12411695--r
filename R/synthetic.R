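#' Draw ground-truth parameters for a synthetic community
#'
#' Generates a complete parameter bundle from the generative model itself:
#' log-scale species-level traits, trait-regression coefficients Gamma at a
#' stated effect scale, environmental responses Beta as the trait-implied
#' means plus deviations with covariance V, latent factor loadings with
#' decaying per-factor scales, and log-normal residual SDs.  Everything is
#' recorded so a fitted model can be checked against the truth.
#'
#' @param nSpecies number of species.
#' @param traits character vector of trait response types (may be empty).
#' @param nCovariates number of environmental covariates (excluding the
#'   intercept).
#' @param nFactors number of latent factors.
#' @param gammaScale SD of the trait-regression coefficients.
#' @param betaSD SD of the beta deviations around the trait-implied means
#'   (V = betaSD^2 I).
#' @param lambdaScale loading SD of the first factor; factor h uses
#'   \code{lambdaScale * 2^(-(h-1)/2)} (halving the variance per factor).
#' @param sigma residual SD of the log-normal columns.
#' @param traitSD SD of the species-level log trait values.
#' @param seed RNG seed (\code{NULL}: continue the current stream).
#' @return a list of class \code{jstdmTruth} with elements \code{T} (species
#'   x traits, log scale), \code{Gamma}, \code{V}, \code{Beta},
#'   \code{Lambda}, \code{sigma}, \code{rtypes}, \code{covariateNames},
#'   \code{unitNames} and the settings.
#' @export
generateParameters <- function(nSpecies, traits = character(),
                               nCovariates = 2L, nFactors = 2L,
                               gammaScale = 0.3, betaSD = 0.5,
                               lambdaScale = 0.7, sigma = 0.5,
                               traitSD = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rtypes <- responseTypes(traits)
  nz <- nrow(rtypes)
  species <- sprintf("sp%02d", seq_len(nSpecies))
  covariateNames <- sprintf("env%d", seq_len(nCovariates))
  nc <- nCovariates + 1L
  Tr <- matrix(rnorm(nSpecies * length(traits), 0, traitSD),
               nSpecies, length(traits), dimnames = list(species, traits))
  Tm <- cbind("(Intercept)" = 1, Tr)
  Ttilde <- expandTraitDesign(Tm, rtypes$name, species)
  q <- ncol(Ttilde)
  Gamma <- matrix(rnorm(nc * q, 0, gammaScale), nc, q,
                  dimnames = list(c("(Intercept)", covariateNames),
                                  colnames(Ttilde)))
  p <- nz * nSpecies
  Beta <- Gamma %*% t(Ttilde) + matrix(rnorm(nc * p, 0, betaSD), nc, p)
  lamScales <- lambdaScale * 2^(-(seq_len(nFactors) - 1) / 2)
  Lambda <- matrix(rnorm(nFactors * p), nFactors, p) * lamScales
  dimnames(Lambda) <- list(NULL, rownames(Ttilde))
  structure(list(T = Tr, Gamma = Gamma, V = diag(betaSD^2, nc),
                 Beta = Beta, Lambda = Lambda, sigma = sigma,
                 rtypes = rtypes, species = species,
                 covariateNames = covariateNames,
                 unitNames = rownames(Ttilde),
                 settings = list(nSpecies = nSpecies, traits = traits,
                                 nCovariates = nCovariates,
                                 nFactors = nFactors, gammaScale = gammaScale,
                                 betaSD = betaSD, lambdaScale = lambdaScale,
                                 sigma = sigma, traitSD = traitSD,
                                 seed = seed)),
            class = "jstdmTruth")
}

#' Generate a synthetic community from a truth bundle
#'
#' Simulates sites from the exact generative model: standard-normal
#' covariates, standard-normal factor scores, the extended linear predictor
#' \code{L = X Beta + H Lambda}, presence by a unit-variance probit
#' (\code{PA = 1(L_PA + N(0,1) > 0)}), positive continuous abundance
#' \code{exp(L_ABUC + N(0, sigma))} where the species is present and 0
#' otherwise, and traits \code{exp(L_trait + N(0, sigma))} where present and
#' missing otherwise -- reproducing the structural missingness of the hurdle
#' data model.
#'
#' @param truth a \code{jstdmTruth} bundle from [generateParameters()].
#' @param nSites number of sites.
#' @param seed RNG seed (\code{NULL}: continue the current stream).
#' @return a list with \code{abundance} (sites x species),
#'   \code{traits} (named list of sites x species tables), \code{covariates}
#'   (sites x covariates data.frame), plus the simulated \code{X}, \code{H}
#'   and the \code{truth}.
#' @export
generateCommunity <- function(truth, nSites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  species <- truth$species
  S <- length(species)
  sites <- sprintf("site%03d", seq_len(nSites))
  nc <- length(truth$covariateNames) + 1L
  X <- cbind(1, matrix(rnorm(nSites * (nc - 1L)), nSites, nc - 1L))
  colnames(X) <- c("(Intercept)", truth$covariateNames)
  rownames(X) <- sites
  H <- matrix(rnorm(nSites * nrow(truth$Lambda)), nSites, nrow(truth$Lambda))
  L <- X %*% truth$Beta + H %*% truth$Lambda
  colIdx <- function(z) (match(z, truth$rtypes$name) - 1L) * S + seq_len(S)
  pa <- (L[, colIdx("PA"), drop = FALSE] + rnorm(nSites * S) > 0) * 1
  dimnames(pa) <- list(sites, species)
  ab <- exp(L[, colIdx("ABUC"), drop = FALSE] +
              rnorm(nSites * S, 0, truth$sigma))
  ab[pa == 0] <- 0
  dimnames(ab) <- list(sites, species)
  traitTables <- list()
  for (z in setdiff(truth$rtypes$name, c("PA", "ABUC"))) {
    tv <- exp(L[, colIdx(z), drop = FALSE] + rnorm(nSites * S, 0, truth$sigma))
    tv[pa == 0] <- NA_real_
    dimnames(tv) <- list(sites, species)
    traitTables[[z]] <- tv
  }
  cov <- as.data.frame(X[, -1, drop = FALSE])
  rownames(cov) <- sites
  list(abundance = ab, traits = traitTables, covariates = cov,
       X = X, H = H, truth = truth)
}

#' Case-study-shaped synthetic fixture
#'
#' A full input bundle mirroring the tundra case-study design: 325 sites, 65
#' species, five response types (PA, ABUC, SLA, LA, MH) and three
#' environmental covariates named GDD, FDD and SM.  Presence-absence
#' intercepts are calibrated so that species prevalences target an evenly
#' spread 15--50\% of sites (median about 0.3), which keeps every species
#' above the usual 25-site inclusion filter; the assembled multiresponse
#' matrix has 65 x 5 = 325 column units.
#'
#' @param seed RNG seed.
#' @return the list returned by [generateCommunity()], with covariates
#'   renamed GDD/FDD/SM.
#' @export
caseStudyFixture <- function(seed = 1L) {
  set.seed(seed)
  truth <- generateParameters(
    nSpecies = 65L, traits = c("SLA", "LA", "MH"), nCovariates = 3L,
    nFactors = 3L, gammaScale = 0.25, betaSD = 0.3, lambdaScale = 0.5,
    sigma = 0.5, seed = NULL)
  truth$covariateNames <- c("GDD", "FDD", "SM")
  rownames(truth$Gamma) <- c("(Intercept)", truth$covariateNames)

  # calibrate PA intercepts to prevalence targets spread over 15-50%
  S <- 65L
  paCols <- seq_len(S)
  targets <- seq(0.15, 0.50, length.out = S)[sample.int(S)]
  vPA <- colSums(truth$Beta[-1, paCols, drop = FALSE]^2) +
    colSums(truth$Lambda[, paCols, drop = FALSE]^2)
  truth$Beta[1, paCols] <- qnorm(targets) * sqrt(1 + vPA)

  out <- generateCommunity(truth, 325L, seed = NULL)
  colnames(out$covariates) <- c("GDD", "FDD", "SM")
  colnames(out$X) <- c("(Intercept)", "GDD", "FDD", "SM")
  out
}
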