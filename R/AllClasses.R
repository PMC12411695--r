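#' @import methods
#' @importFrom stats rnorm runif rgamma pnorm qnorm dnorm sd var cor quantile
#'   rWishart setNames
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Multi-response community experiment
#'
#' Container for the multiresponse matrix of a joint species-trait
#' distribution model (JSTDM).  Each species contributes one row ("column
#' unit") per response type: presence-absence (\code{PA}), abundance
#' conditional on presence (\code{ABUC}), and one row per site-level trait.
#' The container extends \linkS4class{SummarizedExperiment} with column units
#' as rows and sites as columns, and carries two assays:
#' \describe{
#'   \item{\code{values}}{responses on the model scale -- \code{PA} rows hold
#'     0/1 indicators, all other rows hold natural-log transformed values;
#'     unobserved cells are \code{NA}.}
#'   \item{\code{observed}}{logical mask; abundance and trait cells are
#'     unobserved exactly where the species is absent (the hurdle structure).}
#' }
#' Row metadata records the species, response type and observation family of
#' every column unit.
#'
#' @seealso [assembleMultiresponse()], [filterByPrevalence()],
#'   [disassembleMultiresponse()]
#' @export
setClass("MultiResponseExperiment", contains = "SummarizedExperiment")

setValidity("MultiResponseExperiment", function(object) {
  msg <- character()
  if (!all(c("values", "observed") %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'values' and 'observed' are required")
  rd <- rowData(object)
  if (!all(c("species", "rtype", "family") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'species', 'rtype' and 'family'")
  if (length(msg)) return(msg)
  vals <- assay(object, "values")
  obs <- assay(object, "observed")
  if (!is.logical(obs))
    msg <- c(msg, "'observed' assay must be logical")
  if (any(obs & !is.finite(vals)))
    msg <- c(msg, "non-finite values flagged as observed")
  if (anyDuplicated(paste(rd$species, rd$rtype)))
    msg <- c(msg, "duplicated (species, response type) pairs")
  isPA <- rd$rtype == "PA"
  if (any(isPA)) {
    pav <- vals[isPA, , drop = FALSE]
    if (!all(pav[obs[isPA, , drop = FALSE]] %in% c(0, 1)))
      msg <- c(msg, "PA cells must be 0/1")
    if (!all(obs[isPA, , drop = FALSE]))
      msg <- c(msg, "PA cells must always be observed")
    # hurdle consistency: a non-PA cell can only be observed where PA = 1
    paRow <- match(rd$species, rd$species[isPA])
    for (r in which(!isPA)) {
      bad <- obs[r, ] & pav[paRow[r], ] == 0
      if (any(bad))
        msg <- c(msg, sprintf("row '%s' observed where species absent", rownames(object)[r]))
    }
  } else msg <- c(msg, "a PA response type is required")
  if (length(msg)) msg else TRUE
})

#' JSTDM model design
#'
#' Bundles everything the Gibbs sampler consumes: the multiresponse
#' experiment, the environmental design matrix \code{X} (intercept first,
#' covariates centred and scaled by default, with the scaling recorded so
#' predictions can be issued on original covariate scales), the species-level
#' trait matrix \code{T} and its response-type block expansion, and the
#' model-scale response matrix with its observation mask.
#'
#' @slot mre the \linkS4class{MultiResponseExperiment}.
#' @slot X sites x covariates design matrix (first column constant 1).
#' @slot covariates raw covariate table (sites x covariates, original scale).
#' @slot xCenter,xScale recorded covariate scaling (invertible).
#' @slot traitMatrix species x traits matrix used in the trait regression
#'   (intercept column first, traits centred/scaled).
#' @slot traitRaw species x traits log-scale trait values before scaling.
#' @slot tCenter,tScale recorded trait scaling.
#' @slot traitProvenance \code{"supplied"}, \code{"derived"} or \code{"none"}.
#' @slot traitDesign column-units x (types x traits) block expansion of
#'   \code{traitMatrix}: the trait row of species j occupies the block of its
#'   response type and is zero elsewhere.
#' @slot Y sites x column-units model-scale responses (log responses centred
#'   and scaled by default; unobserved cells stored as 0 and never read).
#' @slot mask sites x column-units logical observation mask.
#' @slot yCenter,yScale per-column response scaling (0/1 for PA columns).
#' @export
setClass("JstdmDesign", representation(
  mre = "MultiResponseExperiment",
  X = "matrix",
  covariates = "data.frame",
  xCenter = "numeric",
  xScale = "numeric",
  traitMatrix = "matrix",
  traitRaw = "matrix",
  tCenter = "numeric",
  tScale = "numeric",
  traitProvenance = "character",
  traitDesign = "matrix",
  Y = "matrix",
  mask = "matrix",
  yCenter = "numeric",
  yScale = "numeric"
))

setValidity("JstdmDesign", function(object) {
  msg <- character()
  n <- ncol(object@mre)
  p <- nrow(object@mre)
  if (nrow(object@X) != n) msg <- c(msg, "X rows must match sites")
  if (!all(object@X[, 1] == 1)) msg <- c(msg, "first column of X must be the intercept")
  if (!identical(dim(object@Y), c(n, p))) msg <- c(msg, "Y must be sites x column-units")
  if (!identical(dim(object@mask), c(n, p))) msg <- c(msg, "mask must be sites x column-units")
  if (nrow(object@traitDesign) != p) msg <- c(msg, "trait design rows must match column units")
  if (length(object@yScale) != p || length(object@yCenter) != p)
    msg <- c(msg, "response scaling must have one entry per column unit")
  if (any(object@Y[!object@mask] != 0)) msg <- c(msg, "unobserved Y cells must be stored as 0")
  if (length(msg)) msg else TRUE
})

#' Prior configuration for the JSTDM sampler
#'
#' Holds every hyperparameter of the hierarchical prior: the Gaussian scale of
#' the trait-regression coefficients gamma, the inverse-Wishart prior on the
#' residual covariance V of the beta deviations, the multiplicative-gamma
#' shrinkage hyperparameters of the latent factor loadings (local df
#' \code{nu}, column-shrinkage shapes \code{a1}, \code{a2} and rates
#' \code{b1}, \code{b2}), the inverse-gamma prior on log-normal residual
#' variances, and the number of latent factors.
#'
#' @export
setClass("JstdmPriors", representation(
  nFactors = "integer",
  gammaScale = "numeric",
  vDf = "numeric",      # NA_real_ -> n_c + 1 at fit time
  vScale = "matrix",    # 0 x 0 -> identity at fit time
  nu = "numeric",
  a1 = "numeric", b1 = "numeric",
  a2 = "numeric", b2 = "numeric",
  sigmaShape = "numeric",
  sigmaRate = "numeric"
))

setValidity("JstdmPriors", function(object) {
  msg <- character()
  pos <- c(gammaScale = object@gammaScale, nu = object@nu,
           a1 = object@a1, b1 = object@b1, a2 = object@a2, b2 = object@b2,
           sigmaShape = object@sigmaShape, sigmaRate = object@sigmaRate)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "all prior scales, shapes and rates must be strictly positive")
  if (object@nFactors < 1L) msg <- c(msg, "nFactors must be >= 1")
  if (!is.na(object@vDf) && object@vDf <= 0) msg <- c(msg, "vDf must be positive")
  if (length(msg)) msg else TRUE
})

#' Posterior sample set from the JSTDM Gibbs sampler
#'
#' Thinned post-burn-in posterior draws together with the design, the priors
#' and the full MCMC bookkeeping (iterations, burn-in, thinning, per-chain
#' seeds).  Each draw stores \code{Beta} (environmental responses per column
#' unit), \code{Gamma} (trait-mediated expected responses), \code{V}
#' (residual covariance of the beta deviations), \code{Lambda} (latent factor
#' loadings) and \code{sigma2} (residual variances; fixed at 1 for probit
#' columns).
#'
#' @export
setClass("JstdmFit", representation(
  draws = "list",
  chain = "integer",
  design = "JstdmDesign",
  priors = "JstdmPriors",
  settings = "list"
))

setValidity("JstdmFit", function(object) {
  if (length(object@draws) != length(object@chain))
    return("one chain id per draw required")
  TRUE
})

#' Posterior association summary
#'
#' Streaming summary of the factor-induced association matrix Omega over
#' column units: posterior means on the covariance and correlation scales and
#' per-entry posterior support (the fraction of draws in which the entry is
#' positive, respectively negative; exact zeros count in neither).  Entries
#' with zero posterior variance carry \code{NA} support.
#'
#' @export
setClass("JstdmAssociations", representation(
  meanCov = "matrix",
  meanCor = "matrix",
  supportPos = "matrix",
  supportNeg = "matrix",
  columnUnits = "DataFrame",
  nDraws = "integer"
))

setValidity("JstdmAssociations", function(object) {
  p <- nrow(object@meanCov)
  for (s in c("meanCor", "supportPos", "supportNeg"))
    if (!identical(dim(slot(object, s)), c(p, p)))
      return("all matrices must share the column-unit dimension")
  TRUE
})
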