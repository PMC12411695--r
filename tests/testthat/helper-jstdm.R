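# shared fixtures, built in code

# small community generated from the model itself
tinyCommunity <- function(seed = 42, nSites = 60, nSpecies = 6) {
  truth <- generateParameters(nSpecies, traits = "T1", nCovariates = 2,
                              nFactors = 2, seed = seed)
  generateCommunity(truth, nSites, seed = seed + 1)
}

tinyDesign <- function(com = tinyCommunity()) {
  m <- assembleMultiresponse(com$abundance, com$traits)
  jstdmDesign(m, covariates = com$covariates, speciesTraits = "derived")
}

# one modest fit shared across test files (built on first use)
.shared <- new.env(parent = emptyenv())
sharedFit <- function() {
  if (is.null(.shared$fit)) {
    com <- tinyCommunity()
    .shared$com <- com
    .shared$design <- tinyDesign(com)
    .shared$fit <- runMCMC(.shared$design, jstdmPriors(nFactors = 2),
                           chains = 2, iterations = 600, burnin = 300,
                           thin = 3, seed = 7)
  }
  .shared$fit
}
sharedCommunity <- function() { sharedFit(); .shared$com }
sharedDesign <- function() { sharedFit(); .shared$design }

# design in which every species is present everywhere (no structural
# missingness), handy for analytic prediction oracles
denseDesign <- function(nSites = 4, nSpecies = 1, traits = "T1", seed = 3,
                        scaleResponses = FALSE) {
  set.seed(seed)
  sites <- sprintf("s%02d", seq_len(nSites))
  sp <- sprintf("sp%d", seq_len(nSpecies))
  ab <- matrix(runif(nSites * nSpecies, 1, 5), nSites, nSpecies,
               dimnames = list(sites, sp))
  tt <- lapply(setNames(traits, traits), function(z)
    matrix(runif(nSites * nSpecies, 1, 3), nSites, nSpecies,
           dimnames = list(sites, sp)))
  m <- assembleMultiresponse(ab, tt)
  jstdmDesign(m, scaleResponses = scaleResponses)
}

# hand-built fit around fixed parameter draws
stubFit <- function(design, draws, nFactors = nrow(draws[[1]]$Lambda)) {
  draws <- lapply(draws, function(d) {
    nc <- ncol(design@X)
    q <- ncol(design@traitDesign)
    if (is.null(d$Gamma)) d$Gamma <- matrix(0, nc, q)
    if (is.null(d$V)) d$V <- diag(nc)
    if (is.null(d$sigma2)) d$sigma2 <- rep(1, ncol(design@Y))
    if (is.null(d$Beta)) d$Beta <- matrix(0, nc, ncol(design@Y))
    d
  })
  new("JstdmFit", draws = draws, chain = rep(1L, length(draws)),
      design = design, priors = jstdmPriors(nFactors = nFactors),
      settings = list(chains = 1L, iterations = length(draws),
                      burnin = 0L, thin = 1L, seed = 0L,
                      chainSeeds = 0L, perChain = length(draws)))
}
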