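#' Read model inputs from a manifest
#'
#' The manifest is a JSON file with a \code{files} block naming the CSV
#' tables (\code{abundance}, \code{covariates}, and a named \code{traits}
#' map, one file per trait; sites as rows with the site id in the first
#' column, species as columns, missing cells empty or \code{NA}) plus
#' optional keys \code{min_prevalence}, \code{scale_responses},
#' \code{scale_covariates}.  Paths are resolved relative to the manifest.
#'
#' @param manifest path to the manifest JSON file.
#' @return a list with \code{abundance}, \code{traits}, \code{covariates}
#'   and \code{config}.
#' @export
readInputs <- function(manifest) {
  cfg <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  .stopIfNot(!is.null(cfg$files), "manifest '%s' has no 'files' block", manifest)
  base <- dirname(normalizePath(manifest))
  resolve <- function(f) if (file.exists(f)) f else file.path(base, f)
  readTable <- function(f, what) {
    .stopIfNot(!is.null(f), "manifest is missing the '%s' file", what)
    f <- resolve(f)
    .stopIfNot(file.exists(f), "%s file not found: %s", what, f)
    df <- utils::read.csv(f, check.names = FALSE)
    .stopIfNot(ncol(df) >= 2, "file '%s': a site-id column plus data columns required", f)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1]])
    m
  }
  ab <- readTable(cfg$files$abundance, "abundance")
  traits <- list()
  for (tn in names(cfg$files$traits))
    traits[[tn]] <- readTable(cfg$files$traits[[tn]], paste0("trait '", tn, "'"))
  cov <- NULL
  if (!is.null(cfg$files$covariates))
    cov <- as.data.frame(readTable(cfg$files$covariates, "covariates"))
  list(abundance = ab, traits = traits, covariates = cov,
       config = cfg[setdiff(names(cfg), "files")])
}

#' Write analysis outputs
#'
#' Writes whichever results are present to CSV tables (full \code{\%.17g}
#' precision, so re-reading round-trips numerically) plus a JSON run
#' manifest recording the seeds, every prior hyperparameter, the MCMC
#' settings and the package version.
#'
#' @param results a named list; recognised components: \code{fit}
#'   (\linkS4class{JstdmFit}), \code{associations}
#'   (\linkS4class{JstdmAssociations}), \code{cv} (from [crossValidate()]),
#'   \code{variancePartitioning}, \code{scenario} (from [scenarioPredict()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeOutputs <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  manifest <- list(package = "jstdm",
                   version = as.character(utils::packageVersion("jstdm")))
  put <- function(mat, name) {
    f <- file.path(dir, name)
    .writeNumericCSV(mat, f)
    written <<- c(written, f)
  }
  if (!is.null(results$fit)) {
    fit <- results$fit
    put(posteriorMean(fit, "Beta"), "beta_posterior_mean.csv")
    put(posteriorMean(fit, "Gamma"), "gamma_posterior_mean.csv")
    put(matrix(posteriorMean(fit, "sigma2"), ncol = 1,
               dimnames = list(colnames(fit@design@Y), "sigma2")),
        "sigma2_posterior_mean.csv")
    p <- fit@priors
    manifest$mcmc <- fit@settings
    manifest$priors <- list(nFactors = p@nFactors, gammaScale = p@gammaScale,
                            vDf = if (is.na(p@vDf)) ncol(fit@design@X) + 1 else p@vDf,
                            nu = p@nu, a1 = p@a1, b1 = p@b1, a2 = p@a2,
                            b2 = p@b2, sigmaShape = p@sigmaShape,
                            sigmaRate = p@sigmaRate)
  }
  if (!is.null(results$associations)) {
    a <- results$associations
    put(a@meanCov, "association_covariance.csv")
    put(a@meanCor, "association_correlation.csv")
    put(a@supportPos, "association_support_positive.csv")
    manifest$associationDraws <- a@nDraws
  }
  if (!is.null(results$cv)) {
    f <- file.path(dir, "cross_validation.csv")
    df <- results$cv
    for (cn in c("predicted", "observed"))
      df[[cn]] <- sprintf("%.17g", df[[cn]])
    utils::write.csv(df, f, row.names = FALSE)
    written <- c(written, f)
    manifest$cv <- attr(results$cv, "settings")
  }
  if (!is.null(results$variancePartitioning))
    put(results$variancePartitioning, "variance_partitioning.csv")
  if (!is.null(results$scenario)) {
    sc <- results$scenario
    put(sc$probabilities, "scenario_occurrence_probabilities.csv")
    put(matrix(sc$richness, nrow = 1,
               dimnames = list("richness", names(sc$richness))),
        "scenario_richness.csv")
  }
  mf <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, mf)
  invisible(written)
}

#' @rdname readInputs
#' @param file path to a numeric CSV previously written by [writeOutputs()].
#' @export
readNumericTable <- function(file) .readNumericCSV(file)
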