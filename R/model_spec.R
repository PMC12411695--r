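#' Response-type configuration
#'
#' Builds the table of response types that defines the structure of the
#' multiresponse matrix.  Presence-absence (\code{PA}) is always modelled with
#' a Bernoulli distribution and the probit link; abundance conditional on
#' presence (\code{ABUC}) and every site-level trait are modelled with a
#' log-normal distribution (values enter the model on the natural-log scale).
#'
#' @param traits character vector of trait names (possibly empty).
#' @param abundance include the \code{ABUC} response type (default \code{TRUE}).
#' @return a data.frame with columns \code{name}, \code{family},
#'   \code{transform}, one row per response type, \code{PA} first.
#' @examples
#' responseTypes(c("SLA", "LA", "MH"))
#' @export
responseTypes <- function(traits = character(), abundance = TRUE) {
  nm <- c("PA", if (abundance) "ABUC", traits)
  .stopIfNot(!anyDuplicated(nm), "response type names must be unique")
  data.frame(
    name = nm,
    family = c("bernoulli_probit", rep("lognormal", length(nm) - 1L)),
    transform = c("identity", rep("log", length(nm) - 1L)),
    stringsAsFactors = FALSE
  )
}

.unitNames <- function(rtypes, species) {
  as.vector(vapply(rtypes, function(z) paste(z, species, sep = ":"),
                   character(length(species))))
}

#' Assemble the multiresponse matrix
#'
#' Turns a sites x species abundance table and per-trait sites x species
#' tables into the multiresponse experiment of the joint species-trait model.
#' The hurdle decomposition is applied at assembly time: the \code{PA} column
#' unit of species j is the indicator \code{abundance > 0}; the \code{ABUC}
#' unit is \code{log(abundance)} where the species is present and unobserved
#' otherwise; each trait unit is \code{log(trait)} where a value is present
#' and unobserved otherwise.  Trait values are structurally missing where the
#' species is absent, and a trait value reported at a site where the
#' abundance is zero violates the hurdle data model.
#'
#' Column units are ordered in type-major blocks (all \code{PA} units, then
#' all \code{ABUC}, then each trait), species in the input order within each
#' block; see [columnOrder()] for the species-major permutation.
#'
#' @param abundance sites x species matrix or data.frame of non-negative
#'   abundances (e.g. percentage cover).
#' @param traitTables named list of sites x species tables of site-level
#'   trait values, \code{NA} where unmeasured; dimnames must match
#'   \code{abundance}.
#' @param rtypes response-type table from [responseTypes()]; defaults to
#'   \code{PA} + \code{ABUC} + one type per trait table.
#' @param onInconsistentTrait \code{"error"} (default) fails when a trait is
#'   observed where the species is absent; \code{"mask"} drops such cells
#'   with a warning.
#' @return a \linkS4class{MultiResponseExperiment} with
#'   \code{n_species * n_types} column units.
#' @examples
#' ab <- matrix(c(10, 5, 0, 2), 2, 2,
#'              dimnames = list(c("s1", "s2"), c("spA", "spB")))
#' tr <- matrix(c(1.2, 1.5, NA, 0.7), 2, 2,
#'              dimnames = dimnames(ab))
#' m <- assembleMultiresponse(ab, list(SLA = tr))
#' dim(m)  # 6 column units x 2 sites
#' @export
assembleMultiresponse <- function(abundance, traitTables = list(),
                                  rtypes = NULL,
                                  onInconsistentTrait = c("error", "mask")) {
  onInconsistentTrait <- match.arg(onInconsistentTrait)
  ab <- as.matrix(abundance)
  storage.mode(ab) <- "double"
  .stopIfNot(!is.null(rownames(ab)) && !is.null(colnames(ab)),
             "abundance table needs site row names and species column names")
  .stopIfNot(all(is.finite(ab)) && all(ab >= 0),
             "abundances must be finite and non-negative")
  if (is.null(rtypes)) rtypes <- responseTypes(names(traitTables))
  .stopIfNot(identical(sort(setdiff(rtypes$name, c("PA", "ABUC"))),
                       sort(as.character(names(traitTables)))),
             "trait tables must match the non-PA/ABUC response types")
  sites <- rownames(ab); species <- colnames(ab)
  for (tn in names(traitTables)) {
    tt <- as.matrix(traitTables[[tn]])
    .stopIfNot(identical(rownames(tt), sites) && identical(colnames(tt), species),
               "trait table '%s': site/species indexes do not match the abundance table", tn)
  }
  n <- length(sites); S <- length(species); nz <- nrow(rtypes)
  pa <- (ab > 0) * 1

  blocks <- list(); obsBlocks <- list()
  for (z in rtypes$name) {
    if (z == "PA") {
      blocks[[z]] <- pa
      obsBlocks[[z]] <- matrix(TRUE, n, S)
    } else if (z == "ABUC") {
      v <- matrix(NA_real_, n, S)
      v[ab > 0] <- log(ab[ab > 0])
      blocks[[z]] <- v
      obsBlocks[[z]] <- ab > 0
    } else {
      tt <- as.matrix(traitTables[[z]])
      storage.mode(tt) <- "double"
      obs <- !is.na(tt)
      bad <- obs & tt <= 0
      if (any(bad)) {
        w <- which(bad, arr.ind = TRUE)[1, ]
        stop(sprintf("trait '%s': non-positive value at site '%s', species '%s' (log undefined)",
                     z, sites[w[1]], species[w[2]]), call. = FALSE)
      }
      incons <- obs & ab == 0
      if (any(incons)) {
        w <- which(incons, arr.ind = TRUE)[1, ]
        if (onInconsistentTrait == "error")
          stop(sprintf("trait '%s' observed where abundance is 0 (site '%s', species '%s'); set onInconsistentTrait = 'mask' to drop such cells",
                       z, sites[w[1]], species[w[2]]), call. = FALSE)
        warning(sprintf("trait '%s': masking %d cell(s) observed where the species is absent",
                        z, sum(incons)))
        obs[incons] <- FALSE
      }
      v <- matrix(NA_real_, n, S)
      v[obs] <- log(tt[obs])
      blocks[[z]] <- v
      obsBlocks[[z]] <- obs
    }
  }
  values <- do.call(cbind, blocks)          # sites x (nz*S), type-major
  observed <- do.call(cbind, obsBlocks)
  units <- .unitNames(rtypes$name, species)
  dimnames(values) <- list(sites, units)
  dimnames(observed) <- list(sites, units)
  rd <- DataFrame(
    species = rep(species, times = nz),
    rtype = rep(rtypes$name, each = S),
    family = rep(rtypes$family, each = S),
    row.names = units
  )
  se <- SummarizedExperiment(
    assays = list(values = t(values), observed = t(observed)),
    rowData = rd
  )
  colnames(se) <- sites
  metadata(se)$responseTypes <- rtypes
  new("MultiResponseExperiment", se)
}

#' @describeIn assembleMultiresponse recover the original abundance and trait
#'   tables (natural scale) from an assembled experiment; exact on observed
#'   cells.
#' @param m a \linkS4class{MultiResponseExperiment}.
#' @export
disassembleMultiresponse <- function(m) {
  vals <- responseValues(m)
  obs <- observedMask(m)
  cu <- columnUnits(m)
  species <- unique(cu$species)
  pa <- vals[, cu$rtype == "PA", drop = FALSE]
  colnames(pa) <- cu$species[cu$rtype == "PA"]
  out <- list()
  if ("ABUC" %in% cu$rtype) {
    idx <- which(cu$rtype == "ABUC")
    abv <- exp(vals[, idx, drop = FALSE])
    abv[!obs[, idx, drop = FALSE]] <- 0
    colnames(abv) <- cu$species[idx]
    out$abundance <- abv[, species, drop = FALSE]
  }
  out$traits <- list()
  for (z in setdiff(unique(cu$rtype), c("PA", "ABUC"))) {
    idx <- which(cu$rtype == z)
    tv <- exp(vals[, idx, drop = FALSE])
    tv[!obs[, idx, drop = FALSE]] <- NA_real_
    colnames(tv) <- cu$species[idx]
    out$traits[[z]] <- tv[, species, drop = FALSE]
  }
  out$presence <- pa[, species, drop = FALSE]
  out
}

#' @rdname MultiResponseExperiment-class
#' @param x,object a \linkS4class{MultiResponseExperiment}.
#' @export
responseValues <- function(x) t(assay(x, "values"))

#' @rdname MultiResponseExperiment-class
#' @export
observedMask <- function(x) t(assay(x, "observed"))

#' @rdname MultiResponseExperiment-class
#' @export
columnUnits <- function(x) rowData(x)

#' @rdname MultiResponseExperiment-class
#' @export
speciesNames <- function(x) unique(columnUnits(x)$species)

#' @rdname MultiResponseExperiment-class
#' @export
responseTypeNames <- function(x) unique(columnUnits(x)$rtype)

#' @rdname MultiResponseExperiment-class
#' @param order \code{"type-major"} (the native block layout) or
#'   \code{"species-major"} (all units of one species adjacent).
#' @return \code{columnOrder}: an integer permutation of the column units.
#' @export
columnOrder <- function(x, order = c("type-major", "species-major")) {
  order <- match.arg(order)
  cu <- columnUnits(x)
  if (order == "type-major") seq_len(nrow(cu))
  else order(match(cu$species, speciesNames(x)),
             match(cu$rtype, responseTypeNames(x)))
}

setMethod("show", "MultiResponseExperiment", function(object) {
  cu <- columnUnits(object)
  cat(sprintf("MultiResponseExperiment: %d sites, %d species, %d response types (%s)\n",
              ncol(object), length(unique(cu$species)),
              length(unique(cu$rtype)), paste(unique(cu$rtype), collapse = ", ")))
  cat(sprintf("  %d column units; %.1f%% of cells observed\n",
              nrow(object), 100 * mean(assay(object, "observed"))))
})

#' Filter species by prevalence
#'
#' Retains all column units of species whose presence-absence column sums to
#' at least \code{minSites} occupied sites, mirroring the usual inclusion
#' rule (e.g. species present in at least 25 of 325 sites).
#'
#' @param m a \linkS4class{MultiResponseExperiment}.
#' @param minSites minimum number of occupied sites.
#' @return the filtered experiment; an error if no species survives.
#' @export
filterByPrevalence <- function(m, minSites) {
  .stopIfNot(minSites <= ncol(m), "minSites exceeds the number of sites")
  cu <- columnUnits(m)
  paIdx <- which(cu$rtype == "PA")
  prev <- rowSums(assay(m, "values")[paIdx, , drop = FALSE])
  keepSpecies <- cu$species[paIdx][prev >= minSites]
  if (length(keepSpecies) == 0L)
    stop("prevalence filter removed every species", call. = FALSE)
  out <- m[cu$species %in% keepSpecies, ]
  metadata(out)$prevalenceFilter <-
    list(minSites = minSites, retained = keepSpecies)
  out
}

#' Species-level traits from site-level observations
#'
#' Derives the species-level trait matrix as the mean of observed natural-log
#' site-level values per species -- the species-level trait used to model
#' trait-mediated environmental responses.
#'
#' @param traitTables named list of sites x species trait tables on the
#'   natural scale (\code{NA} where unmeasured), or a
#'   \linkS4class{MultiResponseExperiment} (whose trait units are already on
#'   the log scale).
#' @return species x traits matrix of log-scale species-level trait values
#'   with attribute \code{provenance = "derived"}.
#' @export
speciesLevelTraits <- function(traitTables) {
  if (is(traitTables, "MultiResponseExperiment")) {
    m <- traitTables
    cu <- columnUnits(m)
    traits <- setdiff(unique(cu$rtype), c("PA", "ABUC"))
    species <- speciesNames(m)
    vals <- responseValues(m); obs <- observedMask(m)
    T <- matrix(NA_real_, length(species), length(traits),
                dimnames = list(species, traits))
    for (z in traits) for (j in species) {
      idx <- which(cu$rtype == z & cu$species == j)
      v <- vals[obs[, idx], idx]
      if (length(v) == 0L)
        stop(sprintf("species '%s' has no observed values of trait '%s'", j, z),
             call. = FALSE)
      T[j, z] <- mean(v)
    }
  } else {
    .stopIfNot(length(traitTables) > 0 && !is.null(names(traitTables)),
               "a named list of trait tables is required")
    traits <- names(traitTables)
    species <- colnames(as.matrix(traitTables[[1]]))
    T <- matrix(NA_real_, length(species), length(traits),
                dimnames = list(species, traits))
    for (z in traits) {
      tt <- as.matrix(traitTables[[z]])
      .stopIfNot(all(tt[!is.na(tt)] > 0), "trait '%s' has non-positive values", z)
      lt <- log(tt)
      nObs <- colSums(!is.na(lt))
      if (any(nObs == 0L))
        stop(sprintf("species with no observed values of trait '%s': %s",
                     z, paste(species[nObs == 0L], collapse = ", ")), call. = FALSE)
      T[, z] <- colMeans(lt, na.rm = TRUE)
    }
  }
  attr(T, "provenance") <- "derived"
  T
}

#' Expand the species trait matrix over response types
#'
#' Places the trait row of species j in the block of its response type z and
#' zero elsewhere, producing the column-units x (types x traits) design that
#' makes the trait effects gamma_{klz} -- specific to both predictor k and
#' response type z -- estimable within a single trait regression.  With a
#' single response type the expansion equals the input.
#'
#' @param T species x traits matrix including an intercept column.
#' @param rtypeNames character vector of response-type names (block order).
#' @param species optional species names (defaults to \code{rownames(T)}).
#' @return a \code{(n_species * n_types) x (n_types * n_traits)} matrix, rows
#'   in type-major order.
#' @export
expandTraitDesign <- function(T, rtypeNames, species = rownames(T)) {
  T <- as.matrix(T)
  nz <- length(rtypeNames); S <- nrow(T); nt <- ncol(T)
  out <- matrix(0, nz * S, nz * nt)
  for (z in seq_len(nz)) {
    rows <- (z - 1L) * S + seq_len(S)
    cols <- (z - 1L) * nt + seq_len(nt)
    out[rows, cols] <- T
  }
  rownames(out) <- .unitNames(rtypeNames, if (is.null(species)) seq_len(S) else species)
  colnames(out) <- as.vector(vapply(rtypeNames, function(z)
    paste(z, colnames(T), sep = ":"), character(nt)))
  out
}

.scaleColumns <- function(M) {
  ctr <- colMeans(M)
  scl <- apply(M, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(scaled = sweep(sweep(M, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Construct a JSTDM model design
#'
#' Combines the multiresponse experiment with the environmental design and
#' the species-level trait design.  Covariates and log-scale responses are
#' centred and scaled to unit variance by default (recorded and invertible);
#' presence-absence columns are left untouched.  Passing no covariates gives
#' the intercept-only null model; passing no species traits reduces the trait
#' regression to a grand intercept per response type.
#'
#' @param mre a \linkS4class{MultiResponseExperiment}.
#' @param covariates sites x covariates data.frame on the original scale, or
#'   \code{NULL} for the null model.
#' @param speciesTraits species x traits matrix of log-scale species-level
#'   trait values, \code{"derived"} to average the experiment's observed
#'   site-level values, or \code{NULL} for an intercept-only trait design.
#' @param scaleResponses,scaleCovariates centre/scale log-scale responses and
#'   covariates (defaults \code{TRUE}).
#' @return a \linkS4class{JstdmDesign}.
#' @export
jstdmDesign <- function(mre, covariates = NULL, speciesTraits = NULL,
                        scaleResponses = TRUE, scaleCovariates = TRUE) {
  n <- ncol(mre); sites <- colnames(mre)
  cu <- columnUnits(mre)
  species <- speciesNames(mre)
  rtypeNames <- responseTypeNames(mre)

  # environmental design
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    covariates <- data.frame(row.names = sites)
    X <- matrix(1, n, 1, dimnames = list(sites, "(Intercept)"))
    xCenter <- numeric(0); xScale <- numeric(0)
  } else {
    covariates <- as.data.frame(covariates)
    .stopIfNot(nrow(covariates) == n, "covariate table must have one row per site")
    rownames(covariates) <- sites
    C <- as.matrix(covariates)
    .stopIfNot(all(is.finite(C)), "covariates must be finite")
    if (scaleCovariates) {
      sc <- .scaleColumns(C)
      C <- sc$scaled; xCenter <- sc$center; xScale <- sc$scale
    } else {
      xCenter <- setNames(rep(0, ncol(C)), colnames(C))
      xScale <- setNames(rep(1, ncol(C)), colnames(C))
    }
    X <- cbind("(Intercept)" = 1, C)
  }
  .stopIfNot(qr(X)$rank == ncol(X), "environmental design is rank-deficient")

  # species-level trait design
  if (identical(speciesTraits, "derived")) speciesTraits <- speciesLevelTraits(mre)
  if (is.null(speciesTraits) || NCOL(speciesTraits) == 0L) {
    traitRaw <- matrix(0, length(species), 0, dimnames = list(species, NULL))
    Tm <- matrix(1, length(species), 1, dimnames = list(species, "(Intercept)"))
    tCenter <- numeric(0); tScale <- numeric(0)
    provenance <- "none"
  } else {
    traitRaw <- as.matrix(speciesTraits)
    .stopIfNot(identical(rownames(traitRaw), species),
               "species trait matrix rows must match the species of the experiment")
    provenance <- attr(speciesTraits, "provenance")
    if (is.null(provenance)) provenance <- "supplied"
    sc <- .scaleColumns(traitRaw)
    Tm <- cbind("(Intercept)" = 1, sc$scaled)
    tCenter <- sc$center; tScale <- sc$scale
  }
  Ttilde <- expandTraitDesign(Tm, rtypeNames, species)

  # model-scale responses
  vals <- responseValues(mre)
  mask <- observedMask(mre)
  p <- ncol(vals)
  yCenter <- rep(0, p); yScale <- rep(1, p)
  Y <- vals
  isLN <- cu$family == "lognormal"
  if (scaleResponses) {
    for (c in which(isLN)) {
      v <- vals[mask[, c], c]
      if (length(v) >= 2L && sd(v) > 0) {
        yCenter[c] <- mean(v); yScale[c] <- sd(v)
      } else if (length(v) >= 1L) {
        yCenter[c] <- mean(v)
      }
      Y[mask[, c], c] <- (v - yCenter[c]) / yScale[c]
    }
  }
  Y[!mask] <- 0

  new("JstdmDesign", mre = mre, X = X, covariates = covariates,
      xCenter = xCenter, xScale = xScale,
      traitMatrix = Tm, traitRaw = traitRaw, tCenter = tCenter, tScale = tScale,
      traitProvenance = provenance, traitDesign = Ttilde,
      Y = Y, mask = mask, yCenter = yCenter, yScale = yScale)
}

#' @rdname jstdmDesign
#' @param design a \linkS4class{JstdmDesign}.
#' @param sites site names or indices to keep; scalings are recomputed from
#'   the retained sites (species-level traits are kept fixed).
#' @export
subsetSites <- function(design, sites) {
  jstdmDesign(
    design@mre[, sites],
    covariates = if (ncol(design@covariates)) design@covariates[sites, , drop = FALSE] else NULL,
    speciesTraits = if (design@traitProvenance == "none") NULL else {
      tr <- design@traitRaw
      attr(tr, "provenance") <- design@traitProvenance
      tr
    },
    scaleResponses = TRUE, scaleCovariates = length(design@xScale) > 0
  )
}

setMethod("show", "JstdmDesign", function(object) {
  cat(sprintf("JstdmDesign: %d sites x %d column units; %d covariate(s), %d trait(s) [%s]\n",
              nrow(object@Y), ncol(object@Y), ncol(object@X) - 1L,
              ncol(object@traitMatrix) - 1L, object@traitProvenance))
})
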