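#' Association matrix from a loadings draw
#'
#' The factor-induced covariance among column units: \code{Omega = t(Lambda)
#' \%*\% Lambda}, i.e. the sum over latent factors of the products of the two
#' units' loadings.  Each draw is symmetric positive semidefinite with rank
#' at most the number of factors.
#'
#' @param Lambda a factors x column-units loadings matrix.
#' @return the column-units x column-units covariance matrix.
#' @export
omegaFromLambda <- function(Lambda) crossprod(Lambda)

.corFromCov <- function(om) {
  d <- diag(om)
  s <- ifelse(d > 0, 1 / sqrt(d), NA_real_)
  co <- om * outer(s, s)
  co[which(co > 1)] <- 1
  co[which(co < -1)] <- -1
  diag(co)[d > 0] <- 1
  co
}

#' Posterior association summary
#'
#' Streams over the posterior draws of the loadings, accumulating the
#' posterior mean association matrix on the covariance scale, the mean of the
#' per-draw correlation matrices (each summand is then a valid correlation
#' matrix), and per-entry posterior support: the fraction of draws in which
#' the association is positive, respectively negative (exact zeros count in
#' neither).  Entries whose draws never vary carry undefined (\code{NA})
#' support.
#'
#' @param fit a \linkS4class{JstdmFit}.
#' @return a \linkS4class{JstdmAssociations} object.
#' @export
computeAssociations <- function(fit) {
  nd <- length(fit@draws)
  p <- ncol(fit@draws[[1]]$Lambda)
  sumCov <- matrix(0, p, p)
  sumCov2 <- matrix(0, p, p)
  sumCor <- matrix(0, p, p)
  nCor <- matrix(0, p, p)
  nPos <- matrix(0, p, p)
  nNeg <- matrix(0, p, p)
  for (d in fit@draws) {
    om <- crossprod(d$Lambda)
    sumCov <- sumCov + om
    sumCov2 <- sumCov2 + om^2
    co <- .corFromCov(om)
    ok <- !is.na(co)
    sumCor[ok] <- sumCor[ok] + co[ok]
    nCor <- nCor + ok
    nPos <- nPos + (om > 0)
    nNeg <- nNeg + (om < 0)
  }
  meanCor <- sumCor / nCor
  meanCor[nCor == 0] <- NA_real_
  drawVar <- sumCov2 / nd - (sumCov / nd)^2
  supPos <- nPos / nd
  supNeg <- nNeg / nd
  undef <- drawVar <= 0 & abs(sumCov / nd) < .Machine$double.eps
  supPos[undef] <- NA_real_
  supNeg[undef] <- NA_real_
  cu <- columnUnits(fit@design@mre)
  un <- rownames(cu)
  dimn <- list(un, un)
  new("JstdmAssociations",
      meanCov = structure(sumCov / nd, dimnames = dimn),
      meanCor = structure(meanCor, dimnames = dimn),
      supportPos = structure(supPos, dimnames = dimn),
      supportNeg = structure(supNeg, dimnames = dimn),
      columnUnits = cu, nDraws = as.integer(nd))
}

setMethod("show", "JstdmAssociations", function(object) {
  cat(sprintf("JstdmAssociations: %d column units, %d posterior draws\n",
              nrow(object@meanCov), object@nDraws))
  fl <- supportFlags(object, 0.9)
  cat(sprintf("  at 90%% support: %d positive, %d negative entries (upper triangle)\n",
              sum(fl[upper.tri(fl)] == 1, na.rm = TRUE),
              sum(fl[upper.tri(fl)] == -1, na.rm = TRUE)))
})

#' Signed posterior support calls
#'
#' Flags an association positive (\code{+1}) if the fraction of posterior
#' draws in which it is positive reaches \code{level}, negative (\code{-1})
#' symmetrically, else \code{0}; entries with undefined support are
#' \code{NA}.  Raising the level can only remove flags.
#'
#' @param assoc a \linkS4class{JstdmAssociations} object.
#' @param level posterior support level in (0.5, 1]; default 0.90.
#' @return an integer matrix of flags.
#' @export
supportFlags <- function(assoc, level = 0.90) {
  .stopIfNot(level > 0.5 && level <= 1, "support level must lie in (0.5, 1]")
  if (assoc@nDraws < 100L)
    warning("fewer than 100 posterior draws: support calls are unstable")
  fl <- matrix(0L, nrow(assoc@supportPos), ncol(assoc@supportPos),
               dimnames = dimnames(assoc@supportPos))
  fl[assoc@supportPos >= level] <- 1L
  fl[assoc@supportNeg >= level] <- -1L
  fl[is.na(assoc@supportPos)] <- NA_integer_
  fl
}

#' @rdname supportFlags
#' @export
associationSupport <- function(assoc, level = 0.90) supportFlags(assoc, level)

#' Compare null-model and environmental-model associations
#'
#' Classifies every association entry between the intercept-only null model
#' (raw associations) and the environmental model (residual associations):
#' \emph{retained} (flagged in both), \emph{explained-away} (flagged in the
#' null model only -- the association is accounted for by the measured
#' environment) and \emph{emergent} (flagged in the environmental model
#' only).  Counts are reported per response-type block pair over the upper
#' triangle.
#'
#' @param assocNull,assocEnv \linkS4class{JstdmAssociations} from the null
#'   and the environmental model over identical column units.
#' @param level support level used for both models.
#' @return a list with the entry-wise \code{classification} matrix and a
#'   per-block \code{counts} data.frame.
#' @export
compareAssociations <- function(assocNull, assocEnv, level = 0.90) {
  .stopIfNot(identical(rownames(assocNull@meanCov), rownames(assocEnv@meanCov)),
             "association matrices are over different column units")
  fn <- supportFlags(assocNull, level)
  fe <- supportFlags(assocEnv, level)
  cls <- matrix("unflagged", nrow(fn), ncol(fn), dimnames = dimnames(fn))
  cls[fn != 0 & fe != 0] <- "retained"
  cls[fn != 0 & fe == 0] <- "explained-away"
  cls[fn == 0 & fe != 0] <- "emergent"
  cls[is.na(fn) | is.na(fe)] <- NA_character_
  rt <- assocNull@columnUnits$rtype
  ut <- upper.tri(fn)
  blocks <- expand.grid(z1 = unique(rt), z2 = unique(rt),
                        stringsAsFactors = FALSE)
  blocks <- blocks[match(blocks$z1, unique(rt)) <= match(blocks$z2, unique(rt)), ]
  counts <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    inBlock <- ut & ((outer(rt == blocks$z1[i], rt == blocks$z2[i])) |
                     (outer(rt == blocks$z2[i], rt == blocks$z1[i])))
    tab <- cls[inBlock]
    data.frame(z1 = blocks$z1[i], z2 = blocks$z2[i],
               retained = sum(tab == "retained", na.rm = TRUE),
               explainedAway = sum(tab == "explained-away", na.rm = TRUE),
               emergent = sum(tab == "emergent", na.rm = TRUE))
  }))
  list(classification = cls, counts = counts)
}

#' Posterior share of association variance per latent factor
#'
#' For each draw, the share of the trace of Omega carried by factor h is
#' \code{sum_c lambda_hc^2 / sum_hc lambda_hc^2}; shares are averaged over
#' draws and reported sorted descending, identifying the most influential
#' latent factor.
#'
#' @param fit a \linkS4class{JstdmFit}.
#' @export
factorImportance <- function(fit) {
  shares <- vapply(fit@draws, function(d) {
    tot <- sum(d$Lambda^2)
    if (tot == 0) stop("all-zero loadings draw", call. = FALSE)
    rowSums(d$Lambda^2) / tot
  }, numeric(nrow(fit@draws[[1]]$Lambda)))
  shares <- if (is.null(dim(shares))) matrix(shares, 1) else shares
  m <- rowMeans(shares)
  names(m) <- paste0("factor", seq_along(m))
  sort(m, decreasing = TRUE)
}

#' Variance partitioning over predictors, latent factors and residual
#'
#' For every column unit, the variance of the realized environmental
#' contribution \code{X beta} is split by covariate group and reported next
#' to the latent-factor variance \code{sum_h lambda_h^2} and the residual
#' variance (\code{sigma^2} for log-normal columns, 1 for probit columns),
#' normalised to proportions summing to one and averaged over draws.
#' Empirical covariate variances on the fitted scale are used.
#'
#' @param fit a \linkS4class{JstdmFit}.
#' @param groups named list mapping group names to covariate names; default:
#'   each non-intercept covariate forms its own group.
#' @return a column-units x components proportion matrix.
#' @export
variancePartitioning <- function(fit, groups = NULL) {
  X <- fit@design@X
  covNames <- colnames(X)[-1]
  if (is.null(groups)) {
    groups <- as.list(covNames)
    names(groups) <- covNames
  }
  p <- ncol(fit@design@Y)
  comps <- c(names(groups), "latentFactors", "residual")
  acc <- matrix(0, p, length(comps), dimnames = list(colnames(fit@design@Y), comps))
  for (d in fit@draws) {
    vmat <- matrix(0, p, length(comps))
    for (g in seq_along(groups)) {
      idx <- match(groups[[g]], colnames(X))
      .stopIfNot(!anyNA(idx), "unknown covariate in group '%s'", names(groups)[g])
      contrib <- X[, idx, drop = FALSE] %*% d$Beta[idx, , drop = FALSE]
      vmat[, g] <- apply(contrib, 2, var)
    }
    vmat[, length(groups) + 1L] <- colSums(d$Lambda^2)
    vmat[, length(groups) + 2L] <- d$sigma2
    tot <- rowSums(vmat)
    tot[tot == 0] <- 1
    acc <- acc + vmat / tot
  }
  acc / length(fit@draws)
}
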