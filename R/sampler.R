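#' Prior configuration
#'
#' Defaults follow the established hierarchical-community-model lineage:
#' \code{gamma ~ N(0, gammaScale^2 I)} with \code{gammaScale = 1};
#' \code{V ~ InvWishart(n_c + 1, I)}; factor loadings under the
#' multiplicative gamma process with local df \code{nu = 3}, column-shrinkage
#' shapes \code{a1 = a2 = 50} and rates \code{b1 = b2 = 1}; log-normal
#' residual variances \code{sigma^2 ~ InvGamma(1, 0.1)}.  The number of
#' latent factors is fixed (default 5); the shrinkage prior drives surplus
#' factors towards zero.
#'
#' @param nFactors number of latent factors.
#' @param gammaScale prior SD of the trait-regression coefficients.
#' @param vDf,vScale inverse-Wishart df and scale for the residual covariance
#'   of beta deviations; \code{NA}/\code{NULL} resolve to \code{n_c + 1} and
#'   the identity at fit time.
#' @param nu,a1,b1,a2,b2 multiplicative-gamma shrinkage hyperparameters.
#' @param sigmaShape,sigmaRate inverse-gamma prior on log-normal residual
#'   variances.
#' @return a \linkS4class{JstdmPriors} object.
#' @export
jstdmPriors <- function(nFactors = 5L, gammaScale = 1, vDf = NA_real_,
                        vScale = NULL, nu = 3, a1 = 50, b1 = 1,
                        a2 = 50, b2 = 1, sigmaShape = 1, sigmaRate = 0.1) {
  new("JstdmPriors", nFactors = as.integer(nFactors), gammaScale = gammaScale,
      vDf = vDf, vScale = if (is.null(vScale)) matrix(0, 0, 0) else vScale,
      nu = nu, a1 = a1, b1 = b1, a2 = a2, b2 = b2,
      sigmaShape = sigmaShape, sigmaRate = sigmaRate)
}

setMethod("show", "JstdmPriors", function(object) {
  cat(sprintf("JstdmPriors: %d factor(s); gamma N(0, %.3g^2); nu=%g a1=%g b1=%g a2=%g b2=%g; sigma2 ~ IG(%g, %g)\n",
              object@nFactors, object@gammaScale, object@nu, object@a1,
              object@b1, object@a2, object@b2, object@sigmaShape, object@sigmaRate))
})

# precomputed, chain-invariant quantities the sweep functions consume
.samplerData <- function(design, priors) {
  Y <- design@Y
  mask <- design@mask
  storage.mode(mask) <- "double"
  n <- nrow(Y); p <- ncol(Y)
  X <- design@X; nc <- ncol(X)
  cu <- columnUnits(design@mre)
  isProbit <- cu$family == "bernoulli_probit"
  Ttilde <- design@traitDesign
  q <- ncol(Ttilde)
  XtX <- .maskedCrossprodArray(X, mask)            # nc^2 x p
  list(Y = Y, mask = mask, n = n, p = p, X = X, nc = nc, q = q,
       Ttilde = Ttilde, TtT = crossprod(Ttilde),
       isProbit = isProbit, lnCols = which(!isProbit),
       nObs = colSums(mask), XtX = XtX,
       vDf = if (is.na(priors@vDf)) nc + 1 else priors@vDf,
       vScale = if (length(priors@vScale)) priors@vScale else diag(nc),
       nf = priors@nFactors)
}

# Initial state: ridge-stabilised per-column regressions of the (augmented)
# observed responses on X; small-variance random factors; residual variances
# from the residuals.  Deterministic under a fixed seed.
.initState <- function(dd, priors, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- dd$n; p <- dd$p; nc <- dd$nc; nf <- dd$nf
  Z <- dd$Y
  if (any(dd$isProbit)) {
    pr <- dd$isProbit
    zp <- Z[, pr, drop = FALSE]
    # truncated-normal means at L = 0, sign-consistent with the data
    m0 <- sqrt(2 / pi)
    zp <- ifelse(zp == 1, m0, -m0) * dd$mask[, pr, drop = FALSE]
    Z[, pr] <- zp
  }
  Beta <- matrix(0, nc, p, dimnames = list(colnames(dd$X), colnames(dd$Y)))
  sigma2 <- rep(1, p)
  for (c in seq_len(p)) {
    XtXc <- matrix(dd$XtX[, c], nc, nc)
    b <- crossprod(dd$X, Z[, c] * dd$mask[, c])
    Beta[, c] <- solve(XtXc + 0.01 * diag(nc), b)
    if (!dd$isProbit[c]) {
      r <- (Z[, c] - dd$X %*% Beta[, c]) * dd$mask[, c]
      m <- max(dd$nObs[c], 1)
      sigma2[c] <- max(sum(r^2) / m, 1e-3)
    }
  }
  Gamma <- t(solve(dd$TtT + diag(dd$q), crossprod(dd$Ttilde, t(Beta))))
  list(
    Z = Z, Beta = Beta, Gamma = Gamma,
    V = diag(nc), iV = diag(nc),
    H = matrix(rnorm(n * nf, 0, 0.1), n, nf),
    Lambda = matrix(rnorm(nf * p, 0, 0.1), nf, p),
    sigma2 = sigma2,
    psi = matrix(1, nf, p), delta = rep(1, nf), tau = rep(1, nf)
  )
}

# Albert-Chib truncated-normal augmentation for observed probit cells;
# unobserved cells are untouched.
.updateProbitLatent <- function(state, dd) {
  pr <- which(dd$isProbit)
  if (!length(pr)) return(state)
  L <- dd$X %*% state$Beta[, pr, drop = FALSE] +
    state$H %*% state$Lambda[, pr, drop = FALSE]
  obs <- dd$mask[, pr, drop = FALSE] > 0
  y <- dd$Y[, pr, drop = FALSE]
  z <- state$Z[, pr, drop = FALSE]
  z[obs] <- .rtruncProbit(L[obs], y[obs])
  state$Z[, pr] <- z
  state
}

# moments of the per-column beta full conditional: the textbook Bayesian
# regression posterior with prior N(mu, V) and the residualised response
.betaConditionalMoments <- function(XtXc, Xty, sigma2, iV, mu) {
  P <- XtXc / sigma2 + iV
  U <- tryCatch(chol(P), error = function(e)
    stop("non-positive-definite beta conditional covariance", call. = FALSE))
  b <- Xty / sigma2 + iV %*% mu
  mean <- backsolve(U, forwardsolve(t(U), b))
  list(mean = drop(mean), covariance = chol2inv(U), cholPrecision = U)
}

# joint conjugate block: Gamma | Beta, V -> V | Beta, Gamma -> Beta | rest
.updateBetaGamma <- function(state, dd, priors) {
  nc <- dd$nc; q <- dd$q; p <- dd$p
  # Gamma: multivariate-normal full conditional given Beta and the expanded
  # trait design; prior vec(Gamma) ~ N(0, gammaScale^2 I)
  iV <- state$iV
  Pg <- kronecker(dd$TtT, iV) + diag(1 / priors@gammaScale^2, nc * q)
  bg <- as.vector(iV %*% state$Beta %*% dd$Ttilde)
  Ug <- tryCatch(chol(Pg), error = function(e)
    stop("non-positive-definite gamma conditional covariance", call. = FALSE))
  mg <- backsolve(Ug, forwardsolve(t(Ug), bg))
  state$Gamma <- matrix(mg + backsolve(Ug, rnorm(nc * q)), nc, q,
                        dimnames = list(colnames(dd$X), colnames(dd$Ttilde)))

  # V: inverse-Wishart given the beta deviations from the trait-implied means
  Mu <- state$Gamma %*% t(dd$Ttilde)                 # nc x p
  E <- state$Beta - Mu
  S <- dd$vScale + tcrossprod(E)
  W <- rWishart(1, dd$vDf + p, solve(S))[, , 1]
  state$iV <- W
  state$V <- solve(W)

  # Beta: per-column normal full conditionals given the residualised
  # responses, the trait-implied mean and V; missing cells contribute nothing
  R <- (state$Z - state$H %*% state$Lambda) * dd$mask
  XtR <- crossprod(dd$X, R)                          # nc x p
  invs2 <- 1 / state$sigma2
  Parray <- t(dd$XtX) * invs2 +
    matrix(as.vector(state$iV), p, nc * nc, byrow = TRUE)
  Bmat <- t(XtR) * invs2 + t(state$iV %*% Mu)        # p x nc
  draw <- tryCatch(
    .drawMVNBatch(Parray, Bmat, matrix(rnorm(p * nc), p, nc)),
    error = function(e)
      stop("non-positive-definite beta conditional covariance", call. = FALSE))
  state$Beta <- t(draw)
  dimnames(state$Beta) <- list(colnames(dd$X), colnames(dd$Y))
  state
}

# latent factors: site scores, loadings, and the multiplicative-gamma
# shrinkage locals/column multipliers
.updateFactors <- function(state, dd, priors) {
  n <- dd$n; p <- dd$p; nf <- dd$nf
  S <- (state$Z - dd$X %*% state$Beta) * dd$mask     # masked residuals

  # eta rows: prior N(0, I); unit residual variance for probit columns
  invs2 <- 1 / state$sigma2
  Lsig <- state$Lambda * rep(invs2, each = nf)       # nf x p
  Lp <- t(state$Lambda)                              # p x nf
  prods <- matrix(0, p, nf * nf)
  k <- 0L
  for (b in seq_len(nf)) for (a in seq_len(nf)) {
    k <- k + 1L
    prods[, k] <- Lp[, a] * Lp[, b] * invs2
  }
  Parray <- dd$mask %*% prods                        # n x nf^2
  Parray[, (seq_len(nf) - 1L) * nf + seq_len(nf)] <-
    Parray[, (seq_len(nf) - 1L) * nf + seq_len(nf), drop = FALSE] + 1
  Bmat <- S %*% t(Lsig)                              # n x nf
  state$H <- .drawMVNBatch(Parray, Bmat, matrix(rnorm(n * nf), n, nf))

  # loading columns under the shrinkage prior
  HtH <- .maskedCrossprodArray(state$H, dd$mask)     # nf^2 x p
  HtS <- crossprod(state$H, S)                       # nf x p
  Pl <- t(HtH) * invs2                               # p x nf^2 (row c = vec HtH_c / s2_c)
  diagIdx <- (seq_len(nf) - 1L) * nf + seq_len(nf)
  prior <- t(state$psi * state$tau)                  # p x nf
  Pl[, diagIdx] <- Pl[, diagIdx, drop = FALSE] + prior
  Bl <- t(HtS) * invs2                               # p x nf
  state$Lambda <- t(.drawMVNBatch(Pl, Bl, matrix(rnorm(p * nf), p, nf)))

  # local precisions psi and column multipliers delta (ordered shrinkage)
  lam2 <- state$Lambda^2
  state$psi <- matrix(
    rgamma(nf * p, shape = (priors@nu + 1) / 2,
           rate = (priors@nu + state$tau * lam2) / 2),
    nf, p)
  wsum <- rowSums(state$psi * lam2)                  # length nf
  for (h in seq_len(nf)) {
    tauAll <- cumprod(state$delta)
    shape <- (if (h == 1L) priors@a1 else priors@a2) + p * (nf - h + 1L) / 2
    rate <- (if (h == 1L) priors@b1 else priors@b2) +
      0.5 * sum((tauAll[h:nf] / state$delta[h]) * wsum[h:nf])
    state$delta[h] <- rgamma(1, shape = shape, rate = rate)
  }
  state$tau <- cumprod(state$delta)
  state
}

# residual variances of the log-normal columns; probit columns pinned to 1
.updateSigma <- function(state, dd, priors) {
  ln <- dd$lnCols
  if (!length(ln)) return(state)
  R <- (state$Z - dd$X %*% state$Beta - state$H %*% state$Lambda) * dd$mask
  ssq <- colSums(R[, ln, drop = FALSE]^2)
  state$sigma2[ln] <- 1 / rgamma(length(ln),
                                 shape = priors@sigmaShape + dd$nObs[ln] / 2,
                                 rate = priors@sigmaRate + ssq / 2)
  state
}

.sweep <- function(state, dd, priors) {
  state <- .updateProbitLatent(state, dd)
  state <- .updateBetaGamma(state, dd, priors)
  state <- .updateFactors(state, dd, priors)
  .updateSigma(state, dd, priors)
}

#' Run the blocked Gibbs sampler
#'
#' Fits the joint species-trait distribution model by a blocked Gibbs sweep:
#' truncated-normal augmentation of the probit presence-absence cells, the
#' joint conjugate (Gamma, V, Beta) block, the latent factor block (site
#' scores, loadings, multiplicative-gamma shrinkage), and the log-normal
#' residual variances.  Structurally missing cells (abundance and traits
#' where a species is absent) contribute to no likelihood term.  Defaults
#' mirror a typical production run (4 chains of 37,500 iterations, 12,500
#' burn-in, thinning 100, i.e. 250 retained draws per chain); scale down for
#' exploration.
#'
#' @param design a \linkS4class{JstdmDesign}.
#' @param priors a \linkS4class{JstdmPriors} object.
#' @param chains,iterations,burnin,thin MCMC settings; per chain
#'   \code{floor((iterations - burnin)/thin)} states are retained.
#' @param seed master seed; independent per-chain seeds are derived from it
#'   and recorded in the result.
#' @param verbose print progress every \code{verbose} iterations (0 = quiet).
#' @return a \linkS4class{JstdmFit}.
#' @export
runMCMC <- function(design, priors = jstdmPriors(), chains = 4L,
                    iterations = 37500L, burnin = 12500L, thin = 100L,
                    seed = 1L, verbose = 0L) {
  .stopIfNot(burnin < iterations, "burnin must be smaller than iterations")
  .stopIfNot(thin >= 1L, "thin must be >= 1")
  .stopIfNot(chains >= 1L, "at least one chain required")
  dd <- .samplerData(design, priors)
  set.seed(seed)
  chainSeeds <- sample.int(.Machine$integer.max - 1L, chains)
  perChain <- (iterations - burnin) %/% thin
  draws <- vector("list", chains * perChain)
  chainId <- integer(chains * perChain)
  k <- 0L
  for (ch in seq_len(chains)) {
    set.seed(chainSeeds[ch])
    state <- .initState(dd, priors, seed = NULL)
    for (it in seq_len(iterations)) {
      state <- .sweep(state, dd, priors)
      if (!is.finite(sum(state$Beta) + sum(state$Lambda) + sum(state$sigma2)))
        stop(sprintf("non-finite sampler state at chain %d, iteration %d", ch, it),
             call. = FALSE)
      if (it > burnin && (it - burnin) %% thin == 0L) {
        k <- k + 1L
        draws[[k]] <- list(Beta = state$Beta, Gamma = state$Gamma,
                           V = state$V, Lambda = state$Lambda,
                           sigma2 = state$sigma2)
        chainId[k] <- ch
      }
      if (verbose > 0L && it %% verbose == 0L)
        message(sprintf("chain %d: iteration %d/%d", ch, it, iterations))
    }
  }
  new("JstdmFit", draws = draws, chain = chainId, design = design,
      priors = priors,
      settings = list(chains = chains, iterations = iterations,
                      burnin = burnin, thin = thin, seed = seed,
                      chainSeeds = chainSeeds, perChain = perChain))
}

#' @rdname runMCMC
#' @param fit a \linkS4class{JstdmFit}.
#' @export
nDraws <- function(fit) length(fit@draws)

#' @rdname runMCMC
#' @export
posteriorDraws <- function(fit) fit@draws

#' @rdname runMCMC
#' @export
modelDesign <- function(fit) fit@design

setMethod("show", "JstdmFit", function(object) {
  s <- object@settings
  cat(sprintf("JstdmFit: %d draws (%d chain(s) x %d), %d iterations, burn-in %d, thin %d\n",
              length(object@draws), s$chains, s$perChain, s$iterations,
              s$burnin, s$thin))
  cat(sprintf("  design: %d sites x %d column units; %d latent factor(s)\n",
              nrow(object@design@Y), ncol(object@design@Y), object@priors@nFactors))
})

#' Posterior mean of a parameter block
#'
#' @param fit a \linkS4class{JstdmFit}.
#' @param what one of \code{"Beta"}, \code{"Gamma"}, \code{"V"},
#'   \code{"Lambda"}, \code{"sigma2"}.
#' @param scale for \code{"Beta"}: \code{"model"} returns coefficients on the
#'   fitted (centred/scaled) response and covariate scales; \code{"data"}
#'   maps them back to the original log-response / covariate scales.
#' @export
posteriorMean <- function(fit, what = "Beta", scale = c("model", "data")) {
  scale <- match.arg(scale)
  m <- Reduce(`+`, lapply(fit@draws, `[[`, what)) / length(fit@draws)
  if (what == "Beta" && scale == "data") m <- .betaToDataScale(m, fit@design)
  m
}

# map model-scale coefficients back to original response/covariate scales:
# y = yc + ys * (sum_k beta_k (x_k - xc_k)/xs_k + ...)
.betaToDataScale <- function(Beta, design) {
  out <- Beta
  ys <- design@yScale; yc <- design@yCenter
  nc <- nrow(Beta)
  if (nc > 1L) {
    xs <- design@xScale; xc <- design@xCenter
    for (k in 2:nc) out[k, ] <- Beta[k, ] * ys / xs[k - 1L]
    out[1, ] <- yc + ys * (Beta[1, ] - colSums(Beta[-1, , drop = FALSE] * (xc / xs)))
  } else {
    out[1, ] <- yc + ys * Beta[1, ]
  }
  out
}

#' Convergence diagnostics
#'
#' Potential scale reduction factor (PSRF) and effective sample size for the
#' entries of \code{Beta}, \code{Gamma} and the association matrix
#' \code{Omega}, computed across chains via \pkg{coda}.  Factor loadings and
#' scores are excluded by design: their sign and rotation are not identified,
#' so only rotation-invariant functions of them are monitored.
#'
#' @param fit a \linkS4class{JstdmFit} with at least two chains.
#' @param what parameter blocks to monitor.
#' @return a data.frame with columns \code{block}, \code{parameter},
#'   \code{psrf}, \code{ess}.
#' @export
convergenceDiagnostics <- function(fit, what = c("Beta", "Gamma", "Omega")) {
  chains <- unique(fit@chain)
  .stopIfNot(length(chains) >= 2L, "at least two chains are required for diagnostics")
  out <- list()
  for (blk in what) {
    vecs <- lapply(fit@draws, function(d) {
      v <- if (blk == "Omega") {
        om <- crossprod(d$Lambda)
        om[upper.tri(om, diag = TRUE)]
      } else as.vector(d[[blk]])
      v
    })
    M <- do.call(rbind, vecs)
    keep <- apply(M, 2, function(x) sd(x) > 0)
    if (!any(keep)) next
    M <- M[, keep, drop = FALSE]
    ml <- coda::mcmc.list(lapply(chains, function(ch)
      coda::mcmc(M[fit@chain == ch, , drop = FALSE])))
    # Gelman-Rubin statistic from the between/within decomposition; robust to
    # the zero-between-variance limit (identical chains give PSRF ~ 1)
    nIt <- min(table(fit@chain))
    chainMeans <- vapply(ml, colMeans, numeric(ncol(M)))
    chainVars <- vapply(ml, function(x) apply(x, 2, var), numeric(ncol(M)))
    B <- nIt * apply(rbind(chainMeans), 1, var)
    W <- rowMeans(rbind(chainVars))
    psrf <- sqrt(((nIt - 1) / nIt * W + B / nIt) / W)
    ess <- coda::effectiveSize(ml)
    out[[blk]] <- data.frame(block = blk,
                             parameter = paste0(blk, "[", which(keep), "]"),
                             psrf = as.numeric(psrf), ess = as.numeric(ess),
                             row.names = NULL)
  }
  do.call(rbind, out)
}
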