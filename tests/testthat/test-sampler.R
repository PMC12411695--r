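test_that("initial state is deterministic and regression-based", {
  d <- sharedDesign()
  pr <- jstdmPriors(nFactors = 2)
  dd <- jstdm:::.samplerData(d, pr)
  s1 <- jstdm:::.initState(dd, pr, seed = 11)
  s2 <- jstdm:::.initState(dd, pr, seed = 11)
  expect_identical(s1, s2)
  # intercept-only design, lognormal column: initial beta0 ~ column mean
  dn <- jstdmDesign(d@mre, scaleResponses = FALSE)
  ddn <- jstdm:::.samplerData(dn, pr)
  s <- jstdm:::.initState(ddn, pr, seed = 1)
  c1 <- which(columnUnits(dn@mre)$rtype == "ABUC")[1]
  o <- dn@mask[, c1]
  expect_equal(s$Beta[1, c1], mean(dn@Y[o, c1]), tolerance = 1e-2)
  # probit latents initialised sign-consistent with the observations
  paCols <- which(ddn$isProbit)
  expect_true(all(sign(s$Z[, paCols]) == sign(2 * ddn$Y[, paCols] - 1)))
})

test_that("probit augmentation draws match truncated-normal facts", {
  set.seed(21)
  n <- 4000
  # y = 1 at L = 0: mean of the positive-truncated unit normal is sqrt(2/pi)
  z1 <- jstdm:::.rtruncProbit(rep(0, n), rep(1, n))
  expect_true(all(z1 > 0))
  expect_equal(mean(z1), sqrt(2 / pi), tolerance = 0.05)
  # y = 0 at L = 0: always non-positive
  z0 <- jstdm:::.rtruncProbit(rep(0, n), rep(0, n))
  expect_true(all(z0 <= 0))
  # vanishing truncation: far-positive mean with y = 1 stays near the mean
  z <- jstdm:::.rtruncProbit(rep(6, n), rep(1, n))
  expect_equal(mean(z), 6, tolerance = 0.05)
  # the sweep only touches observed PA cells
  d <- sharedDesign()
  pr <- jstdmPriors(nFactors = 2)
  dd <- jstdm:::.samplerData(d, pr)
  st <- jstdm:::.initState(dd, pr, seed = 2)
  st2 <- jstdm:::.updateProbitLatent(st, dd)
  paCols <- which(dd$isProbit)
  obs <- dd$mask[, paCols] > 0
  y <- dd$Y[, paCols]
  expect_true(all((st2$Z[, paCols][obs] > 0) == (y[obs] == 1)))
  lnCols <- which(!dd$isProbit)
  expect_identical(st2$Z[, lnCols], st$Z[, lnCols])
})

test_that("beta full conditional matches the closed-form regression posterior", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 25; nc <- 3
    X <- cbind(1, matrix(rnorm(n * (nc - 1)), n))
    y <- rnorm(n)
    sigma2 <- runif(1, 0.3, 2)
    A <- matrix(rnorm(nc * nc), nc)
    V <- crossprod(A) + diag(nc)
    mu <- rnorm(nc)
    mom <- jstdm:::.betaConditionalMoments(crossprod(X), crossprod(X, y),
                                           sigma2, solve(V), mu)
    # independent closed form
    Sigma <- solve(crossprod(X) / sigma2 + solve(V))
    m <- Sigma %*% (crossprod(X, y) / sigma2 + solve(V) %*% mu)
    expect_equal(mom$mean, drop(m), tolerance = 1e-10)
    expect_equal(mom$covariance, Sigma, tolerance = 1e-10)
  }
})

test_that("columns without observed cells draw beta from the prior conditional", {
  # no-data limit: the full conditional reduces to N(mu, V)
  nc <- 2
  mom <- jstdm:::.betaConditionalMoments(matrix(0, nc, nc), rep(0, nc),
                                         1, diag(nc) / 4, c(1, -2))
  expect_equal(mom$mean, c(1, -2))
  expect_equal(mom$covariance, diag(nc) * 4)
})

test_that("sigma update follows its inverse-gamma full conditional", {
  d <- denseDesign(nSites = 12, nSpecies = 1, scaleResponses = FALSE)
  pr <- jstdmPriors(nFactors = 1)
  dd <- jstdm:::.samplerData(d, pr)
  st <- jstdm:::.initState(dd, pr, seed = 3)
  st$Beta[] <- 0; st$H[] <- 0; st$Lambda[] <- 0
  c1 <- which(columnUnits(d@mre)$rtype == "ABUC")
  ssq <- sum(d@Y[, c1]^2)
  nObs <- dd$nObs[c1]
  set.seed(41)
  draws <- replicate(4000, jstdm:::.updateSigma(st, dd, pr)$sigma2[c1])
  post <- unname((pr@sigmaRate + ssq / 2) / (pr@sigmaShape + nObs / 2 - 1))
  expect_equal(mean(draws), post, tolerance = 4 * sd(draws) / sqrt(4000) / post)
  # probit variances stay pinned at one
  expect_true(all(replicate(5, jstdm:::.updateSigma(st, dd, pr)$sigma2[1]) == 1))
})

test_that("factor score update matches the scalar conjugate formula", {
  d <- denseDesign(nSites = 10, nSpecies = 1, scaleResponses = FALSE)
  pr <- jstdmPriors(nFactors = 1)
  dd <- jstdm:::.samplerData(d, pr)
  st <- jstdm:::.initState(dd, pr, seed = 5)
  st$Beta[] <- 0
  lam <- c(0, 0.9, 0)                     # one loading on the ABUC column
  s2 <- c(1, 0.5, 1)
  set.seed(51)
  hDraws <- replicate(3000, {
    s <- st
    s$Lambda <- matrix(lam, 1)
    s$sigma2 <- s2
    # freeze loadings/shrinkage after the H draw by reading H immediately
    jstdm:::.updateFactors(s, dd, pr)$H[1, 1]
  })
  prec <- 1 + lam[2]^2 / s2[2]
  mExp <- (lam[2] * st$Z[1, 2] / s2[2]) / prec
  expect_equal(mean(hDraws), mExp, tolerance = 4 / sqrt(prec) / sqrt(3000))
  expect_equal(var(hDraws), 1 / prec, tolerance = 0.15 / prec)
  # prior limit: zero loadings give standard-normal scores
  set.seed(52)
  h0 <- replicate(2000, {
    s <- st; s$Lambda <- matrix(0, 1, 3)
    jstdm:::.updateFactors(s, dd, pr)$H[1, 1]
  })
  expect_equal(mean(h0), 0, tolerance = 0.1)
  expect_equal(var(h0), 1, tolerance = 0.15)
})

test_that("multiplicative-gamma shrinkage orders the column precisions", {
  d <- denseDesign(nSites = 8, nSpecies = 2, scaleResponses = FALSE)
  pr <- jstdmPriors(nFactors = 3)
  dd <- jstdm:::.samplerData(d, pr)
  st <- jstdm:::.initState(dd, pr, seed = 6)
  set.seed(61)
  taus <- replicate(300, jstdm:::.updateFactors(st, dd, pr)$tau)
  mt <- rowMeans(taus)
  expect_true(all(diff(mt) > 0))          # later factors are shrunk harder
})

test_that("runMCMC bookkeeping, determinism and conjugate location", {
  d <- sharedDesign()
  pr <- jstdmPriors(nFactors = 2)
  f1 <- runMCMC(d, pr, chains = 2, iterations = 30, burnin = 10, thin = 4, seed = 3)
  f2 <- runMCMC(d, pr, chains = 2, iterations = 30, burnin = 10, thin = 4, seed = 3)
  expect_identical(f1@draws, f2@draws)
  expect_equal(length(f1@draws), 2 * ((30 - 10) %/% 4))
  expect_equal(unname(table(f1@chain)), c(5L, 5L), ignore_attr = TRUE)
  # thin 1, burn 0 retains every state
  f3 <- runMCMC(d, pr, chains = 1, iterations = 8, burnin = 0, thin = 1, seed = 3)
  expect_equal(length(f3@draws), 8L)
  expect_error(runMCMC(d, pr, iterations = 10, burnin = 10), "burnin")
  # intercept-only model: posterior mean of the data-scale intercept of a
  # well-observed lognormal column sits at the column mean
  dn <- jstdmDesign(sharedCommunity()$abundance |> assembleMultiresponse(
    traitTables = sharedCommunity()$traits))
  fit <- runMCMC(dn, jstdmPriors(nFactors = 1), chains = 1,
                 iterations = 400, burnin = 200, thin = 2, seed = 9)
  cu <- columnUnits(dn@mre)
  c1 <- which(cu$rtype == "ABUC")[which.max(colSums(dn@mask[, cu$rtype == "ABUC"]))]
  pm <- posteriorMean(fit, "Beta", scale = "data")
  vals <- responseValues(dn@mre)
  target <- mean(vals[dn@mask[, c1], c1])
  expect_equal(pm[1, c1], target, tolerance = 3 * sd(vals[dn@mask[, c1], c1]) /
                 sqrt(sum(dn@mask[, c1])))
})

test_that("masked cells never influence the chain", {
  com <- tinyCommunity(seed = 13, nSites = 30, nSpecies = 3)
  m1 <- assembleMultiresponse(com$abundance, com$traits)
  m2 <- m1
  # poison every unobserved cell with garbage; the mask is unchanged
  v <- SummarizedExperiment::assay(m2, "values")
  v[!SummarizedExperiment::assay(m2, "observed")] <- 999
  SummarizedExperiment::assay(m2, "values") <- v
  d1 <- jstdmDesign(m1, covariates = com$covariates, speciesTraits = "derived")
  d2 <- jstdmDesign(m2, covariates = com$covariates, speciesTraits = "derived")
  pr <- jstdmPriors(nFactors = 2)
  f1 <- runMCMC(d1, pr, chains = 1, iterations = 20, burnin = 5, thin = 1, seed = 17)
  f2 <- runMCMC(d2, pr, chains = 1, iterations = 20, burnin = 5, thin = 1, seed = 17)
  expect_identical(f1@draws, f2@draws)
})

test_that("convergence diagnostics flag divergent chains and accept identical ones", {
  d <- denseDesign(nSites = 6, nSpecies = 1, scaleResponses = FALSE)
  set.seed(71)
  mkDraw <- function(shift = 0) list(
    Beta = matrix(rnorm(3, shift), 1, 3),
    Gamma = matrix(0, 1, 3), V = diag(1),
    Lambda = matrix(rnorm(3, shift, 0.5), 1, 3), sigma2 = rep(1, 3))
  good <- c(replicate(200, mkDraw(), simplify = FALSE),
            replicate(200, mkDraw(), simplify = FALSE))
  fitG <- stubFit(d, good, nFactors = 1)
  fitG@chain <- rep(1:2, each = 200)
  dg <- convergenceDiagnostics(fitG, what = "Beta")
  expect_true(all(dg$psrf > 0.98 & dg$psrf < 1.05))
  # identical chains: PSRF ~ 1
  same <- replicate(100, mkDraw(), simplify = FALSE)
  fitS <- stubFit(d, c(same, same), nFactors = 1)
  fitS@chain <- rep(1:2, each = 100)
  dgS <- convergenceDiagnostics(fitS, what = "Beta")
  expect_equal(dgS$psrf, rep(1, nrow(dgS)), tolerance = 0.02)
  # one divergent chain is flagged
  bad <- c(replicate(200, mkDraw(0), simplify = FALSE),
           replicate(200, mkDraw(3), simplify = FALSE))
  fitB <- stubFit(d, bad, nFactors = 1)
  fitB@chain <- rep(1:2, each = 200)
  dgB <- convergenceDiagnostics(fitB, what = "Beta")
  expect_true(all(dgB$psrf > 1.1))
  # a single chain cannot be diagnosed
  expect_error(convergenceDiagnostics(stubFit(d, same, nFactors = 1)),
               "two chains")
})
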