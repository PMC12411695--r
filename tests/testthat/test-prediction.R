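test_that("linear predictor equals the elementwise double sum", {
  set.seed(12)
  n <- 5; nc <- 3; nf <- 2; p <- 4
  draw <- list(Beta = matrix(rnorm(nc * p), nc, p),
               Lambda = matrix(rnorm(nf * p), nf, p))
  X <- cbind(1, matrix(rnorm(n * (nc - 1)), n))
  H <- matrix(rnorm(n * nf), n, nf)
  L <- linearPredictor(draw, X, H)
  brute <- matrix(0, n, p)
  for (i in 1:n) for (c in 1:p) {
    for (k in 1:nc) brute[i, c] <- brute[i, c] + X[i, k] * draw$Beta[k, c]
    for (k in 1:nf) brute[i, c] <- brute[i, c] + H[i, k] * draw$Lambda[k, c]
  }
  expect_equal(L, brute)
  expect_equal(linearPredictor(draw, X, matrix(0, n, nf)), X %*% draw$Beta)
  expect_error(linearPredictor(draw, X[, 1:2], H), "width")
  expect_error(linearPredictor(draw, X, H[, 1, drop = FALSE]), "width")
})

test_that("marginal prediction maps the probit and log-normal scales correctly", {
  d <- denseDesign(nSites = 3, nSpecies = 1, scaleResponses = FALSE)
  # flat model: PA probability is exactly Phi(0) = 1/2
  flat <- stubFit(d, list(list(Lambda = matrix(0, 1, 3))), nFactors = 1)
  pm <- predictMarginal(flat, seed = 1)
  expect_equal(unname(pm$mean[, "PA:sp1"]), rep(0.5, 3))
  # probit intercept 1.6449 gives occurrence probability 0.95
  B <- matrix(0, 1, 3); B[1, 1] <- 1.6449
  shifted <- stubFit(d, list(list(Beta = B, Lambda = matrix(0, 1, 3))),
                     nFactors = 1)
  pm2 <- predictMarginal(shifted, seed = 1)
  expect_equal(unname(pm2$mean[, "PA:sp1"]), rep(0.95, 3), tolerance = 1e-4)
  # median back-transform is exactly exp(L); log mode returns L itself
  B2 <- matrix(0, 1, 3); B2[1, 2] <- 0.7
  fitB <- stubFit(d, list(list(Beta = B2, Lambda = matrix(0, 1, 3))),
                  nFactors = 1)
  expect_equal(unname(predictMarginal(fitB)$mean[, 2]), rep(exp(0.7), 3))
  expect_equal(unname(predictMarginal(fitB, backTransform = "log")$mean[, 2]),
               rep(0.7, 3))
  # mean back-transform adds half the residual variance
  fitC <- stubFit(d, list(list(Beta = B2, Lambda = matrix(0, 1, 3),
                               sigma2 = c(1, 0.5, 1))), nFactors = 1)
  expect_equal(unname(predictMarginal(fitC, backTransform = "mean")$mean[, 2]),
               rep(exp(0.7 + 0.25), 3))
})

test_that("conditioning with zero cross-loadings reduces to marginal prediction", {
  d <- denseDesign(nSites = 3, nSpecies = 1, scaleResponses = FALSE)
  fit <- stubFit(d, list(list(Lambda = matrix(0, 1, 3),
                              Beta = matrix(c(0, 0.4, -0.2), 1, 3))),
                 nFactors = 1)
  pm <- predictMarginal(fit, seed = 2)
  pc <- predictConditional(fit, condition = c("ABUC:sp1" = 2), seed = 2,
                           nSweeps = 5, nDiscard = 1)
  expect_equal(pc$mean, pm$mean)
  # conditioning on everything leaves nothing to update against
  expect_error(predictConditional(fit,
    condition = c("PA:sp1" = 1, "ABUC:sp1" = 2, "T1:sp1" = 1),
    seed = 1), "nothing to predict")
  expect_error(predictConditional(fit, condition = c("PA:sp9" = 1)), "unknown")
  expect_error(predictConditional(fit, condition = c("PA:sp1" = 0.4)), "0 or 1")
})

test_that("conditional predictive means match the Gaussian conditioning oracle", {
  d <- denseDesign(nSites = 3, nSpecies = 1, scaleResponses = FALSE)
  l1 <- 0.8; l2 <- 0.6; s1 <- 0.36; s2 <- 0.25
  fit <- stubFit(d, list(list(Lambda = matrix(c(0, l1, l2), 1, 3),
                              sigma2 = c(1, s1, s2))), nFactors = 1)
  y1 <- c(-1, 0, 2)
  C <- matrix(NA_real_, 3, 3, dimnames = list(NULL, colnames(d@Y)))
  C[, "ABUC:sp1"] <- y1
  nSweeps <- 4000
  pr <- predictConditional(fit, condition = C, conditionScale = "model",
                           nSweeps = nSweeps, nDiscard = 50, seed = 4,
                           backTransform = "log")
  closed <- l2 * l1 * y1 / (l1^2 + s1)
  condVar <- 1 / (1 + l1^2 / s1)
  mcse <- l2 * sqrt(condVar) / sqrt(nSweeps)
  expect_true(all(abs(pr$mean[, "T1:sp1"] - closed) < 3 * mcse + 1e-6))
  # conditioning on a larger abundance raises the predicted trait when the
  # shared loading is positive
  expect_true(pr$mean[3, "T1:sp1"] > pr$mean[1, "T1:sp1"])
})

test_that("scenario prediction composes covariate overrides and conditioning", {
  fit <- sharedFit()
  d <- fit@design
  # empty scenario equals marginal prediction at the reference sites
  empty <- scenarioPredict(fit, jstdmScenario(), seed = 5, nSweeps = 2,
                           nDiscard = 1)
  pm <- predictMarginal(fit, seed = 5)
  cuPA <- columnUnits(d@mre)$rtype == "PA"
  expect_equal(unname(empty$probabilities), unname(pm$mean[, cuPA]))
  # covariate-only scenario equals marginal prediction at the modified X
  sc <- jstdmScenario(covariates = list(env1 = "high"))
  res <- scenarioPredict(fit, sc, seed = 6, nSweeps = 2, nDiscard = 1)
  covMod <- d@covariates
  covMod$env1 <- quantile(covMod$env1, 0.90)
  pm2 <- predictMarginal(fit, newdata = covMod, seed = 6)
  expect_equal(unname(res$probabilities), unname(pm2$mean[, cuPA]))
  # the focal species is excluded from the richness summary
  scF <- jstdmScenario(condition = list("PA:sp01" = 1))
  resF <- scenarioPredict(fit, scF, seed = 7, nSweeps = 5, nDiscard = 2)
  expect_false("sp01" %in% colnames(resF$probabilities))
  expect_true(all(resF$siteRichness <= ncol(resF$probabilities)))
  expect_error(scenarioPredict(fit, jstdmScenario(covariates = list(bogus = 1))),
               "unknown covariate")
})

test_that("focal presence lowers richness under negative associations", {
  # focal PA shares a factor with the other species' PA with opposite sign
  set.seed(31)
  n <- 40
  ab <- matrix(exp(rnorm(n * 4)), n, 4,
               dimnames = list(sprintf("s%02d", 1:n), paste0("sp", 1:4)))
  ab[sample(length(ab), 30)] <- 0
  m <- assembleMultiresponse(ab)
  d <- jstdmDesign(m)
  L <- matrix(0, 1, 8)
  L[1, 1] <- 1.5                            # focal PA loads +
  L[1, 2:4] <- -1.5                         # others load -
  fit <- stubFit(d, replicate(50, list(Lambda = L), simplify = FALSE),
                 nFactors = 1)
  rich1 <- scenarioPredict(fit, jstdmScenario(condition = list("PA:sp1" = 1)),
                           seed = 8, nSweeps = 20, nDiscard = 5)$richness["mean"]
  rich0 <- scenarioPredict(fit, jstdmScenario(condition = list("PA:sp1" = 0)),
                           seed = 8, nSweeps = 20, nDiscard = 5)$richness["mean"]
  expect_lt(rich1, rich0)
})

test_that("expected richness sums occurrence probabilities", {
  expect_equal(unname(expectedRichness(matrix(c(0.5, 0.5), 1, 2))["mean"]), 1)
  expect_equal(unname(expectedRichness(matrix(1, 3, 7))["mean"]), 7)
  set.seed(41)
  P <- matrix(runif(20 * 5), 20, 5)
  r <- expectedRichness(P)
  expect_equal(unname(r["mean"]), mean(rowSums(P)))
  expect_true(r["mean"] <= 5)
  expect_equal(expectedRichness(P[, 5:1]), r)   # ordering invariance
  arr <- array(runif(4 * 3 * 2), c(4, 3, 2))
  rs <- expectedRichness(arr)
  expect_equal(rs$mean, colMeans(apply(arr, c(1, 2), sum)))
  expect_error(expectedRichness(matrix(1.4, 1, 2)), "0, 1")
})

test_that("conditional and marginal predictive draws agree when no information flows", {
  # the conditioned unit carries no loading, so the factor posterior for the
  # new sites equals its prior and the predicted unit keeps its marginal law
  d <- denseDesign(nSites = 1, nSpecies = 1, scaleResponses = FALSE)
  lam <- matrix(c(0, 0, 0.9), 1, 3)        # only the trait loads on the factor
  draws <- replicate(2000, list(Lambda = lam), simplify = FALSE)
  fit <- stubFit(d, draws, nFactors = 1)
  pm <- predictMarginal(fit, seed = 9, backTransform = "log", keepDraws = TRUE)
  pc <- predictConditional(fit, condition = c("ABUC:sp1" = 1), seed = 10,
                           nSweeps = 2, nDiscard = 1, backTransform = "log",
                           keepDraws = TRUE)
  ks <- suppressWarnings(stats::ks.test(pm$draws[, 1, 3], pc$draws[, 1, 3]))
  expect_gt(ks$p.value, 0.01)
})
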