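test_that("hurdle assembly places values and masks where the model expects", {
  ab <- matrix(c(10, 5, 0, 2), 2, 2,
               dimnames = list(c("s1", "s2"), c("spA", "spB")))
  tr <- matrix(c(1.2, 1.5, NA, 0.7), 2, 2, dimnames = dimnames(ab))
  m <- assembleMultiresponse(ab, list(T1 = tr))

  expect_equal(nrow(m), 2 * 3)             # n_species x n_types column units
  vals <- responseValues(m)
  obs <- observedMask(m)
  cu <- columnUnits(m)
  expect_equal(unname(vals[, cu$rtype == "PA"]), cbind(c(1, 1), c(0, 1)))
  expect_equal(vals["s1", "ABUC:spA"], log(10))
  expect_equal(vals["s2", "T1:spB"], log(0.7))
  # ABUC/trait cells unobserved exactly where the species is absent
  expect_false(obs["s1", "ABUC:spB"])
  expect_false(obs["s1", "T1:spB"])
  expect_true(all(obs[, cu$rtype == "PA"]))
  # observed-mask consistency: observed non-PA cell implies PA = 1
  pa <- vals[, cu$rtype == "PA"]
  for (z in c("ABUC", "T1")) {
    idx <- which(cu$rtype == z)
    expect_true(all(pa[obs[, idx]] == 1))
  }
})

test_that("assembly rejects inconsistent inputs and can mask instead", {
  ab <- matrix(c(10, 0), 1, 2, dimnames = list("s1", c("spA", "spB")))
  trBad <- matrix(c(-1, NA), 1, 2, dimnames = dimnames(ab))
  expect_error(assembleMultiresponse(ab, list(T1 = trBad)),
               "non-positive.*spA")
  trIncons <- matrix(c(1.2, 2), 1, 2, dimnames = dimnames(ab))
  expect_error(assembleMultiresponse(ab, list(T1 = trIncons)),
               "observed where abundance is 0")
  expect_warning(
    m <- assembleMultiresponse(ab, list(T1 = trIncons),
                               onInconsistentTrait = "mask"),
    "masking")
  expect_false(observedMask(m)["s1", "T1:spB"])
  trWrong <- matrix(1, 1, 2, dimnames = list("s9", c("spA", "spB")))
  expect_error(assembleMultiresponse(ab, list(T1 = trWrong)), "indexes")
})

test_that("assemble/disassemble round-trips the input tables on observed cells", {
  com <- tinyCommunity(seed = 5, nSites = 30, nSpecies = 4)
  m <- assembleMultiresponse(com$abundance, com$traits)
  back <- disassembleMultiresponse(m)
  expect_equal(back$abundance, com$abundance)
  expect_equal(back$traits$T1, com$traits$T1)
  expect_equal(back$presence, (com$abundance > 0) * 1)
})

test_that("prevalence filter retains species by PA column sums", {
  n <- 40
  ab <- matrix(0, n, 3, dimnames = list(sprintf("s%02d", 1:n),
                                        c("a", "b", "c")))
  ab[1:30, "a"] <- 1; ab[1:25, "b"] <- 1; ab[1:10, "c"] <- 1
  m <- assembleMultiresponse(ab)
  f <- filterByPrevalence(m, 25)
  expect_setequal(speciesNames(f), c("a", "b"))
  expect_equal(speciesNames(filterByPrevalence(m, 0)), speciesNames(m))
  expect_error(filterByPrevalence(m, 35), "removed every species")
  # a species absent everywhere assembles fine and is removed downstream
  ab2 <- cbind(ab, d = 0)
  m2 <- assembleMultiresponse(ab2)
  expect_false("d" %in% speciesNames(filterByPrevalence(m2, 1)))
})

test_that("trait design expansion is block-structured and collapses back", {
  T2 <- matrix(c(1, 1, 0.3, -0.4), 2, 2,
               dimnames = list(c("a", "b"), c("(Intercept)", "t")))
  Tt <- expandTraitDesign(T2, c("PA", "ABUC"))
  expect_equal(dim(Tt), c(4L, 4L))
  hand <- rbind(c(1, 0.3, 0, 0), c(1, -0.4, 0, 0),
                c(0, 0, 1, 0.3), c(0, 0, 1, -0.4))
  expect_equal(unname(Tt), hand)
  # exactly one nonzero block per row; collapse recovers T bit-exactly
  for (z in 1:2) {
    rows <- (z - 1) * 2 + 1:2
    cols <- (z - 1) * 2 + 1:2
    expect_identical(unname(Tt[rows, cols]), unname(T2))
    expect_true(all(Tt[rows, -cols] == 0))
  }
  # single response type: the expansion is the matrix itself
  expect_equal(unname(expandTraitDesign(T2, "PA")), unname(T2))
})

test_that("species-level traits average observed log values", {
  ab <- matrix(c(2, 3, 5, 0, 0, 1), 3, 2,
               dimnames = list(c("s1", "s2", "s3"), c("a", "b")))
  tr <- matrix(c(2, 8, NA, NA, NA, 4), 3, 2, dimnames = dimnames(ab))
  T <- speciesLevelTraits(list(T1 = tr))
  expect_equal(T["a", "T1"], log(4))        # mean(log 2, log 8) = log 4
  expect_equal(T["b", "T1"], log(4))        # single observation
  trNone <- tr; trNone[, "b"] <- NA
  expect_error(speciesLevelTraits(list(T1 = trNone)), "no observed.*b")
  # the experiment-based route agrees with the table route
  m <- assembleMultiresponse(ab, list(T1 = tr))
  expect_equal(speciesLevelTraits(m), T, ignore_attr = TRUE)
})

test_that("design scalings are recorded and invertible", {
  com <- tinyCommunity(seed = 8, nSites = 40, nSpecies = 4)
  d <- tinyDesign(com)
  # covariates standardised, invertibly
  expect_equal(unname(colMeans(d@X[, -1])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(d@X[, -1], 2, sd)), c(1, 1), tolerance = 1e-12)
  rebuilt <- sweep(sweep(d@X[, -1], 2, d@xScale, "*"), 2, d@xCenter, "+")
  expect_equal(unname(rebuilt), unname(as.matrix(com$covariates)))
  # responses: unscaling recovers the raw log values on observed cells
  vals <- responseValues(d@mre)
  for (c in which(columnUnits(d@mre)$family == "lognormal")) {
    o <- d@mask[, c]
    expect_equal(d@Y[o, c] * d@yScale[c] + d@yCenter[c], vals[o, c])
  }
  # unobserved model-scale cells are stored as zero
  expect_true(all(d@Y[!d@mask] == 0))
})

test_that("column ordering is type-major with a stable species-major permutation", {
  com <- tinyCommunity(seed = 3, nSites = 20, nSpecies = 3)
  m <- assembleMultiresponse(com$abundance, com$traits)
  cu <- columnUnits(m)
  expect_equal(cu$rtype, rep(c("PA", "ABUC", "T1"), each = 3))
  perm <- columnOrder(m, "species-major")
  expect_equal(cu$species[perm], rep(speciesNames(m), each = 3))
  expect_identical(columnOrder(m, "type-major"), seq_len(nrow(m)))
})

test_that("null-model and trait-free designs degrade gracefully", {
  com <- tinyCommunity(seed = 4, nSites = 25, nSpecies = 3)
  m <- assembleMultiresponse(com$abundance, com$traits)
  d0 <- jstdmDesign(m)
  expect_equal(ncol(d0@X), 1L)
  expect_equal(ncol(d0@traitMatrix), 1L)
  expect_equal(ncol(d0@traitDesign), nrow(responseTypes("T1")))
  # rank-deficient environmental design is rejected
  bad <- com$covariates
  bad$dup <- bad$env1
  expect_error(jstdmDesign(m, covariates = bad), "rank-deficient")
})
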