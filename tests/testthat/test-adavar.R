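# Brute-force multinomial oracle for the ratio moments: Y only depends on the
# grouped totals (X.u, X.v, rest), so a 3-category multinomial is an exact
# reduction of the 22-category model.
mcRatioMoments <- function(nDraws, n, q1, q2, seed) {
  withSeed(seed, {
    draws <- rmultinom(nDraws, n, c(q1, q2, 1 - q1 - q2))
    y <- draws[1, ] / draws[2, ]
    list(mean = mean(y), sd = sd(y), se = sd(y) / sqrt(nDraws))
  })
}

test_that("the adaptive mean follows its asymptotics and the Monte-Carlo oracle", {
  q1 <- 0.05; q2 <- 0.4
  # n -> Inf: second term vanishes relative to q1/q2
  expect_lt(adavarMean(1e12, q1, q2) / (q1 / q2) - 1, 1e-9)
  # the depth correction is exactly proportional to 1/n
  gap <- function(n) adavarMean(n, q1, q2) - q1 / q2
  expect_equal(gap(2e5), gap(1e5) / 2)

  mc <- mcRatioMoments(2e5, 1e4, q1, q2, seed = 21)
  expect_lt(abs(adavarMean(1e4, q1, q2) - mc$mean), 3 * mc$se)
})

test_that("the adaptive SD scales as 1/sqrt(n) and matches oracle and delta method", {
  q1 <- 0.05; q2 <- 0.4
  expect_equal(adavarSigma(4e5, q1, q2), adavarSigma(1e5, q1, q2) / 2)

  mc <- mcRatioMoments(2e5, 1e4, q1, q2, seed = 22)
  expect_lt(abs(adavarSigma(1e4, q1, q2) / mc$sd - 1), 0.03)

  # independent delta-method derivation from the multinomial covariance:
  # Var(U/V) ~ (EU/EV)^2 (VarU/EU^2 + VarV/EV^2 - 2 Cov/(EU EV)),
  # with VarU = n q1(1-q1), VarV = n q2(1-q2), Cov = -n q1 q2
  withSeed(23, {
    for (i in 1:20) {
      n <- round(runif(1, 1e3, 1e7))
      a <- runif(1, 0.005, 0.1); b <- runif(1, 0.15, 0.6)
      eu <- n * a; ev <- n * b
      varY <- (eu / ev)^2 * (n * a * (1 - a) / eu^2 + n * b * (1 - b) / ev^2 +
                             2 * n * a * b / (eu * ev))
      expect_equal(adavarSigma(n, a, b), sqrt(varY), tolerance = 1e-12)
    }
  })
})

test_that("autosome proportions are estimated depth-independently and sum to one", {
  m <- rbind(c(10, 10, rep(10, 20)), c(30, 30, rep(30, 20)))
  p <- estimateProportions(ChromCountSet(m))
  expect_equal(p, rep(1 / 22, 22), ignore_attr = TRUE)  # scaled copies: uniform

  two <- ChromCountSet(rbind(1:22, (1:22) * 5))
  expect_equal(estimateProportions(two), (1:22) / sum(1:22),
               ignore_attr = TRUE)
  expect_equal(sum(estimateProportions(two)), 1, tolerance = 1e-12)

  pStar <- hg19P()
  cohort <- euploidCohort(200, 3e6, cnvSd = 0, seed = 51)
  pHat <- estimateProportions(cohort)
  se <- sqrt(pStar * (1 - pStar) / 3e6 / 200)
  expect_true(all(abs(pHat - pStar) <= 5 * se))

  bad <- ChromCountSet(rbind(rep(1, 22), rep(0, 22)))
  expect_error(estimateProportions(bad), "zero total")
})

test_that("deviation profiles match multinomial theory when no jitter is injected", {
  train <- euploidCohort(500, 2e6, cnvSd = 0, seed = 61)
  sel <- allEligibleSelector()
  grid <- c(2e5, 5e5, 1e6, 2e6)
  prof <- buildDeviationProfile(train, sel, depthGrid = grid, seed = 62,
                                nReplicates = 2L)
  expect_equal(prof@depths, grid)
  expect_true(all(abs(deviationDifferences(prof)) <= 0.1 * prof@theoreticalSd))
  # and the bias constant stays near zero
  expect_lte(estimateBiasConstant(prof),
             0.15 * mean(prof@theoreticalSd))

  # injected per-sample jitter lifts the observed SD above theory
  trainJ <- euploidCohort(500, 2e6, cnvSd = 0.004, seed = 63)
  profJ <- buildDeviationProfile(trainJ, sel, depthGrid = grid, seed = 64,
                                 nReplicates = 2L)
  expect_true(all(deviationDifferences(profJ) > 0))
  expect_gt(estimateBiasConstant(profJ), 0)

  one <- buildDeviationProfile(train, sel, depthGrid = 1e6, seed = 65)
  expect_length(one@depths, 1)
  expect_true(is.finite(estimateBiasConstant(one)))

  expect_error(
    buildDeviationProfile(train, sel, depthGrid = c(1e6, 4e6), seed = 66),
    "exceeds total")
})

test_that("the bias constant is the floored mean of the deviation differences", {
  prof <- new("DeviationProfile", depths = c(1e6, 2e6, 4e6),
              observedSd = c(3e-4, 2.2e-4, 1.6e-4) + 5e-6,
              theoreticalSd = c(3e-4, 2.2e-4, 1.6e-4),
              nSamples = 10L, nReplicates = 1L)
  expect_equal(estimateBiasConstant(prof), 5e-6)

  neg <- new("DeviationProfile", depths = c(1e6, 2e6),
             observedSd = c(2.9e-4, 2.1e-4),
             theoreticalSd = c(3e-4, 2.2e-4),
             nSamples = 10L, nReplicates = 1L)
  expect_message(cHat <- estimateBiasConstant(neg), "flooring")
  expect_equal(cHat, 0)
})

test_that("SD combination supports linear and quadrature modes", {
  expect_equal(combineSigma(2.5, 0, "linear"), 2.5)
  expect_equal(combineSigma(2.5, 0, "quadrature"), 2.5)
  expect_equal(combineSigma(3, 4, "linear"), 7)
  expect_equal(combineSigma(3, 4, "quadrature"), 5)
  withSeed(9, {
    s <- runif(20, 0.1, 2); cc <- runif(20, 0, 2)
    q <- combineSigma(s, cc, "quadrature")
    expect_true(all(q >= pmax(s, cc) & q <= s + cc + 1e-15))
  })
})

test_that("adaptive training is deterministic and validates its inputs", {
  train <- euploidCohort(60, 1e6, seed = 71)
  sel <- allEligibleSelector()
  m1 <- adavarTrain(train, sel, seed = 72)
  m2 <- adavarTrain(train, sel, seed = 72)
  expect_equal(m1@p, m2@p)
  expect_equal(m1@c, m2@c)
  expect_equal(m1@q1, sum(m1@p * sel@u))
  expect_equal(m1@q2, sum(m1@p * sel@v))
  expect_true(m1@q1 > 0 && m1@q2 > m1@q1 && m1@q1 + m1@q2 <= 1)
  expect_error(adavarTrain(ChromCountSet(matrix(0, 0, 22)), sel, seed = 1),
               "empty training set")
})

test_that("trained models serialize to JSON and back without loss", {
  withr::local_dir(withr::local_tempdir())
  train <- euploidCohort(60, 1e6, seed = 81)
  sel <- ReferenceSelector(21, c(1, 4, 8, 10, 19, 20))
  am <- adavarTrain(train, sel, seed = 82)
  writeModel(am, "ada.json")
  am2 <- readModel("ada.json")
  expect_equal(am2@p, am@p)
  expect_equal(am2@q1, am@q1)
  expect_equal(am2@c, am@c)
  expect_equal(referenceChroms(am2@selector), referenceChroms(sel))

  fm <- fixvarTrain(train, sel)
  writeModel(fm, "fix.json")
  fm2 <- readModel("fix.json")
  expect_equal(fm2@muFix, fm@muFix)
  expect_equal(fm2@sigmaFix, fm@sigmaFix)

  test <- euploidCohort(5, 1e6, seed = 83)
  expect_equal(adavarZscore(test, am2)$z, adavarZscore(test, am)$z)
  expect_equal(fixvarZscore(test, fm2)$z, fixvarZscore(test, fm)$z)
})

test_that("adaptive z-scores are exact at the model mean and scale with depth", {
  p <- hg19P()
  sel <- ReferenceSelector(21, c(1, 4, 8, 10, 19, 20))
  q1 <- sum(p * sel@u); q2 <- sum(p * sel@v)
  model <- new("AdavarModel", selector = sel, p = p, q1 = q1, q2 = q2,
               c = 0, combineMode = "linear", depthGrid = 1e6,
               nTrain = 10L)

  # counts engineered so that Y equals the model mean at the sample's own n
  refIdx <- referenceChroms(sel)
  x <- p * 2e6
  for (i in 1:5) {  # fixed point: target depends on n depends on target
    n <- sum(x)
    x[21] <- adavarMean(n, q1, q2) * sum(x[refIdx])
  }
  z <- adavarZscore(ChromCountSet(x), model)$z
  expect_lt(abs(z), 1e-8)

  # same ratio at n and 4n: |z| doubles (up to the tiny 1/n mean shift)
  y0 <- q1 / q2 * 1.01
  mk <- function(n) {
    xx <- p * n
    xx[21] <- y0 * sum(xx[refIdx])
    ChromCountSet(xx)
  }
  z1 <- adavarZscore(mk(1e6), model)$z
  z4 <- adavarZscore(mk(4e6), model)$z
  expect_equal(abs(z4) / abs(z1), 2, tolerance = 1e-3)
})

test_that("trisomic z-scores grow with sequencing depth at fixed fetal fraction", {
  sel <- allEligibleSelector()
  train <- euploidCohort(300, 3e6, seed = 91)
  model <- adavarTrain(train, sel, seed = 92, nReplicates = 2L)
  meanZ <- vapply(c(1e6, 3e6, 1e7), function(d) {
    tri <- simulateCohort(simCohortConfig(nSamples = 200, depth = d,
                                          trisomyChrom = 21,
                                          fetalFraction = 0.1,
                                          seed = 93))$counts
    mean(adavarZscore(tri, model)$z)
  }, numeric(1))
  expect_true(all(diff(meanZ) > 0))
  expect_true(all(meanZ > 0))
})
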