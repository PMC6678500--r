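makeBinMatrix <- function(counts, gc = NULL) {
  nb <- nrow(counts)
  bins <- data.frame(chrom = "chr1", start = (seq_len(nb) - 1) * 20000,
                     end = seq_len(nb) * 20000)
  if (is.null(gc)) gc <- seq(0.3, 0.6, length.out = nb)
  BinCountMatrix(counts, bins = bins, gc = gc)
}

test_that("empty-bin filtering masks by nonzero fraction and never edits counts", {
  counts <- cbind(s1 = c(5, 0, 2, 0), s2 = c(3, 0, 0, 1))
  x <- makeBinMatrix(counts)

  strict <- filterEmptyBins(x, 1)           # default: zero anywhere drops
  expect_equal(binRetained(strict), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(SummarizedExperiment::assay(strict, "counts"),
               SummarizedExperiment::assay(x, "counts"))

  half <- filterEmptyBins(x, 0.5)           # nonzero in >= half the samples
  expect_equal(binRetained(half), c(TRUE, FALSE, TRUE, TRUE))

  none <- filterEmptyBins(x, 0)             # keep everything, even all-zero
  expect_equal(binRetained(none), rep(TRUE, 4))

  noZero <- makeBinMatrix(cbind(s1 = 1:4, s2 = 2:5))
  expect_equal(binRetained(filterEmptyBins(noZero, 1)), rep(TRUE, 4))

  allZero <- makeBinMatrix(cbind(s1 = c(0, 0), s2 = c(0, 0)))
  expect_error(filterEmptyBins(allZero, 1), "no informative bins")
})

test_that("GC LOESS recovers flat and linear count-GC relationships", {
  set.seed(42)
  gc <- runif(5000, 0.3, 0.6)

  flat <- rpois(5000, 100)
  fitFlat <- fitGcLoess(flat, gc)
  expect_lt(max(abs(fitFlat@fittedGrid - fitFlat@rcAvg)) / fitFlat@rcAvg, 0.02)

  lineMean <- 100 * (1 + 2 * (gc - 0.4))
  fitLine <- fitGcLoess(rpois(5000, lineMean), gc)
  interior <- fitLine@gcGrid > 0.35 & fitLine@gcGrid < 0.55
  truth <- 100 * (1 + 2 * (fitLine@gcGrid[interior] - 0.4))
  expect_lt(max(abs(fitLine@fittedGrid[interior] - truth) / truth), 0.03)

  expect_error(fitGcLoess(flat, rep(0.5, 5000)), "degenerate GC range")
  expect_error(fitGcLoess(flat[1:30], gc[1:30]), ">= 50")
})

test_that("GC correction arithmetic follows the signed and as-printed forms", {
  # a fit whose curve is linear through (0.3, 90), (0.5, 110): rcAvg = 100
  fit <- new("GcCorrectionFit", span = 0.3, gcGrid = c(0.3, 0.5),
             fittedGrid = c(90, 110), rcAvg = 100)
  # RCloess = RCavg: both modes leave the count unchanged
  expect_equal(applyGcCorrection(77, 0.4, fit, "signed"), 77)
  expect_equal(applyGcCorrection(77, 0.4, fit, "as_printed"), 77)
  # RC = 120, RCloess = 110, RCavg = 100 -> 110 in both modes
  expect_equal(applyGcCorrection(120, 0.5, fit, "signed"), 110)
  expect_equal(applyGcCorrection(120, 0.5, fit, "as_printed"), 110)
  # RC = 90, RCloess = 90, RCavg = 100: signed recentres up, as-printed down
  expect_equal(applyGcCorrection(90, 0.3, fit, "signed"), 100)
  expect_equal(applyGcCorrection(90, 0.3, fit, "as_printed"), 80)
})

pcaFixture <- function(nS = 100, nB = 2000, injectSd = 3e-4, seed = 7) {
  set.seed(seed)
  depth <- 3e6
  p <- rep(1 / nB, nB)
  counts <- vapply(seq_len(nS), function(j) as.numeric(rmultinom(1, depth, p)),
                   numeric(nB))
  w <- rnorm(nB)
  w <- w - mean(w)          # sum-zero keeps proportions summing to 1
  w <- w / sqrt(sum(w^2))
  s <- rnorm(nS, 0, injectSd)
  counts <- counts + depth * outer(w, s)
  x <- makeBinMatrix(counts)
  list(x = x, w = w, s = s)
}

test_that("PCA denoiser recovers and removes an injected rank-1 direction", {
  fx <- pcaFixture()
  den <- fitPcaDenoiser(fx$x, 1)
  expect_gt(abs(sum(den@components[1, ] * fx$w)), 0.95)

  varAlong <- function(bm) {
    counts <- SummarizedExperiment::assay(bm, "counts")
    P <- t(counts) / colSums(counts)
    var(drop(P %*% fx$w))
  }
  before <- varAlong(fx$x)
  cleaned <- applyPcaDenoise(fx$x, den)
  expect_lt(varAlong(cleaned) / before, 0.05)

  # idempotence: applying twice equals applying once
  twice <- applyPcaDenoise(cleaned, den)
  a <- SummarizedExperiment::assay(cleaned, "counts")
  b <- SummarizedExperiment::assay(twice, "counts")
  expect_lt(max(abs(a - b)) / max(abs(a)), 1e-9)
})

test_that("PCA denoiser handles the identity, rank-deficient, and mismatch cases", {
  fx <- pcaFixture(nS = 10, nB = 200)
  den0 <- fitPcaDenoiser(fx$x, 0)
  out <- applyPcaDenoise(fx$x, den0)
  expect_equal(SummarizedExperiment::assay(out, "counts"),
               SummarizedExperiment::assay(fx$x, "counts"), tolerance = 1e-12)

  # a sample equal to binMeans + 3 * component1 collapses onto the means
  den <- fitPcaDenoiser(pcaFixture()$x, 1)
  n0 <- 1e6
  v <- (den@binMeans + 3 * den@components[1, ]) * n0
  xm <- makeBinMatrix(matrix(v, ncol = 1, dimnames = list(NULL, "s")))
  got <- drop(SummarizedExperiment::assay(applyPcaDenoise(xm, den), "counts"))
  expect_equal(got, den@binMeans * n0, tolerance = 1e-8, ignore_attr = TRUE)

  dup <- makeBinMatrix(cbind(a = rep(5, 200), b = rep(5, 200), c = rep(5, 200),
                             d = rep(5, 200)))
  expect_error(fitPcaDenoiser(dup, 1), "rank deficient")
  expect_error(fitPcaDenoiser(fx$x, 9), "training samples")
  expect_error(applyPcaDenoise(fx$x, den), "bin set")
})

test_that("chromosome aggregation conserves mass and respects the mask", {
  bins <- data.frame(chrom = rep(c("chr1", "chr2"), each = 2),
                     start = rep(c(0, 20000), 2), end = rep(c(20000, 40000), 2))
  counts <- cbind(s1 = c(1, 2, 3, 4), s2 = c(10, 20, 30, 40))
  x <- BinCountMatrix(counts, bins = bins, gc = rep(0.4, 4))
  agg <- aggregateToChromosomes(x)
  expect_equal(unname(chromCounts(agg)[, 1:2]),
               rbind(c(3, 7), c(30, 70)))
  expect_equal(unname(sampleTotals(agg)), c(10, 100))  # conservation

  SummarizedExperiment::rowData(x)$retained <- c(TRUE, FALSE, TRUE, TRUE)
  agg2 <- aggregateToChromosomes(x)
  expect_equal(unname(chromCounts(agg2)[, 1]), c(1, 10))  # only chr1 changed
  expect_equal(unname(chromCounts(agg2)[, 2]), c(7, 70))
})

test_that("subsampling is an exact, seeded, without-replacement draw", {
  x <- c(1000, 1000, rep(0, 20))
  sub <- subsampleCounts(x, 1000, seed = 3)
  expect_equal(sum(sub), 1000)
  expect_true(all(sub[3:22] == 0))

  # n_target = n returns the input untouched for any seed
  expect_equal(subsampleCounts(x, 2000, seed = 99), setNames(x, paste0("chr", 1:22)))
  expect_error(subsampleCounts(x, 2001, seed = 1), "exceeds total")
  expect_error(subsampleCounts(x + 0.5, 1000, seed = 1), "integer")

  expect_identical(subsampleCounts(x, 500, seed = 7),
                   subsampleCounts(x, 500, seed = 7))

  set <- ChromCountSet(rbind(x, x * 2))
  subSet <- subsampleCounts(set, 900, seed = 5)
  expect_equal(unname(sampleTotals(subSet)), c(900, 900))
})

test_that("subsampled proportions are unbiased with sub-binomial variance", {
  x <- c(40, 30, 20, 10, rep(0, 18))
  n <- sum(x); k <- 25
  draws <- t(vapply(1:2000, function(s) subsampleCounts(x, k, seed = s),
                    numeric(22)))
  expect_equal(colSums(draws[, 5:22]), rep(0, 18), ignore_attr = TRUE)
  p <- x / n
  # unbiasedness: empirical mean within 4 SE of k * p
  se <- sqrt(k * p[1:4] * (1 - p[1:4]) * (n - k) / (n - 1) / 2000)
  expect_true(all(abs(colMeans(draws[, 1:4]) - k * p[1:4]) < 4 * se))
  # finite-population correction: variance strictly below binomial
  vr <- apply(draws[, 1:4], 2, var)
  expect_true(all(vr < k * p[1:4] * (1 - p[1:4])))
})
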