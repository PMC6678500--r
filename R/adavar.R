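# Adaptive-variance model: multinomial ratio moments, bias constant, scoring.

#' Estimate autosome proportions from euploid controls
#'
#' `p_i` is the unweighted mean over samples of `x_i / n`, so every sample
#' contributes equally regardless of its depth (a pooled-count alternative is
#' available via `weighting = "pooled"`). The result sums to 1.
#'
#' @param train a [ChromCountSet-class] of euploid controls (>= 20 samples
#'   recommended; at least 1 required).
#' @param weighting `"sample"` (default, unweighted mean of per-sample
#'   proportions) or `"pooled"` (proportions of summed counts).
#' @return numeric 22-vector summing to 1.
#' @export
estimateProportions <- function(train, weighting = c("sample", "pooled")) {
  weighting <- match.arg(weighting)
  m <- chromCounts(train)
  if (nrow(m) == 0) stopConfig("empty training set")
  n <- rowSums(m)
  if (any(n == 0)) {
    stopConfig("sample %s has zero total count",
               sampleIds(train)[which(n == 0)[1]])
  }
  p <- if (weighting == "sample") colMeans(m / n) else colSums(m) / sum(m)
  p / sum(p)
}

#' Multinomial ratio moments
#'
#' Second-order approximations of the mean and standard deviation of the
#' chromosome ratio `Y = (X.u)/(X.v)` when `X ~ Multinomial(n, p)`, with
#' `q1 = p.u`, `q2 = p.v`:
#' \deqn{\mu(Y) = q_1/q_2 + q_1/(n q_2^2)}
#' \deqn{\sigma(Y) = \sqrt{ (1/n) (q_1/q_2)^2 (1/q_1 + 1/q_2) }}
#' Both depend on the test sample's own total read count `n`, which is what
#' makes the model depth-adaptive. The `1/n` mean term is negligible at
#' production depths but included for fidelity.
#'
#' @param n total autosomal read count (vectorized).
#' @param q1 target proportion, in (0, 1).
#' @param q2 reference-set proportion, in (0, 1).
#' @return numeric vector of means / SDs.
#' @export
adavarMean <- function(n, q1, q2) {
  stopifnot(all(n >= 1), q1 > 0, q1 < 1, q2 > 0, q2 < 1)
  q1 / q2 + q1 / (n * q2^2)
}

#' @rdname adavarMean
#' @export
adavarSigma <- function(n, q1, q2) {
  stopifnot(all(n >= 1), q1 > 0, q1 < 1, q2 > 0, q2 < 1)
  sqrt((1 / n) * (q1 / q2)^2 * (1 / q1 + 1 / q2))
}

#' Combine the multinomial SD with the bias constant
#'
#' `"linear"` adds the constant on the SD scale (`sigma + c`), consistent
#' with how `c` is estimated (the average of observed-minus-theoretical SD
#' differences); `"quadrature"` combines in variance
#' (`sqrt(sigma^2 + c^2)`). See the methods vignette for why linear is the
#' default.
#'
#' @param sigmaAda theoretical multinomial SD (> 0, vectorized).
#' @param c bias constant (>= 0).
#' @param mode `"linear"` (default) or `"quadrature"`.
#' @return corrected SD(s).
#' @export
combineSigma <- function(sigmaAda, c, mode = c("linear", "quadrature")) {
  mode <- match.arg(mode)
  stopifnot(all(sigmaAda > 0), c >= 0)
  if (mode == "quadrature") sqrt(sigmaAda^2 + c^2) else sigmaAda + c
}

.defaultDepthGrid <- function(nMin, nDepths = 8L) {
  hi <- floor(nMin)
  lo <- min(1e6, hi / 10)
  unique(round(exp(seq(log(lo), log(hi), length.out = nDepths))))
}

#' Observed vs theoretical ratio SD across a depth grid
#'
#' Subsamples every training sample to each depth in `depthGrid` (uniform
#' selection without replacement), computes the chromosome ratio per
#' subsample, and records the empirical SD across samples next to the
#' theoretical multinomial SD at that depth. The differences feed
#' [estimateBiasConstant()]. Subsampling seeds derive deterministically from
#' `(seed, depth index, replicate)`, so profiles are reproducible and strata
#' are independent.
#'
#' @param train a [ChromCountSet-class] with integer counts; every sample
#'   must have at least `max(depthGrid)` reads.
#' @param selector a [ReferenceSelector-class].
#' @param p autosome proportions (default: [estimateProportions()] on
#'   `train`).
#' @param depthGrid increasing vector of target depths (default: 8
#'   log-spaced depths up to the cohort minimum).
#' @param seed integer master seed.
#' @param nReplicates independent subsampling replicates per sample and
#'   depth (default 1); replicates sharpen the SD estimate without new
#'   samples.
#' @return A [DeviationProfile-class].
#' @export
buildDeviationProfile <- function(train, selector, p = NULL,
                                  depthGrid = NULL, seed, nReplicates = 1L) {
  n <- sampleTotals(train)
  if (is.null(depthGrid)) depthGrid <- .defaultDepthGrid(min(n))
  depthGrid <- sort(unique(round(depthGrid)))
  if (any(n < max(depthGrid))) {
    bad <- which(n < max(depthGrid))[1]
    stopConfig("depth %g exceeds total reads (%g) of sample %s",
               max(depthGrid), n[bad], sampleIds(train)[bad])
  }
  if (is.null(p)) p <- estimateProportions(train)
  q1 <- sum(p * selector@u)
  q2 <- sum(p * selector@v)
  obs <- vapply(seq_along(depthGrid), function(di) {
    ys <- unlist(lapply(seq_len(nReplicates), function(r) {
      sub <- subsampleCounts(train, depthGrid[di],
                             seed = .deriveSeed(seed, di, r))
      chromosomeRatio(sub, selector)
    }))
    sd(ys)
  }, numeric(1))
  new("DeviationProfile", depths = as.numeric(depthGrid), observedSd = obs,
      theoreticalSd = adavarSigma(depthGrid, q1, q2),
      nSamples = length(train), nReplicates = as.integer(nReplicates))
}

#' Estimate the depth-independent bias constant
#'
#' `c` is the average of the observed-minus-theoretical SD differences
#' across the depth grid, floored at zero (a negative average means the
#' multinomial SD already over-covers; subtracting variance would be
#' unstable).
#'
#' @param profile a [DeviationProfile-class].
#' @return non-negative scalar `c` (units of the chromosome ratio).
#' @export
estimateBiasConstant <- function(profile) {
  d <- deviationDifferences(profile)
  if (!length(d)) stopConfig("empty deviation profile")
  c0 <- mean(d)
  if (c0 < 0) {
    message(sprintf(
      "negative average deviation difference (%.3g); flooring c at 0", c0))
    c0 <- 0
  }
  c0
}

#' Train the adaptive-variance model
#'
#' Estimates the autosome proportions (hence `q1`, `q2`) and the bias
#' constant `c` from euploid controls. All trained quantities are
#' depth-independent, so a model trained at shallow depth transfers to test
#' samples of any depth.
#'
#' @param train a [ChromCountSet-class] of euploid controls with integer
#'   counts.
#' @param selector a [ReferenceSelector-class].
#' @param depthGrid depth grid for `c` estimation (default: 8 log-spaced
#'   depths from `min(1e6, n_min/10)` to the cohort minimum `n_min`).
#' @param combineMode `"linear"` (default) or `"quadrature"`, see
#'   [combineSigma()].
#' @param seed integer seed for the subsampling inside the deviation
#'   profile.
#' @param nReplicates subsampling replicates per stratum (default 1).
#' @return An [AdavarModel-class].
#' @export
adavarTrain <- function(train, selector, depthGrid = NULL,
                        combineMode = c("linear", "quadrature"), seed,
                        nReplicates = 1L) {
  combineMode <- match.arg(combineMode)
  if (length(train) == 0) stopConfig("empty training set")
  p <- estimateProportions(train)
  profile <- buildDeviationProfile(train, selector, p = p,
                                   depthGrid = depthGrid, seed = seed,
                                   nReplicates = nReplicates)
  new("AdavarModel", selector = selector, p = p,
      q1 = sum(p * selector@u), q2 = sum(p * selector@v),
      c = estimateBiasConstant(profile), combineMode = combineMode,
      depthGrid = profile@depths, nTrain = length(train))
}

#' Score samples with the adaptive-variance model
#'
#' For each sample, the expected mean and SD of the chromosome ratio are
#' recomputed from the sample's own total read count `n`:
#' `z = (Y - mu(n)) / combineSigma(sigma(n), c)`, then grey-zone
#' classification.
#'
#' @param x a [ChromCountSet-class].
#' @param model an [AdavarModel-class].
#' @param lower,upper grey-zone thresholds (see [classifyZ()]).
#' @return data.frame with the same schema as [fixvarZscore()],
#'   `model_tag = "ADAVAR"`.
#' @export
adavarZscore <- function(x, model, lower = 2.5, upper = 4) {
  y <- chromosomeRatio(x, model@selector)
  n <- sampleTotals(x)
  if (any(n <= 0)) stopConfig("sample with non-positive total count")
  mu <- adavarMean(n, model@q1, model@q2)
  sigma <- combineSigma(adavarSigma(n, model@q1, model@q2), model@c,
                        mode = model@combineMode)
  z <- (y - mu) / sigma
  .zcallTable(sampleIds(x), n, y, mu, sigma, z, "ADAVAR", lower, upper)
}
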