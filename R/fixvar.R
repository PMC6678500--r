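# Fixed-variance (NCV) model: reference selection, training, scoring.

#' Chromosome ratio statistic
#'
#' `Y = (X.u) / (X.v)`: the ratio of the target chromosome's count to the
#' summed counts of the reference set. Scale-invariant in the counts.
#'
#' @param x a [ChromCountSet-class] or numeric 22-vector.
#' @param selector a [ReferenceSelector-class].
#' @return numeric vector of per-sample ratios.
#' @export
chromosomeRatio <- function(x, selector) {
  m <- if (is(x, "ChromCountSet")) chromCounts(x) else
    matrix(x, nrow = 1, dimnames = list(NULL, .AUTOSOMES))
  num <- drop(m %*% selector@u)
  den <- drop(m %*% selector@v)
  if (any(den <= 0)) {
    bad <- which(den <= 0)[1]
    stopConfig("zero or negative reference mass for sample %s",
               rownames(m)[bad] %||% bad)
  }
  num / den
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lexicographic comparison of two sorted integer vectors; TRUE if a < b
.lexLess <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# tie-aware comparison: smaller CV wins; near-ties (1e-12 relative) resolved
# by smaller set size, then lexicographically smaller chromosome list
.betterSet <- function(cv, chroms, bestCv, bestChroms) {
  if (!is.finite(cv)) return(FALSE)
  if (!is.finite(bestCv)) return(TRUE)
  tol <- 1e-12 * max(abs(cv), abs(bestCv))
  if (cv < bestCv - tol) return(TRUE)
  if (cv > bestCv + tol) return(FALSE)
  if (length(chroms) != length(bestChroms))
    return(length(chroms) < length(bestChroms))
  .lexLess(chroms, bestChroms)
}

.cvOfY <- function(y) sd(y) / mean(y)

#' Select the reference chromosome set
#'
#' Finds the reference set minimizing the coefficient of variation
#' `CV(Y) = sd(Y)/mean(Y)` of the chromosome ratio across euploid training
#' samples. Eligible chromosomes are all autosomes except the target and the
#' common trisomic autosomes 13, 18 and 21. `"exhaustive"` enumerates all
#' 2^18 - 1 non-empty subsets (vectorized, feasible for desk-scale cohorts);
#' `"greedy"` performs forward selection, stopping when the CV no longer
#' improves. Ties are broken by smaller set size, then lexicographically.
#'
#' @param train a [ChromCountSet-class] of euploid controls (>= 20 samples).
#' @param targetChrom target autosome number (1..22).
#' @param strategy `"exhaustive"` (default) or `"greedy"`.
#' @return A [ReferenceSelector-class].
#' @export
selectReferenceSet <- function(train, targetChrom,
                               strategy = c("exhaustive", "greedy")) {
  strategy <- match.arg(strategy)
  X <- chromCounts(train)
  if (nrow(X) < 20) stopConfig("need >= 20 training samples, got %d", nrow(X))
  elig <- setdiff(1:22, unique(c(as.integer(targetChrom), 13L, 18L, 21L)))
  num <- X[, targetChrom]
  Xe <- X[, elig, drop = FALSE]
  nS <- nrow(X)

  if (strategy == "greedy") {
    current <- integer(0)
    bestCv <- Inf
    repeat {
      cand <- setdiff(seq_along(elig), current)
      if (!length(cand)) break
      cvs <- vapply(cand, function(k) {
        den <- rowSums(Xe[, c(current, k), drop = FALSE])
        .cvOfY(num / den)
      }, numeric(1))
      k <- cand[which.min(cvs)]
      if (min(cvs) < bestCv - 1e-15) {
        current <- sort(c(current, k))
        bestCv <- min(cvs)
      } else break
    }
    if (!length(current)) stopConfig("greedy selection found no reference set")
    return(ReferenceSelector(targetChrom, elig[current]))
  }

  nE <- length(elig)
  total <- 2^nE - 1
  powers <- as.integer(2^(seq_len(nE) - 1))
  bestCv <- Inf
  bestChroms <- integer(0)
  chunk <- 8192L
  for (startId in seq(1, total, by = chunk)) {
    ids <- startId:min(startId + chunk - 1, total)
    B <- vapply(powers, function(b) as.numeric(bitwAnd(ids, b) > 0L),
                numeric(length(ids)))        # ids x nE
    D <- Xe %*% t(B)                          # samples x ids
    Y <- num / D
    mu <- colMeans(Y)
    s <- sqrt(pmax(colSums(Y * Y) - nS * mu^2, 0) / (nS - 1))
    cv <- s / mu
    cvMin <- min(cv)
    candIdx <- which(cv <= cvMin * (1 + 1e-12))
    for (ci in candIdx) {
      chroms <- elig[B[ci, ] > 0]
      if (.betterSet(cv[ci], chroms, bestCv, bestChroms)) {
        bestCv <- cv[ci]
        bestChroms <- chroms
      }
    }
  }
  ReferenceSelector(targetChrom, bestChroms)
}

#' Train the fixed-variance model
#'
#' Estimates `mu` and `sigma` of the chromosome ratio over euploid training
#' samples (sample SD, N-1 denominator). These are applied unchanged to every
#' test sample.
#'
#' @param train a [ChromCountSet-class] of euploid controls (>= 3 samples).
#' @param selector a [ReferenceSelector-class].
#' @return A [FixvarModel-class].
#' @export
fixvarTrain <- function(train, selector) {
  if (length(train) < 3) stopConfig("need >= 3 training samples")
  y <- chromosomeRatio(train, selector)
  s <- sd(y)
  if (s == 0) stopConfig("zero variance of training ratios")
  n <- sampleTotals(train)
  new("FixvarModel", selector = selector, muFix = mean(y), sigmaFix = s,
      trainDepths = c(min = min(n), median = median(n), max = max(n)),
      nTrain = length(train))
}

#' Classify a z-score against the grey zone
#'
#' `z >= upper` (default 4) is an aneuploidy-suspect call; `|z| <= lower`
#' (default 2.5) is euploid (the 2.5 boundary is inclusive-euploid, the 4
#' boundary inclusive-suspect); anything between, on either side, is
#' uninformative. `z <= -upper` is flagged suspect as well (depletion
#' direction, recorded separately by the scoring functions).
#'
#' @param z numeric z-score(s); NaN raises an error.
#' @param lower grey-zone lower bound (default 2.5).
#' @param upper grey-zone upper bound (default 4).
#' @return character vector: `"euploid"`, `"uninformative"`, or
#'   `"aneuploidy_suspect"`.
#' @export
classifyZ <- function(z, lower = 2.5, upper = 4) {
  if (!(lower < upper)) stopConfig("thresholds must satisfy lower < upper")
  if (any(is.nan(z)) || anyNA(z)) stopConfig("z-score is NaN")
  out <- rep("uninformative", length(z))
  out[abs(z) >= upper] <- "aneuploidy_suspect"
  out[z <= lower & z > -lower] <- "euploid"
  out
}

.zcallTable <- function(ids, n, y, mu, sigma, z, tag, lower, upper) {
  data.frame(sample_id = ids, n = n, Y = y, mu = mu, sigma = sigma, z = z,
             call = classifyZ(z, lower, upper),
             direction = ifelse(z <= -upper, "low", "high"),
             model_tag = tag, stringsAsFactors = FALSE, row.names = NULL)
}

#' Score samples with the fixed-variance model
#'
#' `z = (Y - mu)/sigma` with the trained constants, then grey-zone
#' classification.
#'
#' @param x a [ChromCountSet-class].
#' @param model a [FixvarModel-class].
#' @param lower,upper grey-zone thresholds (see [classifyZ()]).
#' @return data.frame: `sample_id`, `n`, `Y`, `mu`, `sigma`, `z`, `call`,
#'   `direction`, `model_tag`.
#' @export
fixvarZscore <- function(x, model, lower = 2.5, upper = 4) {
  y <- chromosomeRatio(x, model@selector)
  z <- (y - model@muFix) / model@sigmaFix
  .zcallTable(sampleIds(x), sampleTotals(x), y, model@muFix, model@sigmaFix,
              z, "FIXVAR", lower, upper)
}
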